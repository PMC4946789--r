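# Delimited-text input (feature matrices and label vectors) and embedding
# output with a JSON parameter sidecar.

#' Read a delimited feature matrix
#'
#' Rows are samples, columns features. A sample-id column (by name or index)
#' and a label column may be designated; remaining columns must be numeric.
#'
#' @param path CSV/TSV file path (delimiter inferred from the extension,
#'   override with `sep`).
#' @param sample_id_col optional column name/index holding sample ids.
#' @param label_col optional column name/index holding labels in
#'   \{+1, -1, 0\}.
#' @param header logical; does the file have a header row.
#' @param sep field separator; default `,` (or tab for `.tsv`/`.txt`).
#' @return list: `X` (numeric matrix with rownames = sample ids), `labels`
#'   (integer vector or NULL).
#' @export
read_feature_matrix <- function(path, sample_id_col = NULL, label_col = NULL,
                                header = TRUE, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = header, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  ids <- NULL
  labels <- NULL
  if (!is.null(sample_id_col)) {
    ids <- as.character(df[[sample_id_col]])
    df[[sample_id_col]] <- NULL
  }
  if (!is.null(label_col)) {
    labels <- check_labels(df[[label_col]], nrow(df))
    df[[label_col]] <- NULL
  }
  X <- as.matrix(df)
  storage.mode(X) <- "double"
  if (!is.null(ids)) rownames(X) <- ids
  list(X = as_feature_matrix(X), labels = labels)
}

#' Read a label vector
#'
#' Single-column file (optionally headed) of values in \{+1, -1, 0\};
#' 0 marks unlabelled samples.
#'
#' @inheritParams read_feature_matrix
#' @param n expected length (validated when given).
#' @return integer label vector.
#' @export
read_labels <- function(path, header = TRUE, n = NULL) {
  v <- utils::read.table(path, header = header)[[1]]
  check_labels(v, if (is.null(n)) length(v) else n)
}

#' Write an embedding with its JSON sidecar
#'
#' Writes `<prefix>.csv` (sample_id, y_1..y_k) and `<prefix>.json` recording
#' sigma, kappa, k, the retained eigenvalues and the normalization mode.
#'
#' @param embedding an `address_embedding`.
#' @param prefix output path prefix.
#' @param sample_ids optional ids; defaults to the embedding rownames.
#' @return invisibly, the CSV path.
#' @export
write_embedding <- function(embedding, prefix, sample_ids = NULL) {
  stopifnot(inherits(embedding, "address_embedding"))
  Y <- embedding$Y
  if (is.null(sample_ids)) {
    sample_ids <- if (!is.null(rownames(Y))) rownames(Y) else seq_len(nrow(Y))
  }
  df <- data.frame(sample_id = sample_ids, Y, check.names = FALSE)
  csv <- paste0(prefix, ".csv")
  utils::write.csv(df, csv, row.names = FALSE)
  jsonlite::write_json(
    list(sigma = embedding$sigma, kappa = embedding$kappa, k = embedding$k,
         eigenvalues = embedding$eigenvalues,
         normalization_mode = embedding$normalization),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(csv)
}
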