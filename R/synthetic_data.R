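# Seeded benchmark generators: the two-class 3D Swiss Roll and
# high-dimensional two-class matrices at omics-like scales, so the whole
# pipeline is testable without external downloads.

#' Two-class Swiss Roll
#'
#' Canonical Swiss-Roll manifold: parameter t drawn uniformly on
#' \[1.5 pi, 4.5 pi\], ambient coordinates (t cos t, h, t sin t) with height
#' h uniform on \[0, 21\], plus isotropic Gaussian noise. The class label is
#' +1 where t exceeds `boundary` (default: the arc midpoint 3 pi), so the
#' two classes are contiguous regions of the roll and ambiguous samples
#' concentrate at the class boundary along the manifold.
#'
#' @param n sample count (>= 8).
#' @param noise_sd isotropic ambient noise standard deviation (>= 0).
#' @param boundary manifold-parameter threshold splitting the classes.
#' @param seed integer seed; the generator is fully determined by
#'   (arguments, seed).
#' @return list: `X` (n x 3 matrix), `labels` (+1/-1), `t` (latent manifold
#'   parameter, for oracle checks), `config`.
#' @export
make_swiss_roll <- function(n = 600L, noise_sd = 0.05, boundary = 3 * pi,
                            seed = 1L) {
  n <- as.integer(n)
  if (n < 8L) stop("n must be >= 8")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  with_seed(seed, {
    t <- stats::runif(n, 1.5 * pi, 4.5 * pi)
    h <- stats::runif(n, 0, 21)
    X <- cbind(t * cos(t), h, t * sin(t)) +
      matrix(stats::rnorm(3L * n, sd = noise_sd), n, 3)
    colnames(X) <- c("x", "h", "z")
    labels <- ifelse(t > boundary, 1L, -1L)
    list(X = X, labels = labels, t = t,
         config = list(n = n, noise_sd = noise_sd, boundary = boundary,
                       seed = seed))
  })
}

#' High-dimensional two-class matrix
#'
#' Emulates the shape of expression/proteomics/texture matrices: two
#' class-conditional Gaussians in a `k_latent`-dimensional latent space,
#' class means `separation` latent units apart, pushed through a seeded
#' random linear map to K ambient features, a tanh nonlinearity, and
#' additive Gaussian noise.
#'
#' @param n sample count.
#' @param K ambient feature count (>= k_latent).
#' @param k_latent latent dimensionality.
#' @param separation Euclidean distance between the class means in latent
#'   units (0 = null world, classes identically distributed).
#' @param noise_sd ambient additive noise standard deviation.
#' @param class_balance proportion of +1 samples.
#' @param seed integer seed.
#' @return list: `X` (n x K), `labels` (+1/-1), `config`.
#' @export
make_highdim_twoclass <- function(n = 100L, K = 2000L, k_latent = 10L,
                                  separation = 6, noise_sd = 1,
                                  class_balance = 0.5, seed = 1L) {
  n <- as.integer(n)
  K <- as.integer(K)
  k_latent <- as.integer(k_latent)
  if (K < k_latent || k_latent < 1L) stop("need K >= k_latent >= 1")
  if (separation < 0) stop("separation must be >= 0")
  with_seed(seed, {
    n_pos <- round(n * class_balance)
    labels <- c(rep(1L, n_pos), rep(-1L, n - n_pos))
    mu <- rep(separation / (2 * sqrt(k_latent)), k_latent)  # ||mu - (-mu)|| = separation
    Z <- matrix(stats::rnorm(n * k_latent), n, k_latent) +
      outer(as.numeric(labels), mu)
    A <- matrix(stats::rnorm(k_latent * K, sd = 1 / sqrt(k_latent)), k_latent, K)
    X <- tanh(Z %*% A) + matrix(stats::rnorm(n * K, sd = noise_sd), n, K)
    list(X = X, labels = labels,
         config = list(n = n, K = K, k_latent = k_latent,
                       separation = separation, noise_sd = noise_sd,
                       class_balance = class_balance, seed = seed))
  })
}

#' Default fixture suite description
#'
#' Swiss Roll at n = 600 plus three high-dimensional matrices emulating the
#' scales of published two-class benchmarks: 100 x 2000 (expression-like),
#' 250 x 5000 (proteomics-like), 2000 x 14 (imaging-texture-like).
#'
#' @return named list of generator descriptions.
#' @export
default_fixture_suite <- function() {
  list(
    swiss_roll = list(type = "swiss_roll",
                      args = list(n = 600L, noise_sd = 0.05, seed = 101L)),
    highdim_expression = list(type = "highdim",
                              args = list(n = 100L, K = 2000L, seed = 102L)),
    highdim_proteomic = list(type = "highdim",
                             args = list(n = 250L, K = 5000L, seed = 103L)),
    highdim_texture = list(type = "highdim",
                           args = list(n = 2000L, K = 14L, k_latent = 5L,
                                       seed = 104L))
  )
}

#' Write the seeded fixture suite
#'
#' Materializes the suite as CSV files (features + label column) with a JSON
#' manifest recording every file's generator, arguments and seed, so
#' regeneration from the manifest reproduces the files byte-for-byte.
#'
#' @param out_dir writable output directory (created if missing).
#' @param suite suite description, default [default_fixture_suite()].
#' @return invisibly, the manifest list.
#' @export
write_fixture_suite <- function(out_dir, suite = default_fixture_suite()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (name in names(suite)) {
    entry <- suite[[name]]
    dat <- if (entry$type == "swiss_roll") {
      do.call(make_swiss_roll, entry$args)
    } else {
      do.call(make_highdim_twoclass, entry$args)
    }
    path <- file.path(out_dir, paste0(name, ".csv"))
    df <- as.data.frame(dat$X)
    df$label <- dat$labels
    utils::write.csv(df, path, row.names = FALSE)
    manifest[[name]] <- c(list(file = basename(path), type = entry$type),
                          dat$config)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
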