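test_that("stratified split balances classes with odd extras in E_tr", {
  truth <- c(rep(1L, 52), rep(-1L, 50))
  sp <- stratified_split(truth, 0.5, seed = 4)
  expect_equal(sum(truth[sp$E_tr] == 1), 26)
  expect_equal(sum(truth[sp$E_tr] == -1), 25)
  expect_setequal(c(sp$E_tr, sp$E_ts), 1:102)
  truth2 <- rep(c(1L, -1L), each = 10)
  sp2 <- stratified_split(truth2, 0.5, seed = 1)
  expect_equal(sum(truth2[sp2$E_tr] == 1), 5)
  expect_equal(sum(truth2[sp2$E_ts] == -1), 5)
  expect_identical(stratified_split(truth, 0.5, 9), stratified_split(truth, 0.5, 9))
  # odd class count: extra to E_tr
  truth3 <- c(rep(1L, 5), rep(-1L, 4))
  sp3 <- stratified_split(truth3, 0.5, 2)
  expect_equal(sum(truth3[sp3$E_tr] == 1), 3)
  expect_equal(sum(truth3[sp3$E_tr] == -1), 2)
})

test_that("learning curves: GE rows constant, schedules meet their targets", {
  # balanced classes (30/30) so the l = 50% grid point exhausts the pool
  dat <- make_swiss_roll(60, noise_sd = 0.05, seed = 9)
  cv <- run_learning_curves(dat$X, dat$labels,
                            label_fractions = c(0.1, 0.3, 0.5),
                            n_runs = 2, kappa = 6, k = 2, seed = 3,
                            rf_trees = 20)
  ge <- cv[cv$method == "GE", ]
  for (r in unique(ge$run)) {
    expect_equal(length(unique(ge$acc[ge$run == r])), 1L)
    expect_equal(length(unique(ge$si[ge$run == r])), 1L)
  }
  expect_equal(sort(unique(cv$n_labels)), c(6L, 18L, 30L))
  # final grid point: pools exhausted, AdDReSS == SSAGE within a run
  for (r in unique(cv$run)) {
    ad <- cv[cv$method == "AdDReSS" & cv$run == r & cv$n_labels == 30L, ]
    ss <- cv[cv$method == "SSAGE" & cv$run == r & cv$n_labels == 30L, ]
    expect_equal(ad$acc, ss$acc, tolerance = 1e-12)
    expect_equal(ad$si, ss$si, tolerance = 1e-12)
  }
})

test_that("identical master seeds reproduce curves byte-for-byte", {
  dat <- make_swiss_roll(30, noise_sd = 0.05, seed = 12)
  f1 <- file.path(tempdir(), "curves_a.csv")
  f2 <- file.path(tempdir(), "curves_b.csv")
  args <- list(dat$X, dat$labels, label_fractions = c(0.2, 0.5),
               n_runs = 2, kappa = 5, k = 2, seed = 77, rf_trees = 10)
  write_curves(do.call(run_learning_curves, args), f1)
  write_curves(do.call(run_learning_curves, args), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("efficiency report aggregates means and pairwise measures", {
  # toy 2-run curves with hand-checkable means
  curves <- data.frame(
    method = rep(c("AdDReSS", "SSAGE", "GE"), each = 4),
    run = rep(c(1L, 2L), times = 6),
    label_fraction = rep(rep(c(0.1, 0.5), each = 2), 3),
    n_labels = rep(rep(c(2L, 10L), each = 2), 3),
    acc = c(0.8, 0.9, 0.95, 0.95,   0.7, 0.8, 0.95, 0.95,   0.6, 0.7, 0.6, 0.7),
    si = rep(0.5, 12))
  rep_ <- efficiency_report(curves, n_total = 20)
  mc <- rep_$mean_curves
  expect_equal(mc$acc[mc$method == "AdDReSS" & mc$n_labels == 2L], 0.85)
  expect_equal(mc$acc[mc$method == "SSAGE" & mc$n_labels == 2L], 0.75)
  expect_equal(rep_$empirical_max, 0.95)
  expect_setequal(names(rep_$efficiency),
                  c("AdDReSS|GE", "SSAGE|GE", "AdDReSS|SSAGE"))
  expect_equal(rep_$mig, 0.10)
  expect_gte(rep_$mqe, 0)
  # single-method input: no pairwise measures
  solo <- efficiency_report(curves[curves$method == "GE", ], n_total = 20)
  expect_length(solo$efficiency, 0)
  expect_null(solo$mig)
  # report regeneration is idempotent
  expect_identical(rep_$mean_curves,
                   efficiency_report(curves, n_total = 20)$mean_curves)
})

test_that("report files round-trip through disk", {
  curves <- data.frame(
    method = rep(c("AdDReSS", "SSAGE"), each = 2),
    run = 1L, label_fraction = rep(c(0.1, 0.5), 2),
    n_labels = rep(c(2L, 10L), 2),
    acc = c(0.8, 0.9, 0.7, 0.9), si = 0.4)
  rp <- efficiency_report(curves, n_total = 20)
  dir <- file.path(tempdir(), "alreport")
  write_report(rp, dir)
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(js$mig, 0.1)
  expect_true(file.exists(file.path(dir, "mean_curves.csv")))
  unlink(dir, recursive = TRUE)
})
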