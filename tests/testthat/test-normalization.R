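test_that("fitted maps send empirical quantiles to the Gaussian target", {
  set.seed(101)
  x <- rexp(20001, rate = 2)
  m <- fit_map(x, "f")
  tr <- function(v) apply_map(m, residue_track("s", seq_along(v), v, "f", "raw"))$score

  # the training median maps to (about) the Gaussian mean 0.5
  expect_equal(tr(median(x)), 0.5, tolerance = 1e-3)
  # the 0.8413 empirical quantile maps to ~ 0.5 + 0.1 * qnorm(0.8413) = 0.6
  q <- as.numeric(quantile(x, 0.8413, type = 1))
  expect_equal(tr(q), 0.5 + 0.1 * qnorm(0.8413), tolerance = 2e-3)
  # below the training minimum: the clip floor value
  expect_equal(tr(min(x) - 10), 0.5 + 0.1 * qnorm(m$epsilon))
  # above the maximum: the ceiling
  expect_equal(tr(max(x) + 10), 0.5 + 0.1 * qnorm(1 - m$epsilon))
  # epsilon default: 1/(2n), floored at 1e-6
  expect_equal(m$epsilon, 1 / (2 * length(x)))
})

test_that("fit_map rejects degenerate input", {
  expect_error(fit_map(runif(99), "f"), "at least 100")
  expect_error(fit_map(c(runif(200), NA), "f"), "finite")
  expect_error(fit_map(c(runif(200), Inf), "f"), "finite")
  expect_error(fit_map(runif(200), "f", epsilon = 0.7), "epsilon")
})

test_that("apply_map is monotone, stays inside (0,1), and checks the feature name", {
  set.seed(55)
  m <- fit_map(rlnorm(5000), "f")
  for (i in 1:20) {
    x <- sort(runif(200, -1, 20))
    tr <- residue_track("s", seq_along(x), x, "f", "raw")
    y <- apply_map(m, tr)$score
    expect_true(all(diff(y) >= 0))
    expect_true(all(y > 0 & y < 1))
  }
  const <- residue_track("s", 1:5, rep(median(sort(rlnorm(5000))), 5), "f", "raw")
  wrong <- residue_track("s", 1:3, c(1, 2, 3), "g", "raw")
  expect_error(apply_map(m, wrong), "does not match")
  expect_silent(apply_map(m, wrong, check_feature = FALSE))
})

test_that("ties share one cumulative value", {
  x <- c(rep(1, 300), rep(2, 500), rep(3, 200))
  m <- fit_map(x, "f")
  v <- apply_map(m, residue_track("s", 1:3, c(1, 2, 3), "f", "raw"))$score
  expect_equal(v[1], 0.5 + 0.1 * qnorm(0.3))
  expect_equal(v[2], 0.5 + 0.1 * qnorm(0.8))
  expect_equal(v[3], 0.5 + 0.1 * qnorm(1 - m$epsilon))
})

test_that("transformed training population matches the N(0.5, 0.01) target", {
  set.seed(2024)
  x <- rexp(1e4)^1.5 # strongly skewed
  m <- fit_map(x, "f")
  y <- apply_map(m, residue_track("s", seq_along(x), x, "f", "raw"))$score
  expect_lt(abs(mean(y) - 0.5), 0.01)
  expect_lt(abs(sd(y) - 0.1), 0.01)
})

test_that("map save/load round trip reproduces outputs bit-identically", {
  set.seed(9)
  m <- fit_map(rgamma(3000, 2), "ipp")
  f <- withr::local_tempfile(fileext = ".map")
  save_map(m, f)
  m2 <- load_map(f)
  expect_equal(m2$feature, "ipp")
  probe <- residue_track("s", 1:500, seq(-1, 12, length.out = 500), "ipp", "raw")
  expect_identical(apply_map(m, probe)$score, apply_map(m2, probe)$score)

  # corrupted files are refused
  lines <- readLines(f)
  writeLines(lines[!startsWith(lines, "epsilon")], f)
  expect_error(load_map(f), "missing field.*epsilon")
  writeLines(c(sub("\t1$", "\t99", lines[1]), lines[-1]), f)
  expect_error(load_map(f), "version")
  m$knots <- m$knots[0, ]
  expect_error(save_map(m, f), "no knots")
})

test_that("map bundles save/load with parameters intact", {
  set.seed(10)
  ds <- small_dataset(n = 10)
  maps <- morf_train(ds$sequences, ds$pssms, ds$disorder, ds$chibi,
    params = mcs_params(root_per_extra = FALSE)
  )
  f <- withr::local_tempfile(fileext = ".bundle")
  save_maps(maps, f)
  back <- load_maps(f)
  expect_named(back$maps, names(maps$maps))
  expect_false(back$params$root_per_extra)
  probe <- residue_track("s", 1:100, seq(0, 3, length.out = 100), "ipp", "raw")
  expect_identical(
    apply_map(maps$maps$ipp, probe)$score,
    apply_map(back$maps$ipp, probe)$score
  )
})
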