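mkn <- function(values, feature, seq_id = "s") {
  residue_track(seq_id, seq_along(values), values, feature, "normalized")
}

test_that("ics is the Bayes combination of the three conservation features", {
  # all three non-informative -> 0.5 before any refit
  out <- compute_ics(mkn(0.5, "ipp"), mkn(0.5, "rwgrmp"), mkn(0.5, "wop"))
  expect_equal(out$score, 0.5)
  expect_equal(out$feature[[1]], "ics")
  # (0.6, 0.6, 0.6): odds 1.5^3 = 3.375 -> 3.375/4.375
  out <- compute_ics(mkn(0.6, "ipp"), mkn(0.6, "rwgrmp"), mkn(0.6, "wop"))
  expect_equal(out$score, 3.375 / 4.375, tolerance = 1e-12)
  # with a map the result is re-normalized into (0,1) normalized space
  set.seed(1)
  m <- fit_map(runif(500), "ics")
  out <- compute_ics(mkn(runif(50, .1, .9), "ipp"), mkn(runif(50, .1, .9), "rwgrmp"),
    mkn(runif(50, .1, .9), "wop"),
    map = m
  )
  expect_equal(track_space(out), "normalized")
})

test_that("mcs worked examples reproduce the two scenario rules exactly", {
  p <- mcs_params()
  # scenario 1, k = 3: center of a 7-window with mean disorder 0.50 and
  # conserved ics {0.5, 0.6, 0.7} -> mean 0.6, no root applied
  ics <- mkn(c(0.5, 0.6, 0.7, 0.2, 0.2, 0.2, 0.2), "ics")
  dis <- mkn(rep(0.5, 7), "disorder")
  expect_equal(compute_mcs(ics, dis, p)$score[4], 0.6)

  # scenario 1, k = 4: conserved ics {0.5, 0.6, 0.7, 0.8}, mean 0.65,
  # one extra conserved residue -> square root applied twice: 0.65^(1/4)
  ics <- mkn(c(0.5, 0.6, 0.7, 0.8, 0.2, 0.2, 0.2), "ics")
  expect_equal(compute_mcs(ics, dis, p)$score[4], 0.65^(1 / 4), tolerance = 1e-12)

  # under the alternative boost reading the same window gives 0.65^(1/4) too
  # (one extra residue), but k = 5 distinguishes the readings
  ics5 <- mkn(c(0.5, 0.6, 0.7, 0.8, 0.9, 0.2, 0.2), "ics")
  m5 <- mean(c(0.5, 0.6, 0.7, 0.8, 0.9))
  expect_equal(compute_mcs(ics5, dis, p)$score[4], m5^(1 / 16), tolerance = 1e-12)
  expect_equal(
    compute_mcs(ics5, dis, mcs_params(root_per_extra = FALSE))$score[4],
    m5^(1 / 4),
    tolerance = 1e-12
  )

  # scenario 2: 15-window mean disorder 0.30, all ics <= 0.60, center ics 0.50
  ics <- mkn(c(rep(0.2, 7), 0.5, rep(0.2, 7)), "ics")
  dis <- mkn(rep(0.3, 15), "disorder")
  expect_equal(compute_mcs(ics, dis, mcs_params())$score[8], 0.5 * 0.3)

  # neither scenario: mcs equals ics (disorder exactly at 0.45 fires nothing)
  ics <- mkn(rep(0.42, 15), "ics")
  dis <- mkn(rep(0.45, 15), "disorder")
  expect_equal(compute_mcs(ics, dis, mcs_params())$score, rep(0.42, 15))
})

test_that("scenario outputs respect their direction of adjustment", {
  set.seed(21)
  p <- mcs_params()
  # structured, unconserved stretch: every residue is scenario 2 and is
  # suppressed below its ics (multiplication by a disorder average < 0.45)
  L <- 80
  ics <- mkn(runif(L, 0.05, 0.55), "ics")
  dis <- mkn(runif(L, 0.05, 0.40), "disorder")
  m <- compute_mcs(ics, dis, p)$score
  expect_true(all(m < ics$score))
  expect_true(all(m > 0 & m < 1))
  # disordered, conserved stretch: scenario 1 with k > 3 boosts the
  # conserved mean toward 1 (roots of values in (0,1) only increase them)
  ics <- mkn(runif(L, 0.5, 0.9), "ics")
  dis <- mkn(runif(L, 0.6, 0.95), "disorder")
  m <- compute_mcs(ics, dis, p)$score
  cons_mean <- zoo::rollapply(ics$score, p$disorder_window, mean, partial = TRUE, align = "center")
  expect_true(all(m >= cons_mean - 1e-12))
})

test_that("mcs agrees exactly with a naive per-residue re-implementation", {
  set.seed(99)
  total <- 0
  while (total < 10000) {
    L <- sample(30:150, 1)
    total <- total + L
    ics <- mkn(runif(L, 0.01, 0.99), "ics")
    # mixture disorder so both scenarios and the default branch occur
    dis <- mkn(pmin(pmax(rbeta(L, 0.6, 0.6), 0.01), 0.99), "disorder")
    for (p in list(mcs_params(), mcs_params(root_per_extra = FALSE))) {
      expect_identical(compute_mcs(ics, dis, p)$score, oracle_mcs(ics$score, dis$score, p))
    }
  }
})

test_that("ics fusion does not lose discrimination relative to its components", {
  set.seed(400)
  ds <- simulate_dataset(sim_spec(n_sequences = 60, seed = 17))
  maps <- list(
    ipp = fit_map(extract_many(ds$pssms, extract_ipp)$score, "ipp"),
    rwgrmp = fit_map(extract_many(ds$pssms, extract_rwgrmp)$score, "rwgrmp"),
    wop = fit_map(extract_many(ds$pssms, extract_wop)$score, "wop")
  )
  ipp_n <- apply_map(maps$ipp, extract_many(ds$pssms, extract_ipp))
  rw_n <- complement_track(apply_map(maps$rwgrmp, extract_many(ds$pssms, extract_rwgrmp)))
  wop_n <- apply_map(maps$wop, extract_many(ds$pssms, extract_wop))
  ics <- compute_ics(ipp_n, rw_n, wop_n)
  auc_of <- function(tr) {
    auc_morf(pool_scores(
      tibble::tibble(seq_id = tr$seq_id, pos = tr$pos, score = tr$score),
      ds$annotations
    ))
  }
  a <- vapply(list(ipp_n, rw_n, wop_n), auc_of, numeric(1))
  expect_gte(auc_of(ics), max(a) - 0.02)
})

test_that("mcs validates its inputs", {
  ics <- mkn(runif(10, .1, .9), "ics")
  dis <- mkn(runif(12, .1, .9), "disorder")
  expect_error(compute_mcs(ics, dis), "lengths must match")
  expect_error(mcs_params(disorder_window = 6), "odd")
  expect_error(mcs_params(disorder_hi = 1.2), "Thresholds")
})
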