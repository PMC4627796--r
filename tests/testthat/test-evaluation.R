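test_that("pooling counts morf and non-morf residues and applies masking", {
  scores <- tibble::tibble(seq_id = "s1", pos = 1:50, score = runif(50))
  ann <- tibble::tibble(seq_id = "s1", start = 10L, end = 19L, label = "morf")
  ls <- pool_scores(scores, ann, "all")
  expect_equal(sum(ls$label == "morf"), 10L)
  expect_equal(sum(ls$label == "non_morf"), 40L)

  # a 40-residue MoRF is masked out entirely in short_only mode
  ann40 <- tibble::tibble(seq_id = "s1", start = 5L, end = 44L, label = "morf")
  ls <- pool_scores(scores, ann40, "short_only")
  expect_equal(sum(ls$label == "morf"), 0L)
  expect_equal(nrow(ls), 10L) # the 40 masked residues are gone altogether
  # and kept (alone) in long_only mode
  ls <- pool_scores(scores, ann40, "long_only")
  expect_equal(sum(ls$label == "morf"), 40L)

  # explicitly masked intervals never contribute
  ann_m <- dplyr::bind_rows(ann, tibble::tibble(seq_id = "s1", start = 30L, end = 34L, label = "masked"))
  expect_equal(nrow(pool_scores(scores, ann_m, "all")), 45L)

  expect_error(
    pool_scores(tibble::tibble(seq_id = "zz", pos = 1L, score = 0.5), ann),
    "not annotated.*zz"
  )
})

test_that("short/long masking partitions the morf residues", {
  for (seed in c(3, 14)) {
    ds <- simulate_dataset(sim_spec(
      n_sequences = 25, morf_mode = "mixed",
      length_range = c(60L, 150L), seed = seed
    ))
    scores <- ds$disorder |> dplyr::select(seq_id, pos, score)
    n_morf <- function(mode) {
      sum(pool_scores(scores, ds$annotations, mode)$label == "morf")
    }
    expect_gt(n_morf("short_only"), 0)
    expect_gt(n_morf("long_only"), 0)
    expect_equal(n_morf("all"), n_morf("short_only") + n_morf("long_only"))
  }
})

test_that("roc_curve handles separation, ties and degenerate input", {
  perfect <- scored_labels(c(0.9, 0.8, 0.2, 0.1), c("morf", "morf", "non_morf", "non_morf"))
  r <- roc_curve(perfect)
  expect_true(any(r$fpr == 0 & r$tpr == 1))
  expect_equal(auc_morf(perfect), 1.0)

  all_same <- scored_labels(rep(0.4, 6), rep(c("morf", "non_morf"), 3))
  r <- roc_curve(all_same)
  expect_equal(nrow(r), 2L)
  expect_equal(r$fpr, c(0, 1))
  expect_equal(r$tpr, c(0, 1))
  expect_equal(auc_morf(all_same), 0.5)

  expect_true(all(diff(r$fpr) >= 0))
  one_class <- scored_labels(runif(5), rep("morf", 5))
  expect_error(roc_curve(one_class), "each class")
})

test_that("auc_morf equals the brute-force Mann-Whitney count", {
  set.seed(1234)
  for (i in 1:200) {
    n_pos <- sample(2:15, 1)
    n_neg <- sample(2:25, 1)
    scores <- round(runif(n_pos + n_neg), sample(1:3, 1)) # force ties
    labels <- c(rep("morf", n_pos), rep("non_morf", n_neg))
    ls <- scored_labels(scores, labels)
    expect_equal(auc_morf(ls), oracle_mw_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("auc_morf agrees with an independent ROC implementation", {
  set.seed(88)
  for (i in 1:25) {
    n <- sample(50:200, 1)
    scores <- round(runif(n), 2)
    labels <- sample(c("morf", "non_morf"), n, replace = TRUE, prob = c(0.2, 0.8))
    if (length(unique(labels)) < 2) next
    ls <- scored_labels(scores, labels)
    ref <- suppressMessages(pROC::auc(pROC::roc(
      response = labels == "morf", predictor = scores,
      direction = "<", quiet = TRUE
    )))
    expect_equal(auc_morf(ls), as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("fpr_at_tpr matches an exhaustive threshold scan", {
  perfect <- scored_labels(c(0.9, 0.8, 0.2, 0.1), c("morf", "morf", "non_morf", "non_morf"))
  expect_equal(fpr_at_tpr(perfect, 0.5)$fpr, 0)
  all_same <- scored_labels(rep(0.4, 6), rep(c("morf", "non_morf"), 3))
  expect_equal(fpr_at_tpr(all_same, 0.2)$fpr, 1)
  expect_error(fpr_at_tpr(perfect, 1.5), "\\(0, 1\\]")

  set.seed(55)
  for (i in 1:100) {
    n <- sample(20:80, 1)
    scores <- round(runif(n), 2)
    labels <- sample(c("morf", "non_morf"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    ls <- scored_labels(scores, labels)
    for (tgt in c(0.2, 0.5, 0.9)) {
      expect_equal(
        fpr_at_tpr(ls, tgt)$fpr,
        oracle_fpr_at_tpr(scores, labels, tgt),
        tolerance = 1e-12
      )
    }
  }
})

test_that("sensitivity/specificity at a cutoff sit on the ROC curve", {
  low <- scored_labels(runif(20, 0.5, 0.9), rep(c("morf", "non_morf"), 10))
  expect_equal(
    unlist(sens_spec_at_cutoff(low, 0.1)[c("sensitivity", "specificity")]),
    c(sensitivity = 1, specificity = 0)
  )
  high <- scored_labels(runif(20, 0.01, 0.4), rep(c("morf", "non_morf"), 10))
  expect_equal(
    unlist(sens_spec_at_cutoff(high, 0.9)[c("sensitivity", "specificity")]),
    c(sensitivity = 0, specificity = 1)
  )
  set.seed(3)
  ls <- scored_labels(round(runif(300), 2), sample(c("morf", "non_morf"), 300, TRUE))
  r <- roc_curve(ls)
  for (cutoff in c(0.2, 0.5, 0.66, 0.9)) {
    ss <- sens_spec_at_cutoff(ls, cutoff)
    hit <- any(abs(r$fpr - (1 - ss$specificity)) < 1e-12 & abs(r$tpr - ss$sensitivity) < 1e-12)
    expect_true(hit)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(500)
  scores <- rexp(400)
  labels <- sample(c("morf", "non_morf"), 400, TRUE)
  base <- auc_morf(scored_labels(scores, labels))
  expect_equal(auc_morf(scored_labels(log1p(scores), labels)), base)
  expect_equal(auc_morf(scored_labels(scores^3, labels)), base)
  m <- fit_map(scores, "f")
  normalized <- apply_map(m, residue_track("s", seq_along(scores), scores, "f", "raw"))$score
  expect_equal(auc_morf(scored_labels(normalized, labels)), base)
})
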