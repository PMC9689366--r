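test_that("dice overlap hits its extremes and matches a set-arithmetic oracle", {
  a <- disk_mask(9, 1)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, disk_mask(6, 1, center = c(5, 5))), 0)
  expect_equal(dice(matrix(0, 4, 4), matrix(0, 4, 4)), 1)
  set.seed(8)
  for (i in 1:20) {
    x <- matrix(rbinom(64, 1, 0.4), 8, 8)
    y <- matrix(rbinom(64, 1, 0.4), 8, 8)
    inter <- sum(x == 1 & y == 1)
    ref <- if (sum(x) + sum(y) == 0) 1 else 2 * inter / (sum(x) + sum(y))
    expect_equal(dice(x, y), ref)
  }
  expect_error(dice(a, a[1:4, 1:4]), "mismatch")
})

test_that("classification metrics recover hand-computed confusions", {
  expect_equal(classification_metrics(c(1, 0, 1), c(1, 0, 1)),
               list(bacc = 1, precision = 1, recall = 1))
  # constant-positive predictor on a balanced set
  expect_equal(classification_metrics(rep(1, 10), rep(0:1, 5))$bacc, 0.5)
  # TP=3 FP=1 TN=4 FN=2
  pred <- c(rep(1, 3), rep(1, 1), rep(0, 4), rep(0, 2))
  true <- c(rep(1, 3), rep(0, 1), rep(0, 4), rep(1, 2))
  m <- classification_metrics(pred, true)
  expect_equal(m$bacc, (0.6 + 0.8) / 2)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  # empty denominators are NA-marked
  expect_true(is.na(classification_metrics(c(0, 0), c(0, 0))$precision))
  expect_error(classification_metrics(1, c(1, 0)), "length")
})

test_that("GED matches its definitional cases and stays 0 on equal sets", {
  a <- disk_mask(9, 1)
  r <- ged(list(a), list(a))
  expect_equal(r$two_cross, 0); expect_equal(r$ged, 0)
  b <- disk_mask(6, 1, center = c(5, 5))
  r2 <- ged(list(a), list(b))
  expect_equal(r2$dged2, 2)
  expect_equal(r2$ged, sqrt(2))
  # same set on both sides: two_cross = 2 * within, GED exactly 0
  set.seed(3)
  S <- lapply(1:4, function(i) random_blob(i + 40))
  rs <- ged(S, S)
  expect_equal(rs$two_cross, 2 * rs$within_pred)
  expect_equal(rs$dged2, 0, tolerance = 1e-12)
})

test_that("GED agrees with the brute-force double loop on random sets", {
  for (i in 1:10) {
    preds <- lapply(seq_len(5), function(k) random_blob(100 + i * 10 + k))
    gts <- lapply(seq_len(3), function(k) random_blob(500 + i * 10 + k))
    r <- ged(preds, gts)
    expect_equal(r$dged2, oracle_ged(preds, gts), tolerance = 1e-12)
  }
})

test_that("bacc_2std encodes the interval confusion definitions", {
  mk <- function(mean, std) {
    structure(list(delta_mean = mean, delta_std = std),
              class = "growth_estimate")
  }
  # TP: gt > 2 and lower bound > 2
  expect_equal(bacc_2std(list(mk(3, 0.25)), 3), 1)       # interval [2.5,3.5]
  # FN: gt > 2 but lower bound <= 2
  expect_equal(bacc_2std(list(mk(3, 0.75)), 3), 0)       # interval [1.5,4.5]
  # TN: gt <= 2 and upper bound <= 2
  expect_equal(bacc_2std(list(mk(0.9, 0.45)), 1), 1)     # interval [0,1.8]
  # FP: gt <= 2 but upper bound > 2
  expect_equal(bacc_2std(list(mk(1.25, 0.625)), 1), 0)   # interval [0,2.5]
  four <- list(mk(3, 0.25), mk(3, 0.75), mk(0.9, 0.45), mk(1.25, 0.625))
  expect_equal(bacc_2std(four, c(3, 3, 1, 1)), 0.5)
})

test_that("the interval criterion is at most as generous as the point one", {
  set.seed(14)
  for (rep in 1:10) {
    ests <- lapply(1:40, function(i) {
      structure(list(delta_mean = rnorm(1, 2, 2.5),
                     delta_std = runif(1, 0.1, 1.5),
                     prob_mean = NA), class = "growth_estimate")
    })
    gt <- rnorm(40, 2, 2.5)
    point <- classification_metrics(
      as.integer(vapply(ests, `[[`, numeric(1), "delta_mean") > 2),
      as.integer(gt > 2))$bacc
    expect_lte(bacc_2std(ests, gt), point + 1e-12)
  }
})

test_that("closest-annotator selection uses Mahalanobis and mean Dice", {
  est <- structure(list(delta_mean = 2.2, delta_std = 1),
                   class = "growth_estimate")
  expect_equal(closest_annotator_growth(est, c(2.0, 5.0)), 1L)
  expect_equal(closest_annotator_growth(est, 5.0), 1L)
  # exact ties break to the lowest index
  est_tie <- structure(list(delta_mean = 2, delta_std = 1),
                       class = "growth_estimate")
  expect_equal(closest_annotator_growth(est_tie, c(1, 3)), 1L)
  # zero spread falls back to absolute difference
  est0 <- structure(list(delta_mean = 4, delta_std = 0),
                    class = "growth_estimate")
  expect_equal(closest_annotator_growth(est0, c(1, 3.8, 10)), 2L)
  samples <- list(disk_mask(8, 1), disk_mask(9, 1))
  gts <- list(disk_mask(14, 1, center = c(8, 8)), disk_mask(8, 1))
  expect_equal(closest_annotator_segmentation(samples, gts), 2L)
  expect_equal(closest_annotator_segmentation(samples, gts[2]), 1L)
  # brute-force mean-Dice table agreement
  set.seed(6)
  ss <- lapply(1:4, function(i) random_blob(i + 900))
  gg <- lapply(1:3, function(i) random_blob(i + 950))
  tab <- vapply(gg, function(gt) {
    mean(vapply(ss, function(s) dice(s, gt), numeric(1)))
  }, numeric(1))
  expect_equal(closest_annotator_segmentation(ss, gg), which.max(tab))
})

test_that("growth-size MAE matches the elementwise oracle", {
  mk <- function(d) structure(list(delta_mean = d), class = "growth_estimate")
  expect_equal(mae_growth(list(mk(2), mk(2)), c(2, 2)), 0)
  expect_equal(mae_growth(list(mk(1), mk(3)), c(2, 2)), 1)
  set.seed(5)
  pred <- rnorm(30); gt <- rnorm(30)
  expect_equal(mae_growth(pred, gt), mean(abs(pred - gt)))
})

test_that("stratified reports count cells and the within-24-month aggregate", {
  co <- tiny_cohort(6, 1, seed = 15)
  recs <- co$records
  right <- lapply(recs, function(r) {
    structure(list(prob_mean = ifelse(r$growth_label == 1, 0.9, 0.1)),
              class = "growth_estimate")
  })
  rep1 <- stratified_report(right, recs)
  expect_true(all(rep1$accuracy[!is.na(rep1$accuracy)] == 1))
  expect_equal(sum(rep1$fraction, na.rm = TRUE), 1)
  expect_equal(rep1$accuracy_within_24mo, 1)
  # single wrong record occupies exactly one cell at accuracy 0
  one <- recs[1]
  wrong <- list(structure(list(prob_mean = 1 - one[[1]]$growth_label),
                          class = "growth_estimate"))
  rep2 <- stratified_report(wrong, one)
  expect_equal(sum(rep2$accuracy == 0, na.rm = TRUE), 1)
  expect_equal(sum(is.na(rep2$accuracy)), 15)
  # known per-cell errors match a hand count
  gsize <- vapply(recs, function(r) r$d1_mm - r$d0_mm, numeric(1))
  flip <- gsize > 2 & gsize <= 5
  mixed <- lapply(seq_along(recs), function(i) {
    lab <- recs[[i]]$growth_label
    if (flip[i]) lab <- 1 - lab
    structure(list(prob_mean = ifelse(lab == 1, 0.9, 0.1)),
              class = "growth_estimate")
  })
  rep3 <- stratified_report(mixed, recs)
  if (any(flip)) expect_true(all(rep3$accuracy[3, ] %in% c(0, NA)))
})

test_that("metric aggregations are permutation invariant", {
  co <- tiny_cohort(5, 2, seed = 16)
  recs <- co$records
  ests <- lapply(recs, function(r) {
    structure(list(delta_mean = rnorm(1, 2, 2), delta_std = runif(1, .2, 1),
                   prob_mean = runif(1)), class = "growth_estimate")
  })
  gt <- vapply(recs, function(r) r$d1_mm - r$d0_mm, numeric(1))
  perm <- sample(length(recs))
  expect_equal(mae_growth(ests, gt), mae_growth(ests[perm], gt[perm]))
  expect_equal(bacc_2std(ests, gt), bacc_2std(ests[perm], gt[perm]))
  pred <- as.integer(vapply(ests, `[[`, numeric(1), "prob_mean") > 0.5)
  truth <- vapply(recs, `[[`, integer(1), "growth_label")
  expect_equal(classification_metrics(pred, truth),
               classification_metrics(pred[perm], truth[perm]))
})
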