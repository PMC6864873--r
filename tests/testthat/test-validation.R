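# brute-force IAP: explicit double loop over all (positive, negative) pairs
oracle_iap <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

test_that("iap handles separation, ties and degenerate labels", {
  expect_identical(iap(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_identical(iap(rep(2, 6), c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)), 0.5)
  expect_equal(iap(c(3, 1, 2, 5, 4), c(TRUE, FALSE, TRUE, FALSE, TRUE)),
               oracle_iap(c(3, 1, 2, 5, 4), c(TRUE, FALSE, TRUE, FALSE, TRUE)))
  expect_error(iap(1:3, c(TRUE, TRUE, TRUE)), "IAP undefined")
})

test_that("iap equals the pairwise-comparison oracle on random instances", {
  set.seed(404)
  for (r in 1:200) {
    n <- sample(2:30, 1L)
    scores <- sample(seq(-1, 1, by = 0.25), n, replace = TRUE)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2L, replace = TRUE))
    expect_equal(iap(scores, labels), oracle_iap(scores, labels))
  }
})

test_that("iap agrees with an established AUC implementation", {
  skip_if_not_installed("pROC")
  set.seed(505)
  for (r in 1:20) {
    n <- sample(10:40, 1L)
    scores <- round(rnorm(n), 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2L, replace = TRUE))
    auc <- as.numeric(pROC::auc(pROC::roc(response = labels,
                                          predictor = scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(iap(scores, labels), auc)
  }
})

test_that("compound-out exclusion sets equal brute-force enumeration", {
  ds <- toy_dataset()
  sets <- ddipass:::.exclusion_sets(ds$pairs)
  for (i in seq_len(nrow(ds$pairs))) {
    members <- c(ds$pairs$drug_a[i], ds$pairs$drug_b[i])
    expected <- which(vapply(seq_len(nrow(ds$pairs)), function(j)
      any(c(ds$pairs$drug_a[j], ds$pairs$drug_b[j]) %in% members), logical(1)))
    expect_identical(sets[[i]], expected)
  }
})

test_that("compound-out scores equal a naive refit oracle on the toy set", {
  ds <- toy_dataset()
  rep <- compound_out_loo(ds)
  evaluated <- do.call(rbind, strsplit(rep$pair_ids, "\t", fixed = TRUE))
  for (r in seq_len(nrow(evaluated))) {
    a <- evaluated[r, 1L]; b <- evaluated[r, 2L]
    drop <- ds$pairs$drug_a %in% c(a, b) | ds$pairs$drug_b %in% c(a, b)
    reduced <- ddi_dataset(ds$drugs, ds$pairs[!drop, ])
    m <- ddipass(reduced)
    pred <- predict(m, data.frame(drug_a = a, drug_b = b))
    expect_equal(rep$scores[r, pred$orca_class], pred$score)
  }
})

test_that("compound-out LOO is deterministic and pair-order invariant", {
  ds <- simulate_ddi_dataset(30, 60, seed = 17)
  r1 <- compound_out_loo(ds)
  r2 <- compound_out_loo(ds)
  expect_identical(r1$iap, r2$iap)
  ds2 <- ds
  set.seed(9)
  ds2$pairs <- ds$pairs[sample.int(nrow(ds$pairs)), ]
  r3 <- compound_out_loo(ds2)
  expect_equal(r1$iap, r3$iap)
  expect_equal(r1$average_iap, r3$average_iap)
})

test_that("randomly permuted labels give chance-level IAP", {
  ds <- simulate_ddi_dataset(200, 600, seed = 23)
  set.seed(1001)
  ds$pairs$orca_class <- sample(ds$pairs$orca_class)
  rep <- compound_out_loo(ds)
  # null sampling band per class: Mann-Whitney variance of AUC under H0 is
  # (npos + nneg + 1) / (12 npos nneg); rare classes get the wide band they
  # statistically deserve
  npos <- tabulate(rep$classes, 5L)
  nneg <- length(rep$classes) - npos
  se <- sqrt((npos + nneg + 1) / (12 * npos * nneg))
  expect_true(all(abs(rep$iap - 0.5) <= pmax(3 * se, 0.05), na.rm = TRUE))
  expect_lt(abs(rep$average_iap - 0.5), 0.1)
})

test_that("k-fold folds are seed-deterministic", {
  ds <- simulate_ddi_dataset(40, 80, seed = 29)
  r1 <- kfold_cv(ds, k = 5, seed = 3)
  r2 <- kfold_cv(ds, k = 5, seed = 3)
  expect_identical(r1$iap, r2$iap)
  r3 <- kfold_cv(ds, k = 5, seed = 4)
  expect_false(identical(r1$iap, r3$iap))   # different split, same ballpark
  expect_true(all(abs(r1$iap - r3$iap) < 0.2, na.rm = TRUE))
})

test_that("k = n reduces k-fold CV to pair-out leave-one-out", {
  ds <- simulate_ddi_dataset(25, 40, seed = 37)
  n <- nrow(ds$pairs)
  rep <- kfold_cv(ds, k = n, seed = 1)
  m <- ddipass(ds)
  # with singleton folds the out-of-fold scores are exactly the model's
  # leave-self-out training scores
  idx <- match(rep$pair_ids, paste(ds$pairs$drug_a, ds$pairs$drug_b, sep = "\t"))
  expect_equal(rep$scores, m$training_scores[idx, ])
})

test_that("validation refuses single-class datasets", {
  drugs <- list(methane = mg_methane(), ethane = mg_ethane(),
                benzene = mg_benzene())
  ds <- ddi_dataset(drugs, data.frame(
    drug_a = c("ethane", "benzene"), drug_b = c("methane", "methane"),
    orca_class = c(3L, 3L)))
  expect_error(compound_out_loo(ds), "IAP undefined")
  expect_error(kfold_cv(ds, k = 2, seed = 1), "IAP undefined")
})

test_that("k-fold tracks compound-out closely on a planted-rule dataset", {
  ds <- simulate_ddi_dataset(200, 600, seed = 41)
  loo <- compound_out_loo(ds)
  kf <- kfold_cv(ds, k = 20, seed = 41)
  expect_true(all(abs(loo$iap - kf$iap) <= 0.05, na.rm = TRUE))
  # pair-out style k-fold is never systematically harder than compound-out
  expect_gte(kf$average_iap, loo$average_iap - 0.02)
})
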