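# Validation protocols: IAP (AUC) scoring, compound-out leave-one-out and
# stratified k-fold cross-validation.
#
# The compound-out protocol is a cold-start test: when a pair (x, y) is
# evaluated, *every* training pair containing x or y is excluded before
# refitting, so the model has never seen either molecule.  Per-class IAP uses
# the raw class score as the ranking statistic (Pa - Pi is a monotone
# transform of it, so the ranking is the same); the reported average is the
# unweighted mean over classes for which IAP is defined.

#' Invariant Accuracy of Prediction (IAP / AUC)
#'
#' Sample estimate of the probability that a randomly chosen positive example
#' scores higher than a randomly chosen negative one, ties counted half --
#' identical to the area under the ROC curve with mid-rank tie handling.
#'
#' @param scores Numeric vector of scores.
#' @param labels Logical vector (or coercible): `TRUE` = positive.
#' @return IAP in \[0, 1\].
#' @export
#' @examples
#' iap(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))  # 1
iap <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels))
    stop("iap: 'scores' and 'labels' must be equal-length and NA-free")
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0L || nneg == 0L)
    stop("IAP undefined: need at least one positive and one negative label")
  r <- rank(scores)   # mid-ranks for ties
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# exclusion set of each pair: indices of all pairs sharing a compound with it
# (including the pair itself)
.exclusion_sets <- function(pairs) {
  a <- pairs$drug_a; b <- pairs$drug_b
  lapply(seq_len(nrow(pairs)), function(i)
    which(a == a[i] | a == b[i] | b == a[i] | b == b[i]))
}

# per-class IAP table from a score matrix (n x 5) and class labels
.per_class_iap <- function(scores, classes) {
  vapply(.ORCA_CLASSES, function(c) {
    lab <- classes == c
    if (!any(lab) || all(lab)) return(NA_real_)
    iap(scores[, c], lab)
  }, numeric(1))
}

.new_cv_report <- function(protocol, scores, classes, pair_ids, dataset,
                           skipped = character(0), seed = NULL, k = NULL) {
  iaps <- .per_class_iap(scores, classes)
  structure(list(protocol = protocol,
                 iap = stats::setNames(iaps, paste0("class", .ORCA_CLASSES)),
                 average_iap = mean(iaps, na.rm = TRUE),
                 n_per_class = tabulate(dataset$pairs$orca_class, 5L),
                 n_evaluated = length(classes),
                 scores = scores, classes = classes, pair_ids = pair_ids,
                 skipped = skipped, seed = seed, k = k),
            class = "ddipass_cv")
}

#' @export
print.ddipass_cv <- function(x, ...) {
  cat(sprintf("DDI severity cross-validation: %s%s\n", x$protocol,
              if (!is.null(x$k)) sprintf(" (k = %d, seed = %s)", x$k,
                                         format(x$seed)) else ""))
  cat(sprintf("  %-8s %6s %8s\n", "class", "N", "IAP"))
  for (c in .ORCA_CLASSES) {
    cat(sprintf("  %-8d %6d %8s\n", c, x$n_per_class[c],
                ifelse(is.na(x$iap[c]), "--", sprintf("%.3f", x$iap[c]))))
  }
  cat(sprintf("  average IAP: %.3f   (%d pairs evaluated%s)\n", x$average_iap,
              x$n_evaluated,
              if (length(x$skipped)) sprintf(", %d skipped", length(x$skipped)) else ""))
  invisible(x)
}

#' @export
plot.ddipass_cv <- function(x, ...) {
  graphics::barplot(x$iap, ylim = c(0, 1), ylab = "IAP",
                    xlab = "ORCA class",
                    names.arg = .ORCA_CLASSES,
                    main = paste("Per-class IAP:", x$protocol), ...)
  graphics::abline(h = 0.5, lty = 2)
  invisible(x)
}

#' Compound-out leave-one-out cross-validation
#'
#' For every labeled pair (x, y), refits the classifier on the dataset with
#' *all* pairs containing x or y removed, then scores (x, y) for the five
#' ORCA classes. Per-class IAP is computed over all evaluated pairs with the
#' raw class score as the ranking statistic. Pairs whose exclusion leaves an
#' untrainable remainder (no pairs, or a single class) are skipped and listed
#' in the report. Deterministic: no randomness is involved.
#'
#' @param dataset A [ddi_dataset()].
#' @param level MNA level (default 2).
#' @param alpha Smoothing weight (default 1).
#' @return Object of class `ddipass_cv`.
#' @export
compound_out_loo <- function(dataset, level = 2L, alpha = 1) {
  stopifnot(inherits(dataset, "ddi_dataset"))
  if (length(unique(dataset$pairs$orca_class)) < 2L)
    stop("IAP undefined: dataset contains a single ORCA class")
  ft <- .featurize_dataset(dataset, as.integer(level))
  n <- length(ft$codes)
  if (n < 2L) stop("compound_out_loo: need at least two pairs")
  V <- length(ft$vocab)
  d_n <- tabulate(unlist(ft$codes, use.names = FALSE), V)
  d_nc <- matrix(0L, nrow = V, ncol = 5L)
  for (c in .ORCA_CLASSES) {
    idx <- unlist(ft$codes[ft$classes == c], use.names = FALSE)
    if (length(idx)) d_nc[, c] <- tabulate(idx, V)
  }
  class_counts <- tabulate(ft$classes, 5L)

  a <- ft$pairs$drug_a; b <- ft$pairs$drug_b
  excl_sets <- .exclusion_sets(ft$pairs)
  scores <- matrix(NA_real_, n, 5L)
  keep <- logical(n)
  for (i in seq_len(n)) {
    excl <- excl_sets[[i]]
    cc <- class_counts - tabulate(ft$classes[excl], 5L)
    n_rem <- n - length(excl)
    if (n_rem < 1L || sum(cc > 0L) < 2L) next    # untrainable remainder
    ki <- ft$codes[[i]]
    dn <- d_n[ki]
    dnc <- d_nc[ki, , drop = FALSE]
    for (q in excl) {
      m <- match(ft$codes[[q]], ki, nomatch = 0L)
      m <- m[m > 0L]
      if (length(m)) {
        dn[m] <- dn[m] - 1L
        cq <- ft$classes[q]
        dnc[m, cq] <- dnc[m, cq] - 1L
      }
    }
    scores[i, ] <- .pass_raw_scores(dn, dnc, cc / n_rem, alpha)
    keep[i] <- TRUE
  }
  .new_cv_report("compound-out LOO",
                 scores[keep, , drop = FALSE], ft$classes[keep],
                 paste(a, b, sep = "\t")[keep], dataset,
                 skipped = paste(a, b, sep = "\t")[!keep])
}

#' Stratified k-fold cross-validation
#'
#' Shuffles the labeled pairs with `seed`, deals them into `k` near-equal
#' folds stratified by ORCA class, fits the classifier on each training
#' complement and scores the held-out fold. Per-class IAP is computed over
#' the pooled out-of-fold scores, so folds that happen to lack a class
#' remain usable. Folds split by *pair*: the same compound may appear on
#' both sides of a split, which makes this protocol easier than
#' [compound_out_loo()].
#'
#' @param dataset A [ddi_dataset()].
#' @param k Number of folds (default 20); `k = nrow(pairs)` reduces to
#'   pair-out LOO.
#' @param seed Integer seed driving the fold assignment (required).
#' @param level MNA level (default 2).
#' @param alpha Smoothing weight (default 1).
#' @return Object of class `ddipass_cv`.
#' @export
kfold_cv <- function(dataset, k = 20L, seed, level = 2L, alpha = 1) {
  stopifnot(inherits(dataset, "ddi_dataset"))
  if (missing(seed)) stop("kfold_cv: 'seed' is required for reproducible folds")
  k <- as.integer(k)
  n <- nrow(dataset$pairs)
  if (k < 2L || k > n) stop("kfold_cv: need 2 <= k <= number of pairs")
  if (length(unique(dataset$pairs$orca_class)) < 2L)
    stop("IAP undefined: dataset contains a single ORCA class")

  ft <- .featurize_dataset(dataset, as.integer(level))
  V <- length(ft$vocab)
  d_n <- tabulate(unlist(ft$codes, use.names = FALSE), V)
  d_nc <- matrix(0L, nrow = V, ncol = 5L)
  for (c in .ORCA_CLASSES) {
    idx <- unlist(ft$codes[ft$classes == c], use.names = FALSE)
    if (length(idx)) d_nc[, c] <- tabulate(idx, V)
  }
  class_counts <- tabulate(ft$classes, 5L)

  # stratified fold assignment: shuffle within class, concatenate class
  # blocks, deal round-robin over the concatenation -- consecutive positions
  # (hence each class) spread evenly over folds, and k = n yields singleton
  # folds
  set.seed(as.integer(seed))
  ord <- unlist(lapply(.ORCA_CLASSES, function(c) {
    idx <- which(ft$classes == c)
    idx[sample.int(length(idx))]
  }), use.names = FALSE)
  fold <- integer(n)
  fold[ord] <- rep_len(seq_len(k), n)

  scores <- matrix(NA_real_, n, 5L)
  keep <- logical(n)
  for (f in seq_len(k)) {
    in_fold <- which(fold == f)
    if (!length(in_fold)) next
    codes_f <- unlist(ft$codes[in_fold], use.names = FALSE)
    dn_f <- tabulate(codes_f, V)
    dnc_f <- matrix(0L, nrow = V, ncol = 5L)
    for (c in .ORCA_CLASSES) {
      idx <- unlist(ft$codes[intersect(in_fold, which(ft$classes == c))],
                    use.names = FALSE)
      if (length(idx)) dnc_f[, c] <- tabulate(idx, V)
    }
    cc <- class_counts - tabulate(ft$classes[in_fold], 5L)
    n_rem <- n - length(in_fold)
    if (n_rem < 1L || sum(cc > 0L) < 2L) next
    priors <- cc / n_rem
    for (i in in_fold) {
      ki <- ft$codes[[i]]
      scores[i, ] <- .pass_raw_scores(d_n[ki] - dn_f[ki],
                                      d_nc[ki, , drop = FALSE] -
                                        dnc_f[ki, , drop = FALSE],
                                      priors, alpha)
      keep[i] <- TRUE
    }
  }
  .new_cv_report(sprintf("%d-fold CV (stratified by class, split by pair)", k),
                 scores[keep, , drop = FALSE], ft$classes[keep],
                 paste(ft$pairs$drug_a, ft$pairs$drug_b, sep = "\t")[keep],
                 dataset,
                 skipped = paste(ft$pairs$drug_a, ft$pairs$drug_b,
                                 sep = "\t")[!keep],
                 seed = as.integer(seed), k = k)
}
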