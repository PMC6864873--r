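# Dataset summary statistics: pair combinatorics, class distribution,
# label coverage of the pairwise space.

#' Number of possible unordered drug pairs
#'
#' `n * (n - 1) / 2` distinct unordered pairs of `n` drugs; e.g. a library of
#' 767 drugs spans 293,761 possible pairwise combinations.
#'
#' @param n Number of drugs (>= 2).
#' @return Integer-valued numeric.
#' @export
possible_pairs <- function(n) {
  n <- as.numeric(n)
  if (length(n) != 1L || is.na(n) || n < 2 || n != floor(n))
    stop("possible_pairs: 'n' must be a single integer >= 2")
  n * (n - 1) / 2
}

# half-up decimal rounding (display only; raw values are kept in the object)
.round_half_up <- function(x, digits = 2L) floor(x * 10^digits + 0.5) / 10^digits

#' Summarize a DDI dataset
#'
#' Computes library and pair-table statistics: per-class counts, the number
#' of possible pairwise combinations of the library, the percentage of them
#' that carry a label (coverage), and the count of unlabeled pairs. Raw
#' (unrounded) values are stored; percentages are rounded half-up to two
#' decimals for display only.
#'
#' @param object A [ddi_dataset()].
#' @param ... Unused.
#' @return Object of class `ddi_summary`.
#' @export
summary.ddi_dataset <- function(object, ...) {
  n_drugs <- length(object$drugs)
  n_pairs <- nrow(object$pairs)
  n_possible <- if (n_drugs >= 2L) possible_pairs(n_drugs) else 0
  pairs_per_drug <- table(factor(c(object$pairs$drug_a, object$pairs$drug_b),
                                 levels = names(object$drugs)))
  structure(list(
    n_drugs = n_drugs,
    n_pairs = n_pairs,
    class_counts = stats::setNames(tabulate(object$pairs$orca_class, 5L),
                                   paste0("class", 1:5)),
    n_possible_pairs = n_possible,
    coverage_percent = if (n_possible > 0) 100 * n_pairs / n_possible else 0,
    n_unlabeled_pairs = n_possible - n_pairs,
    pairs_per_drug = as.integer(pairs_per_drug)
  ), class = "ddi_summary")
}

#' @export
print.ddi_summary <- function(x, ...) {
  cat(sprintf("DDI dataset: %d drugs, %d labeled pairs\n", x$n_drugs, x$n_pairs))
  cat("  per ORCA class 1..5: ", paste(x$class_counts, collapse = " / "),
      "\n", sep = "")
  cat(sprintf("  possible pairs: %s   labeled coverage: %.2f%%   unlabeled: %s\n",
              format(x$n_possible_pairs, big.mark = ","),
              .round_half_up(x$coverage_percent),
              format(x$n_unlabeled_pairs, big.mark = ",")))
  invisible(x)
}
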