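# PASS-style naive Bayes classifier over PoSMNA descriptors.
#
# Each ORCA class c is treated one-vs-rest.  For a descriptor d the smoothed
# conditional probability is
#     P(c|d) = (n(d,c) + alpha * pi_c) / (n(d) + alpha)
# with n(d) the number of training pairs containing d, n(d,c) those of class
# c, pi_c the class prior and alpha a Laplace-type smoothing weight.  The raw
# class score of a query pair is the arcsine-transform mean over its known
# descriptors,
#     S_c = sin( mean_d arcsin(2 P(c|d) - 1) ),
# which lives in [-1, 1] and falls back to 2 pi_c - 1 when no descriptor is
# known.  Pa and Pi are rank positions of S_c within the leave-self-out score
# distributions of the training actives / non-actives for class c, with
# mid-rank treatment of ties.

.ORCA_CLASSES <- 1:5

# featurize a dataset once: MNA sets per drug, PoSMNA codes per pair
.featurize_dataset <- function(dataset, level) {
  stopifnot(inherits(dataset, "ddi_dataset"))
  mna_sets <- lapply(dataset$drugs, function(g) {
    tryCatch(mna_descriptors(g, level),
             error = function(e) stop("featurization failed for drug '", g$id,
                                      "': ", conditionMessage(e), call. = FALSE))
  })
  pairs <- dataset$pairs
  feats <- lapply(seq_len(nrow(pairs)), function(i) {
    build_posmna(mna_sets[[pairs$drug_a[i]]], mna_sets[[pairs$drug_b[i]]])$descriptors
  })
  vocab <- unique(unlist(feats, use.names = FALSE))
  vocab <- vocab[order(vocab, method = "radix")]
  codes <- lapply(feats, match, table = vocab)
  list(mna_sets = mna_sets, vocab = vocab, codes = codes,
       classes = pairs$orca_class, pairs = pairs)
}

# raw scores for all five classes given the query's adjusted per-descriptor
# counts (dn: n(d) vector; dnc: matrix length(dn) x 5) and class priors
.pass_raw_scores <- function(dn, dnc, priors, alpha) {
  known <- dn > 0L
  if (!any(known)) return(2 * priors - 1)
  p <- sweep(dnc[known, , drop = FALSE], 2L, alpha * priors, "+") /
    (dn[known] + alpha)
  z <- 2 * p - 1
  z[z > 1] <- 1; z[z < -1] <- -1
  sin(colMeans(asin(z)))
}

#' Fit a PASS-style DDI severity model
#'
#' Trains the naive Bayes classifier on a labeled [ddi_dataset()]: PoSMNA
#' descriptors are generated for every pair, per-class descriptor counts are
#' accumulated, and each training pair is scored with its own contribution
#' removed from the counts (leave-self-out), producing the per-class score
#' distributions that calibrate Pa/Pi at prediction time.
#'
#' @param dataset A [ddi_dataset()] with at least two ORCA classes present.
#' @param level MNA level of the descriptors (default 2).
#' @param alpha Smoothing weight toward the class prior (default 1).
#' @return Object of class `ddipass`.
#' @seealso [predict.ddipass()], [compound_out_loo()], [kfold_cv()]
#' @export
ddipass <- function(dataset, level = 2L, alpha = 1) {
  stopifnot(inherits(dataset, "ddi_dataset"))
  n <- nrow(dataset$pairs)
  if (n < 1L) stop("ddipass: dataset has no labeled pairs")
  if (length(unique(dataset$pairs$orca_class)) < 2L)
    stop("ddipass: training requires at least two ORCA classes")
  if (alpha <= 0) stop("ddipass: alpha must be > 0")
  level <- as.integer(level)

  ft <- .featurize_dataset(dataset, level)
  V <- length(ft$vocab)
  d_n <- tabulate(unlist(ft$codes, use.names = FALSE), V)
  d_nc <- matrix(0L, nrow = V, ncol = 5L)
  for (c in .ORCA_CLASSES) {
    idx <- unlist(ft$codes[ft$classes == c], use.names = FALSE)
    if (length(idx)) d_nc[, c] <- tabulate(idx, V)
  }
  class_counts <- tabulate(ft$classes, 5L)

  # leave-self-out training scores
  ts <- matrix(NA_real_, nrow = n, ncol = 5L)
  for (i in seq_len(n)) {
    ki <- ft$codes[[i]]
    dn <- d_n[ki] - 1L
    dnc <- d_nc[ki, , drop = FALSE]
    ci <- ft$classes[i]
    dnc[, ci] <- dnc[, ci] - 1L
    cc <- class_counts
    cc[ci] <- cc[ci] - 1L
    ts[i, ] <- .pass_raw_scores(dn, dnc, cc / (n - 1L), alpha)
  }

  structure(list(level = level, alpha = alpha,
                 classes = .ORCA_CLASSES,
                 n_pairs = n, class_counts = class_counts,
                 vocab = ft$vocab, d_n = d_n, d_nc = d_nc,
                 pairs = ft$pairs, pair_codes = ft$codes,
                 training_scores = ts,
                 mna_sets = ft$mna_sets,
                 call = match.call()),
            class = "ddipass")
}

# descriptor strings of a query pair, resolved against model or user structures
.query_descriptors <- function(object, id_a, id_b, structures) {
  get_set <- function(id) {
    if (!is.null(structures) && id %in% names(structures)) {
      g <- structures[[id]]
      if (inherits(g, "mna_set")) return(g)
      return(mna_descriptors(g, object$level))
    }
    if (id %in% names(object$mna_sets)) return(object$mna_sets[[id]])
    stop("unknown drug '", id, "': supply its structure via 'structures'")
  }
  build_posmna(get_set(id_a), get_set(id_b))$descriptors
}

# Pa/Pi calibration of one raw score vector against the training distributions
.calibrate_pa_pi <- function(object, raw) {
  ts <- object$training_scores
  cls <- object$pairs$orca_class
  pa <- pi_ <- numeric(5L)
  for (c in .ORCA_CLASSES) {
    act <- ts[cls == c, c]
    oth <- ts[cls != c, c]
    pa[c] <- if (length(act)) {
      (sum(act < raw[c]) + 0.5 * sum(act == raw[c])) / length(act)
    } else 0
    pi_[c] <- if (length(oth)) {
      (sum(oth > raw[c]) + 0.5 * sum(oth == raw[c])) / length(oth)
    } else 0
  }
  list(pa = pa, pi = pi_)
}

#' Predict ORCA severity classes for drug pairs
#'
#' Scores each query pair against all five ORCA classes and calibrates the
#' raw scores into Pa (probability of belonging to the class) and Pi
#' (probability of the opposite) by their rank within the model's
#' leave-self-out training score distributions. Descriptors never seen in
#' training are ignored; a pair with no known descriptor falls back to the
#' prior score. Predictions are symmetric in the two drugs.
#'
#' @param object A fitted [ddipass()] model.
#' @param newdata `data.frame` with columns `drug_a`, `drug_b` (IDs known to
#'   the model or resolvable through `structures`).
#' @param structures Optional named list of [molgraph()] (or `mna_set`)
#'   objects for drugs outside the training library.
#' @param ... Unused.
#' @return `data.frame` with one row per pair and class: `drug_a`, `drug_b`,
#'   `orca_class`, `score` (raw), `pa`, `pi`; within each pair rows are
#'   ordered by `pa - pi` decreasing.
#' @export
predict.ddipass <- function(object, newdata, structures = NULL, ...) {
  if (inherits(newdata, "ddi_dataset")) newdata <- newdata$pairs
  stopifnot(is.data.frame(newdata), all(c("drug_a", "drug_b") %in% names(newdata)))
  out <- vector("list", nrow(newdata))
  for (i in seq_len(nrow(newdata))) {
    a <- newdata$drug_a[i]; b <- newdata$drug_b[i]
    desc <- .query_descriptors(object, a, b, structures)
    ki <- match(desc, object$vocab)
    ki <- ki[!is.na(ki)]
    raw <- .pass_raw_scores(object$d_n[ki],
                            object$d_nc[ki, , drop = FALSE],
                            object$class_counts / object$n_pairs,
                            object$alpha)
    cal <- .calibrate_pa_pi(object, raw)
    ord <- order(cal$pa - cal$pi, decreasing = TRUE)
    out[[i]] <- data.frame(drug_a = a, drug_b = b,
                           orca_class = .ORCA_CLASSES[ord],
                           score = raw[ord], pa = cal$pa[ord], pi = cal$pi[ord],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.ddipass <- function(x, ...) {
  cat("PASS-style DDI severity model (PoSMNA naive Bayes)\n")
  cat(sprintf("  MNA level: %d   smoothing alpha: %g\n", x$level, x$alpha))
  cat(sprintf("  training pairs: %d   drugs: %d   descriptor vocabulary: %d\n",
              x$n_pairs, length(x$mna_sets), length(x$vocab)))
  cat("  pairs per ORCA class 1..5: ",
      paste(x$class_counts, collapse = " / "), "\n", sep = "")
  invisible(x)
}

#' @describeIn ddipass Training-set self-consistency: per-class IAP of the
#'   leave-self-out scores, plus model size statistics.
#' @param object,x A `ddipass` model.
#' @param ... Unused.
#' @export
summary.ddipass <- function(object, ...) {
  cls <- object$pairs$orca_class
  iaps <- vapply(.ORCA_CLASSES, function(c) {
    lab <- cls == c
    if (!any(lab) || all(lab)) return(NA_real_)
    iap(object$training_scores[, c], lab)
  }, numeric(1))
  structure(list(model = object, self_iap = iaps,
                 mean_self_iap = mean(iaps, na.rm = TRUE)),
            class = "summary.ddipass")
}

#' @export
print.summary.ddipass <- function(x, ...) {
  print(x$model)
  cat("  leave-self-out IAP per class: ",
      paste(ifelse(is.na(x$self_iap), "--", sprintf("%.3f", x$self_iap)),
            collapse = " / "), "\n", sep = "")
  cat(sprintf("  mean: %.3f\n", x$mean_self_iap))
  invisible(x)
}

#' @describeIn ddipass Smoothed per-descriptor class probabilities
#'   `P(c|d)`, a `length(vocab) x 5` matrix.
#' @export
coef.ddipass <- function(object, ...) {
  priors <- object$class_counts / object$n_pairs
  p <- sweep(object$d_nc, 2L, object$alpha * priors, "+") /
    (object$d_n + object$alpha)
  dimnames(p) <- list(object$vocab, paste0("class", .ORCA_CLASSES))
  p
}

.DDIPASS_FORMAT <- "ddipass-model/1"

#' Save / load a fitted model as JSON
#'
#' Lossless JSON round-trip of a [ddipass()] model: predictions after
#' `read_ddipass(write_ddipass(m, f))` are identical to those of `m`.
#' A format version field guards against loading incompatible files.
#'
#' @param model A fitted `ddipass` model.
#' @param path File path.
#' @return `write_ddipass` returns `path` invisibly; `read_ddipass` returns
#'   the model.
#' @export
write_ddipass <- function(model, path) {
  stopifnot(inherits(model, "ddipass"))
  payload <- list(
    format = .DDIPASS_FORMAT,
    package_version = as.character(utils::packageVersion("ddipass")),
    level = model$level, alpha = model$alpha,
    n_pairs = model$n_pairs, class_counts = model$class_counts,
    vocab = model$vocab, d_n = model$d_n,
    d_nc = as.data.frame(model$d_nc),
    pairs = model$pairs, pair_codes = model$pair_codes,
    training_scores = as.data.frame(model$training_scores),
    mna_sets = lapply(model$mna_sets, function(s)
      list(molecule_id = s$molecule_id, level = s$level,
           descriptors = s$descriptors))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ddipass
#' @export
read_ddipass <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) stop("cannot read model file '", path,
                                               "': ", conditionMessage(e),
                                               call. = FALSE))
  if (!identical(payload$format, .DDIPASS_FORMAT))
    stop("model file '", path, "': unsupported format version '",
         payload$format %||% "<missing>", "'")
  mna_sets <- lapply(payload$mna_sets, function(s)
    structure(list(molecule_id = s$molecule_id, level = as.integer(s$level),
                   descriptors = as.character(s$descriptors)),
              class = "mna_set"))
  structure(list(level = as.integer(payload$level), alpha = payload$alpha,
                 classes = .ORCA_CLASSES,
                 n_pairs = as.integer(payload$n_pairs),
                 class_counts = as.integer(payload$class_counts),
                 vocab = as.character(payload$vocab),
                 d_n = as.integer(payload$d_n),
                 d_nc = unname(as.matrix(payload$d_nc)),
                 pairs = as.data.frame(payload$pairs),
                 pair_codes = lapply(payload$pair_codes, as.integer),
                 training_scores = unname(as.matrix(payload$training_scores)),
                 mna_sets = mna_sets,
                 call = NULL),
            class = "ddipass")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
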