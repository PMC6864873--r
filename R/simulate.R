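# Synthetic DDI benchmark generator.
#
# Emulates the statistical shape of a curated DDI severity training set: a
# library of a few hundred small-molecule graphs built from a fragment
# grammar, and a sparse labeled pair table whose ORCA class distribution is
# skewed (class 3 dominant, classes 1 and 5 rare) and whose labels are driven
# by hidden pharmacophore-motif co-occurrence rules plus optional label
# noise.  Scaffolds use only C and O; motifs carry N and/or S, so motif
# presence is detectable unambiguously by subgraph matching and the
# generator's bookkeeping can be audited.

# Motif catalogue.  Each motif is a multi-atom fragment (>= 4 heavy atoms, so
# MNA/2 neighbourhoods can see it) with a designated attachment atom.
.MOTIFS <- list(
  sulfonamide = list(
    element = c("S", "O", "O", "N", "C"),
    bonds = cbind(c(1L, 1L, 1L, 4L), c(2L, 3L, 4L, 5L), c(2L, 2L, 1L, 1L)),
    attach = 1L),
  pyridine = list(
    element = c("C", "C", "C", "C", "C", "N"),
    bonds = cbind(c(1L, 2L, 3L, 4L, 5L, 6L), c(2L, 3L, 4L, 5L, 6L, 1L),
                  c(2L, 1L, 2L, 1L, 2L, 1L)),
    attach = 3L),
  amide = list(   # N,N-dimethyl amide: 5 heavy atoms keep it visible at MNA/2
    element = c("C", "O", "N", "C", "C"),
    bonds = cbind(c(1L, 1L, 3L, 3L), c(2L, 3L, 4L, 5L), c(2L, 1L, 1L, 1L)),
    attach = 1L),
  thiophene = list(   # decoy: present in molecules, ignored by the class rules
    element = c("S", "C", "C", "C", "C"),
    bonds = cbind(c(1L, 2L, 3L, 4L, 5L), c(2L, 3L, 4L, 5L, 1L),
                  c(1L, 2L, 1L, 2L, 1L)),
    attach = 3L)
)

#' Pharmacophore motif catalogue of the synthetic generator
#'
#' Returns the motif fragments that the generator plants into synthetic
#' molecules, as heavy-atom [molgraph()] objects with an `attach` attribute
#' (the atom index bonded to the scaffold). The first three motifs drive the
#' hidden class rules; the fourth is a decoy.
#'
#' @return Named list of `molgraph` objects.
#' @export
ddi_motifs <- function() {
  out <- lapply(names(.MOTIFS), function(nm) {
    m <- .MOTIFS[[nm]]
    g <- molgraph(nm, m$element, m$bonds)
    attr(g, "attach") <- m$attach
    g
  })
  stats::setNames(out, names(.MOTIFS))
}

# ---- fragment-grammar molecule assembly --------------------------------

# builder state: element vector, bond matrix, per-atom bond order sum
.frag_free <- function(st) {
  vapply(seq_along(st$element), function(i) {
    v <- .VALENCES[[st$element[i]]]
    if (is.null(v)) return(0L)
    v <- v[v >= st$ordsum[i]]
    if (!length(v)) 0L else as.integer(min(v) - st$ordsum[i])
  }, integer(1))
}

.frag_attach <- function(st, element, bonds, at, frag_attach, order = 1L) {
  off <- length(st$element)
  st$element <- c(st$element, element)
  st$ordsum <- c(st$ordsum, integer(length(element)))
  if (NROW(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1L] + off; j <- bonds[r, 2L] + off; o <- bonds[r, 3L]
      st$bonds <- rbind(st$bonds, c(i, j, o))
      st$ordsum[i] <- st$ordsum[i] + o
      st$ordsum[j] <- st$ordsum[j] + o
    }
  }
  if (!is.null(at)) {
    st$bonds <- rbind(st$bonds, c(at, frag_attach + off, order))
    st$ordsum[at] <- st$ordsum[at] + order
    st$ordsum[frag_attach + off] <- st$ordsum[frag_attach + off] + order
  }
  st
}

.chain_bonds <- function(len) {
  if (len < 2L) return(matrix(integer(0), ncol = 3L))
  cbind(seq_len(len - 1L), seq_len(len - 1L) + 1L, 1L)
}

.ring_bonds <- function(len) {
  cbind(seq_len(len), c(seq_len(len - 1L) + 1L, 1L), 1L)
}

# one random scaffold (C/O only, saturated)
.random_scaffold <- function() {
  kind <- sample(c("chain", "ring5", "ring6", "ring6_tail"), 1L,
                 prob = c(0.35, 0.15, 0.3, 0.2))
  st <- switch(kind,
    chain = {
      len <- sample(3:5, 1L)
      list(element = rep("C", len), bonds = .chain_bonds(len),
           ordsum = integer(len))
    },
    ring5 = list(element = rep("C", 5L), bonds = .ring_bonds(5L),
                 ordsum = integer(5L)),
    ring6 = list(element = rep("C", 6L), bonds = .ring_bonds(6L),
                 ordsum = integer(6L)),
    ring6_tail = {
      st0 <- list(element = rep("C", 6L), bonds = .ring_bonds(6L),
                  ordsum = integer(6L))
      .frag_attach(st0, "C", NULL, 1L, 1L)
    })
  st$ordsum <- integer(length(st$element))
  for (r in seq_len(nrow(st$bonds))) {
    st$ordsum[st$bonds[r, 1L]] <- st$ordsum[st$bonds[r, 1L]] + st$bonds[r, 3L]
    st$ordsum[st$bonds[r, 2L]] <- st$ordsum[st$bonds[r, 2L]] + st$bonds[r, 3L]
  }
  # 0-1 decorations: methyl, hydroxyl or methoxy.  Scaffolds are kept small
  # (3-7 heavy atoms) relative to the motifs so that a planted motif
  # dominates a molecule's MNA/2 neighbourhood set -- the construction's
  # guarantee that planted classes stay recoverable under compound-out
  # validation.
  for (d in seq_len(sample(0:1, 1L))) {
    free <- which(.frag_free(st) > 0L & st$element == "C")
    if (!length(free)) break
    at <- free[sample.int(length(free), 1L)]
    st <- switch(sample(c("methyl", "hydroxyl", "methoxy"), 1L),
      methyl = .frag_attach(st, "C", NULL, at, 1L),
      hydroxyl = .frag_attach(st, "O", NULL, at, 1L),
      methoxy = .frag_attach(st, c("O", "C"), cbind(1L, 2L, 1L), at, 1L))
  }
  st
}

#' Generate a synthetic small-molecule library
#'
#' Assembles `n_molecules` valence-valid, connected molecular graphs from a
#' fragment grammar (alkyl chains, 5/6-membered carbocycles, O
#' substitutions) and plants 0-3 pharmacophore motifs from [ddi_motifs()]
#' into each, drawn independently with `motif_probs`. Fully deterministic
#' per `seed`.
#'
#' @param n_molecules Library size (default 200).
#' @param seed Integer seed (required).
#' @param n_motifs How many catalogue motifs to use (3 or 4; default 4, the
#'   fourth being a decoy that the class rules ignore).
#' @param motif_probs Per-motif inclusion probabilities (recycled/truncated
#'   to `n_motifs`).
#' @return Named list of heavy-atom [molgraph()] objects with attributes
#'   `motifs` (molecules x motifs logical matrix) and `motif_atoms`
#'   (per-molecule list of planted motif atom indices).
#' @export
simulate_ddi_library <- function(n_molecules = 200L, seed,
                                 n_motifs = 4L,
                                 motif_probs = c(0.15, 0.35, 0.35, 0.10)) {
  if (missing(seed)) stop("simulate_ddi_library: 'seed' is required")
  n_motifs <- as.integer(n_motifs)
  if (n_motifs < 3L || n_motifs > length(.MOTIFS))
    stop("simulate_ddi_library: n_motifs must be 3 or 4 (rules need 3 motifs)")
  motif_probs <- rep_len(motif_probs, n_motifs)
  set.seed(as.integer(seed))
  ids <- sprintf(paste0("M%0", max(3L, nchar(n_molecules)), "d"),
                 seq_len(n_molecules))
  motif_names <- names(.MOTIFS)[seq_len(n_motifs)]
  motifs <- matrix(FALSE, n_molecules, n_motifs,
                   dimnames = list(ids, motif_names))
  motif_atoms <- vector("list", n_molecules)
  out <- vector("list", n_molecules)
  for (i in seq_len(n_molecules)) {
    st <- .random_scaffold()
    n_scaffold <- length(st$element)
    present <- which(stats::runif(n_motifs) < motif_probs)
    if (length(present) > 3L) present <- sort(sample(present, 3L))
    atoms <- list()
    for (m in present) {
      fv <- .frag_free(st)
      free <- which(fv > 0L & st$element == "C" &
                      seq_along(st$element) <= n_scaffold)
      if (!length(free))
        stop("simulate_ddi_library: no free attachment site left for motif '",
             motif_names[m], "' (scaffold too small for the motif load)")
      at <- free[sample.int(length(free), 1L)]
      off <- length(st$element)
      mt <- .MOTIFS[[m]]
      st <- .frag_attach(st, mt$element, mt$bonds, at, mt$attach)
      atoms[[motif_names[m]]] <- off + seq_along(mt$element)
    }
    motifs[i, present] <- TRUE
    motif_atoms[[i]] <- atoms
    out[[i]] <- molgraph(ids[i], st$element, st$bonds)
  }
  names(out) <- ids
  names(motif_atoms) <- ids
  attr(out, "motifs") <- motifs
  attr(out, "motif_atoms") <- motif_atoms
  out
}

# hidden labeling rule on motif co-occurrence; m* are logical vectors of the
# two molecules' motif sets (sulfonamide, pyridine, amide; decoy ignored)
.ddi_rule_class <- function(ma, mb) {
  if ((ma[1L] && mb[2L]) || (mb[1L] && ma[2L])) return(1L)
  if (ma[1L] || mb[1L]) return(2L)
  if ((ma[2L] && mb[3L]) || (mb[2L] && ma[3L]) || (ma[2L] && mb[2L])) return(3L)
  if (ma[2L] || mb[2L] || ma[3L] || mb[3L]) return(4L)
  5L
}

#' Generate a labeled synthetic pair table
#'
#' Samples `n_pairs` distinct unordered pairs from the library, labels each
#' by the hidden motif co-occurrence rules (sulfonamide x pyridine across the
#' pair is contraindicated; a lone sulfonamide is provisionally
#' contraindicated; pyridine with amide -- or pyridine on both sides -- is
#' conditional; any remaining pyridine/amide is minimal risk; motif-free
#' pairs do not interact), rebalancing the sampling so the realized
#' rule-class proportions match `class_proportions` exactly, then flips each
#' label to a random other class with probability `label_noise_rate`.
#'
#' @param library Output of [simulate_ddi_library()].
#' @param n_pairs Number of labeled pairs (default 600).
#' @param class_proportions Target class-1..5 proportions (default skewed
#'   like a curated severity compendium: 3/11/54/25/6 percent).
#' @param label_noise_rate Probability of flipping a label (default 0).
#' @param seed Integer seed (required).
#' @return A [ddi_dataset()] (hydrogen-complete, ring-perceived structures)
#'   with attribute `ground_truth`: a `data.frame` of rule class, observed
#'   class and flip indicator per pair.
#' @export
simulate_ddi_pairs <- function(library, n_pairs = 600L,
                               class_proportions = c(59, 236, 1139, 523, 133) / 2090,
                               label_noise_rate = 0, seed) {
  if (missing(seed)) stop("simulate_ddi_pairs: 'seed' is required")
  motifs <- attr(library, "motifs")
  if (is.null(motifs)) stop("simulate_ddi_pairs: 'library' must come from simulate_ddi_library()")
  if (label_noise_rate < 0 || label_noise_rate >= 1)
    stop("simulate_ddi_pairs: label_noise_rate must be in [0, 1)")
  if (abs(sum(class_proportions) - 1) > 1e-8 || length(class_proportions) != 5L)
    stop("simulate_ddi_pairs: class_proportions must be 5 values summing to 1")
  n <- length(library)
  if (n_pairs > possible_pairs(n))
    stop("simulate_ddi_pairs: n_pairs exceeds the number of possible pairs")
  set.seed(as.integer(seed))

  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  rule <- vapply(seq_len(nrow(idx)), function(r)
    .ddi_rule_class(motifs[idx[r, 1L], ], motifs[idx[r, 2L], ]), integer(1))

  # largest-remainder apportionment of n_pairs over the five classes
  quota <- class_proportions * n_pairs
  target <- floor(quota)
  rem <- n_pairs - sum(target)
  if (rem > 0) {
    extra <- order(quota - target, decreasing = TRUE)[seq_len(rem)]
    target[extra] <- target[extra] + 1L
  }
  avail <- tabulate(rule, 5L)
  short <- which(target > avail)
  if (length(short))
    stop("simulate_ddi_pairs: only ", paste(avail[short], collapse = ", "),
         " candidate pairs available for class(es) ",
         paste(short, collapse = ", "), " but ",
         paste(target[short], collapse = ", "),
         " requested; increase n_molecules or motif frequencies")
  take <- unlist(lapply(1:5, function(c) {
    b <- which(rule == c)
    b[sample.int(length(b), target[c])]
  }), use.names = FALSE)
  take <- take[sample.int(length(take))]   # shuffle row order

  ids <- names(library)
  observed <- rule[take]
  flipped <- stats::runif(length(take)) < label_noise_rate
  if (any(flipped)) {
    observed[flipped] <- vapply(observed[flipped], function(c)
      sample(setdiff(1:5, c), 1L), integer(1))
  }
  pairs <- data.frame(drug_a = ids[idx[take, 1L]],
                      drug_b = ids[idx[take, 2L]],
                      orca_class = observed, stringsAsFactors = FALSE)
  drugs <- lapply(library, function(g) perceive_rings(add_hydrogens(g)))
  ds <- ddi_dataset(drugs, pairs)
  attr(ds, "ground_truth") <- data.frame(
    drug_a = ids[idx[take, 1L]], drug_b = ids[idx[take, 2L]],
    rule_class = rule[take], orca_class = observed, flipped = flipped,
    stringsAsFactors = FALSE)
  attr(ds, "motifs") <- motifs
  ds
}

#' One-call synthetic benchmark dataset
#'
#' Convenience wrapper: [simulate_ddi_library()] with `seed`, then
#' [simulate_ddi_pairs()] with `seed + 1`.
#'
#' @inheritParams simulate_ddi_library
#' @inheritParams simulate_ddi_pairs
#' @return A [ddi_dataset()], as from [simulate_ddi_pairs()].
#' @export
simulate_ddi_dataset <- function(n_molecules = 200L, n_pairs = 600L,
                                 class_proportions = c(59, 236, 1139, 523, 133) / 2090,
                                 label_noise_rate = 0, seed,
                                 n_motifs = 4L,
                                 motif_probs = c(0.15, 0.35, 0.35, 0.10)) {
  if (missing(seed)) stop("simulate_ddi_dataset: 'seed' is required")
  lib <- simulate_ddi_library(n_molecules, seed = seed, n_motifs = n_motifs,
                              motif_probs = motif_probs)
  simulate_ddi_pairs(lib, n_pairs = n_pairs,
                     class_proportions = class_proportions,
                     label_noise_rate = label_noise_rate,
                     seed = as.integer(seed) + 1L)
}
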