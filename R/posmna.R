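# PoSMNA descriptors: pairwise descriptors for unordered molecule pairs.
#
# A drug pair is represented by the set of all pairs of MNA descriptors, one
# from each molecule, each written as "d1 d2" with d1 <= d2 under the MNA
# collation.  The construction is symmetric in the two molecules by design.

#' Build the PoSMNA descriptor set of a molecule pair
#'
#' Forms the cross product of the two molecules' MNA descriptor sets; each
#' element joins the two MNA strings with a single space, the smaller string
#' (under the mark-blind MNA collation) first. The result is a set: duplicate
#' pair strings collapse. `build_posmna(A, B)` and `build_posmna(B, A)` are
#' identical.
#'
#' @param set_a,set_b [mna_descriptors()] sets of the two molecules (same
#'   level).
#' @return Object of class `posmna_set`: list with `pair_id` (canonically
#'   ordered molecule IDs), `level`, `descriptors` (sorted character vector).
#' @export
build_posmna <- function(set_a, set_b) {
  stopifnot(inherits(set_a, "mna_set"), inherits(set_b, "mna_set"))
  if (set_a$level != set_b$level)
    stop("build_posmna: MNA levels differ (", set_a$level, " vs ", set_b$level, ")")
  if (!length(set_a$descriptors) || !length(set_b$descriptors))
    stop("build_posmna: empty MNA descriptor set")
  da <- rep(set_a$descriptors, times = length(set_b$descriptors))
  db <- rep(set_b$descriptors, each = length(set_a$descriptors))
  # byte-wise comparison under the collation, vectorized via radix ranks
  ka <- .mna_key(da); kb <- .mna_key(db)
  rk <- .byte_rank(c(ka, kb)); rka <- rk[seq_along(ka)]; rkb <- rk[-seq_along(ka)]
  rr <- .byte_rank(c(da, db)); rra <- rr[seq_along(da)]; rrb <- rr[-seq_along(da)]
  swap <- rka > rkb | (rka == rkb & rra > rrb)
  left <- ifelse(swap, db, da)
  right <- ifelse(swap, da, db)
  ids <- c(set_a$molecule_id, set_b$molecule_id)
  ids <- ids[order(ids, method = "radix")]
  structure(list(pair_id = ids, level = set_a$level,
                 descriptors = sort(unique(paste(left, right)), method = "radix")),
            class = "posmna_set")
}

#' PoSMNA descriptors straight from two structures
#'
#' Convenience wrapper: computes both molecules' MNA sets at `level` and
#' builds their PoSMNA set.
#'
#' @param mol_a,mol_b [molgraph()] objects.
#' @param level MNA level (default 2).
#' @return A `posmna_set`, as from [build_posmna()].
#' @export
posmna_pair <- function(mol_a, mol_b, level = 2L) {
  build_posmna(mna_descriptors(mol_a, level), mna_descriptors(mol_b, level))
}

#' @export
print.posmna_set <- function(x, ...) {
  cat(sprintf("<posmna_set> (%s, %s): %d descriptor pairs at MNA/%d\n",
              x$pair_id[1L], x$pair_id[2L], length(x$descriptors), x$level))
  invisible(x)
}
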