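# Multilevel Neighbourhoods of Atoms (MNA) descriptors.
#
# An MNA descriptor describes an atom by its label -- the element symbol,
# prefixed with "-" when the atom is not a ring member -- and, in parentheses,
# the concatenated level-(k-1) descriptors of all its neighbours, sorted under
# a fixed collation.  MNA/2 (level 2) rooted at each heavy atom is the default
# representation throughout the package.

# Canonical sibling collation: compare strings with every "-" removed,
# byte-wise; break ties on the raw string, byte-wise.  Plain byte ordering
# would place "-H" before ring-"C", which contradicts the neighbour order
# observed in reference MNA strings (e.g. "C(CCC-H)" before "-H(C)"); the
# mark-blind comparison reproduces them.
.mna_key <- function(x) gsub("-", "", x, fixed = TRUE)

.mna_order <- function(x) order(.mna_key(x), x, method = "radix")

.mna_sort <- function(x) x[.mna_order(x)]

#' Atom labels for MNA generation
#'
#' The level-0 MNA descriptor of an atom: its element symbol, prefixed with
#' `-` iff the atom is not a member of any ring. Hydrogens are always `-H`.
#'
#' @param graph A [molgraph()] (hydrogen-complete, rings perceived).
#' @return Character vector of labels, one per atom.
#' @export
atom_labels <- function(graph) {
  stopifnot(inherits(graph, "molgraph"))
  if (any(!nzchar(graph$element))) stop("atom_labels: empty element symbol")
  paste0(ifelse(graph$in_ring, "", "-"), graph$element)
}

# per-atom MNA strings at the requested level (vector over all atoms)
.mna_levels <- function(graph, level) {
  lab <- atom_labels(graph)
  if (level == 0L) return(lab)
  adj <- .adjacency(graph)
  cur <- lab
  for (k in seq_len(level)) {
    cur <- vapply(seq_along(lab), function(i) {
      nb <- adj[[i]]
      paste0(lab[i], "(",
             if (length(nb)) paste0(.mna_sort(cur[nb]), collapse = "") else "",
             ")")
    }, character(1))
  }
  cur
}

#' MNA descriptor of a single atom
#'
#' Computes the level-`level` MNA string rooted at atom `root`. Level 0 is the
#' atom label; level k wraps the label around the sorted level-(k-1)
#' descriptors of all neighbours (hydrogens included; sibling duplicates
#' retained).
#'
#' @param graph A [molgraph()].
#' @param root Atom index.
#' @param level Non-negative recursion depth (default 2, i.e. MNA/2).
#' @return List with elements `text`, `level`, `root_atom_index`.
#' @export
#' @examples
#' m <- perceive_rings(add_hydrogens(molgraph("methane", "C", NULL)))
#' mna_descriptor(m, 1, 2)$text  # "-C(-H(-C)-H(-C)-H(-C)-H(-C))"
mna_descriptor <- function(graph, root, level = 2L) {
  stopifnot(inherits(graph, "molgraph"))
  level <- as.integer(level)
  if (is.na(level) || level < 0L) stop("mna_descriptor: level must be >= 0")
  root <- as.integer(root)
  if (root < 1L || root > length(graph$element)) stop("mna_descriptor: invalid root")
  list(text = .mna_levels(graph, level)[root],
       level = level, root_atom_index = root)
}

#' MNA descriptor set of a molecule
#'
#' The set of distinct MNA strings rooted at each *heavy* (non-hydrogen) atom
#' of the molecule. Duplicates arising from topologically equivalent atoms
#' collapse, so the set has at most one entry per heavy atom and is invariant
#' under atom reordering.
#'
#' @param graph A [molgraph()].
#' @param level MNA level (default 2).
#' @return Object of class `mna_set`: list with `molecule_id`, `level`,
#'   `descriptors` (sorted character vector).
#' @export
mna_descriptors <- function(graph, level = 2L) {
  stopifnot(inherits(graph, "molgraph"))
  heavy <- which(graph$element != "H")
  if (!length(heavy)) stop("mna_descriptors: molecule '", graph$id,
                           "' has no heavy atoms")
  all_lv <- .mna_levels(graph, as.integer(level))
  structure(list(molecule_id = graph$id, level = as.integer(level),
                 descriptors = .mna_sort(unique(all_lv[heavy]))),
            class = "mna_set")
}

#' @export
print.mna_set <- function(x, ...) {
  cat(sprintf("<mna_set> %s: %d distinct MNA/%d descriptors\n",
              x$molecule_id, length(x$descriptors), x$level))
  invisible(x)
}
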