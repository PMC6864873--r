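# Molecular graphs and structure/table I/O.
#
# A molgraph is the substrate for MNA descriptor generation: a
# hydrogen-complete, connected atom/bond graph in which every atom carries an
# element symbol and a ring-membership flag.

# Default valences used to materialize implicit hydrogens.  For elements with
# several common valences the smallest one that accommodates the explicit bond
# order sum is used; unknown elements receive no implicit hydrogens.
.VALENCES <- list(
  H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L,
  Si = 4L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  Cl = 1L, Br = 1L, I = 1L
)

#' Construct a molecular graph
#'
#' Builds the atom/bond graph that underlies all descriptor generation. Atoms
#' are element symbols; bonds are undirected and carry an integer order (1-3).
#' The constructor canonicalizes and validates the adjacency (no self-loops,
#' no duplicate edges); it does not add hydrogens or perceive rings -- see
#' [add_hydrogens()] and [perceive_rings()], or load structures with
#' [read_structures()] which applies the full pipeline.
#'
#' @param id Drug identifier (non-empty string; surrounding whitespace is
#'   stripped).
#' @param element Character vector of element symbols, one per atom.
#' @param bonds Integer matrix with 2 or 3 columns (`from`, `to`, optional
#'   `order`, default 1); zero rows allowed for single-atom molecules.
#' @param in_ring Optional logical vector of ring-membership flags; if `NULL`
#'   all atoms are marked non-ring until [perceive_rings()] is run.
#' @return An object of class `molgraph`.
#' @export
#' @examples
#' ethane <- molgraph("ethane", c("C", "C"), cbind(1, 2))
#' ethane <- perceive_rings(add_hydrogens(ethane))
molgraph <- function(id, element, bonds, in_ring = NULL) {
  id <- trimws(as.character(id))
  if (length(id) != 1L || !nzchar(id)) stop("molgraph: 'id' must be a non-empty string")
  element <- as.character(element)
  n <- length(element)
  if (n < 1L) stop("molgraph: at least one atom required")
  if (any(!nzchar(trimws(element)))) stop("molgraph: empty element symbol")
  element <- trimws(element)

  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- matrix(integer(0), ncol = 3L)
  } else {
    bonds <- as.matrix(bonds)
    if (ncol(bonds) == 2L) bonds <- cbind(bonds, 1L)
    if (ncol(bonds) != 3L) stop("molgraph: 'bonds' needs columns from, to[, order]")
    storage.mode(bonds) <- "integer"
    if (any(is.na(bonds))) stop("molgraph: NA in bond block")
    if (any(bonds[, 1:2] < 1L) || any(bonds[, 1:2] > n))
      stop("molgraph: bond references atom outside 1..", n)
    if (any(bonds[, 1L] == bonds[, 2L])) stop("molgraph: self-loop bond")
    if (any(bonds[, 3L] < 1L | bonds[, 3L] > 3L))
      stop("molgraph: bond order must be 1, 2 or 3 (aromatic type 4 not supported; supply a Kekule structure)")
    # canonical low-high orientation, detect duplicates in either orientation
    a <- pmin(bonds[, 1L], bonds[, 2L]); b <- pmax(bonds[, 1L], bonds[, 2L])
    if (anyDuplicated(a * (n + 1L) + b)) stop("molgraph: duplicate bond")
    bonds <- cbind(a, b, bonds[, 3L], deparse.level = 0L)
  }
  colnames(bonds) <- c("from", "to", "order")

  if (is.null(in_ring)) in_ring <- rep(FALSE, n)
  if (length(in_ring) != n) stop("molgraph: 'in_ring' length mismatch")

  structure(list(id = id, element = element, in_ring = as.logical(in_ring),
                 bonds = bonds),
            class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  nh <- sum(x$element == "H")
  cat(sprintf("<molgraph> %s: %d atoms (%d heavy, %d H), %d bonds, %d ring atoms\n",
              x$id, length(x$element), length(x$element) - nh, nh,
              nrow(x$bonds), sum(x$in_ring)))
  invisible(x)
}

# adjacency list (neighbour atom indices, in bond-table order)
.adjacency <- function(graph) {
  n <- length(graph$element)
  b <- graph$bonds
  f <- factor(c(b[, 1L], b[, 2L]), levels = seq_len(n))
  unname(split(c(b[, 2L], b[, 1L]), f))
}

# per-atom sum of explicit bond orders
.bond_order_sum <- function(graph) {
  n <- length(graph$element)
  b <- graph$bonds
  s <- numeric(n)
  if (nrow(b)) {
    t1 <- tapply(b[, 3L], factor(b[, 1L], levels = seq_len(n)), sum)
    t2 <- tapply(b[, 3L], factor(b[, 2L], levels = seq_len(n)), sum)
    s <- ifelse(is.na(t1), 0, t1) + ifelse(is.na(t2), 0, t2)
  }
  as.integer(s)
}

.free_valence <- function(graph) {
  bs <- .bond_order_sum(graph)
  vapply(seq_along(graph$element), function(i) {
    v <- .VALENCES[[graph$element[i]]]
    if (is.null(v)) return(0L)
    v <- v[v >= bs[i]]
    if (!length(v)) 0L else as.integer(min(v) - bs[i])
  }, integer(1))
}

#' Materialize implicit hydrogens
#'
#' Adds explicit hydrogen atoms so that every atom reaches its default
#' valence (C 4; N 3; O 2; S 2/4/6; P 3/5; halogens 1; unknown elements get
#' none). Idempotent: structures that already carry explicit hydrogens gain
#' none, because explicit bonds count toward the valence.
#'
#' @param graph A [molgraph()].
#' @return The graph with hydrogens appended after the existing atoms.
#' @export
add_hydrogens <- function(graph) {
  stopifnot(inherits(graph, "molgraph"))
  nh <- .free_valence(graph)
  nh[graph$element == "H"] <- 0L
  total <- sum(nh)
  if (total == 0L) return(graph)
  n <- length(graph$element)
  hidx <- n + seq_len(total)
  parents <- rep(seq_len(n), nh)
  g <- graph
  g$element <- c(g$element, rep("H", total))
  g$in_ring <- c(g$in_ring, rep(FALSE, total))
  g$bonds <- rbind(g$bonds,
                   cbind(parents, hidx, rep(1L, total), deparse.level = 0L))
  colnames(g$bonds) <- c("from", "to", "order")
  g
}

#' Mark atoms that lie on a cycle
#'
#' Sets `in_ring = TRUE` for every atom that is a member of at least one cycle
#' of the graph. Membership in *any* cycle is used (an edge lies on a cycle
#' iff it is not a bridge), which is independent of any smallest-set-of-
#' smallest-rings basis choice. Hydrogens are never ring members.
#'
#' @param graph A [molgraph()].
#' @return The graph with `in_ring` recomputed.
#' @export
perceive_rings <- function(graph) {
  stopifnot(inherits(graph, "molgraph"))
  n <- length(graph$element)
  graph$in_ring <- rep(FALSE, n)
  b <- graph$bonds
  if (nrow(b) == 0L) return(graph)
  ig <- igraph::make_graph(edges = as.vector(t(b[, 1:2, drop = FALSE])),
                           n = n, directed = FALSE)
  br <- as.integer(igraph::bridges(ig))
  cyc <- setdiff(seq_len(nrow(b)), br)
  if (length(cyc)) {
    graph$in_ring[unique(as.vector(b[cyc, 1:2]))] <- TRUE
  }
  graph
}

# Keep the largest connected fragment: most heavy atoms, tie broken by total
# atom count, still tied -> error (the record is ambiguous).
.largest_fragment <- function(graph) {
  n <- length(graph$element)
  b <- graph$bonds
  ig <- igraph::make_graph(edges = as.vector(t(b[, 1:2, drop = FALSE])),
                           n = n, directed = FALSE)
  comp <- igraph::components(ig)
  if (comp$no == 1L) return(graph)
  heavy <- tapply(graph$element != "H", comp$membership, sum)
  total <- tabulate(comp$membership, comp$no)
  best_h <- max(heavy)
  cand <- which(heavy == best_h)
  if (length(cand) > 1L) {
    cand <- cand[total[cand] == max(total[cand])]
    if (length(cand) > 1L)
      stop(sprintf("structure '%s': tied largest fragments; cannot choose", graph$id))
  }
  keep <- which(comp$membership == cand[1L])
  remap <- match(seq_len(n), keep)
  kb <- b[b[, 1L] %in% keep & b[, 2L] %in% keep, , drop = FALSE]
  molgraph(graph$id, graph$element[keep],
           cbind(remap[kb[, 1L]], remap[kb[, 2L]], kb[, 3L]))
}

# parse one MDL V2000 molblock (lines up to but excluding the "$$$$")
.parse_molblock <- function(lines, recno) {
  where <- sprintf("structure record %d", recno)
  if (length(lines) < 4L) stop(where, ": truncated record")
  id <- trimws(lines[1L])
  if (!nzchar(id)) stop(where, ": missing drug ID on the name line")
  counts <- lines[4L]
  if (grepl("V3000", counts, fixed = TRUE))
    stop(where, " ('", id, "'): V3000 molblocks are not supported")
  na <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nb <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(na) || is.na(nb) || na < 1L)
    stop(where, " ('", id, "'): unparsable counts line")
  if (length(lines) < 4L + na + nb) stop(where, " ('", id, "'): truncated atom/bond block")

  atom_lines <- lines[4L + seq_len(na)]
  element <- trimws(substr(atom_lines, 32L, 34L))
  if (any(!nzchar(element))) stop(where, " ('", id, "'): atom with empty element symbol")
  legacy_chg <- suppressWarnings(as.integer(substr(atom_lines, 37L, 39L)))
  legacy_chg[is.na(legacy_chg)] <- 0L

  bonds <- NULL
  if (nb > 0L) {
    bond_lines <- lines[4L + na + seq_len(nb)]
    a <- suppressWarnings(as.integer(substr(bond_lines, 1L, 3L)))
    b <- suppressWarnings(as.integer(substr(bond_lines, 4L, 6L)))
    o <- suppressWarnings(as.integer(substr(bond_lines, 7L, 9L)))
    if (any(is.na(a)) || any(is.na(b)) || any(is.na(o)))
      stop(where, " ('", id, "'): unparsable bond line")
    if (any(o == 4L))
      stop(where, " ('", id, "'): aromatic bond type 4 not supported; supply a Kekule structure")
    bonds <- cbind(a, b, o)
  }

  props <- lines[-seq_len(4L + na + nb)]
  if (any(grepl("^M  (CHG|ISO|RAD)", props)) || any(legacy_chg != 0L))
    warning(where, " ('", id, "'): charge/isotope/radical information ignored",
            call. = FALSE)

  molgraph(id, element, bonds)
}

#' Read molecular structures from an SDF or MOL file
#'
#' Parses MDL V2000 records (a single molblock or an SDF with `$$$$` record
#' separators), keeps the largest connected fragment of each record (salts and
#' co-crystallized counter-ions are dropped), materializes implicit hydrogens
#' and perceives ring membership. The record's name line supplies the drug ID.
#'
#' @param path Path to an SDF or MOL file (V2000).
#' @return Named list of [molgraph()] objects, one per record, keyed by
#'   drug ID.
#' @export
read_structures <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(lines)))) stop("empty structure file: ", path)
  recs <- split(lines, cumsum(c(0L, head(trimws(lines) == "$$$$", -1L))))
  recs <- lapply(recs, function(r) r[trimws(r) != "$$$$"])
  recs <- recs[vapply(recs, function(r) any(nzchar(trimws(r))), logical(1))]
  if (!length(recs)) stop("empty structure file: ", path)
  out <- vector("list", length(recs))
  ids <- character(length(recs))
  for (i in seq_along(recs)) {
    g <- .parse_molblock(recs[[i]], i)
    g <- .largest_fragment(g)
    g <- perceive_rings(add_hydrogens(g))
    out[[i]] <- g
    ids[i] <- g$id
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate drug id in structure file: ", paste(dup, collapse = ", "))
  names(out) <- ids
  out
}

#' Write molecular structures to an SDF file
#'
#' Emits one MDL V2000 record per graph (atoms exactly as stored, zeroed
#' coordinates), separated by `$$$$`. Output is byte-deterministic, which the
#' synthetic-data generator relies on.
#'
#' @param drugs A named list of [molgraph()] objects, or a single one.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structures <- function(drugs, path) {
  if (inherits(drugs, "molgraph")) drugs <- list(drugs)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (g in drugs) {
    stopifnot(inherits(g, "molgraph"))
    na <- length(g$element); nb <- nrow(g$bonds)
    writeLines(c(
      g$id, "  ddipass", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              0, 0, 0, g$element),
      if (nb) sprintf("%3d%3d%3d  0", g$bonds[, 1L], g$bonds[, 2L], g$bonds[, 3L]),
      "M  END", "$$$$"
    ), con)
  }
  invisible(path)
}

# byte-wise (C locale) comparison rank for canonical pair orientation
.byte_rank <- function(x) {
  u <- unique(x)
  match(x, u[order(u, method = "radix")])
}

# element-wise "a sorts after b" under byte order (ranks over the pooled set)
.byte_gt <- function(a, b) {
  r <- .byte_rank(c(a, b))
  n <- length(a)
  r[seq_len(n)] > r[-seq_len(n)]
}

#' Read a labeled pairs table
#'
#' Reads the tab-separated pair table dialect: UTF-8, header
#' `drug_a<TAB>drug_b<TAB>orca_class`, `#` comment lines skipped. Pairs are
#' canonicalized to byte-order `(min_id, max_id)` orientation; duplicate pairs
#' (in either orientation) are rejected, naming both offending lines and
#' whether their labels conflict.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with columns `drug_a`, `drug_b`, `orca_class`.
#' @export
read_pairs_table <- function(path) {
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lineno <- seq_along(raw)
  keep <- nzchar(trimws(raw)) & !startsWith(trimws(raw), "#")
  raw <- raw[keep]; lineno <- lineno[keep]
  if (length(raw) < 1L) stop("pairs table is empty: ", path)
  header <- trimws(strsplit(raw[1L], "\t", fixed = TRUE)[[1L]])
  if (length(header) != 3L || !identical(header, c("drug_a", "drug_b", "orca_class")))
    stop("pairs table header must be 'drug_a<TAB>drug_b<TAB>orca_class'")
  raw <- raw[-1L]; lineno <- lineno[-1L]
  if (!length(raw)) {
    return(data.frame(drug_a = character(0), drug_b = character(0),
                      orca_class = integer(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(raw, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad))
    stop("pairs table line ", lineno[bad[1L]], ": expected 3 tab-separated fields")
  m <- matrix(trimws(unlist(fields)), ncol = 3L, byrow = TRUE)
  a <- m[, 1L]; b <- m[, 2L]
  cls <- suppressWarnings(as.integer(m[, 3L]))
  bad <- which(is.na(cls) | cls < 1L | cls > 5L | as.character(cls) != m[, 3L])
  if (length(bad))
    stop("pairs table line ", lineno[bad[1L]], ": orca_class '", m[bad[1L], 3L],
         "' is not an integer in 1..5")
  bad <- which(a == b)
  if (length(bad))
    stop("pairs table line ", lineno[bad[1L]], ": self-pair '", a[bad[1L]], "'")
  swap <- .byte_gt(a, b)
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  key <- paste(a, b, sep = "\t")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    first <- which(key == key[d])[1L]
    kind <- if (cls[first] != cls[d]) "conflicting duplicate pair" else "duplicate pair"
    stop("pairs table: ", kind, " (", a[d], ", ", b[d], ") on lines ",
         lineno[first], " and ", lineno[d])
  }
  data.frame(drug_a = a, drug_b = b, orca_class = cls, stringsAsFactors = FALSE)
}

#' Write a pairs table
#'
#' Writes the canonical TSV dialect accepted by [read_pairs_table()]: pairs in
#' `(min_id, max_id)` orientation, rows sorted byte-wise.
#'
#' @param pairs `data.frame` with columns `drug_a`, `drug_b`, `orca_class`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pairs_table <- function(pairs, path) {
  a <- trimws(as.character(pairs$drug_a))
  b <- trimws(as.character(pairs$drug_b))
  cls <- as.integer(pairs$orca_class)
  swap <- .byte_gt(a, b)
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  ord <- order(a, b, method = "radix")
  writeLines(c("drug_a\tdrug_b\torca_class",
               sprintf("%s\t%s\t%d", a[ord], b[ord], cls[ord])),
             path, useBytes = TRUE)
  invisible(path)
}

#' Assemble a labeled DDI dataset
#'
#' Binds a drug library to a labeled pair table and validates the invariants:
#' every drug referenced by a pair exists, pairs are unordered and unique,
#' no self-pairs, classes in 1..5.
#'
#' @param drugs Named list of [molgraph()] objects.
#' @param pairs `data.frame` with columns `drug_a`, `drug_b`, `orca_class`.
#' @return An object of class `ddi_dataset` with elements `drugs` and `pairs`.
#' @export
ddi_dataset <- function(drugs, pairs) {
  if (!length(drugs) || !all(vapply(drugs, inherits, logical(1), "molgraph")))
    stop("ddi_dataset: 'drugs' must be a non-empty named list of molgraph objects")
  if (is.null(names(drugs)) || any(!nzchar(names(drugs))))
    stop("ddi_dataset: 'drugs' must be named by drug ID")
  pairs <- data.frame(drug_a = trimws(as.character(pairs$drug_a)),
                      drug_b = trimws(as.character(pairs$drug_b)),
                      orca_class = as.integer(pairs$orca_class),
                      stringsAsFactors = FALSE)
  if (any(is.na(pairs$orca_class)) || any(pairs$orca_class < 1L | pairs$orca_class > 5L))
    stop("ddi_dataset: orca_class must be in 1..5")
  if (any(pairs$drug_a == pairs$drug_b)) stop("ddi_dataset: self-pair present")
  swap <- .byte_gt(pairs$drug_a, pairs$drug_b)
  tmp <- pairs$drug_a[swap]
  pairs$drug_a[swap] <- pairs$drug_b[swap]
  pairs$drug_b[swap] <- tmp
  if (anyDuplicated(paste(pairs$drug_a, pairs$drug_b, sep = "\t")))
    stop("ddi_dataset: duplicate pair (possibly in opposite orientation)")
  missing <- setdiff(unique(c(pairs$drug_a, pairs$drug_b)), names(drugs))
  if (length(missing))
    stop("ddi_dataset: pairs reference unknown drugs: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  rownames(pairs) <- NULL
  structure(list(drugs = drugs, pairs = pairs), class = "ddi_dataset")
}

#' @export
print.ddi_dataset <- function(x, ...) {
  cat(sprintf("<ddi_dataset> %d drugs, %d labeled pairs\n",
              length(x$drugs), nrow(x$pairs)))
  tab <- tabulate(x$pairs$orca_class, 5L)
  cat("  ORCA classes 1..5: ", paste(tab, collapse = " / "), "\n", sep = "")
  invisible(x)
}
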