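# Molecule builders and small graph utilities shared across the test files.
# Everything is constructed in code; no binary fixtures.

complete_mol <- function(g) perceive_rings(add_hydrogens(g))

mg_methane <- function() complete_mol(molgraph("methane", "C", NULL))

mg_ethane <- function() complete_mol(molgraph("ethane", c("C", "C"), cbind(1L, 2L)))

mg_propane <- function() {
  complete_mol(molgraph("propane", rep("C", 3), cbind(1:2, 2:3)))
}

mg_benzene <- function(id = "benzene") {
  complete_mol(molgraph(id, rep("C", 6),
                        cbind(1:6, c(2:6, 1L), c(2L, 1L, 2L, 1L, 2L, 1L))))
}

mg_cyclopropane <- function() {
  complete_mol(molgraph("cyclopropane", rep("C", 3),
                        cbind(c(1L, 2L, 3L), c(2L, 3L, 1L))))
}

mg_cyclopentane <- function(id = "cyclopentane") {
  complete_mol(molgraph(id, rep("C", 5), cbind(1:5, c(2:5, 1L))))
}

mg_biphenyl <- function() {
  ring <- function(off) cbind(off + 1:6, off + c(2:6, 1L),
                              c(2L, 1L, 2L, 1L, 2L, 1L))
  complete_mol(molgraph("biphenyl", rep("C", 12),
                        rbind(ring(0L), ring(6L), c(1L, 7L, 1L))))
}

mg_ethanol <- function(id = "ethanol") {
  complete_mol(molgraph(id, c("C", "C", "O"), cbind(1:2, 2:3)))
}

# phenyl ring (Kekule) with an ethyl-hydrazine tail: C6H5-CH2-CH2-NH-NH2
mg_phenelzine <- function() {
  complete_mol(molgraph("Phenelzine", c(rep("C", 8), "N", "N"),
    rbind(cbind(1:6, c(2:6, 1L), c(2L, 1L, 2L, 1L, 2L, 1L)),
          c(1L, 7L, 1L), c(7L, 8L, 1L), c(8L, 9L, 1L), c(9L, 10L, 1L))))
}

# 2-phenylcyclopropan-1-amine
mg_tranylcypromine <- function() {
  complete_mol(molgraph("Tranylcypromine", c(rep("C", 9), "N"),
    rbind(cbind(1:6, c(2:6, 1L), c(2L, 1L, 2L, 1L, 2L, 1L)),
          c(1L, 7L, 1L), c(7L, 8L, 1L), c(8L, 9L, 1L), c(7L, 9L, 1L),
          c(8L, 10L, 1L))))
}

# random connected graph (tree plus a few chords); not valence-realistic,
# used for graph-level properties such as ring perception
random_connected_graph <- function(n, id = "rnd") {
  stopifnot(n >= 2)
  parent <- vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1))
  bonds <- cbind(parent, 2:n, 1L)
  extra <- sample(0:3, 1L)
  for (e in seq_len(extra)) {
    ij <- sort(sample.int(n, 2L))
    key <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
    if (!paste(ij[1], ij[2]) %in% key) bonds <- rbind(bonds, c(ij[1], ij[2], 1L))
  }
  molgraph(id, sample(c("C", "N", "O"), n, replace = TRUE), bonds)
}

# apply an atom permutation to a molgraph (perm[i] = new index of old atom i)
permute_molgraph <- function(g, perm) {
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  b <- g$bonds
  molgraph(g$id, g$element[inv],
           cbind(perm[b[, 1L]], perm[b[, 2L]], b[, 3L]),
           in_ring = g$in_ring[inv])
}

# plain-R BFS: are u and v connected, optionally ignoring one bond row?
bfs_connected <- function(n, bonds, u, v, drop_edge = NULL) {
  keep <- setdiff(seq_len(nrow(bonds)), drop_edge)
  adj <- rep(list(integer(0)), n)
  for (r in keep) {
    i <- bonds[r, 1L]; j <- bonds[r, 2L]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n); seen[u] <- TRUE; queue <- u
  while (length(queue)) {
    x <- queue[1L]; queue <- queue[-1L]
    for (y in adj[[x]]) if (!seen[y]) { seen[y] <- TRUE; queue <- c(queue, y) }
  }
  seen[v]
}

# brute-force cycle membership: an atom lies on a cycle iff one of its bonds
# does, and a bond lies on a cycle iff its endpoints stay connected when the
# bond is removed
oracle_ring_atoms <- function(g) {
  n <- length(g$element)
  on_cycle <- logical(n)
  for (r in seq_len(nrow(g$bonds))) {
    u <- g$bonds[r, 1L]; v <- g$bonds[r, 2L]
    if (bfs_connected(n, g$bonds, u, v, drop_edge = r)) {
      on_cycle[u] <- TRUE; on_cycle[v] <- TRUE
    }
  }
  on_cycle
}

# 5-compound / 6-pair toy dataset used by the classifier and validation tests
toy_dataset <- function() {
  drugs <- list(mg_methane(), mg_ethane(), mg_benzene(), mg_cyclopentane(),
                mg_ethanol())
  names(drugs) <- c("methane", "ethane", "benzene", "cyclopentane", "ethanol")
  pairs <- data.frame(
    drug_a = c("methane", "methane", "ethane", "benzene", "cyclopentane", "ethane"),
    drug_b = c("ethane", "benzene", "benzene", "cyclopentane", "ethanol", "ethanol"),
    orca_class = c(1L, 3L, 3L, 2L, 5L, 3L),
    stringsAsFactors = FALSE)
  ddi_dataset(drugs, pairs)
}

golden_sdf_path <- function() {
  system.file("extdata", "golden_structures.sdf", package = "ddipass",
              mustWork = TRUE)
}

# recursive-descent check that a string obeys the MNA grammar
mna_grammar_ok <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  pos <- 1L
  parse_label <- function() {
    if (pos <= length(chars) && chars[pos] == "-") pos <<- pos + 1L
    if (pos > length(chars) || !grepl("^[A-Z]$", chars[pos])) return(FALSE)
    pos <<- pos + 1L
    if (pos <= length(chars) && grepl("^[a-z]$", chars[pos])) pos <<- pos + 1L
    TRUE
  }
  parse_desc <- function() {
    if (!parse_label()) return(FALSE)
    if (pos <= length(chars) && chars[pos] == "(") {
      pos <<- pos + 1L
      while (pos <= length(chars) && chars[pos] != ")") {
        if (!parse_desc()) return(FALSE)
      }
      if (pos > length(chars)) return(FALSE)
      pos <<- pos + 1L
    }
    TRUE
  }
  parse_desc() && pos == length(chars) + 1L
}

# the collation used throughout: mark-blind byte order, raw bytes as tie-break
collation_leq <- function(x, y) {
  kx <- gsub("-", "", x, fixed = TRUE); ky <- gsub("-", "", y, fixed = TRUE)
  u <- c(kx, ky); r <- match(u, sort(unique(u), method = "radix"))
  if (r[1L] != r[2L]) return(r[1L] < r[2L])
  u <- c(x, y); r <- match(u, sort(unique(u), method = "radix"))
  r[1L] <= r[2L]
}
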