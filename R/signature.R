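# Canonical signatures of stereoisomers.
#
# A stereoisomer is compared to others through a *set* of canonical strings:
# one string per symmetry operation of the coordination polyhedron, obtained
# by relabeling the donor-vertex assignment by that operation (improper
# operations additionally invert all tetrahedral parities) and canonicalizing
# the resulting vertex-colored molecular graph. Two stereoisomers are
# equivalent iff their signature sets share an element; the sets of two
# equivalent stereoisomers are in fact identical, so deduplication can key on
# the lexicographically smallest element.
#
# Canonicalization: BLISS canonical labeling (igraph) of a graph in which
# every bond is subdivided by a dummy vertex colored by bond order/dativeness,
# and every atom is colored by (element, charge, isotope, aromaticity, donor
# vertex label). Tetrahedral parities are appended in the canonical frame:
# each center's parity is re-expressed relative to the ascending canonical
# order of its four neighbors, which makes the string invariant under any
# atom renumbering.

sig_context <- function(graph) {
  stopifnot(inherits(graph, "cdn_complex_graph"))
  na <- n_atoms(graph)
  nb <- nrow(graph$bonds)
  edges <- matrix(0L, nrow = 2L * nb, ncol = 2L)
  for (k in seq_len(nb)) {
    d <- na + k
    edges[2L * k - 1L, ] <- c(graph$bonds$i[k], d)
    edges[2L * k, ] <- c(graph$bonds$j[k], d)
  }
  g <- igraph::make_empty_graph(n = na + nb, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  a <- graph$atoms
  atom_cols <- paste0("A|", a$element, "|", a$charge, "|", a$isotope, "|",
                      as.integer(a$arom))
  bond_cols <- paste0("B|", graph$bonds$order, "|", as.integer(graph$bonds$dative))
  list(graph = graph, g = g, na = na,
       base_cols = c(atom_cols, bond_cols),
       edge_ends = edges,
       donor_atoms = graph$donors$gatom,
       adj = adjacency_list(graph))
}

# canonical string for one donor-vertex assignment + parity assignment.
# donor_vertex: integer vector, one vertex index per donor label (in
# graph$donors order); parities: named integer vector (+1/-1), names are
# global atom indices of stereo-expanded donor atoms. Ligand-internal stereo
# stored on the graph is always included.
sig_string <- function(ctx, donor_vertex, parities = integer(), flip = FALSE) {
  cols <- ctx$base_cols
  cols[ctx$donor_atoms] <- paste0(cols[ctx$donor_atoms], "|D", donor_vertex)
  ranks <- match(cols, sort(unique(cols)))
  lab <- as.integer(igraph::canonical_permutation(ctx$g, colors = ranks)$labeling)
  vpart <- paste(cols[order(lab)], collapse = ";")
  e1 <- lab[ctx$edge_ends[, 1]]
  e2 <- lab[ctx$edge_ends[, 2]]
  lo <- pmin(e1, e2); hi <- pmax(e1, e2)
  ord <- order(lo, hi)
  epart <- paste(lo[ord], hi[ord], sep = "-", collapse = ";")

  stereo <- ctx$graph$stereo
  if (length(parities)) {
    for (nm in names(parities)) {
      center <- as.integer(nm)
      nb <- sort(ctx$adj[[center]])
      stereo[[length(stereo) + 1L]] <- list(center = center, nbrs = nb,
                                            parity = parities[[nm]])
    }
  }
  spart <- ""
  if (length(stereo)) {
    recs <- vapply(stereo, function(st) {
      p <- st$parity * (if (flip) -1L else 1L)
      canon_nbrs <- lab[st$nbrs]
      p <- p * perm_sign(order(canon_nbrs))
      sprintf("%d:%+d", lab[st$center], p)
    }, "")
    spart <- paste(recs[order(vapply(stereo, function(st) lab[st$center], 0L))],
                   collapse = ";")
  }
  paste(vpart, epart, spart, sep = "#")
}

adjacency_list <- function(mol) {
  adj <- vector("list", n_atoms(mol))
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# signature set of one stereomer under a symmetry group, with an optional
# shared memo environment mapping (vertex assignment, parities) -> string
sig_set <- function(ctx, arrangement, parities, group, memo = NULL) {
  out <- character(length(group$elements))
  for (k in seq_along(group$elements)) {
    e <- group$elements[[k]]
    dv <- e$perm[arrangement]
    flip <- e$improper
    key <- paste0(paste(dv, collapse = ","), "|",
                  paste(names(parities), parities * (if (flip) -1L else 1L),
                        collapse = ","))
    s <- if (!is.null(memo)) memo[[key]] else NULL
    if (is.null(s)) {
      s <- sig_string(ctx, dv, parities, flip)
      if (!is.null(memo)) memo[[key]] <- s
    }
    out[k] <- s
  }
  sort(unique(out))
}

#' Canonical signature set of a stereoisomer
#'
#' One canonical string per symmetry operation of the polyhedron, applied to
#' the donor-vertex labels (improper operations also invert tetrahedral
#' parities); duplicates collapse into a set. Relabeling the stereoisomer by
#' any group element leaves the set unchanged, and two stereoisomers are
#' equivalent iff their sets intersect.
#'
#' @param stereomer a `cdn_stereomer`
#' @param group a `cdn_symgroup` matching the stereomer's geometry
#' @return sorted character vector of canonical strings
#' @export
signature <- function(stereomer, group) {
  stopifnot(inherits(stereomer, "cdn_stereomer"))
  ctx <- sig_context(stereomer$graph)
  sig_set(ctx, stereomer$arrangement, stereomer$parities, group)
}
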