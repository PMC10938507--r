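# Feasibility filters: substructure rules that remove high-energy or
# nonlocalizable donor arrangements. Both rules are heuristics and can rule
# out isomers within ~10 kJ/mol of feasible ones, so each has an off switch
# and removed stereoisomers are always returned with their reasons.

#' Feasibility-filter configuration
#'
#' @param apply_trans_bidentate remove arrangements in which a short-linker
#'   bidentate chelate spans two trans vertices (rule 1)
#' @param apply_fac_rigid_tridentate remove arrangements in which a rigid
#'   tridentate ligand (terpyridine-like: all linker atoms aromatic or
#'   sp2-in-ring) sits facially (rule 2)
#' @param max_chelate_path_for_trans_ban largest number of linker atoms
#'   between the two donors for which the trans ban applies; the default 4
#'   bans trans chelation for rings of up to 6 members (metal + 2 donors + 4
#'   linkers), whose closure would force a near-linear donor-metal-donor
#'   fragment into a small ring
#' @return a `cdn_filter_config`
#' @export
filter_config <- function(apply_trans_bidentate = TRUE,
                          apply_fac_rigid_tridentate = TRUE,
                          max_chelate_path_for_trans_ban = 4L) {
  stopifnot(max_chelate_path_for_trans_ban >= 1L)
  structure(list(apply_trans_bidentate = isTRUE(apply_trans_bidentate),
                 apply_fac_rigid_tridentate = isTRUE(apply_fac_rigid_tridentate),
                 max_chelate_path_for_trans_ban =
                   as.integer(max_chelate_path_for_trans_ban)),
            class = "cdn_filter_config")
}

ligand_igraph <- function(mol) {
  g <- igraph::make_empty_graph(n = n_atoms(mol), directed = FALSE)
  if (nrow(mol$bonds)) {
    g <- igraph::add_edges(g, t(as.matrix(mol$bonds[, c("i", "j")])))
  }
  g
}

# linker atom count of the shortest through-ligand path between two donors
linker_path_length <- function(lig, a, b) {
  g <- ligand_igraph(lig$mol)
  p <- igraph::shortest_paths(g, a, b)$vpath[[1]]
  if (length(p) == 0L) return(Inf)
  length(p) - 2L
}

# structural rigidity: every atom interior to the donor-donor linker paths is
# aromatic or sp2 inside a ring
is_rigid_tridentate <- function(lig) {
  if (lig$denticity != 3L) return(FALSE)
  mol <- lig$mol
  g <- ligand_igraph(mol)
  igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  d <- lig$donors$atom
  pairs <- utils::combn(d, 2L)
  for (k in seq_len(ncol(pairs))) {
    others <- setdiff(d, pairs[, k])
    gg <- igraph::delete_vertices(g, as.character(others))
    sp <- suppressWarnings(
      igraph::shortest_paths(gg, as.character(pairs[1, k]),
                             as.character(pairs[2, k]))$vpath[[1]])
    if (length(sp) == 0L) next       # no path avoiding the third donor
    ids <- as.integer(names(sp))
    interior <- setdiff(ids, pairs[, k])
    if (length(interior) == 0L) next
    ok <- vapply(interior, function(a) {
      mol$atoms$arom[a] || atom_sp2_in_ring(mol, a)
    }, TRUE)
    if (!all(ok)) return(FALSE)
  }
  TRUE
}

# sp2 (carries a double bond) and member of a ring
atom_sp2_in_ring <- function(mol, a) {
  has_double <- any((mol$bonds$i == a | mol$bonds$j == a) & mol$bonds$order >= 2)
  if (!has_double) return(FALSE)
  g <- ligand_igraph(mol)
  # atom is in a ring iff removing it does not disconnect all its neighbors
  # (cheap test: edge count >= vertex count within its component, checked via
  # igraph coreness)
  igraph::coreness(g)[a] >= 2
}

#' Remove trans-spanning short bidentate chelates (rule 1)
#'
#' A bidentate ligand whose two donors sit on trans vertices would close a
#' small chelate ring across a near-linear donor-metal-donor fragment; such
#' arrangements are removed when the through-ligand linker path is at most
#' `max_chelate_path_for_trans_ban` atoms.
#'
#' @param stereomers list of `cdn_stereomer`
#' @param config a [filter_config()]
#' @return `list(kept = , removed = , reasons = )`; with the rule switched
#'   off nothing is removed
#' @export
filter_trans_bidentate <- function(stereomers, config = filter_config()) {
  run_filter(stereomers, function(s) {
    if (!config$apply_trans_bidentate) return(NA_character_)
    defn <- s$defn
    dt <- defn$donor_table
    for (li in seq_along(defn$ligands)) {
      lig <- defn$ligands[[li]]
      if (lig$denticity < 2L) next
      rows <- which(dt$ligand == li)
      verts <- s$arrangement[dt$label[rows]]
      pairs <- utils::combn(seq_along(rows), 2L)
      for (k in seq_len(ncol(pairs))) {
        v1 <- verts[pairs[1, k]]; v2 <- verts[pairs[2, k]]
        if (vertex_relation(defn$geometry, v1, v2) != "trans") next
        np <- linker_path_length(lig, dt$atom[rows[pairs[1, k]]],
                                 dt$atom[rows[pairs[2, k]]])
        if (np <= config$max_chelate_path_for_trans_ban) {
          return(sprintf(
            "trans-bidentate: ligand %d donors on trans vertices %d,%d with %d-atom linker",
            li, v1, v2, np))
        }
      }
    }
    NA_character_
  })
}

#' Remove facially arranged rigid tridentate ligands (rule 2)
#'
#' A rigid tridentate ligand (all donor-donor linker atoms aromatic or
#' sp2-in-ring, as in terpyridines) cannot fold into a facial arrangement;
#' fac placements of such ligands are removed.
#'
#' @inheritParams filter_trans_bidentate
#' @return `list(kept = , removed = , reasons = )`
#' @export
filter_fac_rigid_tridentate <- function(stereomers, config = filter_config()) {
  run_filter(stereomers, function(s) {
    if (!config$apply_fac_rigid_tridentate) return(NA_character_)
    defn <- s$defn
    dt <- defn$donor_table
    for (li in seq_along(defn$ligands)) {
      lig <- defn$ligands[[li]]
      if (lig$denticity != 3L) next
      if (!is_rigid_tridentate(lig)) next
      verts <- s$arrangement[dt$label[dt$ligand == li]]
      pairs <- utils::combn(verts, 2L)
      any_trans <- any(vertex_relation(defn$geometry, pairs[1, ], pairs[2, ]) == "trans")
      if (!any_trans) {
        return(sprintf("fac-rigid-tridentate: ligand %d facially arranged on vertices %s",
                       li, paste(sort(verts), collapse = ",")))
      }
    }
    NA_character_
  })
}

run_filter <- function(stereomers, reason_fun) {
  reasons <- vapply(stereomers, reason_fun, "")
  removed <- which(!is.na(reasons))
  list(kept = stereomers[setdiff(seq_along(stereomers), removed)],
       removed = stereomers[removed],
       reasons = reasons[removed])
}

# apply both rules; kept set is order-independent because each rule decides
# per-stereomer
apply_filters <- function(stereomers, config = filter_config()) {
  f1 <- filter_trans_bidentate(stereomers, config)
  f2 <- filter_fac_rigid_tridentate(f1$kept, config)
  list(kept = f2$kept,
       removed = c(f1$removed, f2$removed),
       reasons = c(f1$reasons, f2$reasons))
}
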