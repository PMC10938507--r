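# Stereoisomer enumeration: raw donor placements on polyhedron vertices,
# expansion of donor-atom stereocenters, and deduplication via canonical
# signature sets under the polyhedron symmetry group.

new_stereomer <- function(defn, graph, arrangement, parities = integer()) {
  structure(list(defn = defn, graph = graph,
                 arrangement = as.integer(arrangement),
                 parities = parities, signature = NULL),
            class = "cdn_stereomer")
}

#' @export
print.cdn_stereomer <- function(x, ...) {
  cat(sprintf("<cdn_stereomer> %s %s%+d: donors on vertices [%s]%s\n",
              x$defn$geometry, x$defn$metal, x$defn$metal_charge,
              paste(x$arrangement, collapse = ","),
              if (length(x$parities))
                paste0(", parities ", paste(names(x$parities), x$parities,
                                            sep = ":", collapse = " "))
              else ""))
  invisible(x)
}

#' Enumerate all raw donor placements
#'
#' Every bijection of the donor labels onto the polyhedron vertices, before
#' any symmetry reduction: 720 placements for 6 donors on an octahedron, 24
#' for 4 donors on a square plane. In fixed-stereochemistry mode the single
#' requested placement (map number = vertex index) is returned.
#'
#' @param defn a `cdn_complex`
#' @return list of `cdn_stereomer` objects (no stereocenter expansion yet)
#' @export
enumerate_raw_arrangements <- function(defn) {
  stopifnot(inherits(defn, "cdn_complex"))
  graph <- build_graph(defn)
  pinned <- fixed_parities(graph)
  if (defn$fixed) {
    arr <- defn$donor_table$map
    return(list(new_stereomer(defn, graph, arr, pinned)))
  }
  nv <- if (defn$geometry == "OH") 6L else 4L
  perms <- all_permutations(nv)
  lapply(seq_len(nrow(perms)), function(k)
    new_stereomer(defn, graph, perms[k, ], pinned))
}

# parities of isotope-pinned donors, as a named vector keyed by global atom
fixed_parities <- function(graph) {
  d <- graph$donors
  sel <- !is.na(d$pinned)
  if (!any(sel)) return(integer())
  stats::setNames(as.integer(d$pinned[sel]), as.character(d$gatom[sel]))
}

# donor atoms that may become tetrahedral stereocenters on coordination:
# 4-coordinate (counting the metal), not pinned, and without two identical
# single-atom substituents (e.g. the two H of a primary amine)
candidate_stereo_donors <- function(graph) {
  adj <- adjacency_list(graph)
  deg <- lengths(adj)
  out <- integer()
  for (r in seq_len(nrow(graph$donors))) {
    a <- graph$donors$gatom[r]
    if (!is.na(graph$donors$pinned[r])) next
    nb <- adj[[a]]
    if (length(nb) != 4L) next
    leaves <- nb[deg[nb] == 1L & nb != graph$metal]
    if (anyDuplicated(graph$atoms$element[leaves])) next
    out <- c(out, a)
  }
  out
}

# all parity combinations over the candidate donors of one stereomer
expand_all_parities <- function(stereomer, candidates) {
  if (length(candidates) == 0L) return(list(stereomer))
  combos <- expand.grid(rep(list(c(1L, -1L)), length(candidates)))
  lapply(seq_len(nrow(combos)), function(k) {
    p <- stats::setNames(as.integer(combos[k, ]), as.character(candidates))
    s <- stereomer
    s$parities <- c(stereomer$parities, p)
    s
  })
}

#' Expand donor-atom stereocenters of a stereoisomer
#'
#' A donor atom that is four-coordinate after coordination (counting the
#' metal) can be a genuine tetrahedral stereocenter, as for a coordinated
#' secondary amine. For each such unpinned donor both configurations are
#' generated, and the two are kept only if they are genuinely distinct under
#' the symmetry group (signature sets disjoint); isotope-pinned donors keep
#' their configuration and non-stereogenic donors yield a single variant.
#'
#' @param stereomer a `cdn_stereomer` with its arrangement assigned
#' @param group symmetry group used for the distinctness check; defaults to
#'   the rotation group of the stereomer's geometry
#' @return list of `cdn_stereomer` objects
#' @export
expand_donor_stereocenters <- function(stereomer, group = NULL) {
  stopifnot(inherits(stereomer, "cdn_stereomer"))
  if (is.null(group)) group <- rotation_group(stereomer$defn$geometry)
  ctx <- sig_context(stereomer$graph)
  memo <- new.env(hash = TRUE)
  candidates <- candidate_stereo_donors(stereomer$graph)
  out <- list(stereomer)
  for (a in candidates) {
    nxt <- list()
    for (s in out) {
      plus <- s; plus$parities <- c(s$parities, stats::setNames(1L, as.character(a)))
      minus <- s; minus$parities <- c(s$parities, stats::setNames(-1L, as.character(a)))
      sp <- sig_set(ctx, plus$arrangement, plus$parities, group, memo)
      sm <- sig_set(ctx, minus$arrangement, minus$parities, group, memo)
      if (length(intersect(sp, sm))) {
        plus$signature <- sp
        nxt[[length(nxt) + 1L]] <- plus
      } else {
        plus$signature <- sp; minus$signature <- sm
        nxt[[length(nxt) + 1L]] <- plus
        nxt[[length(nxt) + 1L]] <- minus
      }
    }
    out <- nxt
  }
  out
}

#' Deduplicate stereoisomers via signature-set orbits
#'
#' Groups stereoisomers whose canonical signature sets intersect (equivalently
#' coincide) and keeps one deterministic representative per class: the member
#' whose identity-operation canonical string is lexicographically smallest.
#'
#' @param stereomers list of `cdn_stereomer` sharing one complex definition
#' @param group a `cdn_symgroup`; include reflections to merge enantiomers
#' @return list of representative `cdn_stereomer`s, each carrying its
#'   signature set and a `class_size` field
#' @export
deduplicate <- function(stereomers, group) {
  if (length(stereomers) == 0L) return(stereomers)
  ctx <- sig_context(stereomers[[1L]]$graph)
  memo <- new.env(hash = TRUE)
  sigs <- lapply(stereomers, function(s) {
    if (!is.null(s$signature) && !group$includes_reflections) s$signature
    else sig_set(ctx, s$arrangement, s$parities, group, memo)
  })
  own <- vapply(stereomers, function(s)
    sig_string(ctx, s$arrangement, s$parities), "")
  keys <- vapply(sigs, `[[`, "", 1L)   # sets are sorted; min element keys the class
  classes <- split(seq_along(stereomers), keys)
  reps <- lapply(classes, function(idx) {
    best <- idx[order(own[idx])][1L]
    r <- stereomers[[best]]
    r$signature <- sigs[[best]]
    r$class_size <- length(idx)
    r
  })
  reps <- reps[order(vapply(reps, function(r) min(which(keys == r$signature[1L])), 0L))]
  names(reps) <- NULL
  reps
}

#' Classify the donor arrangement of a stereoisomer
#'
#' Tridentate ligands are labeled `fac` (all three donors mutually cis) or
#' `mer` (two donors trans). A bidentate-coordinated pincer is labeled `bi`
#' when a side arm is decoordinated and `bic` when the central donor is
#' decoordinated, inferred from which potential donor heteroatom carries no
#' mark. Complexes of only monodentate ligands are labeled by the cis/trans
#' (or fac/mer) pattern of their repeated ligands; patterns with no defined
#' label give `"unclassified"`.
#'
#' @param stereomer a `cdn_stereomer`
#' @return a configuration label string
#' @export
classify_arrangement <- function(stereomer) {
  defn <- stereomer$defn
  geom <- defn$geometry
  arr <- stereomer$arrangement
  dt <- defn$donor_table
  labels <- character()
  for (li in seq_along(defn$ligands)) {
    lig <- defn$ligands[[li]]
    verts <- arr[dt$label[dt$ligand == li]]
    if (lig$denticity >= 3L) {
      pairs <- utils::combn(verts, 2L)
      any_trans <- any(vertex_relation(geom, pairs[1, ], pairs[2, ]) == "trans")
      labels <- c(labels, if (any_trans) "mer" else "fac")
    } else if (lig$denticity == 2L) {
      mode <- pincer_bidentate_mode(lig)
      if (!is.na(mode)) labels <- c(labels, mode)
    }
  }
  if (length(labels)) return(paste(labels, collapse = "-"))
  # monodentate-only patterns
  if (all(vapply(defn$ligands, `[[`, 0L, "denticity") == 1L)) {
    types <- vapply(defn$ligands, `[[`, "", "smiles")
    tab <- table(types)
    if (any(tab == 2L) && all(tab %in% c(1L, 2L, 4L))) {
      t2 <- sort(names(tab)[tab == 2L])
      rel <- vapply(t2, function(ty) {
        verts <- arr[dt$label[types[dt$ligand] == ty]]
        vertex_relation(geom, verts[1], verts[2])
      }, "")
      return(paste(unique(rel), collapse = "-"))
    }
    if (length(tab) == 2L && all(tab == 3L) && geom == "OH") {
      verts <- arr[dt$label[types[dt$ligand] == names(tab)[1L]]]
      pairs <- utils::combn(verts, 2L)
      any_trans <- any(vertex_relation(geom, pairs[1, ], pairs[2, ]) == "trans")
      return(if (any_trans) "mer" else "fac")
    }
  }
  "unclassified"
}

# bi (arm decoordinated) vs bic (central donor decoordinated) for a ligand
# with two marked donors and at least one unmarked donor-capable heteroatom
pincer_bidentate_mode <- function(lig) {
  mol <- lig$mol
  g <- igraph::graph_from_edgelist(as.matrix(mol$bonds[, c("i", "j")]),
                                   directed = FALSE)
  if (igraph::vcount(g) < n_atoms(mol)) {
    g <- igraph::add_vertices(g, n_atoms(mol) - igraph::vcount(g))
  }
  d <- lig$donors$atom
  cand <- setdiff(which(mol$atoms$element %in% c("N", "P", "S", "O", "As")),
                  d)
  if (length(cand) == 0L) return(NA_character_)
  path <- as.integer(igraph::shortest_paths(g, d[1], d[2])$vpath[[1]])
  interior <- setdiff(path, d)
  if (any(cand %in% interior)) return("bic")
  for (u in cand) {
    p1 <- as.integer(igraph::shortest_paths(g, u, d[1])$vpath[[1]])
    p2 <- as.integer(igraph::shortest_paths(g, u, d[2])$vpath[[1]])
    if (d[2] %in% p1 || d[1] %in% p2) return("bi")
  }
  NA_character_
}

#' Enumerate the distinct stereoisomers of a complex
#'
#' The full pipeline: all raw donor placements, expansion of donor-atom
#' stereocenters, deduplication through canonical signature sets under the
#' polyhedron symmetry group (optionally merging enantiomers via improper
#' operations), and feasibility filtering.
#'
#' @param defn a `cdn_complex` from [assemble_complex()]
#' @param merge_enantiomers merge mirror-image stereoisomers (useful when the
#'   complexes will be treated in an achiral environment); default `FALSE`
#' @param filters a [filter_config()]; set rules to `FALSE` to keep
#'   chemically strained arrangements
#' @return a tibble with one row per distinct stereoisomer: `id`, `label`
#'   (fac/mer/cis/trans/bi/bic classification), `kept`, `removed_reason`, and
#'   a `stereomer` list-column. Pipeline stage counts (raw, expanded,
#'   deduplicated, kept) are attached as attribute `"counts"`.
#' @examples
#' \donttest{
#' lig <- generate_fixtures("monodentate")[1:4]
#' defn <- assemble_complex("Pd2+", "SP", as.list(lig))
#' enumerate_stereomers(defn)
#' }
#' @export
enumerate_stereomers <- function(defn, merge_enantiomers = FALSE,
                                 filters = filter_config()) {
  stopifnot(inherits(defn, "cdn_complex"))
  group <- rotation_group(defn$geometry, include_reflections = merge_enantiomers)
  raw <- enumerate_raw_arrangements(defn)
  graph <- raw[[1L]]$graph
  candidates <- candidate_stereo_donors(graph)
  expanded <- unlist(lapply(raw, expand_all_parities, candidates = candidates),
                     recursive = FALSE)
  uniq <- deduplicate(expanded, group)
  for (k in seq_along(uniq)) uniq[[k]]$uid <- k
  filt <- apply_filters(uniq, filters)
  kept_ids <- vapply(filt$kept, function(s) s$uid, 0L)
  n <- length(uniq)
  reasons <- rep(NA_character_, n)
  for (r in seq_along(filt$removed)) {
    reasons[filt$removed[[r]]$uid] <- filt$reasons[r]
  }
  tib <- tibble::tibble(
    id = seq_len(n),
    label = vapply(uniq, classify_arrangement, ""),
    kept = seq_len(n) %in% kept_ids,
    removed_reason = reasons,
    stereomer = uniq
  )
  attr(tib, "counts") <- c(raw = length(raw), expanded = length(expanded),
                           deduplicated = n, kept = sum(tib$kept))
  tib
}
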