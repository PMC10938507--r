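# 3D structure generation: distance-bounds construction with metal-center
# constraints, metric-matrix distance-geometry embedding, arrangement
# verification, and relaxation with a harmonic force field supplemented for
# dative bonds (stretch equilibria from covalent radii, ideal-geometry angles
# at the metal, zero torsional barriers across dative bonds).

#' Embedding and relaxation parameters
#'
#' @param metal_donor_tol fractional tolerance on the metal-donor target
#'   distance (sum of covalent radii); default 10 percent
#' @param bond_tol fractional tolerance on ordinary bond lengths
#' @param angle_tol fractional tolerance on 1-3 distances
#' @param angle_threshold donor-metal-donor angle (degrees) separating cis
#'   from trans classifications during verification
#' @param max_retries re-seeded embedding attempts per requested conformer
#'   before the stereoisomer is declared nonlocalizable
#' @param chiral_weight penalty weight of tetrahedral-parity constraints
#' @return list of parameters
#' @export
embed_params <- function(metal_donor_tol = 0.10, bond_tol = 0.04,
                         angle_tol = 0.08, angle_threshold = 135,
                         max_retries = 10L, chiral_weight = 10) {
  list(metal_donor_tol = metal_donor_tol, bond_tol = bond_tol,
       angle_tol = angle_tol, angle_threshold = angle_threshold,
       max_retries = as.integer(max_retries), chiral_weight = chiral_weight)
}

# idealized bond angle at an atom from its bond pattern
hybrid_angle <- function(mol, a) {
  if (mol$atoms$arom[a]) return(120)
  sel <- mol$bonds$i == a | mol$bonds$j == a
  orders <- mol$bonds$order[sel & !mol$bonds$dative]
  if (any(orders == 3) || sum(orders == 2) >= 2) return(180)
  if (any(orders == 2)) return(120)
  109.47
}

# law of cosines for the 1-3 distance across an apex angle (degrees)
d13 <- function(a, b, theta) sqrt(a^2 + b^2 - 2 * a * b * cos(theta * pi / 180))

# chirality constraint rows (n1..n4, sign, vmin) for ligand-internal stereo
# plus donor-atom parities; volume is det[n2-n1, n3-n1, n4-n1] over the
# neighbors in ascending-index order, and parity +1 demands a negative volume
chiral_rows <- function(graph, parities, vmin = 0.5) {
  adj <- adjacency_list(graph)
  rows <- list()
  for (st in graph$stereo) {
    nb <- st$nbrs
    # re-express parity for ascending neighbor order
    p <- st$parity * perm_sign(order(nb))
    rows[[length(rows) + 1L]] <- c(sort(nb), -p, vmin)
  }
  for (nm in names(parities)) {
    a <- as.integer(nm)
    nb <- sort(adj[[a]])
    rows[[length(rows) + 1L]] <- c(nb, -parities[[nm]], vmin)
  }
  if (length(rows) == 0L) return(matrix(0, 0, 6))
  do.call(rbind, rows)
}

#' Distance-bounds specification for a stereoisomer
#'
#' Metal-donor pairs are constrained to the sum of the covalent radii (within
#' `metal_donor_tol`); donor-donor pairs get the cis (`sqrt(d1^2+d2^2)`) or
#' trans (`d1+d2`) target implied by their vertices; bonded and 1-3 pairs get
#' covalent-geometry targets, and all remaining pairs generic lower bounds.
#' The matrices are triangle-smoothed before use.
#'
#' @param stereomer a `cdn_stereomer` with its arrangement fixed
#' @param params [embed_params()]
#' @return list with bounds matrices `L`, `U`, chirality constraints, and a
#'   `feasible` flag (FALSE when the smoothed bounds are contradictory)
#' @export
build_bounds <- function(stereomer, params = embed_params()) {
  graph <- stereomer$graph
  n <- n_atoms(graph)
  el <- graph$atoms$element
  rad <- covalent_radius(el)
  adj <- adjacency_list(graph)

  L <- outer(rad, rad, function(a, b) 0.8 * (a + b) + 0.5)
  U <- matrix(999, n, n)
  diag(L) <- 0; diag(U) <- 0

  r0 <- matrix(NA_real_, n, n)
  for (k in seq_len(nrow(graph$bonds))) {
    i <- graph$bonds$i[k]; j <- graph$bonds$j[k]
    t0 <- rad[i] + rad[j]
    tol <- if (graph$bonds$dative[k]) params$metal_donor_tol else params$bond_tol
    r0[i, j] <- t0; r0[j, i] <- t0
    L[i, j] <- L[j, i] <- t0 * (1 - tol)
    U[i, j] <- U[j, i] <- t0 * (1 + tol)
  }

  arr <- stereomer$arrangement
  donor_vertex <- integer(n)
  donor_vertex[graph$donors$gatom] <- arr[graph$donors$label]
  geom <- graph$geometry

  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) < 2L) next
    prs <- utils::combn(nb, 2L)
    for (q in seq_len(ncol(prs))) {
      i <- prs[1, q]; k <- prs[2, q]
      theta <- if (j == graph$metal) {
        if (vertex_relation(geom, donor_vertex[i], donor_vertex[k]) == "trans") 180 else 90
      } else {
        hybrid_angle(graph, j)
      }
      t0 <- d13(r0[i, j], r0[k, j], theta)
      tol <- params$angle_tol
      lo <- t0 * (1 - tol); hi <- t0 * (1 + tol)
      if (lo > L[i, k]) { L[i, k] <- lo; L[k, i] <- lo }
      if (hi < U[i, k]) { U[i, k] <- hi; U[k, i] <- hi }
    }
  }

  sm <- cpp_smooth_bounds(L, U)
  list(L = sm$L, U = sm$U, feasible = sm$feasible,
       chiral = chiral_rows(graph, stereomer$parities),
       natoms = n, params = params)
}

# metric-matrix embedding of one random distance sample
dg_initial_coords <- function(bounds) {
  n <- bounds$natoms
  D <- bounds$L
  w <- matrix(stats::runif(n * n), n, n)
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  D <- bounds$L + w * (bounds$U - bounds$L)
  D[cbind(seq_len(n), seq_len(n))] <- 0
  D2 <- D^2
  Jc <- diag(n) - 1 / n
  B <- -0.5 * Jc %*% D2 %*% Jc
  e <- eigen(B, symmetric = TRUE)
  X <- e$vectors[, 1:3] %*% diag(sqrt(pmax(e$values[1:3], 1e-4)))
  X
}

refine_against_bounds <- function(X, bounds) {
  n <- bounds$natoms
  fn <- function(p) cpp_dg_error(p, bounds$L, bounds$U, bounds$chiral,
                                 bounds$params$chiral_weight)$f
  gr <- function(p) cpp_dg_error(p, bounds$L, bounds$U, bounds$chiral,
                                 bounds$params$chiral_weight)$g
  res <- stats::optim(as.vector(X), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = 600))
  matrix(res$par, n, 3)
}

coords_ok_parities <- function(coords, bounds) {
  ch <- bounds$chiral
  if (nrow(ch) == 0L) return(TRUE)
  for (r in seq_len(nrow(ch))) {
    v <- det(rbind(coords[ch[r, 2], ] - coords[ch[r, 1], ],
                   coords[ch[r, 3], ] - coords[ch[r, 1], ],
                   coords[ch[r, 4], ] - coords[ch[r, 1], ]))
    if (sign(v) != sign(ch[r, 5]) || abs(v) < 1e-3) return(FALSE)
  }
  TRUE
}

new_conformer <- function(stereomer, coords, energy, seed) {
  structure(list(elements = stereomer$graph$atoms$element,
                 coords = coords, energy = energy,
                 stereomer = stereomer, seed = seed, verified = TRUE),
            class = "cdn_conformer")
}

#' @export
print.cdn_conformer <- function(x, ...) {
  cat(sprintf("<cdn_conformer> %d atoms, energy %.3f (seed %d)\n",
              length(x$elements), x$energy, x$seed))
  invisible(x)
}

#' Verify the realized donor arrangement of a conformer
#'
#' Each donor-metal-donor angle is classified cis (below `angle_threshold`
#' degrees) or trans (at or above it) and compared with the classification
#' implied by the intended vertex assignment; verification passes only if
#' every pair agrees.
#'
#' @param conformer a `cdn_conformer` (or any list with `coords` and a
#'   `stereomer`)
#' @param arrangement optional explicit vertex assignment; defaults to the
#'   conformer's parent stereoisomer
#' @param angle_threshold degrees; default 135 (midpoint of the ideal 90/180)
#' @return logical
#' @export
verify_arrangement <- function(conformer, arrangement = NULL,
                               angle_threshold = 135) {
  s <- conformer$stereomer
  graph <- s$graph
  if (is.null(arrangement)) arrangement <- s$arrangement
  coords <- conformer$coords
  m <- coords[graph$metal, ]
  d <- graph$donors
  if (nrow(d) < 2L) return(TRUE)
  prs <- utils::combn(seq_len(nrow(d)), 2L)
  for (q in seq_len(ncol(prs))) {
    a <- d$gatom[prs[1, q]]; b <- d$gatom[prs[2, q]]
    va <- coords[a, ] - m; vb <- coords[b, ] - m
    ang <- acos(pmin(1, pmax(-1, sum(va * vb) /
                               (sqrt(sum(va^2)) * sqrt(sum(vb^2)))))) * 180 / pi
    got <- if (ang >= angle_threshold) "trans" else "cis"
    want <- vertex_relation(graph$geometry,
                            arrangement[d$label[prs[1, q]]],
                            arrangement[d$label[prs[2, q]]])
    if (got != want) return(FALSE)
  }
  TRUE
}

# force-field term construction for one stereomer
ff_terms <- function(stereomer, params = embed_params()) {
  graph <- stereomer$graph
  n <- n_atoms(graph)
  rad <- covalent_radius(graph$atoms$element)
  adj <- adjacency_list(graph)
  arr <- stereomer$arrangement
  donor_vertex <- integer(n)
  donor_vertex[graph$donors$gatom] <- arr[graph$donors$label]

  b <- graph$bonds
  bonds <- cbind(b$i, b$j, rad[b$i] + rad[b$j], ifelse(b$dative, 150, 300))

  ang <- list()
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) < 2L) next
    prs <- utils::combn(nb, 2L)
    for (q in seq_len(ncol(prs))) {
      i <- prs[1, q]; k <- prs[2, q]
      if (j == graph$metal) {
        theta <- if (vertex_relation(graph$geometry, donor_vertex[i],
                                     donor_vertex[k]) == "trans") 180 else 90
        kth <- 100
      } else {
        theta <- hybrid_angle(graph, j)
        kth <- if (graph$metal %in% c(i, k)) 30 else 50
      }
      ang[[length(ang) + 1L]] <- c(i, j, k, theta * pi / 180, kth)
    }
  }
  angles <- if (length(ang)) do.call(rbind, ang) else matrix(0, 0, 5)

  # nonbonded repulsion between atoms >= 3 bonds apart
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, t(as.matrix(b[, c("i", "j")])))
  hops <- igraph::distances(g)
  far <- which(hops >= 3 & upper.tri(hops), arr.ind = TRUE)
  nbm <- if (nrow(far)) {
    cbind(far[, 1], far[, 2],
          1.1 * (rad[far[, 1]] + rad[far[, 2]]) + 0.6, 25)
  } else matrix(0, 0, 4)

  # planarity restraints on aromatic/sp2 atoms with three neighbors
  pl <- list()
  for (a in seq_len(n)) {
    if (length(adj[[a]]) != 3L) next
    sp2 <- graph$atoms$arom[a] ||
      any((b$i == a | b$j == a) & b$order == 2 & !b$dative)
    if (sp2) pl[[length(pl) + 1L]] <- c(a, adj[[a]], 40)
  }
  planar <- if (length(pl)) do.call(rbind, pl) else matrix(0, 0, 5)

  list(bonds = bonds, angles = angles, nb = nbm,
       chiral = chiral_rows(graph, stereomer$parities),
       planar = planar, natoms = n, params = params)
}

ff_value <- function(p, terms) {
  cpp_ff_energy(p, terms$bonds, terms$angles, terms$nb, terms$chiral,
                terms$params$chiral_weight * 50, terms$planar, terms$natoms)
}

#' Relax a conformer with the dative-supplemented harmonic force field
#'
#' Bond stretches use covalent-radius equilibria (dative metal-donor bonds
#' get their own generic force constant), angles at the metal use the ideal
#' 90/180-degree equilibria implied by the vertex arrangement, torsions
#' across dative bonds carry no barrier, and tetrahedral parities are held by
#' signed-volume restraints. The minimized energy is never above the input
#' energy, and the donor arrangement is re-verified afterwards; a conformer
#' failing re-verification is returned with `verified = FALSE`.
#'
#' @param conformer a `cdn_conformer`
#' @param params [embed_params()]
#' @return the relaxed `cdn_conformer` (field `energy` updated; the
#'   pre-relaxation energy is kept as `energy_initial`)
#' @export
relax <- function(conformer, params = embed_params()) {
  s <- conformer$stereomer
  terms <- tryCatch(ff_terms(s, params), error = function(e) NULL)
  frozen <- FALSE
  if (is.null(terms)) {
    # fall back to a constrained relaxation with the metal frozen and
    # stretch terms only
    frozen <- TRUE
    graph <- s$graph
    rad <- covalent_radius(ifelse(graph$atoms$element %in%
                                    names(.covalent_radius),
                                  graph$atoms$element, "C"))
    b <- graph$bonds
    terms <- list(bonds = cbind(b$i, b$j, rad[b$i] + rad[b$j], 300),
                  angles = matrix(0, 0, 5), nb = matrix(0, 0, 4),
                  chiral = matrix(0, 0, 6), planar = matrix(0, 0, 5),
                  natoms = n_atoms(graph), params = params)
    message("force-field setup failed; relaxing with metal frozen")
  }
  n <- terms$natoms
  metal <- s$graph$metal
  p0 <- as.vector(conformer$coords)
  e0 <- ff_value(p0, terms)$f
  fn <- function(p) ff_value(p, terms)$f
  gr <- function(p) {
    g <- ff_value(p, terms)$g
    if (frozen) g[c(metal, metal + n, metal + 2 * n)] <- 0
    g
  }
  res <- stats::optim(p0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = 500))
  out <- conformer
  out$coords <- matrix(res$par, n, 3)
  out$energy_initial <- e0
  out$energy <- min(res$value, e0)
  if (res$value > e0) out$coords <- conformer$coords  # minimizer must not go uphill
  out$verified <- verify_arrangement(out, angle_threshold = params$angle_threshold)
  out
}

#' Embed a stereoisomer into 3D conformers
#'
#' Bounds-matrix distance geometry with metal-center constraints: random
#' distances are drawn within the smoothed bounds, embedded via the metric
#' matrix, refined against the bounds (with tetrahedral-parity restraints),
#' verified against the intended donor arrangement, relaxed, and re-verified.
#' Each requested conformer is retried with fresh sub-seeds up to
#' `params$max_retries` times; a stereoisomer yielding no verified conformer
#' is reported as nonlocalizable (attribute, not an error), mirroring the
#' interpretation that such configurations are exceptionally high in energy.
#'
#' @param stereomer a `cdn_stereomer`
#' @param n_conformers conformers to generate (default 5, the screening
#'   setting used for pincer complexes)
#' @param seed integer seed; the same (stereomer, seed) pair reproduces
#'   bitwise-identical coordinates
#' @param params [embed_params()]
#' @return list of verified `cdn_conformer`s; attribute `"nonlocalizable"`
#'   is TRUE when empty because embedding failed (with `"reason"` attached)
#' @export
embed <- function(stereomer, n_conformers = 5L, seed = 1L,
                  params = embed_params()) {
  stopifnot(inherits(stereomer, "cdn_stereomer"), n_conformers >= 1L)
  bounds <- build_bounds(stereomer, params)
  if (!bounds$feasible) {
    out <- list()
    attr(out, "nonlocalizable") <- TRUE
    attr(out, "reason") <- "contradictory distance bounds after smoothing"
    return(out)
  }
  out <- list()
  for (k in seq_len(n_conformers)) {
    conf <- NULL
    for (t in seq_len(bounds$params$max_retries)) {
      subseed <- (as.integer(seed) + 7919L * k + 104729L * t) %% 2147483629L
      set.seed(subseed)
      X <- dg_initial_coords(bounds)
      X <- refine_against_bounds(X, bounds)
      cand <- new_conformer(stereomer, X, NA_real_, subseed)
      if (!coords_ok_parities(X, bounds)) next
      if (!verify_arrangement(cand, angle_threshold = params$angle_threshold)) next
      cand <- relax(cand, params)
      if (!isTRUE(cand$verified)) next
      if (!coords_ok_parities(cand$coords, bounds)) next
      conf <- cand
      break
    }
    if (!is.null(conf)) out[[length(out) + 1L]] <- conf
  }
  if (length(out) == 0L) {
    attr(out, "nonlocalizable") <- TRUE
    attr(out, "reason") <- "no embedding attempt reproduced the intended arrangement"
  }
  out
}

#' Build 3D structures with fixed stereochemistry
#'
#' For a definition assembled with `fixed = TRUE`, where every donor's
#' atom-map number is an explicit octahedron (or square-plane) vertex index,
#' the single requested arrangement is embedded without any stereoisomer
#' search. Linear (2 donors) and square-pyramidal (5 donors) structures are
#' special cases of the octahedron; unoccupied vertices carry no constraint.
#'
#' @param defn a `cdn_complex` with `fixed = TRUE`
#' @inheritParams embed
#' @return list of `cdn_conformer`s as from [embed()]
#' @export
build_fixed <- function(defn, n_conformers = 5L, seed = 1L,
                        params = embed_params()) {
  stopifnot(inherits(defn, "cdn_complex"))
  if (!defn$fixed) stop("build_fixed() requires a definition assembled with fixed = TRUE")
  s <- enumerate_raw_arrangements(defn)[[1L]]
  embed(s, n_conformers = n_conformers, seed = seed, params = params)
}
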