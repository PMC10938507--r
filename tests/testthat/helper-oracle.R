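# Independent brute-force oracle for stereoisomer counting.
#
# Instead of canonical labeling, the oracle computes orbits of the explicit
# group action on raw donor placements: the polyhedron symmetry group acts on
# vertices (improper elements flip all donor parities), and graph
# automorphisms of the assembled complex (BLISS generators, closed by BFS)
# act on donor labels, transferring stereocenter parities with the sign of
# the induced neighbor permutation. Orbits are counted by breadth-first
# search over the full state space (all placements x all parity patterns).
# Ligand-internal stereocenters and isotope pins are outside the oracle's
# model; the property-test pool avoids them.

perm_sign_oracle <- function(p) {
  n <- length(p)
  visited <- logical(n)
  s <- 1L
  for (i in seq_len(n)) {
    if (!visited[i]) {
      j <- i; len <- 0L
      while (!visited[j]) { visited[j] <- TRUE; j <- p[j]; len <- len + 1L }
      if (len %% 2L == 0L) s <- -s
    }
  }
  s
}

# donor-label automorphism actions (label permutation + parity signs)
oracle_donor_actions <- function(graph) {
  na <- coordenum:::n_atoms(graph)
  nb <- nrow(graph$bonds)
  edges <- matrix(0L, 2L * nb, 2L)
  for (k in seq_len(nb)) {
    edges[2L * k - 1L, ] <- c(graph$bonds$i[k], na + k)
    edges[2L * k, ] <- c(graph$bonds$j[k], na + k)
  }
  g <- igraph::make_empty_graph(n = na + nb, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  a <- graph$atoms
  cols <- c(paste0("A|", a$element, "|", a$charge, "|", a$isotope, "|",
                   as.integer(a$arom)),
            paste0("B|", graph$bonds$order, "|", as.integer(graph$bonds$dative)))
  ranks <- match(cols, sort(unique(cols)))
  gens <- igraph::automorphism_group(g, colors = ranks)

  donors <- graph$donors$gatom
  k <- length(donors)
  cands <- coordenum:::candidate_stereo_donors(graph)
  adj <- coordenum:::adjacency_list(graph)

  induced <- function(vmap) {
    lperm <- match(vmap[donors], donors)
    if (any(is.na(lperm))) return(NULL)
    # signs are source-indexed: moving the parity of label l to slot
    # lperm[l] multiplies it by signs[l]
    signs <- rep(1L, k)
    for (l in seq_len(k)) {
      d <- donors[l]
      if (!(d %in% cands)) next
      nbo <- sort(adj[[d]])
      signs[l] <- perm_sign_oracle(order(vmap[nbo]))
    }
    list(lperm = lperm, signs = signs)
  }

  gen_acts <- list()
  for (gen in gens) {
    act <- induced(as.integer(gen))
    if (!is.null(act)) gen_acts[[length(gen_acts) + 1L]] <- act
  }
  # close under composition
  id <- list(lperm = seq_len(k), signs = rep(1L, k))
  acts <- list()
  seen <- new.env(hash = TRUE)
  queue <- c(list(id), gen_acts)
  while (length(queue)) {
    e <- queue[[1]]; queue <- queue[-1]
    key <- paste(c(e$lperm, e$signs), collapse = ",")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    acts[[length(acts) + 1L]] <- e
    for (gn in gen_acts) {
      # composition gn o e: the state transform is S'[lperm[l]] = S[l]*signs[l],
      # so (gn o e) sends S[l] to slot gn$lperm[e$lperm[l]] with the product
      # of the two transfer signs picked up along the way
      lp <- integer(k); sg <- rep(1L, k)
      for (l in seq_len(k)) {
        m <- e$lperm[l]
        lp[l] <- gn$lperm[m]
        sg[l] <- e$signs[l] * gn$signs[m]
      }
      queue[[length(queue) + 1L]] <- list(lperm = lp, signs = sg)
    }
  }
  acts
}

# orbit count of the explicit action on (placement, parity) states
oracle_orbit_count <- function(defn, merge_enantiomers = FALSE) {
  graph <- build_graph(defn)
  grp <- rotation_group(defn$geometry, include_reflections = merge_enantiomers)
  acts <- oracle_donor_actions(graph)
  donors <- graph$donors$gatom
  k <- length(donors)
  cands <- coordenum:::candidate_stereo_donors(graph)
  ci <- match(cands, donors)               # candidate labels
  nv <- if (defn$geometry == "OH") 6L else 4L
  placements <- coordenum:::all_permutations(nv)

  par_combos <- if (length(ci)) {
    as.matrix(expand.grid(rep(list(c(1L, -1L)), length(ci))))
  } else matrix(0L, 1, 0)

  state_key <- function(v, p) paste(c(v, p), collapse = ",")
  states <- new.env(hash = TRUE)
  all_states <- list()
  for (r in seq_len(nrow(placements))) {
    for (q in seq_len(nrow(par_combos))) {
      v <- placements[r, ]
      p <- rep(0L, k)
      if (length(ci)) p[ci] <- par_combos[q, ]
      all_states[[length(all_states) + 1L]] <- list(v = v, p = p)
    }
  }
  visited <- new.env(hash = TRUE)
  orbits <- 0L
  for (st in all_states) {
    k0 <- state_key(st$v, st$p)
    if (!is.null(visited[[k0]])) next
    orbits <- orbits + 1L
    queue <- list(st)
    visited[[k0]] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      succs <- list()
      for (ge in grp$elements) {
        v2 <- ge$perm[cur$v]
        p2 <- if (ge$improper) -cur$p else cur$p
        succs[[length(succs) + 1L]] <- list(v = v2, p = p2)
      }
      for (ac in acts) {
        v2 <- integer(k); p2 <- integer(k)
        for (l in seq_len(k)) {
          v2[ac$lperm[l]] <- cur$v[l]
          p2[ac$lperm[l]] <- cur$p[l] * ac$signs[l]
        }
        succs[[length(succs) + 1L]] <- list(v = v2, p = p2)
      }
      for (s2 in succs) {
        k2 <- state_key(s2$v, s2$p)
        if (is.null(visited[[k2]])) {
          visited[[k2]] <- TRUE
          queue[[length(queue) + 1L]] <- s2
        }
      }
    }
  }
  orbits
}

# Burnside count over the product group, valid when no stereocenters exist:
# orbits = average number of placements fixed by (g, a)
oracle_burnside_count <- function(defn) {
  graph <- build_graph(defn)
  stopifnot(length(coordenum:::candidate_stereo_donors(graph)) == 0L)
  grp <- rotation_group(defn$geometry)
  acts <- oracle_donor_actions(graph)
  donors <- graph$donors$gatom
  nv <- if (defn$geometry == "OH") 6L else 4L
  placements <- coordenum:::all_permutations(nv)
  total <- 0L
  for (ge in grp$elements) {
    for (ac in acts) {
      fixed <- 0L
      for (r in seq_len(nrow(placements))) {
        v <- placements[r, ]
        v2 <- integer(length(v))
        v2[ac$lperm] <- ge$perm[v]
        if (all(v2 == v)) fixed <- fixed + 1L
      }
      total <- total + fixed
    }
  }
  total / (length(grp$elements) * length(acts))
}
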