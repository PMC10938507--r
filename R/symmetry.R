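# Vertex conventions and symmetry groups of the coordination polyhedra.
#
# Octahedron: vertices 1..6 with trans pairs (1,6), (2,4), (3,5):
#   1 = +z, 6 = -z, 2 = +x, 4 = -x, 3 = +y, 5 = -y.
# Square plane: vertices 1..4 with trans pairs (1,3), (2,4):
#   1 = +x, 2 = +y, 3 = -x, 4 = -y.

vertex_coords <- function(geometry) {
  switch(geometry,
    OH = rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0),
               c(-1, 0, 0), c(0, -1, 0), c(0, 0, -1)),
    SP = rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0)),
    stop("unknown geometry '", geometry, "'"))
}

trans_pairs <- function(geometry) {
  switch(geometry,
    OH = rbind(c(1L, 6L), c(2L, 4L), c(3L, 5L)),
    SP = rbind(c(1L, 3L), c(2L, 4L)),
    stop("unknown geometry '", geometry, "'"))
}

# "cis" or "trans" for two distinct vertex indices (vectorized)
vertex_relation <- function(geometry, v1, v2) {
  tp <- trans_pairs(geometry)
  trans_keys <- paste(tp[, 1], tp[, 2])
  ifelse(paste(pmin(v1, v2), pmax(v1, v2)) %in% trans_keys, "trans", "cis")
}

compose_perm <- function(g, h) g[h]   # (g o h)(v) = g[h[v]]

perm_key <- function(perm, improper) paste0(paste(perm, collapse = ","),
                                            if (improper) "|i" else "|p")

close_group <- function(generators) {
  elems <- list()
  seen <- new.env(hash = TRUE)
  queue <- generators
  nv <- length(generators[[1]]$perm)
  id <- list(perm = seq_len(nv), improper = FALSE)
  queue <- c(list(id), queue)
  while (length(queue)) {
    e <- queue[[1]]
    queue <- queue[-1]
    k <- perm_key(e$perm, e$improper)
    if (!is.null(seen[[k]])) next
    seen[[k]] <- TRUE
    elems[[length(elems) + 1L]] <- e
    for (g in generators) {
      queue[[length(queue) + 1L]] <- list(
        perm = compose_perm(g$perm, e$perm),
        improper = xor(g$improper, e$improper))
    }
  }
  elems
}

#' Vertex-permutation symmetry group of a coordination polyhedron
#'
#' Builds the rotation group of the octahedron (24 vertex permutations) or of
#' the square plane (8 permutations) by closing a small generator set under
#' composition; the claimed order, closure and presence of inverses are
#' verified at construction time. With `include_reflections = TRUE`, improper
#' operations are added (used for enantiomer merging); improper elements are
#' flagged, since they additionally invert all tetrahedral parities. For the
#' square plane the improper operations realize the same 8 vertex
#' permutations (the out-of-plane mirror fixes every vertex), so only the
#' parity flag distinguishes them.
#'
#' @param geometry `"OH"` or `"SP"`
#' @param include_reflections add improper (mirror) operations
#' @return a `cdn_symgroup`: list of elements, each `list(perm, improper)`
#' @examples
#' length(rotation_group("OH")$elements)  # 24
#' length(rotation_group("SP")$elements)  # 8
#' @export
rotation_group <- function(geometry, include_reflections = FALSE) {
  geometry <- match.arg(geometry, c("OH", "SP"))
  gens <- if (geometry == "OH") {
    list(
      list(perm = c(1L, 3L, 4L, 5L, 2L, 6L), improper = FALSE),  # 90 deg about z
      list(perm = c(5L, 2L, 1L, 4L, 6L, 3L), improper = FALSE)   # 90 deg about x
    )
  } else {
    list(
      list(perm = c(2L, 3L, 4L, 1L), improper = FALSE),          # 90 deg in plane
      list(perm = c(1L, 4L, 3L, 2L), improper = FALSE)           # C2 through 1,3
    )
  }
  if (include_reflections) {
    mirror <- if (geometry == "OH") {
      list(perm = c(6L, 2L, 3L, 4L, 5L, 1L), improper = TRUE)    # z -> -z
    } else {
      list(perm = seq_len(4L), improper = TRUE)                  # out-of-plane mirror
    }
    gens <- c(gens, list(mirror))
  }
  elems <- close_group(gens)
  expected <- if (geometry == "OH") 24L else 8L
  if (include_reflections) expected <- expected * 2L
  if (length(elems) != expected) {
    stop("symmetry group construction failed: got ", length(elems),
         " elements, expected ", expected)
  }
  # sanity: closure and inverses
  keys <- vapply(elems, function(e) perm_key(e$perm, e$improper), "")
  for (e in elems) {
    inv <- order(e$perm)
    if (!(perm_key(inv, e$improper) %in% keys)) stop("group lacks an inverse")
  }
  structure(list(geometry = geometry, elements = elems,
                 includes_reflections = include_reflections),
            class = "cdn_symgroup")
}

#' Distinct vertex permutations of a symmetry group
#'
#' @param group a `cdn_symgroup`
#' @return matrix with one row per distinct vertex permutation
#' @export
group_permutations <- function(group) {
  m <- do.call(rbind, lapply(group$elements, `[[`, "perm"))
  unique(m)
}

#' @export
print.cdn_symgroup <- function(x, ...) {
  cat(sprintf("<cdn_symgroup> %s: %d elements (%d distinct vertex permutations)%s\n",
              x$geometry, length(x$elements), nrow(group_permutations(x)),
              if (x$includes_reflections) ", reflections included" else ""))
  invisible(x)
}

# all permutations of 1..n as a matrix (n! rows); n <= 7 in practice
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 0L
  for (pos in seq_len(n)) {
    for (k in seq_len(nrow(sub))) {
      r <- r + 1L
      row <- integer(n)
      row[pos] <- n
      row[-pos] <- sub[k, ]
      out[r, ] <- row
    }
  }
  out
}
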