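first_kept <- function(res) res$stereomer[[which(res$kept)[1]]]

test_that("bounds encode the metal-center geometry", {
  defn <- oh6()
  res <- enum_nofilter(defn)
  s <- first_kept(res)
  b <- build_bounds(s, embed_params(metal_donor_tol = 0))
  g <- s$graph
  rad <- coordenum:::covalent_radius(g$atoms$element)
  dv <- integer(coordenum:::n_atoms(g))
  dv[g$donors$gatom] <- s$arrangement[g$donors$label]
  for (p in utils::combn(g$donors$gatom, 2, simplify = FALSE)) {
    d1 <- rad[1] + rad[p[1]]; d2 <- rad[1] + rad[p[2]]
    rel <- coordenum:::vertex_relation("OH", dv[p[1]], dv[p[2]])
    target <- if (rel == "trans") d1 + d2 else sqrt(d1^2 + d2^2)
    mid <- (b$L[p[1], p[2]] + b$U[p[1], p[2]]) / 2
    expect_equal(mid, target, tolerance = 0.1)
    # with zero tolerances the metal-donor bounds pinch to the target
    expect_equal(b$L[1, p[1]], b$U[1, p[1]])
  }
  expect_error(
    build_bounds(structure(list(graph = local({
      gg <- g; gg$atoms$element[2] <- "Xx"; gg
    }), arrangement = s$arrangement, parities = integer(), defn = defn),
    class = "cdn_stereomer")),
    "covalent radius")
})

test_that("embedding is deterministic and verified", {
  defn <- oh6()
  res <- enum_nofilter(defn)
  s <- first_kept(res)
  c1 <- embed(s, n_conformers = 2, seed = 99)
  c2 <- embed(s, n_conformers = 2, seed = 99)
  expect_length(c1, 2L)
  expect_identical(c1[[1]]$coords, c2[[1]]$coords)
  expect_identical(c1[[2]]$coords, c2[[2]]$coords)
  # different seeds explore different conformers
  c3 <- embed(s, n_conformers = 1, seed = 100)
  expect_false(identical(c1[[1]]$coords, c3[[1]]$coords))
  for (cf in c1) {
    expect_true(cf$verified)
    expect_true(verify_arrangement(cf))
    expect_lte(cf$energy, cf$energy_initial + 1e-9)
  }
})

test_that("verify_arrangement classifies ideal and perturbed geometries", {
  defn <- oh6()
  s <- first_kept(enum_nofilter(defn))
  g <- s$graph
  n <- coordenum:::n_atoms(g)
  # synthetic coordinates: donors exactly on their vertices, rest far away
  coords <- matrix(10, n, 3) + matrix(stats::rnorm(3 * n, sd = .1), n, 3)
  coords[g$metal, ] <- 0
  vc <- coordenum:::vertex_coords("OH") * 2.1
  coords[g$donors$gatom, ] <- vc[s$arrangement[g$donors$label], ]
  conf <- coordenum:::new_conformer(s, coords, 0, 1L)
  expect_true(verify_arrangement(conf))
  # angles perturbed by ~10 degrees still classify correctly
  set.seed(4)
  pert <- coords + matrix(stats::rnorm(3 * n, sd = 0.18), n, 3)
  pert[g$metal, ] <- 0
  expect_true(verify_arrangement(coordenum:::new_conformer(s, pert, 0, 1L)))
  # two cis-intended donors forced to 180 degrees fail verification
  bad <- coords
  cispair <- which(coordenum:::vertex_relation(
    "OH", s$arrangement[g$donors$label[1]],
    s$arrangement[g$donors$label]) == "cis")[2]
  bad[g$donors$gatom[cispair], ] <- -bad[g$donors$gatom[1], ]
  expect_false(verify_arrangement(coordenum:::new_conformer(s, bad, 0, 1L)))
})

test_that("relaxation lowers the energy and keeps the arrangement", {
  dxnx <- assemble_complex("Ru2+", "OH", as.list(c(XNX, MONO[c(1, 2, 2)])))
  res <- enumerate_stereomers(dxnx)
  for (k in which(res$kept)[1:3]) {
    cf <- embed(res$stereomer[[k]], n_conformers = 2, seed = 5)
    for (c1 in cf) {
      expect_true(c1$verified)
      expect_lte(c1$energy, c1$energy_initial)
      expect_true(verify_arrangement(c1))
    }
  }
})

test_that("all 30 octahedral stereoisomers of six distinct ligands embed", {
  res <- enum_nofilter(oh6())
  ok <- 0L
  for (k in seq_len(nrow(res))) {
    cf <- embed(res$stereomer[[k]], n_conformers = 1, seed = 17)
    ok <- ok + (length(cf) >= 1L)
  }
  expect_gte(ok, 29L)
})

test_that("embedded donor stereocenters realize their parities", {
  dxnx <- assemble_complex("Ru2+", "OH", as.list(c(XNX, MONO[c(1, 2, 2)])))
  res <- enum_nofilter(dxnx)
  with_par <- which(vapply(res$stereomer, function(s) length(s$parities) > 0, TRUE))
  s <- res$stereomer[[with_par[1]]]
  cf <- embed(s, n_conformers = 1, seed = 23)
  expect_length(cf, 1L)
  b <- build_bounds(s)
  expect_true(coordenum:::coords_ok_parities(cf[[1]]$coords, b))
  # the opposite parity embeds to the opposite signed volume
  s2 <- s
  s2$parities[1] <- -s$parities[1]
  cf2 <- embed(s2, n_conformers = 1, seed = 23)
  b2 <- build_bounds(s2)
  expect_true(coordenum:::coords_ok_parities(cf2[[1]]$coords, b2))
  expect_false(coordenum:::coords_ok_parities(cf2[[1]]$coords, b))
})

test_that("fixed-stereochemistry builds cover linear and square-pyramidal", {
  # two donors on trans vertices 1 and 6: near-linear D-M-D
  dlin <- assemble_complex("Ag+", "OH",
                           list("[C-:1]#[O+]", "[C-:6]#[O+]"), fixed = TRUE)
  cf <- build_fixed(dlin, n_conformers = 1, seed = 2)
  expect_length(cf, 1L)
  co <- cf[[1]]$coords
  g <- coordenum:::n_atoms  # silence lint
  d <- cf[[1]]$stereomer$graph$donors$gatom
  m <- co[1, ]
  v1 <- co[d[1], ] - m; v2 <- co[d[2], ] - m
  ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  expect_gte(ang, 135)

  # five donors: square-pyramidal motif, verified against its arrangement
  d5 <- assemble_complex("Fe2+", "OH",
                         as.list(sprintf("[Cl-:%d]", c(1, 2, 3, 4, 6))),
                         fixed = TRUE)
  cf5 <- build_fixed(d5, n_conformers = 1, seed = 3)
  expect_length(cf5, 1L)
  expect_true(verify_arrangement(cf5[[1]]))

  # duplicate vertex assignment is rejected
  expect_error(assemble_complex("Fe2+", "OH",
                                as.list(sprintf("[Cl-:%d]", c(1, 1, 3, 4, 6))),
                                fixed = TRUE),
               "unique map numbers")
})

test_that("a full fixed 6-donor build matches one enumerated stereoisomer", {
  lig_fixed <- c("[C-:1]#[O+]", "[H-:6]", "CC#[N:2]", "[Cl-:4]",
                 "[NH3:3]", "[OH2:5]")
  dfx <- assemble_complex("Ru2+", "OH", as.list(lig_fixed), fixed = TRUE)
  sfx <- enumerate_raw_arrangements(dfx)[[1]]
  grp <- rotation_group("OH")
  sig_fx <- signature(sfx, grp)
  res <- enum_nofilter(oh6())
  hits <- vapply(res$stereomer, function(s)
    length(intersect(signature(s, grp), sig_fx)) > 0, TRUE)
  expect_equal(sum(hits), 1L)
})
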