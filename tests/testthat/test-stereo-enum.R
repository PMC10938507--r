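test_that("raw placements enumerate every donor-to-vertex bijection", {
  expect_length(enumerate_raw_arrangements(oh6()), 720L)
  expect_length(enumerate_raw_arrangements(sp4()), 24L)
  # fixed-vertex mode: exactly the one requested placement
  dfx <- assemble_complex("Ru2+", "OH",
                          list("[C-:1]#[O+]", "[C-:6]#[O+]"), fixed = TRUE)
  raw <- enumerate_raw_arrangements(dfx)
  expect_length(raw, 1L)
  expect_equal(raw[[1]]$arrangement, c(1L, 6L))
})

test_that("signature sets are orbit-invariant and detect cis/trans", {
  defn <- assemble_complex("Ru2+", "OH",
                           as.list(c(rep(MONO[1], 4), rep(MONO[4], 2))))
  grp <- rotation_group("OH")
  raw <- enumerate_raw_arrangements(defn)
  s <- raw[[1]]
  sig0 <- signature(s, grp)
  # relabeling by any group permutation leaves the signature set unchanged
  for (e in grp$elements[c(2, 7, 13, 24)]) {
    s2 <- s
    s2$arrangement <- e$perm[s$arrangement]
    expect_equal(signature(s2, grp), sig0)
  }
  # cis and trans placements of the two B ligands have disjoint sets
  dt <- defn$donor_table
  blab <- dt$label[dt$ligand %in% c(5, 6)]
  is_trans <- function(x) coordenum:::vertex_relation(
    "OH", x$arrangement[blab[1]], x$arrangement[blab[2]]) == "trans"
  s_cis <- raw[[which(!vapply(raw, is_trans, TRUE))[1]]]
  s_trans <- raw[[which(vapply(raw, is_trans, TRUE))[1]]]
  expect_length(intersect(signature(s_cis, grp), signature(s_trans, grp)), 0L)
})

test_that("six identical ligands collapse to a single class", {
  defn <- assemble_complex("Cr", "OH", as.list(rep(MONO[1], 6)))
  res <- enum_nofilter(defn)
  expect_equal(nrow(res), 1L)
  expect_equal(res$stereomer[[1]]$class_size, 720L)
})

test_that("deduplication reproduces the classical stereoisomer counts", {
  expect_equal(nrow(enum_nofilter(oh6())), 30L)
  expect_equal(nrow(enum_nofilter(sp4())), 3L)
  cases <- list(
    list(lig = c(rep(MONO[1], 4), rep(MONO[4], 2)), geom = "OH", n = 2L,
         labels = c("cis", "trans")),
    list(lig = c(rep(MONO[1], 3), rep(MONO[4], 3)), geom = "OH", n = 2L,
         labels = c("fac", "mer")),
    list(lig = c(rep(MONO[1], 2), rep(MONO[4], 2)), geom = "SP", n = 2L,
         labels = c("cis", "trans"))
  )
  for (cs in cases) {
    res <- enum_nofilter(assemble_complex("Ru2+", cs$geom, as.list(cs$lig)))
    expect_equal(nrow(res), cs$n)
    expect_setequal(res$label, cs$labels)
  }
})

test_that("deduplicate is idempotent and independent of input order", {
  defn <- assemble_complex("Ru2+", "OH",
                           as.list(c(EN, MONO[1:4])))
  grp <- rotation_group("OH")
  raw <- enumerate_raw_arrangements(defn)
  d1 <- deduplicate(raw, grp)
  d2 <- deduplicate(d1, grp)
  expect_equal(length(d1), length(d2))
  expect_equal(lapply(d1, `[[`, "arrangement"), lapply(d2, `[[`, "arrangement"))
  set.seed(1)
  d3 <- deduplicate(sample(raw), grp)
  expect_equal(length(d3), length(d1))
  key <- function(x) sort(vapply(x, function(s) s$signature[1], ""))
  expect_equal(key(d3), key(d1))
})

test_that("signature equivalence is transitive on a small system", {
  defn <- assemble_complex("Ru2+", "SP",
                           as.list(c(rep(MONO[1], 2), rep(MONO[4], 2))))
  grp <- rotation_group("SP")
  raw <- enumerate_raw_arrangements(defn)
  sigs <- lapply(raw, signature, group = grp)
  n <- length(sigs)
  related <- function(a, b) length(intersect(sigs[[a]], sigs[[b]])) > 0
  for (a in seq_len(n)) for (b in seq_len(n)) for (cc in seq_len(n)) {
    if (related(a, b) && related(b, cc)) expect_true(related(a, cc))
  }
})

test_that("donor stereocenter expansion follows coordination chemistry", {
  # CO donor carbon: only two substituent groups, no expansion
  defn <- assemble_complex("Cr", "OH", as.list(rep(MONO[1], 6)))
  raw <- enumerate_raw_arrangements(defn)
  expect_length(expand_donor_stereocenters(raw[[1]]), 1L)

  # secondary-amine central donor of the XNX pincer becomes stereogenic:
  # a mer placement splits into two geometrical isomers
  dxnx <- assemble_complex("Ru2+", "OH", as.list(c(XNX, MONO[c(1, 2, 2)])))
  res <- enum_nofilter(dxnx)
  mers <- res[res$label == "mer", ]
  expect_gt(nrow(mers), 0L)
  raw <- enumerate_raw_arrangements(dxnx)
  mer1 <- mers$stereomer[[1]]
  base <- raw[[1]]
  base$arrangement <- mer1$arrangement
  ex <- expand_donor_stereocenters(base)
  expect_length(ex, 2L)
  expect_setequal(vapply(ex, function(s) s$parities[[1]], 0L), c(1L, -1L))

  # the same ligand with the amine pinned by an isotope label gives one variant
  xnx_pin <- "C[S:1]CC[11NH:2]CC[S:3]C"
  dpin <- assemble_complex("Ru2+", "OH", as.list(c(xnx_pin, MONO[c(1, 2, 2)])))
  rawp <- enumerate_raw_arrangements(dpin)
  basep <- rawp[[1]]
  basep$arrangement <- mer1$arrangement
  expect_length(expand_donor_stereocenters(basep), 1L)
  # the pinned enumeration never exceeds the unpinned one, and every
  # emitted stereoisomer carries the pinned configuration
  rpin <- enum_nofilter(dpin)
  expect_lte(nrow(rpin), nrow(res))
  pin_atom <- as.character(build_graph(dpin)$donors$gatom[
    dpin$donor_table$map == 2L & dpin$donor_table$ligand == 1L])
  expect_true(all(vapply(rpin$stereomer, function(s)
    identical(s$parities[[pin_atom]], 1L), TRUE)))
})

test_that("enantiomer merging removes exactly the chiral pairs", {
  g24 <- rotation_group("OH")
  g48 <- rotation_group("OH", include_reflections = TRUE)
  for (lig in list(MONO, c(EN, MONO[1:4]), c(XNX, MONO[c(1, 2, 2)]))) {
    defn <- assemble_complex("Ru2+", "OH", as.list(lig))
    rot <- enum_nofilter(defn)
    mir <- enum_nofilter(defn, merge_enantiomers = TRUE)
    expect_gte(nrow(rot), nrow(mir))
    # a representative is chiral iff its reflected images contribute new
    # canonical strings; each chiral pair loses one member on merging
    n_chiral <- sum(vapply(mir$stereomer, function(s)
      !setequal(signature(s, g24), signature(s, g48)), TRUE))
    expect_equal(nrow(rot) - nrow(mir), n_chiral)
  }
})

test_that("classify_arrangement implements the fac/mer and bi/bic rules", {
  dxnx <- assemble_complex("Ru2+", "OH", as.list(c(XNX, MONO[c(1, 2, 2)])))
  raw <- enumerate_raw_arrangements(dxnx)
  s <- raw[[1]]
  dt <- dxnx$donor_table
  tri <- dt$label[dt$ligand == 1L]
  # donors on vertices {1,2,6}: 1 and 6 are trans, so mer
  s$arrangement[tri] <- c(1L, 2L, 6L)
  s$arrangement[-tri] <- c(3L, 4L, 5L)
  expect_equal(classify_arrangement(s), "mer")
  # donors on {1,2,3}: mutually cis, fac
  s$arrangement[tri] <- c(1L, 2L, 3L)
  s$arrangement[-tri] <- c(4L, 5L, 6L)
  expect_equal(classify_arrangement(s), "fac")

  # XNX coordinated through the two arms only (central N unmarked) -> bic
  bic_lig <- "C[S:1]CC[NH]CC[S:2]C"
  dbic <- assemble_complex("Ru2+", "OH",
                           as.list(c(bic_lig, "CC#[N:1]", MONO[c(1, 2, 2)])))
  rbic <- enum_nofilter(dbic)
  expect_true(all(rbic$label == "bic"))
  # central N plus one arm marked -> bi
  bi_lig <- "C[S:1]CC[NH:2]CCSC"
  dbi <- assemble_complex("Ru2+", "OH",
                          as.list(c(bi_lig, "CC#[N:1]", MONO[c(1, 2, 2)])))
  rbi <- enum_nofilter(dbi)
  expect_true(all(rbi$label == "bi"))
})

test_that("pipeline counts are monotone along the stages", {
  defn <- assemble_complex("Ru2+", "OH", as.list(c(TERPY, MONO[c(1, 2, 3)])))
  res <- enumerate_stereomers(defn)
  counts <- attr(res, "counts")
  expect_true(counts[["raw"]] >= counts[["deduplicated"]])
  expect_true(counts[["expanded"]] >= counts[["deduplicated"]])
  expect_true(counts[["deduplicated"]] >= counts[["kept"]])
})
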