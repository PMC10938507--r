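test_that("parse_ligand identifies marked donors in map order", {
  co <- parse_ligand("[C-:1]#[O+]")
  expect_equal(co$denticity, 1L)
  expect_equal(co$mol$atoms$element[co$donors$atom], "C")

  mecn <- parse_ligand("CC#[N:1]")
  expect_equal(mecn$denticity, 1L)
  expect_equal(mecn$mol$atoms$element[mecn$donors$atom], "N")

  xnx <- parse_ligand(XNX)
  expect_equal(xnx$denticity, 3L)
  # central donor (map 2) is a secondary amine nitrogen: N with one H and
  # two carbon neighbors
  central <- xnx$donors$atom[xnx$donors$map == 2L]
  expect_equal(xnx$mol$atoms$element[central], "N")
  expect_equal(xnx$mol$atoms$hcount[central], 1L)
  # donors come back in ascending map order
  expect_equal(xnx$donors$map, 1:3)
})

test_that("parse_ligand rejects bad input with informative errors", {
  expect_error(parse_ligand("C1CC"), "C1CC")           # unclosed ring
  expect_error(parse_ligand("C(#N"), "unmatched")
  expect_error(parse_ligand("CCO"), "no donor atoms")
  expect_error(parse_ligand("[Ru:1]"), "not mononuclear-compatible")
})

test_that("isotope labels pin donor configuration and are consumed", {
  pinned <- parse_ligand("C[S:1]CC[11NH:2]CC[S:3]C")
  expect_equal(pinned$donors$pinned[pinned$donors$map == 2L], 1L)
  # the reserved isotope is stripped from the stored graph
  expect_true(all(pinned$mol$atoms$isotope == 0L))
  pinned2 <- parse_ligand("C[S:1]CC[22NH:2]CC[S:3]C")
  expect_equal(pinned2$donors$pinned[pinned2$donors$map == 2L], -1L)
  # a genuine isotope elsewhere is preserved
  iso <- parse_ligand("[13C]C#[N:1]")
  expect_equal(iso$mol$atoms$isotope[1], 13L)
})

test_that("assemble_complex validates donor counts against the geometry", {
  pn3p <- "[P:1](C)(C)Nc1cccc(N[P:3](C)(C))[n:2]1"
  defn <- assemble_complex("Ru2+", "OH",
                           as.list(c(pn3p, "[H-:1]", "[H-:1]", "[C-:1]#[O+]")))
  expect_equal(defn$total_donor_count, 6L)
  expect_equal(defn$metal, "Ru")
  expect_equal(defn$metal_charge, 2L)

  expect_s3_class(sp4(), "cdn_complex")
  expect_error(assemble_complex("Pd", "SP", as.list(rep("[C-:1]#[O+]", 5))),
               "donor count mismatch")
  expect_error(assemble_complex("Pd", "SP", list()), "empty")
  expect_error(assemble_complex("C", "SP", as.list(rep("[C-:1]#[O+]", 4))),
               "not a metal")
})

test_that("central atom notation accepts charge variants", {
  for (s in c("Ru2+", "Ru+2", "[Ru+2]")) {
    m <- coordenum:::parse_central_atom(s)
    expect_equal(m$element, "Ru")
    expect_equal(m$charge, 2L)
  }
  expect_equal(coordenum:::parse_central_atom("Mn+")$charge, 1L)
  expect_equal(coordenum:::parse_central_atom("Pd")$charge, 0L)
})

test_that("total complex charge is metal plus ligand formal charges", {
  # CO is net neutral ([C-]#[O+]); hydride and chloride each carry -1
  defn <- oh6()
  expect_equal(defn$total_charge, 2L - 2L)
  expect_equal(sp4()$total_charge, 2L - 1L)   # CO, MeCN, Cl-, OH2 on Pd2+
})

test_that("build_graph wires the metal to every donor via dative bonds", {
  defn <- oh6()
  g <- build_graph(defn)
  dative <- g$bonds[g$bonds$dative, ]
  expect_equal(nrow(dative), 6L)
  expect_true(all(dative$j == g$metal))
  expect_setequal(dative$i, g$donors$gatom)

  # tridentate pincer: three metal-donor bonds, one ligand component
  d2 <- assemble_complex("Ru2+", "OH", as.list(c(XNX, MONO[c(1, 2, 2)])))
  g2 <- build_graph(d2)
  expect_equal(sum(g2$bonds$dative & g2$bonds$i %in%
                     g2$donors$gatom[g2$donors$ligand == 1L]), 3L)

  # removing the metal restores the disjoint union of the ligands
  ig <- coordenum:::ligand_igraph(g2)
  ig <- igraph::delete_vertices(ig, g2$metal)
  comp <- igraph::components(ig)
  expect_equal(comp$no, length(d2$ligands))
})

test_that("ligand SMILES round-trips preserve graph and donor marks", {
  for (smi in c(MONO, EN, BIPY, XNX, TERPY,
                generate_fixtures("fig5a")[c(1, 5, 9)])) {
    l1 <- parse_ligand(smi)
    l2 <- parse_ligand(coordenum:::write_smiles(l1$mol))
    expect_equal(coordenum:::mol_formula(l2$mol),
                 coordenum:::mol_formula(l1$mol), info = smi)
    expect_equal(l2$denticity, l1$denticity, info = smi)
    expect_equal(l2$donors$map, l1$donors$map, info = smi)
    expect_equal(sort(l2$mol$atoms$element[l2$donors$atom]),
                 sort(l1$mol$atoms$element[l1$donors$atom]), info = smi)
  }
})

test_that("parsed compositions agree with an independent SMILES reader", {
  # OpenBabel, available on the command line, acts as the external oracle
  # for the parser's atom/hydrogen bookkeeping
  count_atoms <- function(formula) {
    formula <- sub("[+-]+$", "", formula)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
    toks <- regmatches(formula, list(m))[[1]]
    el <- sub("[0-9]+$", "", toks)
    n <- as.integer(sub("^[A-Za-z]+", "", paste0(toks, "")))
    n[is.na(n)] <- 1L
    sort(stats::setNames(n, el))
  }
  my_counts <- function(mol) {
    el <- c(mol$atoms$element, rep("H", sum(mol$atoms$hcount, na.rm = TRUE)))
    sort(table(el))
  }
  smis <- c(MONO, EN, XNX, TERPY, generate_fixtures("fig5a")[c(3, 7, 14)])
  ob <- system2("obabel", c(paste0("-:", shQuote(unname(smis))), "-otxt",
                            "--append", "formula"),
                stdout = TRUE, stderr = FALSE)
  for (i in seq_along(smis)) {
    mine <- my_counts(parse_ligand(smis[i])$mol)
    ref <- count_atoms(ob[i])
    expect_equal(as.integer(mine), as.integer(ref), info = smis[i])
    expect_equal(names(mine), names(ref), info = smis[i])
  }
})

test_that("assemble_complex is order-insensitive downstream", {
  lig <- c(EN, MONO[1:4])
  d1 <- assemble_complex("Ru2+", "OH", as.list(lig))
  d2 <- assemble_complex("Ru2+", "OH", as.list(rev(lig)))
  r1 <- enum_nofilter(d1)
  r2 <- enum_nofilter(d2)
  expect_equal(nrow(r1), nrow(r2))
  expect_equal(sort(table(r1$label)), sort(table(r2$label)))
})
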