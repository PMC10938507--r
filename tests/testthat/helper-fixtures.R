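# Shared fixture shortcuts for the test suite.

MONO <- generate_fixtures("monodentate")
XNX <- generate_fixtures("tridentate_pincer_xnx")
TERPY <- generate_fixtures("tridentate_rigid_terpy")
EN <- generate_fixtures("bidentate_flexible")
BIPY <- generate_fixtures("bidentate_rigid")

oh6 <- function(ligands = MONO, metal = "Ru2+") {
  assemble_complex(metal, "OH", as.list(ligands))
}

sp4 <- function(ligands = MONO[c("carbonyl", "acetonitrile", "chloride", "aqua")],
                metal = "Pd2+") {
  assemble_complex(metal, "SP", as.list(ligands))
}

# enumeration with both feasibility filters off (raw stereochemical census)
enum_nofilter <- function(defn, ...) {
  enumerate_stereomers(defn, filters = filter_config(FALSE, FALSE), ...)
}

# ligand pool for randomized property tests; free of internal stereocenters
# and isotope pins (the orbit oracle does not model either)
ORACLE_POOL <- list(
  mono = c("[C-:1]#[O+]", "[H-:1]", "CC#[N:1]", "[Cl-:1]", "[NH3:1]",
           "[OH2:1]", "[F-:1]", "C[NH2:1]"),
  bi = c("[NH2:1]CC[NH2:2]", "[NH2:1]CC[SH:2]", "c1ccc(-c2cccc[n:2]2)[n:1]c1",
         "[PH2:1]CCC[PH2:2]", "C[NH:1]CC[O-:2]"),
  tri = c("C[S:1]CC[NH:2]CC[S:3]C", "[NH2:1]CC[NH:2]CC[NH2:3]",
          "c1cc[n:1]c(-c2cccc(-c3cccc[n:3]3)[n:2]2)c1")
)

# random ligand multiset totalling `total` donors (seeded by caller)
random_multiset <- function(total) {
  repeat {
    picks <- character()
    left <- total
    while (left > 0L) {
      dent_max <- min(left, 3L)
      dent <- sample(seq_len(dent_max), 1L)
      pool <- ORACLE_POOL[[c("mono", "bi", "tri")[dent]]]
      picks <- c(picks, sample(pool, 1L))
      left <- left - dent
    }
    return(picks)
  }
}
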