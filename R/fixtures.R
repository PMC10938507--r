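# Ligand generators used by the test-suite, the examples and the CLI demos.
# Everything is produced programmatically, so the package needs no external
# structure files.

# arm donor group with substituents in branches; ring digit 6 keeps phenyl
# closures clear of the backbone's digit 1
fig5a_arm <- function(arm, R, map) {
  r_smi <- c(Me = "C", iPr = "C(C)C", Ph = "c6ccccc6")[[R]]
  switch(arm,
    N = sprintf("[N:%d](%s)(%s)", map, r_smi, r_smi),
    P = sprintf("[P:%d](%s)(%s)", map, r_smi, r_smi),
    S = sprintf("[S:%d](%s)", map, r_smi),
    stop("unknown arm type ", arm))
}

fig5a_ligand <- function(arm, R, backbone) {
  a1 <- fig5a_arm(arm, R, 1L)
  a3 <- fig5a_arm(arm, R, 3L)
  if (backbone == "py") {
    paste0(a1, "Cc1cccc(C", a3, ")[n:2]1")
  } else {
    paste0(a1, "CC[NH:2]CC", a3)
  }
}

#' Generate fixture ligand sets
#'
#' Deterministic donor-marked SMILES collections used throughout the tests
#' and examples:
#'
#' * `"monodentate"`: six mutually distinct single-donor ligands (carbonyl,
#'   hydride, acetonitrile, chloride, ammine, aqua).
#' * `"bidentate_flexible"`: ethylenediamine-like chelate (2-atom sp3 linker).
#' * `"bidentate_rigid"`: 2,2'-bipyridine-like chelate.
#' * `"tridentate_pincer_xnx"`: flexible model XNX pincer whose central donor
#'   is a secondary amine (a tetrahedral stereocenter once coordinated).
#' * `"tridentate_rigid_terpy"`: 2,2':6',2''-terpyridine-like rigid ligand.
#' * `"fig5a"`: the combinatorial pincer family: NNN/PNP/SNS arms with
#'   R = Me, iPr on -NR2 and -SR and R = Me, iPr, Ph on -PR2, on a pyridine
#'   or aliphatic-amine central N backbone (14 ligands).
#' * `"bidentate_random"`: `params$n` random flexible chelates with seeded
#'   linker lengths (1-4 sp3 carbons) and donor types.
#'
#' @param kind fixture family, see above
#' @param params optional list of family parameters (`n` for the random set)
#' @param seed RNG seed for the random family
#' @return named character vector of ligand SMILES
#' @export
generate_fixtures <- function(kind = c("monodentate", "bidentate_flexible",
                                       "bidentate_rigid",
                                       "tridentate_pincer_xnx",
                                       "tridentate_rigid_terpy", "fig5a",
                                       "bidentate_random"),
                              params = list(), seed = NULL) {
  kind <- match.arg(kind)
  switch(kind,
    monodentate = c(
      carbonyl = "[C-:1]#[O+]",
      hydride = "[H-:1]",
      acetonitrile = "CC#[N:1]",
      chloride = "[Cl-:1]",
      ammine = "[NH3:1]",
      aqua = "[OH2:1]"
    ),
    bidentate_flexible = c(en = "[NH2:1]CC[NH2:2]"),
    bidentate_rigid = c(bipy = "c1ccc(-c2cccc[n:2]2)[n:1]c1"),
    tridentate_pincer_xnx = c(xnx = "C[S:1]CC[NH:2]CC[S:3]C"),
    tridentate_rigid_terpy = c(
      terpy = "c1cc[n:1]c(-c2cccc(-c3cccc[n:3]3)[n:2]2)c1"
    ),
    fig5a = {
      combos <- rbind(
        expand.grid(arm = "N", R = c("Me", "iPr"), backbone = c("py", "aliph"),
                    stringsAsFactors = FALSE),
        expand.grid(arm = "P", R = c("Me", "iPr", "Ph"), backbone = c("py", "aliph"),
                    stringsAsFactors = FALSE),
        expand.grid(arm = "S", R = c("Me", "iPr"), backbone = c("py", "aliph"),
                    stringsAsFactors = FALSE)
      )
      out <- vapply(seq_len(nrow(combos)), function(k)
        fig5a_ligand(combos$arm[k], combos$R[k], combos$backbone[k]), "")
      names(out) <- sprintf("%s%s%s_%s_%s", combos$arm, "N", combos$arm,
                            combos$R, combos$backbone)
      out
    },
    bidentate_random = {
      n <- if (is.null(params$n)) 5L else as.integer(params$n)
      if (!is.null(seed)) set.seed(seed)
      donors <- c("[NH2:%d]", "[PH2:%d]", "[SH:%d]", "[O-:%d]")
      out <- character(n)
      for (k in seq_len(n)) {
        len <- sample(1:4, 1L)
        d1 <- sprintf(sample(donors, 1L), 1L)
        d2 <- sprintf(sample(donors, 1L), 2L)
        out[k] <- paste0(d1, paste(rep("C", len), collapse = ""), d2)
      }
      names(out) <- sprintf("rand%02d", seq_len(n))
      out
    }
  )
}

#' Auxiliary ligand sets of the pincer screening study
#'
#' Metal-specific auxiliary ligands completing an octahedral pincer complex:
#' `(XNX)Mn(CO)2H` for Mn+, `(XNX)Fe(CO)H2` for Fe2+ and `(XNX)Ru(CO)H2`
#' for Ru2+, optionally with a coordinating solvent (MeCN) replacing a
#' decoordinated pincer arm in bidentate binding modes.
#'
#' @param metal `"Mn+"`, `"Fe2+"` or `"Ru2+"`
#' @return character vector of three auxiliary ligand SMILES
#' @export
pincer_auxiliaries <- function(metal = c("Mn+", "Fe2+", "Ru2+")) {
  metal <- match.arg(metal)
  co <- "[C-:1]#[O+]"
  h <- "[H-:1]"
  if (metal == "Mn+") c(co, co, h) else c(co, h, h)
}
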