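# Parsing and validation of the metal-ligand system: ligands with donor marks,
# the complex definition, and the assembled molecular graph with dative bonds.

# reserved isotope values that pin the stereoconfiguration of a donor atom;
# they are consumed (stripped from the graph) when the ligand is parsed
.pin_isotopes <- c(`11` = 1L, `22` = -1L)

#' Parse a donor-marked ligand SMILES
#'
#' Donor atoms are the atoms carrying a nonzero atom-map number, taken in
#' ascending map order. A donor atom additionally carrying the reserved
#' isotope label 11 or 22 has its tetrahedral configuration after coordination
#' pinned (11 = parity +1, 22 = parity -1, in the same sense as `@`/`@@` with
#' neighbors listed in ascending atom order and the metal last); the reserved
#' isotope is removed from the stored graph.
#'
#' @param smiles ligand SMILES with at least one atom-map-numbered donor atom
#' @return a `cdn_ligand`: the parsed graph plus a donor table
#' @examples
#' parse_ligand("[C-:1]#[O+]")          # carbonyl, C donor
#' parse_ligand("CC#[N:1]")             # acetonitrile, N donor
#' parse_ligand("[NH2:1]CC[NH2:2]")     # ethylenediamine-like chelate
#' @export
parse_ligand <- function(smiles) {
  mol <- tryCatch(parse_smiles(smiles), error = function(e) {
    stop("failed to parse ligand SMILES '", smiles, "': ", conditionMessage(e),
         call. = FALSE)
  })
  donor_idx <- which(mol$atoms$map > 0L)
  if (length(donor_idx) == 0L) {
    stop("ligand '", smiles, "': no donor atoms marked (need nonzero atom-map numbers)",
         call. = FALSE)
  }
  if (any(is_metal_element(mol$atoms$element))) {
    stop("ligand '", smiles, "': contains a metal atom; not mononuclear-compatible",
         call. = FALSE)
  }
  ord <- order(mol$atoms$map[donor_idx], donor_idx)
  donor_idx <- donor_idx[ord]
  pinned <- rep(NA_integer_, length(donor_idx))
  for (k in seq_along(donor_idx)) {
    iso <- mol$atoms$isotope[donor_idx[k]]
    key <- as.character(iso)
    if (iso > 0L && key %in% names(.pin_isotopes)) {
      pinned[k] <- .pin_isotopes[[key]]
      mol$atoms$isotope[donor_idx[k]] <- 0L
    }
  }
  structure(list(
    smiles = smiles,
    mol = mol,
    donors = data.frame(atom = donor_idx,
                        map = mol$atoms$map[donor_idx],
                        pinned = pinned),
    denticity = length(donor_idx)
  ), class = "cdn_ligand")
}

#' @export
print.cdn_ligand <- function(x, ...) {
  cat(sprintf("<cdn_ligand> %s  (denticity %d, donors at atom(s) %s)\n",
              x$smiles, x$denticity, paste(x$donors$atom, collapse = ", ")))
  invisible(x)
}

parse_central_atom <- function(central_atom) {
  s <- gsub("\\[|\\]", "", trimws(central_atom))
  m <- regexec("^([A-Z][a-z]?)(?:([0-9]*)([+-])|([+-])([0-9]*))?$", s)[[1]]
  g <- regmatches(s, list(m))[[1]]
  if (length(g) == 0L) stop("cannot parse central atom '", central_atom, "'", call. = FALSE)
  element <- g[2]
  charge <- 0L
  if (g[4] != "") {                      # "Ru2+" style
    mag <- if (g[3] == "") 1L else as.integer(g[3])
    charge <- if (g[4] == "+") mag else -mag
  } else if (g[5] != "") {               # "Ru+2" style
    mag <- if (g[6] == "") 1L else as.integer(g[6])
    charge <- if (g[5] == "+") mag else -mag
  }
  if (!is_metal_element(element)) {
    stop("central atom '", element, "' is not a metal", call. = FALSE)
  }
  list(element = element, charge = charge)
}

#' Assemble and validate a complex definition
#'
#' Checks that the total donor count matches the requested coordination
#' geometry: 6 for octahedral (`"OH"`), 4 for square-planar (`"SP"`) in
#' enumeration mode. With `fixed = TRUE` (fixed-stereochemistry mode) the
#' atom-map numbers are interpreted as explicit octahedron vertex indices and
#' 2, 4, 5 or 6 donors are allowed (linear and square-pyramidal structures
#' being special cases of the octahedron).
#'
#' @param central_atom central metal with formal charge, e.g. `"Ru2+"`,
#'   `"Mn+"`, `"[Fe+2]"`, `"Pd"`
#' @param geometry `"OH"` (octahedral) or `"SP"` (square-planar)
#' @param ligands list of `cdn_ligand` objects (or SMILES strings, which are
#'   parsed on the fly)
#' @param fixed interpret map numbers as fixed polyhedron vertices
#' @return a validated `cdn_complex` definition
#' @examples
#' assemble_complex("Pd", "SP", list("[C-:1]#[O+]", "[C-:1]#[O+]",
#'                                   "[C-:1]#[O+]", "[C-:1]#[O+]"))
#' @export
assemble_complex <- function(central_atom, geometry, ligands, fixed = FALSE) {
  geometry <- match.arg(geometry, c("OH", "SP"))
  if (length(ligands) == 0L) stop("ligand list is empty", call. = FALSE)
  ligands <- lapply(ligands, function(l) {
    if (inherits(l, "cdn_ligand")) l else parse_ligand(l)
  })
  metal <- parse_central_atom(central_atom)
  denticities <- vapply(ligands, `[[`, 0L, "denticity")
  total <- sum(denticities)
  required <- if (geometry == "OH") 6L else 4L
  if (!fixed && total != required) {
    stop("donor count mismatch: ", total, " donors marked but geometry ",
         geometry, " requires ", required, call. = FALSE)
  }
  if (fixed) {
    allowed <- if (geometry == "OH") c(2L, 4L, 5L, 6L) else c(2L, 4L)
    if (!(total %in% allowed)) {
      stop("donor count mismatch: fixed-stereochemistry mode with geometry ",
           geometry, " allows ", paste(allowed, collapse = "/"),
           " donors, got ", total, call. = FALSE)
    }
    maps <- unlist(lapply(ligands, function(l) l$donors$map))
    nv <- if (geometry == "OH") 6L else 4L
    if (anyDuplicated(maps) || any(maps < 1L | maps > nv)) {
      stop("fixed-stereochemistry mode requires unique map numbers in 1..",
           nv, " (vertex indices)", call. = FALSE)
    }
  }
  donor_table <- do.call(rbind, lapply(seq_along(ligands), function(li) {
    d <- ligands[[li]]$donors
    data.frame(ligand = li, atom = d$atom, map = d$map, pinned = d$pinned)
  }))
  donor_table$label <- seq_len(nrow(donor_table))
  total_charge <- metal$charge +
    sum(vapply(ligands, function(l) sum(l$mol$atoms$charge), 0L))
  structure(list(
    metal = metal$element,
    metal_charge = metal$charge,
    geometry = geometry,
    ligands = ligands,
    donor_table = donor_table,
    total_donor_count = total,
    total_charge = total_charge,
    fixed = fixed
  ), class = "cdn_complex")
}

#' @export
print.cdn_complex <- function(x, ...) {
  cat(sprintf("<cdn_complex> %s%+d, geometry %s, %d ligand(s), %d donors, total charge %+d\n",
              x$metal, x$metal_charge, x$geometry, length(x$ligands),
              x$total_donor_count, x$total_charge))
  for (l in x$ligands) cat("  ", l$smiles, "\n")
  invisible(x)
}

#' Build the hydrogen-explicit molecular graph of the assembled complex
#'
#' The metal is atom 1; ligand atoms (with explicit hydrogens) follow in
#' ligand order. Each donor atom is connected to the metal by a dative bond,
#' so ligand-internal bonds, charges and stereocenters are unchanged by
#' coordination.
#'
#' @param defn a `cdn_complex`
#' @param arrangement optional donor arrangement (vertex index per donor
#'   label) stored on the result
#' @return a `cdn_mol` with extra fields `donors` (donor bookkeeping table
#'   with global atom indices), `metal` (atom index 1) and `geometry`
#' @export
build_graph <- function(defn, arrangement = NULL) {
  stopifnot(inherits(defn, "cdn_complex"))
  atoms <- data.frame(element = defn$metal, arom = FALSE,
                      charge = defn$metal_charge, isotope = 0L,
                      hcount = 0L, map = 0L, stringsAsFactors = FALSE)
  bonds <- data.frame(i = integer(), j = integer(), order = numeric(),
                      dative = logical())
  stereo <- list()
  donors <- defn$donor_table
  donors$gatom <- NA_integer_
  offset <- 1L
  lig_atoms <- vector("list", length(defn$ligands))
  for (li in seq_along(defn$ligands)) {
    lm <- add_hydrogens(defn$ligands[[li]]$mol)
    lig_atoms[[li]] <- offset + seq_len(n_atoms(lm))
    atoms <- rbind(atoms, lm$atoms)
    if (nrow(lm$bonds)) {
      b <- lm$bonds
      b$i <- b$i + offset
      b$j <- b$j + offset
      bonds <- rbind(bonds, b)
    }
    for (st in lm$stereo) {
      st$center <- st$center + offset
      st$nbrs <- st$nbrs + offset
      stereo[[length(stereo) + 1L]] <- st
    }
    sel <- donors$ligand == li
    donors$gatom[sel] <- donors$atom[sel] + offset
    offset <- offset + n_atoms(lm)
  }
  # dative donor -> metal bonds
  bonds <- rbind(bonds, data.frame(i = donors$gatom, j = 1L, order = 1,
                                   dative = TRUE))
  g <- new_mol(atoms, bonds, stereo)
  g$donors <- donors
  g$metal <- 1L
  g$geometry <- defn$geometry
  g$ligand_atoms <- lig_atoms
  g$arrangement <- arrangement
  class(g) <- c("cdn_complex_graph", class(g))
  g
}
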