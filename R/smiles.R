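# Minimal molecular-graph container and a SMILES reader/writer supporting the
# donor-marking dialect used throughout the package: atom-map numbers label
# donor atoms, isotopes may pin donor stereoconfiguration, and tetrahedral
# @/@@ centers are kept as ordered-neighbor parities.
#
# A `cdn_mol` is a list with
#   atoms  : data.frame(element, arom, charge, isotope, hcount, map)
#   bonds  : data.frame(i, j, order, dative)   order 1.5 encodes aromatic
#   stereo : list of list(center, nbrs, parity); nbrs is the ordered vector of
#            the four neighbor atom indices (0 = the implicit hydrogen), and
#            parity +1 corresponds to "@" with respect to that order.

.organic_subset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

new_mol <- function(atoms, bonds, stereo = list()) {
  structure(list(atoms = atoms, bonds = bonds, stereo = stereo),
            class = "cdn_mol")
}

n_atoms <- function(mol) nrow(mol$atoms)

#' @export
print.cdn_mol <- function(x, ...) {
  cat(sprintf("<cdn_mol> %d atoms, %d bonds, %d stereocenters\n",
              nrow(x$atoms), nrow(x$bonds), length(x$stereo)))
  invisible(x)
}

empty_atoms <- function() {
  data.frame(element = character(), arom = logical(), charge = integer(),
             isotope = integer(), hcount = integer(), map = integer(),
             stringsAsFactors = FALSE)
}

# sign of the permutation taking `from` onto `to` (same multiset, distinct)
perm_sign <- function(p) {
  n <- length(p)
  visited <- logical(n)
  sign <- 1L
  for (i in seq_len(n)) {
    if (!visited[i]) {
      j <- i
      len <- 0L
      while (!visited[j]) {
        visited[j] <- TRUE
        j <- p[j]
        len <- len + 1L
      }
      if (len %% 2L == 0L) sign <- -sign
    }
  }
  sign
}

parse_charge_token <- function(tok) {
  if (is.na(tok) || tok == "") return(0L)
  s <- substr(tok, 1, 1)
  sgn <- if (s == "+") 1L else -1L
  rest <- substr(tok, 2, nchar(tok))
  if (rest == "") return(sgn)
  if (grepl("^[0-9]+$", rest)) return(sgn * as.integer(rest))
  # "++" / "---" style
  sgn * (1L + nchar(rest))
}

#' Parse a SMILES string into a molecular graph
#'
#' Supports the daylight dialect used for ligand input: organic-subset and
#' bracket atoms, aromatic lowercase atoms, charges, isotopes, atom-map
#' numbers, ring closures (including `%nn`), branches, and tetrahedral
#' `@`/`@@` centers. Directional bond symbols (`/`, `\`) are accepted but
#' their double-bond geometry is not retained.
#'
#' @param smiles a single SMILES string describing one connected molecule
#' @return a `cdn_mol` molecular graph
#' @keywords internal
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  s <- trimws(smiles)
  if (s == "") stop("invalid SMILES: empty string")
  if (grepl(".", s, fixed = TRUE)) {
    stop("invalid SMILES '", smiles, "': disconnected components ('.') are not supported")
  }

  atoms <- list()
  bonds <- list()
  nbrs <- list()          # per-atom ordered neighbor records
  chiral <- integer()     # 0 none, 1 "@", 2 "@@"
  ring_open <- list()     # digit -> list(atom, order, event)
  event_counter <- 0L

  prev <- NA_integer_
  pending <- NA_character_
  stack <- integer()

  bracket_re <- "^\\[([0-9]+)?([A-Za-z][a-z]?|\\*)(@@|@)?(H[0-9]*)?((?:[+-][0-9]+)|\\++|-+)?(?::([0-9]+))?\\]"
  organic_re <- "^(Cl|Br|B|C|N|O|P|S|F|I|b|c|n|o|p|s)"

  add_atom <- function(element, arom, charge, isotope, hcount, map, chi) {
    idx <- length(atoms) + 1L
    atoms[[idx]] <<- list(element = element, arom = arom, charge = charge,
                          isotope = isotope, hcount = hcount, map = map)
    nbrs[[idx]] <<- integer()
    chiral[idx] <<- chi
    if (!is.na(prev)) nbrs[[idx]] <<- c(nbrs[[idx]], prev)
    # implicit hydrogen holds its as-written position in the chiral order
    if (chi > 0L && !is.na(hcount) && hcount > 0L) {
      nbrs[[idx]] <<- c(nbrs[[idx]], 0L)
    }
    if (!is.na(prev)) {
      ord <- resolve_order(pending, prev, idx)
      bonds[[length(bonds) + 1L]] <<- list(i = prev, j = idx, order = ord)
      nbrs[[prev]] <<- c(nbrs[[prev]], idx)
    }
    pending <<- NA_character_
    prev <<- idx
    idx
  }

  resolve_order <- function(sym, a, b) {
    if (is.na(sym)) {
      if (atoms[[a]]$arom && atoms[[b]]$arom) return(1.5)
      return(1)
    }
    switch(sym, "-" = 1, "/" = 1, "\\" = 1, "=" = 2, "#" = 3, ":" = 1.5,
           stop("invalid SMILES '", smiles, "': unsupported bond symbol '", sym, "'"))
  }

  handle_ring <- function(digit) {
    key <- as.character(digit)
    if (is.null(ring_open[[key]])) {
      event_counter <<- event_counter + 1L
      ring_open[[key]] <<- list(atom = prev, sym = pending, event = event_counter)
      nbrs[[prev]] <<- c(nbrs[[prev]], -event_counter)
    } else {
      op <- ring_open[[key]]
      ring_open[[key]] <<- NULL
      sym <- if (!is.na(pending)) pending else op$sym
      ord <- resolve_order(sym, op$atom, prev)
      bonds[[length(bonds) + 1L]] <<- list(i = op$atom, j = prev, order = ord)
      nbrs[[op$atom]] <<- replace(nbrs[[op$atom]], nbrs[[op$atom]] == -op$event, prev)
      nbrs[[prev]] <<- c(nbrs[[prev]], op$atom)
    }
    pending <<- NA_character_
  }

  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    rest <- substr(s, i, n)
    ch <- substr(s, i, i)
    if (ch == "(") {
      if (is.na(prev)) stop("invalid SMILES '", smiles, "': branch before any atom")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) stop("invalid SMILES '", smiles, "': unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- ch
      i <- i + 1L
    } else if (grepl("^[0-9]", ch)) {
      handle_ring(as.integer(ch))
      i <- i + 1L
    } else if (ch == "%") {
      m <- regmatches(rest, regexpr("^%[0-9]{2}", rest))
      if (length(m) == 0L) stop("invalid SMILES '", smiles, "': malformed % ring closure")
      handle_ring(as.integer(substr(m, 2, 3)))
      i <- i + 3L
    } else if (ch == "[") {
      m <- regmatches(rest, regexec(bracket_re, rest))[[1]]
      if (length(m) == 0L) stop("invalid SMILES '", smiles, "': malformed bracket atom at position ", i)
      iso <- if (m[2] == "") 0L else as.integer(m[2])
      elem_tok <- m[3]
      if (elem_tok == "*") stop("invalid SMILES '", smiles, "': wildcard atoms not supported")
      arom <- elem_tok %in% c("b", "c", "n", "o", "p", "s", "se", "as")
      element <- if (arom) {
        paste0(toupper(substr(elem_tok, 1, 1)), substr(elem_tok, 2, nchar(elem_tok)))
      } else elem_tok
      chi <- if (m[4] == "@@") 2L else if (m[4] == "@") 1L else 0L
      # "H" with no digit means one hydrogen; absent means zero
      hc <- if (m[5] == "") 0L else if (m[5] == "H") 1L else as.integer(substr(m[5], 2, nchar(m[5])))
      charge <- parse_charge_token(if (m[6] == "") NA_character_ else m[6])
      map <- if (m[7] == "") 0L else as.integer(m[7])
      add_atom(element, arom, charge, iso, hc, map, chi)
      i <- i + nchar(m[1])
    } else {
      m <- regmatches(rest, regexpr(organic_re, rest))
      if (length(m) == 0L) {
        stop("invalid SMILES '", smiles, "': unexpected character '", ch, "' at position ", i)
      }
      arom <- m %in% c("b", "c", "n", "o", "p", "s")
      element <- if (arom) toupper(m) else m
      add_atom(element, arom, 0L, 0L, NA_integer_, 0L, 0L)
      i <- i + nchar(m)
    }
  }
  if (length(stack) > 0L) stop("invalid SMILES '", smiles, "': unmatched '('")
  if (length(ring_open) > 0L) stop("invalid SMILES '", smiles, "': unclosed ring bond(s)")
  if (length(atoms) == 0L) stop("invalid SMILES '", smiles, "': no atoms")

  atoms_df <- data.frame(
    element = vapply(atoms, `[[`, "", "element"),
    arom = vapply(atoms, `[[`, TRUE, "arom"),
    charge = vapply(atoms, `[[`, 0L, "charge"),
    isotope = vapply(atoms, `[[`, 0L, "isotope"),
    hcount = vapply(atoms, function(a) as.integer(a$hcount), 0L),
    map = vapply(atoms, `[[`, 0L, "map"),
    stringsAsFactors = FALSE
  )
  bonds_df <- if (length(bonds)) {
    data.frame(i = vapply(bonds, `[[`, 0L, "i"),
               j = vapply(bonds, `[[`, 0L, "j"),
               order = vapply(bonds, `[[`, 0, "order"),
               dative = FALSE)
  } else {
    data.frame(i = integer(), j = integer(), order = numeric(), dative = logical())
  }

  # implicit hydrogens for bare organic-subset atoms
  bsum <- numeric(nrow(atoms_df))
  for (k in seq_len(nrow(bonds_df))) {
    bsum[bonds_df$i[k]] <- bsum[bonds_df$i[k]] + bonds_df$order[k]
    bsum[bonds_df$j[k]] <- bsum[bonds_df$j[k]] + bonds_df$order[k]
  }
  for (a in which(is.na(atoms_df$hcount))) {
    vals <- .default_valences[[atoms_df$element[a]]]
    if (is.null(vals)) {
      atoms_df$hcount[a] <- 0L
    } else {
      cand <- vals[vals >= bsum[a] - 1e-9]
      atoms_df$hcount[a] <- if (length(cand) == 0L) 0L else {
        as.integer(round(min(cand) - bsum[a]))
      }
    }
  }

  # assemble stereo records; only tetrahedral (4 neighbors incl. implicit H)
  stereo <- list()
  for (a in which(chiral > 0L)) {
    nb <- nbrs[[a]]
    if (length(nb) != 4L) {
      warning("stereo mark on atom ", a, " of '", smiles,
              "' is not tetrahedral (", length(nb), " neighbors); dropped")
      next
    }
    stereo[[length(stereo) + 1L]] <- list(
      center = a, nbrs = nb,
      parity = if (chiral[a] == 1L) 1L else -1L
    )
  }

  new_mol(atoms_df, bonds_df, stereo)
}

# hydrogen count the parser would infer for a bare (non-bracket) atom token
implied_hcount <- function(element, arom, bsum) {
  vals <- .default_valences[[element]]
  if (is.null(vals)) return(NA_integer_)
  cand <- vals[vals >= bsum - 1e-9]
  if (length(cand) == 0L) 0L else as.integer(round(min(cand) - bsum))
}

#' Write a molecular graph back to SMILES
#'
#' Inverse of [parse_smiles()]: emits ring-closure digits for cycles, brackets
#' atoms carrying charge/isotope/map/stereo information, and recomputes the
#' `@`/`@@` symbol of each tetrahedral center for the as-written neighbor
#' order. Dative bonds are written as plain single bonds.
#'
#' @param mol a `cdn_mol`
#' @return a SMILES string
#' @keywords internal
write_smiles <- function(mol) {
  na <- n_atoms(mol)
  if (na == 0L) stop("cannot write SMILES for an empty molecule")
  adj <- vector("list", na)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    adj[[i]] <- c(adj[[i]], k)
    adj[[j]] <- c(adj[[j]], k)
  }
  other_end <- function(k, a) if (mol$bonds$i[k] == a) mol$bonds$j[k] else mol$bonds$i[k]

  visited <- logical(na)
  tree_children <- vector("list", na)   # bond indices, in DFS order
  parent_bond <- rep(NA_integer_, na)
  ring_bonds <- integer()
  # iterative DFS for spanning tree
  order_stack <- list(list(atom = 1L, from = NA_integer_))
  visited[1L] <- TRUE
  dfs <- function(a) {
    for (k in adj[[a]]) {
      if (!is.na(parent_bond[a]) && k == parent_bond[a]) next
      b <- other_end(k, a)
      if (!visited[b]) {
        visited[b] <<- TRUE
        parent_bond[b] <<- k
        tree_children[[a]] <<- c(tree_children[[a]], k)
        dfs(b)
      } else if (!(k %in% ring_bonds)) {
        ring_bonds <<- c(ring_bonds, k)
      }
    }
  }
  dfs(1L)
  if (!all(visited)) stop("cannot write SMILES: molecule is disconnected")

  # assign ring digits per ring bond
  ring_digit <- integer(0)
  if (length(ring_bonds)) ring_digit <- stats::setNames(seq_along(ring_bonds), ring_bonds)

  stereo_by_center <- list()
  for (st in mol$stereo) stereo_by_center[[as.character(st$center)]] <- st

  bond_sym <- function(k, a, b) {
    o <- mol$bonds$order[k]
    if (o == 2) return("=")
    if (o == 3) return("#")
    if (o == 1.5) return("")
    if (mol$atoms$arom[a] && mol$atoms$arom[b]) return("-")
    ""
  }

  atom_token <- function(a, written_nbrs) {
    at <- mol$atoms[a, ]
    bsum <- sum(mol$bonds$order[c(parent_bond[a], tree_children[[a]],
                                  ring_bonds[ring_bonds %in% adj[[a]]])],
                na.rm = TRUE)
    st <- stereo_by_center[[as.character(a)]]
    elem_tok <- if (at$arom) tolower(at$element) else at$element
    plain_ok <- at$element %in% .organic_subset && at$charge == 0L &&
      at$isotope == 0L && at$map == 0L && is.null(st) &&
      identical(at$hcount, implied_hcount(at$element, at$arom, bsum))
    if (plain_ok) return(elem_tok)
    chi_tok <- ""
    if (!is.null(st)) {
      # parity of the permutation stored-order -> written-order
      stored <- st$nbrs
      written <- written_nbrs
      # the implicit H sits right after the parent atom (first if no parent)
      if (at$hcount > 0L) {
        written <- append(written, 0L, after = if (is.na(parent_bond[a])) 0L else 1L)
      }
      if (!setequal(stored, written) || length(written) != 4L) {
        stop("internal error: stereo neighbor mismatch at atom ", a)
      }
      sgn <- perm_sign(match(written, stored))
      p <- st$parity * sgn
      chi_tok <- if (p == 1L) "@" else "@@"
    }
    h_tok <- if (at$hcount == 1L) "H" else if (at$hcount > 1L) paste0("H", at$hcount) else ""
    q <- at$charge
    q_tok <- if (q > 0L) paste0("+", if (q > 1L) q else "") else
      if (q < 0L) paste0("-", if (q < -1L) -q else "") else ""
    iso_tok <- if (at$isotope > 0L) at$isotope else ""
    map_tok <- if (at$map > 0L) paste0(":", at$map) else ""
    paste0("[", iso_tok, elem_tok, chi_tok, h_tok, q_tok, map_tok, "]")
  }

  emit <- function(a, parent) {
    # written neighbor order: parent, (implicit H inside token), ring partners, children
    ring_here <- ring_bonds[vapply(ring_bonds, function(k)
      mol$bonds$i[k] == a || mol$bonds$j[k] == a, TRUE)]
    written <- integer()
    if (!is.na(parent)) written <- c(written, parent)
    written <- c(written, vapply(ring_here, other_end, 0L, a = a))
    kids <- tree_children[[a]]
    written <- c(written, vapply(kids, other_end, 0L, a = a))
    out <- atom_token(a, written)
    for (k in ring_here) {
      d <- ring_digit[[as.character(k)]]
      sym <- bond_sym(k, a, other_end(k, a))
      out <- paste0(out, sym, if (d > 9) paste0("%", d) else d)
    }
    nk <- length(kids)
    for (idx in seq_along(kids)) {
      k <- kids[idx]
      b <- other_end(k, a)
      sub <- paste0(bond_sym(k, a, b), emit(b, a))
      out <- if (idx < nk) paste0(out, "(", sub, ")") else paste0(out, sub)
    }
    out
  }

  emit(1L, NA_integer_)
}

# molecular formula, e.g. "C2H8N2" (Hill-ish order, implicit H included)
mol_formula <- function(mol) {
  counts <- table(mol$atoms$element)
  h <- sum(mol$atoms$hcount, na.rm = TRUE) +
    sum(names(counts) == "H") * 0  # explicit H already in counts
  if ("H" %in% names(counts)) h <- h + counts[["H"]]
  counts <- counts[names(counts) != "H"]
  els <- sort(names(counts))
  if ("C" %in% els) els <- c("C", setdiff(els, "C"))
  out <- ""
  for (e in els) {
    out <- paste0(out, e, if (counts[[e]] > 1) counts[[e]] else "")
    if (e == "C" && h > 0) out <- paste0(out, "H", if (h > 1) h else "")
  }
  if (!("C" %in% els) && h > 0) out <- paste0(out, "H", if (h > 1) h else "")
  out
}

# replace implicit hydrogens by explicit H vertices (needed for embedding and
# for stereo bookkeeping in the assembled complex)
add_hydrogens <- function(mol) {
  na0 <- n_atoms(mol)
  atoms <- mol$atoms
  bonds <- mol$bonds
  stereo <- mol$stereo
  next_idx <- na0
  for (a in seq_len(na0)) {
    hc <- atoms$hcount[a]
    if (is.na(hc) || hc == 0L) next
    h_ids <- integer(hc)
    for (h in seq_len(hc)) {
      next_idx <- next_idx + 1L
      atoms <- rbind(atoms, data.frame(element = "H", arom = FALSE, charge = 0L,
                                       isotope = 0L, hcount = 0L, map = 0L))
      bonds <- rbind(bonds, data.frame(i = a, j = next_idx, order = 1, dative = FALSE))
      h_ids[h] <- next_idx
    }
    atoms$hcount[a] <- 0L
    # implicit-H placeholder in stereo records becomes the first added H
    for (s in seq_along(stereo)) {
      if (stereo[[s]]$center == a && any(stereo[[s]]$nbrs == 0L)) {
        stereo[[s]]$nbrs[stereo[[s]]$nbrs == 0L] <- h_ids[1L]
      }
    }
  }
  new_mol(atoms, bonds, stereo)
}
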