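# XYZ input/output. The comment line of each written file carries a
# machine-readable key=value record (schema "coordenum:1") sufficient to
# rebuild an equivalent stereoisomer: central atom, geometry, donor-marked
# ligand SMILES, vertex arrangement, donor parities, and provenance.

fnv1a_hex <- function(s) {
  # polynomial rolling hash, used only as a short content checksum
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

metadata_line <- function(conformer) {
  s <- conformer$stereomer
  defn <- s$defn
  ligs <- vapply(defn$ligands, function(l) write_smiles(l$mol), "")
  # parities are stored per donor *label* (stable under SMILES re-writing),
  # not per atom index
  par_tok <- if (length(s$parities)) {
    lab <- s$graph$donors$label[match(as.integer(names(s$parities)),
                                      s$graph$donors$gatom)]
    paste(lab, s$parities, sep = ":", collapse = ",")
  } else "-"
  sig_rep <- if (!is.null(s$signature)) fnv1a_hex(s$signature[1L]) else "-"
  paste(
    "coordenum:1",
    paste0("metal=", defn$metal),
    paste0("charge=", defn$metal_charge),
    paste0("geometry=", defn$geometry),
    paste0("fixed=", as.integer(defn$fixed)),
    paste0("ligands=", paste(ligs, collapse = ",")),
    paste0("arrangement=", paste(s$arrangement, collapse = ";")),
    paste0("parities=", par_tok),
    paste0("sig=", sig_rep),
    paste0("energy=", formatC(conformer$energy, digits = 6, format = "g")),
    paste0("seed=", conformer$seed)
  )
}

#' Write a conformer to an XYZ file
#'
#' Standard XYZ (atom count, comment, element x y z at six decimal places);
#' the comment line carries the structured metadata record that lets
#' [read_xyz()] rebuild an equivalent stereoisomer without information loss.
#'
#' @param conformer a verified `cdn_conformer`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_xyz <- function(conformer, path) {
  stopifnot(inherits(conformer, "cdn_conformer"))
  n <- length(conformer$elements)
  lines <- c(
    as.character(n),
    metadata_line(conformer),
    sprintf("%-3s %14.6f %14.6f %14.6f", conformer$elements,
            conformer$coords[, 1], conformer$coords[, 2], conformer$coords[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}

parse_metadata <- function(line) {
  if (!startsWith(line, "coordenum:1")) return(NULL)
  toks <- strsplit(line, " ", fixed = TRUE)[[1]][-1]
  kv <- strsplit(toks, "=", fixed = TRUE)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  names(vals) <- vapply(kv, `[[`, "", 1L)
  vals
}

#' Read an XYZ file written by [write_xyz()] (or plain XYZ)
#'
#' @param path XYZ file path
#' @return `list(conformer = , stereomer = )`; for a plain XYZ without the
#'   package's metadata record, `stereomer` is `NULL` and a warning is
#'   issued. Malformed files produce an error naming the offending line.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("malformed XYZ '", path, "': fewer than 2 lines")
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L) stop("malformed XYZ '", path, "': line 1 is not an atom count")
  if (length(lines) < 2L + n) {
    stop("malformed XYZ '", path, "': expected ", n, " coordinate lines, found ",
         length(lines) - 2L)
  }
  el <- character(n)
  xyz <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    parts <- strsplit(trimws(lines[2L + k]), "[[:space:]]+")[[1]]
    if (length(parts) < 4L) {
      stop("malformed XYZ '", path, "': coordinate line ", 2L + k,
           " has fewer than 4 fields")
    }
    v <- suppressWarnings(as.numeric(parts[2:4]))
    if (any(is.na(v))) {
      stop("malformed XYZ '", path, "': non-numeric coordinates on line ", 2L + k)
    }
    el[k] <- parts[1L]
    xyz[k, ] <- v
  }
  meta <- parse_metadata(lines[2L])
  if (is.null(meta)) {
    warning("no metadata record on comment line of '", path,
            "'; returning bare coordinates")
    conf <- structure(list(elements = el, coords = xyz, energy = NA_real_,
                           stereomer = NULL, seed = NA_integer_,
                           verified = NA),
                      class = "cdn_conformer")
    return(list(conformer = conf, stereomer = NULL))
  }
  ligs <- strsplit(meta[["ligands"]], ",", fixed = TRUE)[[1]]
  defn <- assemble_complex(paste0(meta[["metal"]],
                                  ifelse(as.integer(meta[["charge"]]) >= 0, "+", "-"),
                                  abs(as.integer(meta[["charge"]]))),
                           meta[["geometry"]], as.list(ligs),
                           fixed = meta[["fixed"]] == "1")
  graph <- build_graph(defn)
  arrangement <- as.integer(strsplit(meta[["arrangement"]], ";", fixed = TRUE)[[1]])
  parities <- integer()
  if (meta[["parities"]] != "-") {
    pt <- strsplit(strsplit(meta[["parities"]], ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
    labs <- vapply(pt, function(x) as.integer(x[1]), 0L)
    gatoms <- graph$donors$gatom[match(labs, graph$donors$label)]
    parities <- stats::setNames(vapply(pt, function(x) as.integer(x[2]), 0L),
                                as.character(gatoms))
  }
  s <- new_stereomer(defn, graph, arrangement, parities)
  if (length(el) != n_atoms(graph)) {
    stop("metadata of '", path, "' rebuilds a complex with ", n_atoms(graph),
         " atoms but the file holds ", length(el))
  }
  conf <- structure(list(elements = el, coords = xyz,
                         energy = as.numeric(meta[["energy"]]),
                         stereomer = s,
                         seed = as.integer(meta[["seed"]]),
                         verified = NA),
                    class = "cdn_conformer")
  list(conformer = conf, stereomer = s)
}
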