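#' Read a macromolecular coordinate file
#'
#' Parses a PDB or mmCIF file into a `ribs_structure`: a flat atom table
#' keyed by (chain, residue number, insertion code, atom name). Alternate
#' locations are resolved immediately after parsing -- for each atom key the
#' altloc with the highest occupancy is kept, ties broken by lexicographically
#' smallest altloc identifier -- so downstream selections always see exactly
#' one atom per key. Waters are excluded by default.
#'
#' Only the first model of a multi-model file is read; the crystallographic
#' entries this package targets are single-model.
#'
#' @param path Path to a `.pdb`/`.ent` or `.cif`/`.mmcif` file.
#' @param format Format hint; `"auto"` (default) detects from the extension.
#' @param entry_id Entry identifier to attach; defaults to the file base name
#'   without extension, upper-cased.
#' @param keep_waters Keep water residues (HOH/WAT/DOD)? Default `FALSE`.
#' @return An object of class `ribs_structure`: a list with elements
#'   `entry_id`, `atoms` (data frame with columns `model`, `chain`, `resno`,
#'   `insert`, `resid`, `elety`, `elesy`, `x`, `y`, `z`, `o`, `alt`) and
#'   `format`.
#' @seealso [write_structure()], [select_atoms()]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           entry_id = NULL, keep_waters = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("coordinate file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      pdb = "pdb", ent = "pdb",
      cif = "cif", mmcif = "cif",
      stop("cannot detect coordinate format from extension '.", ext,
           "'; pass format = \"pdb\" or \"cif\"", call. = FALSE)
    )
  }
  raw <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    } else {
      suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE))
    },
    error = function(e) {
      stop("failed to parse ", format, " file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  at <- raw$atom
  if (is.null(at) || nrow(at) == 0) {
    stop("no atoms parsed from '", path, "'", call. = FALSE)
  }
  atoms <- data.frame(
    model  = 1L,
    chain  = as.character(at$chain),
    resno  = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resid  = as.character(at$resid),
    elety  = as.character(at$elety),
    elesy  = ifelse(is.na(at$elesy), "", as.character(at$elesy)),
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    o = ifelse(is.na(at$o), 1, as.numeric(at$o)),
    alt = ifelse(is.na(at$alt), "", as.character(at$alt)),
    stringsAsFactors = FALSE
  )
  if (!keep_waters) {
    atoms <- atoms[!atoms$resid %in% c("HOH", "WAT", "DOD", "H2O"), ,
                   drop = FALSE]
  }
  if (nrow(atoms) == 0) {
    stop("no non-water atoms in '", path, "'", call. = FALSE)
  }
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in '", path, "'", call. = FALSE)
  }
  bad_occ <- atoms$o < 0 | atoms$o > 1
  if (any(bad_occ)) {
    warning(sum(bad_occ), " occupancy value(s) outside [0, 1] clamped")
    atoms$o <- pmin(pmax(atoms$o, 0), 1)
  }
  atoms <- resolve_altlocs(atoms)
  if (is.null(entry_id)) {
    entry_id <- toupper(tools::file_path_sans_ext(basename(path)))
  }
  new_structure(entry_id, atoms, format)
}

new_structure <- function(entry_id, atoms, format) {
  rownames(atoms) <- NULL
  structure(
    list(entry_id = entry_id, atoms = atoms, format = format),
    class = "ribs_structure"
  )
}

#' @export
print.ribs_structure <- function(x, ...) {
  cat("<ribs_structure> ", x$entry_id, ": ", nrow(x$atoms), " atoms, chains ",
      paste(sort(unique(x$atoms$chain)), collapse = " "),
      " [", x$format, "]\n", sep = "")
  invisible(x)
}

# Keep one altloc per (chain, resno, insert, elety): highest occupancy,
# ties by lexicographic altloc id.
resolve_altlocs <- function(atoms) {
  ord <- order(atoms$chain, atoms$resno, atoms$insert, atoms$elety,
               -atoms$o, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "\r")
  atoms <- atoms[!duplicated(key), , drop = FALSE]
  rownames(atoms) <- NULL
  atoms
}

#' Write a structure as a PDB file
#'
#' Emits standard fixed-column ATOM records with three-decimal coordinates
#' (C `%.3f` rounding). Residue numbers above 9999 and multi-character chain
#' identifiers cannot be represented in PDB columns and raise an error.
#'
#' @param structure A `ribs_structure`.
#' @param path Output file path.
#' @param format Only `"pdb"` is supported.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, format = "pdb") {
  stopifnot(inherits(structure, "ribs_structure"))
  format <- match.arg(format, "pdb")
  at <- structure$atoms
  if (nrow(at) == 0) {
    stop("refusing to write an empty structure", call. = FALSE)
  }
  if (any(at$resno > 9999L | at$resno < -999L)) {
    stop("residue numbers outside the PDB range [-999, 9999] cannot be written",
         call. = FALSE)
  }
  if (any(nchar(at$chain) > 1L)) {
    stop("chain ids longer than one character cannot be written as PDB",
         call. = FALSE)
  }
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(at)),
    resno = at$resno,
    resid = at$resid,
    eleno = seq_len(nrow(at)),
    elety = at$elety,
    chain = at$chain,
    insert = ifelse(at$insert == "", NA, at$insert),
    alt = ifelse(at$alt == "", NA, at$alt),
    o = at$o,
    b = rep(0, nrow(at)),
    elesy = at$elesy,
    end = TRUE
  )
  invisible(path)
}

#' Define an atom selection
#'
#' @param chains Character vector of chain ids.
#' @param ranges Residue ranges: a list of inclusive `c(start, end)` integer
#'   pairs, or a two-column matrix. `NULL` selects all residues.
#' @param atom_names Atom names to keep; `NULL` (or empty) means all atoms.
#' @return A `ribs_selection`.
#' @export
selection <- function(chains, ranges = NULL, atom_names = "P") {
  ranges <- normalize_ranges(ranges)
  if (!is.null(ranges) && any(ranges[, 1] > ranges[, 2])) {
    stop("selection range with start > end", call. = FALSE)
  }
  structure(
    list(chains = as.character(chains), ranges = ranges,
         atom_names = if (length(atom_names)) as.character(atom_names) else NULL),
    class = "ribs_selection"
  )
}

normalize_ranges <- function(ranges) {
  if (is.null(ranges)) return(NULL)
  if (is.matrix(ranges)) {
    storage.mode(ranges) <- "integer"
    return(ranges)
  }
  if (is.numeric(ranges) && length(ranges) == 2) ranges <- list(ranges)
  do.call(rbind, lapply(ranges, function(r) as.integer(r[1:2])))
}

#' Select atoms from a structure
#'
#' Filters the atom table by chain, residue ranges and atom name, returning
#' atoms ordered by (chain, residue number, insertion code). With the default
#' atom name `"P"` this yields one backbone phosphorus per modeled RNA
#' residue, the single atom per residue used for all rigid-body fits.
#'
#' An empty result is returned with a warning, not an error, so callers can
#' distinguish a missing chain from a malformed request.
#'
#' @param structure A `ribs_structure`.
#' @param sel A `ribs_selection` (see [selection()]).
#' @return Data frame of matching atoms (possibly zero rows), ordered.
#' @export
select_atoms <- function(structure, sel) {
  stopifnot(inherits(structure, "ribs_structure"),
            inherits(sel, "ribs_selection"))
  at <- structure$atoms
  keep <- at$chain %in% sel$chains
  if (!is.null(sel$ranges)) {
    in_range <- rep(FALSE, nrow(at))
    for (i in seq_len(nrow(sel$ranges))) {
      in_range <- in_range |
        (at$resno >= sel$ranges[i, 1] & at$resno <= sel$ranges[i, 2])
    }
    keep <- keep & in_range
  }
  if (!is.null(sel$atom_names)) {
    keep <- keep & at$elety %in% sel$atom_names
  }
  out <- at[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("selection matched no atoms (chains ",
            paste(sel$chains, collapse = ","), ")")
  }
  out <- out[order(out$chain, out$resno, out$insert), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair equivalent atoms between two atom lists
#'
#' Deposited models routinely differ in which residues are modeled, so two
#' selections of "the same" domain rarely have identical lengths. Atoms are
#' matched on the key (residue number, insertion code, atom name) -- chains
#' are assumed to be already mapped -- and the order-aligned intersection is
#' returned. Falling below `min_pairs` is an error; losing more than 20% of
#' the smaller list is a warning.
#'
#' @param a,b Atom data frames as returned by [select_atoms()].
#' @param min_pairs Minimum acceptable number of pairs (default 50).
#' @return A list with aligned data frames `a` and `b` (equal row counts).
#' @export
pair_atoms <- function(a, b, min_pairs = 50L) {
  key <- function(d) paste(d$resno, d$insert, d$elety, sep = "\r")
  ka <- key(a); kb <- key(b)
  if (anyDuplicated(ka) || anyDuplicated(kb)) {
    stop("atom lists must be unique on (resno, insert, atom name)",
         call. = FALSE)
  }
  common <- intersect(ka, kb)
  ia <- match(common, ka)
  # order pairs by a's (resno, insert, elety) sort order for determinism
  ia <- sort(ia)
  common <- ka[ia]
  ib <- match(common, kb)
  n <- length(common)
  if (n < min_pairs) {
    stop("only ", n, " atom pairs matched; minimum required is ", min_pairs,
         " (inputs had ", length(ka), " and ", length(kb), " atoms)",
         call. = FALSE)
  }
  if (n < 0.8 * min(length(ka), length(kb))) {
    warning("matched ", n, " pairs from lists of ", length(ka), " and ",
            length(kb), " atoms (< 80% of the smaller list)")
  } else if (n < max(length(ka), length(kb))) {
    warning("matched ", n, " pairs from lists of ", length(ka), " and ",
            length(kb), " atoms")
  }
  list(a = a[ia, , drop = FALSE], b = b[ib, , drop = FALSE])
}

#' Define a rigid domain
#'
#' A domain is a residue range set on one molecule, three marker residues
#' whose P atoms define its orientation frame, an optional explicit core
#' residue list used for the rigid-body fit (defaults to all residues in the
#' ranges), and a map from structure entry id to chain id.
#'
#' The defaults shipped with [default_domains()] follow the conventional
#' E. coli-style 16S/23S numbering: head = 16S 930-1380 with markers
#' 984/940/1106; body markers 41/127/911.
#'
#' @param name Domain name, one of `"head"`, `"body"`, `"anchor23S"`.
#' @param molecule `"16S"` or `"23S"`.
#' @param ranges Residue ranges as in [selection()].
#' @param markers Exactly three marker residue numbers, inside the ranges.
#'   `NULL` for anchor domains that are only ever fit targets.
#' @param core Optional explicit core residue numbers (subset of the ranges).
#' @param chain_map Named character vector mapping entry id to chain id; the
#'   name `"default"` supplies a fallback for unlisted entries.
#' @return A `ribs_domain`.
#' @export
domain_definition <- function(name, molecule, ranges, markers = NULL,
                              core = NULL, chain_map = c(default = "A")) {
  name <- match.arg(name, c("head", "body", "anchor23S"))
  molecule <- match.arg(molecule, c("16S", "23S"))
  ranges <- normalize_ranges(ranges)
  in_ranges <- function(r) {
    any(r >= ranges[, 1] & r <= ranges[, 2])
  }
  if (!is.null(markers)) {
    markers <- as.integer(markers)
    if (length(markers) != 3L) {
      stop("exactly three marker residues are required", call. = FALSE)
    }
    if (!all(vapply(markers, in_ranges, logical(1)))) {
      stop("marker residues must lie inside the domain residue ranges",
           call. = FALSE)
    }
  }
  if (!is.null(core)) {
    core <- as.integer(core)
    if (!all(vapply(core, in_ranges, logical(1)))) {
      stop("core residues must be a subset of the domain residue ranges",
           call. = FALSE)
    }
  }
  structure(
    list(name = name, molecule = molecule, ranges = ranges,
         markers = markers, core = core, chain_map = chain_map),
    class = "ribs_domain"
  )
}

#' Resolve the chain id of a domain within a structure
#'
#' @param domain A `ribs_domain`.
#' @param structure A `ribs_structure` (or an entry id string).
#' @param override Optional chain id that bypasses the map (used for
#'   asymmetric-unit copy selection).
#' @return Chain id string.
#' @export
chain_for <- function(domain, structure, override = NULL) {
  if (!is.null(override)) return(override)
  id <- if (inherits(structure, "ribs_structure")) structure$entry_id else structure
  cm <- domain$chain_map
  if (id %in% names(cm)) return(unname(cm[[id]]))
  if ("default" %in% names(cm)) return(unname(cm[["default"]]))
  if (length(cm) == 1 && is.null(names(cm))) return(unname(cm))
  stop("no chain mapped for entry '", id, "' in domain '", domain$name, "'",
       call. = FALSE)
}

# Selection of a domain's core P atoms (explicit core list if present,
# otherwise every residue in the ranges).
core_selection <- function(domain, structure, chain = NULL) {
  ch <- chain_for(domain, structure, chain)
  if (!is.null(domain$core)) {
    selection(ch, ranges = cbind(domain$core, domain$core), atom_names = "P")
  } else {
    selection(ch, ranges = domain$ranges, atom_names = "P")
  }
}

# Selection of all the domain's P atoms (full ranges, used for per-residue
# displacement vectors).
domain_selection <- function(domain, structure, chain = NULL) {
  selection(chain_for(domain, structure, chain), ranges = domain$ranges,
            atom_names = "P")
}

#' Default head/body/anchor domain definitions
#'
#' Head = 16S rRNA nucleotides 930-1380 (markers 984, 940, 1106);
#' body = the remainder of the 16S (markers 41, 127, 911); anchor = the 23S
#' rRNA. Chain maps default to the synthetic generator's chains
#' (anchor `"A"`, 16S `"B"`) and should be overridden per deposited entry.
#'
#' @param chain_16S,chain_23S Default chain ids.
#' @return Named list of `ribs_domain` objects: `head`, `body`, `anchor`.
#' @export
default_domains <- function(chain_16S = "B", chain_23S = "A") {
  list(
    head = domain_definition(
      "head", "16S", list(c(930L, 1380L)), markers = c(984L, 940L, 1106L),
      chain_map = c(default = chain_16S)),
    body = domain_definition(
      "body", "16S", list(c(1L, 929L), c(1381L, 1542L)),
      markers = c(41L, 127L, 911L),
      chain_map = c(default = chain_16S)),
    anchor = domain_definition(
      "anchor23S", "23S", list(c(1L, 2904L)),
      chain_map = c(default = chain_23S))
  )
}

# Extract an n x 3 coordinate matrix from an atom data frame.
atom_coords <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

# Coordinates of the P atoms of a domain's three markers, in marker order.
marker_coords <- function(structure, domain, chain = NULL) {
  ch <- chain_for(domain, structure, chain)
  at <- structure$atoms
  out <- matrix(NA_real_, 3, 3)
  for (i in 1:3) {
    hit <- which(at$chain == ch & at$resno == domain$markers[i] &
                 at$elety == "P")
    if (length(hit) != 1) {
      stop("marker residue ", domain$markers[i], " (chain ", ch,
           ") does not resolve to exactly one P atom in entry ",
           structure$entry_id, call. = FALSE)
    }
    out[i, ] <- c(at$x[hit], at$y[hit], at$z[hit])
  }
  out
}
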