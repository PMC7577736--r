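#' Specify a single atom
#'
#' @param chain Chain id.
#' @param resno Residue number (author numbering).
#' @param atom Atom name.
#' @param insert Insertion code (default empty).
#' @return A `ribs_atomspec`.
#' @export
atom_spec <- function(chain, resno, atom, insert = "") {
  structure(list(chain = as.character(chain), resno = as.integer(resno),
                 atom = as.character(atom), insert = as.character(insert)),
            class = "ribs_atomspec")
}

resolve_atom <- function(structure, spec) {
  at <- structure$atoms
  hit <- which(at$chain == spec$chain & at$resno == spec$resno &
               at$insert == spec$insert & at$elety == spec$atom)
  if (length(hit) != 1) {
    stop("atom ", spec$chain, "/", spec$resno, spec$insert, "/", spec$atom,
         " resolves to ", length(hit), " atoms in entry ",
         structure$entry_id, call. = FALSE)
  }
  c(at$x[hit], at$y[hit], at$z[hit])
}

residue_atoms <- function(structure, chain, resno, heavy_only = TRUE,
                          insert = NULL) {
  at <- structure$atoms
  keep <- at$chain == chain & at$resno == resno
  if (!is.null(insert)) keep <- keep & at$insert == insert
  if (heavy_only) keep <- keep & !(toupper(at$elesy) %in% "H")
  at[keep, , drop = FALSE]
}

#' Distance between two named atoms
#'
#' Euclidean distance in Angstrom, e.g. between the N4 of an anticodon C34
#' and the N3 of the codon's third nucleotide to score the single hydrogen
#' bond of a C-C mismatch pair.
#'
#' @param structure A `ribs_structure`.
#' @param a,b `ribs_atomspec` objects.
#' @return Distance in Angstrom.
#' @export
atom_distance <- function(structure, a, b) {
  pa <- resolve_atom(structure, a)
  pb <- resolve_atom(structure, b)
  sqrt(sum((pa - pb)^2))
}

#' Minimum inter-residue atom distance
#'
#' Minimum pairwise distance between the (by default heavy) atoms of two
#' residues. An unmodeled residue yields `NA` with a warning rather than an
#' error, so contact classification can report "undetermined".
#'
#' @param structure A `ribs_structure`.
#' @param res_a,res_b Residues as `list(chain =, resno =)`.
#' @param heavy_only Exclude hydrogens (default `TRUE`).
#' @return Minimum distance in Angstrom, or `NA_real_`.
#' @export
min_residue_distance <- function(structure, res_a, res_b, heavy_only = TRUE) {
  a <- residue_atoms(structure, res_a$chain, res_a$resno, heavy_only)
  b <- residue_atoms(structure, res_b$chain, res_b$resno, heavy_only)
  if (nrow(a) == 0 || nrow(b) == 0) {
    warning("residue ", if (nrow(a) == 0) paste0(res_a$chain, "/", res_a$resno)
            else paste0(res_b$chain, "/", res_b$resno),
            " is not modeled; distance undetermined")
    return(NA_real_)
  }
  xa <- atom_coords(a)
  xb <- atom_coords(b)
  # squared cross-distances via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2 a.b
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  sqrt(max(0, min(d2)))
}

#' Classify a residue-residue contact
#'
#' A contact (e.g. the 16S G966-C1400 gate between the 30S head and body
#' domains) is `intact` when the minimum heavy-atom distance is at or below
#' the cutoff, `broken` when above it, and `undetermined` when either
#' residue is unmodeled. The cutoff default of 4.0 Angstrom is a
#' conventional heavy-atom contact threshold and is always reported
#' alongside the call.
#'
#' @inheritParams min_residue_distance
#' @param cutoff Contact cutoff in Angstrom (default 4.0).
#' @return A `ribs_contact`: `res_a`, `res_b`, `distance`, `status`,
#'   `cutoff`.
#' @export
classify_contact <- function(structure, res_a, res_b, cutoff = 4.0) {
  d <- withCallingHandlers(
    min_residue_distance(structure, res_a, res_b),
    warning = function(w) invokeRestart("muffleWarning")
  )
  status <- if (is.na(d)) "undetermined" else if (d <= cutoff) "intact"
            else "broken"
  structure(list(res_a = res_a, res_b = res_b, distance = d,
                 status = status, cutoff = cutoff),
            class = "ribs_contact")
}

#' @export
print.ribs_contact <- function(x, ...) {
  cat(sprintf("<ribs_contact> %s/%d -- %s/%d: %s (min %.2f A, cutoff %.1f A)\n",
              x$res_a$chain, x$res_a$resno, x$res_b$chain, x$res_b$resno,
              x$status, if (is.na(x$distance)) NA else x$distance, x$cutoff))
  invisible(x)
}

#' Nearest mRNA phosphate to a base residue
#'
#' Finds the mRNA residue whose backbone P atom lies nearest any heavy atom
#' of the query residue -- the measurement that identifies which mRNA
#' phosphate the 16S G926 nucleobase engages at the E-site 3' boundary.
#' Ties are broken toward the lower residue number.
#'
#' @param structure A `ribs_structure`.
#' @param base_res Query residue as `list(chain =, resno =)`.
#' @param mrna_chain Chain id of the mRNA.
#' @return List with `resno` (mRNA residue number) and `distance` (Angstrom).
#' @export
nearest_phosphate <- function(structure, base_res, mrna_chain) {
  base <- residue_atoms(structure, base_res$chain, base_res$resno)
  if (nrow(base) == 0) {
    stop("query residue ", base_res$chain, "/", base_res$resno,
         " is not modeled", call. = FALSE)
  }
  at <- structure$atoms
  p_atoms <- at[at$chain == mrna_chain & at$elety == "P", , drop = FALSE]
  if (nrow(p_atoms) == 0) {
    stop("no P atoms on chain '", mrna_chain, "'", call. = FALSE)
  }
  xb <- atom_coords(base)
  xp <- atom_coords(p_atoms)
  d2 <- outer(rowSums(xp^2), rowSums(xb^2), "+") - 2 * tcrossprod(xp, xb)
  dmin <- sqrt(pmax(0, apply(d2, 1, min)))
  best <- order(dmin, p_atoms$resno)[1]
  list(resno = p_atoms$resno[best], distance = dmin[best])
}

#' mRNA backbone kink angle at a vertex residue
#'
#' Measures how sharply the mRNA path turns as it leaves the E site. The
#' incoming direction is `P(vertex - 1) -> P(vertex)`; the outgoing
#' direction is `P(vertex) -> P(vertex + 2)` (a two-step vector chosen to
#' span the codon). The returned value is the turn angle between the two
#' directions: 0 degrees for a straight path, 90 for a right-angle turn.
#'
#' @param structure A `ribs_structure`.
#' @param mrna_chain Chain id of the mRNA.
#' @param vertex Residue number of the kink vertex.
#' @return Turn angle in degrees.
#' @export
mrna_kink <- function(structure, mrna_chain, vertex) {
  p_of <- function(resno) {
    at <- structure$atoms
    hit <- which(at$chain == mrna_chain & at$resno == resno & at$elety == "P")
    if (length(hit) != 1) {
      stop("P atom of mRNA residue ", resno, " (chain ", mrna_chain,
           ") is missing", call. = FALSE)
    }
    c(at$x[hit], at$y[hit], at$z[hit])
  }
  v_in <- p_of(vertex) - p_of(vertex - 1L)
  v_out <- p_of(vertex + 2L) - p_of(vertex)
  cosang <- sum(v_in * v_out) / (sqrt(sum(v_in^2)) * sqrt(sum(v_out^2)))
  acos(min(1, max(-1, cosang))) * 180 / pi
}
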