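#' Wrap an angle into (-180, 180] degrees
#'
#' @param x Angle(s) in degrees.
#' @return Wrapped angle(s).
#' @export
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[abs(y + 180) < 1e-12] <- 180
  y
}

# Align `mobile` onto `reference` using the anchor domain's core P atoms and
# return the transformed structure plus the superposition diagnostics.
align_on_anchor <- function(mobile, reference, anchor, min_pairs = 50L,
                            mobile_chain = NULL, reference_chain = NULL) {
  a <- select_atoms(mobile, core_selection(anchor, mobile, mobile_chain))
  b <- select_atoms(reference, core_selection(anchor, reference, reference_chain))
  pr <- pair_atoms(a, b, min_pairs)
  sup <- superpose(atom_coords(pr$a), atom_coords(pr$b))
  list(structure = transform_structure(mobile, sup$transform),
       superposition = sup)
}

# Fit the reference (classical) domain core onto the same domain in `target`
# (both already in the anchor-aligned frame). The returned transform carries
# reference-frame points -- in particular the marker P atoms -- into the
# target's domain orientation even when the target's own markers are
# unmodeled.
fit_domain <- function(reference, target, domain, min_pairs = 50L,
                       reference_chain = NULL, target_chain = NULL) {
  a <- select_atoms(reference, core_selection(domain, reference, reference_chain))
  b <- select_atoms(target, core_selection(domain, target, target_chain))
  pr <- pair_atoms(a, b, min_pairs)
  superpose(atom_coords(pr$a), atom_coords(pr$b))
}

#' Calibrate the pure-swivel axis from a reference structure pair
#'
#' The classical (unrotated) structure defines the zero orientation; the
#' fully swiveled structure defines, together with it, the tilt-free swivel
#' axis. Both structures are placed in a common frame by aligning the
#' swiveled one onto the classical one over the anchor domain's core P atoms
#' (23S core for the body domain; 16S body core for the head domain). The
#' classical domain core is then fitted onto the swiveled domain core,
#' carrying the three marker P atoms; the rotation between the classical
#' marker frame and the fitted marker frame yields the swivel axis and the
#' calibration magnitude.
#'
#' The axis direction is the one for which the swiveled reference has
#' positive net swivel, so the counterclockwise swivel of the head (viewed
#' with the E-, P-, A-tRNA sites left to right) is positive by construction.
#' A point on the screw axis of the calibration motion is stored as the
#' rotation centre used by [decompose_displacements()].
#'
#' @param classical Classical (zero-orientation) `ribs_structure`.
#' @param swiveled Fully swiveled reference `ribs_structure`.
#' @param domain The mobile domain (`ribs_domain`), e.g. the head.
#' @param anchor The domain held fixed for the alignment (`ribs_domain`),
#'   e.g. the 16S body for head calibration.
#' @param min_pairs Minimum paired core atoms for any fit.
#' @param classical_chains,swiveled_chains Optional named chain overrides
#'   (`c(domain = , anchor = )`) for asymmetric-unit copy selection.
#' @return A `ribs_calibration`: `domain`, `anchor`, `zero_frame`
#'   (`ribs_frame` of the classical markers), `axis` (unit 3-vector),
#'   `axis_point` (point on the swivel axis line), `frame` (3x3 matrix whose
#'   columns are the calibration axes, z = swivel axis), `magnitude`
#'   (degrees) and `provenance`.
#' @export
calibrate_swivel <- function(classical, swiveled, domain, anchor,
                             min_pairs = 50L,
                             classical_chains = NULL, swiveled_chains = NULL) {
  al <- align_on_anchor(swiveled, classical, anchor, min_pairs,
                        mobile_chain = swiveled_chains$anchor,
                        reference_chain = classical_chains$anchor)
  fit <- fit_domain(classical, al$structure, domain, min_pairs,
                    reference_chain = classical_chains$domain,
                    target_chain = swiveled_chains$domain)
  mk0 <- marker_coords(classical, domain, classical_chains$domain)
  zero_frame <- frame_from_markers(mk0[1, ], mk0[2, ], mk0[3, ])
  mk1 <- apply_transform(fit$transform, mk0)
  obs_frame <- frame_from_markers(mk1[1, ], mk1[2, ], mk1[3, ])
  rel <- rotation_between_frames(zero_frame, obs_frame)
  aa <- axis_angle(rel)
  if (aa$angle < 0.1) {
    stop("degenerate calibration: rotation angle ", format(aa$angle),
         " degrees is below the 0.1 degree threshold", call. = FALSE)
  }
  u <- aa$axis
  # in-plane reference direction: zero-frame e1 projected off the axis
  e1 <- zero_frame$axes[, 1] - sum(zero_frame$axes[, 1] * u) * u
  if (sqrt(sum(e1^2)) < 1e-6) {
    e1 <- zero_frame$axes[, 2] - sum(zero_frame$axes[, 2] * u) * u
  }
  e1 <- unit(e1)
  frame <- cbind(e1, cross3(u, e1), u)
  cal <- structure(
    list(domain = domain, anchor = anchor, zero_frame = zero_frame,
         axis = u,
         axis_point = screw_axis_point(fit$transform$rotation,
                                       fit$transform$translation, u),
         frame = frame, magnitude = aa$angle,
         provenance = c(classical = classical$entry_id,
                        swiveled = swiveled$entry_id)),
    class = "ribs_calibration"
  )
  self <- euler_zxz(rel, cal)
  if (self$theta >= 0.5) {
    warning("calibration pair is not tilt-free: swiveled reference ",
            "decomposes with theta = ", sprintf("%.3f", self$theta),
            " degrees")
  }
  cal
}

#' @export
print.ribs_calibration <- function(x, ...) {
  cat(sprintf(
    "<ribs_calibration> domain %s: swivel axis (%.4f, %.4f, %.4f), magnitude %.3f deg\n",
    x$domain$name, x$axis[1], x$axis[2], x$axis[3], x$magnitude))
  invisible(x)
}

# z-x-z Euler extraction from a rotation matrix already expressed in the
# calibration frame: R = Rz(psi) %*% Rx(theta) %*% Rz(phi).
euler_zxz_matrix <- function(r) {
  deg <- 180 / pi
  # sin(theta) from the z column/row keeps full precision near 0 and 180,
  # where acos(r33) would lose ~sqrt(eps)
  sy <- sqrt((r[1, 3]^2 + r[2, 3]^2 + r[3, 1]^2 + r[3, 2]^2) / 2)
  theta <- atan2(sy, r[3, 3]) * deg
  if (sy < 1e-11) {
    # gimbal lock: only the in-plane sum (difference at 180) is defined;
    # report it all in psi so phi + psi stays well defined and continuous.
    # The threshold is kept tiny (sin theta < 1e-11) because collapsing phi
    # to zero costs a commutator error of order theta * phi in the
    # recomposition; above it the regular formulas are the accurate route.
    phi <- 0
    psi <- atan2(r[2, 1], r[1, 1]) * deg
  } else {
    psi <- atan2(r[1, 3], -r[2, 3]) * deg
    phi <- atan2(r[3, 1], r[3, 2]) * deg
  }
  list(phi = phi, theta = theta, psi = psi)
}

#' Euler-angle decomposition of a rotation in the calibration frame
#'
#' Expresses the rotation in the calibration frame (z = pure-swivel axis)
#' and decomposes it as intrinsic z-x-z: `R = Rz(psi) Rx(theta) Rz(phi)`.
#' `phi + psi` is the net swivel angle, `theta` the tilt, and `phi` the tilt
#' direction. Near gimbal lock (`theta` within 1e-6 degrees of 0 or 180)
#' `phi` is set to 0 and `psi` carries the full in-plane angle, so the net
#' swivel is always well defined; `tilt_direction_defined` flags whether
#' `phi` is interpretable (tilt of at least 0.5 degrees).
#'
#' @param transform A `ribs_transform` or 3x3 rotation matrix (in the lab
#'   frame shared with the calibration).
#' @param calibration A `ribs_calibration`.
#' @return A `ribs_euler`: `phi`, `theta`, `psi`, `net_swivel`, `tilt`,
#'   `tilt_direction`, `tilt_direction_defined`.
#' @export
euler_zxz <- function(transform, calibration) {
  r <- if (inherits(transform, "ribs_transform")) transform$rotation
       else as.matrix(transform)
  stopifnot(inherits(calibration, "ribs_calibration"))
  m <- calibration$frame
  e <- euler_zxz_matrix(t(m) %*% r %*% m)
  structure(
    list(phi = e$phi, theta = e$theta, psi = e$psi,
         net_swivel = wrap_angle(e$phi + e$psi),
         tilt = e$theta,
         tilt_direction = e$phi,
         tilt_direction_defined = e$theta >= 0.5),
    class = "ribs_euler"
  )
}

#' @export
print.ribs_euler <- function(x, ...) {
  cat(sprintf(
    "<ribs_euler> net swivel %.3f deg, tilt %.3f deg (phi %.3f, theta %.3f, psi %.3f)\n",
    x$net_swivel, x$tilt, x$phi, x$theta, x$psi))
  invisible(x)
}

#' Compute the orientation of a domain in a model structure
#'
#' Runs the full protocol for one structure: (1) align the model onto the
#' classical reference over the anchor core P atoms; (2) fit the classical
#' domain core onto the model's domain core, recording the core-fit RMSD and
#' atom count; (3) carry the classical marker P atoms through that fit and
#' build the model's marker frame; (4) decompose the rotation from the
#' calibration's zero frame to the model frame into Euler angles about the
#' calibrated swivel axis.
#'
#' @param model `ribs_structure` to analyse.
#' @param calibration `ribs_calibration` for the domain.
#' @param classical The classical reference `ribs_structure` used in the
#'   calibration.
#' @param domain,anchor `ribs_domain` definitions (same as calibration).
#' @param min_pairs Minimum paired atoms for any fit (default 50).
#' @param copy Label for the asymmetric-unit copy being analysed.
#' @param model_chains Optional named chain overrides
#'   (`c(domain = , anchor = )`) for the model.
#' @return A `ribs_orientation`: entry id, copy, domain name, the
#'   `ribs_euler` decomposition plus flattened `net_swivel`, `tilt`,
#'   `tilt_direction`, and fit diagnostics `core_rmsd` and `n_atoms`.
#' @export
compute_orientation <- function(model, calibration, classical, domain, anchor,
                                min_pairs = 50L, copy = "1",
                                model_chains = NULL) {
  stopifnot(inherits(calibration, "ribs_calibration"))
  al <- align_on_anchor(model, classical, anchor, min_pairs,
                        mobile_chain = model_chains$anchor)
  fit <- fit_domain(classical, al$structure, domain, min_pairs,
                    target_chain = model_chains$domain)
  mk0 <- marker_coords(classical, domain)
  mk <- apply_transform(fit$transform, mk0)
  obs_frame <- frame_from_markers(mk[1, ], mk[2, ], mk[3, ])
  rel <- rotation_between_frames(calibration$zero_frame, obs_frame)
  eu <- euler_zxz(rel, calibration)
  structure(
    list(entry_id = model$entry_id, copy = copy, domain = domain$name,
         euler = eu,
         net_swivel = eu$net_swivel, tilt = eu$tilt,
         tilt_direction = eu$tilt_direction,
         tilt_direction_defined = eu$tilt_direction_defined,
         core_rmsd = fit$rmsd_after, n_atoms = fit$n_atoms,
         anchor_rmsd = al$superposition$rmsd_after,
         rotation = rel),
    class = "ribs_orientation"
  )
}

#' @export
print.ribs_orientation <- function(x, ...) {
  cat(sprintf(
    "<ribs_orientation> %s (copy %s) %s: net swivel %.3f deg, tilt %.3f deg [core rmsd %.3f A, n = %d]\n",
    x$entry_id, x$copy, x$domain, x$net_swivel, x$tilt, x$core_rmsd,
    x$n_atoms))
  if (!x$tilt_direction_defined) {
    cat("  (tilt < 0.5 deg: tilt direction undefined)\n")
  }
  invisible(x)
}

#' @export
as.data.frame.ribs_orientation <- function(x, ...) {
  data.frame(
    entry = x$entry_id, copy = x$copy, domain = x$domain,
    phi = x$euler$phi, theta = x$euler$theta, psi = x$euler$psi,
    net_swivel = x$net_swivel, tilt = x$tilt,
    tilt_direction = if (x$tilt_direction_defined) x$tilt_direction else NA_real_,
    core_rmsd = x$core_rmsd, n_atoms = x$n_atoms,
    stringsAsFactors = FALSE
  )
}

#' Decompose per-residue head displacements into swivel and tilt components
#'
#' After aligning the model onto the classical reference over the anchor
#' core, every paired domain P atom contributes a total displacement vector
#' `x_model - x_classical`. The swivel component is what a pure rotation by
#' the measured net swivel about the calibrated swivel-axis line would have
#' produced; the tilt component is the exact remainder, so the two components
#' sum to the total by construction.
#'
#' @inheritParams compute_orientation
#' @param orientation The `ribs_orientation` of this model (supplies the net
#'   swivel angle).
#' @return Data frame with one row per paired P atom: `chain`, `resno`,
#'   `insert`, total/swivel/tilt vector columns (`*_x`, `*_y`, `*_z`) and the
#'   displacement norms.
#' @export
decompose_displacements <- function(model, classical, orientation, calibration,
                                    domain, anchor, min_pairs = 50L,
                                    model_chains = NULL) {
  al <- align_on_anchor(model, classical, anchor, min_pairs,
                        mobile_chain = model_chains$anchor)
  a <- select_atoms(classical, domain_selection(domain, classical))
  b <- select_atoms(al$structure,
                    domain_selection(domain, al$structure,
                                     model_chains$domain))
  pr <- pair_atoms(a, b, min_pairs)
  x0 <- atom_coords(pr$a)
  x1 <- atom_coords(pr$b)
  total <- x1 - x0
  rs <- rotation_about_axis(calibration$axis, orientation$net_swivel)
  p <- calibration$axis_point
  swivel <- sweep(sweep(x0, 2, p) %*% t(rs), 2, p, "+") - x0
  tilt <- total - swivel
  out <- data.frame(
    chain = pr$a$chain, resno = pr$a$resno, insert = pr$a$insert,
    total_x = total[, 1], total_y = total[, 2], total_z = total[, 3],
    swivel_x = swivel[, 1], swivel_y = swivel[, 2], swivel_z = swivel[, 3],
    tilt_x = tilt[, 1], tilt_y = tilt[, 2], tilt_z = tilt[, 3],
    stringsAsFactors = FALSE
  )
  out$total_norm <- sqrt(rowSums(total^2))
  out$swivel_norm <- sqrt(rowSums(swivel^2))
  out$tilt_norm <- sqrt(rowSums(tilt^2))
  out
}
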