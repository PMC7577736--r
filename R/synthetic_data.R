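#' Ground truth for a synthetic pseudo-ribosome
#'
#' Collects every quantity that determines a generated structure triple, so
#' that regenerating from the same truth is bit-identical. Head angles are
#' the intrinsic z-x-z Euler angles applied in the swivel-axis frame; the
#' net swivel is `phi + psi` and the tilt is `theta`.
#'
#' @param phi,theta,psi Head Euler angles in degrees (`theta >= 0`).
#' @param body_angle Optional small in-plane rotation of the whole 16S
#'   stand-in about the global z axis through the body centroid (degrees).
#' @param axis Swivel axis direction (need not be unit length; must be
#'   non-zero).
#' @param sigma Isotropic Gaussian noise, Angstrom per coordinate, added to
#'   the model structure.
#' @param seed Integer seed; all randomness flows from it.
#' @param n_anchor,n_body,n_head P-atom counts per domain (each >= 50).
#'   Defaults 300/442/178; body and head match the core-residue counts used
#'   for the deposited-structure analysis.
#' @param reference_swivel In-plane rotation of the swiveled reference
#'   structure (degrees, default 21).
#' @return A `ribs_truth`.
#' @export
synthetic_truth <- function(phi = 0, theta = 0, psi = 0, body_angle = 0,
                            axis = c(0, 0, 1), sigma = 0, seed = 1L,
                            n_anchor = 300L, n_body = 442L, n_head = 178L,
                            reference_swivel = 21) {
  if (theta < 0) stop("theta must be non-negative", call. = FALSE)
  if (sqrt(sum(axis^2)) < 1e-12) {
    stop("degenerate swivel axis (zero vector)", call. = FALSE)
  }
  if (min(n_anchor, n_body, n_head) < 50L) {
    stop("each domain needs at least 50 atoms", call. = FALSE)
  }
  structure(
    list(phi = phi, theta = theta, psi = psi, body_angle = body_angle,
         axis = unit(as.numeric(axis)), sigma = sigma,
         seed = as.integer(seed),
         n_anchor = as.integer(n_anchor), n_body = as.integer(n_body),
         n_head = as.integer(n_head), reference_swivel = reference_swivel),
    class = "ribs_truth"
  )
}

# Run `expr` under set.seed(seed) while preserving the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# n residue numbers inside [lo, hi] including the markers, spread evenly.
spread_residues <- function(n, lo, hi, markers = integer()) {
  if (n > hi - lo + 1L) stop("domain range too small for ", n, " residues",
                             call. = FALSE)
  pool <- setdiff(lo:hi, markers)
  m <- n - length(markers)
  idx <- unique(round(seq(1, length(pool), length.out = m)))
  extra <- setdiff(seq_along(pool), idx)
  if (length(idx) < m) idx <- sort(c(idx, extra[seq_len(m - length(idx))]))
  sort(c(as.integer(markers), pool[idx]))
}

# Uniform sample inside an axis-aligned ellipsoid.
sample_ellipsoid <- function(n, center, radii) {
  out <- matrix(NA_real_, n, 3)
  got <- 0L
  while (got < n) {
    cand <- matrix(runif(3L * (n - got), -1, 1), ncol = 3)
    keep <- rowSums(cand^2) <= 1
    k <- sum(keep)
    if (k > 0) {
      out[(got + 1L):(got + k), ] <- cand[keep, , drop = FALSE]
      got <- got + k
    }
  }
  sweep(sweep(out, 2, radii, "*"), 2, center, "+")
}

triangle_area <- function(p1, p2, p3) {
  0.5 * sqrt(sum(cross3(p2 - p1, p3 - p1)^2))
}

p_atom_frame <- function(chain, resno, xyz) {
  data.frame(
    model = 1L, chain = chain, resno = as.integer(resno), insert = "",
    resid = "G", elety = "P", elesy = "P",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    o = 1, alt = "",
    stringsAsFactors = FALSE
  )
}

# Rotate rows of xyz about the axis line (direction u through point p).
rotate_about_line <- function(xyz, rotation, point) {
  sweep(sweep(xyz, 2, point) %*% t(rotation), 2, point, "+")
}

#' Generate a synthetic pseudo-ribosome triple
#'
#' Emulates the three-domain rigid architecture used by the head-motion
#' protocol: an anchor cloud (23S stand-in, chain `"A"`), and a 16S stand-in
#' (chain `"B"`) split into a body (residues 1-929, markers 41/127/911) and
#' a head (residues 930-1380, markers 984/940/1106). Domain clouds are
#' sampled uniformly in well-separated ellipsoids so rigid fits are
#' well-conditioned; marker triangles are guaranteed non-degenerate.
#'
#' Three structures are returned: the classical (unrotated) reference; a
#' swiveled reference whose head is rotated by a fixed pure in-plane angle
#' about the truth axis (used to calibrate the swivel axis); and the model,
#' whose head is rotated by `Rz(psi) Rx(theta) Rz(phi)` in the axis frame
#' (about the same axis line), optionally followed by a whole-16S body
#' rotation, with Gaussian noise added to every model coordinate.
#'
#' @param truth A `ribs_truth` (see [synthetic_truth()]).
#' @return List with `classical`, `swiveled`, `model` (`ribs_structure`),
#'   `truth`, `domains` (head/body/anchor `ribs_domain` list) and
#'   `axis_point` (the rotation centre on the swivel axis line).
#' @export
generate_pseudo_ribosome <- function(truth) {
  stopifnot(inherits(truth, "ribs_truth"))
  with_local_seed(truth$seed, {
    anchor_res <- seq_len(truth$n_anchor)
    body_res <- spread_residues(truth$n_body, 1L, 929L, c(41L, 127L, 911L))
    head_res <- spread_residues(truth$n_head, 930L, 1380L,
                                c(940L, 984L, 1106L))
    anchor_xyz <- sample_ellipsoid(truth$n_anchor, c(0, 0, 0), c(40, 35, 30))
    body_xyz <- sample_ellipsoid(truth$n_body, c(85, 0, 0), c(35, 30, 25))
    marker_ok <- function(xyz, res, markers) {
      idx <- match(markers, res)
      triangle_area(xyz[idx[1], ], xyz[idx[2], ], xyz[idx[3], ]) > 5
    }
    tries <- 0L
    while (!marker_ok(body_xyz, body_res, c(41L, 127L, 911L))) {
      body_xyz <- sample_ellipsoid(truth$n_body, c(85, 0, 0), c(35, 30, 25))
      if ((tries <- tries + 1L) > 100L) stop("degenerate body markers")
    }
    head_xyz <- sample_ellipsoid(truth$n_head, c(85, 55, 10), c(25, 22, 18))
    tries <- 0L
    while (!marker_ok(head_xyz, head_res, c(984L, 940L, 1106L))) {
      head_xyz <- sample_ellipsoid(truth$n_head, c(85, 55, 10), c(25, 22, 18))
      if ((tries <- tries + 1L) > 100L) stop("degenerate head markers")
    }
    axis_point <- colMeans(head_xyz)

    u <- truth$axis
    # orthonormal frame with e3 = swivel axis
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- unit(ref - sum(ref * u) * u)
    m_axis <- cbind(e1, cross3(u, e1), u)

    build <- function(head_coords, body_coords = body_xyz,
                      anchor_coords = anchor_xyz, id) {
      new_structure(id, rbind(
        p_atom_frame("A", anchor_res, anchor_coords),
        p_atom_frame("B", body_res, body_coords),
        p_atom_frame("B", head_res, head_coords)
      ), "pdb")
    }

    classical <- build(head_xyz, id = "SYNTH_CLASSICAL")

    r_ref <- rotation_about_axis(u, truth$reference_swivel)
    swiveled <- build(rotate_about_line(head_xyz, r_ref, axis_point),
                      id = "SYNTH_SWIVELED")

    head_model <- if (truth$phi == 0 && truth$theta == 0 && truth$psi == 0) {
      head_xyz     # bit-identical to the classical head
    } else {
      r_head <- m_axis %*% rot_z(truth$psi) %*% rot_x(truth$theta) %*%
        rot_z(truth$phi) %*% t(m_axis)
      rotate_about_line(head_xyz, r_head, axis_point)
    }
    body_model <- body_xyz
    if (truth$body_angle != 0) {
      r_body <- rot_z(truth$body_angle)
      body_center <- colMeans(body_xyz)
      body_model <- rotate_about_line(body_model, r_body, body_center)
      head_model <- rotate_about_line(head_model, r_body, body_center)
    }
    model <- build(head_model, body_coords = body_model, id = "SYNTH_MODEL")
    if (truth$sigma > 0) {
      n <- nrow(model$atoms)
      model$atoms$x <- model$atoms$x + rnorm(n, 0, truth$sigma)
      model$atoms$y <- model$atoms$y + rnorm(n, 0, truth$sigma)
      model$atoms$z <- model$atoms$z + rnorm(n, 0, truth$sigma)
    }

    domains <- list(
      head = domain_definition("head", "16S", list(c(930L, 1380L)),
                               markers = c(984L, 940L, 1106L),
                               chain_map = c(default = "B")),
      body = domain_definition("body", "16S", list(c(1L, 929L)),
                               markers = c(41L, 127L, 911L),
                               chain_map = c(default = "B")),
      anchor = domain_definition("anchor23S", "23S",
                                 list(c(1L, truth$n_anchor)),
                                 chain_map = c(default = "A"))
    )
    list(classical = classical, swiveled = swiveled, model = model,
         truth = truth, domains = domains, axis_point = axis_point)
  })
}

# Calibrate and measure one generated pseudo-ribosome; returns truth vs
# estimate for the head domain.
recover_once <- function(truth, min_pairs = 50L) {
  gen <- generate_pseudo_ribosome(truth)
  cal <- calibrate_swivel(gen$classical, gen$swiveled,
                          gen$domains$head, gen$domains$body,
                          min_pairs = min_pairs)
  ori <- compute_orientation(gen$model, cal, gen$classical,
                             gen$domains$head, gen$domains$body,
                             min_pairs = min_pairs)
  true_net <- wrap_angle(truth$phi + truth$psi)
  list(orientation = ori,
       error_net_swivel = abs(wrap_angle(ori$net_swivel - true_net)),
       error_tilt = abs(ori$tilt - truth$theta))
}

#' Parameter-recovery experiment over an angle/noise grid
#'
#' For every combination of head angles and noise level, generates
#' `replicates` pseudo-ribosomes (each with its own deterministic seed
#' derived from `base_seed`), runs the full calibrate-and-decompose
#' pipeline, and summarizes recovery of the net swivel and tilt.
#'
#' @param angles Data frame with columns `phi`, `theta`, `psi` (degrees);
#'   one row per angle cell.
#' @param sigmas Numeric vector of noise levels (Angstrom).
#' @param replicates Replicates per cell (>= 1).
#' @param base_seed Integer base seed; replicate seeds are
#'   `base_seed + 0, 1, 2, ...` in a fixed order.
#' @param n_head,n_body,n_anchor Cloud sizes passed to the generator.
#' @param axis Swivel axis used by the generator.
#' @return Data frame with one row per (angle cell, sigma): the truth
#'   columns plus `bias_net_swivel`, `mae_net_swivel`, `rmse_net_swivel`,
#'   `bias_tilt`, `mae_tilt`, `rmse_tilt` and `replicates`.
#' @export
recovery_experiment <- function(angles, sigmas, replicates, base_seed,
                                n_head = 178L, n_body = 442L,
                                n_anchor = 300L, axis = c(0, 0, 1)) {
  stopifnot(is.data.frame(angles),
            all(c("phi", "theta", "psi") %in% names(angles)),
            replicates >= 1)
  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(angles))) {
    for (s in sigmas) {
      err_net <- err_tilt <- signed_net <- signed_tilt <- numeric(replicates)
      for (r in seq_len(replicates)) {
        truth <- synthetic_truth(
          phi = angles$phi[i], theta = angles$theta[i], psi = angles$psi[i],
          axis = axis, sigma = s, seed = as.integer(base_seed) + k,
          n_anchor = n_anchor, n_body = n_body, n_head = n_head)
        k <- k + 1L
        rec <- recover_once(truth)
        err_net[r] <- rec$error_net_swivel
        err_tilt[r] <- rec$error_tilt
        signed_net[r] <- wrap_angle(
          rec$orientation$net_swivel - wrap_angle(truth$phi + truth$psi))
        signed_tilt[r] <- rec$orientation$tilt - truth$theta
      }
      rows[[length(rows) + 1L]] <- data.frame(
        phi = angles$phi[i], theta = angles$theta[i], psi = angles$psi[i],
        net_swivel_true = wrap_angle(angles$phi[i] + angles$psi[i]),
        sigma = s, replicates = replicates,
        bias_net_swivel = mean(signed_net),
        mae_net_swivel = mean(err_net),
        rmse_net_swivel = sqrt(mean(signed_net^2)),
        bias_tilt = mean(signed_tilt),
        mae_tilt = mean(err_tilt),
        rmse_tilt = sqrt(mean(signed_tilt^2))
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
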