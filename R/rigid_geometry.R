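#' Construct a rigid transform
#'
#' A proper rigid-body motion `x -> R x + t`. The rotation must be
#' orthonormal with determinant +1 (reflections are rejected).
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation vector (Angstrom).
#' @return A `ribs_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (norm(crossprod(rotation) - diag(3), "F") > 1e-9) {
    stop("rotation matrix is not orthonormal", call. = FALSE)
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("rotation matrix is not proper (det != +1)", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation),
            class = "ribs_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param transform A `ribs_transform`.
#' @param coords An n x 3 coordinate matrix (or length-3 vector).
#' @return Transformed coordinates with the input's shape.
#' @export
apply_transform <- function(transform, coords) {
  stopifnot(inherits(transform, "ribs_transform"))
  vec <- is.null(dim(coords))
  m <- if (vec) matrix(coords, 1, 3) else as.matrix(coords)
  out <- m %*% t(transform$rotation) +
    matrix(transform$translation, nrow(m), 3, byrow = TRUE)
  if (vec) as.numeric(out) else out
}

# Transform every atom of a structure.
transform_structure <- function(structure, transform) {
  xyz <- apply_transform(transform, atom_coords(structure$atoms))
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

coords_rmsd <- function(a, b) {
  sqrt(mean(rowSums((a - b)^2)))
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rigid motion minimizing the RMSD of `mobile` onto
#' `target` by the SVD closed form, with the determinant correction that
#' excludes reflections. Superposition is unweighted: every paired atom
#' counts equally.
#'
#' @param mobile,target n x 3 coordinate matrices (or atom data frames with
#'   `x`,`y`,`z` columns) of equal length n >= 3, not all collinear.
#' @return A `ribs_superposition`: `transform` (`ribs_transform`),
#'   `rmsd_before`, `rmsd_after` (Angstrom) and `n_atoms`.
#' @export
superpose <- function(mobile, target) {
  m <- if (is.data.frame(mobile)) atom_coords(mobile) else as.matrix(mobile)
  t_ <- if (is.data.frame(target)) atom_coords(target) else as.matrix(target)
  if (nrow(m) != nrow(t_)) {
    stop("mobile and target have different lengths (", nrow(m), " vs ",
         nrow(t_), ")", call. = FALSE)
  }
  if (nrow(m) < 3) {
    stop("at least 3 points are required for superposition", call. = FALSE)
  }
  cm <- colMeans(m); ct <- colMeans(t_)
  mc <- sweep(m, 2, cm); tc <- sweep(t_, 2, ct)
  for (cc in list(mc, tc)) {
    d <- svd(cc, nu = 0, nv = 0)$d
    if (d[2] < 1e-8 * max(d[1], 1)) {
      stop("degenerate (collinear) point configuration", call. = FALSE)
    }
  }
  h <- crossprod(mc, tc)                 # 3x3 covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- rigid_transform(r, ct - as.numeric(r %*% cm))
  fitted <- apply_transform(tr, m)
  structure(
    list(transform = tr,
         rmsd_before = coords_rmsd(m, t_),
         rmsd_after = coords_rmsd(fitted, t_),
         n_atoms = nrow(m)),
    class = "ribs_superposition"
  )
}

#' @export
print.ribs_superposition <- function(x, ...) {
  cat(sprintf("<ribs_superposition> n = %d, rmsd %.4f -> %.4f A\n",
              x$n_atoms, x$rmsd_before, x$rmsd_after))
  invisible(x)
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector",
                                    call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Orthonormal frame from three marker points
#'
#' Builds a right-handed frame with origin at `p1`:
#' `e1 = unit(p2 - p1)`, `e3 = unit((p2 - p1) x (p3 - p1))`, `e2 = e3 x e1`.
#' Any fixed right-handed construction applied consistently to reference and
#' model yields identical relative rotations; this one is the package's
#' documented choice.
#'
#' @param p1,p2,p3 Length-3 marker coordinates (non-collinear).
#' @return A `ribs_frame`: `origin` and `axes` (3x3 matrix, columns e1,e2,e3).
#' @export
frame_from_markers <- function(p1, p2, p3) {
  v1 <- p2 - p1
  v2 <- p3 - p1
  n <- cross3(v1, v2)
  if (0.5 * sqrt(sum(n^2)) <= 1e-6) {
    stop("marker points are collinear (triangle area <= 1e-6 A^2)",
         call. = FALSE)
  }
  e1 <- unit(v1)
  e3 <- unit(n)
  e2 <- cross3(e3, e1)
  structure(list(origin = as.numeric(p1), axes = cbind(e1, e2, e3)),
            class = "ribs_frame")
}

#' Rotation carrying one frame onto another
#'
#' Returns the rigid transform whose rotation maps the reference frame's
#' axes exactly onto the observed frame's axes
#' (`R = A_obs %*% t(A_ref)`) and whose translation maps the reference
#' origin to the observed origin.
#'
#' @param reference,observed `ribs_frame` objects.
#' @return A `ribs_transform`.
#' @export
rotation_between_frames <- function(reference, observed) {
  stopifnot(inherits(reference, "ribs_frame"), inherits(observed, "ribs_frame"))
  r <- observed$axes %*% t(reference$axes)
  rigid_transform(r, observed$origin - as.numeric(r %*% reference$origin))
}

# Robust rotation-matrix -> unit quaternion (w, x, y, z), Shepperd's method.
rotmat_to_quat <- function(r) {
  tr <- r[1, 1] + r[2, 2] + r[3, 3]
  if (tr >= max(r[1, 1], r[2, 2], r[3, 3])) {
    s <- sqrt(1 + tr) * 2
    q <- c(0.25 * s,
           (r[3, 2] - r[2, 3]) / s,
           (r[1, 3] - r[3, 1]) / s,
           (r[2, 1] - r[1, 2]) / s)
  } else if (r[1, 1] >= max(r[2, 2], r[3, 3])) {
    s <- sqrt(1 + r[1, 1] - r[2, 2] - r[3, 3]) * 2
    q <- c((r[3, 2] - r[2, 3]) / s,
           0.25 * s,
           (r[1, 2] + r[2, 1]) / s,
           (r[1, 3] + r[3, 1]) / s)
  } else if (r[2, 2] >= r[3, 3]) {
    s <- sqrt(1 + r[2, 2] - r[1, 1] - r[3, 3]) * 2
    q <- c((r[1, 3] - r[3, 1]) / s,
           (r[1, 2] + r[2, 1]) / s,
           0.25 * s,
           (r[2, 3] + r[3, 2]) / s)
  } else {
    s <- sqrt(1 + r[3, 3] - r[1, 1] - r[2, 2]) * 2
    q <- c((r[2, 1] - r[1, 2]) / s,
           (r[1, 3] + r[3, 1]) / s,
           (r[2, 3] + r[3, 2]) / s,
           0.25 * s)
  }
  q / sqrt(sum(q^2))
}

#' Axis and angle of a rotation
#'
#' Extracted via the unit quaternion (numerically stable through 0 and 180
#' degrees). The angle is reported in `[0, 180]` degrees; for angles below
#' 1e-8 degrees the axis is the `(0, 0, 1)` convention.
#'
#' @param transform A `ribs_transform` or a 3x3 rotation matrix.
#' @return List with `axis` (unit 3-vector) and `angle` (degrees).
#' @export
axis_angle <- function(transform) {
  r <- if (inherits(transform, "ribs_transform")) transform$rotation
       else as.matrix(transform)
  q <- rotmat_to_quat(r)
  if (q[1] < 0) q <- -q
  s <- sqrt(sum(q[2:4]^2))
  angle <- 2 * atan2(s, q[1]) * 180 / pi
  axis <- if (angle < 1e-8) c(0, 0, 1) else q[2:4] / s
  list(axis = as.numeric(axis), angle = angle)
}

#' Rotation matrix from axis and angle
#'
#' Rodrigues' formula.
#'
#' @param axis Rotation axis (normalized internally).
#' @param angle Angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- unit(as.numeric(axis))
  a <- angle * pi / 180
  k <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(a) * k + (1 - cos(a)) * (k %*% k)
}

rot_z <- function(angle) rotation_about_axis(c(0, 0, 1), angle)
rot_x <- function(angle) rotation_about_axis(c(1, 0, 0), angle)

# Minimal-norm point on the screw axis of the rigid motion (R, t):
# solves (I - R) p = t_perp with t_perp the translation component
# perpendicular to the rotation axis u. Points on the axis line map onto the
# axis line, so rotating about the line through p reproduces the in-plane
# part of the motion.
screw_axis_point <- function(rotation, translation, axis) {
  u <- unit(axis)
  t_perp <- translation - sum(translation * u) * u
  a <- diag(3) - rotation
  sv <- svd(a)
  d_inv <- ifelse(sv$d > 1e-9 * max(sv$d), 1 / sv$d, 0)
  p <- sv$v %*% (d_inv * crossprod(sv$u, t_perp))
  as.numeric(p)
}
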