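# A calibration with the identity frame (z = global z), built directly so
# the matrix-level Euler extraction can be tested in isolation.
identity_calibration <- function() {
  structure(
    list(domain = NULL, anchor = NULL,
         zero_frame = frame_from_markers(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
         axis = c(0, 0, 1), axis_point = c(0, 0, 0),
         frame = diag(3), magnitude = 21,
         provenance = c(classical = "ID", swiveled = "ID")),
    class = "ribs_calibration")
}

zxz <- function(phi, theta, psi) {
  headswivel:::rot_z(psi) %*% headswivel:::rot_x(theta) %*%
    headswivel:::rot_z(phi)
}

test_that("z-x-z decomposition recovers explicitly constructed rotations", {
  cal <- identity_calibration()
  e <- euler_zxz(diag(3), cal)
  expect_equal(c(e$phi, e$theta, e$psi), c(0, 0, 0))
  expect_equal(e$net_swivel, 0)
  # pure in-plane rotation of 18 degrees
  e <- euler_zxz(headswivel:::rot_z(18), cal)
  expect_equal(e$net_swivel, 18, tolerance = 1e-9)
  expect_equal(e$tilt, 0, tolerance = 1e-9)
  # matrix built by explicit multiplication: psi 10, theta 5, phi 8
  e <- euler_zxz(zxz(8, 5, 10), cal)
  expect_equal(e$net_swivel, 18, tolerance = 1e-9)
  expect_equal(e$tilt, 5, tolerance = 1e-9)
  expect_equal(e$phi, 8, tolerance = 1e-9)
  expect_equal(e$psi, 10, tolerance = 1e-9)
})

test_that("decomposition recomposes to the input rotation for 1000 random cases", {
  cal <- identity_calibration()
  withr::local_seed(21)
  thetas <- c(runif(960, 0, 179.99), runif(20, 0, 1e-7), rep(180, 20))
  for (th in thetas) {
    r <- zxz(runif(1, -179, 180), th, runif(1, -179, 180))
    e <- euler_zxz(r, cal)
    expect_lt(frobenius(zxz(e$phi, e$theta, e$psi), r), 1e-9)
  }
})

test_that("net swivel is continuous and monotone through gimbal lock", {
  cal <- identity_calibration()
  angles <- seq(17.9, 18.1, by = 0.01)
  net <- vapply(angles, function(a) euler_zxz(headswivel:::rot_z(a), cal)$net_swivel,
                numeric(1))
  expect_equal(net, angles, tolerance = 1e-9)
  expect_true(all(diff(net) > 0))
})

test_that("tilt direction is flagged undefined below half a degree of tilt", {
  cal <- identity_calibration()
  expect_false(euler_zxz(headswivel:::rot_z(18), cal)$tilt_direction_defined)
  expect_true(euler_zxz(zxz(8, 5, 10), cal)$tilt_direction_defined)
})

test_that("calibrating a structure against itself is rejected as degenerate", {
  gen <- generate_pseudo_ribosome(synthetic_truth(seed = 31))
  expect_error(
    calibrate_swivel(gen$classical, gen$classical,
                     gen$domains$head, gen$domains$body),
    "degenerate calibration")
})

test_that("calibration recovers a synthetic pure-swivel axis and magnitude", {
  u <- headswivel:::unit(c(0.3, -0.5, 0.81))
  gen <- generate_pseudo_ribosome(
    synthetic_truth(axis = u, seed = 32, reference_swivel = 20))
  cal <- calibrate_swivel(gen$classical, gen$swiveled,
                          gen$domains$head, gen$domains$body)
  expect_equal(cal$magnitude, 20, tolerance = 1e-6)
  expect_equal(abs(sum(cal$axis * u)), 1, tolerance = 1e-6)
})

test_that("the classical reference decomposes to exactly zero orientation", {
  gen <- generate_pseudo_ribosome(synthetic_truth(seed = 33))
  cal <- calibrate_swivel(gen$classical, gen$swiveled,
                          gen$domains$head, gen$domains$body)
  ori <- compute_orientation(gen$classical, cal, gen$classical,
                             gen$domains$head, gen$domains$body)
  expect_lt(abs(ori$net_swivel), 1e-9)
  expect_lt(abs(ori$tilt), 1e-9)
  expect_lt(ori$core_rmsd, 1e-9)
})

test_that("the swiveled reference decomposes to its calibration magnitude, tilt-free", {
  gen <- generate_pseudo_ribosome(synthetic_truth(seed = 34))
  cal <- calibrate_swivel(gen$classical, gen$swiveled,
                          gen$domains$head, gen$domains$body)
  ori <- compute_orientation(gen$swiveled, cal, gen$classical,
                             gen$domains$head, gen$domains$body)
  expect_lt(ori$tilt, 1e-6)
  expect_equal(ori$net_swivel, cal$magnitude, tolerance = 1e-6)
})

test_that("noiseless synthetic head angles are recovered exactly", {
  gen <- generate_pseudo_ribosome(
    synthetic_truth(phi = 10, theta = 5, psi = 8, seed = 35))
  cal <- calibrate_swivel(gen$classical, gen$swiveled,
                          gen$domains$head, gen$domains$body)
  ori <- compute_orientation(gen$model, cal, gen$classical,
                             gen$domains$head, gen$domains$body)
  expect_equal(ori$net_swivel, 18, tolerance = 1e-6)
  expect_equal(ori$tilt, 5, tolerance = 1e-6)
  expect_equal(ori$n_atoms, 178)
})

test_that("recovery is invariant to the marker-frame convention", {
  # permuting the marker order changes the constructed frame but not the
  # relative rotation, as long as the same convention is applied to
  # reference and model
  base <- synthetic_truth(phi = -20, theta = 7, psi = 50, seed = 36,
                          axis = c(0.2, 0.1, 0.97))
  gen <- generate_pseudo_ribosome(base)
  results <- lapply(list(c(984L, 940L, 1106L), c(940L, 1106L, 984L)),
    function(mk) {
      dom <- domain_definition("head", "16S", list(c(930L, 1380L)),
                               markers = mk, chain_map = c(default = "B"))
      cal <- calibrate_swivel(gen$classical, gen$swiveled, dom,
                              gen$domains$body)
      compute_orientation(gen$model, cal, gen$classical, dom,
                          gen$domains$body)
    })
  expect_equal(results[[1]]$net_swivel, results[[2]]$net_swivel,
               tolerance = 1e-9)
  expect_equal(results[[1]]$tilt, results[[2]]$tilt, tolerance = 1e-9)
})

test_that("orientation computation respects the minimum-pair threshold", {
  gen <- generate_pseudo_ribosome(synthetic_truth(seed = 37, n_head = 60))
  cal <- calibrate_swivel(gen$classical, gen$swiveled,
                          gen$domains$head, gen$domains$body)
  expect_error(
    compute_orientation(gen$model, cal, gen$classical,
                        gen$domains$head, gen$domains$body, min_pairs = 100),
    "minimum required is 100")
})

test_that("displacements of the classical structure against itself vanish", {
  gen <- generate_pseudo_ribosome(synthetic_truth(seed = 38))
  cal <- calibrate_swivel(gen$classical, gen$swiveled,
                          gen$domains$head, gen$domains$body)
  ori <- compute_orientation(gen$classical, cal, gen$classical,
                             gen$domains$head, gen$domains$body)
  d <- decompose_displacements(gen$classical, gen$classical, ori, cal,
                               gen$domains$head, gen$domains$body)
  expect_lt(max(d$total_norm), 1e-9)
  expect_lt(max(d$swivel_norm), 1e-9)
  expect_lt(max(d$tilt_norm), 1e-9)
})

test_that("pure-swivel models have negligible tilt components", {
  u <- headswivel:::unit(c(-0.1, 0.4, 0.91))
  gen <- generate_pseudo_ribosome(
    synthetic_truth(psi = 18, axis = u, seed = 39))
  cal <- calibrate_swivel(gen$classical, gen$swiveled,
                          gen$domains$head, gen$domains$body)
  ori <- compute_orientation(gen$model, cal, gen$classical,
                             gen$domains$head, gen$domains$body)
  d <- decompose_displacements(gen$model, gen$classical, ori, cal,
                               gen$domains$head, gen$domains$body)
  expect_lt(max(d$tilt_norm), 1e-9)
  expect_gt(min(d$swivel_norm), 0)   # the head actually moved
})

test_that("swivel and tilt components sum exactly to the total displacement", {
  gen <- generate_pseudo_ribosome(
    synthetic_truth(phi = 10, theta = 5, psi = 8, sigma = 0.3, seed = 40))
  cal <- calibrate_swivel(gen$classical, gen$swiveled,
                          gen$domains$head, gen$domains$body)
  ori <- compute_orientation(gen$model, cal, gen$classical,
                             gen$domains$head, gen$domains$body)
  d <- decompose_displacements(gen$model, gen$classical, ori, cal,
                               gen$domains$head, gen$domains$body)
  resid <- cbind(d$swivel_x + d$tilt_x - d$total_x,
                 d$swivel_y + d$tilt_y - d$total_y,
                 d$swivel_z + d$tilt_z - d$total_z)
  expect_lt(max(abs(resid)), 1e-12)
})

test_that("angle wrapping maps into (-180, 180]", {
  expect_equal(wrap_angle(190), -170)
  expect_equal(wrap_angle(-190), 170)
  expect_equal(wrap_angle(180), 180)
  expect_equal(wrap_angle(-180), 180)
  expect_equal(wrap_angle(540), 180)
  expect_equal(wrap_angle(c(0, 359, 361)), c(0, -1, 1))
})
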