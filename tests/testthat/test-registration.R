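test_that("head frame is the identity for fiducials already in the frame", {
  t <- build_head_frame(c(0, 100, 0), c(-70, 0, 0), c(70, 0, 0))
  expect_lt(max(abs(t$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(t$translation)), 1e-12)
  expect_equal(t$scale, 1)
})

test_that("head frame maps fiducials onto the definitional axes", {
  set.seed(101)
  for (i in 1:25) {
    nasion <- rnorm(3, c(0, 90, 20), 10)
    lpa <- rnorm(3, c(-75, 0, 0), 10)
    rpa <- rnorm(3, c(75, 0, 0), 10)
    t <- build_head_frame(nasion, lpa, rpa)
    f <- transform_coords(t, rbind(nasion, lpa, rpa))
    # LPA/RPA on the x-axis, symmetric about the origin
    expect_lt(max(abs(f[2:3, 2:3])), 1e-9)
    expect_lt(abs(f[2, 1] + f[3, 1]), 1e-9)
    # nasion in the z = 0 plane of the frame, on the anterior side; its
    # x-offset is whatever the fiducial geometry dictates (the origin is
    # the LPA-RPA midpoint, not the nasion's foot point)
    expect_lt(abs(f[1, 3]), 1e-9)
    expect_gt(f[1, 2], 0)
  }
})

test_that("head frame undoes a known rotation of the fiducials", {
  set.seed(102)
  nasion <- c(0, 100, 0); lpa <- c(-70, 0, 0); rpa <- c(70, 0, 0)
  for (i in 1:10) {
    R <- random_rotation()
    shift <- rnorm(3, 0, 50)
    rot <- function(p) as.numeric(R %*% p) + shift
    t <- build_head_frame(rot(nasion), rot(lpa), rot(rpa))
    # composing the recovered frame with the applied motion gives identity
    composed <- t$rotation %*% R
    expect_lt(max(abs(composed - diag(3))), 1e-9)
    expect_lt(max(abs(as.numeric(t$rotation %*% shift) + t$translation)),
              1e-9)
  }
})

test_that("head frame rejects degenerate fiducials", {
  expect_error(build_head_frame(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0)),
               "coincide")
  expect_error(build_head_frame(c(2, 0, 0), c(-1, 0, 0), c(1, 0, 0)),
               "collinear")
})

test_that("fit_rigid solves trivial cases exactly", {
  src <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), 4, 3,
                byrow = TRUE) * 50
  fit <- fit_rigid(src, src)
  expect_lt(max(abs(fit$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(fit$translation)), 1e-12)
  expect_equal(fit$scale, 1)
  expect_lt(fit_residual(fit), 1e-12)

  shifted <- sweep(src, 2, c(5, -3, 2), "+")
  fit2 <- fit_rigid(src, shifted)
  expect_lt(max(abs(fit2$rotation - diag(3))), 1e-12)
  expect_equal(fit2$translation, c(5, -3, 2), tolerance = 1e-12)
})

test_that("fit_rigid recovers constructed noise-free transforms", {
  set.seed(103)
  for (i in 1:25) {
    src <- matrix(runif(30, -100, 100), 10, 3)
    R <- random_rotation()
    tr <- rnorm(3, 0, 100)
    tgt <- sweep(src %*% t(R), 2, tr, "+")
    fit <- fit_rigid(src, tgt)
    # elementwise rotation error: the acos-based angle saturates at
    # sqrt(machine eps) and cannot resolve 1e-9
    expect_lt(max(abs(fit$rotation - R)), 1e-9)
    expect_lt(max(abs(fit$translation - tr)), 1e-9)
    expect_lt(fit_residual(fit), 1e-9)
  }
})

test_that("fit_rigid never returns a reflection", {
  set.seed(104)
  for (i in 1:20) {
    src <- matrix(runif(18, -50, 50), 6, 3)
    mirrored <- src
    mirrored[, 1] <- -mirrored[, 1]
    fit <- fit_rigid(src, mirrored)
    expect_gt(det(fit$rotation), 0.999999999)
  }
})

test_that("fit_rigid residual is invariant under a common rigid motion", {
  set.seed(105)
  src <- matrix(runif(24, -80, 80), 8, 3)
  tgt <- src + matrix(rnorm(24, 0, 3), 8, 3)
  base <- fit_residual(fit_rigid(src, tgt))
  for (i in 1:10) {
    R <- random_rotation()
    tr <- rnorm(3, 0, 40)
    move <- function(X) sweep(X %*% t(R), 2, tr, "+")
    expect_equal(fit_residual(fit_rigid(move(src), move(tgt))), base,
                 tolerance = 1e-9)
  }
})

test_that("allowing scale never increases the residual", {
  set.seed(106)
  for (i in 1:10) {
    src <- matrix(runif(24, -80, 80), 8, 3)
    tgt <- 1.07 * src %*% t(random_rotation()) +
      matrix(rnorm(24, 0, 2), 8, 3)
    rigid <- fit_residual(fit_rigid(src, tgt, allow_scaling = FALSE))
    scaled <- fit_residual(fit_rigid(src, tgt, allow_scaling = TRUE))
    expect_lte(scaled, rigid + 1e-12)
  }
})

test_that("fit_rigid enforces its contract", {
  src <- matrix(runif(12), 4, 3)
  expect_error(fit_rigid(src, src[1:3, ]), "identical dimensions")
  expect_error(fit_rigid(src[1:2, ], src[1:2, ]), "at least 3")
  coincident <- matrix(1, 5, 3)
  expect_error(fit_rigid(coincident, matrix(runif(15), 5, 3)),
               "degenerate")
})

test_that("apply_transform maps points and composes with its inverse", {
  ps <- probe_set(data.frame(label = c("D1", "S1", "Nasion"),
                             x = c(0, 10, 0), y = c(0, 0, 95),
                             z = c(0, 5, 10)), space = "scanner")
  t_id <- rigid_transform()
  expect_equal(apply_transform(t_id, ps)$points, ps$points)

  t_shift <- rigid_transform(translation = c(1, 1, 1))
  moved <- apply_transform(t_shift, ps)
  expect_equal(as.numeric(moved$points[1, 2:4]), c(1, 1, 1))

  set.seed(107)
  t_rand <- rigid_transform(random_rotation(), rnorm(3, 0, 30), 1)
  round_trip <- apply_transform(transform_invert(t_rand),
                                apply_transform(t_rand, ps, "head"),
                                "scanner")
  expect_lt(max(abs(as.matrix(round_trip$points[, 2:4]) -
                      as.matrix(ps$points[, 2:4]))), 1e-9)
})

test_that("align is exact on sets already in reference coordinates", {
  set.seed(108)
  ps <- random_probe_set(n = 10)
  for (mode in c("landmark_based", "landmark_free")) {
    res <- align(ps, ps, mode = mode)
    expect_lt(fit_residual(res$transform), 1e-9)
    expect_lt(max(abs(as.matrix(res$probe_set$points[, 2:4]) -
                        as.matrix(ps$points[, 2:4]))), 1e-9)
  }
})

test_that("landmark-free alignment recovers a pure rotation exactly", {
  set.seed(109)
  mri <- random_probe_set(n = 12)
  th <- 20 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1),
               3, 3)
  scan <- apply_transform(rigid_transform(Rz, c(4, -7, 2)), mri, "scanner")
  res <- align(scan, mri, mode = "landmark_free")
  expect_lt(fit_residual(res$transform), 1e-9)
  expect_lt(rotation_angle(res$transform$rotation %*% Rz), 1e-9)
  expect_lt(max(abs(as.matrix(res$probe_set$points[, 2:4]) -
                      as.matrix(mri$points[, 2:4]))), 1e-9)
})

test_that("landmark-based alignment onto the montage lands in MNI space", {
  m <- load_montage("standard_1005")
  layout <- place_optodes(make_head(566), cohort_config())
  res <- align(layout$probe_set, m, mode = "landmark_based")
  expect_equal(res$probe_set$space, "mni")
  # fiducials land on the montage fiducials up to the 3-point LS fit:
  # the RMS residual over the control points matches fit_residual
  fid <- fiducial_coords(res$probe_set)
  tgt <- fiducial_coords(m)
  rms <- sqrt(mean(rowSums((fid - tgt[rownames(fid), ])^2)))
  expect_equal(rms, fit_residual(res$transform), tolerance = 1e-9)
})

test_that("landmark-free residual is symmetric between the two sets", {
  set.seed(110)
  a <- random_probe_set(n = 9)
  b <- a
  b$points[, 2:4] <- b$points[, 2:4] + matrix(rnorm(36, 0, 2), 12, 3)
  r_ab <- fit_residual(align(a, b, mode = "landmark_free")$transform)
  r_ba <- fit_residual(align(b, a, mode = "landmark_free")$transform)
  expect_equal(r_ab, r_ba, tolerance = 1e-9)
})

test_that("align enforces mode preconditions and warns on unmatched labels", {
  no_fid <- probe_set(data.frame(label = c("S1", "S2", "S3", "S4"),
                                 x = runif(4), y = runif(4), z = runif(4)),
                      space = "scanner")
  full <- random_probe_set(n = 6)
  expect_error(align(no_fid, full, mode = "landmark_based"), "Nasion")
  expect_error(align(full, no_fid, mode = "landmark_free"), ">= 3 shared")

  extra <- full
  extra$points$label[1] <- "Zonly"
  expect_warning(align(extra, full, mode = "landmark_free"), "Zonly")
})

test_that("transform JSON export round-trips", {
  set.seed(111)
  t0 <- rigid_transform(random_rotation(), rnorm(3), 1.03)
  back <- transform_from_json(transform_to_json(t0))
  expect_lt(max(abs(back$rotation - t0$rotation)), 1e-12)
  expect_lt(max(abs(back$translation - t0$translation)), 1e-12)
  expect_equal(back$scale, t0$scale, tolerance = 1e-12)
})

test_that("rigid_transform rejects reflections and bad scales", {
  refl <- diag(c(-1, 1, 1))
  expect_error(rigid_transform(refl), "proper")
  expect_error(rigid_transform(scale = -2), "positive")
  expect_error(rigid_transform(matrix(2 * diag(3), 3, 3)), "orthonormal")
})
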