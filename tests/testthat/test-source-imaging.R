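test_that("the source grid has the documented density and frame", {
  g6 <- make_source_grid()           # full-scale default: 6 mm / 96 mm
  expect_gt(n_voxels(g6), 15000)
  expect_lt(n_voxels(g6), 19000)
  expect_true(all(sqrt(rowSums(g6$voxels^2)) <= 96))
  expect_error(make_source_grid(spacing = 0), "spacing")
})

test_that("radial and central dipoles are magnetically silent", {
  lf <- tiny_leadfield()
  grid <- tiny_grid()
  scale <- sqrt(max(vapply(seq_len(n_voxels(grid)),
                           function(v) sum(lf$gains[, v, ]^2), numeric(1L))))
  for (v in c(5L, 200L, 700L)) {
    r0 <- grid$voxels[v, ]
    if (sum(r0^2) == 0) next
    radial_gain <- lf$gains[, v, ] %*% (r0 / sqrt(sum(r0^2)))
    expect_lt(max(abs(radial_gain)) / scale, 1e-12)
  }
  centre <- which(rowSums(grid$voxels^2) == 0)
  expect_equal(max(abs(lf$gains[, centre, ])), 0)
})

test_that("lead fields are linear in the dipole moment", {
  lf <- tiny_leadfield()
  L <- lf$gains[, 300L, ]
  q <- c(0.3, -1.2, 0.5)
  expect_equal(as.numeric(L %*% (2 * q)), 2 * as.numeric(L %*% q), tolerance = 1e-12)
})

test_that("geometry violations raise errors", {
  arr <- tiny_array()
  far <- make_source_grid(spacing = 40, radius = 120)
  expect_error(sphere_leadfield(arr, far), "conductor sphere")
  inside_arr <- make_sensor_array(8L, 90, seed = 1L)
  expect_error(sphere_leadfield(inside_arr, tiny_grid()), "outside")
})

test_that("beamformer weights satisfy the unit-gain constraint", {
  fx <- tiny_seizure()
  lf <- tiny_leadfield()
  bp <- bandpass(fx$sim$recording, c(8, 12))
  src <- beamform(bp$data[, 2001:6000], lf)
  gains <- vapply(which(!src$silent), function(v) {
    l <- lf$gains[, v, ] %*% src$orientations[v, ]
    sum(src$weights[v, ] * l)
  }, numeric(1L))
  expect_equal(gains, rep(1, length(gains)), tolerance = 1e-9)
})

test_that("a noise-free single source is localized exactly", {
  grid <- tiny_grid()
  vox <- 412L
  spec <- simulation_spec(grid$voxels[vox, , drop = FALSE], matrix(c(1, 7), 1L),
                          duration_s = 8, rate_hz = 1000, noise_sd = 0, seed = 2L)
  sim <- simulate_recording(spec, tiny_array())
  src <- beamform(sim$recording$data[, 1001:7000], tiny_leadfield())
  asi <- accumulate_source_imaging(src)
  expect_equal(which.max(asi$strength), vox)
})

test_that("two uncorrelated sources at SNR 10 are both recovered", {
  grid <- tiny_grid()
  v1 <- 412L; v2 <- 700L
  spec <- simulation_spec(grid$voxels[c(v1, v2), ], matrix(c(1, 7), 1L),
                          duration_s = 8, rate_hz = 1000, snr = 10,
                          coupling = 0, seed = 6L)
  sim <- simulate_recording(spec, tiny_array())
  src <- beamform(sim$recording$data[, 1001:7000], tiny_leadfield())
  asi <- accumulate_source_imaging(src)
  top <- order(-asi$strength)[1:10]
  d <- function(v, set) min(sqrt(rowSums(sweep(grid$voxels[set, , drop = FALSE],
                                               2, grid$voxels[v, ])^2)))
  expect_lte(d(v1, top), 2 * grid$spacing)
  expect_lte(d(v2, top), 2 * grid$spacing)
})

test_that("beamforming demands regularization for short segments", {
  lf <- tiny_leadfield()
  short <- matrix(rnorm(32 * 40, sd = 1e-13), 32)
  expect_error(beamform(short, lf, regularization = 0), "regularization")
  expect_s3_class(beamform(short, lf, regularization = 0.05), "meg_source_activity")
})

test_that("accumulated source imaging sums activity as declared", {
  Q <- matrix(0, 3, 100)
  Q[2, ] <- 1
  asi <- accumulate_source_imaging(Q)
  expect_equal(asi$strength, c(0, 100, 0))
  expect_equal(asi$n_timepoints, 100L)
  # signed accumulation of a whole-period zero-mean sine cancels
  Q[3, ] <- sin(2 * pi * (1:100) / 20)
  expect_lt(abs(accumulate_source_imaging(Q, mode = "signed")$strength[3L]), 1e-10)
  expect_gt(accumulate_source_imaging(Q, mode = "magnitude")$strength[3L], 0)
  expect_error(accumulate_source_imaging(matrix(0, 3, 0)), "empty segment")
})

test_that("accumulation is additive over concatenated segments", {
  set.seed(8)
  A <- matrix(rnorm(40), 4); B <- matrix(rnorm(60), 4)
  joint <- accumulate_source_imaging(cbind(A, B))$strength
  parts <- accumulate_source_imaging(A)$strength + accumulate_source_imaging(B)$strength
  expect_equal(joint, parts, tolerance = 1e-12)
})

test_that("maps are homogeneous in the data and invariant to channel permutation", {
  fx <- tiny_seizure()
  lf <- tiny_leadfield()
  arr <- tiny_array()
  seg <- fx$sim$recording$data[, 2001:6000]
  base <- accumulate_source_imaging(beamform(seg, lf))$strength
  scaled <- accumulate_source_imaging(beamform(-2.5 * seg, lf))$strength
  expect_equal(scaled, 2.5 * base, tolerance = 1e-8)

  set.seed(1)
  perm <- sample(nrow(seg))
  arr_p <- arr
  arr_p$positions <- arr$positions[perm, ]
  arr_p$orientations <- arr$orientations[perm, ]
  arr_p$channel_ids <- arr$channel_ids[perm]
  lf_p <- sphere_leadfield(arr_p, tiny_grid())
  permuted <- accumulate_source_imaging(beamform(seg[perm, ], lf_p))$strength
  expect_equal(permuted, base, tolerance = 1e-6)
})

test_that("predominant-region assignment is deterministic with priority ties", {
  grid <- tiny_grid(); atlas <- tiny_atlas()
  labels <- assign_regions(grid, atlas)
  strength <- rep(0, n_voxels(grid))
  mfc <- which(labels == "MFC")[3L]
  strength[mfc] <- 1
  asi <- structure(list(strength = strength, n_timepoints = 10L,
                        mode = "magnitude", grid = grid), class = "asi_map")
  expect_equal(predominant_region(asi, atlas)$label, "MFC")

  # exact tie between an FC voxel and a TH voxel: priority order decides
  strength2 <- rep(0, n_voxels(grid))
  fc <- which(labels == "FC")[1L]; th <- which(labels == "TH")[1L]
  strength2[c(fc, th)] <- 1
  asi2 <- structure(list(strength = strength2, n_timepoints = 10L,
                         mode = "magnitude", grid = grid), class = "asi_map")
  expect_equal(predominant_region(asi2, atlas)$label, "FC")

  asi0 <- structure(list(strength = rep(0, n_voxels(grid)), n_timepoints = 1L,
                         mode = "magnitude", grid = grid), class = "asi_map")
  expect_error(predominant_region(asi0, atlas), "all-zero")
})

test_that("every grid voxel receives exactly one atlas label", {
  labels <- assign_regions(tiny_grid(), tiny_atlas())
  expect_false(anyNA(labels))
  expect_setequal(unique(labels), atlas_labels(tiny_atlas()))
})
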