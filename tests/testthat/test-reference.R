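cfg0 <- reference_config(erosion_radius_mm = c(aorta = 0, liver = 0),
                         min_voxels = 4)

grid_with_values <- function(vals, n = 6) {
  arr <- array(0, c(n, n, n))
  arr[seq_along(vals)] <- vals
  mask <- array(FALSE, c(n, n, n))
  mask[seq_along(vals)] <- TRUE
  g <- voxel_grid(arr, c(1, 1, 1))
  list(suv = g, mask = binary_mask(mask, template = g))
}

test_that("erosion is the identity at radius 0 and always a subset", {
  arr <- array(runif(8^3) > 0.4, c(8, 8, 8))
  g <- voxel_grid(array(1, c(8, 8, 8)), c(1, 1, 1))
  m <- binary_mask(arr, template = g)
  expect_identical(mask_array(erode_mask(m, 0)), mask_array(m))
  for (r in c(1, 2)) {
    big <- binary_mask(array(TRUE, c(8, 8, 8)), template = g)
    er <- erode_mask(big, r)
    expect_true(all(mask_array(er) | !mask_array(er)))
    expect_true(all(which(mask_array(er)) %in% which(mask_array(big))))
  }
})

test_that("erosion of a digital ball matches the brute-force oracle", {
  n <- 13
  cc <- seq_len(n) - 7  # center at voxel 7, isotropic 1 mm
  ball <- outer(outer(cc^2, cc^2, "+"), cc^2, "+") <= 25
  g <- voxel_grid(array(0, c(n, n, n)), c(1, 1, 1))
  er <- erode_mask(binary_mask(ball, template = g), 5)
  # only the center voxel survives eroding a radius-5 ball by 5 mm
  center_lin <- 7 + (7 - 1) * n + (7 - 1) * n^2
  expect_equal(which(mask_array(er)), center_lin)
  expect_identical(mask_array(er), bf_erode(ball, 5))
  # a looser structuring radius agrees with brute force as well
  er3 <- erode_mask(binary_mask(ball, template = g), 3)
  expect_identical(mask_array(er3), bf_erode(ball, 3))
})

test_that("blood pool is the mean of the interquartile band", {
  f <- grid_with_values(1:8)
  expect_equal(as.numeric(blood_pool_reference(f$suv, f$mask, cfg0)), 4.5)

  cgrid <- grid_with_values(rep(2.3, 30))
  expect_equal(as.numeric(blood_pool_reference(cgrid$suv, cgrid$mask, cfg0)),
               2.3)

  # voxels outside the mask never contribute
  f2 <- grid_with_values(1:8)
  f2$suv$data[100] <- 100
  expect_equal(as.numeric(blood_pool_reference(f2$suv, f2$mask, cfg0)), 4.5)

  few <- grid_with_values(c(1, 2))
  expect_error(blood_pool_reference(few$suv, few$mask, cfg0), "minimum")
})

test_that("blood pool equals the brute-force IQR-mean oracle to 1e-9", {
  set.seed(42)
  for (rep in 1:200) {
    v <- rexp(sample(8:200, 1)) * runif(1, 0.5, 5)
    f <- grid_with_values(v, n = 8)
    expect_equal(as.numeric(blood_pool_reference(f$suv, f$mask, cfg0)),
                 bf_iqr_mean(v), tolerance = 1e-9)
  }
})

test_that("the mixture fit recovers bimodal and unimodal parameters", {
  set.seed(7)
  x <- c(rnorm(3750, 6, 0.4), rnorm(1250, 3, 0.4))
  fit <- fit_gmm_1d(x)
  expect_equal(fit$components$mean, c(3, 6), tolerance = 0.1 / 3)
  expect_equal(fit$components$weight, c(0.25, 0.75), tolerance = 0.05)
  expect_true(fit$converged)

  uni <- fit_gmm_1d(rnorm(4000, 6, 0.3))
  expect_true(all(abs(uni$components$mean - 6) < 0.3))

  const <- fit_gmm_1d(rep(5, 100))
  expect_true("unimodal" %in% const$flags)
})

test_that("EM log-likelihood is non-decreasing over iterations", {
  set.seed(8)
  x <- c(rnorm(300, 6, 0.4), rnorm(100, 3, 0.4))
  cfgs <- lapply(1:30, function(k)
    reference_config(gmm_max_iter = k, gmm_tol = 0))
  lls <- vapply(cfgs, function(cf) fit_gmm_1d(x, cf)$loglik, 0)
  expect_true(all(diff(lls) > -1e-8))
})

test_that("liver reference resists the low-uptake artifact", {
  spec <- small_liver_spec(3)
  ph <- make_phantom(spec)
  liver <- mask_from_label(ph$labels, 1L, "liver")
  est <- liver_reference(ph$suv, liver)
  expect_lt(abs(as.numeric(est) - 6), 0.15)
  # the naive mean is biased low by about the artifact mass
  er <- erode_mask(liver, 8)
  naive <- mean(suv_in_mask(ph$suv, er))
  expect_gt(abs(naive - 6), 0.5)
  expect_equal(naive, 0.7 * 6 + 0.3 * 3, tolerance = 0.35)

  cgrid <- grid_with_values(rep(4.2, 64), n = 8)
  expect_equal(as.numeric(liver_reference(cgrid$suv, cgrid$mask, cfg0)), 4.2)
})

test_that("both references scale exactly with the image", {
  spec <- small_liver_spec(5)
  ph <- make_phantom(spec)
  liver <- mask_from_label(ph$labels, 1L, "liver")
  doubled <- voxel_grid(ph$suv$data * 2, ph$suv$spacing)
  expect_equal(as.numeric(liver_reference(doubled, liver)),
               2 * as.numeric(liver_reference(ph$suv, liver)),
               tolerance = 1e-12)
  f <- grid_with_values(rexp(50) + 1, n = 8)
  f2 <- f
  f2$suv$data <- f2$suv$data * 2
  expect_equal(as.numeric(blood_pool_reference(f2$suv, f$mask, cfg0)),
               2 * as.numeric(blood_pool_reference(f$suv, f$mask, cfg0)),
               tolerance = 1e-12)
})

test_that("sphere VOIs average exactly the voxel centers they cover", {
  g <- voxel_grid(array(3.3, c(20, 20, 20)), c(3, 3, 3))
  expect_equal(as.numeric(sphere_roi_reference(g, c(30, 30, 30), 10)), 3.3)

  # count matches a brute-force center-in-sphere count
  ctr <- c(31, 29, 30)
  v <- sphere_roi_reference(g, ctr, 10)
  cc <- (1:20 - 0.5) * 3
  bf <- 0
  for (x in 1:20) for (y in 1:20) for (z in 1:20)
    if (sum((c(cc[x], cc[y], cc[z]) - ctr)^2) < 25) bf <- bf + 1
  expect_gte(bf, 1)
  expect_equal(attr(v, "n_voxels"), bf)

  expect_error(sphere_roi_reference(g, c(500, 500, 500), 10),
               "no voxel centers")
})

test_that("the EM fit agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(21)
  x <- c(rnorm(1500, 6, 0.4), rnorm(500, 3, 0.4))
  ours <- fit_gmm_1d(x)
  ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(ours$components$mean), sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.05)
  expect_equal(sort(ours$components$weight), sort(ref$parameters$pro),
               tolerance = 0.05)
})
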