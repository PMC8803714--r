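test_that("uniform-speed limit marches a ball clipped by the radius cap", {
  g <- voxel_grid(array(5, c(30, 30, 30)), c(3, 3, 3))
  cfg <- fastmarch_config(t_arrival = 12, max_radius_mm = 40)
  seg <- fast_march_segment(g, c(15, 15, 15), cfg, blood_pool = 5)
  # speed is 1 everywhere (SUV == seed), so arrival time ~ distance;
  # the first-order solver overestimates diagonal distances slightly
  arr <- mask_array(seg)
  idx <- which(arr, arr.ind = TRUE)
  d <- sqrt(rowSums((sweep(idx, 2, c(15, 15, 15)) * 3)^2))
  expect_lte(max(d), 12)
  expect_gte(sum(arr), sum(d <= 9))
  # radius cap binds when t_arrival is large
  seg2 <- fast_march_segment(g, c(15, 15, 15),
                             fastmarch_config(t_arrival = 1000,
                                              max_radius_mm = 12),
                             blood_pool = 5)
  idx2 <- which(mask_array(seg2), arr.ind = TRUE)
  expect_lte(max(sqrt(rowSums((sweep(idx2, 2, c(15, 15, 15)) * 3)^2))), 12)
})

test_that("an isolated blurred sphere is segmented close to truth", {
  g <- blob_grid(list(les(c(72, 72, 72), 10, 5)))
  seg <- fast_march_segment(g$suv, hottest_voxel(g$suv), fastmarch_config(),
                            blood_pool = 1.8)
  sa <- mask_array(seg)
  expect_gte(dice_arrays(sa, g$truth[[1]]), 0.7)
  expect_lte(abs(sum(sa) / sum(g$truth[[1]]) - 1), 0.3)
})

test_that("background gaps act as arrival-time barriers between lesions", {
  g <- blob_grid(list(les(c(52, 72, 72), 10, 5), les(c(82, 72, 72), 10, 5)))
  seed <- c(ceiling(52 / 3), 24, 24)
  seg <- fast_march_segment(g$suv, seed, fastmarch_config(), blood_pool = 1.8)
  expect_equal(sum(mask_array(seg) & g$truth[[2]]), 0)
  expect_gte(dice_arrays(mask_array(seg), g$truth[[1]]), 0.7)
})

test_that("raising the arrival threshold never shrinks the segment", {
  g <- blob_grid(list(les(c(72, 72, 72), 14, 4)))
  seed <- hottest_voxel(g$suv)
  prev <- NULL
  for (tv in c(6, 10, 15, 22)) {
    seg <- fast_march_segment(g$suv, seed, fastmarch_config(t_arrival = tv),
                              blood_pool = 1.8)
    cur <- which(mask_array(seg))
    if (!is.null(prev)) expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("a seed at or below the background floor is rejected", {
  g <- voxel_grid(array(0.5, c(10, 10, 10)), c(3, 3, 3))
  expect_error(fast_march_segment(g, c(5, 5, 5), fastmarch_config(),
                                  blood_pool = 1.8),
               "seed below background")
})

test_that("quantification handles uniform, sub-mL and ramp lesions", {
  # uniform lesion: max = peak = mean
  g <- voxel_grid(array(7, c(12, 12, 12)), c(3, 3, 3))
  mask <- array(FALSE, c(12, 12, 12))
  mask[3:8, 3:8, 3:8] <- TRUE  # 216 voxels * 0.027 mL = 5.832 mL
  q <- quantify(g, binary_mask(mask, template = g))
  expect_equal(q$suv_max, 7)
  expect_equal(q$suv_peak, 7)
  expect_equal(q$suv_mean, 7)
  expect_equal(q$volume_ml, 5.832)

  # single hot voxel: sub-mL fallback
  m1 <- array(FALSE, c(12, 12, 12))
  m1[6, 6, 6] <- TRUE
  g2 <- g
  g2$data[6, 6, 6] <- 10
  q1 <- quantify(g2, binary_mask(m1, template = g))
  expect_equal(q1$suv_peak, 10)
  expect_equal(q1$suv_mean, 10)
  expect_true("sub_ml" %in% q1$flags)

  expect_error(quantify(g, binary_mask(array(FALSE, c(12, 12, 12)),
                                       template = g)), "empty mask")

  # linear ramp: mean < peak < max, each matching the brute-force oracle
  n <- 10
  ramp <- array(rep(seq(1, 10, length.out = n), each = 1), c(n, n, n))
  for (x in 1:n) ramp[x, , ] <- x
  gr <- voxel_grid(ramp, c(3, 3, 3))
  mr <- array(FALSE, c(n, n, n))
  mr[2:9, 3:8, 3:8] <- TRUE
  qr <- quantify(gr, binary_mask(mr, template = gr))
  expect_lt(qr$suv_mean, qr$suv_peak)
  expect_lt(qr$suv_peak, qr$suv_max)
  expect_equal(qr$suv_peak, bf_suv_peak(ramp, mr, c(3, 3, 3)),
               tolerance = 1e-12)
  expect_equal(qr$suv_max, max(ramp[mr]))
  expect_equal(qr$suv_mean, mean(ramp[mr]))
})

test_that("region growing at 50% SUVmax leaks where fast marching holds", {
  # a 2:1 lesion 9 mm from a hot structure: the 50% cut sits at the
  # background level, so the grown region floods through it
  g <- blob_grid(list(les(c(60, 72, 72), 12, 2), les(c(87, 72, 72), 24, 10)))
  seed <- c(20, 24, 24)
  smax <- max(g$suv$data[g$truth[[1]]])
  grow <- label_components(g$suv$data >= 0.5 * smax)
  rg <- grow == grow[seed[1], seed[2], seed[3]]
  expect_lt(dice_arrays(rg, g$truth[[1]]), 0.5)

  seg <- fast_march_segment(g$suv, seed, fastmarch_config(), blood_pool = 1.8)
  expect_gte(dice_arrays(mask_array(seg), g$truth[[1]]), 0.7)
})
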