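test_that("suppression flattens excretory organs and decays with distance", {
  spec <- phantom_spec(seed = 21)
  ph <- make_phantom(spec)
  field <- fit_suppression(ph$suv, ph$labels)
  supp <- suppress_uptake(ph$suv, field)
  kid <- ph$labels$data == 4L
  expect_lt(mean(supp$data[kid]), 0.1 * mean(ph$suv$data[kid]))
  blad <- ph$labels$data == 6L
  expect_lt(mean(supp$data[blad]), 0.1 * mean(ph$suv$data[blad]))

  # a lesion 40 mm away from the kidney edge keeps its SUVmax
  spec2 <- phantom_spec(lesions = list(
    phantom_lesion(c(234, 210, 260), 12, 6, "lymph")), seed = 21)
  ph2 <- make_phantom(spec2)
  field2 <- fit_suppression(ph2$suv, ph2$labels)
  supp2 <- suppress_uptake(ph2$suv, field2)
  idx <- ph2$truth$lesions[[1]]$mask_idx
  expect_lt(abs(max(supp2$data[idx]) - max(ph2$suv$data[idx])) /
              max(ph2$suv$data[idx]), 0.05)
})

test_that("a label map without modeled organs yields a zero field", {
  arr <- array(0.8, c(24, 24, 24))
  g <- voxel_grid(arr, c(3, 3, 3))
  lab <- voxel_grid(array(0L, c(24, 24, 24)), c(3, 3, 3))
  w <- capture_warnings(field <- fit_suppression(g, lab))
  expect_length(w, 4)  # liver, two kidneys, bladder
  expect_match(w, "missing", all = TRUE)
  expect_true(all(field$data == 0))
})

test_that("blob detection finds one blurred sphere at position and scale", {
  g <- blob_grid(list(les(c(72, 72, 72), 10, 8)))
  cfg <- detection_config()
  mask <- binary_mask(array(TRUE, dim(g$suv$data)), template = g$suv)
  cands <- blob_detect(g$suv, mask, cfg, "bone")
  expect_equal(nrow(cands), 1)
  expect_lte(max(abs(c(cands$x_mm, cands$y_mm, cands$z_mm) - 72)), 3)
  expect_true(cands$scale_mm %in% c(8, 12))  # one scale-step around 10 mm

  # uniform field: no candidates
  u <- voxel_grid(array(2, c(24, 24, 24)), c(3, 3, 3))
  umask <- binary_mask(array(TRUE, c(24, 24, 24)), template = u)
  expect_equal(nrow(blob_detect(u, umask, cfg, "bone")), 0)

  # empty mask is allowed and yields an empty list
  emask <- binary_mask(array(FALSE, dim(g$suv$data)), template = g$suv)
  expect_equal(nrow(blob_detect(g$suv, emask, cfg, "bone")), 0)
})

test_that("two separated spheres give exactly two candidates", {
  g <- blob_grid(list(les(c(52, 72, 72), 10, 6), les(c(92, 72, 72), 10, 6)))
  mask <- binary_mask(array(TRUE, dim(g$suv$data)), template = g$suv)
  cands <- blob_detect(g$suv, mask, detection_config(), "bone")
  expect_equal(nrow(cands), 2)
  expect_lt(max(abs(sort(cands$x_mm) - c(52, 92))), 2)
})

test_that("threshold detection follows component semantics", {
  g <- blob_grid(list(les(c(72, 72, 72), 14, 4)))  # realized max < 4.3
  mask <- binary_mask(array(TRUE, dim(g$suv$data)), template = g$suv)
  realized <- max(g$suv$data)
  expect_lt(realized, 4.3)
  expect_gt(realized, 3.0)
  expect_equal(nrow(threshold_detect(g$suv, mask, 4.3)), 0)
  expect_equal(nrow(threshold_detect(g$suv, mask, 3.0)), 1)

  # two touching supra-threshold spheres form a single component
  g2 <- blob_grid(list(les(c(64, 72, 72), 12, 8), les(c(76, 72, 72), 12, 8)))
  mask2 <- binary_mask(array(TRUE, dim(g2$suv$data)), template = g2$suv)
  expect_equal(nrow(threshold_detect(g2$suv, mask2, 4.3)), 1)
})

test_that("filter rules reject by first failed rule with a named reason", {
  lab <- voxel_grid(array(0L, c(10, 10, 10)), c(3, 3, 3), kind = "label")
  lab$data[5, 5, 5] <- 6L  # bladder voxel
  mkrec <- function(i, suv_max, volume_ml = 1) {
    list(candidate = list(i = i, j = 5, k = 5, response = 1),
         suv_max = suv_max, suv_mean = suv_max / 2, volume_ml = volume_ml)
  }
  rules <- list(min_suv_max = 2, min_suv_mean = 0, min_volume_ml = 0.1,
                max_volume_ml = Inf, excluded_labels = 6L,
                exclusion_margin_mm = 0)
  out <- filter_candidates(list(mkrec(1, 1.2), mkrec(1, 5), mkrec(5, 50)),
                           lab, rules)
  expect_equal(out[[1]]$reject_reason, "suv_max")
  expect_true(out[[2]]$kept)
  expect_equal(out[[3]]$reject_reason, "location")

  # an empty rule set keeps everything
  none <- list(min_suv_max = 0, min_suv_mean = 0, min_volume_ml = 0,
               max_volume_ml = Inf, excluded_labels = integer(),
               exclusion_margin_mm = 0)
  out2 <- filter_candidates(list(mkrec(5, 0.1, 0.01)), lab, none)
  expect_true(out2[[1]]$kept)
})

test_that("the orchestrator assigns compartments and honours missing labels", {
  spec <- phantom_spec(lesions = list(
    phantom_lesion(c(150, 230, 210), 12, 5, "lymph"),
    phantom_lesion(c(192, 228, 300), 12, 5, "bone")), seed = 13)
  ph <- make_phantom(spec)
  cands <- detect_lesions(ph$suv, ph$labels)
  near <- function(ctr, comp) {
    sel <- cands$compartment == comp
    any(sqrt((cands$x_mm[sel] - ctr[1])^2 + (cands$y_mm[sel] - ctr[2])^2 +
               (cands$z_mm[sel] - ctr[3])^2) <= 10)
  }
  expect_true(near(c(150, 230, 210), "lymph"))
  expect_true(near(c(192, 228, 300), "bone"))

  # no prostate label: warning and no prostate candidates
  nop <- ph$labels
  nop$data[nop$data == 7L] <- 0L
  expect_warning(c2 <- detect_lesions(ph$suv, nop), "prostate")
  expect_equal(sum(c2$compartment == "prostate"), 0)

  # no bone labels at all: error
  nob <- ph$labels
  nob$data[nob$data %in% c(11:15, 101:151)] <- 0L
  expect_error(detect_lesions(ph$suv, nob), "bone")
})

test_that("candidate lists are deterministic and translation-equivariant", {
  g <- blob_grid(list(les(c(60, 66, 72), 10, 7)))
  mask <- binary_mask(array(TRUE, dim(g$suv$data)), template = g$suv)
  c1 <- blob_detect(g$suv, mask, detection_config(), "bone")
  c2 <- blob_detect(g$suv, mask, detection_config(), "bone")
  expect_identical(c1, c2)

  shift <- c(2, 1, 3)  # voxels
  g2 <- blob_grid(list(les(c(60, 66, 72) + shift * 3, 10, 7)))
  c3 <- blob_detect(g2$suv, mask, detection_config(), "bone")
  expect_equal(c(c3$i, c3$j, c3$k), c(c1$i, c1$j, c1$k) + shift)
  expect_equal(c3$response, c1$response, tolerance = 1e-10)
})

test_that("a lesion-free phantom yields no bone candidates and no kept
           findings inside excluded organs", {
  spec <- phantom_suite(1, seed = 77, lesions = FALSE)[[1]]
  ph <- make_phantom(spec)
  an <- analyze(ph$suv, ph$labels)
  expect_equal(sum(an$candidates$compartment == "bone"), 0)
  excl <- array(ph$labels$data %in% c(4L, 5L, 6L), dim(ph$labels$data))
  for (rec in an$lesions) {
    cand <- rec$candidate
    expect_false(excl[cand$i, cand$j, cand$k])
  }
})
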