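mk_mask <- function(arr, g) binary_mask(arr, template = g)

test_that("dice follows the overlap formula, symmetrically", {
  g <- voxel_grid(array(0, c(8, 8, 8)), c(1, 1, 1))
  a <- array(FALSE, c(8, 8, 8)); a[1:2] <- TRUE
  b <- array(FALSE, c(8, 8, 8)); b[2:3] <- TRUE
  expect_equal(dice(mk_mask(a, g), mk_mask(b, g)), 0.5)  # 2*1/(2+2)
  expect_equal(dice(mk_mask(a, g), mk_mask(a, g)), 1)
  d <- array(FALSE, c(8, 8, 8)); d[30:35] <- TRUE
  expect_equal(dice(mk_mask(a, g), mk_mask(d, g)), 0)
  expect_warning(v <- dice(mk_mask(array(FALSE, c(8, 8, 8)), g),
                           mk_mask(array(FALSE, c(8, 8, 8)), g)), "empty")
  expect_equal(v, 1)
  g2 <- voxel_grid(array(0, c(4, 4, 4)), c(1, 1, 1))
  expect_error(dice(mk_mask(a, g), mk_mask(array(FALSE, c(4, 4, 4)), g2)),
               "mismatch")

  set.seed(1)
  for (rep in 1:100) {
    aa <- array(runif(8^3) > 0.6, c(8, 8, 8))
    bb <- array(runif(8^3) > 0.6, c(8, 8, 8))
    expect_identical(dice(mk_mask(aa, g), mk_mask(bb, g)),
                     dice(mk_mask(bb, g), mk_mask(aa, g)))
    expect_equal(dice(mk_mask(aa, g), mk_mask(bb, g)),
                 2 * sum(aa & bb) / (sum(aa) + sum(bb)))
  }
})

fake_truth <- function(centers, diameter = 10) {
  list(lesions = lapply(seq_len(nrow(centers)), function(i)
    list(center = centers[i, ], diameter = diameter)),
    spacing = c(3, 3, 3))
}
fake_det <- function(centers, resp = NULL) {
  lapply(seq_len(nrow(centers)), function(i)
    list(centroid_mm = centers[i, ], spacing = c(3, 3, 3),
         candidate = list(response = if (is.null(resp)) 1 else resp[i])))
}

test_that("matching is one-to-one and greedy by response", {
  ctrs <- rbind(c(30, 30, 30), c(90, 90, 90))
  m <- match_lesions(fake_truth(ctrs), fake_det(ctrs))
  expect_equal(nrow(m$pairs), 2)
  expect_equal(length(m$false_positives), 0)

  m0 <- match_lesions(fake_truth(ctrs), list())
  expect_equal(sort(m0$missed_truth), c(1, 2))

  # two detections near one truth lesion: one match + one false positive
  both <- rbind(c(30, 30, 30), c(34, 30, 30))
  m2 <- match_lesions(fake_truth(matrix(c(30, 30, 30), 1)), fake_det(both))
  expect_equal(nrow(m2$pairs), 1)
  expect_equal(length(m2$false_positives), 1)

  # a far detection never matches
  m3 <- match_lesions(fake_truth(matrix(c(30, 30, 30), 1)),
                      fake_det(matrix(c(90, 90, 90), 1)))
  expect_equal(nrow(m3$pairs), 0)
  expect_equal(length(m3$false_positives), 1)
})

test_that("sensitivity is a percentage with a Wilson interval", {
  s <- sensitivity(c(9, 10))
  expect_equal(s$sensitivity_pct, 90)
  expect_lt(s$ci_pct[1], 90)
  expect_gt(s$ci_pct[2], 90)
  expect_equal(sensitivity(c(10, 10))$sensitivity_pct, 100)
  expect_equal(sensitivity(c(172, 188))$sensitivity_pct, 91.489, tolerance = 1e-4)
  expect_error(sensitivity(c(0, 0)), "no truth")
  # sensitivity + miss rate = 100 exactly
  m <- match_lesions(fake_truth(rbind(c(30, 30, 30), c(90, 90, 90))),
                     fake_det(matrix(c(30, 30, 30), 1)))
  s2 <- sensitivity(m)
  expect_identical(s2$sensitivity_pct +
                     100 * length(m$missed_truth) / s2$total, 100)
})

test_that("pearson matches the covariance formula with Fisher-z interval", {
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  p <- pearson(x, y)
  r_bf <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(p$r, r_bf, tolerance = 1e-12)
  expect_equal(pearson(1:10, 1:10 * 2)$r, 1)
  expect_equal(pearson(1:10, -(1:10))$r, -1)
  expect_error(pearson(1:10, rep(1, 10)), "constant")
  expect_error(pearson(1:2, 1:2), "length >= 3")
})

test_that("icc2 equals the ANOVA mean-square construction", {
  # identical columns reproduce perfectly
  v <- c(3, 5, 9, 2, 7)
  expect_equal(icc2(cbind(v, v)), 1, tolerance = 1e-12)

  # rater noise far above subject variance drives the ICC to zero
  set.seed(2)
  subj <- rnorm(60, 0, 0.1)
  m <- cbind(subj + rnorm(60, 0, 10), subj + rnorm(60, 0, 10),
             subj + rnorm(60, 0, 10))
  expect_lt(abs(icc2(m)), 0.15)

  # 6 x 4 matrix against an independent aov() mean-square oracle
  ratings <- matrix(c(9, 2, 5, 8,
                      6, 1, 3, 2,
                      8, 4, 6, 8,
                      7, 1, 2, 6,
                      10, 5, 6, 9,
                      6, 2, 4, 7), nrow = 6, byrow = TRUE)
  df <- data.frame(y = as.vector(ratings),
                   subj = factor(rep(1:6, 4)),
                   rater = factor(rep(1:4, each = 6)))
  ms <- summary(aov(y ~ subj + rater, df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 4; n <- 6
  icc_bf <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(icc2(ratings), icc_bf, tolerance = 1e-12)

  expect_error(icc2(matrix(c(1, NA, 2, 3), 2)), "missing")
})

test_that("per-method SDs use the sample convention", {
  expect_equal(unname(reference_sd(cbind(a = c(2, 2, 2), b = 1:3))), c(0, 1))
  expect_error(reference_sd(matrix(1, 1, 2)), "at least 2")
})

test_that("reports survive a JSON round trip and flatten to CSV", {
  dir <- withr::local_tempdir()
  rep0 <- make_report()
  expect_s3_class(rep0, "agreement_report")
  write_report(rep0, file.path(dir, "empty.json"), file.path(dir, "empty.csv"))
  expect_equal(nrow(read.csv(file.path(dir, "empty.csv"))), 0)

  rep1 <- make_report(
    dice_per_region = c(femur = 0.95, thorax = 0.88),
    sensitivity = list(bone = sensitivity(c(9, 10))),
    fp_per_patient = 3.5,
    pearson = list(bp = pearson(c(1, 2, 3, 4), c(1.1, 2.2, 2.9, 4.2))),
    sd_per_method = c(automated = 0.21, reader_1 = 0.23),
    icc = c(suv_max = 1))
  write_report(rep1, file.path(dir, "r.json"), file.path(dir, "r.csv"))
  back <- read_report(file.path(dir, "r.json"))
  expect_equal(back$dice_per_region[["femur"]], 0.95)
  expect_equal(back$sensitivity$bone$sensitivity_pct, 90)
  expect_equal(back$sd_per_method[["automated"]], 0.21)
  csv <- read.csv(file.path(dir, "r.csv"))
  expect_equal(nrow(csv), 2 + 1 + 1 + 1 + 2 + 1)
})
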