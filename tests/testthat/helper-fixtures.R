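# Fixtures are generated in code: blurred-sphere grids for the detector and
# segmenter, small liver-only phantoms for the reference estimator, and
# independent brute-force oracles for the statistics they are checked
# against.

# uniform background with spherical inserts, blurred by a Gaussian PSF
blob_grid <- function(lesions, bg = 1, n = 48, sp = 3, fwhm = 6) {
  cc <- (seq_len(n) - 0.5) * sp
  arr <- array(bg, c(n, n, n))
  truth <- list()
  for (les in lesions) {
    sph <- psmaquant:::shape_membership(
      psmaquant:::shape_ellipsoid(les$center, rep(les$diameter / 2, 3)),
      cc, cc, cc)
    arr[sph] <- les$suv
    truth[[length(truth) + 1]] <- sph
  }
  if (fwhm > 0)
    arr <- psmaquant:::gaussian_blur_arr(arr, rep(fwhm / 2.354820045, 3),
                                         rep(sp, 3))
  list(suv = voxel_grid(arr, rep(sp, 3)), truth = truth, spacing = rep(sp, 3))
}

les <- function(center, diameter, suv)
  list(center = center, diameter = diameter, suv = suv)

hottest_voxel <- function(grid) {
  w <- which(grid$data == max(grid$data), arr.ind = TRUE)
  w[1, ]
}

dice_arrays <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# liver-only phantom on a small grid (for mixture-recovery experiments)
small_liver_spec <- function(seed, liver_suv = 6, artifact = c(0.3, 0.5),
                             noise = 0.1) {
  phantom_spec(shape = c(48L, 48L, 48L), spacing = c(3, 3, 3),
               background_suv = 0.8,
               body = list(center = c(72, 72), radii = c(68, 66)),
               organs = list(psmaquant:::phantom_organ(
                 "liver", 1L, liver_suv,
                 psmaquant:::shape_ellipsoid(c(72, 72, 72), c(40, 36, 32)))),
               lesions = list(), psf_fwhm = 6, noise_factor = noise,
               liver_artifact = artifact, seed = seed)
}

# ---- independent oracles ----------------------------------------------------

# percentile by sorting + linear interpolation between order statistics
bf_percentile <- function(v, p) {
  s <- sort(v)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# IQR-mean: filter to [Q1, Q3] inclusive, then average
bf_iqr_mean <- function(v) {
  q1 <- bf_percentile(v, 0.25)
  q3 <- bf_percentile(v, 0.75)
  mean(v[v >= q1 & v <= q3])
}

# brute-force erosion: voxel survives iff every ball offset stays inside
bf_erode <- function(arr, radius_vox) {
  d <- dim(arr)
  r <- radius_vox
  out <- array(FALSE, d)
  offs <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 + offs$dz^2 <= r^2 + 1e-9, ]
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!arr[x, y, z]) next
    keep <- TRUE
    for (o in seq_len(nrow(offs))) {
      u <- c(x + offs$dx[o], y + offs$dy[o], z + offs$dz[o])
      if (any(u < 1) || any(u > d) || !arr[u[1], u[2], u[3]]) {
        keep <- FALSE
        break
      }
    }
    out[x, y, z] <- keep
  }
  out
}

# brute-force SUVpeak: scan every in-mask center, average in-mask voxels
# whose centers fall inside the peak sphere
bf_suv_peak <- function(suv_arr, mask_arr, spacing, volume_ml = 1) {
  r <- (3 * volume_ml * 1000 / (4 * pi))^(1 / 3)
  d <- dim(suv_arr)
  centers <- which(mask_arr, arr.ind = TRUE)
  best <- -Inf
  for (i in seq_len(nrow(centers))) {
    acc <- 0
    cnt <- 0
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      if (!mask_arr[x, y, z]) next
      dd <- sum(((c(x, y, z) - centers[i, ]) * spacing)^2)
      if (dd <= r^2) {
        acc <- acc + suv_arr[x, y, z]
        cnt <- cnt + 1
      }
    }
    best <- max(best, acc / cnt)
  }
  best
}

# random connected-ish mask: an ellipsoid with jittered radii
random_lesion_fixture <- function(n = 12, sp = 3) {
  ctr <- runif(3, 0.35, 0.65) * n * sp
  radii <- runif(3, 4, 14)
  cc <- (seq_len(n) - 0.5) * sp
  mask <- psmaquant:::shape_membership(
    psmaquant:::shape_ellipsoid(ctr, radii), cc, cc, cc)
  if (!any(mask)) mask[ceiling(n / 2), ceiling(n / 2), ceiling(n / 2)] <- TRUE
  field <- array(runif(n^3, 0.5, 1), c(n, n, n)) +
    psmaquant:::gaussian_blur_arr(array(rnorm(n^3), c(n, n, n)),
                                  rep(4, 3), rep(sp, 3)) * 2
  field <- pmax(field, 0.01)
  grid <- voxel_grid(field, rep(sp, 3))
  list(suv = grid, mask = binary_mask(mask, template = grid))
}
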