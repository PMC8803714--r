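# Reference-organ uptake: blood pool from the eroded thoracic aorta
# (interquartile-range mean) and liver from the dominant mode of a
# two-component Gaussian mixture fitted to the eroded liver intensities
# (robust to breathing-related regions of artifactually low uptake).

#' Reference quantification settings
#'
#' @param erosion_radius_mm named vector of per-organ erosion radii in mm
#'   (spherical element, anisotropy-aware). Defaults: aorta 4, liver 8 -
#'   about 1-3 PET voxels, large enough to clear boundary spill-over while
#'   keeping the aorta nonempty.
#' @param iqr_bounds lower/upper percentiles (default 25/75) defining the
#'   interquartile band for the blood-pool mean.
#' @param min_voxels minimum voxel count after erosion.
#' @param gmm_max_iter,gmm_tol EM iteration cap and log-likelihood tolerance.
#' @param gmm_sigma_floor lower bound on component SDs (SUV).
#' @param gmm_unimodal_tol if the two component means are closer than this,
#'   the fit is declared unimodal and the overall mean is used (flagged).
#' @param gmm_weight_floor if the higher-mean component has weight below
#'   this, fall back to the larger-weight component (guards against fitting
#'   a tiny high tail).
#' @return list of class `reference_config`.
#' @export
reference_config <- function(erosion_radius_mm = c(aorta = 4, liver = 8),
                             iqr_bounds = c(25, 75), min_voxels = 10,
                             gmm_max_iter = 500, gmm_tol = 1e-6,
                             gmm_sigma_floor = 1e-3, gmm_unimodal_tol = 0.1,
                             gmm_weight_floor = 0.2) {
  stopifnot(iqr_bounds[1] >= 0, iqr_bounds[1] < iqr_bounds[2],
            iqr_bounds[2] <= 100, all(erosion_radius_mm >= 0))
  structure(list(erosion_radius_mm = erosion_radius_mm,
                 iqr_bounds = iqr_bounds, min_voxels = min_voxels,
                 gmm_max_iter = gmm_max_iter, gmm_tol = gmm_tol,
                 gmm_sigma_floor = gmm_sigma_floor,
                 gmm_unimodal_tol = gmm_unimodal_tol,
                 gmm_weight_floor = gmm_weight_floor),
            class = "reference_config")
}

#' Erode a binary mask by a physical radius
#'
#' Morphological erosion by a sphere of the given radius in mm; the radius
#' is converted per axis by the voxel spacing, so anisotropic grids erode by
#' the same physical distance in every direction. Radius 0 is the identity.
#'
#' @param mask `binary_mask`.
#' @param radius_mm erosion radius in mm (>= 0).
#' @param spacing voxel spacing, default taken from the mask.
#' @return eroded `binary_mask` (always a subset of the input).
#' @export
erode_mask <- function(mask, radius_mm, spacing = mask$grid$spacing) {
  stopifnot(radius_mm >= 0)
  if (radius_mm == 0) return(mask)
  arr <- mask_array(mask)
  out <- cpp_morph(as.vector(arr), dim(arr), radius_mm / spacing, TRUE)
  out <- array(out, dim(arr))
  if (!any(out))
    stop("erosion by ", radius_mm,
         " mm left no voxels in '", mask$label_name,
         "'; reduce the erosion radius")
  binary_mask(out, label_name = mask$label_name, template = mask$grid)
}

dilate_mask_arr <- function(arr, radius_mm, spacing) {
  if (radius_mm <= 0) return(arr)
  array(cpp_morph(as.vector(arr), dim(arr), radius_mm / spacing, FALSE),
        dim(arr))
}

#' Blood-pool reference SUV (interquartile-range mean)
#'
#' Erodes the (thoracic) aorta mask, computes the lower/upper percentiles of
#' the SUVs inside it (linear interpolation between order statistics,
#' bounds inclusive), and returns the mean of the values within that band.
#'
#' @param suv SUV `voxel_grid`.
#' @param aorta thoracic-aorta `binary_mask`.
#' @param cfg [reference_config()].
#' @return scalar SUV with attribute `n_voxels`.
#' @export
blood_pool_reference <- function(suv, aorta, cfg = reference_config()) {
  er <- erode_mask(aorta, cfg$erosion_radius_mm[["aorta"]])
  v <- suv_in_mask(suv, er)
  if (length(v) < cfg$min_voxels)
    stop("only ", length(v), " aorta voxels after erosion (minimum ",
         cfg$min_voxels, ")")
  q <- quantile(v, cfg$iqr_bounds / 100, type = 7, names = FALSE)
  out <- mean(v[v >= q[1] & v <= q[2]])
  attr(out, "n_voxels") <- length(v)
  out
}

#' Fit a 1D two-component Gaussian mixture by EM
#'
#' Deterministic fit: means initialised at the 25th/75th percentiles of the
#' data, equal weights, common SD initialised at the sample SD. Component
#' SDs are floored; if the converged means are closer than
#' `gmm_unimodal_tol` the fit is flagged `"unimodal"`.
#'
#' @param values numeric vector (length >= 2 * components).
#' @param cfg [reference_config()].
#' @return list with `components` (data.frame `weight`, `mean`, `sd`,
#'   ordered by increasing mean), `loglik`, `iterations`, `converged`,
#'   `flags` (character vector, possibly empty).
#' @export
fit_gmm_1d <- function(values, cfg = reference_config()) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 4) stop("need at least 4 values for a 2-component fit")
  flags <- character()
  mu <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  s0 <- max(sd(x), cfg$gmm_sigma_floor)
  if (mu[2] - mu[1] < 1e-12) {
    # degenerate (near-constant) input: collapses to a single component
    comp <- data.frame(weight = c(0.5, 0.5), mean = c(mu[1], mu[2]),
                       sd = rep(max(s0, cfg$gmm_sigma_floor), 2))
    return(list(components = comp, loglik = NA_real_, iterations = 0L,
                converged = TRUE, flags = c("degenerate", "unimodal")))
  }
  w <- c(0.5, 0.5)
  sg <- c(s0, s0)
  ll_old <- -Inf
  iter <- 0L
  converged <- FALSE
  for (iter in seq_len(cfg$gmm_max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], sg[1])
    d2 <- w[2] * dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    r2 <- d2 / tot
    r1 <- 1 - r2
    n1 <- sum(r1); n2 <- sum(r2)
    if (n1 < 1e-10 || n2 < 1e-10) { flags <- c(flags, "collapsed"); break }
    w <- c(n1, n2) / n
    mu <- c(sum(r1 * x) / n1, sum(r2 * x) / n2)
    sg <- c(sqrt(sum(r1 * (x - mu[1])^2) / n1),
            sqrt(sum(r2 * (x - mu[2])^2) / n2))
    sg <- pmax(sg, cfg$gmm_sigma_floor)
    ll <- sum(log(tot))
    if (is.finite(ll_old) && ll - ll_old < cfg$gmm_tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  ord <- order(mu)
  comp <- data.frame(weight = w[ord], mean = mu[ord], sd = sg[ord])
  if (abs(diff(comp$mean)) < cfg$gmm_unimodal_tol)
    flags <- c(flags, "unimodal")
  list(components = comp, loglik = ll_old, iterations = iter,
       converged = converged, flags = flags)
}

#' Liver reference SUV (dominant mixture mode)
#'
#' Erodes the liver mask, fits a two-component Gaussian mixture to the
#' intensities, and returns the mean of the dominant-uptake component: the
#' component with the larger mean, because the artifact this estimator
#' corrects (breathing attenuation) produces regions of artifactually *low*
#' uptake. If that component's weight is below `gmm_weight_floor`, the
#' larger-weight component is used instead (with a warning); if the fit is
#' unimodal the overall mean is returned (flagged).
#'
#' @param suv SUV `voxel_grid`.
#' @param liver liver `binary_mask`.
#' @param cfg [reference_config()].
#' @return scalar SUV with attributes `gmm`, `n_voxels`, `flags`.
#' @export
liver_reference <- function(suv, liver, cfg = reference_config()) {
  er <- erode_mask(liver, cfg$erosion_radius_mm[["liver"]])
  v <- suv_in_mask(suv, er)
  if (length(v) < cfg$min_voxels)
    stop("only ", length(v), " liver voxels after erosion (minimum ",
         cfg$min_voxels, ")")
  fit <- fit_gmm_1d(v, cfg)
  flags <- fit$flags
  if ("unimodal" %in% flags) {
    out <- mean(v)
  } else {
    hi <- which.max(fit$components$mean)
    if (fit$components$weight[hi] < cfg$gmm_weight_floor) {
      warning("higher-mean mixture component has weight ",
              signif(fit$components$weight[hi], 3),
              " < ", cfg$gmm_weight_floor,
              "; using the larger-weight component")
      hi <- which.max(fit$components$weight)
      flags <- c(flags, "weight_fallback")
    }
    out <- fit$components$mean[hi]
  }
  attr(out, "gmm") <- fit$components
  attr(out, "n_voxels") <- length(v)
  attr(out, "flags") <- flags
  out
}

#' Fixed-sphere VOI mean (manual-reader emulation)
#'
#' Mean SUV over voxels whose centers lie inside a sphere; emulates the
#' manual method of placing a fixed volume of interest (1 cm diameter in the
#' descending thoracic aorta, 3 cm in the liver).
#'
#' @param suv SUV `voxel_grid`.
#' @param center_mm sphere center in mm (world frame of the grid).
#' @param diameter_mm sphere diameter in mm.
#' @return scalar SUV with attribute `n_voxels`.
#' @export
sphere_roi_reference <- function(suv, center_mm, diameter_mm) {
  sp <- suv$spacing
  cc <- voxel_centers_mm(dim(suv$data), sp)
  r <- diameter_mm / 2
  sph <- shape_membership(shape_ellipsoid(center_mm, rep(r, 3) + 1e-9),
                          cc$x, cc$y, cc$z)
  n <- sum(sph)
  if (n == 0)
    stop("sphere at (", paste(signif(center_mm, 4), collapse = ", "),
         ") mm contains no voxel centers")
  out <- mean(suv$data[sph])
  attr(out, "n_voxels") <- n
  out
}

#' Reference values for a study (blood pool + liver)
#'
#' Orchestrates [blood_pool_reference()] (thoracic aorta label only; the
#' manual comparator for blood pool is the descending thoracic aorta) and
#' [liver_reference()] over a label map.
#'
#' @param suv SUV `voxel_grid`.
#' @param labels label `voxel_grid` using the [label_vocabulary()] ids.
#' @param cfg [reference_config()].
#' @return list of class `reference_values`: `blood_pool`, `liver`,
#'   `n_voxels`, `gmm`, `flags`, `method`.
#' @export
reference_values <- function(suv, labels, cfg = reference_config()) {
  aorta <- mask_from_label(labels, 2L, "aorta_thoracic")
  if (sum(mask_array(aorta)) == 0) stop("thoracic aorta label (2) missing")
  liver <- mask_from_label(labels, 1L, "liver")
  if (sum(mask_array(liver)) == 0) stop("liver label (1) missing")
  bp <- blood_pool_reference(suv, aorta, cfg)
  lv <- liver_reference(suv, liver, cfg)
  structure(list(blood_pool = as.numeric(bp), liver = as.numeric(lv),
                 n_voxels = c(aorta = attr(bp, "n_voxels"),
                              liver = attr(lv, "n_voxels")),
                 gmm = attr(lv, "gmm"),
                 flags = attr(lv, "flags"),
                 method = c(blood_pool = "iqr_mean_eroded_aorta",
                            liver = "gmm_dominant_mode_eroded_liver")),
            class = "reference_values")
}
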