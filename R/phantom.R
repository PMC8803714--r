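# Synthetic trunk phantom: co-registered SUV volume, organ label map and
# lesion ground truth with the statistical structure the pipeline assumes
# (organ-specific uptake, PSF blur, variance-scaled Gaussian noise, and a
# breathing-type low-uptake artifact in the superior liver).

# ---- geometric primitives ---------------------------------------------------
# Shapes are defined in mm in the grid's world frame (voxel centers at
# (i - 0.5) * spacing). `inflate` grows every radius by a margin in mm.

shape_ellipsoid <- function(center, radii) {
  list(type = "ellipsoid", center = as.numeric(center), radii = as.numeric(radii))
}
shape_tube <- function(center_xy, radius_xy, zlim) {
  if (length(radius_xy) == 1) radius_xy <- rep(radius_xy, 2)
  list(type = "tube", center = as.numeric(center_xy),
       radii = as.numeric(radius_xy), zlim = as.numeric(zlim))
}
shape_shell <- function(center_xy, outer_xy, inner_xy, zlim) {
  list(type = "shell", center = as.numeric(center_xy),
       outer = as.numeric(outer_xy), inner = as.numeric(inner_xy),
       zlim = as.numeric(zlim))
}

# membership of points (n x 3 matrix, mm) in a shape
shape_contains_pts <- function(shape, pts, inflate = 0) {
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  switch(shape$type,
    ellipsoid = {
      r <- shape$radii + inflate
      ((x - shape$center[1]) / r[1])^2 + ((y - shape$center[2]) / r[2])^2 +
        ((z - shape$center[3]) / r[3])^2 < 1
    },
    tube = {
      r <- shape$radii + inflate
      in_xy <- ((x - shape$center[1]) / r[1])^2 +
               ((y - shape$center[2]) / r[2])^2 < 1
      in_xy & z >= shape$zlim[1] - inflate & z < shape$zlim[2] + inflate
    },
    shell = {
      ro <- shape$outer + inflate
      ri <- pmax(shape$inner - inflate, 1e-6)
      fo <- ((x - shape$center[1]) / ro[1])^2 + ((y - shape$center[2]) / ro[2])^2
      fi <- ((x - shape$center[1]) / ri[1])^2 + ((y - shape$center[2]) / ri[2])^2
      fo < 1 & fi >= 1 & z >= shape$zlim[1] - inflate & z < shape$zlim[2] + inflate
    },
    stop("unknown shape type: ", shape$type))
}

# membership over the whole grid, via separable outer sums where possible
shape_membership <- function(shape, xs, ys, zs) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  switch(shape$type,
    ellipsoid = {
      ex <- ((xs - shape$center[1]) / shape$radii[1])^2
      ey <- ((ys - shape$center[2]) / shape$radii[2])^2
      ez <- ((zs - shape$center[3]) / shape$radii[3])^2
      outer(outer(ex, ey, "+"), ez, "+") < 1
    },
    tube = {
      ex <- ((xs - shape$center[1]) / shape$radii[1])^2
      ey <- ((ys - shape$center[2]) / shape$radii[2])^2
      inz <- zs >= shape$zlim[1] & zs < shape$zlim[2]
      m2 <- outer(ex, ey, "+") < 1
      outer(m2, inz, "&")
    },
    shell = {
      fo <- outer(((xs - shape$center[1]) / shape$outer[1])^2,
                  ((ys - shape$center[2]) / shape$outer[2])^2, "+") < 1
      fi <- outer(((xs - shape$center[1]) / shape$inner[1])^2,
                  ((ys - shape$center[2]) / shape$inner[2])^2, "+") >= 1
      inz <- zs >= shape$zlim[1] & zs < shape$zlim[2]
      outer(fo & fi, inz, "&")
    },
    stop("unknown shape type: ", shape$type))
}

phantom_organ <- function(name, label, suv, shapes) {
  if (!is.null(shapes$type)) shapes <- list(shapes)
  list(name = name, label = as.integer(label), suv = as.numeric(suv),
       shapes = shapes)
}

# ---- default trunk geometry -------------------------------------------------

#' Default trunk organ set for the phantom
#'
#' A fixed, non-overlapping trunk-scale geometry (384 x 384 x 480 mm world
#' box): liver and lung ellipsoids, kidney ellipsoids, bladder and prostate
#' spheres, thoracic/abdominal aorta tubes, and the 5 skeletal regions as
#' tubes/shells (femoral tubes, pelvic ring, lumbar and thoracic spine
#' columns, rib-cage shell). Uptakes default to a PSMA-like biodistribution
#' ordering (excretory >> liver >> blood pool >> bone/background).
#'
#' @param uptake named list/vector overriding default mean SUVs:
#'   `liver`, `blood_pool`, `kidneys`, `bladder`, `prostate`, `lungs`, `bone`.
#' @return list of organ descriptors (name, label id, SUV, shapes).
#' @export
default_phantom_organs <- function(uptake = list()) {
  u <- utils::modifyList(
    list(liver = 6.0, blood_pool = 1.8, kidneys = 30, bladder = 60,
         prostate = 1.5, lungs = 0.4, bone = 1.0),
    as.list(uptake))
  list(
    phantom_organ("liver", 1L, u$liver,
                  shape_ellipsoid(c(145, 185, 225), c(40, 38, 30))),
    phantom_organ("aorta_thoracic", 2L, u$blood_pool,
                  shape_tube(c(192, 208), 9, c(242, 362))),
    phantom_organ("aorta_abdominal", 3L, u$blood_pool,
                  shape_tube(c(192, 208), 8, c(185, 240))),
    phantom_organ("kidney_left", 4L, u$kidneys,
                  shape_ellipsoid(c(234, 210, 178), c(14, 13, 18))),
    phantom_organ("kidney_right", 5L, u$kidneys,
                  shape_ellipsoid(c(150, 210, 178), c(14, 13, 18))),
    phantom_organ("urinary_bladder", 6L, u$bladder,
                  shape_ellipsoid(c(192, 190, 162), c(20, 20, 20))),
    phantom_organ("prostate", 7L, u$prostate,
                  shape_ellipsoid(c(192, 190, 118), c(14, 14, 14))),
    phantom_organ("lung_left", 8L, u$lungs,
                  shape_ellipsoid(c(232, 185, 320), c(24, 28, 48))),
    phantom_organ("lung_right", 9L, u$lungs,
                  shape_ellipsoid(c(152, 185, 320), c(24, 28, 48))),
    phantom_organ("femur", 11L, u$bone,
                  list(shape_tube(c(147, 192), 12, c(20, 100)),
                       shape_tube(c(237, 192), 12, c(20, 100)))),
    phantom_organ("pelvic region", 12L, u$bone,
                  shape_shell(c(192, 192), c(62, 45), c(47, 32), c(100, 138))),
    phantom_organ("lumbar vertebrae", 13L, u$bone,
                  shape_tube(c(192, 228), 10, c(140, 238))),
    phantom_organ("thoracic vertebrae", 14L, u$bone,
                  shape_tube(c(192, 228), 10, c(242, 362))),
    phantom_organ("thorax", 15L, u$bone,
                  shape_shell(c(192, 192), c(80, 58), c(70, 52), c(262, 378)))
  )
}

#' Phantom lesion descriptor
#' @param center_mm length-3 lesion center in mm.
#' @param diameter_mm sphere diameter in mm (> 0).
#' @param suv uniform interior SUV before blurring (the peak value).
#' @param compartment one of `"bone"`, `"lymph"`, `"prostate"`.
#' @return lesion descriptor list.
#' @export
phantom_lesion <- function(center_mm, diameter_mm, suv,
                           compartment = c("bone", "lymph", "prostate")) {
  compartment <- match.arg(compartment)
  stopifnot(diameter_mm > 0, suv > 0, length(center_mm) == 3)
  list(center = as.numeric(center_mm), diameter = as.numeric(diameter_mm),
       suv = as.numeric(suv), compartment = compartment)
}

#' Phantom specification
#'
#' Declarative description of a synthetic PSMA PET study: grid geometry,
#' organ set with mean uptakes, background SUV, lesion list, point-spread
#' FWHM, noise model and liver artifact.
#'
#' @param shape grid dimensions, default `c(128, 128, 160)`.
#' @param spacing voxel spacing mm, default `c(3, 3, 3)`.
#' @param background_suv soft-tissue background SUV inside the body outline.
#' @param body elliptical-cylinder body outline (`center` xy mm, `radii` xy mm).
#' @param organs organ list, default [default_phantom_organs()].
#' @param lesions list of [phantom_lesion()] descriptors.
#' @param psf_fwhm isotropic Gaussian PSF FWHM in mm (0 disables blur).
#' @param noise_factor Gaussian noise scale: sd = `noise_factor * sqrt(SUV)`
#'   per voxel (variance-scaling surrogate for Poisson counting noise);
#'   0 disables noise.
#' @param liver_artifact length-2 `(fraction, multiplier)`: the superior
#'   `fraction` of liver voxels has uptake multiplied by `multiplier` (< 1),
#'   emulating breathing-related low-uptake regions. `c(0, 1)` disables.
#' @param seed RNG seed for the noise draw.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L, 160L), spacing = c(3, 3, 3),
                         background_suv = 0.8,
                         body = list(center = c(192, 192), radii = c(90, 65)),
                         organs = default_phantom_organs(),
                         lesions = list(),
                         psf_fwhm = 6, noise_factor = 0.1,
                         liver_artifact = c(0.3, 0.5), seed = 1L) {
  stopifnot(length(shape) == 3, all(shape >= 8), length(spacing) == 3,
            all(spacing > 0), background_suv >= 0, psf_fwhm >= 0,
            noise_factor >= 0, length(liver_artifact) == 2,
            liver_artifact[1] >= 0, liver_artifact[1] < 1,
            liver_artifact[2] > 0)
  for (les in lesions) stopifnot(les$diameter > 0)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 background_suv = background_suv, body = body,
                 organs = organs, lesions = lesions, psf_fwhm = psf_fwhm,
                 noise_factor = noise_factor,
                 liver_artifact = as.numeric(liver_artifact),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

voxel_centers_mm <- function(shape, spacing) {
  list(x = (seq_len(shape[1]) - 0.5) * spacing[1],
       y = (seq_len(shape[2]) - 0.5) * spacing[2],
       z = (seq_len(shape[3]) - 0.5) * spacing[3])
}

# label map alone (used for lesion placement in the suite sampler)
phantom_labels_array <- function(spec) {
  cc <- voxel_centers_mm(spec$shape, spec$spacing)
  lab <- array(0L, spec$shape)
  for (org in spec$organs) {
    mem <- array(FALSE, spec$shape)
    for (sh in org$shapes) mem <- mem | shape_membership(sh, cc$x, cc$y, cc$z)
    if (any(lab[mem] != 0L))
      stop("overlapping organ geometries: '", org$name, "' intersects label ",
           paste(unique(lab[mem][lab[mem] != 0L]), collapse = ","))
    lab[mem] <- org$label
  }
  lab
}

body_membership <- function(spec) {
  cc <- voxel_centers_mm(spec$shape, spec$spacing)
  ex <- ((cc$x - spec$body$center[1]) / spec$body$radii[1])^2
  ey <- ((cc$y - spec$body$center[2]) / spec$body$radii[2])^2
  outer(outer(ex, ey, "+") < 1, rep(TRUE, spec$shape[3]), "&")
}

#' Generate a phantom
#'
#' Builds the piecewise-constant organ uptake map, paints spherical lesions
#' (uniform interior SUV), applies the liver low-uptake artifact, convolves
#' with the Gaussian PSF, adds variance-scaled Gaussian noise (seeded), and
#' clamps at zero. Ground truth stores each lesion's true mask, center, peak
#' SUV and compartment plus the realized (post blur/noise) SUVmax, and every
#' organ's clean (pre-noise, pre-artifact) mean SUV.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `suv` (`voxel_grid`), `labels` (`voxel_grid`),
#'   and `truth` (list with `lesions` and `organ_clean_means`).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  cc <- voxel_centers_mm(spec$shape, spec$spacing)
  lab <- phantom_labels_array(spec)
  body <- body_membership(spec)

  suv_by_label <- setNames(vapply(spec$organs, `[[`, 0, "suv"),
                           vapply(spec$organs, `[[`, 0L, "label"))
  clean <- array(0, spec$shape)
  clean[body] <- spec$background_suv
  for (org in spec$organs) clean[lab == org$label] <- org$suv

  organ_clean_means <- vapply(spec$organs, function(org)
    mean(clean[lab == org$label]), 0)
  names(organ_clean_means) <- vapply(spec$organs, `[[`, "", "name")

  # lesions: spherical, uniform interior, peak value at center
  bone_ids <- c(unname(BONE_REGIONS), 101:151)
  taken <- array(FALSE, spec$shape)
  lesion_masks <- vector("list", length(spec$lesions))
  for (i in seq_along(spec$lesions)) {
    les <- spec$lesions[[i]]
    ctr_vox <- pmin(pmax(ceiling(les$center / spec$spacing), 1L), spec$shape)
    ctr_lab <- lab[ctr_vox[1], ctr_vox[2], ctr_vox[3]]
    in_body <- body[ctr_vox[1], ctr_vox[2], ctr_vox[3]]
    ok <- switch(les$compartment,
                 bone = ctr_lab %in% bone_ids,
                 prostate = ctr_lab == 7L,
                 lymph = ctr_lab == 0L && in_body)
    if (!ok)
      stop("lesion ", i, " center is outside its '", les$compartment,
           "' compartment (label at center: ", ctr_lab, ")")
    r <- les$diameter / 2
    sph <- shape_membership(
      shape_ellipsoid(les$center, rep(r, 3) + 1e-9), cc$x, cc$y, cc$z)
    if (!any(sph)) stop("lesion ", i, " covers no voxel centers")
    if (any(taken & sph)) stop("lesion masks overlap (lesion ", i, ")")
    taken <- taken | sph
    clean[sph] <- pmax(clean[sph], les$suv)
    lesion_masks[[i]] <- which(sph)
  }

  # breathing artifact: superior cap of the liver at reduced uptake
  art <- spec$liver_artifact
  if (art[1] > 0 && any(lab == 1L)) {
    liv_idx <- which(lab == 1L)
    zi <- ((liv_idx - 1L) %/% (spec$shape[1] * spec$shape[2])) + 1L
    ord <- order(zi, liv_idx, decreasing = TRUE)
    n_art <- floor(art[1] * length(liv_idx))
    sel <- liv_idx[ord[seq_len(n_art)]]
    clean[sel] <- clean[sel] * art[2]
  }

  img <- clean
  if (spec$psf_fwhm > 0) {
    sigma_vox <- (spec$psf_fwhm / 2.354820045) / spec$spacing
    img <- array(cpp_gaussian_blur(as.vector(img), spec$shape, sigma_vox),
                 spec$shape)
  }
  if (spec$noise_factor > 0) {
    set.seed(spec$seed)
    img <- img + rnorm(length(img)) * spec$noise_factor * sqrt(pmax(img, 0))
    img[img < 0] <- 0
  }

  labels <- voxel_grid(lab, spec$spacing, kind = "label")
  suv <- voxel_grid(img, spec$spacing, kind = "suv", frame = labels$frame)

  lesions_truth <- lapply(seq_along(spec$lesions), function(i) {
    les <- spec$lesions[[i]]
    list(id = i, center = les$center, diameter = les$diameter,
         suv = les$suv, compartment = les$compartment,
         mask_idx = lesion_masks[[i]],
         realized_suvmax = max(img[lesion_masks[[i]]]))
  })
  list(suv = suv, labels = labels,
       truth = list(lesions = lesions_truth,
                    organ_clean_means = organ_clean_means,
                    spacing = spec$spacing, shape = spec$shape))
}

#' Ground-truth lesion mask as a binary_mask
#' @param truth `truth` element of [make_phantom()] output.
#' @param i lesion index.
#' @param template `voxel_grid` supplying geometry (the phantom SUV grid).
#' @return `binary_mask`
#' @export
truth_lesion_mask <- function(truth, i, template) {
  arr <- array(FALSE, dim(template$data))
  arr[truth$lesions[[i]]$mask_idx] <- TRUE
  binary_mask(arr, label_name = paste0("truth_lesion_", i), template = template)
}

# ---- multi-patient suite ----------------------------------------------------

#' Across-patient variability model for the phantom suite
#'
#' Per-patient organ uptakes are drawn from normal distributions (truncated
#' at a small positive floor) and lesions are placed at random in their
#' compartments. Defaults emulate a PSMA-avid metastatic population: blood
#' pool ~ N(1.8, 0.2), liver ~ N(6.0, 1.2), lesion peak SUV uniform on
#' (4, 12) and diameters uniform on (8, 20) mm.
#'
#' @param blood_pool,liver,kidneys,bladder,background,bone,prostate
#'   length-2 `(mean, sd)` vectors.
#' @param n_lesions integer vector sampled uniformly for the per-patient
#'   lesion count.
#' @param diameter_mm,lesion_suv length-2 `(min, max)` for uniform draws.
#' @param compartment_probs named probabilities for `bone`, `lymph`,
#'   `prostate` lesion placement (at most one prostate lesion per patient).
#' @return list of class `suite_variability`.
#' @export
suite_variability <- function(blood_pool = c(1.8, 0.2), liver = c(6.0, 1.2),
                              kidneys = c(30, 5), bladder = c(60, 12),
                              background = c(0.8, 0.08), bone = c(1.0, 0.1),
                              prostate = c(1.5, 0.2),
                              n_lesions = 2:6, diameter_mm = c(8, 20),
                              lesion_suv = c(4, 12),
                              compartment_probs = c(bone = 0.45, lymph = 0.45,
                                                    prostate = 0.10)) {
  structure(list(blood_pool = blood_pool, liver = liver, kidneys = kidneys,
                 bladder = bladder, background = background, bone = bone,
                 prostate = prostate, n_lesions = n_lesions,
                 diameter_mm = diameter_mm, lesion_suv = lesion_suv,
                 compartment_probs = compartment_probs),
            class = "suite_variability")
}

rnorm_floor <- function(n, ms, floor) pmax(rnorm(n, ms[1], ms[2]), floor)

# sample lesion centers for one patient; geometry is the fixed default trunk
sample_lesions <- function(n, vb, labels_arr, spec0) {
  bone_ids <- unname(BONE_REGIONS)
  bone_idx <- which(array(labels_arr %in% bone_ids, dim(labels_arr)))
  organs_inflated <- spec0$organs
  placed <- list()
  comps <- sample(names(vb$compartment_probs), n, replace = TRUE,
                  prob = vb$compartment_probs)
  if (sum(comps == "prostate") > 1)
    comps[comps == "prostate"][-1] <- "lymph"
  for (comp in comps) {
    d <- runif(1, vb$diameter_mm[1], vb$diameter_mm[2])
    s <- runif(1, vb$lesion_suv[1], vb$lesion_suv[2])
    ok <- FALSE
    for (try in seq_len(400)) {
      if (comp == "bone") {
        vi <- bone_idx[sample.int(length(bone_idx), 1)]
        ijk <- arrayInd(vi, dim(labels_arr))
        ctr <- (as.numeric(ijk) - 0.5) * spec0$spacing
      } else if (comp == "prostate") {
        d <- min(d, 13)
        repeat {
          off <- runif(3, -1, 1) * 9
          if (sum(off^2) < 81) break
        }
        ctr <- c(192, 190, 118) + off
      } else {  # lymph: soft tissue inside the body, clear of organs
        ctr <- c(runif(1, spec0$body$center[1] - spec0$body$radii[1],
                       spec0$body$center[1] + spec0$body$radii[1]),
                 runif(1, spec0$body$center[2] - spec0$body$radii[2],
                       spec0$body$center[2] + spec0$body$radii[2]),
                 runif(1, 40, spec0$shape[3] * spec0$spacing[3] - 40))
        margin <- d / 2 + 6
        in_body <- ((ctr[1] - spec0$body$center[1]) /
                      (spec0$body$radii[1] - margin))^2 +
                   ((ctr[2] - spec0$body$center[2]) /
                      (spec0$body$radii[2] - margin))^2 < 1
        if (!in_body) next
        clear <- TRUE
        for (org in organs_inflated) {
          for (sh in org$shapes) {
            if (shape_contains_pts(sh, matrix(ctr, 1, 3), inflate = 10)) {
              clear <- FALSE; break
            }
          }
          if (!clear) break
        }
        if (!clear) next
      }
      sep_ok <- TRUE
      for (p in placed)
        if (sqrt(sum((ctr - p$center)^2)) < (d + p$diameter) / 2 + 12) {
          sep_ok <- FALSE; break
        }
      if (!sep_ok) next
      ok <- TRUE
      break
    }
    if (ok)
      placed[[length(placed) + 1]] <- phantom_lesion(ctr, d, s, comp)
  }
  placed
}

#' Generate a reproducible suite of phantom specifications
#'
#' Draws per-patient organ uptakes and lesion configurations from
#' [suite_variability()] distributions. Volumes are not materialised (a
#' 50-patient suite of full volumes would be several GB); call
#' [make_phantom()] on each returned spec, one patient at a time.
#'
#' @param n_patients number of patients (>= 1).
#' @param variability a [suite_variability()].
#' @param seed integer seed; the suite is reproducible from it.
#' @param lesions logical; `FALSE` yields lesion-free phantoms.
#' @return list of `phantom_spec` objects, one per patient.
#' @export
phantom_suite <- function(n_patients, variability = suite_variability(),
                          seed = 1L, lesions = TRUE) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  vb <- variability
  spec0 <- phantom_spec()
  labels_arr <- phantom_labels_array(spec0)
  set.seed(seed)
  out <- vector("list", n_patients)
  for (p in seq_len(n_patients)) {
    uptake <- list(
      blood_pool = rnorm_floor(1, vb$blood_pool, 0.5),
      liver = rnorm_floor(1, vb$liver, 1.5),
      kidneys = rnorm_floor(1, vb$kidneys, 5),
      bladder = rnorm_floor(1, vb$bladder, 10),
      prostate = rnorm_floor(1, vb$prostate, 0.5),
      bone = rnorm_floor(1, vb$bone, 0.3),
      lungs = 0.4)
    bg <- rnorm_floor(1, vb$background, 0.3)
    les <- list()
    if (lesions) {
      n_les <- vb$n_lesions[sample.int(length(vb$n_lesions), 1)]
      les <- sample_lesions(n_les, vb, labels_arr, spec0)
    }
    out[[p]] <- phantom_spec(
      background_suv = bg,
      organs = default_phantom_organs(uptake),
      lesions = les,
      seed = sample.int(.Machine$integer.max, 1))
  }
  out
}

#' Read a phantom specification from JSON
#'
#' Accepts a JSON object with any subset of `shape`, `spacing`,
#' `background_suv`, `uptake` (organ mean-SUV overrides for
#' [default_phantom_organs()]), `lesions` (array of objects with `center`,
#' `diameter`, `suv`, `compartment`), `psf_fwhm`, `noise_factor`,
#' `liver_artifact` and `seed`. Omitted fields keep package defaults; the
#' trunk geometry itself is fixed.
#'
#' @param path JSON file path.
#' @return [phantom_spec()]
#' @export
phantom_spec_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- c("shape", "spacing", "background_suv", "uptake", "lesions",
             "psf_fwhm", "noise_factor", "liver_artifact", "seed")
  extra <- setdiff(names(x), known)
  if (length(extra) > 0)
    stop("unknown phantom field(s): ", paste(extra, collapse = ", "))
  lesions <- list()
  if (!is.null(x$lesions) && NROW(x$lesions) > 0 && length(x$lesions) > 0) {
    ldf <- x$lesions
    lesions <- lapply(seq_len(nrow(ldf)), function(i)
      phantom_lesion(unlist(ldf$center[i]), ldf$diameter[i], ldf$suv[i],
                     ldf$compartment[i]))
  }
  args <- list(organs = default_phantom_organs(as.list(x$uptake)),
               lesions = lesions)
  for (f in c("shape", "spacing", "background_suv", "psf_fwhm",
              "noise_factor", "liver_artifact", "seed"))
    if (!is.null(x[[f]])) args[[f]] <- x[[f]]
  do.call(phantom_spec, args)
}
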