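#' 3D voxel grid with physical geometry
#'
#' Container for a 3D scalar (SUV) or integer (label) volume together with
#' its voxel spacing in mm, a 4x4 voxel-to-world affine, and a frame
#' identifier tying co-registered grids together. Voxel indices are 0-based
#' in world computations; all masks and maps are assumed to live on the PET
#' grid (resampling of externally supplied segmentations is the caller's
#' concern).
#'
#' @param data 3D numeric or integer array.
#' @param spacing length-3 positive numeric, voxel edge lengths in mm.
#' @param affine 4x4 voxel-to-world matrix; default `diag(c(spacing, 1))`.
#' @param kind `"suv"` for scalar uptake grids (negative values are clamped
#'   to 0 with a warning), `"label"` for integer grids (kept exact).
#' @param frame identifier shared by co-registered grids; defaults to a
#'   geometry-derived string.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, spacing, affine = NULL,
                       kind = c("suv", "label"), frame = NULL) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3D array, got ", length(dim(data)), " dimensions")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  affine <- matrix(as.numeric(affine), 4, 4)
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
  nbad <- sum(!is.finite(data))
  if (nbad > 0)
    stop("volume contains ", nbad, " non-finite voxel(s)")
  if (kind == "label") {
    storage.mode(data) <- "integer"
  } else {
    d <- dim(data)
    data <- as.numeric(data)
    dim(data) <- d
    nneg <- sum(data < 0)
    if (nneg > 0) {
      warning("clamped ", nneg, " negative SUV voxel(s) to 0")
      data[data < 0] <- 0
    }
  }
  if (is.null(frame))
    frame <- paste0("g", paste(dim(data), collapse = "x"), "_",
                    paste(signif(spacing, 6), collapse = "x"))
  structure(list(data = data, spacing = spacing, affine = affine,
                 frame = frame, kind = kind),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid %s  %s  spacing %s mm  frame %s>\n",
              x$kind, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"), x$frame))
  invisible(x)
}

#' Check that two grids share a frame (shape, spacing, affine)
#' @param a,b `voxel_grid` objects.
#' @param tol numeric tolerance on spacing/affine entries.
#' @return logical
#' @export
same_frame <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$affine - b$affine) < tol)
}

#' Binary mask on a voxel grid
#'
#' @param grid `voxel_grid` whose data is coercible to 0/1, or a logical
#'   array plus `template` grid supplying the geometry.
#' @param label_name organ or lesion identifier string.
#' @param template optional `voxel_grid` giving geometry when `grid` is a
#'   plain logical/numeric array.
#' @return An object of class `binary_mask` with fields `grid` (label-kind
#'   `voxel_grid` holding 0/1) and `label_name`.
#' @export
binary_mask <- function(grid, label_name = "mask", template = NULL) {
  if (!inherits(grid, "voxel_grid")) {
    stopifnot(inherits(template, "voxel_grid"))
    arr <- array(as.integer(as.logical(grid)), dim(template$data))
    grid <- voxel_grid(arr, template$spacing, template$affine, kind = "label",
                       frame = template$frame)
  } else {
    vals <- unique(as.vector(grid$data))
    if (!all(vals %in% c(0L, 1L, 0, 1, TRUE, FALSE)))
      stop("mask grid must contain only 0/1")
    grid <- voxel_grid(array(as.integer(grid$data != 0), dim(grid$data)),
                       grid$spacing, grid$affine, kind = "label",
                       frame = grid$frame)
  }
  structure(list(grid = grid, label_name = label_name), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask '%s'  %d voxels>\n", x$label_name,
              sum(x$grid$data)))
  invisible(x)
}

mask_array <- function(mask) mask$grid$data != 0L

#' Extract a binary mask for one or more label ids
#' @param labels label-kind `voxel_grid`.
#' @param ids integer label id(s).
#' @param label_name name for the resulting mask.
#' @return `binary_mask`
#' @export
mask_from_label <- function(labels, ids, label_name = paste(ids, collapse = "+")) {
  binary_mask(array(labels$data %in% as.integer(ids), dim(labels$data)),
              label_name = label_name, template = labels)
}

#' Read a NIfTI volume into a voxel grid
#'
#' Scalar (floating point) volumes are treated as SUV and clamped at zero;
#' integer-typed volumes are treated as label maps and preserved exactly.
#'
#' @param path path to a NIfTI-1/2 `.nii`/`.nii.gz` file.
#' @param kind `"auto"` (from on-disk datatype), `"suv"`, or `"label"`.
#' @return `voxel_grid`
#' @export
read_volume <- function(path, kind = c("auto", "suv", "label")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    dim(img) <- d[1:3]
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop("expected 3D volume, got ", length(d), "D")
  hdr <- RNifti::niftiHeader(img)
  int_codes <- c(2L, 4L, 8L, 256L, 512L, 768L, 1024L, 1280L)
  if (kind == "auto")
    kind <- if (hdr$datatype %in% int_codes) "label" else "suv"
  spacing <- abs(hdr$pixdim[2:4])
  affine <- matrix(RNifti::xform(img), 4, 4)
  arr <- array(as.vector(img), d)
  nbad <- sum(!is.finite(arr))
  if (nbad > 0)
    stop("volume contains ", nbad, " non-finite voxel(s): ", path)
  voxel_grid(arr, spacing, affine, kind = kind)
}

#' Write a voxel grid to NIfTI
#'
#' Label grids are written as int32 (bit-exact round trip); SUV grids as
#' float64.
#'
#' @param grid `voxel_grid`.
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!dir.exists(dirname(path)))
    stop("cannot write '", path, "': directory does not exist")
  dt <- if (grid$kind == "label") "int32" else "double"
  img <- RNifti::asNifti(grid$data)
  img <- RNifti::`pixdim<-`(img, grid$spacing)
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Volume of one voxel in millilitres
#' @param spacing length-3 voxel spacing in mm.
#' @return scalar volume in mL (`prod(spacing) / 1000`).
#' @export
voxel_volume_ml <- function(spacing) {
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  prod(spacing) / 1000
}

# ---- label vocabulary -------------------------------------------------------

BONE_REGIONS <- c(femur = 11L, `pelvic region` = 12L,
                  `lumbar vertebrae` = 13L, `thoracic vertebrae` = 14L,
                  thorax = 15L)

#' Organ label vocabulary
#'
#' The package-defined integer label vocabulary: reference organs (liver,
#' thoracic/abdominal aorta), excretory organs (kidneys, urinary bladder),
#' visceral organs (prostate - optional post-prostatectomy - and lungs), the
#' 5 skeletal regions, and a 51-bone list (femurs, hip bones + sacrum, L1-L5,
#' T1-T12, 24 ribs, sternum, clavicles, scapulae) each mapped to exactly one
#' of the 5 regions. Ids are package-defined; the clinical convention only
#' names the organs.
#'
#' @return data.frame with columns `id`, `name`, `compartment`
#'   (`bone`/`visceral`/`reference`/`excretory`), `region`, `region_id`
#'   (`NA` for non-bone labels).
#' @export
label_vocabulary <- function() {
  soft <- data.frame(
    id = 1:9,
    name = c("liver", "aorta_thoracic", "aorta_abdominal", "kidney_left",
             "kidney_right", "urinary_bladder", "prostate", "lung_left",
             "lung_right"),
    compartment = c("reference", "reference", "reference", "excretory",
                    "excretory", "excretory", "visceral", "visceral",
                    "visceral"),
    region = NA_character_, region_id = NA_integer_,
    stringsAsFactors = FALSE)
  regions <- data.frame(
    id = unname(BONE_REGIONS), name = names(BONE_REGIONS),
    compartment = "bone", region = names(BONE_REGIONS),
    region_id = unname(BONE_REGIONS), stringsAsFactors = FALSE)
  bone_names <- c(
    "femur_left", "femur_right",
    "hip_left", "hip_right", "sacrum",
    paste0("vertebra_L", 1:5),
    paste0("vertebra_T", 1:12),
    paste0("rib_left_", 1:12), paste0("rib_right_", 1:12),
    "sternum", "clavicle_left", "clavicle_right",
    "scapula_left", "scapula_right")
  bone_region <- c(rep("femur", 2), rep("pelvic region", 3),
                   rep("lumbar vertebrae", 5), rep("thoracic vertebrae", 12),
                   rep("thorax", 29))
  stopifnot(length(bone_names) == 51L, length(bone_region) == 51L)
  bones <- data.frame(
    id = 100L + seq_len(51L), name = bone_names, compartment = "bone",
    region = bone_region, region_id = unname(BONE_REGIONS[bone_region]),
    stringsAsFactors = FALSE)
  out <- rbind(soft, regions, bones)
  stopifnot(!anyDuplicated(out$id))
  out
}

#' Write / read the label vocabulary as JSON
#' @param path JSON file path.
#' @return `write_label_vocabulary` returns `path` invisibly;
#'   `read_label_vocabulary` returns the vocabulary data.frame.
#' @export
write_label_vocabulary <- function(path) {
  jsonlite::write_json(label_vocabulary(), path, dataframe = "rows",
                       na = "null", auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_label_vocabulary
#' @export
read_label_vocabulary <- function(path) {
  df <- jsonlite::fromJSON(path)
  df$id <- as.integer(df$id)
  df$region_id <- as.integer(df$region_id)
  df
}

#' Collapse individual bone labels to the 5 skeletal regions
#'
#' Each bone voxel is relabelled to its region id; region-level bone ids and
#' visceral/reference/excretory labels pass through unchanged, so the total
#' labelled voxel count is conserved.
#'
#' @param labels label-kind `voxel_grid`.
#' @param vocab vocabulary data.frame, default [label_vocabulary()].
#' @return relabelled `voxel_grid`.
#' @export
group_bones <- function(labels, vocab = label_vocabulary()) {
  stopifnot(inherits(labels, "voxel_grid"), labels$kind == "label")
  ids <- sort(unique(as.vector(labels$data)))
  ids <- ids[ids != 0L]
  unknown <- setdiff(ids, vocab$id)
  if (length(unknown) > 0)
    stop("unknown label id(s): ", paste(unknown, collapse = ", "))
  out <- labels$data
  bone <- vocab[vocab$compartment == "bone" & vocab$id %in% ids, ]
  for (i in seq_len(nrow(bone)))
    if (bone$id[i] != bone$region_id[i])
      out[labels$data == bone$id[i]] <- bone$region_id[i]
  voxel_grid(out, labels$spacing, labels$affine, kind = "label",
             frame = labels$frame)
}

# SUV values within a mask
suv_in_mask <- function(suv, mask) {
  stopifnot(inherits(suv, "voxel_grid"))
  if (!same_frame(suv, mask$grid)) stop("mask and SUV grid frames differ")
  as.vector(suv$data[mask_array(mask)])
}

#' Label 26-connected components of a mask
#' @param mask `binary_mask` or logical array.
#' @param template `voxel_grid` geometry when `mask` is a plain array.
#' @return integer array of component labels (0 = background), components
#'   numbered in deterministic raster-scan order.
#' @export
label_components <- function(mask, template = NULL) {
  if (inherits(mask, "binary_mask")) {
    arr <- mask_array(mask)
  } else arr <- mask != 0
  d <- dim(arr)
  lab <- cpp_label_components(as.vector(arr), as.integer(d))
  array(lab, d)
}
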