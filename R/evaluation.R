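# Agreement and detection-performance statistics: Dice overlap, lesion
# matching against ground truth, sensitivity with Wilson intervals, Pearson
# correlation with Fisher-z intervals, per-method SD, and intraclass
# correlation ICC(2,1).

#' Dice overlap of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`. Two empty masks are defined to agree
#' perfectly (Dice 1, with a warning): agreement on absence.
#'
#' @param A,B `binary_mask` objects on the same frame.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(A, B) {
  a <- mask_array(A); b <- mask_array(B)
  if (!identical(dim(a), dim(b))) stop("mask shape mismatch")
  na <- sum(a); nb <- sum(b)
  if (na == 0 && nb == 0) {
    warning("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(a & b) / (na + nb)
}

#' Match detected lesions against ground truth
#'
#' Greedy one-to-one matching in order of descending detection response.
#' A detection matches an unmatched truth lesion when the truth center lies
#' inside the detected mask, or the centroid distance is at most
#' `max(true radius, max_dist_mm)`; among eligible truth lesions the nearest
#' is taken. The criterion is a package definition (the clinical reference
#' standard was human review) and is configurable.
#'
#' @param truth `truth` element of [make_phantom()] output (or any list with
#'   `lesions` carrying `center`, `diameter`, and optionally `mask_idx`).
#' @param detections list of lesion records, each with `centroid_mm`,
#'   `mask_idx` (optional) and `candidate$response`.
#' @param dims grid dimensions (needed to test center-inside-mask).
#' @param max_dist_mm distance floor of the criterion, default 10.
#' @return list of class `match_result`: `pairs` (data.frame
#'   `truth_id`, `detection_id`, `dist_mm`), `missed_truth`,
#'   `false_positives`, `criterion`.
#' @export
match_lesions <- function(truth, detections, dims = NULL, max_dist_mm = 10) {
  n_truth <- length(truth$lesions)
  resp <- vapply(detections, function(d) {
    r <- d$candidate$response
    if (is.null(r) || !is.finite(r)) 0 else r
  }, 0)
  ord <- order(-resp)
  matched_truth <- rep(FALSE, n_truth)
  pairs <- data.frame(truth_id = integer(), detection_id = integer(),
                      dist_mm = numeric())
  fp <- integer()
  for (di in ord) {
    det <- detections[[di]]
    best <- NA_integer_
    best_d <- Inf
    for (ti in seq_len(n_truth)) {
      if (matched_truth[ti]) next
      les <- truth$lesions[[ti]]
      dmm <- sqrt(sum((les$center - det$centroid_mm)^2))
      inside <- FALSE
      if (!is.null(det$mask_idx) && !is.null(dims)) {
        cv <- pmin(pmax(ceiling(les$center /
                                  (truth$spacing %||% det$spacing)), 1L), dims)
        lin <- (cv[3] - 1) * dims[1] * dims[2] + (cv[2] - 1) * dims[1] + cv[1]
        inside <- lin %in% det$mask_idx
      }
      ok <- inside || dmm <= max(les$diameter / 2, max_dist_mm)
      if (ok && dmm < best_d) {
        best <- ti
        best_d <- dmm
      }
    }
    if (is.na(best)) {
      fp <- c(fp, di)
    } else {
      matched_truth[best] <- TRUE
      pairs <- rbind(pairs, data.frame(truth_id = best, detection_id = di,
                                       dist_mm = best_d))
    }
  }
  structure(list(pairs = pairs, missed_truth = which(!matched_truth),
                 false_positives = fp,
                 criterion = sprintf("center-in-mask | dist <= max(r, %g mm)",
                                     max_dist_mm)),
            class = "match_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detection sensitivity with Wilson 95% CI
#'
#' Percent of truth lesions matched, with the Wilson score interval.
#'
#' @param match a `match_result`, or a length-2 vector `c(matched, total)`.
#' @return list: `sensitivity_pct`, `ci_pct` (length 2), `matched`, `total`.
#' @export
sensitivity <- function(match) {
  if (inherits(match, "match_result")) {
    matched <- nrow(match$pairs)
    total <- matched + length(match$missed_truth)
  } else {
    matched <- match[1]
    total <- match[2]
  }
  if (total < 1) stop("no truth lesions to evaluate")
  ci <- suppressWarnings(
    prop.test(matched, total, correct = FALSE)$conf.int)
  list(sensitivity_pct = 100 * matched / total,
       ci_pct = 100 * as.numeric(ci), matched = matched, total = total)
}

#' Pearson correlation with Fisher-z 95% CI
#' @param x,y numeric vectors (length >= 3, nonzero variance).
#' @return list: `r`, `ci` (length 2), `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need paired vectors of length >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input")
  ct <- cor.test(x, y, method = "pearson", conf.level = 0.95)
  list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int), n = length(x))
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement
#' (Shrout-Fleiss convention):
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`
#' from the two-way ANOVA mean squares of an `n` subjects x `k` raters
#' matrix.
#'
#' @param ratings complete numeric matrix, subjects in rows, raters in
#'   columns (`n >= 2`, `k >= 2`).
#' @return scalar ICC estimate.
#' @export
icc2 <- function(ratings) {
  m <- as.matrix(ratings)
  if (anyNA(m)) stop("ratings matrix has missing cells")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters")
  gm <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sst <- sum((m - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (abs(denom) < 1e-300) return(NaN)
  (msr - mse) / denom
}

#' Sample SD of reference values per method
#'
#' Across-patient standard deviation (n-1 denominator) for each
#' quantification method, the shape used to compare automated against
#' manual-reader consistency.
#'
#' @param values numeric matrix or data.frame, patients in rows, methods in
#'   columns.
#' @return named numeric vector of SDs.
#' @export
reference_sd <- function(values) {
  m <- as.matrix(values)
  if (nrow(m) < 2) stop("need at least 2 patients")
  apply(m, 2, sd)
}

#' Assemble, write and re-read an agreement report
#'
#' Aggregates evaluation components into a versioned report that serialises
#' losslessly to JSON and flattens to CSV (one row per metric/group).
#'
#' @param dice_per_region named numeric vector (optional).
#' @param sensitivity named list of [sensitivity()] results (optional).
#' @param fp_per_patient numeric scalar (optional).
#' @param pearson named list of [pearson()] results (optional).
#' @param sd_per_method named numeric vector (optional).
#' @param icc named numeric vector of ICC(2,1) values (optional).
#' @return list of class `agreement_report`.
#' @export
make_report <- function(dice_per_region = NULL, sensitivity = NULL,
                        fp_per_patient = NULL, pearson = NULL,
                        sd_per_method = NULL, icc = NULL) {
  structure(list(schema_version = "1.0",
                 dice_per_region = dice_per_region,
                 sensitivity = sensitivity,
                 fp_per_patient = fp_per_patient,
                 pearson = pearson,
                 sd_per_method = sd_per_method,
                 icc = icc),
            class = "agreement_report")
}

#' @rdname make_report
#' @param report an `agreement_report`.
#' @param json_path,csv_path output paths (either may be `NULL`).
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    out <- unclass(report)
    for (f in c("dice_per_region", "sd_per_method", "icc"))
      if (!is.null(out[[f]])) out[[f]] <- as.list(out[[f]])
    jsonlite::write_json(out, json_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  if (!is.null(csv_path)) {
    rows <- report_rows(report)
    write.csv(rows, csv_path, row.names = FALSE)
  }
  invisible(report)
}

report_rows <- function(report) {
  rows <- list()
  add <- function(metric, group, value, lo = NA, hi = NA)
    rows[[length(rows) + 1]] <<- data.frame(metric = metric, group = group,
                                            value = value, lo = lo, hi = hi)
  for (nm in names(report$dice_per_region))
    add("dice", nm, report$dice_per_region[[nm]])
  for (nm in names(report$sensitivity)) {
    s <- report$sensitivity[[nm]]
    add("sensitivity_pct", nm, s$sensitivity_pct, s$ci_pct[1], s$ci_pct[2])
  }
  if (!is.null(report$fp_per_patient))
    add("fp_per_patient", "all", report$fp_per_patient)
  for (nm in names(report$pearson)) {
    p <- report$pearson[[nm]]
    add("pearson_r", nm, p$r, p$ci[1], p$ci[2])
  }
  for (nm in names(report$sd_per_method))
    add("sd", nm, report$sd_per_method[[nm]])
  for (nm in names(report$icc))
    add("icc2", nm, report$icc[[nm]])
  if (length(rows) == 0)
    return(data.frame(metric = character(), group = character(),
                      value = numeric(), lo = numeric(), hi = numeric()))
  do.call(rbind, rows)
}

#' @rdname make_report
#' @export
read_report <- function(json_path) {
  x <- jsonlite::fromJSON(json_path, simplifyDataFrame = FALSE)
  structure(x, class = "agreement_report")
}
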