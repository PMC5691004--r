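# Image-quality metrics: per-ROI mean/std CT numbers, mean CT-number
# error against a ground-truth volume (with error-propagated standard
# deviation), and spatial nonuniformity (SNU) over a set of ROIs:
#   SNU = (max ROI mean - min ROI mean) / 1000 x 100%.
# The SNU error is SNU(test) - SNU(reference); a reference (planning CT)
# is needed because the true SNU of an anatomy is generally not zero.

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Mean and standard deviation of an ROI
#'
#' @param volume a [ct_volume()] in HU.
#' @param roi a [roi_box()] inside the volume.
#' @return named numeric: `mean` and `sd` (population standard deviation)
#'   in HU.
#' @export
roi_stats <- function(volume, roi) {
  v <- roi_values(volume, roi)
  c(mean = mean(v), sd = pop_sd(v))
}

check_same_geometry <- function(test, ref) {
  if (!identical(dim(test$values), dim(ref$values)))
    stop("test and reference volume shapes differ: ",
         paste(dim(test$values), collapse = "x"), " vs ",
         paste(dim(ref$values), collapse = "x"), call. = FALSE)
  if (max(abs(test$spacing - ref$spacing)) > 1e-6)
    stop("test and reference voxel spacings differ", call. = FALSE)
}

#' Mean CT-number error of an ROI
#'
#' The error is `reference mean - test mean`; the associated standard
#' deviation is propagated as `sqrt(sd_test^2 + sd_ref^2)`.
#'
#' @param test,ref [ct_volume()]s in HU on the same grid.
#' @param roi a [roi_box()].
#' @return named numeric: `error` and `sd` in HU.
#' @export
ct_error <- function(test, ref, roi) {
  check_same_geometry(test, ref)
  st <- roi_stats(test, roi)
  sr <- roi_stats(ref, roi)
  c(error = unname(sr["mean"] - st["mean"]),
    sd = unname(sqrt(st["sd"]^2 + sr["sd"]^2)))
}

#' Spatial nonuniformity over a set of ROIs
#'
#' @param volume a [ct_volume()] in HU.
#' @param rois list of at least two [roi_box()]es.
#' @return SNU in percent (always >= 0).
#' @export
snu <- function(volume, rois) {
  if (length(rois) < 2L)
    stop("SNU needs at least two ROIs", call. = FALSE)
  means <- vapply(rois, function(r) roi_stats(volume, r)["mean"], 0)
  (max(means) - min(means)) / 1000 * 100
}

#' SNU error of a test volume against a reference
#'
#' `snu(test) - snu(ref)`; signed (negative means the test volume is more
#' uniform than the reference).
#'
#' @inheritParams ct_error
#' @param rois list of at least two [roi_box()]es.
#' @return SNU error in percent.
#' @export
snu_error <- function(test, ref, rois) {
  check_same_geometry(test, ref)
  snu(test, rois) - snu(ref, rois)
}

#' Full metrics report for a test volume against a reference
#'
#' @inheritParams snu_error
#' @return an object of class `metrics_report`: data frame `per_roi`
#'   (label, test/ref mean and sd, error, propagated sd) plus fields
#'   `snu_test`, `snu_ref`, `snu_error` (percent).
#' @export
evaluate_volumes <- function(test, ref, rois) {
  check_same_geometry(test, ref)
  per_roi <- do.call(rbind, lapply(rois, function(r) {
    st <- roi_stats(test, r)
    sr <- roi_stats(ref, r)
    data.frame(label = r$label,
               test_mean = st["mean"], test_sd = st["sd"],
               ref_mean = sr["mean"], ref_sd = sr["sd"],
               error = sr["mean"] - st["mean"],
               error_sd = sqrt(st["sd"]^2 + sr["sd"]^2),
               row.names = NULL)
  }))
  structure(list(per_roi = per_roi,
                 snu_test = snu(test, rois),
                 snu_ref = snu(ref, rois),
                 snu_error = snu(test, rois) - snu(ref, rois)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  print(x$per_roi, digits = 4)
  cat(sprintf("SNU test %.2f%%  ref %.2f%%  error %.2f%%\n",
              x$snu_test, x$snu_ref, x$snu_error))
  invisible(x)
}

#' Write a metrics report as structured text
#'
#' One tab-separated record per ROI followed by the volume-level SNU
#' fields as `key<TAB>value` lines.
#'
#' @param report a `metrics_report`.
#' @param path output path.
#' @export
write_metrics_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(format(report$per_roi, digits = 8), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(sprintf("snu_test\t%.6f", report$snu_test), con)
  writeLines(sprintf("snu_ref\t%.6f", report$snu_ref), con)
  writeLines(sprintf("snu_error\t%.6f", report$snu_error), con)
  invisible(path)
}
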