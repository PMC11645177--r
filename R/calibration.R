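# Linear calibration of R2* against iron concentration, fitted on per-vial
# ROI means, and its inversion to concentration maps. ROI statistics follow
# the mean +/- SD (n), SE = SD/sqrt(n) reporting convention.

#' Linear R2*-vs-concentration calibration model
#'
#' `R2* = slope * cFe + intercept`, with `cFe` in ug/mL and rates in s^-1.
#'
#' @param slope s^-1 per (ug/mL); non-zero for an invertible model.
#' @param intercept s^-1 (the carrier-medium rate at zero iron).
#' @param r_squared coefficient of determination in `[0, 1]` (`NA` for a
#'   model stated rather than fitted).
#' @param n_points number of calibration points (`NA` when stated).
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(slope, intercept, r_squared = NA_real_,
                              n_points = NA_integer_) {
  if (!is.finite(slope)) stop("slope must be finite", call. = FALSE)
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop("r_squared must lie in [0, 1]", call. = FALSE)
  }
  if (!is.na(n_points) && n_points < 2) {
    stop("a fitted model needs n_points >= 2", call. = FALSE)
  }
  structure(
    list(slope = slope, intercept = intercept,
         r_squared = r_squared, n_points = as.integer(n_points)),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> R2* = %.4g x cFe + %.4g", x$slope, x$intercept))
  if (!is.na(x$r_squared)) cat(sprintf("  (R^2 = %.4f, n = %d)", x$r_squared, x$n_points))
  cat("\n")
  invisible(x)
}

#' ROI summary statistics
#'
#' Mean, population SD (divisor n), pixel count and SE = SD/sqrt(n) over the
#' valid voxels of a region. For a [relaxation_map()] input, invalid voxels
#' are excluded; for a plain array, non-finite voxels are excluded.
#'
#' @param x a [relaxation_map()] or a numeric array.
#' @param mask logical array on the same grid.
#' @return An object of class `roi_summary` with fields `mean`, `sd`, `n`,
#'   `se`.
#' @export
roi_stats <- function(x, mask) {
  if (inherits(x, "relaxation_map")) {
    values <- x$values
    usable <- x$valid
  } else {
    values <- x
    usable <- is.finite(x)
  }
  if (!identical(dim(values), dim(mask))) {
    stop("mask grid does not match the field", call. = FALSE)
  }
  v <- values[mask & usable]
  n <- length(v)
  if (n == 0) stop("no valid voxel inside the ROI", call. = FALSE)
  mu <- mean(v)
  sd_pop <- sqrt(sum((v - mu)^2) / n)
  structure(
    list(mean = mu, sd = sd_pop, n = n, se = sd_pop / sqrt(n)),
    class = "roi_summary"
  )
}

#' @export
print.roi_summary <- function(x, ...) {
  cat(sprintf("<roi_summary> %.4g +/- %.4g (n = %d), SE = %.4g\n",
              x$mean, x$sd, x$n, x$se))
  invisible(x)
}

#' Fit the linear calibration from per-vial points
#'
#' Ordinary least squares of mean R2* on iron concentration. Calibration is
#' fitted on per-vial ROI means, not pooled voxels, mirroring how calibration
#' tables tabulate phantom data.
#'
#' @param cfe iron concentrations (ug/mL), at least 2 distinct values.
#' @param mean_r2star per-vial mean R2* (s^-1), same length.
#' @return A [calibration_model()] with `r_squared` and `n_points` filled in.
#' @export
#' @examples
#' fit_calibration(c(0, 10, 20), c(88, 188, 288)) # slope 10, intercept 88
fit_calibration <- function(cfe, mean_r2star) {
  if (length(cfe) != length(mean_r2star) || length(cfe) < 2) {
    stop("need >= 2 (cfe, mean R2*) pairs", call. = FALSE)
  }
  if (length(unique(cfe)) < 2) {
    stop("all concentrations identical; calibration is not identifiable",
         call. = FALSE)
  }
  fit <- stats::lm(mean_r2star ~ cfe)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((mean_r2star - mean(mean_r2star))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  calibration_model(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = max(0, min(1, r2)),
    n_points = length(cfe)
  )
}

#' Invert a calibration to iron concentration
#'
#' Without a baseline, `cFe = (R2* - intercept)/slope` (the phantom mode:
#' the intercept is the carrier-medium rate). With a per-voxel or scalar
#' baseline, `cFe = (R2* - baseline R2*)/slope` (the in vivo mode: tissue
#' baseline R2* replaces the intercept). Negative concentrations are
#' retained -- they are informative about the noise floor -- and counted in
#' the `n_negative` attribute; set `clip_negative = TRUE` to clamp to 0.
#'
#' @param r2star numeric scalar/array of rates (s^-1), or a
#'   [relaxation_map()] (invalid voxels propagate as `NA`).
#' @param calib a [calibration_model()] with non-zero slope.
#' @param baseline_r2star optional scalar or array baseline (s^-1).
#' @param clip_negative clamp negative concentrations to 0 (default `FALSE`).
#' @return Concentration in ug/mL with the same shape as the input, with
#'   attribute `n_negative` (count before any clipping).
#' @export
concentration_from_r2star <- function(r2star, calib, baseline_r2star = NULL,
                                      clip_negative = FALSE) {
  stopifnot(inherits(calib, "calibration_model"))
  if (calib$slope == 0) stop("calibration slope is 0; not invertible", call. = FALSE)
  values <- if (inherits(r2star, "relaxation_map")) {
    v <- r2star$values
    v[!r2star$valid] <- NA_real_
    v
  } else {
    r2star
  }
  ref <- if (is.null(baseline_r2star)) calib$intercept else baseline_r2star
  conc <- (values - ref) / calib$slope
  n_neg <- sum(conc < 0, na.rm = TRUE)
  if (clip_negative) conc <- pmax(conc, 0)
  attr(conc, "n_negative") <- n_neg
  conc
}

#' Serialize / restore a calibration model as JSON
#'
#' @param calib a [calibration_model()].
#' @param path JSON file path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` returns a [calibration_model()].
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "calibration_model"))
  jsonlite::write_json(unclass(calib), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_model(
    slope = x$slope, intercept = x$intercept,
    r_squared = if (is.null(x$r_squared)) NA_real_ else x$r_squared,
    n_points = if (is.null(x$n_points)) NA_integer_ else x$n_points
  )
}

#' Per-vial calibration points from a phantom R2* map
#'
#' Summarizes each vial ROI of a fitted phantom map and pairs the per-vial
#' mean rates with the vial iron concentrations. Vials whose ROI holds no
#' valid voxel are dropped (with a warning) rather than poisoning the fit.
#'
#' @param map a [relaxation_map()] of the phantom.
#' @param vial_layout integer label array (0 background, 1..n vials).
#' @param cfe iron concentration (ug/mL) per vial label.
#' @return A data.frame with columns `vial`, `cfe`, `mean`, `sd`, `n`, `se`.
#' @export
vial_calibration_points <- function(map, vial_layout, cfe) {
  n_vials <- length(cfe)
  rows <- lapply(seq_len(n_vials), function(v) {
    mask <- vial_layout == v
    st <- tryCatch(roi_stats(map, mask), error = function(e) NULL)
    if (is.null(st)) return(NULL)
    data.frame(vial = v, cfe = cfe[v], mean = st$mean, sd = st$sd,
               n = st$n, se = st$se)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0) {
    warning(dropped, " vial(s) had no valid voxel and were dropped",
            call. = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) < 2) {
    stop("fewer than 2 vials produced valid statistics", call. = FALSE)
  }
  out
}
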