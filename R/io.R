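# On-disk interchange: NIfTI-1 volumes with JSON sidecars for images and
# maps, delimited text for calibration tables and reports.

params_to_list <- function(params) {
  p <- unclass(params)
  p[!vapply(p, is.null, logical(1))]
}

params_from_list <- function(p) {
  acquisition_params(
    echo_times = p$echo_times, repetition_time = p$repetition_time,
    flip_angle = if (is.null(p$flip_angle)) NA_real_ else p$flip_angle,
    field_of_view = p$field_of_view, matrix_size = p$matrix_size,
    slice_thickness = p$slice_thickness, n_slices = p$n_slices,
    bandwidth_per_pixel = if (is.null(p$bandwidth_per_pixel)) NA_real_ else p$bandwidth_per_pixel,
    kind = p$kind, name = p$name
  )
}

#' Write a multi-echo image as NIfTI volumes with a JSON sidecar
#'
#' Writes one 3D volume per echo (`<prefix>_echo<i>.nii.gz`), a 4D variant
#' (`<prefix>_4d.nii.gz`, echo along the 4th dimension) and a JSON sidecar
#' (`<prefix>.json`) holding the acquisition parameters and frame time.
#'
#' @param image a [multi_echo_image()].
#' @param prefix output path prefix (directories must exist).
#' @return Character vector of the files written, invisibly.
#' @export
write_multi_echo_image <- function(image, prefix) {
  stopifnot(inherits(image, "multi_echo_image"))
  vx <- voxel_sizes(image$params)
  n_echo <- dim(image$data)[4]
  files <- character(0)
  for (e in seq_len(n_echo)) {
    f <- sprintf("%s_echo%d.nii.gz", prefix, e)
    vol <- image$data[, , , e, drop = FALSE]
    dim(vol) <- dim(image$data)[1:3]
    write_nifti(vol, f, pixdim = vx,
                description = sprintf("TE=%gms", image$params$echo_times[e]))
    files <- c(files, f)
  }
  f4 <- sprintf("%s_4d.nii.gz", prefix)
  write_nifti(image$data, f4, pixdim = c(vx, 1))
  sidecar <- sprintf("%s.json", prefix)
  jsonlite::write_json(
    list(acquisition = params_to_list(image$params),
         frame_time_min = image$frame_time),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null", na = "null",
    pretty = TRUE
  )
  invisible(c(files, f4, sidecar))
}

#' Read a multi-echo image written by [write_multi_echo_image()]
#'
#' @param prefix the path prefix used at write time.
#' @return A [multi_echo_image()].
#' @export
read_multi_echo_image <- function(prefix) {
  sidecar <- sprintf("%s.json", prefix)
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  params <- params_from_list(meta$acquisition)
  vol <- read_nifti(sprintf("%s_4d.nii.gz", prefix))
  multi_echo_image(vol$data, params,
                   frame_time = if (is.null(meta$frame_time_min)) NULL
                                else meta$frame_time_min)
}

#' Write a relaxation map (values + validity mask + provenance)
#'
#' `<prefix>.nii.gz` holds the rates (invalid voxels as NaN),
#' `<prefix>_mask.nii.gz` the validity mask, `<prefix>.json` kind, units and
#' any provenance supplied.
#'
#' @param map a [relaxation_map()].
#' @param prefix output path prefix.
#' @param provenance named list recorded verbatim in the sidecar (e.g.
#'   preset, sigma, SNR threshold).
#' @return Files written, invisibly.
#' @export
write_relaxation_map <- function(map, prefix, provenance = list()) {
  stopifnot(inherits(map, "relaxation_map"))
  vx <- if (is.null(map$params)) c(1, 1, 1) else voxel_sizes(map$params)
  vals <- map$values
  vals[!map$valid] <- NaN
  f_val <- sprintf("%s.nii.gz", prefix)
  f_mask <- sprintf("%s_mask.nii.gz", prefix)
  write_nifti(vals, f_val, pixdim = vx, description = paste(map$kind, "s^-1"))
  write_nifti(map$valid, f_mask, pixdim = vx, datatype = "uint8")
  sidecar <- sprintf("%s.json", prefix)
  jsonlite::write_json(
    c(list(kind = map$kind, units = "s^-1",
           n_valid = sum(map$valid), n_voxels = length(map$valid),
           invalid_reasons = as.list(table(map$reason[!map$valid]))),
      provenance),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(f_val, f_mask, sidecar))
}

#' Write / read a logical mask as NIfTI
#'
#' @param mask logical array.
#' @param path `.nii` / `.nii.gz` path.
#' @return `write_mask()`: `path` invisibly; `read_mask()`: logical array.
#' @export
write_mask <- function(mask, path) {
  write_nifti(mask, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  read_nifti(path)$data > 0
}

#' Read a phantom calibration table
#'
#' Parses a delimited text table with the seven calibration columns: sample
#' number, formulation concentration (mg/mL), iron concentration (ug/mL),
#' mean R2*, SD, pixel count n and SE. Accepts tab-, comma- or
#' whitespace-separated files, with or without a header line; extra
#' whitespace is tolerated. Malformed rows are reported with their line
#' numbers.
#'
#' @param path path to the table. The package ships the 11-vial reference
#'   table as `system.file("extdata", "table1_phantom_calibration.tsv",
#'   package = "ferrokin")`.
#' @return A data.frame with columns `sample`, `c_mg_ml`, `cfe_ug_ml`,
#'   `mean_r2star`, `sd`, `n`, `se`.
#' @export
read_table1 <- function(path) {
  if (!file.exists(path)) stop("calibration table not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(trimws(lines) != "")
  if (length(keep) == 0) stop("calibration table is empty: ", path, call. = FALSE)
  cols <- c("sample", "c_mg_ml", "cfe_ug_ml", "mean_r2star", "sd", "n", "se")
  parse_line <- function(line) {
    fields <- strsplit(trimws(line), "[\t,;]+|[[:space:]]+")[[1]]
    fields <- fields[fields != ""]
    suppressWarnings(as.numeric(fields))
  }
  rows <- list()
  bad <- integer(0)
  for (i in keep) {
    vals <- parse_line(lines[i])
    if (length(vals) == 7 && !anyNA(vals)) {
      rows[[length(rows) + 1]] <- vals
    } else if (i == keep[1] && anyNA(vals)) {
      next  # header line
    } else {
      bad <- c(bad, i)
    }
  }
  if (length(bad) > 0) {
    stop("malformed calibration rows at line(s) ", paste(bad, collapse = ", "),
         " of ", path, call. = FALSE)
  }
  if (length(rows) == 0) stop("no data rows in calibration table: ", path, call. = FALSE)
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- cols
  out$sample <- as.integer(out$sample)
  out$n <- as.integer(out$n)
  out
}

#' Write a time course as CSV and JSON
#'
#' @param tc a [roi_timecourse()].
#' @param prefix output path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @return Files written, invisibly.
#' @export
write_timecourse <- function(tc, prefix) {
  stopifnot(inherits(tc, "roi_timecourse"))
  df <- data.frame(
    roi = tc$roi_name,
    time_min = tc$times,
    conc_ug_ml = tc$concentrations,
    sd = vapply(tc$summaries, `[[`, numeric(1), "sd"),
    n = vapply(tc$summaries, `[[`, numeric(1), "n"),
    se = vapply(tc$summaries, `[[`, numeric(1), "se")
  )
  f_csv <- sprintf("%s.csv", prefix)
  utils::write.csv(df, f_csv, row.names = FALSE)
  f_json <- sprintf("%s.json", prefix)
  jsonlite::write_json(df, f_json, digits = NA, pretty = TRUE)
  invisible(c(f_csv, f_json))
}

#' Plot an ROI time course, or a tumor/normal pair
#'
#' Base-graphics concentration-vs-time plot written as PNG.
#'
#' @param tcs list of [roi_timecourse()] objects to overlay.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
plot_timecourses <- function(tcs, path) {
  grDevices::png(path, width = 800, height = 600)
  on.exit(grDevices::dev.off())
  all_t <- range(unlist(lapply(tcs, `[[`, "times")))
  all_c <- range(unlist(lapply(tcs, `[[`, "concentrations")))
  graphics::plot(NA, xlim = all_t, ylim = all_c,
                 xlab = "time (min)", ylab = "iron concentration (ug/mL)")
  for (i in seq_along(tcs)) {
    graphics::lines(tcs[[i]]$times, tcs[[i]]$concentrations, col = i, lwd = 2)
    graphics::points(tcs[[i]]$times, tcs[[i]]$concentrations, col = i, pch = 16)
  }
  graphics::legend("topright",
                   legend = vapply(tcs, `[[`, character(1), "roi_name"),
                   col = seq_along(tcs), lwd = 2)
  graphics::abline(v = 0, lty = 3)
  invisible(path)
}
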