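#' Acquisition parameters for a multi-echo MRI sequence
#'
#' Container for the sequence geometry and timing that the synthetic
#' generator, the relaxometry fits and the slice resampler need: echo times,
#' repetition time, flip angle, field of view, matrix size, slice geometry
#' and receiver bandwidth. Echo times are stored in milliseconds throughout;
#' relaxation rates are always reported in s^-1, and the ms-to-s conversion
#' happens inside the fitting routines, never at I/O boundaries.
#'
#' @param echo_times numeric vector of echo times (ms), strictly increasing,
#'   all positive. At least one echo.
#' @param repetition_time repetition time TR (ms).
#' @param flip_angle excitation flip angle (degrees). May be `NA` when a
#'   protocol does not document it.
#' @param field_of_view numeric vector of in-plane field of view (mm), length
#'   2, optionally with a third through-plane extent.
#' @param matrix_size integer vector of in-plane voxel counts, length 2.
#' @param slice_thickness slice thickness (mm), > 0.
#' @param n_slices number of slices, >= 1.
#' @param bandwidth_per_pixel receiver bandwidth per pixel (Hz).
#' @param kind relaxation-rate kind measured by this sequence: `"R2*"` for
#'   gradient-echo sequences, `"R2"` for spin-echo.
#' @param name optional preset label carried through provenance records.
#'
#' @return An object of class `acquisition_params`.
#' @seealso [acquisition_preset()] for the named protocol presets.
#' @export
acquisition_params <- function(echo_times,
                               repetition_time,
                               flip_angle = NA_real_,
                               field_of_view,
                               matrix_size,
                               slice_thickness,
                               n_slices,
                               bandwidth_per_pixel = NA_real_,
                               kind = c("R2*", "R2"),
                               name = NULL) {
  kind <- match.arg(kind)
  echo_times <- as.numeric(echo_times)
  if (length(echo_times) < 1 || any(!is.finite(echo_times)) ||
      any(echo_times <= 0)) {
    stop("echo_times must be positive and finite", call. = FALSE)
  }
  if (length(echo_times) > 1 && any(diff(echo_times) <= 0)) {
    stop("echo_times must be strictly increasing", call. = FALSE)
  }
  matrix_size <- as.integer(matrix_size)
  if (length(matrix_size) != 2 || any(matrix_size < 1)) {
    stop("matrix_size must be two voxel counts >= 1", call. = FALSE)
  }
  if (!is.numeric(slice_thickness) || slice_thickness <= 0) {
    stop("slice_thickness must be > 0", call. = FALSE)
  }
  n_slices <- as.integer(n_slices)
  if (n_slices < 1) stop("n_slices must be >= 1", call. = FALSE)
  structure(
    list(
      echo_times = echo_times,
      repetition_time = as.numeric(repetition_time),
      flip_angle = as.numeric(flip_angle),
      field_of_view = as.numeric(field_of_view),
      matrix_size = matrix_size,
      slice_thickness = as.numeric(slice_thickness),
      n_slices = n_slices,
      bandwidth_per_pixel = as.numeric(bandwidth_per_pixel),
      kind = kind,
      name = name
    ),
    class = "acquisition_params"
  )
}

#' Named acquisition presets
#'
#' Four protocols used by the pipeline:
#' \describe{
#'   \item{`spin-echo-T2`}{2D multi-echo spin echo for R2 (=1/T2) mapping:
#'     TR 4000 ms, 10 TEs 15--150 ms in steps of 15 ms, 128 x 128 matrix,
#'     24 slices of 1 mm, 260 Hz/pixel.}
#'   \item{`swi-multiecho`}{multi-echo gradient echo (SWI) for R2* mapping:
#'     TR 35 ms, 5 TEs 5.292--25.292 ms in steps of 5 ms, FA 12 deg,
#'     FOV 32 x 32 x 24 mm, 128 x 128 x 48 matrix, 0.5 mm slices,
#'     253 Hz/pixel.}
#'   \item{`dual-echo-dynamic`}{fast dual-echo 2D gradient echo repeated
#'     dynamically: TR 92 ms, TEs 1.85 and 7.2 ms, FA 12 deg, 192 x 192
#'     matrix, 7 slices of 2 mm, 510 Hz/pixel.}
#'   \item{`phantom-multiecho`}{multi-echo gradient echo used for the vial
#'     phantom: TR 35 ms, 8 TEs 1.6--12.1 ms with 1.5 ms echo spacing,
#'     FOV 50 x 50 x 16 mm, 128 x 128 x 10 matrix, 1.6 mm slices,
#'     1183.7125 Hz/pixel. The protocol's flip angle is not documented and
#'     is stored as `NA`.}
#' }
#'
#' @param name one of `"spin-echo-T2"`, `"swi-multiecho"`,
#'   `"dual-echo-dynamic"`, `"phantom-multiecho"`.
#' @return An [acquisition_params()] object.
#' @export
#' @examples
#' acquisition_preset("dual-echo-dynamic")$echo_times
acquisition_preset <- function(name) {
  switch(
    name,
    "spin-echo-T2" = acquisition_params(
      echo_times = seq(15, 150, by = 15),
      repetition_time = 4000,
      flip_angle = 90,
      field_of_view = c(32, 32, 24),
      matrix_size = c(128, 128),
      slice_thickness = 1,
      n_slices = 24,
      bandwidth_per_pixel = 260,
      kind = "R2",
      name = name
    ),
    "swi-multiecho" = acquisition_params(
      echo_times = seq(5.292, 25.292, by = 5),
      repetition_time = 35,
      flip_angle = 12,
      field_of_view = c(32, 32, 24),
      matrix_size = c(128, 128),
      slice_thickness = 0.5,
      n_slices = 48,
      bandwidth_per_pixel = 253,
      kind = "R2*",
      name = name
    ),
    "dual-echo-dynamic" = acquisition_params(
      echo_times = c(1.85, 7.2),
      repetition_time = 92,
      flip_angle = 12,
      field_of_view = c(32, 32),
      matrix_size = c(192, 192),
      slice_thickness = 2,
      n_slices = 7,
      bandwidth_per_pixel = 510,
      kind = "R2*",
      name = name
    ),
    "phantom-multiecho" = acquisition_params(
      echo_times = seq(1.6, 12.1, by = 1.5),
      repetition_time = 35,
      flip_angle = NA_real_,
      field_of_view = c(50, 50, 16),
      matrix_size = c(128, 128),
      slice_thickness = 1.6,
      n_slices = 10,
      bandwidth_per_pixel = 1183.7125,
      kind = "R2*",
      name = name
    ),
    stop("unknown acquisition preset: ", name, call. = FALSE)
  )
}

#' Rescale the voxel grid of an acquisition
#'
#' Returns a copy of `params` with a different matrix size and slice count,
#' keeping timing, field of view and kind. Used to run scaled-down synthetic
#' studies with the timing of a full protocol.
#'
#' @param params an [acquisition_params()] object.
#' @param dims integer vector `c(nx, ny, nz)`.
#' @return An [acquisition_params()] object.
#' @export
scale_acquisition_grid <- function(params, dims) {
  stopifnot(inherits(params, "acquisition_params"), length(dims) == 3)
  params$matrix_size <- as.integer(dims[1:2])
  params$n_slices <- as.integer(dims[3])
  params
}

#' Voxel-grid dimensions of an acquisition
#'
#' @param params an [acquisition_params()] object.
#' @return Integer vector `c(nx, ny, nz)`.
#' @export
grid_dims <- function(params) {
  c(params$matrix_size, params$n_slices)
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat(sprintf(
    "<acquisition_params%s> %s, %d echoes (%.3f-%.3f ms), TR %.0f ms, grid %s, slice %.2f mm\n",
    if (is.null(x$name)) "" else paste0(": ", x$name),
    x$kind, length(x$echo_times), min(x$echo_times), max(x$echo_times),
    x$repetition_time, paste(grid_dims(x), collapse = "x"),
    x$slice_thickness
  ))
  invisible(x)
}

# Voxel sizes (mm) implied by FOV / matrix; falls back to 1 mm in-plane when
# the FOV is not informative. Used only for NIfTI pixdim metadata.
voxel_sizes <- function(params) {
  fov <- params$field_of_view
  ms <- params$matrix_size
  inplane <- if (length(fov) >= 2 && all(is.finite(fov[1:2]))) {
    fov[1:2] / ms
  } else {
    c(1, 1)
  }
  c(inplane, params$slice_thickness)
}
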