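# Synthetic agarose vial phantom: the forward model of the relaxometry
# stage. Each vial voxel decays mono-exponentially, S(TE) = S0 exp(-R2* TE),
# with R2* set by a generative linear calibration against iron concentration,
# and magnitude (Rician) noise applied per voxel per echo.

#' Convert a dextran formulation concentration to iron concentration
#'
#' The iron-labeled dextran stock carries a fixed iron mass fraction
#' (2.4 mg Fe per 5 mg/mL of formulation, i.e. 0.48). Vial concentrations are
#' stated in mg/mL of formulation; MRI calibrations work in ug/mL of iron.
#'
#' @param c_dextran dextran formulation concentration (mg/mL), >= 0.
#' @param iron_fraction iron mass per formulation mass (dimensionless, in
#'   (0, 1]). Default 0.48, the 2.4/5 stock ratio.
#' @return Iron concentration in ug/mL (`c_dextran * iron_fraction * 1000`).
#' @export
#' @examples
#' dextran_to_iron_concentration(0.02) # 9.6 ug/mL
dextran_to_iron_concentration <- function(c_dextran, iron_fraction = 0.48) {
  if (any(!is.finite(c_dextran)) || any(c_dextran < 0)) {
    stop("dextran concentration must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(iron_fraction) || length(iron_fraction) != 1 ||
      iron_fraction <= 0 || iron_fraction > 1) {
    stop("iron_fraction must be a single value in (0, 1]", call. = FALSE)
  }
  c_dextran * iron_fraction * 1000
}

#' Generative R2* for a given iron concentration
#'
#' Applies a linear calibration forwards: `R2* = slope * cFe + intercept`.
#' This is the generator-side counterpart of [concentration_from_r2star()].
#'
#' @param cfe iron concentration (ug/mL), >= 0 (vectorised).
#' @param calib a [calibration_model()].
#' @return R2* in s^-1.
#' @export
true_r2star_from_concentration <- function(cfe, calib) {
  stopifnot(inherits(calib, "calibration_model"))
  if (any(!is.finite(cfe)) || any(cfe < 0)) {
    stop("iron concentration must be finite and >= 0", call. = FALSE)
  }
  calib$slope * cfe + calib$intercept
}

#' Vial layout of disks on a voxel grid
#'
#' Arranges `n_vials` circular vials (cylinders through all slices) on a
#' regular in-plane grid, mimicking a tube rack seen down the bore. Voxels
#' outside every vial are background (label 0).
#'
#' @param dims integer grid dimensions `c(nx, ny, nz)`.
#' @param n_vials number of vials.
#' @param radius vial radius in voxels; chosen automatically from the grid
#'   when `NULL`.
#' @return Integer array of `dims` with labels `0` (background) and
#'   `1..n_vials`.
#' @export
vial_layout_disks <- function(dims, n_vials, radius = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1), n_vials >= 1)
  n_cols <- ceiling(sqrt(n_vials))
  n_rows <- ceiling(n_vials / n_cols)
  if (is.null(radius)) {
    radius <- max(1, floor(min(dims[1] / n_cols, dims[2] / n_rows) / 2 * 0.6))
  }
  cx <- (seq_len(n_cols) - 0.5) * dims[1] / n_cols
  cy <- (seq_len(n_rows) - 0.5) * dims[2] / n_rows
  labels <- array(0L, dim = dims)
  x <- matrix(seq_len(dims[1]), dims[1], dims[2])
  y <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  for (v in seq_len(n_vials)) {
    row <- (v - 1) %/% n_cols + 1
    col <- (v - 1) %% n_cols + 1
    disk <- (x - cx[col])^2 + (y - cy[row])^2 <= radius^2
    for (z in seq_len(dims[3])) {
      slice <- labels[, , z]
      if (any(slice[disk] != 0L)) stop("vial regions overlap", call. = FALSE)
      slice[disk] <- v
      labels[, , z] <- slice
    }
  }
  labels
}

#' Specification of a synthetic vial phantom
#'
#' @param vial_concentrations dextran concentrations (mg/mL), one per vial.
#'   Default: the 11-vial dilution series 0, 0.02, 0.04, ..., 0.20 mg/mL.
#' @param iron_fraction iron mass fraction of the formulation (default 0.48).
#' @param vial_layout integer label array (`0` background, `1..n` vials) as
#'   produced by [vial_layout_disks()], or `NULL` to build the default layout
#'   on the acquisition grid at generation time.
#' @param base_signal unitless magnitude S0 inside vials (default 1000).
#' @param true_calibration generative [calibration_model()] linking iron
#'   concentration to R2*. Default: slope 10.02 s^-1 per ug/mL, intercept
#'   88.028 s^-1 (agarose background rate).
#' @param noise_sigma Rician noise level in the same unit as `base_signal`
#'   (default 50, i.e. sigma/S0 = 0.05).
#' @param noise_model `"rician"` (magnitude of complex Gaussian; the noise
#'   statistics of magnitude MRI) or `"gaussian"` (additive; intended for
#'   oracle tests only).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(vial_concentrations = seq(0, 0.20, by = 0.02),
                         iron_fraction = 0.48,
                         vial_layout = NULL,
                         base_signal = 1000,
                         true_calibration = calibration_model(10.02, 88.028),
                         noise_sigma = 50,
                         noise_model = c("rician", "gaussian")) {
  noise_model <- match.arg(noise_model)
  if (any(vial_concentrations < 0)) {
    stop("vial concentrations must be >= 0", call. = FALSE)
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (!is.null(vial_layout)) {
    lab <- sort(unique(as.integer(vial_layout)))
    lab <- lab[lab != 0L]
    if (length(lab) > 0 &&
        (max(lab) > length(vial_concentrations) || min(lab) < 1L)) {
      stop("vial_layout labels must index vial_concentrations", call. = FALSE)
    }
  }
  structure(
    list(
      vial_concentrations = as.numeric(vial_concentrations),
      iron_fraction = iron_fraction,
      vial_layout = vial_layout,
      base_signal = base_signal,
      true_calibration = true_calibration,
      noise_sigma = noise_sigma,
      noise_model = noise_model
    ),
    class = "phantom_spec"
  )
}

#' Multi-echo magnitude image container
#'
#' @param data numeric 4D array `(x, y, z, echo)` of magnitudes, all >= 0
#'   (Gaussian-noise simulations may carry negative values; magnitude data
#'   never do).
#' @param params the [acquisition_params()] the image was "acquired" with;
#'   the echo extent of `data` must equal `length(params$echo_times)`.
#' @param frame_time acquisition time stamp in minutes (dynamic studies), or
#'   `NULL`.
#' @return An object of class `multi_echo_image`.
#' @export
multi_echo_image <- function(data, params, frame_time = NULL) {
  stopifnot(inherits(params, "acquisition_params"))
  if (length(dim(data)) != 4) stop("data must be a 4D (x,y,z,echo) array", call. = FALSE)
  if (dim(data)[4] != length(params$echo_times)) {
    stop("echo extent of data must match params$echo_times", call. = FALSE)
  }
  structure(
    list(data = data, params = params, frame_time = frame_time),
    class = "multi_echo_image"
  )
}

#' @export
print.multi_echo_image <- function(x, ...) {
  cat(sprintf(
    "<multi_echo_image> %s grid, %d echoes%s\n",
    paste(dim(x$data)[1:3], collapse = "x"), dim(x$data)[4],
    if (is.null(x$frame_time)) "" else sprintf(", t = %g min", x$frame_time)
  ))
  invisible(x)
}

# Apply magnitude noise to a noiseless signal array. Rician: magnitude of
# the complex signal after adding iid Gaussian noise of sd sigma to both
# quadratures (real channel aligned with the signal).
apply_magnitude_noise <- function(signal, sigma, model = "rician") {
  if (sigma == 0) return(signal)
  n <- length(signal)
  if (model == "rician") {
    sqrt((signal + rnorm(n, sd = sigma))^2 + rnorm(n, sd = sigma)^2)
  } else {
    signal + rnorm(n, sd = sigma)
  }
}

# Evaluate and restore the RNG state around seeded generation so library
# calls do not perturb the caller's random stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a multi-echo phantom image
#'
#' Forward-simulates the vial phantom: every voxel of vial `v` holds
#' `S(TE) = S0 exp(-R2*_v TE)` with `R2*_v` given by the generative
#' calibration at the vial's iron concentration; background voxels have zero
#' underlying signal. Magnitude noise is applied per voxel per echo. The same
#' seed always yields a bit-identical image.
#'
#' @param spec a [phantom_spec()].
#' @param params an [acquisition_params()] with at least 2 echoes (default:
#'   the `phantom-multiecho` preset).
#' @param seed integer seed.
#' @return A [multi_echo_image()]. The generative truth travels along as
#'   attributes: `vial_layout` (label array), `true_r2star` (per-vial rates,
#'   s^-1) and `true_cfe` (per-vial iron concentrations, ug/mL).
#' @export
generate_phantom_image <- function(spec,
                                   params = acquisition_preset("phantom-multiecho"),
                                   seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(params, "acquisition_params"))
  if (length(params$echo_times) < 2) {
    stop("phantom generation needs at least 2 echoes", call. = FALSE)
  }
  layout <- spec$vial_layout
  if (is.null(layout)) {
    layout <- vial_layout_disks(grid_dims(params), length(spec$vial_concentrations))
  }
  dims <- dim(layout)
  cfe <- dextran_to_iron_concentration(spec$vial_concentrations, spec$iron_fraction)
  r2s <- true_r2star_from_concentration(cfe, spec$true_calibration)
  te_s <- params$echo_times / 1000
  n_echo <- length(te_s)
  # per-voxel rate; background (label 0) carries no signal at all
  rate_vox <- array(0, dim = dims)
  in_vial <- layout > 0L
  rate_vox[in_vial] <- r2s[layout[in_vial]]
  s0_vox <- array(0, dim = dims)
  s0_vox[in_vial] <- spec$base_signal
  signal <- array(0, dim = c(dims, n_echo))
  for (e in seq_len(n_echo)) {
    signal[, , , e] <- s0_vox * exp(-rate_vox * te_s[e])
  }
  noisy <- with_seed(seed, apply_magnitude_noise(signal, spec$noise_sigma,
                                                 spec$noise_model))
  img <- multi_echo_image(array(noisy, dim = c(dims, n_echo)), params)
  attr(img, "vial_layout") <- layout
  attr(img, "true_r2star") <- r2s
  attr(img, "true_cfe") <- cfe
  img
}
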