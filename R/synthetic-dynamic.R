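# Synthetic dynamic dual-echo study: nine pre-injection baseline frames
# followed by post-injection frames at stated minutes, with tumor, normal
# tissue and ventricle compartments following configurable iron-concentration
# time courses. Tracer raises the compartment R2* linearly:
# R2*(t) = baseline R2* + slope * c(t).

#' Piecewise-linear tracer concentration curve
#'
#' A concentration time course through anchor points. By construction the
#' curve is 0 at and before injection (t <= 0); beyond the last anchor it
#' holds the last value.
#'
#' @param times anchor times (minutes), strictly increasing, all > 0.
#' @param concentrations iron concentration (ug/mL) at each anchor, >= 0.
#' @return An object of class `tracer_curve`.
#' @export
tracer_curve <- function(times, concentrations) {
  times <- as.numeric(times)
  concentrations <- as.numeric(concentrations)
  if (length(times) != length(concentrations) || length(times) < 1) {
    stop("times and concentrations must be equal-length, non-empty", call. = FALSE)
  }
  if (any(diff(times) <= 0) || any(times <= 0)) {
    stop("anchor times must be positive and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(concentrations)) || any(concentrations < 0)) {
    stop("tracer curve concentrations must be finite and >= 0", call. = FALSE)
  }
  structure(list(times = times, concentrations = concentrations),
            class = "tracer_curve")
}

#' Evaluate a tracer curve
#'
#' @param curve a [tracer_curve()].
#' @param t times in minutes (vectorised).
#' @return Iron concentration (ug/mL); 0 for `t <= 0`.
#' @export
curve_value <- function(curve, t) {
  stopifnot(inherits(curve, "tracer_curve"))
  out <- stats::approx(
    x = c(0, curve$times), y = c(0, curve$concentrations),
    xout = pmax(t, 0), rule = 2
  )$y
  out[t <= 0] <- 0
  out
}

#' Default tumor / normal / ventricle compartment masks
#'
#' Lays out three disjoint compartments on a grid: a ventricle block near the
#' left of the field of view (the injection site), a tumor disk in the right
#' hemisphere and a mirrored contralateral normal-tissue disk. Voxels in no
#' compartment are background (zero signal).
#'
#' @param dims integer grid dimensions `c(nx, ny, nz)`.
#' @return Named list of logical arrays `tumor`, `normal`, `ventricle`.
#' @export
default_compartments <- function(dims) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims[1:2] >= 16), dims[3] >= 1)
  x <- array(rep(seq_len(dims[1]), times = dims[2] * dims[3]), dim = dims)
  y <- array(rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3]), dim = dims)
  r <- max(2, round(min(dims[1:2]) / 6))
  tumor <- (x - round(dims[1] * 0.72))^2 + (y - round(dims[2] * 0.5))^2 <= r^2
  normal <- (x - round(dims[1] * 0.28))^2 + (y - round(dims[2] * 0.5))^2 <= r^2
  ventricle <- abs(x - round(dims[1] * 0.5)) <= max(1, round(dims[1] / 16)) &
    abs(y - round(dims[2] * 0.2)) <= max(1, round(dims[2] / 10))
  if (any(tumor & normal) || any(tumor & ventricle) || any(normal & ventricle)) {
    stop("default compartments overlap on this grid; supply masks explicitly",
         call. = FALSE)
  }
  list(tumor = tumor, normal = normal, ventricle = ventricle)
}

#' Specification of a synthetic dynamic tracer study
#'
#' @param n_baseline_frames number of pre-injection frames (default 9).
#' @param post_injection_times post-injection sampling times in minutes,
#'   strictly increasing (default `c(30, 45, 60, 90, 120)`).
#' @param compartment_masks named list of disjoint logical arrays on a common
#'   grid. Names must match `concentration_curves` / `baseline_r2star`.
#' @param concentration_curves named list of [tracer_curve()] objects (or
#'   `NULL` entries for compartments that never see tracer), one per
#'   compartment.
#' @param baseline_r2star named numeric vector of pre-tracer R2* (s^-1) per
#'   compartment.
#' @param true_calibration generative [calibration_model()] (slope used to
#'   convert concentration to delta-R2*).
#' @param base_signal unitless S0 inside compartments (default 1000).
#' @param noise_sigma magnitude noise level (default 20, sigma/S0 = 0.02).
#' @param noise_model `"rician"` or `"gaussian"`.
#' @param baseline_frame_spacing spacing of the baseline frames in minutes
#'   (default 0.25, the 15 s dynamic repeat); baseline frames get stamps
#'   `-(n-1)*spacing, ..., -spacing, 0` by convention.
#' @param label free-text scenario label carried into reports.
#' @param metadata named list of scenario metadata (e.g. dextran size,
#'   osmolarity); not interpreted by the generator.
#' @return An object of class `dynamic_study_spec`.
#' @export
dynamic_study_spec <- function(n_baseline_frames = 9,
                               post_injection_times = c(30, 45, 60, 90, 120),
                               compartment_masks,
                               concentration_curves,
                               baseline_r2star,
                               true_calibration = calibration_model(10.02, 88.028),
                               base_signal = 1000,
                               noise_sigma = 20,
                               noise_model = c("rician", "gaussian"),
                               baseline_frame_spacing = 0.25,
                               label = "custom",
                               metadata = list()) {
  noise_model <- match.arg(noise_model)
  if (n_baseline_frames < 1) stop("need at least one baseline frame", call. = FALSE)
  if (any(diff(post_injection_times) <= 0) || any(post_injection_times <= 0)) {
    stop("post_injection_times must be positive and strictly increasing",
         call. = FALSE)
  }
  nm <- names(compartment_masks)
  if (is.null(nm) || !all(nm %in% names(baseline_r2star)) ||
      !all(nm %in% names(concentration_curves))) {
    stop("compartment names must be shared by masks, curves and baseline R2*",
         call. = FALSE)
  }
  dims <- dim(compartment_masks[[1]])
  total <- array(0L, dim = dims)
  for (m in compartment_masks) {
    if (!identical(dim(m), dims)) stop("compartment masks must share a grid", call. = FALSE)
    total <- total + m
  }
  if (any(total > 1L)) stop("compartment masks must be disjoint", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  structure(
    list(
      n_baseline_frames = as.integer(n_baseline_frames),
      post_injection_times = as.numeric(post_injection_times),
      compartment_masks = compartment_masks,
      concentration_curves = concentration_curves,
      baseline_r2star = baseline_r2star,
      true_calibration = true_calibration,
      base_signal = base_signal,
      noise_sigma = noise_sigma,
      noise_model = noise_model,
      baseline_frame_spacing = baseline_frame_spacing,
      label = label,
      metadata = metadata
    ),
    class = "dynamic_study_spec"
  )
}

#' Frame time stamps of a dynamic study
#'
#' Baseline frames at `-(n-1)*spacing, ..., 0`; post-injection frames at
#' their stated minutes.
#'
#' @param spec a [dynamic_study_spec()].
#' @return Numeric vector of frame times (minutes), strictly increasing.
#' @export
frame_times <- function(spec) {
  stopifnot(inherits(spec, "dynamic_study_spec"))
  c(
    -rev(seq_len(spec$n_baseline_frames) - 1) * spec$baseline_frame_spacing,
    spec$post_injection_times
  )
}

# Anchor concentrations (ug/mL) at 30/45/60/90/120 min for the six scenario
# presets. Peak tissue concentrations are a few ug/mL so that dual-echo
# signal at TE2 = 7.2 ms stays well above the noise floor, matching the
# operating range a dual-echo protocol with those TEs implies. Shapes encode
# only qualitative behaviour: which stamps are preferential (tumor/normal
# ratio above threshold) and where the tumor peak sits.
GROUP_PRESET_CURVES <- list(
  # 10 kD, 337 mOsm/L: preferential through 90 min, tumor peak at 45 min.
  group1 = list(tumor  = c(4.0, 6.0, 4.5, 2.5, 1.2),
                normal = c(1.5, 2.0, 2.5, 2.0, 1.5)),
  # 5 kD, 337 mOsm/L: preferential for the full two hours, peak 45-60 min.
  group2 = list(tumor  = c(3.5, 5.5, 5.8, 4.5, 3.5),
                normal = c(1.5, 2.0, 2.5, 2.2, 1.8)),
  # 3 kD, 337 mOsm/L: fastest arrival, preferential only to 45 min, peak 30.
  group3 = list(tumor  = c(5.5, 5.0, 2.7, 1.8, 1.0),
                normal = c(2.0, 2.5, 2.8, 2.2, 1.5)),
  # 10 kD, 307 mOsm/L: as group 1 at lower amplitude.
  group4 = list(tumor  = c(3.2, 4.8, 3.6, 2.0, 1.0),
                normal = c(1.2, 1.6, 2.0, 1.6, 1.2)),
  # 10 kD, 353 mOsm/L: as group 1 at slightly higher amplitude.
  group5 = list(tumor  = c(4.4, 6.6, 5.0, 2.8, 1.3),
                normal = c(1.6, 2.2, 2.7, 2.2, 1.6)),
  # 10 kD, 368 mOsm/L: equal distribution, tumor and normal identical.
  group6 = list(tumor  = c(2.5, 3.5, 3.0, 2.5, 2.0),
                normal = c(2.5, 3.5, 3.0, 2.5, 2.0))
)

GROUP_PRESET_METADATA <- list(
  group1 = list(dextran_kd = 10, osmolarity_mosm = 337),
  group2 = list(dextran_kd = 5,  osmolarity_mosm = 337),
  group3 = list(dextran_kd = 3,  osmolarity_mosm = 337),
  group4 = list(dextran_kd = 10, osmolarity_mosm = 307),
  group5 = list(dextran_kd = 10, osmolarity_mosm = 353),
  group6 = list(dextran_kd = 10, osmolarity_mosm = 368)
)

#' Scenario presets for the six experimental groups
#'
#' Returns a ready-to-generate [dynamic_study_spec()] for one of six
#' intraventricular-delivery scenarios. Groups 1-3 vary the dextran size
#' (10/5/3 kD) at 337 mOsm/L; groups 4-6 vary the vehicle osmolarity
#' (307/353/368 mOsm/L) at 10 kD. Qualitative behaviour: groups 1, 4 and 5
#' accumulate preferentially in tumor through 90 min with the tumor peak at
#' 45 min; group 2 stays preferential for the full two hours with its peak in
#' the 45-60 min range; group 3 peaks at 30 min and is preferential only
#' through 45 min; group 6 distributes equally to tumor and normal tissue.
#' Presets differ only in label, metadata and curve shapes.
#'
#' @param name `"group1"` ... `"group6"`.
#' @param dims grid dimensions for the scaled-down study (default
#'   `c(32, 32, 3)`).
#' @param noise_sigma magnitude noise level (default 20 on S0 = 1000).
#' @param base_signal unitless S0 (default 1000).
#' @param concentration_scale multiplies every preset concentration curve
#'   (default 1); useful for scale-equivariance checks.
#' @return A [dynamic_study_spec()].
#' @export
group_preset <- function(name, dims = c(32, 32, 3), noise_sigma = 20,
                         base_signal = 1000, concentration_scale = 1) {
  curves <- GROUP_PRESET_CURVES[[name]]
  if (is.null(curves)) stop("unknown group preset: ", name, call. = FALSE)
  anchors <- c(30, 45, 60, 90, 120)
  masks <- default_compartments(dims)
  dynamic_study_spec(
    n_baseline_frames = 9,
    post_injection_times = anchors,
    compartment_masks = masks,
    concentration_curves = list(
      tumor = tracer_curve(anchors, curves$tumor * concentration_scale),
      normal = tracer_curve(anchors, curves$normal * concentration_scale),
      # the injected ventricle sees an early bolus that washes out
      ventricle = tracer_curve(anchors, c(15, 11, 8, 5, 3) * concentration_scale)
    ),
    baseline_r2star = c(tumor = 30, normal = 20, ventricle = 12),
    base_signal = base_signal,
    noise_sigma = noise_sigma,
    label = name,
    metadata = GROUP_PRESET_METADATA[[name]]
  )
}

#' Generate a dynamic dual-echo study
#'
#' Produces one [multi_echo_image()] per frame. At frame time `t` each
#' compartment decays with `R2*(t) = baseline R2* + slope * c(t)` where `c`
#' is its concentration curve (0 at all baseline frames); voxels outside all
#' compartments carry no signal. Noise streams are derived per frame from
#' the top-level seed, so extending the frame list never reshuffles earlier
#' frames.
#'
#' @param spec a [dynamic_study_spec()].
#' @param params an [acquisition_params()] with >= 2 echoes; defaults to the
#'   `dual-echo-dynamic` preset rescaled to the mask grid.
#' @param seed integer seed.
#' @return List of [multi_echo_image()] frames, each stamped with its time;
#'   the generative truth is attached as attributes `true_concentrations`
#'   (matrix compartment x frame) and `spec`.
#' @export
generate_dynamic_study <- function(spec, params = NULL, seed = 1L) {
  stopifnot(inherits(spec, "dynamic_study_spec"))
  dims <- dim(spec$compartment_masks[[1]])
  if (is.null(params)) {
    params <- scale_acquisition_grid(acquisition_preset("dual-echo-dynamic"), dims)
  }
  if (!identical(grid_dims(params), as.integer(dims))) {
    stop("acquisition grid does not match compartment mask grid", call. = FALSE)
  }
  if (length(params$echo_times) < 2) {
    stop("dynamic generation needs at least 2 echoes", call. = FALSE)
  }
  times <- frame_times(spec)
  n_frames <- length(times)
  comps <- names(spec$compartment_masks)
  conc <- matrix(0, nrow = length(comps), ncol = n_frames,
                 dimnames = list(comps, NULL))
  for (k in comps) {
    cv <- spec$concentration_curves[[k]]
    if (!is.null(cv)) conc[k, ] <- curve_value(cv, times)
  }
  if (any(conc < 0)) stop("concentration curves must be non-negative", call. = FALSE)
  te_s <- params$echo_times / 1000
  n_echo <- length(te_s)
  frame_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_frames))
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    rate <- array(0, dim = dims)
    s0 <- array(0, dim = dims)
    for (k in comps) {
      m <- spec$compartment_masks[[k]]
      rate[m] <- spec$baseline_r2star[[k]] +
        spec$true_calibration$slope * conc[k, f]
      s0[m] <- spec$base_signal
    }
    signal <- array(0, dim = c(dims, n_echo))
    for (e in seq_len(n_echo)) {
      signal[, , , e] <- s0 * exp(-rate * te_s[e])
    }
    noisy <- with_seed(frame_seeds[f],
                       apply_magnitude_noise(signal, spec$noise_sigma,
                                             spec$noise_model))
    frames[[f]] <- multi_echo_image(array(noisy, dim = c(dims, n_echo)),
                                    params, frame_time = times[f])
  }
  attr(frames, "true_concentrations") <- conc
  attr(frames, "spec") <- spec
  frames
}
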