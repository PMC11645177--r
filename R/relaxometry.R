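# Voxelwise relaxation mapping from multi-echo magnitude images.
#
# Two estimators are provided: the dual-echo closed form
# R2* = ln(S(TE1)/S(TE2)) / (TE2 - TE1) used for fast dynamic scans, and a
# per-voxel weighted log-linear exponential fit over the leading echoes whose
# SNR exceeds a threshold (default 3:1). Echo times enter in ms; fitted rates
# always leave in s^-1, and the conversion is centralized here.

#' Voxelwise relaxation-rate map
#'
#' @param values numeric 3D array of rates (s^-1); finite wherever valid.
#' @param s0 fitted signal amplitude array (unitless), same grid.
#' @param valid logical array marking voxels with a usable fit.
#' @param reason character array of per-voxel status codes: `"ok"`,
#'   `"nonpositive_signal"` or `"insufficient_echoes"`. Downstream ROI
#'   statistics exclude invalid voxels rather than absorbing sentinels.
#' @param n_echoes_used integer array of echoes entering each voxel's fit.
#' @param kind `"R2*"` or `"R2"`.
#' @param params [acquisition_params()] that produced the source image.
#' @return An object of class `relaxation_map`.
#' @export
relaxation_map <- function(values, s0, valid, reason, n_echoes_used,
                           kind = c("R2*", "R2"), params = NULL) {
  kind <- match.arg(kind)
  dims <- dim(values)
  stopifnot(
    identical(dim(valid), dims), identical(dim(n_echoes_used), dims),
    identical(dim(s0), dims), identical(dim(reason), dims)
  )
  if (any(valid & !is.finite(values))) {
    stop("valid voxels must carry finite rates", call. = FALSE)
  }
  structure(
    list(values = values, s0 = s0, valid = valid, reason = reason,
         n_echoes_used = n_echoes_used, kind = kind, params = params),
    class = "relaxation_map"
  )
}

#' @export
print.relaxation_map <- function(x, ...) {
  cat(sprintf(
    "<relaxation_map> %s, %s grid, %d/%d voxels valid\n",
    x$kind, paste(dim(x$values), collapse = "x"),
    sum(x$valid), length(x$valid)
  ))
  invisible(x)
}

#' Dual-echo closed-form R2* map
#'
#' Computes `R2* = ln(S(TE1)/S(TE2)) / ((TE2 - TE1)/1000)` per voxel, the
#' exact two-point solution of the mono-exponential decay. Voxels where
#' either echo magnitude is non-positive are marked invalid (reason
#' `"nonpositive_signal"`) instead of raising.
#'
#' @param image a [multi_echo_image()] with at least two echoes.
#' @param te1,te2 the two echo times (ms) to use, `te2 > te1 > 0`; default
#'   the first and last echo of the image. Both must be present in
#'   `image$params$echo_times`.
#' @return A [relaxation_map()] with `n_echoes_used = 2` where valid.
#' @export
dual_echo_r2star <- function(image, te1 = NULL, te2 = NULL) {
  stopifnot(inherits(image, "multi_echo_image"))
  tes <- image$params$echo_times
  if (is.null(te1)) te1 <- tes[1]
  if (is.null(te2)) te2 <- tes[length(tes)]
  if (!(te1 > 0) || !(te2 > te1)) stop("need te2 > te1 > 0", call. = FALSE)
  i1 <- match(te1, tes)
  i2 <- match(te2, tes)
  if (is.na(i1) || is.na(i2)) {
    stop("te1/te2 must be echo times of the image", call. = FALSE)
  }
  s1 <- image$data[, , , i1, drop = FALSE]
  s2 <- image$data[, , , i2, drop = FALSE]
  dims <- dim(image$data)[1:3]
  dim(s1) <- dims
  dim(s2) <- dims
  valid <- s1 > 0 & s2 > 0
  values <- array(NA_real_, dim = dims)
  values[valid] <- log(s1[valid] / s2[valid]) / ((te2 - te1) / 1000)
  s0 <- array(NA_real_, dim = dims)
  # back-extrapolate amplitude to TE = 0 from the first usable echo
  s0[valid] <- s1[valid] * exp(values[valid] * te1 / 1000)
  reason <- array("nonpositive_signal", dim = dims)
  reason[valid] <- "ok"
  n_used <- array(0L, dim = dims)
  n_used[valid] <- 2L
  relaxation_map(values, s0, valid, reason, n_used,
                 kind = image$params$kind, params = image$params)
}

#' Noise-level estimate for magnitude images
#'
#' Either estimated from a signal-free background region -- where the Rician
#' magnitude mean is `sigma * sqrt(pi/2)`, so `sigma = mean / sqrt(pi/2)` --
#' or supplied directly.
#'
#' @param image a [multi_echo_image()] (ignored when `sigma` is supplied).
#' @param background_mask logical array on the image grid marking voxels with
#'   no underlying signal.
#' @param sigma optionally, a known noise level; bypasses estimation.
#' @return An object of class `noise_estimate` with fields `sigma` and
#'   `method` (`"background-roi"` or `"provided"`).
#' @export
estimate_noise_sigma <- function(image = NULL, background_mask = NULL,
                                 sigma = NULL) {
  if (!is.null(sigma)) {
    if (!is.numeric(sigma) || sigma <= 0) {
      stop("provided sigma must be > 0", call. = FALSE)
    }
    return(structure(list(sigma = sigma, method = "provided"),
                     class = "noise_estimate"))
  }
  stopifnot(inherits(image, "multi_echo_image"))
  if (is.null(background_mask) || !any(background_mask)) {
    stop("background mask is empty", call. = FALSE)
  }
  n_echo <- dim(image$data)[4]
  vals <- unlist(lapply(seq_len(n_echo), function(e) {
    v <- image$data[, , , e, drop = FALSE]
    dim(v) <- dim(image$data)[1:3]
    v[background_mask]
  }), use.names = FALSE)
  est <- mean(vals) / sqrt(pi / 2)
  if (!is.finite(est) || est <= 0) {
    stop("background magnitudes give a non-positive sigma (noiseless image?)",
         call. = FALSE)
  }
  structure(list(sigma = est, method = "background-roi"),
            class = "noise_estimate")
}

#' Leading echoes above an SNR threshold
#'
#' Implements the echo-selection rule for multi-echo fitting: keep the
#' longest leading run of echoes whose magnitude exceeds
#' `threshold * sigma`. A return of 0 or 1 makes the voxel unfittable
#' (downstream code marks it invalid); it is not an error here.
#'
#' @param magnitudes per-voxel magnitude decay over echoes.
#' @param sigma noise level, > 0.
#' @param threshold SNR ratio gate (default 3, i.e. the 3:1 rule).
#' @return Integer count of leading echoes kept.
#' @export
#' @examples
#' select_echoes_by_snr(c(900, 500, 200, 90, 40), sigma = 50) # 3
select_echoes_by_snr <- function(magnitudes, sigma, threshold = 3) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  ok <- magnitudes / sigma > threshold
  if (!ok[1] || is.na(ok[1])) return(0L)
  run <- which(!ok | is.na(ok))
  if (length(run) == 0) length(magnitudes) else run[1] - 1L
}

#' Log-linear exponential decay fit
#'
#' Fits `S(TE) = A exp(-rate * TE)` to the first `n_keep` echoes by weighted
#' least squares on `ln S` against TE, with weights `S^2` to undo the
#' variance distortion of the log transform. A second pass re-fits with the
#' first pass's *predicted* magnitudes as weights (`refine_weights`,
#' default on): measured-magnitude weights are correlated with the log-domain
#' noise and bias the fit at modest SNR, predicted weights are not. The
#' refinement is a no-op for two echoes (the fit interpolates regardless of
#' weights) and on noiseless data, where the fit is exact. Echo times in ms;
#' the returned rate is in s^-1.
#'
#' @param echo_times echo times (ms).
#' @param magnitudes magnitudes at each echo.
#' @param n_keep number of leading echoes to fit, >= 2.
#' @param refine_weights refit once with predicted-value weights (default
#'   `TRUE`).
#' @return Named numeric vector `c(rate = , amplitude = )`, or `NA`s when a
#'   kept magnitude is non-positive (the voxel is invalid, not an error).
#' @export
fit_exponential_decay <- function(echo_times, magnitudes,
                                  n_keep = length(magnitudes),
                                  refine_weights = TRUE) {
  if (n_keep < 2) stop("n_keep must be >= 2", call. = FALSE)
  te <- echo_times[seq_len(n_keep)]
  s <- magnitudes[seq_len(n_keep)]
  if (any(!is.finite(s)) || any(s <= 0)) {
    return(c(rate = NA_real_, amplitude = NA_real_))
  }
  wls <- function(w) {
    y <- log(s)
    sw <- sum(w)
    mx <- sum(w * te) / sw
    my <- sum(w * y) / sw
    sxx <- sum(w * (te - mx)^2)
    if (sxx == 0) stop("echo times are degenerate", call. = FALSE)
    slope <- sum(w * (te - mx) * (y - my)) / sxx
    c(slope = slope, intercept = my - slope * mx)
  }
  f <- wls(s^2)
  if (refine_weights && n_keep > 2) {
    pred <- exp(f["intercept"] + f["slope"] * te)
    f <- wls(pred^2)
  }
  c(rate = unname(-f["slope"] * 1000), amplitude = unname(exp(f["intercept"])))
}

#' Multi-echo relaxation map with SNR-gated fitting
#'
#' Per voxel: select the leading echoes with SNR above `threshold` (when a
#' noise estimate is given), then fit a mono-exponential by weighted
#' log-linear least squares. Voxels with fewer than 2 usable echoes are
#' invalid with reason `"insufficient_echoes"`; voxels whose kept magnitudes
#' are non-positive get `"nonpositive_signal"`. Without a noise estimate no
#' gate is applied and all positive-magnitude echoes enter the fit (the
#' noiseless path).
#'
#' Fitting is the two-pass weighted log-linear scheme of
#' [fit_exponential_decay()]. `rician_correction` optionally floor-corrects
#' magnitudes as `sqrt(max(M^2 - 2 sigma^2, 0))` before fitting; it is off by
#' default because the log of a Rician magnitude is already nearly unbiased
#' (its second-moment inflation and the log's concavity cancel to second
#' order in sigma/A), and correcting in the magnitude domain overshoots in
#' the log domain.
#'
#' Echo selection is per voxel by default. When `gate_regions` is given (an
#' integer label array, e.g. the vial layout), the gate is instead applied to
#' each region's mean magnitude decay and the resulting echo count is shared
#' by all voxels of the region; voxels with label 0 keep per-voxel gating.
#' Region gating is how a vial phantom is processed -- gating each voxel on
#' its own noisy magnitudes preferentially keeps voxels whose late echoes
#' fluctuated high, which biases fitted rates low near the gate.
#'
#' @param image a [multi_echo_image()] with >= 2 echoes.
#' @param noise a [estimate_noise_sigma()] result, or `NULL` for no gating.
#' @param threshold SNR gate (default 3).
#' @param kind override the rate kind; defaults to the acquisition's.
#' @param rician_correction logical; see above.
#' @param gate_regions optional integer label array for region-level gating.
#' @return A [relaxation_map()].
#' @export
multi_echo_map <- function(image, noise = NULL, threshold = 3, kind = NULL,
                           rician_correction = FALSE,
                           gate_regions = NULL) {
  stopifnot(inherits(image, "multi_echo_image"))
  dims <- dim(image$data)[1:3]
  n_echo <- dim(image$data)[4]
  if (n_echo < 2) stop("need at least 2 echoes", call. = FALSE)
  if (is.null(kind)) kind <- image$params$kind
  te <- image$params$echo_times
  n_vox <- prod(dims)
  m <- matrix(image$data, nrow = n_vox, ncol = n_echo)

  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_estimate"))
    sigma <- noise$sigma
    ok <- m > threshold * sigma
    run <- ok[, 1]
    n_keep <- as.integer(run)
    for (j in seq_len(n_echo)[-1]) {
      run <- run & ok[, j]
      n_keep <- n_keep + run
    }
    if (!is.null(gate_regions)) {
      if (!identical(dim(gate_regions), dims)) {
        stop("gate_regions grid mismatch", call. = FALSE)
      }
      lab <- as.integer(gate_regions)
      for (r in setdiff(unique(lab), 0L)) {
        rows <- which(lab == r)
        mean_decay <- colMeans(m[rows, , drop = FALSE])
        n_keep[rows] <- select_echoes_by_snr(mean_decay, sigma, threshold)
      }
    }
  } else {
    # no gate: use the longest leading run of positive magnitudes
    ok <- m > 0
    run <- ok[, 1]
    n_keep <- as.integer(run)
    for (j in seq_len(n_echo)[-1]) {
      run <- run & ok[, j]
      n_keep <- n_keep + run
    }
    sigma <- NULL
  }

  if (rician_correction) {
    if (is.null(sigma)) stop("rician_correction needs a noise estimate", call. = FALSE)
    m <- sqrt(pmax(m^2 - 2 * sigma^2, 0))
  }

  values <- rep(NA_real_, n_vox)
  s0 <- rep(NA_real_, n_vox)
  valid <- rep(FALSE, n_vox)
  reason <- ifelse(n_keep >= 1, "insufficient_echoes", "nonpositive_signal")
  if (!is.null(noise)) {
    # distinguish "signal below the SNR gate from echo 1" from true zeros
    reason[n_keep == 0 & m[, 1] <= 0] <- "nonpositive_signal"
    reason[n_keep == 0 & m[, 1] > 0] <- "insufficient_echoes"
  }

  for (k in unique(n_keep[n_keep >= 2])) {
    rows <- which(n_keep == k)
    mk <- m[rows, seq_len(k), drop = FALSE]
    bad <- rowSums(mk <= 0 | !is.finite(mk)) > 0
    if (any(bad)) {
      reason[rows[bad]] <- "nonpositive_signal"
      rows <- rows[!bad]
      mk <- mk[!bad, , drop = FALSE]
    }
    if (length(rows) == 0) next
    tek <- te[seq_len(k)]
    y <- log(mk)
    wls <- function(w) {
      sw <- rowSums(w)
      swx <- w %*% tek
      swy <- rowSums(w * y)
      swxx <- w %*% tek^2
      swxy <- (w * y) %*% tek
      slope <- (sw * swxy - swx * swy) / (sw * swxx - swx^2)
      cbind(slope, (swy - slope * swx) / sw)
    }
    f <- wls(mk^2)
    if (k > 2) {
      # second pass with predicted-value weights (see fit_exponential_decay)
      pred <- exp(matrix(f[, 2], nrow(mk), k) + outer(f[, 1], tek))
      f <- wls(pred^2)
    }
    values[rows] <- -f[, 1] * 1000
    s0[rows] <- exp(f[, 2])
    valid[rows] <- TRUE
    reason[rows] <- "ok"
  }

  if (!any(valid)) {
    stop("no voxel produced a valid fit (whole-image failure)", call. = FALSE)
  }
  relaxation_map(
    array(values, dims), array(s0, dims), array(valid, dims),
    array(reason, dims), array(pmin(n_keep, n_echo), dims),
    kind = kind, params = image$params
  )
}

#' Resample a map to a reference slice geometry
#'
#' Harmonizes slice thickness between co-acquired maps by averaging blocks of
#' thin slices into each thick reference slice (e.g. 48 slices at 0.5 mm
#' into 24 at 1 mm). In-plane geometry must already agree; the thickness
#' ratio must be an integer. An output voxel is valid when at least one
#' contributing voxel is valid, and its value is the mean over the valid
#' contributors, so means over fully-valid regions are conserved.
#'
#' @param map a [relaxation_map()].
#' @param reference an [acquisition_params()] giving the target geometry.
#' @return A [relaxation_map()] on the reference grid.
#' @export
resample_to_reference <- function(map, reference) {
  stopifnot(inherits(map, "relaxation_map"),
            inherits(reference, "acquisition_params"))
  src <- map$params
  if (is.null(src)) stop("map carries no acquisition geometry", call. = FALSE)
  if (!identical(src$matrix_size, reference$matrix_size)) {
    stop("in-plane geometry differs between source and reference", call. = FALSE)
  }
  ratio <- reference$slice_thickness / src$slice_thickness
  if (abs(ratio - round(ratio)) > 1e-8 || ratio < 1) {
    stop("slice thicknesses are not integer multiples", call. = FALSE)
  }
  ratio <- as.integer(round(ratio))
  nz_src <- dim(map$values)[3]
  nz_out <- nz_src %/% ratio
  if (nz_out < 1 || nz_out * ratio != nz_src) {
    stop("source slice count is not divisible by the thickness ratio", call. = FALSE)
  }
  dims_out <- c(dim(map$values)[1:2], nz_out)
  acc <- function(field) {
    out <- array(0, dim = dims_out)
    cnt <- array(0L, dim = dims_out)
    for (j in seq_len(ratio)) {
      sl <- seq(j, nz_src, by = ratio)
      v <- field[, , sl, drop = FALSE]
      ok <- map$valid[, , sl, drop = FALSE]
      v[!ok] <- 0
      out <- out + v
      cnt <- cnt + ok
    }
    list(sum = out, count = cnt)
  }
  a_val <- acc(map$values)
  a_s0 <- acc(map$s0)
  a_ne <- acc(map$n_echoes_used + 0)
  valid <- a_val$count > 0L
  values <- array(NA_real_, dim = dims_out)
  s0 <- array(NA_real_, dim = dims_out)
  n_used <- array(0L, dim = dims_out)
  values[valid] <- a_val$sum[valid] / a_val$count[valid]
  s0[valid] <- a_s0$sum[valid] / a_s0$count[valid]
  n_used[valid] <- as.integer(round(a_ne$sum[valid] / a_ne$count[valid]))
  reason <- array("insufficient_echoes", dim = dims_out)
  reason[valid] <- "ok"
  out_params <- src
  out_params$slice_thickness <- reference$slice_thickness
  out_params$n_slices <- nz_out
  relaxation_map(values, s0, valid, reason, n_used,
                 kind = map$kind, params = out_params)
}
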