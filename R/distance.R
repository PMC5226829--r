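#' Quantum catch of a receptor
#'
#' Photon catch of one receptor channel viewing a reflecting surface:
#' `Q = sum R(l) I(l) S(l) dl` over the working grid, with reflectance in
#' fractional units (percent / 100). Catches are in relative units; absolute
#' calibration is unnecessary because the von Kries correction and the
#' log-ratio contrast cancel any per-channel scale.
#'
#' @param reflectance Fractional reflectance values on the grid (0--1 scale).
#' @param irradiance Illuminant values on the grid (relative photon flux).
#' @param sensitivity Receptor sensitivity values on the grid.
#' @param step Grid spacing in nm.
#' @return Non-negative scalar catch.
#' @export
quantum_catch <- function(reflectance, irradiance, sensitivity, step = 1) {
  n <- length(reflectance)
  if (length(irradiance) != n || length(sensitivity) != n) {
    rlang::abort("reflectance, irradiance and sensitivity must share one grid.")
  }
  if (all(sensitivity == 0)) rlang::abort("all-zero sensitivity curve.")
  sum(reflectance * irradiance * sensitivity) * step
}

#' von Kries-corrected relative quantum catches
#'
#' Normalizes each channel's catch by its catch of the adapting illuminant,
#' `q_i = Q_i / sum I(l) S_i(l) dl`, the standard approximation of colour
#' constancy. A flat reflectance of level `c` yields `q_i = c` in every
#' channel, and any rescaling of the illuminant or of a single channel's
#' sensitivity cancels from downstream contrasts.
#'
#' @param catches Numeric vector of absolute catches, one per channel.
#' @param irradiance Illuminant values on the grid.
#' @param sensitivities Matrix of sensitivities, grid points x channels.
#' @param step Grid spacing in nm.
#' @return Numeric vector of relative catches `q`.
#' @export
von_kries <- function(catches, irradiance, sensitivities, step = 1) {
  sensitivities <- as.matrix(sensitivities)
  if (length(catches) != ncol(sensitivities)) {
    rlang::abort("one catch per sensitivity column is required.")
  }
  norm <- as.numeric(crossprod(sensitivities, irradiance)) * step
  if (any(norm <= 0)) {
    rlang::abort("zero von Kries normalizer: illuminant invisible to a channel.")
  }
  catches / norm
}

#' Channel Weber fractions from photoreceptor densities
#'
#' The receptor-noise model takes each channel's noise-to-signal ratio
#' (Weber fraction) to scale inversely with the square root of its relative
#' density: `w_i = nu / sqrt(eta_i)`. The single noise scale `nu` is fixed so
#' that the most abundant channel has exactly the reference Weber fraction
#' (0.05 by default); density ties are broken towards LWS, the conventional
#' reference channel.
#'
#' @param densities Relative densities, length 4 (SWS1, SWS2, MWS, LWS),
#'   positive.
#' @param weber_ref Weber fraction assigned to the most abundant channel.
#' @return Named numeric vector of 4 Weber fractions, with the reference
#'   channel recorded in attribute `reference`.
#' @export
#' @examples
#' weber_fractions(c(1, 2, 2, 4)) # 0.100 0.0707 0.0707 0.0500
weber_fractions <- function(densities, weber_ref = 0.05) {
  densities <- as.numeric(densities)
  if (length(densities) != 4 || any(!is.finite(densities)) || any(densities <= 0)) {
    rlang::abort("`densities` must be 4 positive finite values.")
  }
  if (weber_ref <= 0 || weber_ref >= 1) {
    rlang::abort("`weber_ref` must be in (0, 1).")
  }
  ref <- max(which(densities == max(densities))) # tie -> latest channel (LWS)
  nu <- weber_ref * sqrt(densities[ref])
  w <- rlang::set_names(nu / sqrt(densities), CHANNELS)
  attr(w, "reference") <- CHANNELS[ref]
  w
}

#' Receptor-noise chromatic distance (JND)
#'
#' Chromatic contrast between two stimuli seen by a tetrachromat, in
#' just-noticeable-difference units: the noise-weighted distance between the
#' two log relative-catch vectors after discarding their common (achromatic)
#' component. With per-channel signals `df_i = ln(q_i^A / q_i^B)` and noises
#' `e_i` equal to the Weber fractions,
#' \deqn{\Delta S^2 = \frac{\sum_{i<j} (e_k e_l)^2 (df_i - df_j)^2}
#'   {\sum_k \prod_{i \ne k} e_i^2}}
#' written out as the standard four-receptor formula. `DS = 1` is the
#' discrimination threshold; `DS = 0` iff all `df_i` are equal, so any two
#' flat (grey) spectra are indistinguishable.
#'
#' @param q_a,q_b Strictly positive relative catch vectors (length 4). A zero
#'   or negative catch is an error (the spectrum is invisible to a channel);
#'   callers should floor reflectance rather than rely on silent epsilons.
#' @param webers Channel Weber fractions, e.g. from [weber_fractions()].
#' @return List of class `jnd_contrast` with `delta_f` (length 4) and
#'   `delta_s` (scalar, JND).
#' @export
#' @examples
#' w <- weber_fractions(c(1, 2, 2, 4))
#' jnd_distance(c(1, 1, 1, 1), c(1.2, 1, 1, 0.9), w)$delta_s
jnd_distance <- function(q_a, q_b, webers) {
  q_a <- as.numeric(q_a)
  q_b <- as.numeric(q_b)
  e <- as.numeric(webers)
  if (length(q_a) != 4 || length(q_b) != 4 || length(e) != 4) {
    rlang::abort("`q_a`, `q_b` and `webers` must have length 4.")
  }
  if (any(q_a <= 0) || any(q_b <= 0)) {
    rlang::abort(
      "non-positive quantum catch: spectrum invisible to a channel; floor the reflectance instead."
    )
  }
  if (any(e <= 0)) rlang::abort("Weber fractions must be positive.")
  df <- log(q_a / q_b)
  num <- (e[1] * e[2])^2 * (df[4] - df[3])^2 +
    (e[1] * e[3])^2 * (df[4] - df[2])^2 +
    (e[1] * e[4])^2 * (df[3] - df[2])^2 +
    (e[2] * e[3])^2 * (df[4] - df[1])^2 +
    (e[2] * e[4])^2 * (df[3] - df[1])^2 +
    (e[3] * e[4])^2 * (df[2] - df[1])^2
  den <- (e[1] * e[2] * e[3])^2 + (e[1] * e[2] * e[4])^2 +
    (e[1] * e[3] * e[4])^2 + (e[2] * e[3] * e[4])^2
  structure(
    list(
      delta_f = rlang::set_names(df, CHANNELS),
      delta_s = sqrt(num / den)
    ),
    class = "jnd_contrast"
  )
}

#' @export
print.jnd_contrast <- function(x, ...) {
  cat(sprintf("<jnd_contrast> delta_S = %.4g JND\n", x$delta_s))
  invisible(x)
}

# Internal vectorized form: df is a 4 x n matrix of log catch ratios; returns
# n chromatic distances. Same algebra as jnd_distance().
jnd_from_delta_f <- function(df, e) {
  num <- (e[1] * e[2])^2 * (df[4, ] - df[3, ])^2 +
    (e[1] * e[3])^2 * (df[4, ] - df[2, ])^2 +
    (e[1] * e[4])^2 * (df[3, ] - df[2, ])^2 +
    (e[2] * e[3])^2 * (df[4, ] - df[1, ])^2 +
    (e[2] * e[4])^2 * (df[3, ] - df[1, ])^2 +
    (e[3] * e[4])^2 * (df[2, ] - df[1, ])^2
  den <- (e[1] * e[2] * e[3])^2 + (e[1] * e[2] * e[4])^2 +
    (e[1] * e[3] * e[4])^2 + (e[2] * e[3] * e[4])^2
  sqrt(num / den)
}
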