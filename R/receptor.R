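CHANNELS <- c("SWS1", "SWS2", "MWS", "LWS")

# Visual-pigment template constants (A1 chromophore): alpha-band exponential
# sums plus a Gaussian beta-band whose centre and width are linear in the
# peak-absorbance wavelength.
PIGMENT_TEMPLATE <- list(
  A = 69.7, B = 28, b = 0.922, C = -14.9, c = 1.104, D = 0.674,
  a0 = 0.8795, a1 = 0.0459, a2 = 300, a3 = 11940,
  beta_amp = 0.26,
  beta_centre = function(lmax) 189 + 0.315 * lmax,
  beta_width = function(lmax) -40.5 + 0.195 * lmax
)

# Oil-droplet transmission constants: T(l) = exp(-exp(-b (l - lambda_o))) with
# decay rate b = 2.89 * Bmid and 1/e point lambda_o = lambda_cut + 1.08 / (2.89 * Bmid).
DROPLET_CONSTANTS <- list(b_scale = 2.89, o_offset = 1.08, half_max = 0.5)

#' Visual pigment absorbance from its peak wavelength
#'
#' Evaluates the near-universal A1 visual-pigment template: an alpha band
#' parameterized by the peak-absorbance wavelength `lambda_max` plus an
#' optional Gaussian beta band (on by default) whose centre and width are
#' linear functions of `lambda_max`. The result is normalized to unit peak.
#'
#' @param lambda_max Peak absorbance wavelength (nm), inside the grid range.
#' @param wl Working wavelength grid.
#' @param beta_band Include the beta band? Default `TRUE`.
#' @return Tibble with columns `wavelength` and `absorbance` (unit peak).
#' @export
#' @examples
#' a <- pigment_absorbance(564)
#' a$wavelength[which.max(a$absorbance)] # 564
pigment_absorbance <- function(lambda_max, wl = spectral_grid(),
                               beta_band = TRUE) {
  if (lambda_max < min(wl) || lambda_max > max(wl)) {
    rlang::abort("`lambda_max` must lie inside the wavelength grid.")
  }
  tc <- PIGMENT_TEMPLATE
  x <- lambda_max / as.numeric(wl)
  a <- tc$a0 + tc$a1 * exp(-(lambda_max - tc$a2)^2 / tc$a3)
  alpha <- 1 / (exp(tc$A * (a - x)) + exp(tc$B * (tc$b - x)) +
    exp(tc$C * (tc$c - x)) + tc$D)
  s <- alpha
  if (beta_band) {
    beta <- tc$beta_amp *
      exp(-((as.numeric(wl) - tc$beta_centre(lambda_max)) /
        tc$beta_width(lambda_max))^2)
    s <- s + beta
  }
  tibble::tibble(wavelength = as.numeric(wl), absorbance = s / max(s))
}

#' Oil droplet descriptor
#'
#' Avian cones (other than the double cones) sit behind carotenoid oil
#' droplets acting as long-pass cut-off filters. T-type droplets (paired with
#' SWS1) do not filter in 300--700 nm and are represented explicitly as a
#' non-filtering droplet. For C/Y/R types the transmission curve is derived
#' from the cut-off wavelength `lambda_cut` and the absorbance-tangent
#' gradient `b_mid`; when only the half-maximum wavelength `lambda_mid` is
#' reported, `b_mid` is recovered from the tangent-line geometry
#' `b_mid = 0.5 / (lambda_mid - lambda_cut)`.
#'
#' @param kind Droplet type: `"T"`, `"C"`, `"Y"` or `"R"`.
#' @param lambda_cut Cut-off wavelength (nm); required for non-T types.
#' @param b_mid Absorbance gradient at half-maximum (per nm).
#' @param lambda_mid Half-maximum wavelength (nm); alternative to `b_mid`.
#' @return List of class `oil_droplet` with fields `kind`, `lambda_cut`,
#'   `b_mid`, and the derived 1/e point `lambda_o` and decay rate `b`.
#' @export
oil_droplet <- function(kind = c("T", "C", "Y", "R"), lambda_cut = NULL,
                        b_mid = NULL, lambda_mid = NULL) {
  kind <- rlang::arg_match(kind)
  if (kind == "T") {
    out <- list(kind = "T", lambda_cut = NA_real_, b_mid = NA_real_,
      lambda_o = NA_real_, b = NA_real_)
    class(out) <- "oil_droplet"
    return(out)
  }
  if (is.null(lambda_cut)) {
    rlang::abort(sprintf("%s-type droplet requires `lambda_cut`.", kind))
  }
  if (is.null(b_mid) && is.null(lambda_mid)) {
    rlang::abort("supply exactly one of `b_mid` or `lambda_mid`.")
  }
  if (!is.null(b_mid) && !is.null(lambda_mid)) {
    rlang::abort("supply exactly one of `b_mid` or `lambda_mid`, not both.")
  }
  dc <- DROPLET_CONSTANTS
  if (is.null(b_mid)) {
    if (lambda_mid <= lambda_cut) {
      rlang::abort("`lambda_mid` must exceed `lambda_cut`.")
    }
    b_mid <- dc$half_max / (lambda_mid - lambda_cut)
  }
  if (b_mid <= 0) rlang::abort("`b_mid` must be positive.")
  out <- list(
    kind = kind, lambda_cut = lambda_cut, b_mid = b_mid,
    lambda_o = lambda_cut + dc$o_offset / (dc$b_scale * b_mid),
    b = dc$b_scale * b_mid
  )
  class(out) <- "oil_droplet"
  out
}

#' Oil droplet transmission curve
#'
#' T-type droplets transmit fully across 300--700 nm. Other types follow the
#' Gompertz-type cut-off `T(l) = exp(-exp(-b (l - lambda_o)))`, which equals
#' exactly `1/e` at the derived point `lambda_o` and rises monotonically
#' towards 1 at long wavelengths.
#'
#' @param droplet An [oil_droplet()].
#' @param wl Working wavelength grid.
#' @return Tibble with columns `wavelength` and `transmission` in `[0, 1]`.
#' @export
droplet_transmission <- function(droplet, wl = spectral_grid()) {
  stopifnot(inherits(droplet, "oil_droplet"))
  wl_n <- as.numeric(wl)
  if (droplet$kind == "T") {
    return(tibble::tibble(wavelength = wl_n, transmission = 1))
  }
  tr <- exp(-exp(-droplet$b * (wl_n - droplet$lambda_o)))
  tibble::tibble(wavelength = wl_n, transmission = tr)
}

#' Ocular media transmission from its 50% point
#'
#' The combined cornea-plus-lens transmission of the avian eye is a smooth
#' long-pass filter fully characterized, for modelling purposes, by the
#' wavelength of 50% transmission (T50). It is modelled here as a logistic
#' sigmoid `1 / (1 + exp(-slope (l - t50)))` whose default slope of 0.08 per
#' nm gives a 10--90% rise over about 55 nm, matching published avian
#' ocular-media curves.
#'
#' @param t50 Wavelength of 50% transmission (nm), typically 314--395.
#' @param wl Working wavelength grid.
#' @param slope Sigmoid steepness (per nm).
#' @return Tibble with columns `wavelength` and `transmission`.
#' @export
#' @examples
#' tr <- ocular_transmission(324)
#' tr$transmission[tr$wavelength == 324] # 0.5
ocular_transmission <- function(t50, wl = spectral_grid(), slope = 0.08) {
  if (t50 < min(wl) || t50 > max(wl)) {
    rlang::abort("`t50` must lie inside the wavelength grid.")
  }
  wl_n <- as.numeric(wl)
  tibble::tibble(
    wavelength = wl_n,
    transmission = 1 / (1 + exp(-slope * (wl_n - t50)))
  )
}

#' Spectral sensitivity of one cone channel
#'
#' Pointwise product of pigment absorbance, oil-droplet transmission and
#' ocular-media transmission, renormalized to unit peak. The normalization is
#' arbitrary: any per-channel scale factor cancels in the von Kries-corrected
#' quantum-catch ratios that feed the chromatic distance.
#'
#' @param lambda_max Pigment peak wavelength (nm).
#' @param droplet An [oil_droplet()].
#' @param t50 Ocular-media 50% transmission wavelength (nm), or `NULL` to skip
#'   ocular filtering.
#' @param wl Working wavelength grid.
#' @param beta_band Include the pigment template beta band?
#' @param ocular_slope Ocular sigmoid steepness (per nm).
#' @return Tibble with columns `wavelength` and `sensitivity` (unit peak).
#' @export
channel_sensitivity <- function(lambda_max, droplet = oil_droplet("T"),
                                t50 = NULL, wl = spectral_grid(),
                                beta_band = TRUE, ocular_slope = 0.08) {
  s <- pigment_absorbance(lambda_max, wl, beta_band = beta_band)$absorbance
  s <- s * droplet_transmission(droplet, wl)$transmission
  if (!is.null(t50)) {
    s <- s * ocular_transmission(t50, wl, slope = ocular_slope)$transmission
  }
  tibble::tibble(wavelength = as.numeric(wl), sensitivity = s / max(s))
}

#' Construct a tetrachromatic visual model
#'
#' Bundles one complete parameterization of an avian eye: the four single-cone
#' pigment peaks (SWS1, SWS2, MWS, LWS), their oil droplets, the ocular-media
#' T50, the relative photoreceptor densities, the reference Weber fraction of
#' the most abundant channel, and the adapting illuminant.
#'
#' @param eye_type `"UVS"` or `"VS"` (violet- vs ultraviolet-sensitive SWS1).
#' @param lambda_max Named numeric of length 4 (`SWS1`, `SWS2`, `MWS`, `LWS`).
#' @param droplets List of 4 [oil_droplet()]s in the same order; `NULL` gives
#'   a T droplet on SWS1 and unfiltered defaults elsewhere.
#' @param t50 Ocular media T50 (nm).
#' @param densities Relative photoreceptor densities, length 4, positive.
#' @param weber_ref Weber fraction of the most abundant channel (default 0.05).
#' @param illuminant Illuminant name (see [builtin_illuminant()]).
#' @param beta_band Include pigment beta bands?
#' @param ocular_slope Ocular sigmoid steepness (per nm).
#' @return Object of class `visual_model`.
#' @seealso [build_average_eye()] for the standard average UVS/VS models.
#' @export
visual_model <- function(eye_type = c("UVS", "VS"), lambda_max, droplets = NULL,
                         t50, densities = c(1, 2, 2, 4), weber_ref = 0.05,
                         illuminant = "ideal", beta_band = TRUE,
                         ocular_slope = 0.08) {
  eye_type <- rlang::arg_match(eye_type)
  lambda_max <- as.numeric(lambda_max[CHANNELS])
  if (anyNA(lambda_max)) {
    rlang::abort("`lambda_max` must be named SWS1, SWS2, MWS, LWS.")
  }
  if (is.null(droplets)) droplets <- rep(list(oil_droplet("T")), 4)
  stopifnot(length(droplets) == 4, all(vapply(droplets, inherits, TRUE, "oil_droplet")))
  densities <- as.numeric(densities)
  if (length(densities) != 4 || any(densities <= 0)) {
    rlang::abort("`densities` must be 4 positive values.")
  }
  if (weber_ref <= 0 || weber_ref >= 1) {
    rlang::abort("`weber_ref` must be in (0, 1).")
  }
  illuminant <- rlang::arg_match0(illuminant, ILLUMINANT_NAMES)
  structure(
    list(
      eye_type = eye_type,
      lambda_max = rlang::set_names(lambda_max, CHANNELS),
      droplets = rlang::set_names(droplets, CHANNELS),
      t50 = t50,
      densities = rlang::set_names(densities, CHANNELS),
      weber_ref = weber_ref,
      illuminant = illuminant,
      beta_band = beta_band,
      ocular_slope = ocular_slope
    ),
    class = "visual_model"
  )
}

#' @export
print.visual_model <- function(x, ...) {
  cat(sprintf(
    "<visual_model> %s eye, T50 %g nm, illuminant %s\n",
    x$eye_type, x$t50, x$illuminant
  ))
  info <- tidy(x)
  print(info, n = 4)
  invisible(x)
}

#' Tidy a visual model into one row per cone channel
#'
#' @param x A `visual_model`.
#' @param ... Unused.
#' @return Tibble with channel, pigment peak, droplet descriptors, density and
#'   Weber fraction.
#' @method tidy visual_model
#' @export
tidy.visual_model <- function(x, ...) {
  tibble::tibble(
    channel = CHANNELS,
    lambda_max = unname(x$lambda_max),
    droplet = vapply(x$droplets, function(d) d$kind, ""),
    lambda_cut = vapply(x$droplets, function(d) d$lambda_cut, 0),
    b_mid = vapply(x$droplets, function(d) d$b_mid, 0),
    density = unname(x$densities),
    weber = as.numeric(weber_fractions(x$densities, x$weber_ref))
  )
}

# Table of the two standard average avian eyes (UVS and VS).
AVERAGE_EYES <- list(
  UVS = list(
    lambda_max = c(SWS1 = 367, SWS2 = 444, MWS = 501, LWS = 564),
    lambda_cut = c(SWS2 = 411, MWS = 511, LWS = 572),
    b_mid = c(SWS2 = 0.0278, MWS = 0.023, LWS = 0.022),
    t50 = 324
  ),
  VS = list(
    lambda_max = c(SWS1 = 412, SWS2 = 452, MWS = 505, LWS = 565),
    lambda_cut = c(SWS2 = 447, MWS = 510, LWS = 570),
    b_mid = c(SWS2 = 0.0294, MWS = 0.028, LWS = 0.020),
    # the 50% point that reproduces the published average-VS curves
    t50 = 348
  )
)

#' The average UVS and VS avian visual models
#'
#' Standard "average" parameterizations of the two avian eye types used as
#' baselines throughout: template pigment peaks and C/Y/R oil-droplet
#' descriptors per eye type, a T-type (non-filtering) droplet on SWS1,
#' ocular-media T50 of 324 nm (UVS) or 348 nm (VS), Pekin robin photoreceptor
#' densities 1:2:2:4, and a Weber fraction of 0.05 for the most abundant
#' (LWS) channel.
#'
#' @param eye_type `"UVS"` or `"VS"`.
#' @param illuminant Illuminant name (default `"ideal"`).
#' @param ... Passed on to [visual_model()] (e.g. `beta_band`).
#' @return A `visual_model`.
#' @export
#' @examples
#' build_average_eye("UVS")
build_average_eye <- function(eye_type = c("UVS", "VS"), illuminant = "ideal",
                              ...) {
  eye_type <- rlang::arg_match(eye_type)
  p <- AVERAGE_EYES[[eye_type]]
  kinds <- c(SWS2 = "C", MWS = "Y", LWS = "R")
  droplets <- c(
    list(oil_droplet("T")),
    lapply(c("SWS2", "MWS", "LWS"), function(ch) {
      oil_droplet(kinds[[ch]],
        lambda_cut = p$lambda_cut[[ch]],
        b_mid = p$b_mid[[ch]]
      )
    })
  )
  visual_model(
    eye_type = eye_type, lambda_max = p$lambda_max, droplets = droplets,
    t50 = p$t50, densities = c(1, 2, 2, 4), weber_ref = 0.05,
    illuminant = illuminant, ...
  )
}

#' Spectral sensitivities of all four channels of a visual model
#'
#' @param model A [visual_model()].
#' @param wl Working wavelength grid.
#' @return Tibble with columns `channel`, `wavelength`, `sensitivity`.
#' @export
receptor_sensitivities <- function(model, wl = spectral_grid()) {
  purrr::map2(CHANNELS, model$droplets[CHANNELS], function(ch, dr) {
    channel_sensitivity(model$lambda_max[[ch]], dr,
      t50 = model$t50, wl = wl,
      beta_band = model$beta_band, ocular_slope = model$ocular_slope
    ) |>
      dplyr::mutate(channel = ch, .before = 1)
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(channel = factor(.data$channel, levels = CHANNELS))
}

# Internal: 401 x 4 sensitivity matrix for fast pipelines.
sensitivity_matrix <- function(model, wl = spectral_grid()) {
  vapply(CHANNELS, function(ch) {
    channel_sensitivity(model$lambda_max[[ch]], model$droplets[[ch]],
      t50 = model$t50, wl = wl,
      beta_band = model$beta_band, ocular_slope = model$ocular_slope
    )$sensitivity
  }, numeric(length(wl)))
}
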