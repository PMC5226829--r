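#' Simulate a plumage reflectance library with known ground truth
#'
#' Generates per-sex mean reflectance curves for `n_species` species and
#' `n_patches` patches each, mimicking a museum-skin spectral library: each
#' patch is a baseline reflectance level plus one or two Gaussian peaks (an
#' optional long-pass sigmoid patch type adds realism for melanin-like
#' spectra), the female curve equals the male curve with the peak centres
#' shifted and/or amplitudes changed by a controlled sexual effect, and
#' optional spectrally correlated measurement noise is added to each sex
#' independently. Reflectance is clipped to 0--100%. The output is fully
#' determined by `seed`.
#'
#' @param n_species Number of species.
#' @param n_patches Patches per species (default 15).
#' @param species_effect Numeric vector (length `n_species`) of per-species
#'   effect multipliers in `[0, 1]` scaling the sexual differences; default
#'   graded evenly from 0 to 1.
#' @param sex_shift Maximum per-patch peak-centre shift between sexes (nm).
#' @param sex_amp Maximum per-patch amplitude change between sexes (percent
#'   reflectance).
#' @param noise_sd Standard deviation of measurement noise (percent
#'   reflectance) added independently to each sex curve.
#' @param noise_corr Correlation length of the (smooth) noise in nm.
#' @param bare_prob Probability that a patch is bare.
#' @param sigmoid_prob Probability that a patch is a long-pass sigmoid rather
#'   than Gaussian-peaked.
#' @param wl Working wavelength grid.
#' @param seed Integer seed; fully determines the library.
#' @return List of class `plumage_sim` with elements `spectra` (long tibble),
#'   `bare` (mask tibble), `truth` (per-patch true shifts and amplitude
#'   deltas plus the per-species effect multiplier), and `design` (the call
#'   parameters).
#' @export
#' @examples
#' sim <- simulate_plumage(n_species = 2, n_patches = 3, seed = 1)
#' dplyr::count(sim$spectra, species, patch, sex)
simulate_plumage <- function(n_species = 10, n_patches = 15,
                             species_effect = NULL, sex_shift = 10,
                             sex_amp = 0, noise_sd = 0, noise_corr = 20,
                             bare_prob = 0, sigmoid_prob = 0.2,
                             wl = spectral_grid(), seed = 1) {
  if (is.null(species_effect)) {
    species_effect <- if (n_species == 1) 1 else seq(0, 1, length.out = n_species)
  }
  stopifnot(length(species_effect) == n_species)
  withr::with_seed(seed, {
    wl_n <- as.numeric(wl)
    species <- sprintf("sp%02d", seq_len(n_species))
    patches <- sprintf("patch%02d", seq_len(n_patches))
    rows <- list()
    truth <- list()
    bare_rows <- list()
    for (i in seq_len(n_species)) {
      for (j in seq_len(n_patches)) {
        base <- stats::runif(1, 5, 25)
        is_sigmoid <- stats::runif(1) < sigmoid_prob
        shift <- stats::runif(1, 0.25, 1) * sex_shift * species_effect[i]
        amp_delta <- stats::runif(1, 0.25, 1) * sex_amp * species_effect[i]
        if (is_sigmoid) {
          mid <- stats::runif(1, 400, 620)
          amp <- stats::runif(1, 20, 60)
          male <- base + amp / (1 + exp(-(wl_n - mid) / 25))
          female <- (base - amp_delta / 2) +
            (amp - amp_delta) / (1 + exp(-(wl_n - (mid + shift)) / 25))
        } else {
          n_peaks <- sample(1:2, 1)
          centres <- stats::runif(n_peaks, 330, 660)
          amps <- stats::runif(n_peaks, 15, 55)
          widths <- stats::runif(n_peaks, 35, 80)
          male <- base
          female <- base
          for (p in seq_len(n_peaks)) {
            male <- male + amps[p] * exp(-((wl_n - centres[p]) / widths[p])^2)
            female <- female + (amps[p] - amp_delta) *
              exp(-((wl_n - centres[p] - shift) / widths[p])^2)
          }
        }
        if (noise_sd > 0) {
          male <- male + smooth_noise(wl_n, noise_sd, noise_corr)
          female <- female + smooth_noise(wl_n, noise_sd, noise_corr)
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          species = species[i], patch = patches[j],
          sex = rep(c("male", "female"), each = length(wl_n)),
          wavelength = rep(wl_n, 2),
          reflectance = pmin(pmax(c(male, female), 0), 100)
        )
        truth[[length(truth) + 1]] <- tibble::tibble(
          species = species[i], patch = patches[j],
          shift_nm = shift, amp_delta = amp_delta,
          species_effect = species_effect[i]
        )
        bare_rows[[length(bare_rows) + 1]] <- tibble::tibble(
          species = species[i], patch = patches[j],
          bare = stats::runif(1) < bare_prob
        )
      }
    }
    structure(
      list(
        spectra = dplyr::bind_rows(rows),
        bare = dplyr::bind_rows(bare_rows),
        truth = dplyr::bind_rows(truth),
        design = list(
          n_species = n_species, n_patches = n_patches,
          species_effect = species_effect, sex_shift = sex_shift,
          sex_amp = sex_amp, noise_sd = noise_sd, noise_corr = noise_corr,
          bare_prob = bare_prob, sigmoid_prob = sigmoid_prob, seed = seed
        )
      ),
      class = "plumage_sim"
    )
  })
}

#' @export
print.plumage_sim <- function(x, ...) {
  d <- x$design
  cat(sprintf(
    "<plumage_sim> %d species x %d patches, sex_shift %g nm, noise_sd %g%%, seed %d\n",
    d$n_species, d$n_patches, d$sex_shift, d$noise_sd, d$seed
  ))
  invisible(x)
}

# Spectrally correlated (smooth) noise: white Gaussian noise convolved with a
# Gaussian kernel of the given correlation length, rescaled to sd `sd`.
smooth_noise <- function(wl, sd, corr_nm) {
  white <- stats::rnorm(length(wl))
  kernel <- exp(-((seq(-3 * corr_nm, 3 * corr_nm, by = diff(wl[1:2]))) / corr_nm)^2)
  smooth <- stats::filter(c(rev(white), white, rev(white)), kernel / sum(kernel),
    sides = 2
  )[length(wl) + seq_along(wl)]
  smooth <- as.numeric(smooth)
  sd * (smooth - mean(smooth)) / stats::sd(smooth)
}

#' Simulate plumage with sexual differences confined to the ultraviolet
#'
#' Generates patches whose male and female curves differ only below 400 nm
#' (a narrow UV peak present in males and absent or reduced in females),
#' the classic case where inferred dichromatism depends on whether the
#' observer's SWS1 cone is ultraviolet- or violet-sensitive.
#'
#' @param n_patches Number of UV-dimorphic patches.
#' @param uv_centre Peak centre (nm), kept below 400.
#' @param uv_width Gaussian width (nm); small enough that the sex difference
#'   is negligible above 400 nm.
#' @param uv_amp Male UV peak amplitude (percent reflectance).
#' @param wl Working wavelength grid.
#' @param seed Integer seed.
#' @return List of class `plumage_sim` (single species `"uvtest"`); the sex
#'   difference is exactly zero above `uv_centre + 3 * uv_width`.
#' @export
simulate_uv_contrast <- function(n_patches = 2, uv_centre = 345, uv_width = 15,
                                 uv_amp = 30, wl = spectral_grid(), seed = 1) {
  stopifnot(uv_centre + 3 * uv_width < 400)
  withr::with_seed(seed, {
    wl_n <- as.numeric(wl)
    rows <- list()
    truth <- list()
    for (j in seq_len(n_patches)) {
      base <- stats::runif(1, 10, 25)
      shared <- base + 20 * exp(-((wl_n - 550) / 80)^2)
      uv <- uv_amp * exp(-((wl_n - uv_centre) / uv_width)^2)
      uv[wl_n > uv_centre + 3 * uv_width] <- 0
      rows[[j]] <- tibble::tibble(
        species = "uvtest", patch = sprintf("patch%02d", j),
        sex = rep(c("male", "female"), each = length(wl_n)),
        wavelength = rep(wl_n, 2),
        reflectance = pmin(pmax(c(shared + uv, shared), 0), 100)
      )
      truth[[j]] <- tibble::tibble(
        species = "uvtest", patch = sprintf("patch%02d", j),
        shift_nm = 0, amp_delta = uv_amp, species_effect = 1
      )
    }
    structure(
      list(
        spectra = dplyr::bind_rows(rows),
        bare = tibble::tibble(
          species = "uvtest",
          patch = sprintf("patch%02d", seq_len(n_patches)), bare = FALSE
        ),
        truth = dplyr::bind_rows(truth),
        design = list(
          n_species = 1, n_patches = n_patches, uv_centre = uv_centre,
          uv_width = uv_width, uv_amp = uv_amp, seed = seed
        )
      ),
      class = "plumage_sim"
    )
  })
}
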