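# Shared fixtures and independent oracles for the test suite.

# Generic n-receptor noise-limited distance, written as the noise-weighted
# variance of the log catch ratios about their weighted mean. Algebraically
# independent of the 4-receptor determinant expansion used by the package.
oracle_jnd_generic <- function(q_a, q_b, webers) {
  w <- 1 / webers^2
  df <- log(q_a / q_b)
  mu <- sum(w * df) / sum(w)
  sqrt(sum(w * (df - mu)^2))
}

# Pointwise linear interpolation oracle: for each target x find the bracketing
# source points and interpolate by hand.
oracle_interp <- function(x_src, y_src, x_out) {
  vapply(x_out, function(x) {
    i <- max(which(x_src <= x))
    if (x_src[i] == x) return(y_src[i])
    y_src[i] + (y_src[i + 1] - y_src[i]) * (x - x_src[i]) /
      (x_src[i + 1] - x_src[i])
  }, numeric(1))
}

# A flat (grey) reflectance series at `level` percent for one species/patch/sex.
flat_series <- function(species, patch, sex, level, wl = spectral_grid()) {
  tibble::tibble(
    species = species, patch = patch, sex = sex,
    wavelength = as.numeric(wl), reflectance = level
  )
}

# Two-sex spectra for patches whose female curve is the male Gaussian peak
# shifted by `shifts[i]` nm (one patch per shift). Deterministic.
shifted_peak_spectra <- function(shifts, centre = 500, amp = 40, width = 50,
                                 base = 10, wl = spectral_grid()) {
  wl_n <- as.numeric(wl)
  purrr::imap(shifts, function(s, i) {
    dplyr::bind_rows(
      tibble::tibble(
        species = "toy", patch = sprintf("patch%02d", i), sex = "male",
        wavelength = wl_n,
        reflectance = base + amp * exp(-((wl_n - centre) / width)^2)
      ),
      tibble::tibble(
        species = "toy", patch = sprintf("patch%02d", i), sex = "female",
        wavelength = wl_n,
        reflectance = base + amp * exp(-((wl_n - centre - s) / width)^2)
      )
    )
  }) |> purrr::list_rbind()
}

# Tiny reduced parameter space shared by sensitivity tests.
reduced_space <- function(eye_type = "UVS", n_illum = 2, n_t50 = 2,
                          n_sens = 2, n_drop = 2, n_dens = 2) {
  avg <- AVERAGE_EYES_test(eye_type)
  sens_sets <- list(average = avg$lambda_max)
  if (n_sens > 1) {
    shifted <- avg$lambda_max
    shifted["SWS1"] <- shifted["SWS1"] - 10
    sens_sets$sws1_shifted <- shifted
  }
  droplet_from <- function(cuts, b_mids = c(0.0278, 0.023, 0.022)) {
    list(
      SWS2 = dichrosens::oil_droplet("C", cuts[1], b_mid = b_mids[1]),
      MWS = dichrosens::oil_droplet("Y", cuts[2], b_mid = b_mids[2]),
      LWS = dichrosens::oil_droplet("R", cuts[3], b_mid = b_mids[3])
    )
  }
  # the average set reproduces the average-UVS droplets exactly
  droplet_sets <- list(average = droplet_from(c(411, 511, 572)))
  if (n_drop > 1) droplet_sets$shifted <- droplet_from(c(420, 520, 580))
  density_sets <- list(pekin = c(1, 2, 2, 4))
  if (n_dens > 1) density_sets$even <- c(1, 1, 1, 1)
  dichrosens::parameter_space(
    eye_type = eye_type,
    illuminants = c("ideal", "d65")[seq_len(n_illum)],
    t50 = c(324, 344)[seq_len(n_t50)],
    sensitivity_sets = sens_sets,
    droplet_sets = droplet_sets,
    density_sets = density_sets
  )
}

AVERAGE_EYES_test <- function(eye_type) {
  m <- dichrosens::build_average_eye(eye_type)
  list(lambda_max = m$lambda_max)
}
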