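#' Wavelength grid for spectral computations
#'
#' All curves entering one computation must share a single wavelength grid.
#' The working default spans the avian-visible band, 300--700 nm at 1 nm
#' (401 points); spectral integrals are evaluated as grid sums multiplied by
#' the step.
#'
#' @param start,stop Band limits in nm (`start < stop`).
#' @param step Grid spacing in nm (> 0).
#' @return Numeric vector of wavelengths with a `step` attribute.
#' @export
#' @examples
#' wl <- spectral_grid()
#' length(wl) # 401
spectral_grid <- function(start = 300, stop = 700, step = 1) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step))
  if (start >= stop) rlang::abort("`start` must be smaller than `stop`.")
  if (step <= 0) rlang::abort("`step` must be positive.")
  wl <- seq(start, stop, by = step)
  attr(wl, "step") <- step
  wl
}

grid_step <- function(wl) {
  s <- attr(wl, "step")
  if (is.null(s)) s <- stats::median(diff(wl))
  s
}

#' Resample a spectral curve onto a wavelength grid
#'
#' Linear interpolation; extrapolation beyond the source range is refused
#' because reflectance and irradiance measurements carry no information
#' outside the measured band.
#'
#' @param wavelength,value Source curve (numeric vectors, equal length).
#' @param wl Target grid, e.g. [spectral_grid()].
#' @return Numeric vector of values on `wl`.
#' @export
resample_curve <- function(wavelength, value, wl = spectral_grid()) {
  if (length(wavelength) != length(value)) {
    rlang::abort("`wavelength` and `value` must have equal length.")
  }
  if (min(wl) < min(wavelength) || max(wl) > max(wavelength)) {
    rlang::abort(sprintf(
      "target grid [%g, %g] exceeds source range [%g, %g]; extrapolation is not supported.",
      min(wl), max(wl), min(wavelength), max(wavelength)
    ))
  }
  stats::approx(wavelength, value, xout = as.numeric(wl), ties = "ordered")$y
}

#' Resample a long spectra table onto a wavelength grid
#'
#' @param spectra Long tibble with columns `wavelength`, `reflectance`, and any
#'   grouping columns (typically `species`, `patch`, `sex`).
#' @param wl Target grid.
#' @return Tibble on the target grid, same grouping columns.
#' @export
resample_spectra <- function(spectra, wl = spectral_grid()) {
  keys <- setdiff(names(spectra), c("wavelength", "reflectance"))
  spectra |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::reframe(
      wavelength = as.numeric(wl),
      reflectance = resample_curve(.data$wavelength, .data$reflectance, wl)
    )
}

#' Read plumage reflectance spectra from CSV
#'
#' Two dialects are supported. The *wide* dialect has a wavelength column
#' (named `wl` or `wavelength`) plus one column per series, with names encoding
#' `<species><sep><patch><sep><sex>`; the *long* dialect has explicit
#' `species`, `patch`, `sex`, `wavelength` and `reflectance` columns.
#' Reflectance is percent reflectance. Negative values (instrument noise) are
#' clipped to zero; curves are resampled onto `wl`.
#'
#' @param path CSV file.
#' @param dialect `"wide"` or `"long"`.
#' @param sep Separator used in wide column names (default `"_"`); species,
#'   patch and sex must not themselves contain it. The last field is the sex,
#'   the second-to-last the patch, the rest the species.
#' @param wl Working wavelength grid.
#' @return A long tibble with columns `species`, `patch`, `sex`, `wavelength`,
#'   `reflectance` (percent).
#' @export
read_reflectance_csv <- function(path, dialect = c("wide", "long"), sep = "_",
                                 wl = spectral_grid()) {
  dialect <- rlang::arg_match(dialect)
  raw <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  if (dialect == "wide") {
    wl_col <- intersect(c("wl", "wavelength"), names(raw))
    if (length(wl_col) == 0) {
      rlang::abort("wide reflectance CSV must contain a `wl` or `wavelength` column.")
    }
    long <- raw |>
      dplyr::rename(wavelength = dplyr::all_of(wl_col[1])) |>
      tidyr::pivot_longer(-"wavelength",
        names_to = "series", values_to = "reflectance"
      ) |>
      tidyr::separate_wider_regex(
        "series",
        patterns = c(
          species = ".*?", sep, patch = sprintf("[^%s]+", sep), sep,
          sex = sprintf("[^%s]+", sep)
        )
      )
  } else {
    need <- c("species", "patch", "sex", "wavelength", "reflectance")
    if (!all(need %in% names(raw))) {
      rlang::abort(paste0(
        "long reflectance CSV must contain columns: ",
        paste(need, collapse = ", ")
      ))
    }
    long <- raw[need]
  }
  if (!is.numeric(long$reflectance) || !is.numeric(long$wavelength)) {
    rlang::abort("non-numeric wavelength or reflectance values in reflectance CSV.")
  }
  long$sex <- tolower(long$sex)
  if (!all(long$sex %in% c("male", "female", "m", "f"))) {
    rlang::abort("sex labels must be male/female (or m/f).")
  }
  long$sex <- ifelse(long$sex %in% c("m", "male"), "male", "female")
  dup <- long |>
    dplyr::count(.data$species, .data$patch, .data$sex, .data$wavelength) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    rlang::abort(sprintf(
      "duplicate (species, patch, sex) series in reflectance CSV, e.g. %s / %s / %s.",
      dup$species[1], dup$patch[1], dup$sex[1]
    ))
  }
  long |>
    dplyr::mutate(reflectance = pmax(.data$reflectance, 0)) |>
    resample_spectra(wl = wl)
}

#' Write plumage reflectance spectra to CSV
#'
#' Inverse of [read_reflectance_csv()]; both dialects are supported and
#' round-trip exactly (up to numeric formatting).
#'
#' @param spectra Long spectra tibble.
#' @param path Output file.
#' @inheritParams read_reflectance_csv
#' @return `path`, invisibly.
#' @export
write_reflectance_csv <- function(spectra, path, dialect = c("wide", "long"),
                                  sep = "_") {
  dialect <- rlang::arg_match(dialect)
  if (dialect == "long") {
    readr::write_csv(spectra, path)
  } else {
    wide <- spectra |>
      tidyr::unite("series", "species", "patch", "sex", sep = sep) |>
      tidyr::pivot_wider(names_from = "series", values_from = "reflectance") |>
      dplyr::rename(wl = "wavelength")
    readr::write_csv(wide, path)
  }
  invisible(path)
}

#' Read a bare-patch mask from CSV
#'
#' Species-by-patch 0/1 matrix marking patches that are bare skin rather than
#' feathers (bare patches lose their colour in museum skins and are excluded
#' from dichromatism scores). First column is the species label; remaining
#' columns are patch labels with 0/1 (or logical) cells.
#'
#' @param path CSV file.
#' @param spectra Optional spectra tibble to validate labels against; unknown
#'   species or patches in the mask are an error.
#' @return Tibble with columns `species`, `patch`, `bare` (logical).
#' @export
read_bare_mask_csv <- function(path, spectra = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  names(raw)[1] <- "species"
  mask <- raw |>
    tidyr::pivot_longer(-"species", names_to = "patch", values_to = "bare") |>
    dplyr::mutate(bare = as.logical(.data$bare))
  if (anyNA(mask$bare)) rlang::abort("bare-mask cells must be 0/1 or TRUE/FALSE.")
  if (!is.null(spectra)) {
    bad_sp <- setdiff(unique(mask$species), unique(spectra$species))
    bad_pt <- setdiff(unique(mask$patch), unique(spectra$patch))
    if (length(bad_sp) > 0 || length(bad_pt) > 0) {
      rlang::abort(sprintf(
        "bare mask refers to unknown labels: %s",
        paste(c(bad_sp, bad_pt), collapse = ", ")
      ))
    }
  }
  mask
}

ILLUMINANT_NAMES <- c(
  "ideal", "forest_shade", "woodland_shade", "blue_sky",
  "d65", "woodland_gaps", "cloudy_sky"
)

#' Built-in illuminant irradiance spectra
#'
#' Returns one of the seven irradiance spectra commonly used in visual
#' modelling: the ideal (wavelength-independent) illuminant plus six
#' environmental spectra (standard daylight D65, forest shade, woodland shade,
#' woodland gaps, blue sky, cloudy sky). The ideal illuminant is computed; the
#' six environmental spectra are packaged tables in relative photon-flux
#' units. The packaged tables are *synthetic parametric approximations*
#' (Planck photon spectra at habitat-appropriate colour temperatures with
#' Rayleigh-scattering or foliage weighting, stated in each file header), not
#' measured irradiances; their absolute scale is immaterial because the von
#' Kries correction cancels it.
#'
#' @param name Illuminant name: `"ideal"`, `"forest_shade"`, `"woodland_shade"`,
#'   `"blue_sky"`, `"d65"`, `"woodland_gaps"` or `"cloudy_sky"`.
#' @param wl Working wavelength grid.
#' @return Tibble with columns `wavelength` and `irradiance` (relative photon
#'   flux, positive everywhere).
#' @export
#' @examples
#' builtin_illuminant("ideal")
builtin_illuminant <- function(name = ILLUMINANT_NAMES, wl = spectral_grid()) {
  name <- rlang::arg_match(name)
  if (name == "ideal") {
    return(tibble::tibble(wavelength = as.numeric(wl), irradiance = 1))
  }
  path <- system.file("extdata", "illuminants",
    paste0(name, "_synthetic.csv"),
    package = "dichrosens", mustWork = TRUE
  )
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  tibble::tibble(
    wavelength = as.numeric(wl),
    irradiance = resample_curve(tab$wavelength, tab$irradiance, wl)
  )
}

#' @rdname builtin_illuminant
#' @export
illuminant_names <- function() ILLUMINANT_NAMES
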