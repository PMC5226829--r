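#' Run configuration
#'
#' Assembles and validates a run configuration for the [run_score()],
#' [run_sweep()], [run_permute()] and [run_simulate()] drivers. A
#' configuration is a named list; it can be given directly or as a YAML
#' file. Unknown keys are rejected so that typos never silently fall back to
#' defaults, and every convention switch (discrimination threshold,
#' reflectance floor, percent-change denominator, beta band, ocular slope)
#' has a default that is recorded in the output metadata.
#'
#' @param config Named list or path to a YAML file.
#' @param ... Overrides applied on top of `config`.
#' @return Named list of class `run_config` with all defaults filled in.
#' @export
run_config <- function(config = list(), ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(config, list(...))
  defaults <- list(
    spectra = NULL, # path to reflectance CSV, or a spectra tibble
    dialect = "wide",
    bare = NULL, # path to bare-mask CSV, or a mask tibble
    eye_type = "UVS",
    illuminant = "ideal",
    weber_ref = 0.05,
    threshold = 1,
    refl_floor = 1e-4,
    percent_denom = "smaller",
    beta_band = TRUE,
    ocular_slope = 0.08,
    allow_placeholders = FALSE,
    parameter = NULL, # for run_sweep
    values = NULL, # for run_sweep
    seed = 1, # for run_simulate
    n_species = 10, # for run_simulate
    n_patches = 15,
    sex_shift = 10,
    sex_amp = 0,
    noise_sd = 0,
    bare_prob = 0,
    out_dir = NULL
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    rlang::abort(sprintf(
      "unknown configuration keys: %s", paste(unknown, collapse = ", ")
    ))
  }
  out <- utils::modifyList(defaults, config)
  class(out) <- "run_config"
  out
}

config_metadata <- function(config) {
  scalars <- Filter(function(x) is.atomic(x) && length(x) <= 4, unclass(config))
  list(
    package = "dichrosens",
    version = as.character(utils::packageVersion("dichrosens")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = rlang::hash(scalars),
    conventions = scalars[c(
      "threshold", "refl_floor", "percent_denom", "beta_band",
      "ocular_slope", "weber_ref", "illuminant", "eye_type"
    )]
  )
}

load_config_spectra <- function(config) {
  sp <- config$spectra
  if (is.null(sp)) rlang::abort("configuration requires `spectra`.")
  if (is.character(sp)) {
    sp <- read_reflectance_csv(sp, dialect = config$dialect)
  }
  bare <- config$bare
  if (is.character(bare)) bare <- read_bare_mask_csv(bare, spectra = sp)
  list(spectra = sp, bare = bare)
}

config_model <- function(config) {
  build_average_eye(config$eye_type,
    illuminant = config$illuminant,
    beta_band = config$beta_band, ocular_slope = config$ocular_slope
  )
}

write_outputs <- function(tables, config, prefix) {
  out <- list()
  meta <- config_metadata(config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tables)) {
      readr::write_csv(tables[[nm]],
        file.path(config$out_dir, sprintf("%s_%s.csv", prefix, nm)))
    }
    jsonlite::write_json(meta,
      file.path(config$out_dir, sprintf("%s_metadata.json", prefix)),
      auto_unbox = TRUE, pretty = TRUE
    )
  }
  c(tables, list(metadata = meta))
}

#' Score dichromatism from a run configuration
#'
#' Reads spectra (and bare mask), builds the configured average eye, and
#' produces the raw per-patch contrasts and the species score table; with
#' `out_dir` set, writes them as CSV alongside a metadata JSON carrying the
#' package version, configuration hash and every convention switch.
#'
#' @param config A [run_config()], list, or YAML path.
#' @return List with `patches`, `scores` and `metadata`.
#' @export
run_score <- function(config) {
  config <- run_config(config)
  dat <- load_config_spectra(config)
  model <- config_model(config)
  patches <- patch_jnd(dat$spectra, model,
    bare = dat$bare,
    refl_floor = config$refl_floor
  )
  scores <- score_species(patches, threshold = config$threshold)
  write_outputs(list(patches = patches, scores = scores), config, "score")
}

#' Sweep one parameter from a run configuration
#'
#' @param config A [run_config()] with `parameter` and `values` set (see
#'   [sweep_parameter()]).
#' @return List with `comparisons`, per-condition `scores` and `metadata`.
#' @export
run_sweep <- function(config) {
  config <- run_config(config)
  if (is.null(config$parameter) || is.null(config$values)) {
    rlang::abort("sweep configuration requires `parameter` and `values`.")
  }
  dat <- load_config_spectra(config)
  sweep <- sweep_parameter(dat$spectra, config_model(config),
    parameter = config$parameter, values = config$values,
    bare = dat$bare, threshold = config$threshold,
    refl_floor = config$refl_floor
  )
  all_scores <- purrr::imap(sweep$scores, function(s, nm) {
    dplyr::mutate(s, condition = nm, .before = 1)
  }) |> purrr::list_rbind()
  write_outputs(
    list(comparisons = sweep$comparisons, scores = all_scores),
    config, "sweep"
  )
}

#' Permute the full parameter space from a run configuration
#'
#' @param config A [run_config()]; `eye_type` selects the space, and
#'   `allow_placeholders` must be `TRUE` to use the packaged placeholder
#'   extremes.
#' @return List with `permutations` (one row per combination and species)
#'   and `metadata`.
#' @export
run_permute <- function(config) {
  config <- run_config(config)
  dat <- load_config_spectra(config)
  space <- build_parameter_space(config$eye_type,
    allow_placeholders = config$allow_placeholders
  )
  res <- permute_space(dat$spectra, space,
    bare = dat$bare,
    weber_ref = config$weber_ref, threshold = config$threshold,
    refl_floor = config$refl_floor, beta_band = config$beta_band,
    ocular_slope = config$ocular_slope
  )
  write_outputs(list(permutations = res), config, "permute")
}

#' Simulate a spectra library from a run configuration
#'
#' @param config A [run_config()]; with `out_dir` set, writes the spectra in
#'   the wide CSV dialect, the bare mask, and a JSON truth side-car.
#' @return The `plumage_sim` object with metadata attached.
#' @export
run_simulate <- function(config) {
  config <- run_config(config)
  sim <- simulate_plumage(
    n_species = config$n_species, n_patches = config$n_patches,
    sex_shift = config$sex_shift, sex_amp = config$sex_amp,
    noise_sd = config$noise_sd, bare_prob = config$bare_prob,
    seed = config$seed
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_reflectance_csv(sim$spectra,
      file.path(config$out_dir, "simulated_spectra.csv"),
      dialect = config$dialect
    )
    sim$bare |>
      dplyr::mutate(bare = as.integer(.data$bare)) |>
      tidyr::pivot_wider(names_from = "patch", values_from = "bare") |>
      readr::write_csv(file.path(config$out_dir, "simulated_bare_mask.csv"))
    jsonlite::write_json(sim$truth,
      file.path(config$out_dir, "simulated_truth.json"),
      dataframe = "columns", digits = NA
    )
    jsonlite::write_json(config_metadata(config),
      file.path(config$out_dir, "simulate_metadata.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
  }
  sim$metadata <- config_metadata(config)
  sim
}
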