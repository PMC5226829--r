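#' Default parameter-space configuration
#'
#' Reads the packaged parameter-set configuration: the seven illuminants,
#' per-eye-type ocular-media T50 grids (UVS 314--344 nm in 10 nm steps, VS
#' 335--395 nm in 20 nm steps), pigment-peak and oil-droplet average and
#' extreme sets, and nine photoreceptor density ratios. Extreme physiology
#' entries that are literature-range placeholders rather than measured values
#' carry `placeholder: true`; see [build_parameter_space()].
#'
#' @param path Optional path to an alternative YAML configuration with the
#'   same structure.
#' @return Nested list mirroring the YAML file.
#' @export
default_parameter_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "parameter_space.yaml",
      package = "dichrosens", mustWork = TRUE
    )
  }
  yaml::read_yaml(path)
}

#' Assemble a parameter space for permutation analysis
#'
#' Builds the full Cartesian space of visual-model conditions for one eye
#' type: 7 illuminants x 4 ocular T50 values x 11 pigment-sensitivity sets
#' (average, per-channel min and max, all-min, all-max) x 9 oil-droplet sets
#' (average, per non-T droplet min and max, all-min, all-max) x 9 density
#' ratios -- 24,948 combinations. Because the extreme physiology values in
#' the default configuration are placeholders, the space refuses to build
#' unless `allow_placeholders = TRUE`.
#'
#' @param eye_type `"UVS"` or `"VS"`.
#' @param config Configuration list, see [default_parameter_config()].
#' @param allow_placeholders Permit placeholder physiology values?
#' @return Object of class `parameter_space`.
#' @seealso [parameter_space()] to assemble reduced spaces directly.
#' @export
build_parameter_space <- function(eye_type = c("UVS", "VS"),
                                  config = default_parameter_config(),
                                  allow_placeholders = FALSE) {
  eye_type <- rlang::arg_match(eye_type)
  eye <- config[[tolower(eye_type)]]

  used_placeholders <- character()
  if (isTRUE(eye$lambda_max$placeholder)) {
    used_placeholders <- c(used_placeholders, "lambda_max extremes")
  }
  if (isTRUE(eye$droplets$placeholder)) {
    used_placeholders <- c(used_placeholders, "droplet extremes")
  }
  ph_dens <- names(Filter(function(d) isTRUE(d$placeholder), config$densities))
  used_placeholders <- c(used_placeholders,
    if (length(ph_dens)) paste("densities:", paste(ph_dens, collapse = ", ")))
  if (length(used_placeholders) > 0 && !allow_placeholders) {
    rlang::abort(c(
      "parameter space uses placeholder physiology values:",
      rlang::set_names(used_placeholders, "x"),
      i = "set `allow_placeholders = TRUE` to proceed, or edit the configuration."
    ))
  }

  avg <- unlist(eye$lambda_max$average)[CHANNELS]
  mn <- unlist(eye$lambda_max$min)[CHANNELS]
  mx <- unlist(eye$lambda_max$max)[CHANNELS]
  sens_sets <- c(
    list(average = avg),
    rlang::set_names(lapply(CHANNELS, function(ch) {
      v <- avg; v[ch] <- mn[ch]; v
    }), paste0(CHANNELS, "_min")),
    rlang::set_names(lapply(CHANNELS, function(ch) {
      v <- avg; v[ch] <- mx[ch]; v
    }), paste0(CHANNELS, "_max")),
    list(all_min = mn, all_max = mx)
  )

  droplet_from <- function(desc) {
    rlang::set_names(lapply(c("SWS2", "MWS", "LWS"), function(ch) {
      oil_droplet(c(SWS2 = "C", MWS = "Y", LWS = "R")[[ch]],
        lambda_cut = desc[[ch]]$lambda_cut, b_mid = desc[[ch]]$b_mid
      )
    }), c("SWS2", "MWS", "LWS"))
  }
  d_avg <- eye$droplets$average
  d_min <- eye$droplets$min
  d_max <- eye$droplets$max
  non_t <- c("SWS2", "MWS", "LWS")
  droplet_sets <- c(
    list(average = droplet_from(d_avg)),
    rlang::set_names(lapply(non_t, function(ch) {
      d <- d_avg; d[[ch]] <- d_min[[ch]]; droplet_from(d)
    }), paste0(non_t, "_min")),
    rlang::set_names(lapply(non_t, function(ch) {
      d <- d_avg; d[[ch]] <- d_max[[ch]]; droplet_from(d)
    }), paste0(non_t, "_max")),
    list(all_min = droplet_from(d_min), all_max = droplet_from(d_max))
  )

  density_sets <- lapply(config$densities, function(d) as.numeric(d$values))

  parameter_space(
    eye_type = eye_type,
    illuminants = unlist(config$illuminants),
    t50 = as.numeric(eye$t50),
    sensitivity_sets = sens_sets,
    droplet_sets = droplet_sets,
    density_sets = density_sets
  )
}

#' Assemble a parameter space from explicit sets
#'
#' Lower-level constructor used for reduced spaces in tests and examples.
#'
#' @param eye_type `"UVS"` or `"VS"`.
#' @param illuminants Character vector of illuminant names.
#' @param t50 Numeric vector of ocular T50 values (nm).
#' @param sensitivity_sets Named list of named `lambda_max` vectors
#'   (SWS1..LWS).
#' @param droplet_sets Named list; each element a named list of
#'   [oil_droplet()]s for SWS2, MWS and LWS (SWS1 always gets a T droplet).
#' @param density_sets Named list of length-4 density vectors.
#' @return Object of class `parameter_space`.
#' @export
parameter_space <- function(eye_type, illuminants, t50, sensitivity_sets,
                            droplet_sets, density_sets) {
  stopifnot(
    length(illuminants) > 0, length(t50) > 0,
    length(sensitivity_sets) > 0, length(droplet_sets) > 0,
    length(density_sets) > 0
  )
  structure(
    list(
      eye_type = eye_type,
      illuminants = illuminants,
      t50 = t50,
      sensitivity_sets = sensitivity_sets,
      droplet_sets = droplet_sets,
      density_sets = density_sets
    ),
    class = "parameter_space"
  )
}

#' Number of combinations in a parameter space
#'
#' @param space A `parameter_space`.
#' @return Integer product of the set sizes.
#' @export
n_combinations <- function(space) {
  length(space$illuminants) * length(space$t50) *
    length(space$sensitivity_sets) * length(space$droplet_sets) *
    length(space$density_sets)
}

#' @export
print.parameter_space <- function(x, ...) {
  cat(sprintf(
    "<parameter_space> %s eye: %d illuminants x %d T50 x %d sensitivity x %d droplet x %d density = %d combinations\n",
    x$eye_type, length(x$illuminants), length(x$t50),
    length(x$sensitivity_sets), length(x$droplet_sets),
    length(x$density_sets), n_combinations(x)
  ))
  invisible(x)
}

#' Dichromatism scores under every parameter combination
#'
#' Runs the full pipeline for every combination in a parameter space and
#' returns one row per combination and species: the mean dichromatism score
#' (threshold-floored) and the number of patches above the discrimination
#' threshold. Receptor sensitivity curves are computed once per (sensitivity
#' set, droplet set, T50) triple and reused across illuminants and density
#' ratios, which only rescale catches and noise.
#'
#' @param spectra Long spectra tibble on the working grid (typically one
#'   species; several species are scored together).
#' @param space A [parameter_space()].
#' @param bare Optional bare-patch mask.
#' @param weber_ref Reference Weber fraction (default 0.05).
#' @param wl Working wavelength grid.
#' @param threshold Discrimination threshold in JND.
#' @param refl_floor Minimum fractional reflectance.
#' @param beta_band Include pigment beta bands?
#' @param ocular_slope Ocular sigmoid steepness (per nm).
#' @return Tibble with columns `sensitivity_set`, `droplet_set`, `t50`,
#'   `illuminant`, `density_set`, `species`, `mean_score`,
#'   `n_patches_above`.
#' @export
permute_space <- function(spectra, space, bare = NULL, weber_ref = 0.05,
                          wl = spectral_grid(), threshold = 1,
                          refl_floor = 1e-4, beta_band = TRUE,
                          ocular_slope = 0.08) {
  stopifnot(inherits(space, "parameter_space"))
  if (!is.null(bare)) {
    spectra <- spectra |>
      dplyr::anti_join(dplyr::filter(bare, .data$bare), by = c("species", "patch"))
  }
  step <- grid_step(wl)
  refl <- reflectance_matrix(spectra, wl)
  key <- series_keys(colnames(refl))
  m <- key$sex == "male"
  ord_f <- match(paste(key$species[m], key$patch[m], sep = "\r"),
    paste(key$species[!m], key$patch[!m], sep = "\r"))
  if (anyNA(ord_f)) rlang::abort("both sexes required for every patch.")
  frac <- pmax(refl / 100, refl_floor)
  sp_of_patch <- key$species[m]
  species_levels <- unique(sp_of_patch)
  n_per_species <- as.numeric(table(factor(sp_of_patch, species_levels)))

  illums <- lapply(space$illuminants, function(nm) {
    builtin_illuminant(nm, wl)$irradiance
  })
  names(illums) <- space$illuminants
  webers_sets <- lapply(space$density_sets, weber_fractions, weber_ref = weber_ref)

  out <- vector("list",
    length(space$sensitivity_sets) * length(space$droplet_sets) *
      length(space$t50) * length(space$illuminants))
  k <- 0
  for (ss in names(space$sensitivity_sets)) {
    lmax <- space$sensitivity_sets[[ss]]
    for (ds in names(space$droplet_sets)) {
      drops <- c(list(SWS1 = oil_droplet("T")), space$droplet_sets[[ds]])
      for (t50 in space$t50) {
        sens <- vapply(CHANNELS, function(ch) {
          channel_sensitivity(lmax[[ch]], drops[[ch]],
            t50 = t50, wl = wl,
            beta_band = beta_band, ocular_slope = ocular_slope
          )$sensitivity
        }, numeric(length(wl)))
        for (il in space$illuminants) {
          q <- catch_matrix(frac * 100, sens, illums[[il]], step, refl_floor)
          df <- t(log(q[which(m), , drop = FALSE] /
            q[which(!m)[ord_f], , drop = FALSE]))
          res_d <- lapply(names(webers_sets), function(dn) {
            jnd <- jnd_from_delta_f(df, as.numeric(webers_sets[[dn]]))
            floored <- ifelse(jnd < threshold, 0, jnd)
            tibble::tibble(
              density_set = dn,
              species = species_levels,
              mean_score = as.numeric(
                rowsum(floored, factor(sp_of_patch, species_levels))
              ) / n_per_species,
              n_patches_above = as.numeric(
                rowsum(as.numeric(jnd > threshold),
                  factor(sp_of_patch, species_levels))
              )
            )
          })
          k <- k + 1
          out[[k]] <- dplyr::bind_rows(res_d) |>
            dplyr::mutate(
              sensitivity_set = ss, droplet_set = ds, t50 = t50,
              illuminant = il, .before = 1
            )
        }
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Sweep a single visual-model parameter
#'
#' Rescores all species under each value of one parameter, holding the rest
#' of the baseline model fixed, and compares every pair of conditions
#' (including the baseline). The most divergent pair is the one with the
#' lowest Pearson correlation of species mean scores.
#'
#' @param spectra Long spectra tibble.
#' @param baseline A [visual_model()], typically [build_average_eye()].
#' @param parameter One of `"illuminant"`, `"t50"`, `"lambda_max"`,
#'   `"droplets"`, `"densities"`.
#' @param values Values to sweep: a character vector for `illuminant`, a
#'   numeric vector for `t50`, or a named list (condition label -> value) of
#'   `lambda_max` vectors, droplet lists (SWS2/MWS/LWS) or density vectors.
#' @param bare Optional bare-patch mask.
#' @param threshold Discrimination threshold in JND.
#' @param ... Passed to [patch_jnd()].
#' @return Object of class `parameter_sweep` with elements `scores` (named
#'   list of [score_species()] tibbles), `patches` (named list of raw patch
#'   tibbles), `comparisons` (one [glance()] row per condition pair) and
#'   `most_divergent` (label pair with minimum Pearson r).
#' @export
sweep_parameter <- function(spectra, baseline,
                            parameter = c("illuminant", "t50", "lambda_max",
                              "droplets", "densities"),
                            values, bare = NULL, threshold = 1, ...) {
  parameter <- rlang::arg_match(parameter)
  stopifnot(inherits(baseline, "visual_model"))
  if (is.null(names(values))) {
    names(values) <- if (is.list(values)) {
      paste0(parameter, "_", seq_along(values))
    } else {
      paste0(parameter, "_", values)
    }
  }
  conditions <- lapply(values, function(v) modify_model(baseline, parameter, v))
  labels <- c("baseline", names(conditions))
  models <- c(list(baseline = baseline), conditions)

  patches <- lapply(models, function(mod) patch_jnd(spectra, mod, bare = bare, ...))
  scores <- lapply(patches, score_species, threshold = threshold)

  pairs <- utils::combn(labels, 2, simplify = FALSE)
  comparisons <- purrr::map(pairs, function(p) {
    cmp <- compare_conditions(scores[[p[1]]], scores[[p[2]]], labels = p)
    dplyr::mutate(glance(cmp), condition_a = p[1], condition_b = p[2],
      .before = 1)
  }) |>
    purrr::list_rbind()
  worst <- comparisons[which.min(comparisons$pearson_r), ]
  structure(
    list(
      parameter = parameter,
      scores = scores,
      patches = patches,
      comparisons = comparisons,
      most_divergent = c(worst$condition_a, worst$condition_b)
    ),
    class = "parameter_sweep"
  )
}

#' @export
print.parameter_sweep <- function(x, ...) {
  cat(sprintf(
    "<parameter_sweep> %s: %d conditions, most divergent pair %s vs %s (r = %.4f)\n",
    x$parameter, length(x$scores), x$most_divergent[1], x$most_divergent[2],
    min(x$comparisons$pearson_r)
  ))
  invisible(x)
}

# Replace one parameter of a visual model.
modify_model <- function(model, parameter, value) {
  switch(parameter,
    illuminant = {
      model$illuminant <- value
      model
    },
    t50 = {
      model$t50 <- as.numeric(value)
      model
    },
    lambda_max = {
      v <- unlist(value)[CHANNELS]
      if (anyNA(v)) rlang::abort("`lambda_max` value must name SWS1..LWS.")
      model$lambda_max <- v
      model
    },
    droplets = {
      model$droplets[c("SWS2", "MWS", "LWS")] <- value[c("SWS2", "MWS", "LWS")]
      model
    },
    densities = {
      model$densities <- rlang::set_names(as.numeric(value), CHANNELS)
      model
    }
  )
}

#' Summarize permutation distributions of two eye types
#'
#' Descriptive statistics of the mean-score distributions produced by
#' [permute_space()] for the UVS and VS eye types of one species: the range
#' of each and of the pooled scores, the percent difference
#' `100 * max / min` across the pooled scores, the fraction of the pooled
#' range where the two distributions overlap, and the ratio of the two grand
#' means.
#'
#' @param result_uvs,result_vs Tibbles from [permute_space()], single
#'   species each.
#' @return One-row tibble: `n_uvs`, `n_vs`, `min_uvs`, `max_uvs`, `min_vs`,
#'   `max_vs`, `min_combined`, `max_combined`, `percent_difference`,
#'   `overlap`, `mean_ratio_uvs_vs`.
#' @export
summarize_permutations <- function(result_uvs, result_vs) {
  for (r in list(result_uvs, result_vs)) {
    if (length(unique(r$species)) != 1) {
      rlang::abort("summaries are per species; filter to one species first.")
    }
  }
  u <- result_uvs$mean_score
  v <- result_vs$mean_score
  lo <- min(u, v)
  hi <- max(u, v)
  overlap_len <- min(max(u), max(v)) - max(min(u), min(v))
  tibble::tibble(
    n_uvs = length(u),
    n_vs = length(v),
    min_uvs = min(u), max_uvs = max(u),
    min_vs = min(v), max_vs = max(v),
    min_combined = lo, max_combined = hi,
    percent_difference = if (lo == 0) NA_real_ else 100 * hi / lo,
    overlap = if (hi == lo) 1 else max(0, overlap_len) / (hi - lo),
    mean_ratio_uvs_vs = mean(u) / mean(v)
  )
}
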