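#' Male-female chromatic contrast per plumage patch
#'
#' Computes the raw male vs female chromatic contrast (JND) of every feathered
#' patch of every species under one visual model: reflectance is floored at a
#' small fractional minimum (so no channel sees a strictly zero catch),
#' quantum catches are taken under the model's illuminant, von Kries
#' corrected, and passed through the receptor-noise distance.
#'
#' @param spectra Long spectra tibble (`species`, `patch`, `sex`,
#'   `wavelength`, `reflectance` in percent) on the working grid.
#' @param model A [visual_model()].
#' @param bare Optional bare-patch mask tibble (`species`, `patch`, `bare`);
#'   bare patches are dropped before any computation.
#' @param wl Working wavelength grid.
#' @param refl_floor Minimum fractional reflectance (default `1e-4`) applied
#'   before catches are computed.
#' @return Tibble with columns `species`, `patch`, `jnd` (raw, un-floored).
#' @export
patch_jnd <- function(spectra, model, bare = NULL, wl = spectral_grid(),
                      refl_floor = 1e-4) {
  stopifnot(inherits(model, "visual_model"))
  if (!is.null(bare)) {
    spectra <- spectra |>
      dplyr::anti_join(dplyr::filter(bare, .data$bare), by = c("species", "patch"))
  }
  counts <- spectra |>
    dplyr::distinct(.data$species, .data$patch, .data$sex) |>
    dplyr::count(.data$species, .data$patch)
  if (any(counts$n != 2)) {
    bad <- counts[counts$n != 2, ]
    rlang::abort(sprintf(
      "both sexes required for every patch; missing for e.g. %s / %s.",
      bad$species[1], bad$patch[1]
    ))
  }
  sens <- sensitivity_matrix(model, wl)
  illum <- builtin_illuminant(model$illuminant, wl)$irradiance
  step <- grid_step(wl)
  webers <- weber_fractions(model$densities, model$weber_ref)
  jnd_pipeline(spectra, sens, illum, step, webers, wl, refl_floor)
}

# Core catch -> von Kries -> JND pipeline on a long spectra tibble. Shared by
# patch_jnd() and the permutation driver (which supplies cached sensitivity
# matrices).
jnd_pipeline <- function(spectra, sens, illum, step, webers, wl, refl_floor) {
  refl <- reflectance_matrix(spectra, wl) # grid x (species|patch|sex)
  q <- catch_matrix(refl, sens, illum, step, refl_floor) # series x 4
  key <- series_keys(colnames(refl))
  m <- key$sex == "male"
  ord_f <- match(paste(key$species[m], key$patch[m], sep = "\r"),
    paste(key$species[!m], key$patch[!m], sep = "\r"))
  df <- t(log(q[which(m), , drop = FALSE] /
    q[which(!m)[ord_f], , drop = FALSE])) # 4 x n_patches
  tibble::tibble(
    species = key$species[m],
    patch = key$patch[m],
    jnd = unname(jnd_from_delta_f(df, as.numeric(webers)))
  ) |>
    dplyr::arrange(.data$species, .data$patch)
}

reflectance_matrix <- function(spectra, wl) {
  spectra <- dplyr::arrange(spectra, .data$species, .data$patch, .data$sex,
    .data$wavelength)
  n_wl <- length(wl)
  key <- paste(spectra$species, spectra$patch, spectra$sex, sep = "\r")
  series <- unique(key)
  if (nrow(spectra) != n_wl * length(series)) {
    rlang::abort("every (species, patch, sex) series must cover the full grid.")
  }
  matrix(spectra$reflectance,
    nrow = n_wl,
    dimnames = list(NULL, series)
  )
}

series_keys <- function(series) {
  parts <- strsplit(series, "\r", fixed = TRUE)
  list(
    species = vapply(parts, `[[`, "", 1),
    patch = vapply(parts, `[[`, "", 2),
    sex = vapply(parts, `[[`, "", 3)
  )
}

catch_matrix <- function(refl, sens, illum, step, refl_floor) {
  frac <- pmax(refl / 100, refl_floor)
  q_abs <- crossprod(frac, sens * illum) * step # series x 4
  norm <- as.numeric(crossprod(sens, illum)) * step
  if (any(norm <= 0)) {
    rlang::abort("zero von Kries normalizer: illuminant invisible to a channel.")
  }
  sweep(q_abs, 2, norm, "/")
}

#' Species dichromatism scores from patch contrasts
#'
#' Applies the discrimination-threshold flooring (raw JND < `threshold` is set
#' to 0, so non-detectable differences do not inflate scores) and averages
#' over the feathered patches of each species:
#' `score = sum(floored JND) / n_feathered`.
#'
#' @param patches Tibble from [patch_jnd()] (`species`, `patch`, `jnd`).
#' @param threshold Discrimination threshold in JND (default 1).
#' @return Tibble with one row per species: `n_feathered`, `score`, and
#'   `rank` (1 = most dichromatic, ties averaged).
#' @export
score_species <- function(patches, threshold = 1) {
  scores <- patches |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n_feathered = dplyr::n(),
      score = sum(ifelse(.data$jnd < threshold, 0, .data$jnd)) / dplyr::n()
    )
  scores$rank <- rank_species(scores$score)
  scores
}

#' Rank species by dichromatism score
#'
#' Rank 1 is the most dichromatic species; ties receive the average rank.
#' The direction is a convention only: rank-change magnitudes, the statistics
#' reported by [compare_conditions()], are direction-invariant.
#'
#' @param scores Numeric vector of species mean scores.
#' @return Numeric vector of ranks.
#' @export
rank_species <- function(scores) {
  rank(-scores, ties.method = "average")
}

#' Compare species scores under two model parameterizations
#'
#' Quantifies how much swapping one visual-model parameterization for another
#' changes the dichromatism picture: the Pearson correlation of species mean
#' scores, and the rank statistics (species keeping the same rank; mean, SD
#' and maximum of the absolute rank change, over all species). Also flags the
#' two focal species most affected: by absolute score change and by rank
#' change.
#'
#' @param scores_a,scores_b Score tibbles from [score_species()] over the same
#'   species set.
#' @param labels Length-2 character naming the two conditions.
#' @return Object of class `condition_comparison`; see [glance()] for the
#'   one-row statistics and [tidy()] for the per-species table.
#' @export
compare_conditions <- function(scores_a, scores_b,
                               labels = c("condition_a", "condition_b")) {
  if (!setequal(scores_a$species, scores_b$species)) {
    rlang::abort("the two conditions must cover the same species set.")
  }
  per <- dplyr::inner_join(
    dplyr::select(scores_a, "species", score_a = "score", rank_a = "rank"),
    dplyr::select(scores_b, "species", score_b = "score", rank_b = "rank"),
    by = "species"
  ) |>
    dplyr::mutate(
      score_change = .data$score_b - .data$score_a,
      rank_change = abs(.data$rank_b - .data$rank_a)
    )
  structure(
    list(species = per, labels = labels),
    class = "condition_comparison"
  )
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("<condition_comparison> %s vs %s, %d species\n",
    x$labels[1], x$labels[2], nrow(x$species)))
  print(glance(x))
  invisible(x)
}

#' Per-species table of a condition comparison
#'
#' @param x A `condition_comparison`.
#' @param ... Unused.
#' @return Tibble with per-species scores, ranks and changes under both
#'   conditions.
#' @method tidy condition_comparison
#' @export
tidy.condition_comparison <- function(x, ...) {
  x$species
}

#' One-row summary statistics of a condition comparison
#'
#' @param x A `condition_comparison`.
#' @param ... Unused.
#' @return One-row tibble: `pearson_r`, `n_species`, `equal_rank`,
#'   `mean_rank_change`, `sd_rank_change`, `max_rank_change`, and the focal
#'   species with the largest absolute score change (`focal_by_score`) and
#'   the largest rank change (`focal_by_rank`).
#' @method glance condition_comparison
#' @export
glance.condition_comparison <- function(x, ...) {
  per <- x$species
  tibble::tibble(
    pearson_r = stats::cor(per$score_a, per$score_b),
    n_species = nrow(per),
    equal_rank = sum(per$rank_a == per$rank_b),
    mean_rank_change = mean(per$rank_change),
    sd_rank_change = stats::sd(per$rank_change),
    max_rank_change = max(per$rank_change),
    focal_by_score = per$species[which.max(abs(per$score_change))],
    focal_by_rank = per$species[which.max(per$rank_change)]
  )
}

#' Patch-level changes for a focal species between two conditions
#'
#' For one species, summarizes how its individual patch contrasts moved
#' between two parameterizations: the number of patches below the
#' discrimination threshold under each condition, the number whose raw JND
#' changed by more than `change_threshold`, and the largest single-patch
#' change in JND and in percent. The percent change is computed for the patch
#' with the largest JND change and reported as `NA` when that patch is below
#' threshold under either condition (a percentage of a non-detectable
#' contrast is not meaningful); its denominator convention is selectable and
#' always recorded in the output.
#'
#' @param patches_a,patches_b Raw patch tibbles from [patch_jnd()] under the
#'   two conditions.
#' @param species Focal species label.
#' @param percent_denom Denominator of the percent change: the `"smaller"`
#'   (default) or `"larger"` of the two raw patch JNDs, or `"condition_a"`.
#' @param threshold Discrimination threshold in JND (default 1).
#' @param change_threshold JND change that counts as a real change (default 1).
#' @return One-row tibble: `species`, `n_below_a`, `n_below_b`,
#'   `n_changed`, `max_change_jnd`, `max_change_pct`, `percent_denom`.
#' @export
patch_change_stats <- function(patches_a, patches_b, species,
                               percent_denom = c("smaller", "larger", "condition_a"),
                               threshold = 1, change_threshold = 1) {
  percent_denom <- rlang::arg_match(percent_denom)
  sp <- species
  per <- dplyr::inner_join(
    dplyr::filter(patches_a, .data$species == sp) |>
      dplyr::select("species", "patch", jnd_a = "jnd"),
    dplyr::filter(patches_b, .data$species == sp) |>
      dplyr::select("species", "patch", jnd_b = "jnd"),
    by = c("species", "patch")
  )
  if (nrow(per) == 0) rlang::abort(sprintf("unknown species `%s`.", sp))
  delta <- abs(per$jnd_b - per$jnd_a)
  top <- which.max(delta)
  denom <- switch(percent_denom,
    smaller = pmin(per$jnd_a, per$jnd_b)[top],
    larger = pmax(per$jnd_a, per$jnd_b)[top],
    condition_a = per$jnd_a[top]
  )
  pct <- if (per$jnd_a[top] < threshold || per$jnd_b[top] < threshold) {
    NA_real_
  } else {
    100 * delta[top] / denom
  }
  tibble::tibble(
    species = sp,
    n_below_a = sum(per$jnd_a < threshold),
    n_below_b = sum(per$jnd_b < threshold),
    n_changed = sum(delta > change_threshold),
    max_change_jnd = delta[top],
    max_change_pct = pct,
    percent_denom = percent_denom
  )
}
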