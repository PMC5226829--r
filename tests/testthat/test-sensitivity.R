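test_that("the full parameter space enumerates 7 x 4 x 11 x 9 x 9 combinations", {
  for (eye in c("UVS", "VS")) {
    space <- build_parameter_space(eye, allow_placeholders = TRUE)
    expect_length(space$illuminants, 7)
    expect_length(space$t50, 4)
    expect_length(space$sensitivity_sets, 11)
    expect_length(space$droplet_sets, 9)
    expect_length(space$density_sets, 9)
    expect_equal(n_combinations(space), 24948)
  }
  expect_equal(
    build_parameter_space("UVS", allow_placeholders = TRUE)$t50,
    c(314, 324, 334, 344)
  )
  expect_equal(
    build_parameter_space("VS", allow_placeholders = TRUE)$t50,
    c(335, 355, 375, 395)
  )
})

test_that("placeholder physiology is refused unless explicitly allowed", {
  expect_error(build_parameter_space("UVS"), "placeholder")
})

test_that("reduced spaces enumerate their products", {
  expect_equal(n_combinations(reduced_space()), 32)
  single <- reduced_space(n_illum = 1, n_t50 = 1, n_sens = 1, n_drop = 1, n_dens = 1)
  expect_equal(n_combinations(single), 1)
})

test_that("permutation results cover the space and are order-invariant", {
  sim <- simulate_plumage(n_species = 1, n_patches = 4, seed = 12)
  space <- reduced_space()
  res <- permute_space(sim$spectra, space)
  expect_equal(nrow(res), 32)
  expect_true(all(res$mean_score >= 0))

  # permuting the iteration order leaves the score multiset unchanged
  space_r <- space
  space_r$illuminants <- rev(space_r$illuminants)
  space_r$t50 <- rev(space_r$t50)
  space_r$sensitivity_sets <- rev(space_r$sensitivity_sets)
  res_r <- permute_space(sim$spectra, space_r)
  expect_equal(sort(res_r$mean_score), sort(res$mean_score))
})

test_that("a monochromatic species scores zero everywhere in the space", {
  sim <- simulate_plumage(n_species = 1, n_patches = 3, sex_shift = 0, seed = 13)
  res <- permute_space(sim$spectra, reduced_space())
  expect_equal(res$mean_score, rep(0, 32))
  expect_equal(res$n_patches_above, rep(0, 32))
})

test_that("any combination recomputed standalone matches its in-sweep value", {
  sim <- simulate_plumage(n_species = 1, n_patches = 5, seed = 14)
  space <- reduced_space()
  res <- permute_space(sim$spectra, space)
  row <- res[res$sensitivity_set == "sws1_shifted" & res$droplet_set == "shifted" &
    res$t50 == 344 & res$illuminant == "d65" & res$density_set == "even", ]
  model <- visual_model(
    eye_type = "UVS",
    lambda_max = space$sensitivity_sets$sws1_shifted,
    droplets = c(list(oil_droplet("T")), space$droplet_sets$shifted),
    t50 = 344, densities = c(1, 1, 1, 1), illuminant = "d65"
  )
  direct <- score_species(patch_jnd(sim$spectra, model))
  expect_equal(row$mean_score, direct$score, tolerance = 1e-12)
})

test_that("the baseline combination inside the space equals the direct score", {
  sim <- simulate_plumage(n_species = 1, n_patches = 5, seed = 15)
  space <- reduced_space()
  res <- permute_space(sim$spectra, space)
  base_row <- res[res$sensitivity_set == "average" & res$droplet_set == "average" &
    res$t50 == 324 & res$illuminant == "ideal" & res$density_set == "pekin", ]
  # the reduced space's average sets reproduce the average UVS eye
  direct <- score_species(patch_jnd(sim$spectra, build_average_eye("UVS")))
  expect_equal(base_row$mean_score, direct$score, tolerance = 1e-6)
})

test_that("a single-value sweep is a perfect self-comparison", {
  sim <- simulate_plumage(n_species = 4, n_patches = 3, seed = 16)
  sw <- sweep_parameter(sim$spectra, build_average_eye("UVS"),
    parameter = "t50", values = 324
  )
  expect_equal(nrow(sw$comparisons), 1)
  expect_equal(sw$comparisons$pearson_r, 1)
  expect_equal(sw$comparisons$equal_rank, 4)
})

test_that("an SWS1 sweep moves UV-dimorphic scores more than an LWS sweep", {
  sim <- simulate_uv_contrast(n_patches = 3, seed = 17)
  base <- build_average_eye("UVS")
  shift_channel <- function(ch, delta) {
    v <- base$lambda_max
    v[ch] <- v[ch] + delta
    v
  }
  sw_sws1 <- sweep_parameter(sim$spectra, base,
    parameter = "lambda_max",
    values = list(shifted = shift_channel("SWS1", 20))
  )
  sw_lws <- sweep_parameter(sim$spectra, base,
    parameter = "lambda_max",
    values = list(shifted = shift_channel("LWS", 20))
  )
  d_sws1 <- abs(sw_sws1$scores$shifted$score - sw_sws1$scores$baseline$score)
  d_lws <- abs(sw_lws$scores$shifted$score - sw_lws$scores$baseline$score)
  expect_gt(d_sws1, d_lws)
})

test_that("density sweeps change scores proportionally through the Webers", {
  sim <- simulate_plumage(n_species = 3, n_patches = 4, seed = 18)
  base <- build_average_eye("UVS")
  sw <- sweep_parameter(sim$spectra, base,
    parameter = "densities",
    values = list(even = c(1, 1, 1, 1), noddy = c(1, 9.59, 16.82, 14.29))
  )
  expect_equal(length(sw$scores), 3)
  expect_true(all(sw$comparisons$pearson_r <= 1))
  expect_length(sw$most_divergent, 2)
})

test_that("distribution summaries follow their stated formulas", {
  mk <- function(scores) {
    tibble::tibble(
      sensitivity_set = "s", droplet_set = "d", t50 = 324,
      illuminant = "ideal", density_set = "p", species = "a",
      mean_score = scores, n_patches_above = 0
    )
  }
  # the printed-range arithmetic: 100 * 14.77 / 5.26
  s <- summarize_permutations(mk(c(5.26, 14.77)), mk(c(6, 10)))
  expect_equal(s$percent_difference, 100 * 14.77 / 5.26, tolerance = 1e-12)
  expect_equal(round(s$percent_difference), 281)

  # nested/overlapping ranges: [0, 2] vs [1, 3] overlap over 1/3
  s2 <- summarize_permutations(mk(c(0, 2)), mk(c(1, 3)))
  expect_equal(s2$overlap, 1 / 3)
  expect_true(is.na(s2$percent_difference)) # min is 0

  # identical distributions
  s3 <- summarize_permutations(mk(c(1, 2)), mk(c(1, 2)))
  expect_equal(s3$overlap, 1)
  expect_equal(s3$mean_ratio_uvs_vs, 1)

  # degenerate point distributions: percent difference of (x, x) is 100%
  s4 <- summarize_permutations(mk(c(2, 2)), mk(c(2, 2)))
  expect_equal(s4$percent_difference, 100)
  expect_equal(s4$overlap, 1)
})
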