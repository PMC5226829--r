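test_that("identical male and female spectra give zero contrasts and scores", {
  sim <- simulate_plumage(n_species = 2, n_patches = 4, sex_shift = 0, seed = 4)
  p <- patch_jnd(sim$spectra, build_average_eye("UVS"))
  expect_equal(p$jnd, rep(0, 8), tolerance = 1e-9)
  s <- score_species(p)
  expect_equal(s$score, c(0, 0))
})

test_that("missing sexes and bare patches are handled per contract", {
  sim <- simulate_plumage(n_species = 1, n_patches = 2, seed = 6)
  half <- dplyr::filter(sim$spectra, !(patch == "patch02" & sex == "female"))
  expect_error(patch_jnd(half, build_average_eye("UVS")), "both sexes")

  # a bare patch is excluded from numerator and denominator
  sim15 <- simulate_plumage(n_species = 1, n_patches = 15, seed = 7)
  mask <- sim15$bare
  mask$bare[mask$patch %in% c("patch01", "patch02")] <- TRUE
  p <- patch_jnd(sim15$spectra, build_average_eye("UVS"), bare = mask)
  expect_equal(nrow(p), 13)
  s <- score_species(p)
  expect_equal(s$n_feathered, 13)
})

test_that("flooring and feathered-patch denominators reproduce hand scores", {
  # patches at 0.5 and 2.0 JND: floored to (0, 2), mean 1.0
  toy <- tibble::tibble(
    species = "a", patch = c("p1", "p2"), jnd = c(0.5, 2.0)
  )
  expect_equal(score_species(toy)$score, 1.0)

  # 13 feathered patches all at 1.3: mean stays 1.3
  toy13 <- tibble::tibble(
    species = "a", patch = sprintf("p%02d", 1:13), jnd = rep(1.3, 13)
  )
  expect_equal(score_species(toy13)$score, 1.3)

  # everything sub-threshold floors to a zero score
  toy0 <- tibble::tibble(
    species = "a", patch = c("p1", "p2"), jnd = c(0.99, 0.2)
  )
  expect_equal(score_species(toy0)$score, 0)
})

test_that("flooring is monotone and order-invariant; supra-threshold mean is plain", {
  withr::with_seed(21, {
    for (i in 1:20) {
      jnd <- runif(8, 0, 3)
      t1 <- tibble::tibble(species = "a", patch = sprintf("p%d", 1:8), jnd = jnd)
      bumped <- t1
      k <- sample(8, 1)
      bumped$jnd[k] <- bumped$jnd[k] + runif(1, 0, 2)
      expect_gte(score_species(bumped)$score, score_species(t1)$score)
      shuffled <- t1[sample(8), ]
      expect_equal(score_species(shuffled)$score, score_species(t1)$score)
    }
  })
  all_above <- tibble::tibble(
    species = "a", patch = sprintf("p%d", 1:5), jnd = c(1.2, 3, 2.5, 1.01, 4)
  )
  expect_equal(score_species(all_above)$score, mean(all_above$jnd))
})

test_that("species ranking uses rank 1 for most dichromatic with average ties", {
  expect_equal(rank_species(c(3, 2, 1)), c(1, 2, 3))
  expect_equal(rank_species(c(2, 2, 1)), c(1.5, 1.5, 3))
  scores <- c(0.4, 2.2, 1.7, 0.9)
  perm <- c(3, 1, 4, 2)
  expect_equal(rank_species(scores)[perm], rank_species(scores[perm]))
})

test_that("comparing a condition with itself is the identity comparison", {
  s <- tibble::tibble(
    species = c("a", "b", "c"), n_feathered = 15,
    score = c(3, 2, 1), rank = c(1, 2, 3)
  )
  g <- glance(compare_conditions(s, s))
  expect_equal(g$pearson_r, 1)
  expect_equal(g$equal_rank, 3)
  expect_equal(g$mean_rank_change, 0)
  expect_equal(g$max_rank_change, 0)
})

test_that("fully reversed ranks give the hand-enumerated change statistics", {
  a <- tibble::tibble(
    species = c("a", "b", "c"), n_feathered = 15,
    score = c(3, 2, 1), rank = rank_species(c(3, 2, 1))
  )
  b <- tibble::tibble(
    species = c("a", "b", "c"), n_feathered = 15,
    score = c(1, 2, 3), rank = rank_species(c(1, 2, 3))
  )
  g <- glance(compare_conditions(a, b))
  expect_equal(g$max_rank_change, 2)
  expect_equal(g$mean_rank_change, 4 / 3)
  expect_equal(g$equal_rank, 1)

  # the comparison mirrors: r and all change magnitudes are direction-free
  g2 <- glance(compare_conditions(b, a))
  expect_equal(g2$pearson_r, g$pearson_r)
  expect_equal(g2$mean_rank_change, g$mean_rank_change)
  expect_equal(g2$sd_rank_change, g$sd_rank_change)
  expect_equal(g2$max_rank_change, g$max_rank_change)

  expect_error(
    compare_conditions(a, dplyr::mutate(b, species = c("a", "b", "zz"))),
    "same species"
  )
})

test_that("patch-level change statistics follow the documented conventions", {
  pa <- tibble::tibble(species = "a", patch = c("p1", "p2"), jnd = c(4, 1.5))
  pb <- tibble::tibble(species = "a", patch = c("p1", "p2"), jnd = c(2, 1.6))

  st <- patch_change_stats(pa, pa, "a")
  expect_equal(st$n_changed, 0)
  expect_equal(st$max_change_jnd, 0)

  st2 <- patch_change_stats(pa, pb, "a", percent_denom = "smaller")
  expect_equal(st2$max_change_jnd, 2)
  expect_equal(st2$max_change_pct, 100) # 2 / min(4, 2)
  expect_equal(
    patch_change_stats(pa, pb, "a", percent_denom = "larger")$max_change_pct, 50
  )
  expect_equal(
    patch_change_stats(pa, pb, "a", percent_denom = "condition_a")$max_change_pct, 50
  )

  # one side below threshold: percent change undefined
  pc <- tibble::tibble(species = "a", patch = c("p1", "p2"), jnd = c(0.8, 1.5))
  st3 <- patch_change_stats(pc, pb, "a")
  expect_true(is.na(st3$max_change_pct))
  expect_equal(st3$n_below_a, 1)

  expect_error(patch_change_stats(pa, pb, "missing"), "unknown species")
})

test_that("a UV-confined sexual difference is larger through a UVS eye", {
  sim <- simulate_uv_contrast(n_patches = 2, seed = 2)
  uvs <- patch_jnd(sim$spectra, build_average_eye("UVS"))
  vs <- patch_jnd(sim$spectra, build_average_eye("VS"))
  expect_true(all(uvs$jnd > vs$jnd))
})
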