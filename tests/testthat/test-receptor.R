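test_that("pigment template peaks at lambda_max with unit maximum", {
  for (lm in c(367, 444, 501, 564)) {
    # alpha band alone peaks exactly at the grid point nearest lambda_max
    a0 <- pigment_absorbance(lm, beta_band = FALSE)
    expect_equal(max(a0$absorbance), 1)
    expect_equal(a0$wavelength[which.max(a0$absorbance)], lm)
    expect_equal(sum(a0$absorbance == 1), 1) # unique grid maximum
    # the beta band can pull the combined maximum at most one grid point short
    a <- pigment_absorbance(lm, beta_band = TRUE)
    expect_lte(abs(a$wavelength[which.max(a$absorbance)] - lm), 1)
    expect_equal(max(a$absorbance), 1)
  }
  expect_error(pigment_absorbance(250), "grid")
})

test_that("beta band sits at the template's linear function of lambda_max", {
  # for mid/long-wave pigments the beta bump is well separated from the
  # alpha tail, so the curve has a local maximum at the predicted centre
  for (lm in c(501, 564)) {
    beta_centre <- 189 + 0.315 * lm # independent evaluation of the relation
    a <- pigment_absorbance(lm, beta_band = TRUE)
    short <- dplyr::filter(a, wavelength <= beta_centre + 40)
    local_max <- short$wavelength[which.max(short$absorbance)]
    # the sloping alpha tail skews the bump by a few nm at most
    expect_lt(abs(local_max - beta_centre), 5)
    # no such bump without the beta band
    a0 <- pigment_absorbance(lm, beta_band = FALSE)
    short0 <- dplyr::filter(a0, wavelength <= beta_centre + 40)$absorbance
    expect_lt(max(short0), 0.1)
  }
})

test_that("oil droplet transmission is a monotone cut-off with exact 1/e point", {
  t_type <- droplet_transmission(oil_droplet("T"))
  expect_true(all(t_type$transmission == 1))

  r_type <- oil_droplet("R", lambda_cut = 572, b_mid = 0.022)
  tr <- droplet_transmission(r_type)
  expect_true(all(diff(tr$transmission) >= 0))
  expect_true(all(tr$transmission >= 0 & tr$transmission <= 1))
  expect_gt(tr$transmission[401], 0.95) # approaches 1 at 700 nm
  # independently locate the 1/e crossing of the computed curve
  rising <- tr$transmission > 1e-6 & tr$transmission < 1 - 1e-6
  crossing <- stats::approx(tr$transmission[rising], tr$wavelength[rising],
    xout = exp(-1))$y
  expect_equal(crossing, r_type$lambda_o, tolerance = 1e-3)

  expect_error(oil_droplet("R"), "lambda_cut")
  expect_error(oil_droplet("C", lambda_cut = 411), "exactly one")
})

test_that("b_mid recovered from lambda_mid matches the tangent geometry", {
  d1 <- oil_droplet("C", lambda_cut = 411, b_mid = 0.0278)
  lambda_mid <- 411 + 0.5 / 0.0278
  d2 <- oil_droplet("C", lambda_cut = 411, lambda_mid = lambda_mid)
  expect_equal(d2$b_mid, d1$b_mid)
  expect_equal(d2$lambda_o, d1$lambda_o)
})

test_that("lowering lambda_cut weakly increases droplet transmission everywhere", {
  lo <- droplet_transmission(oil_droplet("Y", 490, b_mid = 0.024))
  hi <- droplet_transmission(oil_droplet("Y", 520, b_mid = 0.024))
  expect_true(all(lo$transmission >= hi$transmission))
})

test_that("ocular media transmission passes through 0.5 at T50 and is monotone", {
  for (t50 in c(324, 348)) {
    tr <- ocular_transmission(t50)
    expect_equal(tr$transmission[tr$wavelength == t50], 0.5)
    expect_true(all(diff(tr$transmission) > 0))
  }
  # raising T50 weakly decreases transmission at every wavelength
  t314 <- ocular_transmission(314)$transmission
  t344 <- ocular_transmission(344)$transmission
  expect_true(all(t344 <= t314))
})

test_that("channel sensitivity composes filters and keeps unit peak", {
  lm <- 444
  plain <- channel_sensitivity(lm) # T droplet, no ocular filter
  expect_equal(plain$sensitivity, pigment_absorbance(lm)$absorbance)

  uvs_sws1 <- channel_sensitivity(367, oil_droplet("T"), t50 = 324)
  peak <- uvs_sws1$wavelength[which.max(uvs_sws1$sensitivity)]
  expect_gte(peak, 367) # ocular filtering removes short-wavelength mass
  expect_equal(max(uvs_sws1$sensitivity), 1)
})

test_that("average eyes carry the standard parameter sets", {
  uvs <- build_average_eye("UVS")
  expect_equal(unname(uvs$lambda_max), c(367, 444, 501, 564))
  expect_equal(uvs$t50, 324)
  expect_equal(unname(uvs$densities), c(1, 2, 2, 4))
  expect_equal(uvs$weber_ref, 0.05)
  expect_equal(
    unname(vapply(uvs$droplets, function(d) d$kind, "")),
    c("T", "C", "Y", "R")
  )
  expect_equal(uvs$droplets$SWS2$lambda_cut, 411)
  expect_equal(uvs$droplets$LWS$b_mid, 0.022)

  vs <- build_average_eye("VS")
  expect_equal(unname(vs$lambda_max), c(412, 452, 505, 565))
  expect_equal(vs$t50, 348)
  expect_equal(vs$droplets$SWS2$b_mid, 0.0294)

  info <- tidy(uvs)
  expect_equal(info$weber, c(0.1, sqrt(2) / 20, sqrt(2) / 20, 0.05))
})

test_that("all transmission curves live in [0, 1] and rise with wavelength", {
  withr::with_seed(7, {
    for (i in 1:20) {
      cut <- runif(1, 380, 600)
      bm <- runif(1, 0.015, 0.035)
      tr <- droplet_transmission(oil_droplet("R", cut, b_mid = bm))$transmission
      expect_true(all(tr >= 0 & tr <= 1))
      expect_true(all(diff(tr) >= 0))
      oc <- ocular_transmission(runif(1, 310, 400))$transmission
      expect_true(all(oc >= 0 & oc <= 1))
      expect_true(all(diff(oc) >= 0))
    }
  })
})
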