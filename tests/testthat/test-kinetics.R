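test_that("conversion curves are cumulative fractions ending at 1", {
  expect_equal(conversion_curve(count_profile(c(3, 0, 0, 0)))$alpha,
               c(1, 1, 1, 1))
  expect_equal(conversion_curve(count_profile(c(1, 1, 1, 1)))$alpha,
               c(0.25, 0.5, 0.75, 1))
  cc <- conversion_curve(count_profile(c(1, 1, 1, 1), layer_spacing_um = 7))
  expect_equal(cc$z_um, c(7, 14, 21, 28))
  expect_error(conversion_curve(count_profile(c(0, 0, 0))), "empty profile")
})

test_that("conversion is scale-invariant and monotone for random profiles", {
  set.seed(1)
  for (i in 1:50) {
    counts <- rpois(sample(4:20, 1), lambda = runif(1, 0.5, 20))
    if (sum(counts) == 0) counts[1] <- 1
    a <- conversion_curve(count_profile(counts))$alpha
    expect_true(all(diff(a) >= -1e-12))
    expect_equal(a[length(a)], 1)
    a7 <- conversion_curve(count_profile(counts * 7))$alpha
    expect_equal(a, a7, tolerance = 1e-12)
  }
})

test_that("Hill parameters are recovered from noiseless scenarios", {
  pr <- generate_count_scenario("hill", list(n = 3, K = 40), 14, 100000,
                                noise_sd = 0, seed = 1)
  f <- fit_conversion_model(conversion_curve(pr), "hill")
  expect_true(f$converged)
  expect_equal(unname(f$params["n"]), 3, tolerance = 0.01)
  expect_equal(unname(f$params["K"]), 40, tolerance = 0.01)
  # fitted Hill curve passes through alpha = 0.5 at z = K exactly
  K <- f$params[["K"]]; n <- f$params[["n"]]
  expect_equal(K^n / (K^n + K^n), 0.5)
})

test_that("model selection prefers the generating regime", {
  surf <- generate_count_scenario("surface", list(k = 0.3), 14, 5000,
                                  noise_sd = 0, seed = 1)
  f <- fit_conversion_model(conversion_curve(surf), "best")
  expect_equal(f$model, "surface_exponential")
  expect_lt(f$candidates["surface_exponential"], f$candidates["hill"])

  hill <- generate_count_scenario("hill", list(n = 3, K = 40), 14, 5000,
                                  noise_sd = 0, seed = 1)
  fh <- fit_conversion_model(conversion_curve(hill), "best")
  expect_equal(fh$model, "hill")
})

test_that("degenerate curves report non-convergence rather than failing", {
  cc <- conversion_curve(count_profile(c(5, 0, 0, 0, 0, 0)))
  f <- fit_conversion_model(cc, "hill")
  expect_s3_class(f, "kinetic_fit")
  expect_true(is.logical(f$converged))
  expect_error(fit_conversion_model(conversion_curve(count_profile(c(1, 1, 1, 1))),
                                    "hill"), "at least 4 points")
})

test_that("proliferation rates are end-count over interval length", {
  profs <- list(count_profile(c(80, 20), day = 1),
                count_profile(c(250, 150), day = 4),
                count_profile(c(400, 300), day = 7))
  r <- proliferation_rate(profs)
  expect_equal(r$rate_cells_per_day, c(100 / 1, 400 / 3, 700 / 3))
  expect_equal(r$name, c("t_1", "t_2", "t_3"))

  # constant C_summ: rates scale as 1/t_d
  same <- list(count_profile(c(50, 50), day = 1),
               count_profile(c(50, 50), day = 4),
               count_profile(c(50, 50), day = 7))
  rs <- proliferation_rate(same)
  expect_equal(rs$rate_cells_per_day, 100 / c(1, 3, 3))

  expect_error(proliferation_rate(profs[1:2]), "missing count profile for day 7")
  expect_error(proliferation_rate(profs[1]), "at least two days")
})

test_that("migration activity matches the closed form on a linear curve", {
  # uniform counts give alpha(z) = z/Z exactly
  n <- 10; spacing <- 7; Z <- n * spacing; rate <- 120
  cc <- conversion_curve(count_profile(rep(4, n), layer_spacing_um = spacing))
  act <- migration_activity_curve(cc, rate)
  analytic <- rate / (act$alpha * Z^2)
  expect_equal(act$activity, analytic, tolerance = 1e-9)
  expect_lt(act$slope, 0)  # activity decreases in alpha for linear curves

  # exact homogeneity in rate
  act2 <- migration_activity_curve(cc, 2 * rate)
  expect_equal(act2$activity, 2 * act$activity, tolerance = 1e-12)
  expect_equal(act2$slope, 2 * act$slope, tolerance = 1e-12)
})

test_that("deep colonisation has lower activity than shallow settling", {
  shallow <- generate_count_scenario("surface", list(k = 0.25), 14, 3000,
                                     noise_sd = 0, seed = 3)
  deep <- generate_count_scenario("hill", list(n = 3, K = 55), 14, 3000,
                                  noise_sd = 0, seed = 3)
  as_ <- migration_activity_curve(conversion_curve(shallow), 100)
  ad <- migration_activity_curve(conversion_curve(deep), 100)
  expect_true(all(ad$activity < as_$activity))
})

test_that("flat conversion segments are resolved at their midpoint and flagged", {
  cc <- conversion_curve(count_profile(c(2, 0, 0, 2), layer_spacing_um = 10))
  act <- migration_activity_curve(cc, 10, alpha_steps = c(0.25, 0.5, 0.75))
  expect_true(act$flagged[2])
  expect_false(any(act$flagged[c(1, 3)]))
  # plateau at alpha = 0.5 spans z = 10..30; midpoint is 20
  expect_equal(act$z_um[2], 20)
})

test_that("activity share behaves like a normalised area", {
  cc <- conversion_curve(count_profile(rep(1, 10)))
  act <- migration_activity_curve(cc, 100)
  act$activity <- rep(5, 9)  # constant activity profile
  expect_equal(activity_share(act, 0.5), 0.5)
  expect_equal(activity_share(act, 0.9), 1)
  expect_equal(activity_share(act, 1), 1)
  expect_equal(activity_share(act, 0.05), 0)
  expect_error(activity_share(act, 0), "cell_fraction")
  act$alpha <- act$alpha[1]; act$activity <- act$activity[1]
  expect_error(activity_share(act, 0.5), "at least 2")
})

test_that("shallow cells dominate the activity share on front-loaded profiles", {
  # most cells near the surface: the first half of the cells accounts for
  # well over half of the total migration activity
  pr <- generate_count_scenario("surface", list(k = 0.08), 14, 4000,
                                noise_sd = 0, seed = 5)
  act <- migration_activity_curve(conversion_curve(pr), 150)
  expect_gt(activity_share(act, 0.5), 0.6)
})
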