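# Occurrence GAM: fitting, GCV bookkeeping, selection, F-ratio test,
# interaction surface.

test_that("intercept-only fit explains zero deviance and GCV matches the
          bookkeeping formula", {
  set.seed(1)
  tab <- data.frame(UDC = rpois(100, 3), z = rnorm(100))
  f0 <- occurrence_gam(tab, list())
  expect_equal(f0$dev_expl, 0, tolerance = 1e-10)
  f1 <- occurrence_gam(tab, list(smooth_term("z")))
  expect_equal(f1$gcv, f1$n * f1$deviance / (f1$n - f1$total_edf)^2,
               tolerance = 1e-12)
  expect_true(f1$phi > 0 && f1$gcv > 0)
  expect_true(f1$dev_expl >= 0 && f1$dev_expl <= 100)
})

test_that("response validation rejects non-count responses", {
  tab <- data.frame(UDC = c(1.5, 2, 3), z = 1:3)
  expect_error(occurrence_gam(tab, list(smooth_term("z"))), "integer")
  tab$UDC <- c(-1L, 2L, 3L)
  expect_error(occurrence_gam(tab, list(smooth_term("z"))), "non-negative")
})

test_that("equidispersed Poisson simulation gives phi near 1 and a nearly
          linear smooth for a log-linear trend", {
  set.seed(101)
  z <- rnorm(500)
  tab <- data.frame(UDC = rpois(500, exp(1 + 0.5 * z)), z = z)
  f <- occurrence_gam(tab, list(smooth_term("z")))
  expect_gt(f$phi, 0.8); expect_lt(f$phi, 1.2)
  expect_lt(unname(f$edf["s(z)"]), 2.5)      # essentially a straight line
  # and the collapse rule linearizes it with the slope recovered
  sel <- backwards_select(tab, list(smooth_term("z")))
  kinds <- vapply(sel$final$terms, `[[`, character(1), "kind")
  if (any(kinds == "linear"))
    expect_equal(unname(coef(sel$final)["z"]), 0.5, tolerance = 0.1)
})

test_that("threefold overdispersion is reflected in the Pearson scale
          estimate", {
  set.seed(202)
  z <- rnorm(500)
  mu <- exp(1 + 0.5 * z)
  tab <- data.frame(UDC = rnbinom(500, mu = mu, size = mu / 2), z = z)
  f <- occurrence_gam(tab, list(smooth_term("z")))
  expect_gt(f$phi, 2.5); expect_lt(f$phi, 3.5)
})

test_that("listwise deletion of incomplete rows is counted", {
  set.seed(3)
  tab <- data.frame(UDC = rpois(60, 2), z = rnorm(60))
  tab$z[c(5, 12)] <- NA
  f <- occurrence_gam(tab, list(smooth_term("z")))
  expect_equal(f$n, 58)
  expect_equal(f$n_dropped, 2)
})

test_that("a variable may not appear in two terms", {
  tab <- data.frame(UDC = rpois(50, 2), a = rnorm(50), b = rnorm(50))
  expect_error(occurrence_gam(tab, list(smooth_term("a"),
                                        smooth2_term("a", "b"))),
               "two terms")
})

test_that("an already-minimal model is a selection fixed point with a full
          trace", {
  set.seed(7)
  z <- rnorm(400)
  tab <- data.frame(UDC = rpois(400, exp(0.5 + sin(z))), z = z)
  sel <- backwards_select(tab, list(smooth_term("z")))
  expect_equal(length(sel$final$terms), 1)
  expect_equal(sum(sel$trace$action == "drop"), 1)  # candidate examined once
  expect_false(sel$trace$accepted[sel$trace$action == "drop"])
})

test_that("selection never returns a worse GCV than the full model", {
  for (seed in c(31, 32, 33)) {
    tab <- simulate_covariate_table(sim_config(seed = seed))
    sel <- backwards_select(tab, list(smooth2_term("HR_temp", "P"),
                                      smooth_term("M"),
                                      smooth_term("HR_discharge")))
    expect_lte(sel$final$gcv, sel$full$gcv * 1.001)
    # accepted removals are monotone in GCV (collapse steps are accepted
    # on the edf rule, not on GCV, so they are excluded here)
    drops <- sel$trace$accepted & sel$trace$action != "collapse"
    expect_true(all(diff(sel$trace$gcv[drops]) <= 1e-8))
  }
})

test_that("selection recovers the generating structure in the majority of
          replicates", {
  hits <- vapply(1:20, function(r) {
    tab <- simulate_covariate_table(sim_config(seed = 300 + r))
    sel <- backwards_select(tab, list(smooth2_term("HR_temp", "P"),
                                      smooth_term("M"),
                                      smooth_term("HR_discharge")))
    vars <- unlist(lapply(sel$final$terms, `[[`, "vars"))
    kinds <- vapply(sel$final$terms, `[[`, character(1), "kind")
    any(kinds == "smooth2") && "HR_discharge" %in% vars &&
      !("M" %in% vars)
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("the F-ratio test flags identical models and rejects wrongly
          dropped active terms", {
  set.seed(11)
  z <- rnorm(300)
  tab <- data.frame(UDC = rpois(300, exp(0.5 + 0.4 * z)), z = z)
  f <- occurrence_gam(tab, list(smooth_term("z")))
  same <- f_ratio_test(f, f)
  expect_identical(same$note, "identical models")
  expect_true(is.na(same$F))

  # power: dropping the active term is detected essentially always
  rej <- vapply(1:15, function(r) {
    set.seed(4000 + r)
    z <- rnorm(300); w <- rnorm(300)
    tab <- data.frame(UDC = rpois(300, exp(0.5 + 0.6 * z)), z = z, w = w)
    full <- occurrence_gam(tab, list(smooth_term("z"), linear_term("w")))
    wrong <- occurrence_gam(tab, list(linear_term("w")))
    f_ratio_test(wrong, full)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.9)

  # non-nested models are refused
  set.seed(12)
  tab2 <- data.frame(UDC = rpois(100, 2), a = rnorm(100), b = rnorm(100))
  fa <- occurrence_gam(tab2, list(smooth_term("a")))
  fb <- occurrence_gam(tab2, list(smooth_term("b")))
  expect_error(f_ratio_test(fa, fb), "subset")
})

test_that("the fitted interaction surface reproduces the planted winter
          peak and the discharge sign", {
  tab <- simulate_covariate_table(sim_config(seed = 41))
  truth <- attr(tab, "truth")
  fit <- occurrence_gam(tab, list(smooth2_term("HR_temp", "P"),
                                  linear_term("HR_discharge")))
  # cold water + short days >> warm water + long days
  g <- data.frame(HR_temp = c(2, 25), P = c(9.5, 15),
                  HR_discharge = median(tab$HR_discharge))
  pr <- predict(fit, g, type = "response")
  expect_gt(pr[1], 10 * pr[2])
  # negative planted discharge slope is recovered in sign
  expect_lt(unname(coef(fit)["HR_discharge"]), 0)

  # fitted surface correlates with planted intensity on the response scale
  pr_all <- predict(fit, tab, type = "response")
  expect_gt(cor(pr_all, truth$lambda), 0.9)

  surf <- interaction_surface(fit, n = 15)
  expect_true(all(c("HR_temp", "P", "link", "response",
                    "extrapolated") %in% names(surf)))
  expect_true(any(surf$extrapolated))    # grid corners leave the data hull
  inhull <- surf[!surf$extrapolated, ]
  cold_short <- inhull$response[inhull$HR_temp < 8 & inhull$P < 10.5]
  warm_long <- inhull$response[inhull$HR_temp > 20 & inhull$P > 13.5]
  expect_gt(min(1, mean(cold_short)), mean(warm_long))
  expect_error(interaction_surface(occurrence_gam(tab,
                                                  list(smooth_term("M")))),
               "2-d")
})

test_that("a constant planted surface yields flat predictions", {
  set.seed(55)
  n <- 300
  tab <- data.frame(UDC = rpois(n, 3), a = rnorm(n), b = rnorm(n))
  fit <- occurrence_gam(tab, list(smooth2_term("a", "b")))
  pr <- predict(fit, tab, type = "response")
  expect_lt(diff(range(pr)) / mean(pr), 0.6)
  expect_lt(unname(fit$edf[1]), 6)
})
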