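# simulated cohorts for recovery checks
sim_gaussian_cohort <- function(n, mu_fun, sigma = 0.1, delta_site = 0,
                                seed = 1) {
  set.seed(seed)
  age <- runif(n, 6, 88)
  sex <- sample(c("f", "m"), n, TRUE)
  site <- sample(c("A", "B"), n, TRUE)
  data.frame(age = age, sex = sex, site = site,
             m = mu_fun(age) + delta_site * (site == "B") +
               rnorm(n, 0, sigma))
}

test_that("constant-parameter data are recovered within Monte Carlo error", {
  d <- sim_gaussian_cohort(2000, function(a) rep(5, length(a)),
                           sigma = 0.5, seed = 21)
  fit <- fit_normative_model(d, "m",
                             normative_config(family = "gaussian",
                                              log10 = FALSE))
  mu_hat <- predict_quantiles(fit, seq(10, 84, by = 2), 0.5)
  expect_lt(max(abs(mu_hat - 5)), 2 * 0.5 / sqrt(2000) * 5)
})

test_that("a pure-noise metric yields a flat fitted location", {
  d <- sim_gaussian_cohort(2000, function(a) rep(0, length(a)),
                           sigma = 1, seed = 22)
  fit <- fit_normative_model(d, "m",
                             normative_config(family = "gaussian",
                                              log10 = FALSE))
  mu_hat <- predict_quantiles(fit, seq(8, 86, by = 1), 0.5)
  expect_lt(diff(range(mu_hat)), 0.1 * 1)
})

test_that("smooth trajectories are recovered well under the RMSE bound", {
  mu_fun <- function(a) 3 + 0.5 * exp(-a / 15) - 0.002 * a
  d <- sim_gaussian_cohort(800, mu_fun, sigma = 0.1, seed = 23)
  fit <- fit_normative_model(d, "m",
                             normative_config(family = "gaussian",
                                              log10 = FALSE))
  ages <- seq(8, 86, by = 2)
  med <- predict_quantiles(fit, ages, 0.5)
  expect_lt(sqrt(mean((med - mu_fun(ages))^2)), 0.5 * 0.1)
})

test_that("site offsets are recovered and harmonize the residuals", {
  delta <- 0.3
  d <- sim_gaussian_cohort(2000, function(a) 2 + 0.01 * a, sigma = 0.1,
                           delta_site = delta, seed = 24)
  fit <- fit_normative_model(d, "m",
                             normative_config(family = "gaussian",
                                              log10 = FALSE))
  K <- ncol(cortexscales:::pspline_basis(50, fit$knots, fit$degree))
  offs <- fit$beta[[1]][K + seq_along(fit$site_levels)]
  est <- offs[2] - offs[1]
  expect_lt(abs(est - delta) / delta, 0.10)

  # harmonization: site offsets absorb > 80% of the between-site gap
  sc <- deviation_score(fit, d)
  gap_fit <- abs(mean(sc[d$site == "B"]) - mean(sc[d$site == "A"]))
  gap_raw <- delta / 0.1  # raw z-scale between-site difference
  expect_lt(gap_fit, 0.2 * gap_raw)
})

test_that("quantile machinery matches closed forms for the gaussian family", {
  d <- sim_gaussian_cohort(500, function(a) rep(0, length(a)), sigma = 1,
                           seed = 25)
  fit <- fit_normative_model(d, "m",
                             normative_config(family = "gaussian",
                                              log10 = FALSE))
  # inject exact standard-normal parameters to isolate the inversion
  fitc <- fit
  K <- ncol(cortexscales:::pspline_basis(50, fit$knots, fit$degree))
  fitc$beta[[1]][] <- 0
  fitc$beta[[2]][] <- 0
  # basis rows sum to 1, so constant coefficient vectors give constants
  q75 <- predict_quantiles(fitc, c(20, 50, 80), 0.75)
  expect_equal(unname(q75), rep(qnorm(0.75), 3), tolerance = 1e-9)
  expect_equal(unname(predict_quantiles(fitc, 50, 0.5)), 0,
               tolerance = 1e-9)
  expect_error(predict_quantiles(fit, 50, 1.2),
               class = "cs_validation_error")

  band <- trajectory_band(fit, seq(10, 80, by = 5))
  expect_true(all(band$lower <= band$center & band$center <= band$upper))
})

test_that("deviation scores are calibrated and anchored at the quantiles", {
  d <- sim_gaussian_cohort(2000, function(a) 1 + 0.01 * a, sigma = 0.2,
                           seed = 26)
  fit <- fit_normative_model(d, "m",
                             normative_config(family = "gaussian",
                                              log10 = FALSE))
  # observation at the fitted median and 0.975 quantile
  one <- d[7, , drop = FALSE]
  eta <- cortexscales:::model_eta(fit, one$age, one$sex, one$site)
  pars <- cortexscales:::family_spec("gaussian")$linkinv(eta)
  one$m <- pars$mu
  expect_equal(as.numeric(deviation_score(fit, one)), 0, tolerance = 1e-9)
  one$m <- pars$mu + qnorm(0.975) * pars$sigma
  expect_equal(as.numeric(deviation_score(fit, one)), qnorm(0.975),
               tolerance = 1e-9)

  sim <- d
  sim$m <- simulate_normative(fit, d, seed = 8)
  sc <- deviation_score(fit, sim)
  expect_gt(stats::ks.test(sc, "pnorm")$p.value, 0.01)

  # unseen site: scored with zero offset and flagged
  new1 <- d[1, , drop = FALSE]
  new1$site <- "Z"
  expect_warning(s <- deviation_score(fit, new1), "unseen")
  expect_true(attr(s, "unseen_site"))
})

test_that("the bcpe family fits its own simulations and stays monotone", {
  co <- lifespan_cohort()
  fit <- fit_normative_model(co, "T@1.86", normative_config())
  expect_true(fit$converged)
  expect_true(all(diff(fit$deviance_path) <= 1e-6))
  sim <- co
  sim[["T@1.86"]] <- simulate_normative(fit, co, seed = 12)
  sc <- deviation_score(fit, sim)
  expect_gt(stats::ks.test(sc, "pnorm")$p.value, 0.01)
})

test_that("bcpe distribution functions are coherent", {
  # tau = 2, nu = 1 is close to a normal on the transformed scale
  x <- seq(0.5, 2, by = 0.01)
  expect_equal(pbcpe(qbcpe(c(0.1, 0.5, 0.9))), c(0.1, 0.5, 0.9),
               tolerance = 1e-9)
  dd <- dbcpe(x, mu = 1, sigma = 0.1, nu = 1, tau = 2)
  expect_equal(sum(dd) * 0.01, 1, tolerance = 1e-3)  # integrates to 1
  expect_equal(qbcpe(0.5, mu = 3, sigma = 0.1, nu = 1, tau = 2), 3,
               tolerance = 1e-9)
})

test_that("the fitter agrees with an independent location-scale smoother", {
  mu_fun <- function(a) 2 + 0.8 * exp(-a / 20)
  d <- sim_gaussian_cohort(1500, mu_fun, sigma = 0.15, seed = 27)
  fit <- fit_normative_model(d, "m",
                             normative_config(family = "gaussian",
                                              log10 = FALSE))
  ages <- seq(10, 84, by = 2)
  med <- predict_quantiles(fit, ages, 0.5)
  g <- mgcv::gam(list(m ~ s(age) + sex + site, ~ s(age)),
                 family = mgcv::gaulss(), data = d)
  ref <- 0
  for (sx in c("f", "m")) for (st in c("A", "B")) {
    w <- mean(d$sex == sx) * mean(d$site == st)
    nd <- data.frame(age = ages,
                     sex = factor(sx, levels = c("f", "m")),
                     site = factor(st, levels = c("A", "B")))
    ref <- ref + w * predict(g, newdata = nd)[, 1]
  }
  expect_lt(sqrt(mean((med - ref)^2)), 0.05)
})

test_that("models serialize to JSON and back without loss", {
  d <- sim_gaussian_cohort(300, function(a) 1 + 0.01 * a, sigma = 0.1,
                           seed = 28)
  fit <- fit_normative_model(d, "m",
                             normative_config(family = "gaussian",
                                              log10 = FALSE))
  tf <- tempfile(fileext = ".json")
  normative_to_json(fit, tf)
  fit2 <- normative_from_json(tf)
  ages <- seq(10, 80, by = 10)
  expect_equal(predict_quantiles(fit2, ages, 0.25),
               predict_quantiles(fit, ages, 0.25), tolerance = 1e-9)
})

test_that("input contracts are enforced", {
  d <- sim_gaussian_cohort(30, function(a) rep(1, length(a)), seed = 29)
  expect_error(fit_normative_model(d, "m"), class = "cs_validation_error")
  d2 <- sim_gaussian_cohort(100, function(a) rep(-1, length(a)), seed = 30)
  expect_error(fit_normative_model(d2, "m", normative_config(log10 = TRUE)),
               class = "cs_validation_error")
  expect_error(fit_normative_model(d2, "nope"),
               class = "cs_validation_error")
})
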