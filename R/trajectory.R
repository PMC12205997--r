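#' Normative model configuration
#'
#' Defaults for the location-scale-shape trajectory fits: Box-Cox power
#' exponential family on log10-transformed metrics, cubic P-spline age
#' smooths (20 equally spaced knots on the fitted age range, second-order
#' difference penalty) on every distribution parameter, site offsets on
#' location and scale, sex offsets on location, scale and skew, both
#' ridge-shrunk as a stand-in for random-effect variance. Smoothing
#' strength is picked from a small grid by generalized AIC.
#'
#' @param family `"bcpe"` (4-parameter) or `"gaussian"` (location-scale).
#' @param log10 fit the metric on the log10 scale.
#' @param age_range knot range in years.
#' @param n_knots number of equally spaced knots.
#' @param degree B-spline degree.
#' @param diff_order difference-penalty order.
#' @param lambda_base per-parameter base smoothing weights.
#' @param lambda_grid multipliers tried by the GAIC grid search.
#' @param ridge ridge weight on site/sex offsets.
#' @param tol outer-loop absolute deviance convergence tolerance.
#' @param max_iter maximum outer iterations.
#' @param warmup outer iterations with shape parameters frozen.
#' @export
normative_config <- function(family = c("bcpe", "gaussian"),
                             log10 = TRUE, age_range = c(6, 88),
                             n_knots = 20, degree = 3, diff_order = 2,
                             lambda_base = c(mu = 1, sigma = 10,
                                             nu = 10, tau = 10),
                             lambda_grid = c(1, 10, 100, 1000),
                             ridge = 0.01, tol = 1e-3, max_iter = 200,
                             warmup = 3) {
  list(family = match.arg(family), log10 = log10, age_range = age_range,
       n_knots = n_knots, degree = degree, diff_order = diff_order,
       lambda_base = lambda_base, lambda_grid = lambda_grid,
       ridge = ridge, tol = tol, max_iter = max_iter, warmup = warmup)
}

pspline_knots <- function(age_range, n_knots, degree) {
  h <- diff(age_range) / (n_knots - 1)
  c(age_range[1] - (degree:1) * h,
    seq(age_range[1], age_range[2], length.out = n_knots),
    age_range[2] + (1:degree) * h)
}

pspline_basis <- function(x, knots, degree) {
  x <- pmin(max(knots) - 1e-9, pmax(min(knots) + 1e-9, x))
  splines::splineDesign(knots, x, ord = degree + 1, outer.ok = TRUE)
}

# design matrix for one distribution parameter: [basis | sites | sex]
build_design <- function(age, sex, site, knots, degree, site_levels,
                         with_site, with_sex) {
  B <- pspline_basis(age, knots, degree)
  X <- B
  blocks <- list(basis = seq_len(ncol(B)))
  if (with_site) {
    S <- vapply(site_levels, function(s) as.numeric(site == s),
                numeric(length(age)))
    if (is.null(dim(S))) S <- matrix(S, nrow = length(age))
    blocks$site <- ncol(X) + seq_len(ncol(S))
    X <- cbind(X, S)
  }
  if (with_sex) {
    blocks$sex <- ncol(X) + 1L
    X <- cbind(X, as.numeric(sex == "m") - 0.5)
  }
  list(X = X, blocks = blocks)
}

penalty_matrix <- function(blocks, p, lambda, diff_order, ridge) {
  P <- diag(1e-8, p)
  K <- length(blocks$basis)
  D <- diff(diag(K), differences = diff_order)
  P[blocks$basis, blocks$basis] <-
    P[blocks$basis, blocks$basis] + lambda * crossprod(D)
  for (bl in c("site", "sex"))
    if (!is.null(blocks[[bl]]))
      P[blocks[[bl]], blocks[[bl]]] <-
        P[blocks[[bl]], blocks[[bl]]] + diag(ridge, length(blocks[[bl]]))
  P
}

#' Fit a normative lifespan trajectory model
#'
#' Penalized maximum-likelihood fit of a 4-parameter (or Gaussian
#' location-scale) distribution whose parameters vary smoothly with age
#' (P-splines) with additive site offsets on location and scale and sex
#' offsets on location, scale and skew. Fitting is cyclic backfitting
#' over the distribution parameters: each inner step is a penalized
#' weighted least-squares update on the working response built from
#' numerically evaluated score and curvature of the log-likelihood with
#' respect to that parameter's linear predictor, with step-halving so the
#' deviance never increases. The smoothing multiplier is selected on a
#' small grid by generalized AIC. Deterministic given data and config.
#'
#' @param data data.frame with columns `age`, `sex` ("f"/"m"), `site`,
#'   and the metric column.
#' @param metric name of the metric column.
#' @param config a [normative_config()].
#' @return object of class `normative_model`.
#' @export
fit_normative_model <- function(data, metric, config = normative_config()) {
  if (!metric %in% names(data))
    cs_stop(sprintf("metric column '%s' not in data", metric),
            "cs_validation_error")
  keep <- complete.cases(data[, c("age", "sex", "site", metric)])
  data <- data[keep, , drop = FALSE]
  n <- nrow(data)
  if (n < 50) cs_stop("need >= 50 observations", "cs_validation_error")
  y <- data[[metric]]
  if (config$log10) {
    if (any(y <= 0))
      cs_stop("log10 transform requires positive metric values",
              "cs_validation_error")
    y <- log10(y)
  }
  if (config$family == "bcpe" && any(y <= 0))
    cs_stop("bcpe family requires positive (transformed) values; disable log10 or use the gaussian family",
            "cs_validation_error")
  fam <- family_spec(config$family)
  site_levels <- sort(unique(as.character(data$site)))
  knots <- pspline_knots(config$age_range, config$n_knots, config$degree)
  with_site <- c(TRUE, TRUE, FALSE, FALSE)[seq_len(fam$npar)]
  with_sex <- c(TRUE, TRUE, TRUE, FALSE)[seq_len(fam$npar)]
  designs <- lapply(seq_len(fam$npar), function(j)
    build_design(data$age, data$sex, data$site, knots, config$degree,
                 site_levels, with_site[j], with_sex[j]))

  fit_once <- function(mult) {
    lambda <- config$lambda_base[seq_len(fam$npar)] * mult
    Pmats <- lapply(seq_len(fam$npar), function(j)
      penalty_matrix(designs[[j]]$blocks, ncol(designs[[j]]$X),
                     lambda[j], config$diff_order, config$ridge))
    # initialization: smooth location, constant dispersion/shape
    beta <- vector("list", fam$npar)
    init_target <- switch(fam$name, gaussian = y, bcpe = log(y))
    X1 <- designs[[1]]$X
    beta[[1]] <- solve(crossprod(X1) + Pmats[[1]], crossprod(X1, init_target))
    eta1 <- drop(X1 %*% beta[[1]])
    s0 <- sd(init_target - eta1)
    const_fit <- function(j, value) {
      Xj <- designs[[j]]$X
      drop(solve(crossprod(Xj) + Pmats[[j]],
                 crossprod(Xj, rep(value, n))))
    }
    if (fam$npar >= 2) beta[[2]] <- const_fit(2, log(max(s0, 1e-6)))
    if (fam$npar >= 3) beta[[3]] <- const_fit(3, 1)
    if (fam$npar >= 4) beta[[4]] <- const_fit(4, log(2))
    eta <- vapply(seq_len(fam$npar),
                  function(j) drop(designs[[j]]$X %*% beta[[j]]),
                  numeric(n))
    devi <- function(eta) -2 * sum(fam$loglik(y, fam$linkinv(eta)))
    dev <- devi(eta)
    dev_path <- dev
    converged <- FALSE
    for (it in seq_len(config$max_iter)) {
      dev_prev_outer <- dev
      active <- seq_len(fam$npar)
      if (it <= config$warmup && fam$npar > 2) active <- 1:2
      for (j in active) {
        Xj <- designs[[j]]$X
        h <- 1e-4 * (1 + abs(eta[, j]))
        ep <- em <- eta
        ep[, j] <- eta[, j] + h
        em[, j] <- eta[, j] - h
        ll0 <- fam$loglik(y, fam$linkinv(eta))
        llp <- fam$loglik(y, fam$linkinv(ep))
        llm <- fam$loglik(y, fam$linkinv(em))
        u <- (llp - llm) / (2 * h)
        wpp <- (llp - 2 * ll0 + llm) / h^2
        w <- pmax(-wpp, 1e-6)
        bad <- !is.finite(u) | !is.finite(w)
        u[bad] <- 0; w[bad] <- 1e-6
        z <- eta[, j] + pmin(20, pmax(-20, u / w))
        XtW <- t(Xj * w)
        new_beta <- tryCatch(
          drop(solve(XtW %*% Xj + Pmats[[j]], XtW %*% z)),
          error = function(e) beta[[j]])
        old_beta <- beta[[j]]
        step <- 1
        repeat {
          cand <- old_beta + step * (new_beta - old_beta)
          eta_c <- eta
          eta_c[, j] <- drop(Xj %*% cand)
          dev_c <- devi(eta_c)
          if (is.finite(dev_c) && dev_c <= dev + 1e-8) {
            beta[[j]] <- cand; eta <- eta_c; dev <- dev_c
            break
          }
          step <- step / 2
          if (step < 1e-4) break  # keep previous beta
        }
      }
      dev_path <- c(dev_path, dev)
      if (abs(dev_prev_outer - dev) < config$tol && it > config$warmup) {
        converged <- TRUE
        break
      }
    }
    # effective dof at the converged weights
    edf <- 0
    for (j in seq_len(fam$npar)) {
      Xj <- designs[[j]]$X
      h <- 1e-4 * (1 + abs(eta[, j]))
      ep <- em <- eta
      ep[, j] <- eta[, j] + h; em[, j] <- eta[, j] - h
      ll0 <- fam$loglik(y, fam$linkinv(eta))
      wpp <- (fam$loglik(y, fam$linkinv(ep)) - 2 * ll0 +
              fam$loglik(y, fam$linkinv(em))) / h^2
      w <- pmax(-wpp, 1e-6)
      XtWX <- t(Xj * w) %*% Xj
      edf <- edf + sum(diag(solve(XtWX + Pmats[[j]], XtWX)))
    }
    list(beta = beta, dev = dev, dev_path = dev_path, edf = edf,
         converged = converged, lambda = lambda)
  }

  fits <- lapply(config$lambda_grid, fit_once)
  gaic <- vapply(fits, function(f) f$dev + 2 * f$edf, numeric(1))
  best <- fits[[which.min(gaic)]]
  if (!best$converged)
    warning(sprintf("normative fit for '%s' did not converge within %d iterations",
                    metric, config$max_iter))
  sigma_chk <- fam$linkinv(vapply(seq_len(fam$npar), function(j)
    drop(designs[[j]]$X %*% best$beta[[j]]), numeric(n)))$sigma
  if (any(!is.finite(sigma_chk)) || any(sigma_chk <= 0))
    cs_stop("fitted sigma is not positive over the data", "cs_fit_error")

  structure(list(
    metric = metric, family = fam$name, log10 = config$log10,
    knots = knots, degree = config$degree, diff_order = config$diff_order,
    npar = fam$npar, beta = best$beta, lambda = best$lambda,
    ridge = config$ridge,
    with_site = with_site, with_sex = with_sex,
    site_levels = site_levels,
    site_prop = as.numeric(table(factor(data$site, site_levels)) / n),
    sex_prop = c(f = mean(data$sex == "f"), m = mean(data$sex == "m")),
    age_range = config$age_range, n = n,
    deviance = best$dev, deviance_path = best$dev_path,
    edf = best$edf, gaic_grid = data.frame(multiplier = config$lambda_grid,
                                           gaic = gaic),
    converged = best$converged), class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf(
    "normative_model [%s] for '%s'%s: n = %d, deviance = %.2f, edf = %.1f%s\n",
    x$family, x$metric, if (x$log10) " (log10)" else "", x$n, x$deviance,
    x$edf, if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

# linear predictors for arbitrary subjects; unseen sites get zero offset
model_eta <- function(model, age, sex, site) {
  n <- length(age)
  unseen <- !(as.character(site) %in% model$site_levels)
  eta <- matrix(0, n, model$npar)
  for (j in seq_len(model$npar)) {
    d <- build_design(age, sex, site, model$knots, model$degree,
                      model$site_levels, model$with_site[j],
                      model$with_sex[j])
    eta[, j] <- drop(d$X %*% model$beta[[j]])
  }
  attr(eta, "unseen_site") <- unseen
  eta
}

# marginal (population) distribution parameters: site offsets averaged by
# training proportions on the predictor scale, then the sex-specific
# natural-parameter sets averaged by training sex proportions
marginal_parameters <- function(model, ages) {
  n <- length(ages)
  pars_by_sex <- lapply(c("f", "m"), function(sx) {
    eta <- matrix(0, n, model$npar)
    for (j in seq_len(model$npar)) {
      B <- pspline_basis(ages, model$knots, model$degree)
      beta <- model$beta[[j]]
      K <- ncol(B)
      etaj <- drop(B %*% beta[seq_len(K)])
      pos <- K
      if (model$with_site[j]) {
        offs <- beta[pos + seq_along(model$site_levels)]
        etaj <- etaj + sum(offs * model$site_prop)
        pos <- pos + length(model$site_levels)
      }
      if (model$with_sex[j])
        etaj <- etaj + beta[pos + 1L] * ((sx == "m") - 0.5)
      eta[, j] <- etaj
    }
    family_spec(model$family)$linkinv(eta)
  })
  w <- model$sex_prop[c("f", "m")]
  pars <- lapply(names(pars_by_sex[[1]]), function(p)
    w[1] * pars_by_sex[[1]][[p]] + w[2] * pars_by_sex[[2]][[p]])
  names(pars) <- names(pars_by_sex[[1]])
  pars
}

#' Population quantile curves
#'
#' Inverse-CDF of the fitted family at the marginalized distribution
#' parameters (sex-specific parameter sets averaged with the cohort sex
#' proportions; site offsets averaged with site proportions), producing a
#' single overall trajectory. Values are on the fitted scale (log10 if
#' the model was fitted on log10).
#'
#' @param model a `normative_model`.
#' @param ages age grid (years).
#' @param q quantile in (0, 1).
#' @return numeric vector of quantile values over `ages`.
#' @export
predict_quantiles <- function(model, ages, q = 0.5) {
  if (q <= 0 || q >= 1)
    cs_stop("q must be in (0, 1)", "cs_validation_error")
  if (any(ages < model$age_range[1] - 1e-9) ||
      any(ages > model$age_range[2] + 1e-9))
    warning("extrapolating outside the fitted age range")
  pars <- marginal_parameters(model, ages)
  family_spec(model$family)$quantile(q, pars)
}

#' Interquartile trajectory band
#'
#' @param model a `normative_model`.
#' @param ages age grid.
#' @param probs lower/center/upper quantiles.
#' @return data.frame `age`, `lower`, `center`, `upper`.
#' @export
trajectory_band <- function(model, ages, probs = c(0.25, 0.5, 0.75)) {
  data.frame(age = ages,
             lower = predict_quantiles(model, ages, probs[1]),
             center = predict_quantiles(model, ages, probs[2]),
             upper = predict_quantiles(model, ages, probs[3]))
}

#' Individual deviation scores
#'
#' Quantile-residual style score: the standard-normal inverse of the
#' fitted CDF at the observation, using the subject's own sex and site
#' offsets. Subjects from sites unseen in training are scored with a zero
#' site offset and flagged in the `unseen_site` attribute.
#'
#' @param model a `normative_model`.
#' @param newdata data.frame with `age`, `sex`, `site` and the metric
#'   column.
#' @return numeric scores with attribute `unseen_site`.
#' @export
deviation_score <- function(model, newdata) {
  y <- newdata[[model$metric]]
  if (model$log10) y <- log10(y)
  eta <- model_eta(model, newdata$age, newdata$sex, newdata$site)
  if (any(attr(eta, "unseen_site")))
    warning("site(s) unseen in training scored with zero site offset")
  pars <- family_spec(model$family)$linkinv(eta)
  Fv <- family_spec(model$family)$cdf(y, pars)
  Fv <- pmin(1 - 1e-12, pmax(1e-12, Fv))
  out <- qnorm(Fv)
  attr(out, "unseen_site") <- attr(eta, "unseen_site")
  out
}

#' Simulate observations from a fitted normative model
#'
#' Draws metric values at the covariates of `newdata` from the fitted
#' conditional distribution (back-transformed from log10 if needed);
#' used for calibration checks of the deviation scores.
#'
#' @param model a `normative_model`.
#' @param newdata data.frame with `age`, `sex`, `site`.
#' @param seed optional integer seed.
#' @return numeric vector on the original metric scale.
#' @export
simulate_normative <- function(model, newdata, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eta <- model_eta(model, newdata$age, newdata$sex, newdata$site)
  pars <- family_spec(model$family)$linkinv(eta)
  y <- family_spec(model$family)$rand(nrow(newdata), pars)
  if (model$log10) 10^y else y
}

#' Serialize / restore a normative model as JSON
#'
#' @param model a `normative_model`.
#' @param path file path.
#' @export
normative_to_json <- function(model, path) {
  obj <- unclass(model)
  obj$beta <- lapply(obj$beta, as.numeric)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname normative_to_json
#' @export
normative_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = FALSE)
  obj$beta <- lapply(obj$beta, as.numeric)
  obj$sex_prop <- stats::setNames(as.numeric(unlist(obj$sex_prop)),
                                  c("f", "m"))
  obj$gaic_grid <- as.data.frame(obj$gaic_grid)
  structure(obj, class = "normative_model")
}
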