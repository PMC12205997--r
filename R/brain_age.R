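#' Assemble a brain-age modelling table
#'
#' Pulls the two surface-area predictors (native scale and 1.86 mm) out
#' of a cohort table into syntactic column names for the additive models.
#'
#' @param cohort cohort data.frame (see [make_cohort()]).
#' @param native_col,coarse_col names of the predictor columns.
#' @return data.frame with `age`, `sex`, `site`, `at_native`, `at_coarse`.
#' @export
brainage_data <- function(cohort, native_col = "At@native",
                          coarse_col = "At@1.86") {
  for (cl in c(native_col, coarse_col))
    if (!cl %in% names(cohort))
      cs_stop(sprintf("column '%s' not in cohort", cl),
              "cs_validation_error")
  data.frame(age = cohort$age,
             sex = factor(cohort$sex),
             site = factor(cohort$site),
             at_native = cohort[[native_col]],
             at_coarse = cohort[[coarse_col]])
}

#' Fit a brain-age additive model
#'
#' Age regressed on thin-plate spline smooths of surface area with fixed
#' effects of sex and site (`mgcv::gam`, GCV smoothing selection):
#' model `"native"` uses the native-scale area, `"coarse"` the 1.86 mm
#' area, `"both"` the two smooths together. Adjusted R^2 is
#' `1 - (1 - R^2) (n - 1) / (n - edf - 1)` with `edf` the total effective
#' degrees of freedom of the penalized fit (intercept excluded), so the
#' penalty reflects the actual flexibility spent, not the raw coefficient
#' count. Factors with a single level are dropped with a warning.
#'
#' @param table a [brainage_data()] frame.
#' @param model `"native"`, `"coarse"` or `"both"`.
#' @param k basis dimension per smooth.
#' @return object of class `brain_age_model`.
#' @export
fit_brain_age <- function(table, model = c("both", "native", "coarse"),
                          k = 10) {
  model <- match.arg(model)
  table <- droplevels(table)
  terms <- switch(model,
    native = "s(at_native, k = %d, bs = \"tp\")",
    coarse = "s(at_coarse, k = %d, bs = \"tp\")",
    both = "s(at_native, k = %d, bs = \"tp\") + s(at_coarse, k = %d, bs = \"tp\")")
  rhs <- if (model == "both") sprintf(terms, k, k) else sprintf(terms, k)
  for (fx in c("sex", "site")) {
    if (nlevels(table[[fx]]) > 1L) {
      rhs <- paste(rhs, "+", fx)
    } else {
      warning(sprintf("factor '%s' has a single level; term dropped", fx))
    }
  }
  fml <- stats::as.formula(paste("age ~", rhs))
  fit <- mgcv::gam(fml, data = table, method = "GCV.Cp")
  n <- nrow(table)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((table$age - mean(table$age))^2)
  r2 <- 1 - rss / tss
  edf <- sum(fit$edf) - 1  # exclude intercept
  adj <- 1 - (1 - r2) * (n - 1) / (n - edf - 1)
  structure(list(model_id = model, fit = fit, n = n, r2 = r2, edf = edf,
                 adj_r2 = adj, k = k),
            class = "brain_age_model")
}

#' @export
print.brain_age_model <- function(x, ...) {
  cat(sprintf("brain_age_model [%s]: n = %d, edf = %.1f, adjusted R^2 = %.3f\n",
              x$model_id, x$n, x$edf, x$adj_r2))
  invisible(x)
}

#' Bootstrap distributions of adjusted R^2
#'
#' Case-resampling bootstrap: subjects are resampled with replacement and
#' each model refitted per replicate. Identical seeds give identical
#' samples. Replicates where a factor loses all but one level are refitted
#' without that term and flagged.
#'
#' @param table a [brainage_data()] frame.
#' @param models model ids to bootstrap.
#' @param B number of replicates.
#' @param seed integer seed.
#' @param k basis dimension per smooth.
#' @param resample optional function `(n, b) -> indices` overriding the
#'   default `sample(n, replace = TRUE)` (e.g. identity for tests).
#' @return object of class `bootstrap_result`: data.frame `samples`
#'   (`model`, `replicate`, `adj_r2`, `flagged`), plus `B`, `seed` and a
#'   per-model summary (median, IQR).
#' @export
bootstrap_adjusted_r2 <- function(table, models = c("native", "coarse", "both"),
                                  B = 1000, seed = 1L, k = 10,
                                  resample = NULL) {
  if (B < 1) cs_stop("B must be >= 1", "cs_validation_error")
  set.seed(seed)
  n <- nrow(table)
  idx_list <- lapply(seq_len(B), function(b)
    if (is.null(resample)) sample.int(n, replace = TRUE) else resample(n, b))
  out <- list()
  for (m in models) {
    vals <- numeric(B)
    flag <- logical(B)
    for (b in seq_len(B)) {
      tb <- table[idx_list[[b]], , drop = FALSE]
      res <- withCallingHandlers(
        fit_brain_age(tb, model = m, k = k),
        warning = function(w) {
          flag[b] <<- TRUE
          invokeRestart("muffleWarning")
        })
      vals[b] <- res$adj_r2
    }
    out[[m]] <- data.frame(model = m, replicate = seq_len(B),
                           adj_r2 = vals, flagged = flag,
                           stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, out)
  rownames(samples) <- NULL
  summ <- do.call(rbind, lapply(split(samples$adj_r2, samples$model),
    function(v) data.frame(median = median(v),
                           q25 = quantile(v, 0.25),
                           q75 = quantile(v, 0.75))))
  summ$model <- rownames(summ)
  rownames(summ) <- NULL
  structure(list(samples = samples, B = B, seed = seed,
                 summary = summ[, c("model", "median", "q25", "q75")]),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap_result: B = %d, seed = %d\n", x$B, x$seed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Predicted versus chronological age
#'
#' Per-subject predictions of a fitted brain-age model paired with
#' chronological age, plus the least-squares slope of predicted on
#' actual age. With noisy predictors the slope attenuates strictly below
#' 1 (regression toward the mean); no bias correction is applied.
#'
#' @param model a `brain_age_model`.
#' @param table a [brainage_data()] frame.
#' @return list with `data` (data.frame `age`, `predicted`) and `slope`.
#' @export
predicted_vs_actual <- function(model, table) {
  pred <- as.numeric(predict(model$fit, newdata = table))
  slope <- stats::cov(pred, table$age) / stats::var(table$age)
  list(data = data.frame(age = table$age, predicted = pred),
       slope = slope)
}
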