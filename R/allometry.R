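# Allometric scaling of surface area on volume.
#
# Ordinary least squares of log10(SA) on log10(V); the slope is the scaling
# exponent beta, compared against the isometric expectation of 2/3 and
# across measurement methods via a log(volume) x method interaction model.

#' Fit the log-log scaling of surface area on volume
#'
#' @param surface_areas,volumes Positive numeric vectors (mm^2, mm^3).
#' @param method Optional method label stored in the result.
#' @param conf_level Confidence level for the slope CI (default 0.95).
#' @return A `scaling_fit` list: `method`, `beta` (slope), `beta_se`,
#'   `alpha` (intercept, log10 units), `r_squared`, `beta_ci_low`,
#'   `beta_ci_high`, `p_value` (slope = 0), `n`, `df`, and the underlying
#'   `lm` fit. With n = 2 the fit is exact and CI/p are `NA` with
#'   `ci_defined = FALSE`.
#' @export
fit_scaling <- function(surface_areas, volumes, method = NA_character_,
                        conf_level = 0.95) {
  n <- length(surface_areas)
  if (n != length(volumes) || n < 2) {
    stop("fit_scaling: need >= 2 paired values", call. = FALSE)
  }
  if (any(surface_areas <= 0) || any(volumes <= 0)) {
    stop("fit_scaling: surface areas and volumes must be positive",
         call. = FALSE)
  }
  df <- data.frame(lsa = log10(surface_areas), lv = log10(volumes))
  fit <- stats::lm(lsa ~ lv, data = df)
  cf <- stats::coef(fit)
  out <- list(method = method, beta = unname(cf["lv"]),
              alpha = unname(cf["(Intercept)"]),
              r_squared = summary(fit)$r.squared,
              n = n, df = n - 2L, fit = fit, conf_level = conf_level)
  if (n > 2) {
    sm <- summary(fit)$coefficients
    out$beta_se <- sm["lv", "Std. Error"]
    out$p_value <- sm["lv", "Pr(>|t|)"]
    ci <- stats::confint(fit, "lv", level = conf_level)
    out$beta_ci_low <- ci[1]
    out$beta_ci_high <- ci[2]
    out$ci_defined <- TRUE
  } else {
    out$beta_se <- NA_real_
    out$p_value <- NA_real_
    out$beta_ci_low <- NA_real_
    out$beta_ci_high <- NA_real_
    out$ci_defined <- FALSE
  }
  class(out) <- "scaling_fit"
  out
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf(
    "<scaling_fit>%s beta = %.4g, alpha = %.4g, R^2 = %.3f, n = %d\n",
    if (is.na(x$method)) "" else paste0(" [", x$method, "]"),
    x$beta, x$alpha, x$r_squared, x$n))
  if (x$ci_defined) {
    cat(sprintf("  %g%% CI beta (%.4g, %.4g), p = %.4g\n",
                100 * x$conf_level, x$beta_ci_low, x$beta_ci_high,
                x$p_value))
  } else {
    cat("  CI undefined (saturated fit)\n")
  }
  invisible(x)
}

#' Test a scaling fit against isometry
#'
#' Two-sided Wald t-test of H0: beta = `beta0` (default 2/3, the isometric
#' expectation for surface area on volume) using the slope's standard error;
#' algebraically identical to a single linear-hypothesis test on the slope.
#'
#' @param fit A [fit_scaling()] result with at least 1 residual df.
#' @param beta0 Null scaling exponent (default 2/3).
#' @return List: `t_statistic`, `df`, `p_value`, `beta0`.
#' @export
test_isometry <- function(fit, beta0 = 2 / 3) {
  stopifnot(inherits(fit, "scaling_fit"))
  if (fit$df < 1 || !fit$ci_defined) {
    stop("degenerate_fit: isometry test needs residual df >= 1",
         call. = FALSE)
  }
  if (fit$beta_se == 0) {
    t <- if (fit$beta == beta0) 0 else sign(fit$beta - beta0) * Inf
  } else {
    t <- (fit$beta - beta0) / fit$beta_se
  }
  p <- 2 * stats::pt(-abs(t), df = fit$df)
  list(t_statistic = t, df = fit$df, p_value = p, beta0 = beta0)
}

#' Compare scaling across measurement methods
#'
#' Fits the full-interaction model `log10(SA) ~ log10(V) * method` over a
#' combined size table and reports per-contrast interaction p-values (do the
#' slopes differ between methods?), the overall interaction F-test, a
#' per-method [fit_scaling()], and each method's isometry test.
#'
#' @param data Data frame with columns `surface_area_mm2`, `volume_mm3`,
#'   `method` (>= 2 methods, each with >= 3 points).
#' @return A `method_comparison` list: `fits` (named list of scaling fits),
#'   `isometry` (named list of [test_isometry()] results),
#'   `interaction_p_values` (per method contrast vs the reference method),
#'   `interaction_F`, `interaction_p` (overall), `model` (the `lm`),
#'   `anova` (the sequential ANOVA table).
#' @export
compare_methods <- function(data) {
  need <- c("surface_area_mm2", "volume_mm3", "method")
  if (!all(need %in% names(data))) {
    stop("compare_methods: data needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  methods <- unique(data$method)
  if (length(methods) < 2) {
    stop("compare_methods: need at least two methods", call. = FALSE)
  }
  counts <- table(data$method)
  if (any(counts < 3)) {
    stop("compare_methods: every method needs >= 3 points", call. = FALSE)
  }
  if (any(data$surface_area_mm2 <= 0) || any(data$volume_mm3 <= 0)) {
    stop("compare_methods: values must be positive", call. = FALSE)
  }
  d <- data.frame(lsa = log10(data$surface_area_mm2),
                  lv = log10(data$volume_mm3),
                  method = factor(data$method))
  full <- stats::lm(lsa ~ lv * method, data = d)
  an <- stats::anova(full)
  sm <- summary(full)$coefficients
  inter <- grep("^lv:method", rownames(sm), value = TRUE)
  interaction_p <- stats::setNames(sm[inter, "Pr(>|t|)"],
                                   sub("^lv:method", "", inter))
  fits <- lapply(levels(d$method), function(mt) {
    sel <- data$method == mt
    fit_scaling(data$surface_area_mm2[sel], data$volume_mm3[sel],
                method = mt)
  })
  names(fits) <- levels(d$method)
  iso <- lapply(fits, test_isometry)
  structure(list(fits = fits, isometry = iso,
                 interaction_p_values = interaction_p,
                 interaction_F = an["lv:method", "F value"],
                 interaction_p = an["lv:method", "Pr(>F)"],
                 model = full, anova = an),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison>\n")
  for (f in x$fits) print(f)
  cat(sprintf("  interaction: F = %.4g, p = %.4g\n", x$interaction_F,
              x$interaction_p))
  for (nm in names(x$isometry)) {
    cat(sprintf("  isometry [%s]: t = %.4g, p = %.4g\n", nm,
                x$isometry[[nm]]$t_statistic, x$isometry[[nm]]$p_value))
  }
  invisible(x)
}

#' Tabular view of scaling fits
#'
#' @param fits A list of `scaling_fit` objects (or a `method_comparison`).
#' @return Data frame mirroring the usual per-method fit report: beta,
#'   alpha, R^2, p, CI bounds, isometry p.
#' @export
scaling_fit_table <- function(fits) {
  if (inherits(fits, "method_comparison")) {
    iso <- fits$isometry
    fits <- fits$fits
  } else {
    iso <- lapply(fits, function(f) {
      if (f$df >= 1 && f$ci_defined) test_isometry(f) else
        list(p_value = NA_real_)
    })
  }
  do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(method = f$method, n = f$n, beta = f$beta, alpha = f$alpha,
               r_squared = f$r_squared, p_value = f$p_value,
               beta_ci_low = f$beta_ci_low, beta_ci_high = f$beta_ci_high,
               isometry_p = iso[[i]]$p_value, stringsAsFactors = FALSE)
  }))
}
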