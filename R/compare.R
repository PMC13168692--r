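# Paired comparison of geometric estimates against 3D-model measurements:
# percent error, mean signed error, normality-gated paired tests, and the
# multiplicative correction that inverts a known underestimation fraction.

#' Percent error of a geometric estimate against a model measurement
#'
#' `|geometric - model| / model * 100`. Vectorized.
#'
#' @param geometric,model Positive numeric vectors of equal length.
#' @return Percent errors (non-negative).
#' @export
percent_error <- function(geometric, model) {
  if (length(geometric) != length(model)) {
    stop("percent_error: inputs must have equal length", call. = FALSE)
  }
  if (any(!is.finite(model)) || any(model <= 0)) {
    stop("percent_error: model measurements must be positive", call. = FALSE)
  }
  abs(geometric - model) / model * 100
}

#' Mean signed error of paired measurements
#'
#' Mean of `geometric - model`; negative means the geometric method
#' underestimates.
#'
#' @inheritParams percent_error
#' @return A single number.
#' @export
mean_signed_error <- function(geometric, model) {
  if (length(geometric) != length(model)) {
    stop("mean_signed_error: inputs must have equal length", call. = FALSE)
  }
  mean(geometric - model)
}

#' Invert a known underestimation fraction
#'
#' Recovers the theoretical (model) size from a geometric estimate known to
#' underestimate it by `fraction`: `geometric * (1 - fraction)^-1`. The
#' argument is a *fraction* in [0, 1), not a percentage; divide percent
#' errors by 100 first.
#'
#' @param geometric_value Geometric estimate(s).
#' @param percent_error_fraction Underestimation fraction(s) in [0, 1).
#' @return Corrected value(s).
#' @export
corrected_size <- function(geometric_value, percent_error_fraction) {
  if (any(percent_error_fraction < 0 | percent_error_fraction >= 1)) {
    stop("corrected_size: fraction must be in [0, 1); got a percentage?",
         call. = FALSE)
  }
  geometric_value / (1 - percent_error_fraction)
}

#' Paired comparison of two measurement methods
#'
#' Tests whether geometric estimates differ from model measurements:
#' paired differences are checked for normality (Shapiro-Wilk at
#' `normality_alpha`); a paired t-test is used when the check passes, a
#' Wilcoxon signed-rank test otherwise (both statistics are always reported,
#' `test_used` names the gated choice). Percent error (mean +/- standard
#' error over specimens) and the mean signed error are computed over the
#' same pair set.
#'
#' @param geometric,model Positive paired measurement vectors (same
#'   specimens, same order), length >= 3.
#' @param normality_alpha Shapiro-Wilk significance gate (default 0.05).
#' @return A `paired_comparison` list: `n`, `t_statistic`, `df`,
#'   `t_p_value`, `wilcoxon_v`, `wilcoxon_p`, `normality_p`, `test_used`,
#'   `p_value`, `percent_error_mean`, `percent_error_se`,
#'   `mean_signed_error`.
#' @export
paired_comparison <- function(geometric, model, normality_alpha = 0.05) {
  n <- length(geometric)
  if (n != length(model)) {
    stop("paired_comparison: inputs must have equal length", call. = FALSE)
  }
  if (n < 3) {
    stop("insufficient_data: paired comparison needs n >= 3", call. = FALSE)
  }
  if (any(geometric <= 0) || any(model <= 0)) {
    stop("paired_comparison: measurements must be positive", call. = FALSE)
  }
  d <- geometric - model
  pe <- percent_error(geometric, model)
  out <- list(n = n,
              percent_error_mean = mean(pe),
              percent_error_se = stats::sd(pe) / sqrt(n),
              mean_signed_error = mean(d))
  if (all(d == 0) || stats::sd(d) == 0) {
    # degenerate: constant differences, no dispersion to test against
    out$t_statistic <- NA_real_
    out$df <- n - 1L
    out$t_p_value <- NA_real_
    out$wilcoxon_v <- NA_real_
    out$wilcoxon_p <- NA_real_
    out$normality_p <- NA_real_
    out$test_used <- "degenerate"
    out$p_value <- if (all(d == 0)) 1 else NA_real_
    class(out) <- "paired_comparison"
    return(out)
  }
  tt <- stats::t.test(geometric, model, paired = TRUE)
  wt <- suppressWarnings(stats::wilcox.test(geometric, model, paired = TRUE))
  sw <- stats::shapiro.test(d)
  out$t_statistic <- unname(tt$statistic)
  out$df <- unname(tt$parameter)
  out$t_p_value <- tt$p.value
  out$wilcoxon_v <- unname(wt$statistic)
  out$wilcoxon_p <- wt$p.value
  out$normality_p <- sw$p.value
  if (sw$p.value >= normality_alpha) {
    out$test_used <- "paired_t"
    out$p_value <- tt$p.value
  } else {
    out$test_used <- "wilcoxon_signed_rank"
    out$p_value <- wt$p.value
  }
  class(out) <- "paired_comparison"
  out
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf(
    "<paired_comparison> n = %d, %s: p = %.4g (t = %.4g, df = %g; normality p = %.3g)\n",
    x$n, x$test_used, x$p_value, x$t_statistic, x$df, x$normality_p))
  cat(sprintf("  %% error = %.3f +/- %.3f, mean signed error = %.3f\n",
              x$percent_error_mean, x$percent_error_se, x$mean_signed_error))
  invisible(x)
}

#' Method-comparison report over a paired size table
#'
#' Joins a geometric and a model size table on specimen and scope and runs
#' [paired_comparison()] for every scope x quantity cell, producing one row
#' per body region and measurement: test statistic, p-value, test used,
#' percent error (mean +/- SE) and mean signed error.
#'
#' @param geometric,model Long size tables (columns `specimen_id`, `scope`,
#'   `surface_area_mm2`, `volume_mm3`).
#' @param scopes Scopes to compare (default head, mesosoma, metasoma and the
#'   tagmata sum).
#' @param normality_alpha Shapiro-Wilk gate passed through.
#' @return A data frame, one row per scope x quantity.
#' @export
comparison_table <- function(geometric, model,
                             scopes = c(TAGMA_LABELS, "tagmata_sum"),
                             normality_alpha = 0.05) {
  rows <- list()
  for (sc in scopes) {
    g <- geometric[geometric$scope == sc, ]
    m <- model[model$scope == sc, ]
    ids <- intersect(g$specimen_id, m$specimen_id)
    if (length(ids) < 3) {
      stop("insufficient_data: fewer than 3 paired specimens for scope ", sc,
           call. = FALSE)
    }
    g <- g[match(ids, g$specimen_id), ]
    m <- m[match(ids, m$specimen_id), ]
    for (q in c("volume", "surface_area")) {
      col <- if (q == "volume") "volume_mm3" else "surface_area_mm2"
      cmp <- paired_comparison(g[[col]], m[[col]],
                               normality_alpha = normality_alpha)
      rows[[paste(sc, q)]] <- data.frame(
        scope = sc, quantity = q, n = cmp$n,
        t_statistic = cmp$t_statistic, p_value = cmp$p_value,
        test_used = cmp$test_used, normality_p = cmp$normality_p,
        wilcoxon_p = cmp$wilcoxon_p,
        percent_error_mean = cmp$percent_error_mean,
        percent_error_se = cmp$percent_error_se,
        mean_signed_error = cmp$mean_signed_error,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Per-tagma correction fractions from a comparison table
#'
#' Extracts the mean percent error (as a fraction) for each tagma's surface
#' area, zeroing tagmata whose comparison is not significant at `alpha`
#' (no evidence of bias means no correction), for use with
#' [apply_surface_correction()].
#'
#' @param comparison A [comparison_table()] result.
#' @param alpha Significance threshold (default 0.05).
#' @param only_significant Zero out non-significant tagmata (default
#'   `TRUE`).
#' @return Named numeric vector `c(head =, thorax =, abdomen =)` of
#'   fractions in [0, 1).
#' @export
correction_fractions <- function(comparison, alpha = 0.05,
                                 only_significant = TRUE) {
  sa <- comparison[comparison$quantity == "surface_area", ]
  pick <- function(scope) {
    row <- sa[sa$scope == scope, ]
    if (nrow(row) != 1) return(0)
    f <- row$percent_error_mean / 100
    if (only_significant && (is.na(row$p_value) || row$p_value >= alpha)) {
      return(0)
    }
    min(f, 0.999999)
  }
  c(head = pick("head"), thorax = pick("mesosoma"),
    abdomen = pick("metasoma"))
}
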