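#' Percent-difference Bland-Altman agreement
#'
#' Quantifies agreement between corrected and baseline NSE on the relative
#' scale: per pair, `100 * (corrected - baseline) / denominator`, where the
#' denominator is the pair mean (classical Bland-Altman ratio plot, the
#' default) or the baseline value. Reports the mean difference, the sample
#' (n-1) SD, and the 95% limits of agreement `mean +/- z * SD` with
#' z = 1.96. When the specimens' HI values are supplied, a Spearman rank
#' correlation of the percent differences against HI checks that the
#' residual bias is independent of hemolysis severity.
#'
#' @param baseline,corrected positive paired measurements (ug/L), length
#'   >= 2.
#' @param denominator `"mean"` or `"baseline"`.
#' @param hi optional HI values of the (hemolyzed) specimens; adds
#'   `spearman_r_vs_hi` / `spearman_p` to the result.
#' @param z limit-of-agreement multiplier (default 1.96 for 95% limits).
#' @return An object of class `"agreement_result"`: `mean_diff_pct`,
#'   `sd_diff_pct`, `loa_lower_pct`, `loa_upper_pct`, `n_pairs`, the
#'   per-pair `diff_pct` and `avg`, and optionally the Spearman fields.
#' @examples
#' bland_altman_percent(c(100, 100), c(110, 90), denominator = "baseline")
#' @export
bland_altman_percent <- function(baseline, corrected,
                                 denominator = c("mean", "baseline"),
                                 hi = NULL, z = 1.96) {
  denominator <- match.arg(denominator)
  if (length(baseline) != length(corrected))
    stop("baseline and corrected must have equal length")
  if (length(baseline) < 2L) stop("need at least 2 pairs")
  if (any(!is.finite(baseline)) || any(!is.finite(corrected)))
    stop("values must be finite")
  if (any(baseline <= 0) || any(corrected <= 0))
    stop("values must be positive")
  denom <- switch(denominator,
                  mean = (baseline + corrected) / 2,
                  baseline = baseline)
  diff_pct <- 100 * (corrected - baseline) / denom
  m <- mean(diff_pct)
  s <- stats::sd(diff_pct)
  loa <- loa_from_moments(m, s, z)
  res <- list(mean_diff_pct = m, sd_diff_pct = s,
              loa_lower_pct = loa[["lower"]], loa_upper_pct = loa[["upper"]],
              n_pairs = length(baseline), z = z, denominator = denominator,
              diff_pct = diff_pct, avg = (baseline + corrected) / 2,
              spearman_r_vs_hi = NA_real_, spearman_p = NA_real_)
  if (!is.null(hi)) {
    sp <- diff_vs_hi_independence(diff_pct, hi)
    res$spearman_r_vs_hi <- sp[["rho"]]
    res$spearman_p <- sp[["p"]]
  }
  structure(res, class = "agreement_result")
}

#' Limits of agreement from summary moments
#'
#' @param mean_pct mean percent difference.
#' @param sd_pct SD of percent differences (>= 0).
#' @param z multiplier (default 1.96).
#' @return Named numeric `c(lower, upper)` = `mean_pct -/+ z * sd_pct`.
#' @examples
#' loa_from_moments(1.92, 5.23)  # c(-8.33, 12.17) at 2 decimals
#' @export
loa_from_moments <- function(mean_pct, sd_pct, z = 1.96) {
  stopifnot(sd_pct >= 0, z >= 0)
  c(lower = mean_pct - z * sd_pct, upper = mean_pct + z * sd_pct)
}

#' Spearman independence of residual bias from HI
#'
#' Rank correlation between per-pair percent differences and the specimens'
#' HI, with the standard large-sample p-value. A correction that fully
#' removes the hemolysis effect leaves differences uncorrelated with HI.
#'
#' @param diff_pct percent differences.
#' @param hi HI values, same length (>= 3).
#' @return Named numeric `c(rho, p)`.
#' @export
diff_vs_hi_independence <- function(diff_pct, hi) {
  hi <- hi_value(hi)
  if (length(diff_pct) != length(hi)) stop("length mismatch")
  if (length(diff_pct) < 3L) stop("need at least 3 pairs")
  if (length(unique(diff_pct)) < 2L || length(unique(hi)) < 2L)
    stop("constant input: Spearman correlation undefined")
  ct <- suppressWarnings(stats::cor.test(diff_pct, hi, method = "spearman",
                                         exact = FALSE))
  c(rho = unname(ct$estimate), p = ct$p.value)
}

#' Acceptability of agreement against a bias limit
#'
#' Agreement passes when both limits of agreement lie within the symmetric
#' bias band (boundary inclusive). The default +/-20% band reflects an assay
#' intermediate precision of CV <= 10%: about 95% of repeat results fall
#' within +/-20% of the original, and differences under 20% carry no
#' clinical weight in tumor-marker trend monitoring.
#'
#' @param result an `"agreement_result"`.
#' @param bias_limit half-width of the acceptability band in percent
#'   (default 20, must be positive).
#' @return `TRUE` (pass) or `FALSE`.
#' @export
acceptability <- function(result, bias_limit = 20) {
  stopifnot(inherits(result, "agreement_result"), bias_limit > 0)
  result$loa_lower_pct >= -bias_limit && result$loa_upper_pct <= bias_limit
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Bland-Altman percent-difference agreement (n = %d, denominator = %s)\n",
              x$n_pairs, x$denominator))
  cat(sprintf("  mean difference %.2f%%, SD %.2f%%\n",
              x$mean_diff_pct, x$sd_diff_pct))
  cat(sprintf("  %.2f%% limits of agreement: %.2f%% to %.2f%%\n",
              100 * (2 * stats::pnorm(x$z) - 1),
              x$loa_lower_pct, x$loa_upper_pct))
  if (!is.na(x$spearman_r_vs_hi))
    cat(sprintf("  difference vs HI: Spearman r = %.3f, p = %.3f\n",
                x$spearman_r_vs_hi, x$spearman_p))
  invisible(x)
}

#' @export
plot.agreement_result <- function(x, ...) {
  graphics::plot(x$avg, x$diff_pct,
                 xlab = "Average of baseline and corrected NSE (ug/L)",
                 ylab = "Difference (%)",
                 main = "Bland-Altman agreement", ...)
  graphics::abline(h = c(x$mean_diff_pct, x$loa_lower_pct, x$loa_upper_pct),
                   lty = c(1, 2, 2), col = "red3")
  invisible(x)
}

#' Write an agreement report as JSON
#'
#' @param result an `"agreement_result"`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_agreement_json <- function(result, path) {
  stopifnot(inherits(result, "agreement_result"))
  keep <- c("mean_diff_pct", "sd_diff_pct", "loa_lower_pct", "loa_upper_pct",
            "spearman_r_vs_hi", "spearman_p", "n_pairs", "z", "denominator")
  jsonlite::write_json(unclass(result)[keep], path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
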