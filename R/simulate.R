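#' Measurement noise model
#'
#' Multiplicative lognormal measurement noise parameterized by coefficients
#' of variation: HI repeatability (within-run) 2%, HI intermediate precision
#' (cross-day) 5%, NSE intermediate precision 10% (the assay's claimed
#' ceiling) and NSE within-run repeatability 2% (typical for
#' electrochemiluminescence immunoassays, and the precision that governs
#' paired measurements of the same specimen run back to back). A lognormal
#' factor with unit mean and the requested CV keeps measurements positive.
#'
#' @param hi_cv_repeat within-run HI CV (default 0.02).
#' @param hi_cv_intermediate cross-day HI CV (default 0.05).
#' @param nse_cv NSE intermediate-precision CV (default 0.10).
#' @param nse_cv_repeat within-run NSE CV (default 0.02).
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(hi_cv_repeat = 0.02, hi_cv_intermediate = 0.05,
                        nse_cv = 0.10, nse_cv_repeat = 0.02) {
  stopifnot(hi_cv_repeat >= 0, hi_cv_intermediate >= 0, nse_cv >= 0,
            nse_cv_repeat >= 0)
  structure(list(hi_cv_repeat = hi_cv_repeat,
                 hi_cv_intermediate = hi_cv_intermediate,
                 nse_cv = nse_cv,
                 nse_cv_repeat = nse_cv_repeat),
            class = "noise_model")
}

# unit-mean lognormal noise factors at a given CV (cv = 0 -> exactly 1)
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# pick the CV pair matching the measurement session layout
noise_cvs <- function(noise, precision = c("repeatability", "intermediate")) {
  precision <- match.arg(precision)
  if (precision == "repeatability")
    list(hi = noise$hi_cv_repeat, nse = noise$nse_cv_repeat)
  else
    list(hi = noise$hi_cv_intermediate, nse = noise$nse_cv)
}

#' Serial halving lysate dilution series
#'
#' Hemolysate HI concentrations obtained by successive 1:2 saline dilution,
#' rounded to 2 decimals. The default spiking design uses a 10-level series
#' starting at HI 6000 (and an alternate 5000 start for low-NSE pools).
#'
#' @param start_hi HI of the most concentrated dilution (> 0).
#' @param n_levels number of dilution levels (>= 1).
#' @return Numeric vector of length `n_levels`, strictly decreasing.
#' @examples
#' make_lysate_series(6000, 10)
#' @export
make_lysate_series <- function(start_hi, n_levels) {
  stopifnot(length(start_hi) == 1L, start_hi > 0,
            length(n_levels) == 1L, n_levels >= 1)
  round(start_hi / 2^(seq_len(n_levels) - 1), 2)
}

#' Spiking experiment design
#'
#' Layout of the in-silico spike-recovery experiment: serum pools, one
#' saline-baseline aliquot plus one aliquot per lysate dilution level, the
#' lysate:serum spiking ratio, and the NSE/HI ratio of the donor lysate.
#' Defaults reproduce the 23-pool x 11-aliquot design: 10-level halving
#' series from HI 6000 for most pools, an alternate series from HI 5000 for
#' the `n_low_pools` lowest-NSE pools, lysate added 1 volume to 10 volumes
#' of serum (spike fraction 1/11), donor R = 0.31.
#'
#' @param n_pools number of serum pools (default 23).
#' @param n_levels dilution levels per pool (default 10; aliquots per pool is
#'   `n_levels + 1` including the baseline).
#' @param start_hi,start_hi_low starting HI of the main and low-NSE series
#'   (defaults 6000 and 5000).
#' @param n_low_pools how many pools use the low series (default 3).
#' @param spike_ratio serum volumes per lysate volume (default 10, i.e. the
#'   lysate ends up as 1/11 of the final volume).
#' @param donor_r NSE/HI ratio of the spiking lysate (default 0.31).
#' @param baseline_hi HI of the unspiked pool serum (default 2, the healthy
#'   median).
#' @return An object of class `"spiking_design"`.
#' @export
spiking_design <- function(n_pools = 23, n_levels = 10,
                           start_hi = 6000, start_hi_low = 5000,
                           n_low_pools = 3, spike_ratio = 10,
                           donor_r = 0.31, baseline_hi = 2) {
  stopifnot(n_pools >= 1, n_levels >= 1, n_low_pools >= 0,
            n_low_pools <= n_pools, spike_ratio > 0, donor_r >= 0,
            baseline_hi >= 0)
  structure(list(n_pools = n_pools,
                 aliquots_per_pool = n_levels + 1L,
                 lysate_hi_series = make_lysate_series(start_hi, n_levels),
                 lysate_hi_series_low = make_lysate_series(start_hi_low,
                                                           n_levels),
                 n_low_pools = n_low_pools,
                 spike_ratio = spike_ratio,
                 spike_fraction = 1 / (1 + spike_ratio),
                 donor_r = donor_r,
                 baseline_hi = baseline_hi),
            class = "spiking_design")
}

#' @export
print.spiking_design <- function(x, ...) {
  cat(sprintf("Spiking design: %d pools x %d aliquots (= %d samples)\n",
              x$n_pools, x$aliquots_per_pool,
              x$n_pools * x$aliquots_per_pool))
  cat("  lysate HI series:", paste(x$lysate_hi_series, collapse = ", "), "\n")
  if (x$n_low_pools > 0)
    cat(sprintf("  low-NSE series (%d pools): %s\n", x$n_low_pools,
                paste(x$lysate_hi_series_low, collapse = ", ")))
  cat(sprintf("  spike fraction %.4g, donor R = %g, pool baseline HI = %g\n",
              x$spike_fraction, x$donor_r, x$baseline_hi))
  invisible(x)
}

# deterministic log-uniform spacing of pool baseline NSE over the spiked range
default_pool_baselines <- function(n_pools, lo = 8.4, hi = 370) {
  exp(seq(log(lo), log(hi), length.out = n_pools))
}

#' Simulate the lysate spiking experiment
#'
#' Generates the full spike-recovery dataset: for every pool, one saline
#' baseline aliquot and one aliquot per lysate dilution level. The truth
#' model per aliquot quantizes the hemolysis level to the instrument's
#' integer HI scale: `HI_true = round(lysate_hi * spike_fraction +
#' baseline_hi)` and `NSE_true = baseline_nse * serum_fraction + donor_r *
#' (HI_true - baseline_hi)` (the saline baseline has `lysate_hi = 0`), so
#' that with all CVs zero the observed fields equal the truth fields exactly
#' and regressing increments on the added HI recovers `donor_r` exactly.
#' Observations multiply the truth by lognormal noise and HI is re-rounded
#' to an integer, matching instrument granularity. All aliquots of the real
#' protocol are measured within one day, so the default `precision` applies
#' the within-run repeatability CVs; `"intermediate"` switches to the
#' cross-day CVs for sensitivity analyses.
#'
#' @param design a [spiking_design()].
#' @param pool_baseline_nse baseline NSE of each pool (ug/L); default spaces
#'   `n_pools` values log-uniformly over 8.4--370 ug/L, with the lowest-NSE
#'   pools assigned the low lysate series.
#' @param noise a [noise_model()].
#' @param precision which CV pair applies: `"repeatability"` (within-run,
#'   the default for this single-day protocol) or `"intermediate"`
#'   (cross-day).
#' @param seed optional RNG seed for a reproducible cohort.
#' @return A `"synthetic_cohort"` data.frame with one row per aliquot:
#'   `record_id, pool_id, aliquot, role` (`baseline`/`spiked`), `lysate_hi`,
#'   `nse_meas, hi_meas`, truth columns `true_nse, true_hi, true_r` and the
#'   pool's `baseline_nse`.
#' @examples
#' cohort <- simulate_spiking_experiment(seed = 1)
#' nrow(cohort)  # 253
#' @export
simulate_spiking_experiment <- function(design = spiking_design(),
                                        pool_baseline_nse = NULL,
                                        noise = noise_model(),
                                        precision = c("repeatability",
                                                      "intermediate"),
                                        seed = NULL) {
  stopifnot(inherits(design, "spiking_design"),
            inherits(noise, "noise_model"))
  cvs <- noise_cvs(noise, precision)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pool_baseline_nse))
    pool_baseline_nse <- default_pool_baselines(design$n_pools)
  if (length(pool_baseline_nse) != design$n_pools)
    stop("need one baseline NSE per pool")
  if (any(pool_baseline_nse < 0.05) || any(pool_baseline_nse > 370))
    stop("pool baseline NSE outside assay measurable range")

  f <- design$spike_fraction
  serum_f <- 1 - f
  # low-NSE pools get the alternate series
  low_pools <- order(pool_baseline_nse)[seq_len(design$n_low_pools)]
  rows <- vector("list", design$n_pools)
  for (p in seq_len(design$n_pools)) {
    series <- if (p %in% low_pools) design$lysate_hi_series_low
              else design$lysate_hi_series
    lysate <- c(0, series)                       # aliquot 1 = saline baseline
    hi_true <- round_half_away(lysate * f + design$baseline_hi)
    nse_true <- pool_baseline_nse[p] * serum_f +
      design$donor_r * (hi_true - hi_true[1L])
    rows[[p]] <- data.frame(
      pool_id = sprintf("pool%02d", p),
      aliquot = seq_along(lysate),
      role = c("baseline", rep("spiked", length(series))),
      lysate_hi = lysate,
      true_nse = nse_true,
      true_hi = hi_true,
      true_r = design$donor_r,
      baseline_nse = pool_baseline_nse[p],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  n <- nrow(out)
  out$nse_meas <- out$true_nse * rlnorm_cv(n, cvs$nse)
  out$hi_meas <- round_half_away(out$true_hi * rlnorm_cv(n, cvs$hi))
  out$record_id <- sprintf("S%03d", seq_len(n))
  out <- out[c("record_id", "pool_id", "aliquot", "role", "lysate_hi",
               "nse_meas", "hi_meas", "true_nse", "true_hi", "true_r",
               "baseline_nse")]
  class(out) <- c("synthetic_cohort", "data.frame")
  out
}

#' Per-aliquot NSE increments from a spiking cohort
#'
#' Subtracts each pool's measured saline-baseline NSE from the spiked
#' aliquots' measured NSE, pairing the increment either with the spiked
#' aliquot's measured HI (`"hi_meas"`, the variable the published model is
#' defined against) or with the baseline-subtracted `"delta_hi"`.
#'
#' @param cohort a spiking `"synthetic_cohort"` (or any data.frame with the
#'   same columns).
#' @param x x-variable mode.
#' @return data.frame with `pool_id`, `hi`, `increment` (spiked rows only),
#'   ready for [fit_increment_model()].
#' @export
spiking_increments <- function(cohort, x = c("hi_meas", "delta_hi")) {
  x <- match.arg(x)
  stopifnot(all(c("pool_id", "role", "nse_meas", "hi_meas") %in%
                  names(cohort)))
  base <- cohort[cohort$role == "baseline", ]
  if (anyDuplicated(base$pool_id))
    stop("more than one baseline aliquot in a pool")
  spiked <- cohort[cohort$role == "spiked", ]
  idx <- match(spiked$pool_id, base$pool_id)
  if (anyNA(idx)) stop("pool without a baseline aliquot")
  data.frame(pool_id = spiked$pool_id,
             hi = if (x == "hi_meas") spiked$hi_meas else
               spiked$hi_meas - base$hi_meas[idx],
             increment = spiked$nse_meas - base$nse_meas[idx])
}

#' Simulate a paired intentional-hemolysis validation cohort
#'
#' Emulates the validation protocol in which each patient's specimen is
#' measured at baseline, then intentionally hemolyzed (freeze-thaw lysis of
#' the patient's own red cells) and re-measured. Each pseudo-patient gets a
#' patient-specific NSE/HI ratio R; the hemolyzed truth is
#' `NSE = baseline + R * dHI + offset` where `dHI` is the added HI and the
#' small positive per-specimen `offset` (uniform on `offset_range`, scaled
#' by R) stands in for lysis products beyond the linear term, so that a
#' positive fitted intercept arises in kind. Baseline HI is 2 (healthy
#' median); the hemolyzed HI (quantized to the instrument's integer scale),
#' R and baseline NSE are drawn log-uniform / uniform over ranges matching
#' the validated cohort (R 0.091--0.467, HI 6--314, NSE 6.94--366.1).
#' Baseline and hemolyzed aliquots of one specimen are assayed back to
#' back, so the default `precision` applies the within-run repeatability
#' CVs rather than the cross-day intermediate precision.
#'
#' @param n number of pseudo-patients (default 47).
#' @param r_range,hi_range,baseline_nse_range sampling ranges (defaults
#'   above).
#' @param noise a [noise_model()].
#' @param precision which CV pair applies: `"repeatability"` (within-run,
#'   the default for these back-to-back paired measurements) or
#'   `"intermediate"` (cross-day).
#' @param offset_range range of the per-specimen offset before scaling by R
#'   (default `c(0, 2)` ug/L; use `c(0, 0)` for a purely proportional
#'   truth).
#' @param baseline_hi baseline specimen HI (default 2).
#' @param seed optional RNG seed.
#' @return A `"synthetic_cohort"` data.frame with two rows per patient
#'   (`role` `baseline` / `hemolyzed`) and truth columns
#'   `true_nse, true_hi, true_r`.
#' @export
make_validation_cohort <- function(n = 47,
                                   r_range = c(0.091, 0.467),
                                   hi_range = c(6, 314),
                                   baseline_nse_range = c(6.94, 366.1),
                                   noise = noise_model(),
                                   precision = c("repeatability",
                                                 "intermediate"),
                                   offset_range = c(0, 2),
                                   baseline_hi = 2,
                                   seed = NULL) {
  cvs <- noise_cvs(noise, precision)
  stopifnot(n >= 1, r_range[1] >= 0, diff(r_range) >= 0,
            hi_range[1] > 0, diff(hi_range) >= 0,
            baseline_nse_range[1] > 0, diff(baseline_nse_range) >= 0,
            inherits(noise, "noise_model"))
  if (!is.null(seed)) set.seed(seed)
  r <- stats::runif(n, r_range[1], r_range[2])
  hem_hi <- round_half_away(exp(stats::runif(n, log(hi_range[1]),
                                             log(hi_range[2]))))
  base_nse <- exp(stats::runif(n, log(baseline_nse_range[1]),
                               log(baseline_nse_range[2])))
  offset <- stats::runif(n, offset_range[1], offset_range[2]) * r
  d_hi <- hem_hi - baseline_hi
  hem_nse <- base_nse + r * d_hi + offset

  patient <- sprintf("P%03d", seq_len(n))
  out <- data.frame(
    record_id = sprintf("V%03d", seq_len(2 * n)),
    patient_id = rep(patient, each = 2),
    role = rep(c("baseline", "hemolyzed"), times = n),
    true_nse = as.vector(rbind(base_nse, hem_nse)),
    true_hi = as.vector(rbind(rep(baseline_hi, n), hem_hi)),
    true_r = rep(r, each = 2),
    stringsAsFactors = FALSE)
  m <- nrow(out)
  out$nse_meas <- out$true_nse * rlnorm_cv(m, cvs$nse)
  out$hi_meas <- round_half_away(out$true_hi * rlnorm_cv(m, cvs$hi))
  out <- out[c("record_id", "patient_id", "role", "nse_meas", "hi_meas",
               "true_nse", "true_hi", "true_r")]
  class(out) <- c("synthetic_cohort", "data.frame")
  out
}

#' Simulate a healthy-control cohort
#'
#' Generates HI and NSE for healthy individuals. Both are right-skewed
#' lognormals; HI is rounded to an integer. The default parameters are set
#' analytically from the target population summaries: NSE median 8.5 ug/L
#' and 95th percentile 11.8 ug/L (meanlog `log(8.5)`, sdlog
#' `log(11.8/8.5)/qnorm(0.95)`), and an integer HI with median 2 and 95th
#' percentile 5 (meanlog `log(2)`, sdlog 0.55).
#'
#' @param n cohort size (default 200).
#' @param hi_meanlog,hi_sdlog lognormal parameters of the latent HI.
#' @param nse_meanlog,nse_sdlog lognormal parameters of NSE.
#' @param seed optional RNG seed.
#' @return A `"synthetic_cohort"` data.frame with `role = "healthy"` rows.
#' @export
make_healthy_cohort <- function(n = 200,
                                hi_meanlog = log(2), hi_sdlog = 0.55,
                                nse_meanlog = log(8.5),
                                nse_sdlog = log(11.8 / 8.5) /
                                  stats::qnorm(0.95),
                                seed = NULL) {
  stopifnot(n >= 1, hi_sdlog >= 0, nse_sdlog >= 0)
  if (!is.null(seed)) set.seed(seed)
  hi_true <- round_half_away(stats::rlnorm(n, hi_meanlog, hi_sdlog))
  nse_true <- stats::rlnorm(n, nse_meanlog, nse_sdlog)
  out <- data.frame(
    record_id = sprintf("H%03d", seq_len(n)),
    patient_id = sprintf("H%03d", seq_len(n)),
    role = "healthy",
    nse_meas = nse_true,
    hi_meas = hi_true,
    true_nse = nse_true,
    true_hi = hi_true,
    true_r = NA_real_,
    stringsAsFactors = FALSE)
  class(out) <- c("synthetic_cohort", "data.frame")
  out
}

#' Write a synthetic cohort as CSV
#'
#' @param cohort a `"synthetic_cohort"`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}
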