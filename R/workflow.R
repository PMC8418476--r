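#' Decision cascade configuration
#'
#' Thresholds for the automated report-decision algorithm: the HI cutoff
#' above which a specimen counts as hemolyzed (default 5), the NSE level
#' above which a hemolyzed result warrants attention (default 16.3 ug/L,
#' the upper reference limit), the trend delta that carries clinical
#' importance (default 25%), and the agreement acceptability band
#' (default 20%). "Above" is strict for all gates.
#'
#' @param hi_cutoff HI cutoff (default 5).
#' @param nse_cutoff NSE gate in ug/L (default 16.3).
#' @param trend_delta_pct percent change vs the prior result that triggers
#'   correction in trend monitoring (default 25).
#' @param bias_limit_pct agreement acceptability half-width (default 20).
#' @return An object of class `"decision_config"`.
#' @export
decision_config <- function(hi_cutoff = 5, nse_cutoff = 16.3,
                            trend_delta_pct = 25, bias_limit_pct = 20) {
  vals <- c(hi_cutoff, nse_cutoff, trend_delta_pct, bias_limit_pct)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all decision thresholds must be positive")
  structure(list(hi_cutoff = hi_cutoff, nse_cutoff = nse_cutoff,
                 trend_delta_pct = trend_delta_pct,
                 bias_limit_pct = bias_limit_pct),
            class = "decision_config")
}

#' Route one specimen through the report-decision cascade
#'
#' Implements the automated processing algorithm for NSE results affected by
#' specimen hemolysis. The rule cascade, evaluated top down with exactly one
#' action per specimen:
#'
#' 1. HI at or below the cutoff: release the result as is.
#' 2. Hemolyzed but NSE at or below the reference limit: release with an HI
#'    annotation (the hemolysis cannot have pushed a clinically relevant
#'    result across the limit in a way that changes management).
#' 3. Hemolyzed, NSE above the limit, and a clinical need for the true
#'    level — auxiliary diagnosis of small-cell lung cancer / neuroblastoma,
#'    or trend supervision where the change versus the prior result exceeds
#'    the trend delta: correct and report (original result, HI and corrected
#'    level together) if the patient's NSE/HI ratio is available, otherwise
#'    request the ratio measurement.
#' 4. Anything else (including trend purpose with no prior result, which is
#'    noted as a warning in the rationale): release with an HI annotation.
#'
#' Correcting only where a clinical action hinges on the result avoids alert
#' fatigue; correction is never applied to non-hemolyzed specimens.
#'
#' @param record a list or one-row data.frame with `specimen_id`, `nse_meas`
#'   (ug/L), `hi`, `purpose` (`"trend"`, `"diagnosis"` or `"other"`), and
#'   optional `prior_nse` and `r` (the patient's NSE/HI ratio; `NA` when not
#'   measured).
#' @param config a [decision_config()].
#' @param model an [personalize()]d `"nse_correction_model"`.
#' @param floor assay lower measurable limit passed to [correct_nse()].
#' @return One-row data.frame: `specimen_id`, `action` (one of `release`,
#'   `release_with_hi_note`, `needs_ratio`, `corrected_report`),
#'   `original_nse`, `hi`, `corrected_nse` (`NA` unless corrected) and
#'   `rationale` (the rule that fired).
#' @examples
#' m <- personalize(increment_model(0.2757, 0.9793), donor_r = 0.31)
#' decide(list(specimen_id = "A", nse_meas = 60.9, hi = 36,
#'             purpose = "diagnosis", r = 0.31), model = m)
#' @export
decide <- function(record, config = decision_config(), model, floor = 0.05) {
  stopifnot(inherits(config, "decision_config"))
  get_field <- function(nm, default = NA) {
    v <- record[[nm]]
    if (is.null(v) || length(v) == 0L) default else v
  }
  id <- get_field("specimen_id", NA_character_)
  nse <- as.numeric(get_field("nse_meas"))
  hi <- hi_value(get_field("hi"))
  purpose <- as.character(get_field("purpose", "other"))
  prior <- as.numeric(get_field("prior_nse"))
  r <- as.numeric(get_field("r"))
  if (!is.finite(nse) || nse < 0.05 || nse > 370)
    stop("nse_meas outside assay measurable range [0.05, 370]")
  if (!is.finite(hi) || hi < 0) stop("invalid HI")
  if (!purpose %in% c("trend", "diagnosis", "other"))
    stop("purpose must be one of trend/diagnosis/other")

  corrected <- NA_real_
  if (hi <= config$hi_cutoff) {
    action <- "release"
    why <- sprintf("rule 1: HI %g <= cutoff %g, no hemolysis interference",
                   hi, config$hi_cutoff)
  } else if (nse <= config$nse_cutoff) {
    action <- "release_with_hi_note"
    why <- sprintf(
      "rule 2: hemolyzed (HI %g) but NSE %g <= reference limit %g",
      hi, nse, config$nse_cutoff)
  } else {
    trend_fires <- purpose == "trend" && is.finite(prior) &&
      abs(nse - prior) / prior * 100 > config$trend_delta_pct
    need <- purpose == "diagnosis" || trend_fires
    if (need) {
      gate <- if (purpose == "diagnosis") "diagnostic purpose (SCLC/NB)"
              else sprintf("trend change %.1f%% > %g%%",
                           abs(nse - prior) / prior * 100,
                           config$trend_delta_pct)
      if (is.na(r)) {
        action <- "needs_ratio"
        why <- sprintf(
          "rule 3: hemolyzed, NSE %g > %g, %s; patient NSE/HI ratio not yet measured",
          nse, config$nse_cutoff, gate)
      } else {
        action <- "corrected_report"
        corrected <- correct_nse(nse, hi, r, model, floor = floor)$nse_corr
        why <- sprintf("rule 3: hemolyzed, NSE %g > %g, %s; corrected with R = %g",
                       nse, config$nse_cutoff, gate, r)
      }
    } else {
      action <- "release_with_hi_note"
      why <- if (purpose == "trend" && !is.finite(prior))
        "rule 4: no clinical-need gate met (warning: trend purpose without a prior result)"
      else
        "rule 4: no clinical-need gate met"
    }
  }
  data.frame(specimen_id = id, action = action, original_nse = nse, hi = hi,
             corrected_nse = corrected, rationale = why,
             stringsAsFactors = FALSE)
}

#' Run the decision pipeline over a batch of specimens
#'
#' Applies [decide()] to every record (in input order) and summarizes
#' hemolysis prevalence overall and within NSE strata. Stratum boundaries
#' are left-open/right-closed intervals on the measured NSE
#' (by default `(0, 16.3]`, `(16.3, 50]`, `(50, 100]`, `(100, 370]`).
#' Malformed records are collected and reported alongside the results, not
#' silently dropped.
#'
#' @param records data.frame of specimen records (columns as in [decide()]).
#' @param config a [decision_config()].
#' @param model an `"nse_correction_model"`.
#' @param strata upper NSE boundaries of the summary strata.
#' @return An object of class `"nse_pipeline_result"`: `entries` (one row
#'   per valid record), `errors` (row index + message for malformed rows),
#'   and `summary` with per-stratum counts, hemolyzed counts and rates (%)
#'   plus the overall rate (`NA` rate for empty strata).
#' @export
run_pipeline <- function(records, config = decision_config(), model,
                         strata = c(16.3, 50, 100, 370)) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  entries <- vector("list", nrow(records))
  errors <- list()
  for (i in seq_len(nrow(records))) {
    e <- tryCatch(decide(records[i, , drop = FALSE], config, model),
                  error = function(err)
                    structure(conditionMessage(err), class = "row_error"))
    if (inherits(e, "row_error")) {
      errors[[length(errors) + 1L]] <-
        data.frame(row = i, message = unclass(e), stringsAsFactors = FALSE)
    } else {
      entries[[i]] <- e
    }
  }
  entries <- do.call(rbind, entries)
  errors <- if (length(errors)) do.call(rbind, errors) else
    data.frame(row = integer(), message = character())
  if (is.null(entries)) stop("no valid records")

  hemolyzed <- entries$hi > config$hi_cutoff
  breaks <- c(0, strata)
  lab <- sprintf("(%g, %g]", breaks[-length(breaks)], breaks[-1])
  stratum <- cut(entries$original_nse, breaks = breaks, labels = lab,
                 right = TRUE)
  n_k <- as.integer(table(stratum))
  h_k <- as.integer(tapply(hemolyzed, stratum, sum, default = 0L))
  summary <- data.frame(
    stratum = c(lab, "overall"),
    n = c(n_k, length(hemolyzed)),
    hemolyzed = c(h_k, sum(hemolyzed)),
    rate_pct = c(ifelse(n_k > 0, 100 * h_k / n_k, NA_real_),
                 100 * mean(hemolyzed)),
    stringsAsFactors = FALSE)
  structure(list(entries = entries, errors = errors, summary = summary,
                 config = config),
            class = "nse_pipeline_result")
}

#' @export
print.nse_pipeline_result <- function(x, ...) {
  cat(sprintf("NSE hemolysis pipeline: %d specimens, %d malformed rows\n",
              nrow(x$entries), nrow(x$errors)))
  cat("Actions:\n")
  print(table(x$entries$action))
  cat("\nHemolysis prevalence by NSE stratum (ug/L):\n")
  s <- x$summary
  s$rate_pct <- ifelse(is.na(s$rate_pct), "n/a", sprintf("%.1f", s$rate_pct))
  print(s, row.names = FALSE)
  invisible(x)
}

specimen_columns <- c("specimen_id", "patient_id", "nse_meas", "hi",
                      "purpose", "prior_nse", "r", "timestamp")

#' Read and write specimen record tables
#'
#' `read_specimens()` reads a CSV of specimen records with required columns
#' `specimen_id, nse_meas, hi` and optional `patient_id, purpose, prior_nse,
#' r, timestamp` (missing optional columns are filled with defaults).
#' Rows failing validation (unparseable numerics, NSE outside the assay
#' range, bad purpose) are accumulated in an `errors` attribute with
#' row-level messages rather than dropped silently. `write_specimens()` and
#' `write_report()` write records / report entries so that a write-read
#' cycle is the identity on valid records.
#'
#' @param path CSV file path.
#' @return For `read_specimens()`: data.frame of valid records with
#'   attribute `"errors"` (data.frame of `row`, `message`).
#' @export
read_specimens <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8", colClasses = "character")
  required <- c("specimen_id", "nse_meas", "hi")
  if (!all(required %in% names(tab)))
    stop("missing required columns: ",
         paste(setdiff(required, names(tab)), collapse = ", "))
  for (opt in setdiff(specimen_columns, names(tab)))
    tab[[opt]] <- if (opt == "purpose") "other" else NA_character_
  tab <- tab[specimen_columns]

  keep <- rep(TRUE, nrow(tab))
  msgs <- list()
  num_or_na <- function(s) suppressWarnings(as.numeric(s))
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    nse <- num_or_na(row$nse_meas)
    hi <- num_or_na(row$hi)
    prior <- num_or_na(row$prior_nse)
    r <- num_or_na(row$r)
    purpose <- if (is.na(row$purpose) || row$purpose == "") "other" else
      row$purpose
    problems <- c(
      if (is.na(nse)) "unparseable nse_meas",
      if (!is.na(nse) && (nse < 0.05 || nse > 370))
        "nse_meas outside assay range [0.05, 370]",
      if (is.na(hi)) "unparseable hi",
      if (!is.na(hi) && hi < 0) "negative hi",
      if (!purpose %in% c("trend", "diagnosis", "other"))
        "invalid purpose",
      if (!is.na(row$prior_nse) && row$prior_nse != "" && is.na(prior))
        "unparseable prior_nse",
      if (!is.na(row$r) && row$r != "" && is.na(r))
        "unparseable r")
    if (length(problems)) {
      keep[i] <- FALSE
      msgs[[length(msgs) + 1L]] <-
        data.frame(row = i, message = paste(problems, collapse = "; "),
                   stringsAsFactors = FALSE)
    }
  }
  out <- tab[keep, , drop = FALSE]
  out$nse_meas <- as.numeric(out$nse_meas)
  out$hi <- as.numeric(out$hi)
  out$prior_nse <- num_or_na(out$prior_nse)
  out$r <- num_or_na(out$r)
  out$purpose[is.na(out$purpose) | out$purpose == ""] <- "other"
  rownames(out) <- NULL
  attr(out, "errors") <- if (length(msgs)) do.call(rbind, msgs) else
    data.frame(row = integer(), message = character())
  out
}

#' @rdname read_specimens
#' @param records data.frame of specimen records.
#' @export
write_specimens <- function(records, path) {
  for (opt in setdiff(specimen_columns, names(records)))
    records[[opt]] <- if (opt == "purpose") "other" else NA
  utils::write.csv(records[specimen_columns], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname read_specimens
#' @param entries report entries from [run_pipeline()] or [decide()].
#' @export
write_report <- function(entries, path) {
  utils::write.csv(entries, path, row.names = FALSE, na = "")
  invisible(path)
}
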