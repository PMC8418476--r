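model <- reported_model()

rec <- function(nse, hi, purpose = "other", prior = NA, r = NA, id = "s1") {
  list(specimen_id = id, nse_meas = nse, hi = hi, purpose = purpose,
       prior_nse = prior, r = r)
}

# independent re-evaluation of the cascade predicates
expected_action <- function(nse, hi, purpose, prior, r,
                            cfg = decision_config()) {
  if (hi <= cfg$hi_cutoff) return("release")
  if (nse <= cfg$nse_cutoff) return("release_with_hi_note")
  trend <- purpose == "trend" && !is.na(prior) &&
    abs(nse - prior) / prior * 100 > cfg$trend_delta_pct
  if (purpose == "diagnosis" || trend)
    return(if (is.na(r)) "needs_ratio" else "corrected_report")
  "release_with_hi_note"
}

test_that("the decision cascade routes the canonical cases", {
  expect_equal(decide(rec(50, 3), model = model)$action, "release")

  e <- decide(rec(60.9, 36, "diagnosis", r = 0.31), model = model)
  expect_equal(e$action, "corrected_report")
  expect_lt(e$corrected_nse, e$original_nse)

  # 11% change does not cross the 25% trend gate
  e2 <- decide(rec(20, 15, "trend", prior = 18), model = model)
  expect_equal(e2$action, "release_with_hi_note")

  # hemolyzed, elevated, diagnostic need, no ratio yet
  expect_equal(decide(rec(60.9, 36, "diagnosis"), model = model)$action,
               "needs_ratio")

  # 30% trend change with a ratio: corrected
  e3 <- decide(rec(26, 15, "trend", prior = 20, r = 0.3), model = model)
  expect_equal(e3$action, "corrected_report")

  # trend purpose without a prior: annotated, warning in the rationale
  e4 <- decide(rec(20, 15, "trend"), model = model)
  expect_equal(e4$action, "release_with_hi_note")
  expect_match(e4$rationale, "warning")

  expect_error(decide(rec(500, 3), model = model), "assay")
  expect_error(decide(rec(20, 3, "screening"), model = model), "purpose")
})

test_that("every record gets exactly one action matching the predicates", {
  grid <- expand.grid(nse = c(10, 16.3, 16.31, 60, 369),
                      hi = c(0, 5, 6, 36, 300),
                      purpose = c("other", "trend", "diagnosis"),
                      prior = c(NA, 50, 12),
                      r = c(NA, 0.31),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    e <- decide(rec(g$nse, g$hi, g$purpose, g$prior, g$r), model = model)
    expect_equal(nrow(e), 1L)
    expect_true(e$action %in% c("release", "release_with_hi_note",
                                "needs_ratio", "corrected_report"))
    expect_equal(e$action,
                 expected_action(g$nse, g$hi, g$purpose, g$prior, g$r),
                 info = paste(g, collapse = "/"))
    # corrected value present iff corrected; never for clean specimens
    expect_equal(!is.na(e$corrected_nse), e$action == "corrected_report")
    if (g$hi <= 5) expect_false(e$action == "corrected_report")
    expect_gt(nchar(e$rationale), 0)
  }
})

test_that("pipeline summary rates equal hand-counted fractions", {
  set.seed(404)
  for (rep in 1:5) {
    n <- sample(30:120, 1)
    records <- data.frame(
      specimen_id = sprintf("s%d", seq_len(n)),
      nse_meas = exp(runif(n, log(1), log(369))),
      hi = sample(0:60, n, replace = TRUE),
      purpose = sample(c("other", "trend", "diagnosis"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    out <- run_pipeline(records, model = model)
    hem <- records$hi > 5
    expect_equal(out$summary$hemolyzed[out$summary$stratum == "overall"],
                 sum(hem))
    expect_equal(out$summary$rate_pct[out$summary$stratum == "overall"],
                 100 * mean(hem))
    # stratum counts add up and match a direct count
    cuts <- cut(records$nse_meas, c(0, 16.3, 50, 100, 370), right = TRUE)
    expect_equal(out$summary$n[1:4], as.integer(table(cuts)))
    expect_equal(out$summary$hemolyzed[1:4],
                 as.integer(tapply(hem, cuts, sum, default = 0)))
  }
})

test_that("pipeline reports empty strata and malformed rows gracefully", {
  records <- data.frame(specimen_id = c("a", "b", "c"),
                        nse_meas = c(10, 20, 1000),  # last outside range
                        hi = c(0, 0, 3),
                        purpose = "other", stringsAsFactors = FALSE)
  out <- run_pipeline(records, model = model)
  expect_equal(nrow(out$entries), 2)
  expect_equal(nrow(out$errors), 1)
  expect_match(out$errors$message, "assay")
  # strata (50,100] and (100,370] are empty
  expect_true(all(is.na(out$summary$rate_pct[3:4])))
  # all HI below cutoff: everything released, zero hemolysis
  expect_true(all(out$entries$action == "release"))
  expect_equal(out$summary$rate_pct[out$summary$stratum == "overall"], 0)
})

test_that("specimen CSV I/O round-trips and accumulates row errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("specimen_id,nse_meas,hi,purpose,prior_nse,r",
               "s1,20.5,3,other,,",
               "s2,60.9,36,diagnosis,,0.31",
               "s3,not_a_number,4,other,,"), f)
  specs <- read_specimens(f)
  expect_equal(nrow(specs), 2)
  errs <- attr(specs, "errors")
  expect_equal(nrow(errs), 1)
  expect_equal(errs$row, 3)
  expect_match(errs$message, "nse_meas")

  # write-read identity on the valid records
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_specimens(specs, f2)
  again <- read_specimens(f2)
  expect_equal(again$specimen_id, specs$specimen_id)
  expect_equal(again$nse_meas, specs$nse_meas)
  expect_equal(again$hi, specs$hi)
  expect_equal(again$r, specs$r)
  expect_equal(nrow(attr(again, "errors")), 0)

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("specimen_id,nse_meas", "s1,10"), f3)
  expect_error(read_specimens(f3), "missing required columns")

  # report writer produces a readable table
  f4 <- withr::local_tempfile(fileext = ".csv")
  out <- run_pipeline(specs, model = model)
  write_report(out$entries, f4)
  expect_equal(nrow(utils::read.csv(f4)), 2)
})
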