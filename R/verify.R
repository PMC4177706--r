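#' Per-cell descriptive summary of a sweep
#'
#' Aggregates a replicated sweep table to one row per design cell, with the
#' minimum, maximum and mean over replicates for each output variable.
#' Exact arithmetic on the table — no resampling — so re-running on the
#' same table is bit-identical.
#'
#' @param sweep A result table from [run_sweep()].
#' @return A `data.frame`: the seven factor columns, `n_replicates`, and
#'   `<var>_min` / `<var>_max` / `<var>_mean` for each output variable.
#' @export
summarize_sweep <- function(sweep) {
  stopifnot(is.data.frame(sweep))
  missing_cols <- setdiff(c(SWEEP_FACTORS, OUTPUT_COUNTS), names(sweep))
  if (length(missing_cols))
    stop("sweep table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out_vars <- intersect(c(OUTPUT_COUNTS, OUTPUT_AUX), names(sweep))
  dt <- data.table::as.data.table(sweep)
  summ <- dt[, c(list(n_replicates = .N),
                 unlist(lapply(.SD, function(v)
                   list(min = min(v), max = max(v), mean = mean(v))),
                   recursive = FALSE)),
             by = SWEEP_FACTORS, .SDcols = out_vars]
  data.table::setnames(summ, gsub("\\.", "_", names(summ)))
  expected <- max(summ$n_replicates)
  short <- summ$n_replicates < expected
  if (any(short)) {
    cell <- summ[which(short)[1L], SWEEP_FACTORS, with = FALSE]
    stop("missing replicates (", summ$n_replicates[which(short)[1L]],
         " of ", expected, ") in cell: ",
         paste(names(cell), unlist(cell), sep = "=", collapse = ", "),
         call. = FALSE)
  }
  data.table::setDF(summ)
  summ
}

# posited relationships: outcome ~ predictors on cell means, with the
# expected coefficient sign for each predictor; `asserted` marks the
# directions treated as must-hold (the rest are reported only)
SIGN_CHECK_SPEC <- list(
  A = list(label = "motives and prior beliefs predict visibility",
           outcome = "visible_mean",
           predictors = c(mean_prior_belief = 1, mean_motives = -1),
           asserted = c(TRUE, TRUE)),
  B = list(label = "visibility and earned authority predict credibility",
           outcome = "mean_credibility_mean",
           predictors = c(mean_earned_authority = 1, visible_mean = -1),
           asserted = c(TRUE, TRUE)),
  C = list(label = "prior beliefs and evidence predict new beliefs (count of revisers)",
           outcome = "revised_beliefs_mean",
           predictors = c(mean_prior_belief = 1, mean_evidence = 1),
           asserted = c(TRUE, TRUE)),
  D = list(label = "visible count and credibility threshold predict availability",
           outcome = "available_mean",
           predictors = c(visible_mean = 1, credibility_threshold = -1),
           asserted = c(TRUE, TRUE)),
  E = list(label = "prior beliefs, evidence and announcer credibility predict need for advice",
           outcome = "need_advice_mean",
           predictors = c(mean_prior_belief = 1, mean_evidence = -1,
                          announcer_credibility_mean = -1),
           asserted = c(FALSE, FALSE, TRUE)),
  F = list(label = "revised assessments predict revised beliefs",
           outcome = "revised_beliefs_mean",
           predictors = c(revised_evidence_assessment_mean = -1,
                          revised_credibility_assessment_mean = 1),
           asserted = c(FALSE, TRUE)),
  G = list(label = "giving and needing advice predict revised beliefs",
           outcome = "revised_beliefs_mean",
           predictors = c(gave_advice_mean = 1, need_advice_mean = 1),
           asserted = c(TRUE, TRUE))
)

#' Directional sign checks on the sweep summary
#'
#' Fits one ordinary-least-squares regression per posited relationship
#' (labels A-G) on the cell-mean summary table and compares each fitted
#' coefficient's sign with the expected direction. Expected signs are
#' fixed constants of the model's posited structure, never re-derived from
#' data. Directions known to be weak/non-significant are reported but not
#' asserted (`asserted = FALSE`). Note the outcome of rows C, F and G is
#' interpreted as the COUNT of agents with revised beliefs.
#'
#' @param summary A table from [summarize_sweep()].
#' @return A `data.frame` of class `ol_sign_report`: one row per
#'   (relationship, predictor) with `relationship`, `description`,
#'   `outcome`, `predictor`, `estimate`, `p_value`, `expected_sign`,
#'   `observed_sign`, `asserted`, `pass`. `pass` is `TRUE` for
#'   non-asserted rows.
#' @export
run_sign_checks <- function(summary) {
  stopifnot(is.data.frame(summary))
  rows <- list()
  for (id in names(SIGN_CHECK_SPEC)) {
    chk <- SIGN_CHECK_SPEC[[id]]
    vars <- c(chk$outcome, names(chk$predictors))
    missing_cols <- setdiff(vars, names(summary))
    if (length(missing_cols))
      stop("summary lacks column(s) for check ", id, ": ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    for (v in names(chk$predictors))
      if (stats::var(summary[[v]]) == 0)
        stop("degenerate regressor (zero variance) in check ", id, ": ", v,
             call. = FALSE)
    fml <- stats::reformulate(names(chk$predictors), response = chk$outcome)
    fit <- stats::lm(fml, data = summary)
    coefs <- summary(fit)$coefficients
    for (j in seq_along(chk$predictors)) {
      v <- names(chk$predictors)[j]
      est <- coefs[v, "Estimate"]
      rows[[length(rows) + 1L]] <- data.frame(
        relationship = id, description = chk$label,
        outcome = chk$outcome, predictor = v,
        estimate = est, p_value = coefs[v, "Pr(>|t|)"],
        expected_sign = unname(chk$predictors[j]),
        observed_sign = sign(est),
        asserted = chk$asserted[j],
        pass = !chk$asserted[j] | sign(est) == unname(chk$predictors[j]),
        stringsAsFactors = FALSE
      )
    }
  }
  report <- do.call(rbind, rows)
  class(report) <- c("ol_sign_report", class(report))
  report
}

#' @export
print.ol_sign_report <- function(x, ...) {
  cat("Sign checks on parameter-sweep cell means\n")
  for (id in unique(x$relationship)) {
    sub <- x[x$relationship == id, ]
    cat(sprintf("%s. %s\n", id, sub$description[1L]))
    for (i in seq_len(nrow(sub)))
      cat(sprintf("   %-38s est %9.4f  expected %s  %s%s\n",
                  sub$predictor[i], sub$estimate[i],
                  ifelse(sub$expected_sign[i] > 0, "+", "-"),
                  ifelse(sub$pass[i], "PASS", "FAIL"),
                  ifelse(sub$asserted[i], "", " (not asserted)")))
  }
  invisible(x)
}

#' Logistic regression for advisor availability
#'
#' Models whether ANY advisor was available in a run (available count > 0)
#' as a function of the unit's settings, across the raw sweep rows. The
#' posited directions — higher prior beliefs and earned authority raise
#' the odds of an available advisor, a higher credibility threshold lowers
#' them — are checked against the fitted coefficients.
#'
#' @param sweep A raw result table from [run_sweep()].
#' @return A list of class `ol_availability_fit`: `coefficients` (estimate,
#'   standard error, z, p per predictor), `checks` (expected vs observed
#'   sign for the three asserted predictors, with `pass`), `separation`
#'   (`TRUE` if the fit showed numerically 0/1 fitted probabilities),
#'   `n`, `n_available`.
#' @export
fit_availability_logistic <- function(sweep) {
  stopifnot(is.data.frame(sweep))
  y <- sweep$available > 0
  if (length(unique(y)) < 2L)
    stop("complete separation: availability outcome is constant (",
         if (all(y)) "all" else "no", " runs had an available advisor)",
         call. = FALSE)
  dat <- cbind(any_available = y, sweep[SWEEP_FACTORS])
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(any_available ~ mean_prior_belief + mean_earned_authority +
                 credibility_threshold + n_staff + mean_evidence +
                 mean_motives + n_educators,
               family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  coefs <- summary(fit)$coefficients
  expected <- c(mean_prior_belief = 1, mean_earned_authority = 1,
                credibility_threshold = -1)
  checks <- data.frame(
    predictor = names(expected),
    expected_sign = unname(expected),
    observed_sign = sign(coefs[names(expected), "Estimate"]),
    row.names = NULL
  )
  checks$pass <- checks$expected_sign == checks$observed_sign
  structure(list(coefficients = coefs, checks = checks,
                 separation = separation, n = nrow(sweep),
                 n_available = sum(y)),
            class = "ol_availability_fit")
}

#' @export
print.ol_availability_fit <- function(x, ...) {
  cat("Logistic regression: any advisor available (",
      x$n_available, "of", x$n, "runs )\n")
  if (x$separation)
    cat("  WARNING: fitted probabilities numerically 0 or 1",
        "(possible separation)\n")
  stats::printCoefmat(x$coefficients, digits = 4)
  cat("Sign checks:\n")
  print(x$checks, row.names = FALSE)
  invisible(x)
}
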