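#' Configure a simulated nursing unit
#'
#' Builds the validated parameter set for one unit: how many agents of each
#' role it contains, the means of the normal distributions that individual
#' attributes (prior belief, earned authority, motives) and announced
#' evidence are drawn from, and the thresholds and tolerances that govern
#' visibility, availability, uncertainty and belief adoption.
#'
#' All attribute scores live on a 1-100 probability-like scale. Draws are
#' Normal(mean, sd) clipped to \[1, 100\]. Defaults describe an "average"
#' unit: 100 staff nurses, 5 educators, 1 manager, all attribute means at
#' 50, evidence mean 60, credibility threshold 65.
#'
#' @param n_staff Number of staff nurses (>= 1). Staff carry unearned
#'   authority 50.
#' @param n_educators Number of nurse educators (>= 0), unearned authority 80.
#' @param n_managers Number of nurse managers (>= 0), unearned authority 90.
#' @param mean_prior_belief,mean_earned_authority,mean_motives,mean_evidence
#'   Means (in \[1,100\]) of the clipped-normal draws for the corresponding
#'   attribute or for the announced evidence.
#' @param sd_attributes Standard deviation of the attribute draws (> 0).
#' @param sd_evidence Standard deviation of the evidence draw (> 0).
#' @param credibility_threshold Minimum credibility (in \[1,100\]) a visible
#'   agent must reach to be available as an advisor.
#' @param evidence_tolerance,credibility_tolerance Maximum absolute
#'   difference (> 0) an agent accepts between its own belief/credibility
#'   and the announcement before becoming uncertain; also the adoption
#'   bounds (inclusive).
#' @param epistemic_visibility_threshold,pragmatic_visibility_threshold
#'   Prior-belief level an agent's belief must strictly exceed to act on it
#'   (become visible), by motive class. Pragmatic must be strictly lower
#'   than epistemic.
#' @param visible_earned_weight,hidden_earned_weight Weight (in \[0,1\]) on
#'   earned authority in the credibility mix for visible / hidden agents.
#' @param announcer_pool Either "all" (any agent may announce evidence,
#'   the default) or "available" (only currently available agents may).
#' @param seed Optional integer seed recorded with the configuration;
#'   consumed by [init_unit()] when no explicit seed is given.
#'
#' @return An object of class `ol_config` (a validated named list).
#' @seealso [init_unit()], [step_unit()], [time_series_config()]
#' @examples
#' cfg <- unit_config(n_staff = 50, mean_prior_belief = 65)
#' cfg$credibility_threshold
#' @export
unit_config <- function(n_staff = 100L,
                        n_educators = 5L,
                        n_managers = 1L,
                        mean_prior_belief = 50,
                        mean_earned_authority = 50,
                        mean_motives = 50,
                        mean_evidence = 60,
                        sd_attributes = 10,
                        sd_evidence = 10,
                        credibility_threshold = 65,
                        evidence_tolerance = 20,
                        credibility_tolerance = 20,
                        epistemic_visibility_threshold = 70,
                        pragmatic_visibility_threshold = 30,
                        visible_earned_weight = 0.8,
                        hidden_earned_weight = 0.2,
                        announcer_pool = c("all", "available"),
                        seed = NULL) {
  cfg <- list(
    n_staff = n_staff, n_educators = n_educators, n_managers = n_managers,
    mean_prior_belief = mean_prior_belief,
    mean_earned_authority = mean_earned_authority,
    mean_motives = mean_motives, mean_evidence = mean_evidence,
    sd_attributes = sd_attributes, sd_evidence = sd_evidence,
    credibility_threshold = credibility_threshold,
    evidence_tolerance = evidence_tolerance,
    credibility_tolerance = credibility_tolerance,
    epistemic_visibility_threshold = epistemic_visibility_threshold,
    pragmatic_visibility_threshold = pragmatic_visibility_threshold,
    visible_earned_weight = visible_earned_weight,
    hidden_earned_weight = hidden_earned_weight,
    announcer_pool = match.arg(announcer_pool),
    seed = seed
  )
  validate_config(cfg)
}

config_error <- function(key, value, allowed) {
  stop(sprintf("configuration error: `%s` = %s is invalid (allowed: %s)",
               key, paste(format(value), collapse = ", "), allowed),
       call. = FALSE)
}

check_count <- function(cfg, key, min) {
  v <- cfg[[key]]
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != trunc(v) || v < min)
    config_error(key, v, sprintf("integer >= %d", min))
  as.integer(v)
}

check_range <- function(cfg, key, lo, hi, strict_lo = FALSE) {
  v <- cfg[[key]]
  ok <- is.numeric(v) && length(v) == 1L && !is.na(v) &&
    (if (strict_lo) v > lo else v >= lo) && v <= hi
  if (!ok)
    config_error(key, v, sprintf("%s%g, %g]", if (strict_lo) "(" else "[", lo, hi))
  as.numeric(v)
}

validate_config <- function(cfg) {
  cfg$n_staff <- check_count(cfg, "n_staff", 1L)
  cfg$n_educators <- check_count(cfg, "n_educators", 0L)
  cfg$n_managers <- check_count(cfg, "n_managers", 0L)
  for (key in c("mean_prior_belief", "mean_earned_authority",
                "mean_motives", "mean_evidence", "credibility_threshold"))
    cfg[[key]] <- check_range(cfg, key, 1, 100)
  for (key in c("sd_attributes", "sd_evidence",
                "evidence_tolerance", "credibility_tolerance"))
    cfg[[key]] <- check_range(cfg, key, 0, Inf, strict_lo = TRUE)
  for (key in c("visible_earned_weight", "hidden_earned_weight"))
    cfg[[key]] <- check_range(cfg, key, 0, 1)
  for (key in c("epistemic_visibility_threshold",
                "pragmatic_visibility_threshold"))
    cfg[[key]] <- check_range(cfg, key, 0, 100)
  if (cfg$pragmatic_visibility_threshold >= cfg$epistemic_visibility_threshold)
    config_error("pragmatic_visibility_threshold",
                 cfg$pragmatic_visibility_threshold,
                 "strictly below epistemic_visibility_threshold")
  if (!is.null(cfg$seed)) {
    if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed))
      config_error("seed", cfg$seed, "a single integer or NULL")
    cfg$seed <- as.integer(cfg$seed)
  }
  structure(cfg, class = "ol_config")
}

#' @export
print.ol_config <- function(x, ...) {
  cat("<ol_config> unit of", x$n_staff, "staff /", x$n_educators,
      "educators /", x$n_managers, "managers\n")
  cat("  means: prior", x$mean_prior_belief, "| earned",
      x$mean_earned_authority, "| motives", x$mean_motives,
      "| evidence", x$mean_evidence, "\n")
  cat("  credibility threshold", x$credibility_threshold,
      "| tolerances (E, C):", x$evidence_tolerance,
      x$credibility_tolerance, "\n")
  invisible(x)
}

#' Configuration for the individual-agent time-series experiment
#'
#' Bundles the "average unit" settings used for the multi-tick trajectory
#' experiment (100 staff + 5 educators + 1 manager = 106 agents, attribute
#' means 50, evidence mean 60, credibility threshold 65) with the number of
#' ticks to chain (default 20, with full state carry-over between ticks).
#'
#' @param n_ticks Number of chained ticks (>= 1).
#' @param ... Overrides passed on to [unit_config()].
#' @return An object of class `ol_ts_config`: a list with elements `unit`
#'   (an `ol_config`) and `n_ticks`.
#' @export
time_series_config <- function(n_ticks = 20L, ...) {
  n_ticks <- as.integer(n_ticks)
  if (is.na(n_ticks) || n_ticks < 1L)
    config_error("n_ticks", n_ticks, "integer >= 1")
  structure(list(unit = unit_config(...), n_ticks = n_ticks),
            class = "ol_ts_config")
}
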