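#' @keywords internal
ROLES <- c("staff_nurse", "educator", "manager")

# unearned authority is fixed by job position
UNEARNED_AUTHORITY <- c(staff_nurse = 50, educator = 80, manager = 90)

#' Unearned authority assigned by role
#'
#' Staff nurses carry 50, educators 80, nurse managers 90 — credibility a
#' position confers regardless of individual performance.
#'
#' @param role Character vector of roles
#'   (`"staff_nurse"`, `"educator"`, `"manager"`).
#' @return Numeric vector of unearned-authority scores.
#' @export
unearned_authority <- function(role) {
  bad <- !role %in% ROLES
  if (any(bad))
    stop("configuration error: unknown role(s): ",
         paste(unique(role[bad]), collapse = ", "), call. = FALSE)
  unname(UNEARNED_AUTHORITY[role])
}

#' Draw clipped-normal attribute scores
#'
#' Individual attributes and announced evidence are Normal(mean, sd) draws
#' clipped to the 1-100 probability scale. Out-of-range draws are clipped,
#' not resampled, so the ordering of condition means is preserved.
#'
#' @param n Number of draws.
#' @param mean Distribution mean, in \[1, 100\].
#' @param sd Standard deviation, > 0.
#' @return Numeric vector of length `n`, each value in \[1, 100\].
#' @export
sample_attribute <- function(n, mean, sd) {
  if (!is.numeric(mean) || length(mean) != 1L || is.na(mean) ||
      mean < 1 || mean > 100)
    config_error("mean", mean, "[1, 100]")
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd <= 0)
    config_error("sd", sd, "(0, Inf)")
  pmin(pmax(stats::rnorm(n, mean, sd), 1), 100)
}

#' Initialize a unit of agents
#'
#' Creates the agents (staff, then educators, then managers, ids 1..n),
#' draws their prior beliefs, earned authority and motives from the
#' configured clipped-normal distributions, assigns unearned authority by
#' role, and computes initial visibility and credibility. Per-tick state
#' (assessments, links, flags) starts cleared.
#'
#' The unit is an environment (class `ol_unit`) mutated in place by
#' [step_unit()] and [commit_and_reset()].
#'
#' @param config An [unit_config()] object.
#' @param seed Optional integer seed applied before the attribute draws;
#'   falls back to `config$seed`; if both are `NULL` the current RNG state
#'   is used.
#' @return An `ol_unit` environment.
#' @examples
#' unit <- init_unit(unit_config(n_staff = 10, n_educators = 2), seed = 1)
#' head(agent_table(unit))
#' @export
init_unit <- function(config, seed = NULL) {
  stopifnot(inherits(config, "ol_config"))
  seed <- if (!is.null(seed)) as.integer(seed) else config$seed
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_staff + config$n_educators + config$n_managers
  if (n < 1L)
    config_error("n_staff + n_educators + n_managers", n, ">= 1")
  role <- rep(ROLES, times = c(config$n_staff, config$n_educators,
                               config$n_managers))
  unit <- new.env(parent = emptyenv())
  unit$config <- config
  unit$n <- n
  unit$agent_id <- seq_len(n)
  unit$role <- role
  unit$unearned_authority <- unearned_authority(role)
  unit$prior_belief <- sample_attribute(n, config$mean_prior_belief,
                                        config$sd_attributes)
  unit$earned_authority <- sample_attribute(n, config$mean_earned_authority,
                                            config$sd_attributes)
  unit$motives <- sample_attribute(n, config$mean_motives,
                                   config$sd_attributes)
  unit$tick_index <- 0L
  unit$ticked <- FALSE
  unit$global <- NULL
  unit$links <- NULL
  reset_tick_state(unit)
  update_visibility(unit)
  compute_credibility(unit)
  unit$available <- unit$visible &
    unit$credibility >= config$credibility_threshold
  class(unit) <- c("ol_unit", "environment")
  unit
}

# clear everything recomputed within a tick
reset_tick_state <- function(unit) {
  n <- unit$n
  unit$assessed_evidence <- numeric(n)
  unit$assessed_credibility <- numeric(n)
  unit$uncertain <- logical(n)
  unit$sought_advice <- logical(n)
  unit$gave_advice_count <- integer(n)
  unit$out_link_count <- integer(n)
  unit$revised_evidence_assessment <- logical(n)
  unit$revised_credibility_assessment <- logical(n)
  unit$revised_belief <- logical(n)
  unit$new_belief <- unit$prior_belief
  invisible(unit)
}

#' Snapshot the per-agent state as a data frame
#'
#' One row per agent with the identity attributes, the evolving
#' visibility/credibility state, and the per-tick assessment and link
#' columns, in the order used by the per-tick CSV export.
#'
#' @param unit An `ol_unit`.
#' @param tick Optional tick index to stamp as the first column.
#' @return A `data.frame` with one row per agent.
#' @export
agent_table <- function(unit, tick = NULL) {
  df <- data.frame(
    agent_id = unit$agent_id,
    role = unit$role,
    prior_belief = unit$prior_belief,
    motives = unit$motives,
    earned_authority = unit$earned_authority,
    visible = unit$visible,
    credibility = unit$credibility,
    assessed_evidence = unit$assessed_evidence,
    assessed_credibility = unit$assessed_credibility,
    uncertain = unit$uncertain,
    available = unit$available,
    in_links = unit$gave_advice_count,
    out_links = unit$out_link_count,
    revised_belief = unit$revised_belief,
    new_belief = unit$new_belief,
    stringsAsFactors = FALSE
  )
  if (!is.null(tick)) df <- cbind(tick = as.integer(tick), df)
  df
}

#' @export
print.ol_unit <- function(x, ...) {
  cat("<ol_unit>", x$n, "agents (",
      x$config$n_staff, "staff,", x$config$n_educators, "educators,",
      x$config$n_managers, "managers ), tick", x$tick_index, "\n")
  cat("  visible:", sum(x$visible), " available:", sum(x$available),
      " mean belief:", round(mean(x$prior_belief), 2), "\n")
  invisible(x)
}
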