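#' Factor levels for the full-factorial parameter sweep
#'
#' The default levels span substantially different units: small to large
#' (50/100/200 staff nurses), few or several educators (3/7), low or high
#' means for prior belief, earned authority and motives (35/65), weak or
#' strong evidence (40/70), and three advisor credibility thresholds
#' (60/70/80) — a 3 x 2 x 2 x 2 x 2 x 2 x 3 = 288-cell grid.
#'
#' @param n_staff,n_educators,mean_prior_belief,mean_earned_authority,mean_motives,mean_evidence,credibility_threshold
#'   Numeric vectors of levels for each factor (each nonempty).
#' @return An object of class `ol_sweep_levels` (named list of level
#'   vectors, in fixed factor order).
#' @export
sweep_levels <- function(n_staff = c(50, 100, 200),
                         n_educators = c(3, 7),
                         mean_prior_belief = c(35, 65),
                         mean_earned_authority = c(35, 65),
                         mean_motives = c(35, 65),
                         mean_evidence = c(40, 70),
                         credibility_threshold = c(60, 70, 80)) {
  levels <- list(n_staff = n_staff, n_educators = n_educators,
                 mean_prior_belief = mean_prior_belief,
                 mean_earned_authority = mean_earned_authority,
                 mean_motives = mean_motives,
                 mean_evidence = mean_evidence,
                 credibility_threshold = credibility_threshold)
  for (key in names(levels)) {
    v <- levels[[key]]
    if (!is.numeric(v) || length(v) == 0L || anyNA(v))
      config_error(key, v, "a nonempty numeric vector of levels")
  }
  structure(levels, class = "ol_sweep_levels")
}

#' Enumerate the factorial design
#'
#' Expands the factor levels into the full Cartesian product, ordered as
#' nested loops over the factors in their listed order (first factor
#' outermost / varying slowest, last factor varying fastest), so the cell
#' order is deterministic and diffable.
#'
#' @param levels An [sweep_levels()] object.
#' @return A `data.frame` with one row per cell and one column per factor.
#' @examples
#' nrow(build_sweep_design(sweep_levels()))  # 288
#' @export
build_sweep_design <- function(levels = sweep_levels()) {
  if (!inherits(levels, "ol_sweep_levels")) levels <- do.call(sweep_levels, levels)
  # expand.grid varies the first factor fastest; reverse to get nested-loop order
  grid <- expand.grid(rev(unclass(levels)), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(grid)), drop = FALSE]
  rownames(grid) <- NULL
  grid
}

# factor columns of a sweep design / result table, in canonical order
SWEEP_FACTORS <- c("n_staff", "n_educators", "mean_prior_belief",
                   "mean_earned_authority", "mean_motives", "mean_evidence",
                   "credibility_threshold")

# the nine canonical per-run output counts
OUTPUT_COUNTS <- c("not_visible", "visible", "available", "gave_advice",
                   "need_advice", "sought_advice",
                   "revised_evidence_assessment",
                   "revised_credibility_assessment", "revised_beliefs")

# auxiliary per-run outputs carried alongside the counts
OUTPUT_AUX <- c("mean_credibility", "mean_new_belief", "announced_evidence",
                "announcer_credibility", "announcer_id")

#' Run the replicated parameter sweep
#'
#' For every design cell and replicate: derives a reproducible substream
#' seed from the master seed, initializes a fresh unit under that cell's
#' settings, runs exactly one tick, and records the output counts. The
#' substream is derived from the cell's factor VALUES excluding the
#' credibility threshold, plus the replicate index, so (a) a row depends
#' only on its own cell and replicate, never on what else is run, and (b)
#' cells differing only in credibility threshold share identical unit
#' draws and announcements, making availability exactly comparable across
#' thresholds.
#'
#' @param design A design from [build_sweep_design()] (or anything with the
#'   seven factor columns).
#' @param replicates Number of replicates per cell (>= 1, default 50).
#' @param master_seed Master seed for substream derivation.
#' @return A `data.frame` with `nrow(design) * replicates` rows: the seven
#'   factor columns, `replicate`, `seed`, the nine output counts and the
#'   auxiliary outputs.
#' @export
run_sweep <- function(design = build_sweep_design(), replicates = 50L,
                      master_seed = 1L) {
  if (!is.data.frame(design) || nrow(design) == 0L)
    config_error("design", "<empty>", "a nonempty design data.frame")
  missing_cols <- setdiff(SWEEP_FACTORS, names(design))
  if (length(missing_cols))
    stop("configuration error: design lacks factor column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L)
    config_error("replicates", replicates, "integer >= 1")

  ncell <- nrow(design)
  out_cols <- c(OUTPUT_COUNTS, OUTPUT_AUX)
  res <- matrix(NA_real_, nrow = ncell * replicates,
                ncol = 2L + length(out_cols))
  colnames(res) <- c("replicate", "seed", out_cols)
  row <- 0L
  for (i in seq_len(ncell)) {
    cell <- design[i, , drop = FALSE]
    cfg <- unit_config(
      n_staff = cell$n_staff, n_educators = cell$n_educators,
      n_managers = 1L,
      mean_prior_belief = cell$mean_prior_belief,
      mean_earned_authority = cell$mean_earned_authority,
      mean_motives = cell$mean_motives,
      mean_evidence = cell$mean_evidence,
      credibility_threshold = cell$credibility_threshold
    )
    for (r in seq_len(replicates)) {
      s <- derive_seed(master_seed, "cell",
                       cell$n_staff, cell$n_educators,
                       cell$mean_prior_belief, cell$mean_earned_authority,
                       cell$mean_motives, cell$mean_evidence,
                       "rep", r)
      set.seed(s)
      unit <- init_unit(cfg)
      rec <- step_unit(unit)$record
      row <- row + 1L
      res[row, ] <- c(r, s, rec[out_cols])
    }
  }
  cbind(design[rep(seq_len(ncell), each = replicates), , drop = FALSE],
        as.data.frame(res), row.names = NULL)
}

#' Run the individual-agent time series
#'
#' Initializes one unit from the time-series configuration and chains
#' `n_ticks` ticks with full state carry-over ([commit_and_reset()]
#' between ticks): advice links are disconnected, revised beliefs replace
#' prior beliefs, and visibility then credibility are recomputed. Earned
#' authority and motives are drawn once and stay constant throughout.
#'
#' @param config A [time_series_config()].
#' @param master_seed Master seed; the initialization and every tick draw
#'   from their own derived substreams.
#' @return A list with `agents` (one row per tick x agent), `edges` (the
#'   tick-stamped advice edge list: `tick`, `seeker_id`, `advisor_id`),
#'   `records` (one row per tick of output counts) and `unit` (final
#'   state).
#' @examples
#' ts <- run_time_series(time_series_config(n_ticks = 3), master_seed = 7)
#' nrow(ts$agents)  # 3 ticks x 106 agents
#' @export
run_time_series <- function(config = time_series_config(),
                            master_seed = 1L) {
  stopifnot(inherits(config, "ol_ts_config"))
  set.seed(derive_seed(master_seed, "ts-init"))
  unit <- init_unit(config$unit)
  n_ticks <- config$n_ticks
  agents <- vector("list", n_ticks)
  edges <- vector("list", n_ticks)
  records <- vector("list", n_ticks)
  for (t in seq_len(n_ticks)) {
    set.seed(derive_seed(master_seed, "ts-tick", t))
    res <- step_unit(unit)
    agents[[t]] <- agent_table(unit, tick = t)
    edges[[t]] <- res$links
    records[[t]] <- as.data.frame(as.list(res$record))
    commit_and_reset(unit)
  }
  list(agents = do.call(rbind, agents),
       edges = do.call(rbind, edges),
       records = do.call(rbind, records),
       unit = unit)
}

#' Agents that repeatedly receive advice links
#'
#' An opinion leader is operationalized as an agent that uncertain peers
#' link to over multiple time points. This counts, for each advisor, the
#' number of DISTINCT ticks at which it received at least one in-link and
#' returns those meeting the cutoff.
#'
#' @param edges Edge list from [run_time_series()] (columns `tick`,
#'   `seeker_id`, `advisor_id`).
#' @param min_ticks Minimum number of distinct link-bearing ticks
#'   (default 2; 1 returns every agent that ever advised).
#' @return Sorted integer vector of advisor agent ids.
#' @export
identify_persistent_advisors <- function(edges, min_ticks = 2L) {
  if (is.null(edges) || nrow(edges) == 0L) return(integer(0))
  ticks_per_advisor <- tapply(edges$tick, edges$advisor_id,
                              function(t) length(unique(t)))
  sort(as.integer(names(ticks_per_advisor)[ticks_per_advisor >= min_ticks]))
}
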