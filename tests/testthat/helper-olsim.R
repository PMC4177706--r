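# shared fixtures, built in code

# a small unit that ticks fast
small_config <- function(...) {
  unit_config(n_staff = 10L, n_educators = 2L, n_managers = 1L, ...)
}

# unit with fully controlled agent state: overwrite the drawn attributes,
# then recompute the derived state exactly as init_unit does
forced_unit <- function(prior_belief, motives,
                        earned_authority = rep(50, length(prior_belief)),
                        role = rep("staff_nurse", length(prior_belief)),
                        config = NULL) {
  n <- length(prior_belief)
  n_staff <- sum(role == "staff_nurse")
  if (is.null(config))
    config <- unit_config(n_staff = max(n_staff, 1L),
                          n_educators = sum(role == "educator"),
                          n_managers = sum(role == "manager"))
  unit <- init_unit(config, seed = 1L)
  stopifnot(unit$n == n)
  unit$prior_belief <- as.numeric(prior_belief)
  unit$motives <- as.numeric(motives)
  unit$earned_authority <- as.numeric(earned_authority)
  unit$new_belief <- unit$prior_belief
  update_visibility(unit)
  compute_credibility(unit)
  unit$available <- unit$visible &
    unit$credibility >= config$credibility_threshold
  unit
}

# check every structural invariant of one completed tick
expect_tick_invariants <- function(unit, res) {
  rec <- res$record
  n <- unit$n
  expect_true(all(unit$prior_belief >= 1 & unit$prior_belief <= 100))
  expect_true(all(unit$new_belief >= 1 & unit$new_belief <= 100))
  expect_true(all(unit$credibility >= 1 & unit$credibility <= 100))
  # conservation
  expect_identical(unname(rec["not_visible"] + rec["visible"]), as.numeric(n))
  expect_equal(sum(unit$out_link_count), sum(unit$gave_advice_count))
  expect_equal(sum(unit$out_link_count), nrow(res$links))
  # subset structure
  expect_true(all(which(unit$available) %in% which(unit$visible)))
  expect_true(all(which(unit$gave_advice_count > 0) %in%
                    which(unit$available)))
  expect_true(all(which(unit$out_link_count > 0) %in%
                    which(unit$uncertain)))
  expect_lte(rec[["sought_advice"]], rec[["need_advice"]])
  # links are valid seeker -> advisor pairs
  if (nrow(res$links)) {
    expect_true(all(res$links$seeker_id != res$links$advisor_id))
    expect_true(all(unit$uncertain[res$links$seeker_id]))
    expect_true(all(unit$available[res$links$advisor_id]))
  }
  # unrevised agents stage no belief change
  keep <- !unit$revised_belief
  expect_identical(unit$new_belief[keep], unit$prior_belief[keep])
}
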