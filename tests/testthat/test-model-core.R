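test_that("sample_attribute draws a clipped normal with the requested mean", {
  set.seed(11)
  x <- sample_attribute(10000, 65, 10)
  expect_true(all(x >= 1 & x <= 100))
  expect_lt(abs(mean(x) - 65), 0.5)  # clipping negligible at mean 65

  set.seed(12)
  lo <- sample_attribute(2000, 1, 10)
  expect_true(all(lo >= 1))
  expect_gt(mean(lo == 1), 0.3)  # about half the mass clips at the floor

  set.seed(13)
  expect_equal(sample_attribute(5, 50, 1e-12), rep(50, 5), tolerance = 1e-9)

  expect_error(sample_attribute(1, 0.5, 10), "mean")
  expect_error(sample_attribute(1, 50, -1), "sd")
})

test_that("motive classification splits at 50 and sets the action threshold", {
  expect_identical(classify_motive(c(49, 50, 88)),
                   c("pragmatic", "epistemic", "epistemic"))
  cfg <- unit_config()
  expect_identical(visibility_threshold(c(88, 30, 50), cfg), c(70, 30, 70))
})

test_that("visibility requires prior belief strictly above the threshold", {
  unit <- forced_unit(prior_belief = c(75, 70, 35, 30, rep(50, 9)),
                      motives = c(88, 88, 30, 30, rep(50, 9)),
                      role = c(rep("staff_nurse", 10),
                               rep("educator", 2), "manager"))
  expect_identical(unit$visible[1:4], c(TRUE, FALSE, TRUE, FALSE))
})

test_that("credibility is the visibility-weighted authority mix", {
  cfg <- unit_config()
  expect_equal(credibility_score(60, 50, TRUE, cfg), 58)
  expect_equal(credibility_score(60, 50, FALSE, cfg), 52)
  expect_equal(credibility_score(50, 50, TRUE, cfg), 50)
  expect_equal(credibility_score(50, 50, FALSE, cfg), 50)
  # clipped into [1, 100]
  expect_equal(credibility_score(100, 90, TRUE,
                                 unit_config(visible_earned_weight = 1)), 100)
  expect_identical(unearned_authority(c("staff_nurse", "educator", "manager")),
                   c(50, 80, 90))
  expect_error(unearned_authority("janitor"), "unknown role")
})

test_that("assessments are absolute differences", {
  expect_equal(assess_evidence(60, 70), 10)
  expect_equal(assess_evidence(55, 55), 0)
  expect_equal(assess_evidence(1, 100), 99)
  expect_equal(assess_announcer_credibility(58, 90), 32)
  for (i in 1:20) {
    a <- runif(1, 1, 100); b <- runif(1, 1, 100)
    expect_identical(assess_announcer_credibility(a, b),
                     assess_announcer_credibility(b, a))
  }
})

test_that("uncertainty is the OR, adoption the AND, of the tolerances", {
  cfg <- unit_config()  # both tolerances 20
  expect_false(determine_uncertainty(0, 0, cfg))
  expect_true(determine_uncertainty(25, 0, cfg))
  expect_true(determine_uncertainty(0, 25, cfg))
  expect_true(adoption_decision(0, 0, cfg))
  expect_false(adoption_decision(21, 0, cfg))
  expect_true(adoption_decision(20, 20, cfg))  # inclusive boundary
  # exact complements for any assessment pair
  ae <- runif(50, 0, 60); ac <- runif(50, 0, 60)
  expect_identical(adoption_decision(ae, ac, cfg),
                   !determine_uncertainty(ae, ac, cfg))
})

test_that("belief revision is the credibility-weighted step toward evidence", {
  expect_equal(revise_belief(60, 60, 80), 60)    # fixed point
  expect_equal(revise_belief(50, 70, 100), 70)   # fully credible announcer
  expect_equal(revise_belief(50, 70, 50), 60)    # hand-computed midpoint
  expect_true(all(revise_belief(runif(100, 1, 100), runif(100, 1, 100),
                                runif(100, 1, 100)) >= 1))
})

test_that("announce_evidence draws uniformly from the configured pool", {
  unit <- init_unit(unit_config(n_staff = 1, n_educators = 0,
                                n_managers = 0), seed = 3)
  g <- announce_evidence(unit)
  expect_identical(g$announcer_id, 1L)  # forced choice
  expect_equal(g$announcer_credibility, unit$credibility[1])

  unit2 <- init_unit(unit_config(n_staff = 5, mean_evidence = 70,
                                 sd_evidence = 1e-12), seed = 4)
  expect_equal(announce_evidence(unit2)$announced_evidence, 70,
               tolerance = 1e-9)

  # empty pool errors (restricted announcer pool, nobody available)
  unit3 <- forced_unit(rep(10, 13), rep(80, 13),
                       role = c(rep("staff_nurse", 10),
                                rep("educator", 2), "manager"),
                       config = unit_config(n_staff = 10, n_educators = 2,
                                            announcer_pool = "available"))
  expect_false(any(unit3$available))
  expect_error(announce_evidence(unit3), "empty")
})

test_that("advice seeking handles empty, singleton and forced pools", {
  cfg <- small_config(credibility_threshold = 99)  # nobody can advise
  unit <- init_unit(cfg, seed = 5)
  res <- step_unit(unit)
  expect_identical(nrow(res$links), 0L)
  expect_equal(unname(res$record[["sought_advice"]]), 0)
  # untouched assessments: still the agent's own differences
  g <- res$global
  own <- abs(unit$prior_belief - g$announced_evidence)
  own[g$announcer_id] <- 0
  expect_equal(unit$assessed_evidence, own)

  # exactly one advisor: every seeker links to it
  unit2 <- forced_unit(
    prior_belief = c(80, rep(15, 9), 15, 15, 15),
    motives = c(88, rep(88, 9), 88, 88, 88),
    earned_authority = c(90, rep(30, 12)),
    role = c(rep("staff_nurse", 10), rep("educator", 2), "manager"),
    config = unit_config(n_staff = 10, n_educators = 2,
                         credibility_threshold = 65,
                         mean_evidence = 90, sd_evidence = 1e-12))
  expect_identical(find_available_advisors(unit2), 1L)
  set.seed(6)
  res2 <- step_unit(unit2)
  if (res2$global$announcer_id != 1L && nrow(res2$links) > 0) {
    expect_true(all(res2$links$advisor_id == 1L))
    # seekers adopt the advisor's perspective on the evidence
    e <- res2$global$announced_evidence
    expect_equal(unit2$assessed_evidence[res2$links$seeker_id],
                 rep(abs(unit2$prior_belief[1] - e), nrow(res2$links)))
  }
})

test_that("generous tolerances yield zero uncertainty and zero links", {
  cfg <- small_config(evidence_tolerance = 1000,
                      credibility_tolerance = 1000)
  unit <- init_unit(cfg, seed = 7)
  res <- step_unit(unit)
  expect_equal(unname(res$record[["need_advice"]]), 0)
  expect_identical(nrow(res$links), 0L)
  # everyone but the announcer adopts
  expect_equal(unname(res$record[["revised_beliefs"]]), unit$n - 1)
})

test_that("identical agents matching the evidence are a fixed point", {
  unit <- forced_unit(rep(60, 13), rep(50, 13),
                      role = c(rep("staff_nurse", 10),
                               rep("educator", 2), "manager"),
                      config = unit_config(n_staff = 10, n_educators = 2,
                                           mean_evidence = 60,
                                           sd_evidence = 1e-12))
  res <- step_unit(unit)
  expect_equal(unit$new_belief, unit$prior_belief, tolerance = 1e-9)
})

test_that("commit replaces beliefs only for revisers and resets state", {
  cfg <- small_config()
  unit <- init_unit(cfg, seed = 8)
  expect_error(commit_and_reset(unit), "before any tick")
  step_unit(unit)
  before <- unit$prior_belief
  staged <- unit$new_belief
  revised <- unit$revised_belief
  commit_and_reset(unit)
  # the belief-commit bug regression: non-revisers keep their prior belief
  expect_identical(unit$prior_belief[!revised], before[!revised])
  expect_identical(unit$prior_belief[revised], staged[revised])
  expect_null(unit$links)
  expect_true(all(unit$out_link_count == 0L))
  expect_true(all(unit$gave_advice_count == 0L))
  expect_false(any(unit$uncertain))

  # an epistemic agent revised up to 80 becomes visible on the next tick
  unit$revised_belief[1] <- TRUE
  unit$new_belief[1] <- 80
  unit$motives[1] <- 88
  unit$ticked <- TRUE
  commit_and_reset(unit)
  expect_true(unit$visible[1])
})
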