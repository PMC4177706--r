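#' Classify an agent's motives
#'
#' Motive scores below 50 are pragmatic (the agent acts to maximize
#' practical interest); scores of 50 and above are epistemic (the agent
#' acts to maximize belief accuracy).
#'
#' @param motives Numeric vector of motive scores in \[1, 100\].
#' @return Character vector, `"pragmatic"` or `"epistemic"`.
#' @export
classify_motive <- function(motives) {
  ifelse(motives < 50, "pragmatic", "epistemic")
}

#' Prior-belief threshold for acting on a belief
#'
#' Epistemic agents demand a high level of confidence before acting
#' (default 70); pragmatic agents act at a lower level (default 30). An
#' agent is visible only when its prior belief strictly exceeds this
#' threshold.
#'
#' @param motives Numeric vector of motive scores.
#' @param config An [unit_config()]; supplies the two threshold levels.
#' @return Numeric vector of thresholds.
#' @export
visibility_threshold <- function(motives, config = unit_config()) {
  ifelse(classify_motive(motives) == "epistemic",
         config$epistemic_visibility_threshold,
         config$pragmatic_visibility_threshold)
}

#' Recompute which agents act on their beliefs
#'
#' An agent is visible iff its prior belief strictly exceeds the
#' motive-dependent threshold from [visibility_threshold()]. Mutates
#' `unit$visible`.
#'
#' @param unit An `ol_unit`.
#' @return The logical visibility vector, invisibly.
#' @export
update_visibility <- function(unit) {
  unit$visible <- unit$prior_belief >
    visibility_threshold(unit$motives, unit$config)
  invisible(unit$visible)
}

#' Credibility as a visibility-weighted authority mix
#'
#' Credibility is w * earned + (1 - w) * unearned authority, where the
#' earned-authority weight w is high (default 0.8) for visible agents —
#' peers judge them on performance — and low (default 0.2) for hidden
#' agents, whose credibility rests mostly on job position. Clipped to
#' \[1, 100\].
#'
#' @param earned,unearned Authority scores.
#' @param visible Logical: is the agent acting on its beliefs?
#' @param config An [unit_config()]; supplies the two weights.
#' @return Numeric credibility scores in \[1, 100\].
#' @export
credibility_score <- function(earned, unearned, visible,
                              config = unit_config()) {
  w <- ifelse(visible, config$visible_earned_weight,
              config$hidden_earned_weight)
  pmin(pmax(w * earned + (1 - w) * unearned, 1), 100)
}

#' Recompute all agents' credibility
#'
#' Applies [credibility_score()] to every agent using current visibility.
#' Mutates `unit$credibility`.
#'
#' @param unit An `ol_unit`.
#' @return The numeric credibility vector, invisibly.
#' @export
compute_credibility <- function(unit) {
  unit$credibility <- credibility_score(unit$earned_authority,
                                        unit$unearned_authority,
                                        unit$visible, unit$config)
  invisible(unit$credibility)
}

#' Announce new evidence
#'
#' One agent, drawn uniformly at random (from all agents by default, or
#' from currently available agents when `announcer_pool = "available"`),
#' broadcasts a new evidence value drawn from the configured clipped-normal
#' evidence distribution. The announcer's current credibility becomes
#' globally visible alongside the evidence.
#'
#' @param unit An `ol_unit`.
#' @return A list (the global state): `announcer_id`, `announced_evidence`,
#'   `announcer_credibility`, `tick_index`.
#' @export
announce_evidence <- function(unit) {
  cfg <- unit$config
  pool <- if (cfg$announcer_pool == "available")
    which(unit$available) else seq_len(unit$n)
  if (length(pool) == 0L)
    stop("configuration error: announcer pool is empty ",
         "(no agent is available to announce)", call. = FALSE)
  announcer <- pool[sample.int(length(pool), 1L)]
  list(announcer_id = announcer,
       announced_evidence = sample_attribute(1L, cfg$mean_evidence,
                                             cfg$sd_evidence),
       announcer_credibility = unit$credibility[announcer],
       tick_index = unit$tick_index + 1L)
}

#' Evidence assessment
#'
#' An agent judges new evidence by how far it sits from its own prior
#' belief: the absolute difference between the two scores.
#'
#' @param prior_belief,announced_evidence Scores in \[1, 100\].
#' @return Non-negative difference score.
#' @export
assess_evidence <- function(prior_belief, announced_evidence) {
  abs(prior_belief - announced_evidence)
}

#' Announcer-credibility assessment
#'
#' An agent compares its own credibility with the announcer's: the
#' absolute difference between the two scores.
#'
#' @param own_credibility,announcer_credibility Scores in \[1, 100\].
#' @return Non-negative difference score.
#' @export
assess_announcer_credibility <- function(own_credibility,
                                         announcer_credibility) {
  abs(own_credibility - announcer_credibility)
}

#' Does the agent need advice?
#'
#' An agent is uncertain — and so needs advice — when EITHER assessment
#' exceeds its tolerance: the evidence sits more than `evidence_tolerance`
#' from the prior belief, or the announcer's credibility differs from the
#' agent's own by more than `credibility_tolerance`.
#'
#' @param assessed_evidence,assessed_credibility Difference scores.
#' @param config An [unit_config()].
#' @return Logical.
#' @export
determine_uncertainty <- function(assessed_evidence, assessed_credibility,
                                  config = unit_config()) {
  assessed_evidence > config$evidence_tolerance |
    assessed_credibility > config$credibility_tolerance
}

#' Agents available to give advice
#'
#' Exactly the agents that are visible AND whose credibility meets the
#' unit's credibility threshold (inclusive).
#'
#' @param unit An `ol_unit`.
#' @return Integer vector of agent ids.
#' @export
find_available_advisors <- function(unit) {
  which(unit$visible &
          unit$credibility >= unit$config$credibility_threshold)
}

#' Adopt the announced evidence?
#'
#' The complement of uncertainty: an agent adopts when BOTH assessments
#' fall within tolerance (inclusive boundaries).
#'
#' @inheritParams determine_uncertainty
#' @return Logical.
#' @export
adoption_decision <- function(assessed_evidence, assessed_credibility,
                              config = unit_config()) {
  assessed_evidence <= config$evidence_tolerance &
    assessed_credibility <= config$credibility_tolerance
}

#' Belief revision rule
#'
#' An adopting agent moves its belief toward the evidence by a fraction
#' equal to the announcer's credibility on the unit scale:
#' `new = prior + (credibility / 100) * (evidence - prior)`, clipped to
#' \[1, 100\]. A fully credible announcer (100) moves the belief all the
#' way to the evidence; belief equal to the evidence is a fixed point.
#'
#' @param prior_belief,announced_evidence Scores in \[1, 100\].
#' @param announcer_credibility Score in \[1, 100\].
#' @return Revised belief in \[1, 100\].
#' @export
revise_belief <- function(prior_belief, announced_evidence,
                          announcer_credibility) {
  pmin(pmax(prior_belief + (announcer_credibility / 100) *
              (announced_evidence - prior_belief), 1), 100)
}

#' Run one tick of the unit
#'
#' Executes the full per-tick sequence, mutating the unit in place:
#' \enumerate{
#'   \item one agent announces evidence ([announce_evidence()]);
#'   \item every other agent assesses the evidence and the announcer's
#'     credibility (absolute differences) and determines uncertainty
#'     (the announcer does not assess its own announcement);
#'   \item available advisors are identified (visible + credibility
#'     threshold);
#'   \item each uncertain agent picks one advisor uniformly at random from
#'     the available pool excluding itself (if any), creating a directed
#'     seeker-to-advisor link and replacing its own assessments with the
#'     advisor's perspective: |advisor prior - evidence| and
#'     |advisor credibility - announcer credibility|; an assessment counts
#'     as "revised" when the advice moved it across its tolerance (the
#'     agent's judgment on that dimension changed);
#'   \item every agent (except the announcer) applies the adoption rule to
#'     its final assessments and, if adopting, revises its belief via
#'     [revise_belief()]; otherwise `new_belief` stays at `prior_belief`.
#' }
#' Beliefs are staged in `new_belief`; they replace `prior_belief` only at
#' [commit_and_reset()].
#'
#' @param unit An `ol_unit`.
#' @return A list with `record` (named numeric: the nine output counts
#'   `not_visible`, `visible`, `available`, `gave_advice`, `need_advice`,
#'   `sought_advice`, `revised_evidence_assessment`,
#'   `revised_credibility_assessment`, `revised_beliefs`, plus auxiliary
#'   `mean_credibility`, `mean_new_belief`, `announced_evidence`,
#'   `announcer_credibility`, `announcer_id`, `tick`), `links` (data.frame
#'   `tick`, `seeker_id`, `advisor_id`) and `global` (the announcement).
#' @export
step_unit <- function(unit) {
  stopifnot(inherits(unit, "ol_unit"))
  cfg <- unit$config
  n <- unit$n
  t <- unit$tick_index + 1L
  unit$tick_index <- t

  reset_tick_state(unit)
  g <- announce_evidence(unit)
  ann <- g$announcer_id
  ev <- g$announced_evidence
  cred_ann <- g$announcer_credibility
  unit$global <- g

  ae <- assess_evidence(unit$prior_belief, ev)
  ac <- assess_announcer_credibility(unit$credibility, cred_ann)
  ae[ann] <- 0
  ac[ann] <- 0
  uncertain <- determine_uncertainty(ae, ac, cfg)
  uncertain[ann] <- FALSE

  unit$available <- unit$visible &
    unit$credibility >= cfg$credibility_threshold
  advisors <- which(unit$available)

  seekers <- which(uncertain)
  link_seeker <- integer(0)
  link_advisor <- integer(0)
  if (length(seekers) && length(advisors)) {
    link_seeker <- link_advisor <- integer(length(seekers))
    k <- 0L
    for (s in seekers) {
      pool <- advisors[advisors != s]
      if (length(pool) == 0L) next
      adv <- pool[sample.int(length(pool), 1L)]
      k <- k + 1L
      link_seeker[k] <- s
      link_advisor[k] <- adv
      new_ae <- assess_evidence(unit$prior_belief[adv], ev)
      new_ac <- assess_announcer_credibility(unit$credibility[adv], cred_ann)
      # a "revised" assessment is one the advice flipped across its
      # tolerance: a changed judgment, not merely a changed number (with
      # continuous draws the numeric value almost surely changes for every
      # seeker, which would make these counts degenerate copies of the
      # sought-advice count)
      unit$revised_evidence_assessment[s] <-
        (new_ae <= cfg$evidence_tolerance) != (ae[s] <= cfg$evidence_tolerance)
      unit$revised_credibility_assessment[s] <-
        (new_ac <= cfg$credibility_tolerance) !=
          (ac[s] <= cfg$credibility_tolerance)
      ae[s] <- new_ae
      ac[s] <- new_ac
    }
    length(link_seeker) <- k
    length(link_advisor) <- k
    unit$sought_advice[link_seeker] <- TRUE
    unit$out_link_count[link_seeker] <- unit$out_link_count[link_seeker] + 1L
    tab <- tabulate(link_advisor, nbins = n)
    unit$gave_advice_count <- unit$gave_advice_count + tab
  }

  adopt <- adoption_decision(ae, ac, cfg)
  adopt[ann] <- FALSE  # announcer does not act on its own announcement
  unit$assessed_evidence <- ae
  unit$assessed_credibility <- ac
  unit$uncertain <- uncertain
  unit$revised_belief <- adopt
  nb <- unit$prior_belief
  if (any(adopt))
    nb[adopt] <- revise_belief(unit$prior_belief[adopt], ev, cred_ann)
  unit$new_belief <- nb
  unit$ticked <- TRUE

  links <- data.frame(tick = rep(t, length(link_seeker)),
                      seeker_id = link_seeker, advisor_id = link_advisor)
  unit$links <- links

  record <- c(
    not_visible = n - sum(unit$visible),
    visible = sum(unit$visible),
    available = length(advisors),
    gave_advice = sum(unit$gave_advice_count > 0L),
    need_advice = sum(uncertain),
    sought_advice = sum(unit$sought_advice),
    revised_evidence_assessment = sum(unit$revised_evidence_assessment),
    revised_credibility_assessment = sum(unit$revised_credibility_assessment),
    revised_beliefs = sum(adopt),
    mean_credibility = mean(unit$credibility),
    mean_new_belief = mean(nb),
    announced_evidence = ev,
    announcer_credibility = cred_ann,
    announcer_id = ann,
    tick = t
  )
  list(record = record, links = links, global = g)
}

#' Commit revised beliefs and reset for the next tick
#'
#' Ends a tick in continuous mode: disconnects all advice links, replaces
#' `prior_belief` with `new_belief` ONLY for agents that actually revised
#' (all others keep their prior belief unchanged), recomputes visibility
#' from the new beliefs and then credibility from the new visibility, and
#' clears all per-tick assessments, flags and link counts.
#'
#' @param unit An `ol_unit` on which [step_unit()] has been run.
#' @return The unit, invisibly.
#' @export
commit_and_reset <- function(unit) {
  stopifnot(inherits(unit, "ol_unit"))
  if (!isTRUE(unit$ticked))
    stop("state error: commit_and_reset() called before any tick",
         call. = FALSE)
  rev <- unit$revised_belief
  unit$prior_belief[rev] <- unit$new_belief[rev]
  reset_tick_state(unit)
  update_visibility(unit)
  compute_credibility(unit)
  unit$available <- unit$visible &
    unit$credibility >= unit$config$credibility_threshold
  unit$links <- NULL
  unit$global <- NULL
  unit$ticked <- FALSE
  invisible(unit)
}
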