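# Analyses over engine output: attribution of lives saved to individual
# interventions, missed-opportunity ranking, input-data summaries, and the
# modeled-versus-measured gap table.

#' Attribute lives saved to individual interventions
#'
#' Within each (year, group, cause) cell, intervention i receives the share
#' (1 - m_i) / sum_j (1 - m_j) of the cell's total lives saved, where m_i
#' is the intervention's combined survival multiplier on that cell: its
#' direct multiplier times its share of every risk-factor path it feeds
#' (split by the same proportional rule within the risk factor).  The
#' proportional rule is order-free and conserves the total exactly; when no
#' intervention moves the cell (sum of losses is zero) every share is zero.
#'
#' @param profile The `ls_profile` the result was projected from.
#' @param scn The `ls_scenario` used.
#' @param result The `ls_projection` returned by [project()] on the same
#'   inputs.
#' @return Data frame (`ls_attribution`) with columns `year`, `group`,
#'   `cause`, `intervention`, `lives_saved`.
#' @export
attribute_lives_saved <- function(profile, scn, result) {
  validate_profile(profile)
  validate_scenario(scn, profile)
  if (!inherits(result, "ls_projection"))
    ls_consistency_error("result must be an ls_projection from project()")
  H <- profile$demography$horizon
  if (result$meta$horizon != H ||
      !setequal(unique(result$deaths$group), names(profile$envelopes)))
    ls_consistency_error(
      "result does not match the profile (horizon or groups differ)")
  paths <- coverage_paths(profile, scn)
  directs <- direct_multiplier_records(profile, paths)
  risks <- risk_factor_records(profile, paths)
  ids <- names(profile$interventions)
  d <- result$deaths
  rows <- vector("list", nrow(d))
  for (r in seq_len(nrow(d))) {
    if (length(ids) == 0) break
    m_i <- per_intervention_multipliers(profile, directs, risks, d$group[r],
                                        d$cause[r], d$year[r] + 1L)
    loss <- 1 - m_i
    tot <- sum(loss)
    share <- if (tot == 0) rep(0, length(ids)) else loss / tot
    rows[[r]] <- data.frame(year = d$year[r], group = d$group[r],
                            cause = d$cause[r], intervention = ids,
                            lives_saved = unname(d$lives_saved[r] * share),
                            stringsAsFactors = FALSE)
  }
  out <- if (length(ids) == 0)
    data.frame(year = integer(), group = character(), cause = character(),
               intervention = character(), lives_saved = numeric())
  else do.call(rbind, rows)
  class(out) <- c("ls_attribution", "data.frame")
  out
}

#' Rank interventions by missed opportunity
#'
#' For each intervention in turn, projects a solo scale-up from its
#' baseline coverage to a standard target (linear ramp from year 1 to the
#' horizon) and records the lives saved in the horizon year.  Interventions
#' already at or above the target have no headroom and score zero.  Returns
#' the interventions sorted by deaths averted (non-increasing; ties broken
#' by id).
#'
#' @param profile A validated `ls_profile`.
#' @param standard_target Coverage every intervention is scaled to
#'   (default 0.9, a conventional programme target).
#' @return Data frame (`ls_ranking`) with columns `intervention`, `name`,
#'   `baseline_coverage`, `deaths_averted`.
#' @export
rank_missed_opportunities <- function(profile, standard_target = 0.9) {
  validate_profile(profile)
  check_proportion(standard_target, "standard_target")
  H <- profile$demography$horizon
  rows <- lapply(profile$interventions, function(iv) {
    target <- max(iv$baseline_coverage, standard_target)
    scn <- scenario(sprintf("solo:%s", iv$id),
                    stats::setNames(target, iv$id), 1L, H)
    averted <- tryCatch({
      res <- project(profile, scn)
      sum(res$deaths$lives_saved[res$deaths$year == H])
    }, ls_saturation_error = function(e) {
      warning(sprintf("intervention %s saturated at baseline: %s", iv$id,
                      conditionMessage(e)), call. = FALSE)
      0
    })
    data.frame(intervention = iv$id, name = iv$name,
               baseline_coverage = iv$baseline_coverage,
               deaths_averted = averted, stringsAsFactors = FALSE)
  })
  out <- if (length(rows) == 0)
    data.frame(intervention = character(), name = character(),
               baseline_coverage = numeric(), deaths_averted = numeric())
  else do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(-out$deaths_averted, out$intervention), ]
  rownames(out) <- NULL
  class(out) <- c("ls_ranking", "data.frame")
  out
}

#' Summarise the input data of a profile
#'
#' The explore-data view: what a planner should eyeball before modelling.
#'
#' @param profile A validated `ls_profile`.
#' @return A list (`ls_summary`) of data frames: `coverage` (intervention x
#'   baseline coverage), `causes` (group x cause x fraction x baseline-year
#'   deaths), `mortality` (group x base rate and units), `risk_factors`
#'   (state prevalences; zero rows when the profile has none).
#' @export
explore_summary <- function(profile) {
  validate_profile(profile)
  coverage <- data.frame(
    intervention = vapply(profile$interventions, `[[`, "", "id"),
    name = vapply(profile$interventions, `[[`, "", "name"),
    baseline_coverage = vapply(profile$interventions, `[[`, 0, "baseline_coverage"),
    stringsAsFactors = FALSE, row.names = NULL)
  grid <- cause_grid(profile)
  denom0 <- vapply(grid$group, function(g) ls_denominator(profile, g)[1],
                   numeric(1))
  causes <- data.frame(
    group = grid$group, cause = grid$cause, fraction = grid$fraction,
    baseline_deaths = denom0 * grid$base_rate /
      vapply(grid$group, ls_rate_scale, numeric(1)) * grid$fraction,
    stringsAsFactors = FALSE, row.names = NULL)
  mortality <- data.frame(
    group = vapply(profile$envelopes, `[[`, "", "group"),
    base_rate = vapply(profile$envelopes, `[[`, 0, "base_rate"),
    per = vapply(vapply(profile$envelopes, `[[`, "", "group"), ls_rate_scale,
                 numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  risk_factors <- if (length(profile$risk_factors) == 0)
    data.frame(risk_factor = character(), state = character(),
               prevalence = numeric())
  else do.call(rbind, lapply(profile$risk_factors, function(rf)
    data.frame(risk_factor = rf$id, state = rf$states,
               prevalence = unname(rf$baseline_prevalence[rf$states]),
               stringsAsFactors = FALSE, row.names = NULL)))
  rownames(risk_factors) <- NULL
  structure(list(coverage = coverage, causes = causes, mortality = mortality,
                 risk_factors = risk_factors),
            class = "ls_summary")
}

#' @export
print.ls_summary <- function(x, ...) {
  cat("== mortality envelopes ==\n"); print(x$mortality)
  cat("== causes of death (baseline year) ==\n"); print(x$causes)
  cat("== intervention coverage ==\n"); print(x$coverage)
  if (nrow(x$risk_factors) > 0) {
    cat("== risk factors ==\n"); print(x$risk_factors)
  }
  invisible(x)
}

#' Convert a proportional mortality reduction to an absolute one
#'
#' Reporting helper: a modelled proportional reduction of r on a baseline
#' rate of R deaths per 1,000 live births is an absolute reduction of
#' R * r deaths per 1,000 live births (e.g. 5% of an under-five mortality
#' rate of 60 per 1,000 is 3 deaths per 1,000 live births) — the number an
#' evaluation survey would have to be powered to detect.
#'
#' @param base_rate Baseline mortality rate (deaths per 1,000 live births).
#' @param proportional_reduction Modelled proportional reduction in `[0, 1]`.
#' @return Absolute rate reduction, same units as `base_rate`.
#' @export
proportional_to_absolute <- function(base_rate, proportional_reduction) {
  if (!is.numeric(base_rate) || anyNA(base_rate) || any(base_rate < 0))
    ls_domain_error("base_rate must be >= 0")
  check_proportion(proportional_reduction, "proportional_reduction")
  base_rate * proportional_reduction
}

#' Compare modelled mortality rates with measured ones
#'
#' Aligns the scenario projection with an observed mortality-rate series
#' for one outcome group and reports, per overlapping year, the modelled
#' rate, the measured rate, and the absolute and relative gaps.  Years
#' missing from the measured series are dropped, never interpolated; this
#' is a learning comparison, not a statistical test.
#'
#' @param result An `ls_projection`.
#' @param measured Data frame with columns `year` (offsets matching the
#'   projection) and `rate` (in the group's units), or a numeric vector
#'   named by year.
#' @param group Outcome group to compare (must be present in the result).
#' @return Data frame with columns `year`, `modeled_rate`, `measured_rate`,
#'   `gap_absolute` (modeled - measured) and `gap_relative`
#'   (gap / measured).
#' @export
compare_to_measured <- function(result, measured, group) {
  if (!inherits(result, "ls_projection"))
    ls_consistency_error("result must be an ls_projection from project()")
  if (is.numeric(measured) && !is.null(names(measured)))
    measured <- data.frame(year = as.integer(names(measured)),
                           rate = unname(measured))
  if (!all(c("year", "rate") %in% names(measured)))
    ls_format_error("measured must have columns 'year' and 'rate'")
  den <- result$denominators
  den <- den[den$group == group, ]
  if (nrow(den) == 0)
    ls_alignment_error(sprintf("group '%s' not present in the projection",
                               group))
  d <- result$deaths[result$deaths$group == group, ]
  scen <- stats::aggregate(deaths_scenario ~ year, data = d, FUN = sum)
  scen <- merge(scen, den[, c("year", "denominator", "scale")], by = "year")
  scen$modeled_rate <- scen$deaths_scenario / scen$denominator * scen$scale
  years <- intersect(scen$year, measured$year)
  if (length(years) == 0)
    ls_alignment_error("no overlapping years between projection and measurement")
  out <- merge(scen[scen$year %in% years, c("year", "modeled_rate")],
               measured[measured$year %in% years, c("year", "rate")],
               by = "year")
  names(out)[names(out) == "rate"] <- "measured_rate"
  out$gap_absolute <- out$modeled_rate - out$measured_rate
  out$gap_relative <- out$gap_absolute / out$measured_rate
  out <- out[order(out$year), ]
  rownames(out) <- NULL
  out
}
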