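# Projection core.
#
# Baseline deaths for a cell (year, group, cause) are
#   denominator(year) * base_rate / scale * cause_fraction,
# with rates held constant at baseline: distal secular trends are assumed
# to be expressed through intervention coverage, so only the modelled
# multipliers move deaths.  Scenario deaths multiply the baseline by a
# survival multiplier per intervention (direct effects) and per risk
# factor (mediated effects); multipliers combine as an independence
# product, with each intervention's affected fraction guarding against
# double counting.

#' Linear coverage interpolation over a scale-up schedule
#'
#' Coverage holds at `c0` before `start`, ramps linearly to `target` at
#' `end`, and stays at `target` through the horizon.
#'
#' @param c0 Baseline coverage (year 0).
#' @param target Target coverage.
#' @param start First year offset of the ramp (>= 1).
#' @param end Year offset at which `target` is reached (`start <= end`).
#' @param horizon Number of projected years.
#' @return Numeric vector of length `horizon + 1`; element 1 is year 0.
#' @export
interpolate_coverage <- function(c0, target, start, end, horizon) {
  check_proportion(c0, "c0")
  check_proportion(target, "target")
  if (start > end)
    ls_schedule_error(sprintf(
      "scale-up start (%d) is after scale-up end (%d)", start, end))
  if (start < 1 || end > horizon)
    ls_schedule_error(sprintf(
      "scale-up window [%d, %d] must lie within [1, horizon = %d]",
      start, end, horizon))
  t <- 0:horizon
  # degenerate ramp (start == end) is a step to target at `start`
  frac <- pmin(1, pmax(0, (t - start + 1) / (end - start + 1)))
  c0 + (target - c0) * frac
}

#' Quality-adjusted (effective) coverage
#'
#' Effective coverage discounts contact coverage (utilization) by service
#' readiness: a contact with an unready provider delivers no effect.
#'
#' @param utilization Proportion of those in need who make contact.
#' @param readiness Proportion of contacts met with ready services; when
#'   `NULL`, utilization is returned unchanged.
#' @return `utilization * readiness`, element-wise.
#' @export
effective_coverage <- function(utilization, readiness = NULL) {
  check_proportion(utilization, "utilization")
  if (is.null(readiness)) return(utilization)
  check_proportion(readiness, "readiness")
  utilization * readiness
}

#' Survival multiplier for one intervention on one cause
#'
#' Residual-mortality form: baseline deaths already exclude deaths averted
#' by baseline coverage `c0`, so scaling coverage to `ct` acts on the
#' residual,
#'   m = 1 - e * AF * (ct - c0) / (1 - e * AF * c0).
#' `m = 1` when coverage does not change; `m > 1` when coverage falls
#' (coverage loss raises mortality).
#'
#' @param efficacy Proportional reduction in amenable deaths among the
#'   covered, in `[0, 1]`.
#' @param affected_fraction Share of the cause's deaths amenable to the
#'   intervention, in `[0, 1]`.
#' @param c0 Baseline (effective) coverage.
#' @param ct Coverage at the year of interest; may be a vector.
#' @return Survival multiplier(s), same length as `ct`.
#' @export
cause_multiplier <- function(efficacy, affected_fraction, c0, ct) {
  check_proportion(efficacy, "efficacy")
  check_proportion(affected_fraction, "affected_fraction")
  check_proportion(c0, "c0")
  check_proportion(ct, "ct")
  x <- efficacy * affected_fraction
  denom <- 1 - x * c0
  if (denom <= 0)
    ls_saturation_error(sprintf(
      "baseline coverage %.3f already removes all amenable deaths (efficacy %.3f x affected fraction %.3f); no residual to act on",
      c0, efficacy, affected_fraction))
  1 - x * (ct - c0) / denom
}

#' Combine independent survival multipliers
#'
#' Independence product across interventions (and risk-factor paths) acting
#' on the same cause; order-independent.  An empty list means no
#' interventions and returns 1.
#'
#' @param ms Numeric vector or list of multipliers, all >= 0 (zero only in
#'   the full-efficacy, full-coverage limit).
#' @return The product.
#' @export
combine_multipliers <- function(ms) {
  ms <- unlist(ms)
  if (length(ms) == 0) return(1)
  if (any(ms < 0)) ls_domain_error("multipliers must be >= 0 to combine")
  prod(ms)
}

#' Shift risk-factor prevalence under intervention coverage
#'
#' Interventions targeting a risk factor remove harmful exposure the way a
#' direct intervention removes amenable deaths: the combined residual
#' multiplier q over the targeting interventions defines a shifted
#' fraction f = 1 - q, and a fraction f of each harmful state's baseline
#' prevalence moves to the reference (last) state.
#'
#' @param rf An `ls_risk_factor`.
#' @param shifts Data frame with one row per targeting effect: columns
#'   `efficacy`, `affected_fraction`, `c0`, `ct` (coverages already
#'   quality-adjusted).  Zero rows leave the prevalence unchanged.
#' @return Named prevalence vector over `rf$states`, summing to 1.
#' @export
shift_risk_prevalence <- function(rf, shifts) {
  p0 <- rf$baseline_prevalence
  if (is.null(shifts) || nrow(shifts) == 0) return(p0)
  q <- 1
  for (k in seq_len(nrow(shifts)))
    q <- q * cause_multiplier(shifts$efficacy[k], shifts$affected_fraction[k],
                              shifts$c0[k], shifts$ct[k])
  f <- 1 - q
  ref <- length(p0)
  pt <- p0
  pt[-ref] <- p0[-ref] * (1 - f)
  pt[ref] <- p0[ref] + f * sum(p0[-ref])
  pt
}

#' Mortality multiplier from a prevalence shift
#'
#' Comparative-risk form: the cause-specific mortality multiplier implied
#' by moving exposure from `p0` to `pt` under state relative risks `rr` is
#' the ratio of population-average relative risk after to before,
#'   M = sum(pt * rr) / sum(p0 * rr).
#'
#' @param p0 Baseline prevalence (named over states).
#' @param pt Shifted prevalence (same states).
#' @param rr Named relative risks per state for one (group, cause).
#' @return Survival multiplier (1 when nothing shifts or risks are flat).
#' @export
risk_multiplier <- function(p0, pt, rr) {
  states <- names(p0)
  if (!setequal(states, names(pt)))
    ls_domain_error("p0 and pt must cover the same states")
  rr_full <- rep(1, length(states))
  names(rr_full) <- states
  rr_full[names(rr)] <- rr
  den <- sum(p0 * rr_full[states])
  if (den <= 0)
    ls_domain_error("degenerate risk: baseline average relative risk is zero")
  sum(pt[states] * rr_full[states]) / den
}

# ---- internal machinery ----------------------------------------------------

# Effective coverage path per intervention under a scenario.
# The scenario-interpolated contact path plays the role of utilization; an
# explicit utilization series (measured-coverage mode) replaces it, and a
# readiness series multiplies either.  Returns, per intervention, the
# year-0 effective coverage c0 and the per-year effective coverage vector.
coverage_paths <- function(profile, scn) {
  H <- profile$demography$horizon
  lapply(profile$interventions, function(iv) {
    target <- if (iv$id %in% names(scn$targets)) scn$targets[[iv$id]] else NULL
    if (!is.null(iv$utilization)) {
      if (!is.null(target))
        ls_log(
          "intervention %s: measured utilization series supplied; scenario target %.2f ignored",
          iv$id, target)
      raw <- iv$utilization
    } else if (is.null(target) || target == iv$baseline_coverage) {
      raw <- rep(iv$baseline_coverage, H + 1L)
    } else {
      if (target < iv$baseline_coverage)
        ls_log(
          "intervention %s: target %.2f below baseline %.2f; coverage loss will raise mortality",
          iv$id, target, iv$baseline_coverage)
      raw <- interpolate_coverage(iv$baseline_coverage, target,
                                  scn$scale_up_start, scn$scale_up_end, H)
    }
    eff <- effective_coverage(raw, iv$readiness)
    list(id = iv$id, c0 = eff[1], values = eff)
  })
}

# Grid of cells the profile defines: one row per (group, cause)
cause_grid <- function(profile) {
  do.call(rbind, lapply(profile$envelopes, function(e)
    data.frame(group = e$group, cause = names(e$cause_fractions),
               fraction = unname(e$cause_fractions),
               base_rate = e$base_rate, row.names = NULL)))
}

# Direct survival multipliers: matrix years x 1 per (intervention, group,
# cause) with a cause-target effect.  Returned as a long list of records
# with the per-year multiplier vector.
direct_multiplier_records <- function(profile, paths) {
  recs <- list()
  for (iv in profile$interventions) {
    pth <- paths[[iv$id]]
    for (ef in iv$effects) {
      if (ef$target_kind != "cause") next
      m <- tryCatch(
        cause_multiplier(ef$efficacy, ef$affected_fraction, pth$c0,
                         pth$values),
        ls_saturation_error = function(e)
          ls_saturation_error(sprintf("intervention %s, cause %s/%s: %s",
                                      iv$id, ef$group, ef$target,
                                      conditionMessage(e))))
      recs[[length(recs) + 1L]] <- list(intervention = iv$id,
                                        group = ef$group, cause = ef$target,
                                        m = m)
    }
  }
  recs
}

# Risk-factor state per year: shifted prevalence, the per-feeder residual
# multipliers q (for attribution), and the per-(group, cause) mortality
# multiplier M.
risk_factor_records <- function(profile, paths) {
  H <- profile$demography$horizon
  out <- list()
  for (rf in profile$risk_factors) {
    feeders <- list()
    for (iv in profile$interventions) {
      for (ef in iv$effects) {
        if (ef$target_kind == "risk_factor" && ef$target == rf$id) {
          pth <- paths[[iv$id]]
          q <- tryCatch(
            cause_multiplier(ef$efficacy, ef$affected_fraction, pth$c0,
                             pth$values),
            ls_saturation_error = function(e)
              ls_saturation_error(sprintf("intervention %s, risk factor %s: %s",
                                          iv$id, rf$id, conditionMessage(e))))
          feeders[[length(feeders) + 1L]] <- list(intervention = iv$id, q = q)
        }
      }
    }
    # combined shift fraction per year
    qprod <- rep(1, H + 1L)
    for (fd in feeders) qprod <- qprod * fd$q
    f <- 1 - qprod
    p0 <- rf$baseline_prevalence
    ref <- length(p0)
    rr <- rf$relative_risks
    cells <- unique(rr[, c("group", "cause")])
    Ms <- list()
    if (nrow(cells) > 0) {
      for (k in seq_len(nrow(cells))) {
        g <- cells$group[k]; cs <- cells$cause[k]
        sub <- rr[rr$group == g & rr$cause == cs, ]
        rrv <- stats::setNames(sub$rr, sub$state)
        M <- vapply(seq_len(H + 1L), function(t) {
          pt <- p0
          pt[-ref] <- p0[-ref] * (1 - f[t])
          pt[ref] <- p0[ref] + f[t] * sum(p0[-ref])
          risk_multiplier(p0, pt, rrv)
        }, numeric(1))
        Ms[[length(Ms) + 1L]] <- list(group = g, cause = cs, M = M)
      }
    }
    out[[rf$id]] <- list(id = rf$id, feeders = feeders, f = f, cells = Ms)
  }
  out
}

# Total survival multiplier for one cell: product of every direct
# multiplier on the (group, cause) and every risk-factor mortality
# multiplier M touching it.
cell_total_multiplier <- function(directs, risks, group, cause, t_idx) {
  m <- 1
  for (rec in directs)
    if (rec$group == group && rec$cause == cause) m <- m * rec$m[t_idx]
  for (rk in risks)
    for (cell in rk$cells)
      if (cell$group == group && cell$cause == cause) m <- m * cell$M[t_idx]
  m
}

# Per-(year, group, cause, intervention) combined survival multiplier m_i:
# the intervention's own direct multipliers times its share of every
# risk-factor path it feeds (the risk factor's 1 - M split across feeders
# proportionally to their 1 - q).  Used both to attribute lives saved and
# to report per-intervention results.
per_intervention_multipliers <- function(profile, directs, risks, group,
                                         cause, t_idx) {
  ids <- names(profile$interventions)
  m <- stats::setNames(rep(1, length(ids)), ids)
  for (rec in directs) {
    if (rec$group == group && rec$cause == cause)
      m[rec$intervention] <- m[rec$intervention] * rec$m[t_idx]
  }
  for (rk in risks) {
    for (cell in rk$cells) {
      if (cell$group != group || cell$cause != cause) next
      Mloss <- 1 - cell$M[t_idx]
      if (length(rk$feeders) == 0 || Mloss == 0) next
      loss <- vapply(rk$feeders, function(fd) 1 - fd$q[t_idx], numeric(1))
      tot <- sum(loss)
      if (tot == 0) next
      share <- loss / tot
      for (j in seq_along(rk$feeders)) {
        id <- rk$feeders[[j]]$intervention
        m[id] <- m[id] * (1 - share[j] * Mloss)
      }
    }
  }
  m
}

#' Project deaths and lives saved under a coverage scenario
#'
#' Runs the year-by-year projection: constant baseline mortality rates on
#' growing denominators give baseline deaths per (year, group, cause);
#' scenario deaths multiply those by the combined direct and risk-factor
#' survival multipliers; lives saved are the difference.  Year 0 is the
#' baseline year and is never altered.
#'
#' @param profile A validated `ls_profile`.
#' @param scn An `ls_scenario`; its targets may cover any subset of the
#'   profile's interventions (the rest hold baseline coverage).
#' @return An `ls_projection`: list with `deaths` (year, group, cause,
#'   deaths_baseline, deaths_scenario, lives_saved), `by_intervention`
#'   (per-intervention attribution of lives saved), `denominators`, and
#'   `meta`.
#' @export
project <- function(profile, scn) {
  validate_profile(profile)
  validate_scenario(scn, profile)
  H <- profile$demography$horizon
  paths <- coverage_paths(profile, scn)
  directs <- direct_multiplier_records(profile, paths)
  risks <- risk_factor_records(profile, paths)
  grid <- cause_grid(profile)
  ids <- names(profile$interventions)

  n_cells <- nrow(grid) * (H + 1L)
  deaths <- data.frame(
    year = rep(0:H, each = nrow(grid)),
    group = rep(grid$group, H + 1L),
    cause = rep(grid$cause, H + 1L),
    deaths_baseline = NA_real_, deaths_scenario = NA_real_,
    lives_saved = NA_real_, stringsAsFactors = FALSE)
  by_rows <- vector("list", n_cells)

  row <- 0L
  for (t in 0:H) {
    for (k in seq_len(nrow(grid))) {
      row <- row + 1L
      g <- grid$group[k]; cs <- grid$cause[k]
      denom <- ls_denominator(profile, g)[t + 1L]
      base <- denom * grid$base_rate[k] / ls_rate_scale(g) * grid$fraction[k]
      m_i <- per_intervention_multipliers(profile, directs, risks, g, cs,
                                          t + 1L)
      m_tot <- cell_total_multiplier(directs, risks, g, cs, t + 1L)
      scen <- base * m_tot
      saved <- base - scen
      deaths$deaths_baseline[row] <- base
      deaths$deaths_scenario[row] <- scen
      deaths$lives_saved[row] <- saved
      if (length(ids) > 0) {
        loss <- 1 - m_i
        tot <- sum(loss)
        attr_i <- if (tot == 0) rep(0, length(ids)) else saved * loss / tot
        by_rows[[row]] <- data.frame(year = t, group = g, cause = cs,
                                     intervention = ids,
                                     lives_saved = unname(attr_i),
                                     stringsAsFactors = FALSE)
      }
    }
  }
  by <- if (length(ids) > 0) do.call(rbind, by_rows) else
    data.frame(year = integer(), group = character(), cause = character(),
               intervention = character(), lives_saved = numeric())
  denominators <- do.call(rbind, lapply(names(profile$envelopes), function(g)
    data.frame(year = 0:H, group = g,
               denominator = ls_denominator(profile, g),
               scale = ls_rate_scale(g), stringsAsFactors = FALSE)))
  res <- structure(list(deaths = deaths, by_intervention = by,
                        denominators = denominators,
                        meta = list(region = profile$region,
                                    scenario = scn$name,
                                    base_year = profile$demography$base_year,
                                    horizon = H)),
                   class = "ls_projection")
  ls_log("total lives saved at horizon (year %d): %.1f", H,
         sum(deaths$lives_saved[deaths$year == H]))
  res
}
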