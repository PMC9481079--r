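# Domain types for the projection model: country profiles, scenarios and
# projection results, with total validation and plain-text readers/writers.
#
# A profile is a plain list with class "ls_profile"; the constructors below
# normalise the pieces and validate_profile() enforces every invariant, so
# that everything downstream can assume a well-formed object.

LS_GROUPS <- c("maternal", "stillbirth", "neonatal", "child_1_59m")
LS_SCHEMA_VERSION <- "1.0"

# Pregnancies slightly exceed live births (stillbirths, late losses); used
# only as the stillbirth denominator when the profile does not supply one.
LS_PREGNANCY_RATIO <- 1.03

# Denominator conventions, fixed per outcome group so that rates convert to
# absolute deaths without unit ambiguity:
#   maternal     deaths per 100,000 live births
#   stillbirth   deaths per   1,000 pregnancies
#   neonatal     deaths per   1,000 live births
#   child_1_59m  deaths per   1,000 live births
ls_rate_scale <- function(group) {
  switch(group, maternal = 1e5, stillbirth = 1e3, neonatal = 1e3,
         child_1_59m = 1e3,
         ls_validation_error(sprintf("unknown outcome group '%s'", group)))
}

ls_denominator <- function(profile, group) {
  if (identical(group, "stillbirth")) profile$demography$pregnancies
  else profile$demography$live_births
}

#' Demography block of a country profile
#'
#' @param base_year Calendar year used as baseline (year index 0).
#' @param horizon Number of projected years beyond the base year (>= 1).
#' @param live_births Per-year live births; either a single number recycled
#'   across all `horizon + 1` years or a vector of length `horizon + 1`.
#' @param pregnancies Optional per-year pregnancies (stillbirth
#'   denominator).  Defaults to `live_births * 1.03`, a pure denominator
#'   convention.
#' @return A list with class `ls_demography`.
#' @export
demography <- function(base_year, horizon, live_births, pregnancies = NULL) {
  horizon <- as.integer(horizon)
  n <- horizon + 1L
  if (length(live_births) == 1L) live_births <- rep(as.numeric(live_births), n)
  if (is.null(pregnancies)) pregnancies <- live_births * LS_PREGNANCY_RATIO
  if (length(pregnancies) == 1L) pregnancies <- rep(as.numeric(pregnancies), n)
  structure(list(base_year = as.integer(base_year), horizon = horizon,
                 live_births = as.numeric(live_births),
                 pregnancies = as.numeric(pregnancies)),
            class = "ls_demography")
}

#' Mortality envelope for one outcome group
#'
#' @param group One of `"maternal"`, `"stillbirth"`, `"neonatal"`,
#'   `"child_1_59m"`.
#' @param base_rate Baseline mortality rate in the group's units (maternal
#'   per 100,000 live births; stillbirth per 1,000 pregnancies; neonatal and
#'   child per 1,000 live births).
#' @param cause_fractions Named numeric vector mapping cause name to the
#'   fraction of the group's deaths it accounts for; must sum to 1.
#' @return A list with class `ls_envelope`.
#' @export
mortality_envelope <- function(group, base_rate, cause_fractions) {
  structure(list(group = group, base_rate = as.numeric(base_rate),
                 cause_fractions = unlist(cause_fractions)),
            class = "ls_envelope")
}

#' A single intervention effect
#'
#' An effect either removes a fraction of amenable cause-specific deaths
#' (`target_kind = "cause"`) or moves exposure out of harmful risk-factor
#' states (`target_kind = "risk_factor"`).
#'
#' @param target_kind `"cause"` or `"risk_factor"`.
#' @param target Cause name or risk-factor id.
#' @param efficacy Proportional reduction in amenable deaths (or harmful
#'   prevalence) among those covered, in `[0, 1]`.
#' @param affected_fraction Share of the target's deaths the intervention
#'   can act on, in `[0, 1]`; the guard against double counting.
#' @param group Outcome group (required for cause targets, ignored for
#'   risk-factor targets).
#' @return A list with class `ls_effect`.
#' @export
effect <- function(target_kind, target, efficacy, affected_fraction,
                   group = NULL) {
  structure(list(target_kind = target_kind, group = group, target = target,
                 efficacy = as.numeric(efficacy),
                 affected_fraction = as.numeric(affected_fraction)),
            class = "ls_effect")
}

#' An intervention with baseline coverage and one or more effects
#'
#' @param id Short unique token.
#' @param name Free-text name.
#' @param baseline_coverage Proportion covered in the base year.
#' @param effects List of [effect()] objects (at least one).
#' @param utilization Optional per-year utilization series (length
#'   `horizon + 1`); when present it replaces the scenario-interpolated
#'   contact-coverage path (measured-coverage mode).
#' @param readiness Optional per-year service-readiness series; effective
#'   coverage is utilization times readiness.
#' @return A list with class `ls_intervention`.
#' @export
intervention <- function(id, name = id, baseline_coverage, effects,
                         utilization = NULL, readiness = NULL) {
  if (inherits(effects, "ls_effect")) effects <- list(effects)
  structure(list(id = id, name = name,
                 baseline_coverage = as.numeric(baseline_coverage),
                 utilization = if (!is.null(utilization)) as.numeric(utilization),
                 readiness = if (!is.null(readiness)) as.numeric(readiness),
                 effects = effects),
            class = "ls_intervention")
}

#' A categorical risk factor
#'
#' @param id Short unique token.
#' @param states Ordered state names; the last state is the reference
#'   (non-exposed) state.
#' @param baseline_prevalence Named proportions over `states`, summing to 1.
#' @param relative_risks Data frame with columns `state`, `group`, `cause`,
#'   `rr` giving the relative risk of each state for each (group, cause)
#'   the factor modulates.  States omitted for a (group, cause) default to
#'   RR 1; the reference state must have RR 1 wherever it appears.
#' @return A list with class `ls_risk_factor`.
#' @export
risk_factor <- function(id, states, baseline_prevalence, relative_risks) {
  rr <- as.data.frame(relative_risks)
  structure(list(id = id, states = as.character(states),
                 baseline_prevalence = unlist(baseline_prevalence)[states],
                 relative_risks = rr),
            class = "ls_risk_factor")
}

#' Assemble a country profile
#'
#' @param region Free-text label for the setting.
#' @param demography A [demography()] object.
#' @param envelopes List of [mortality_envelope()] objects, one per outcome
#'   group present.
#' @param interventions List of [intervention()] objects.
#' @param risk_factors List of [risk_factor()] objects.
#' @param validate Validate before returning (default `TRUE`).
#' @return A list with class `ls_profile`.
#' @export
country_profile <- function(region, demography, envelopes,
                            interventions = list(), risk_factors = list(),
                            validate = TRUE) {
  if (inherits(envelopes, "ls_envelope")) envelopes <- list(envelopes)
  if (inherits(interventions, "ls_intervention"))
    interventions <- list(interventions)
  if (inherits(risk_factors, "ls_risk_factor")) risk_factors <- list(risk_factors)
  names(envelopes) <- vapply(envelopes, `[[`, "", "group")
  names(interventions) <- vapply(interventions, `[[`, "", "id")
  names(risk_factors) <- vapply(risk_factors, `[[`, "", "id")
  prof <- structure(list(schema_version = LS_SCHEMA_VERSION, region = region,
                         demography = demography, envelopes = envelopes,
                         risk_factors = risk_factors,
                         interventions = interventions),
                    class = "ls_profile")
  if (validate) validate_profile(prof)
  prof
}

#' Define a coverage scale-up scenario
#'
#' @param name Free-text scenario name.
#' @param targets Named numeric vector mapping intervention id to target
#'   coverage in `[0, 1]`.
#' @param scale_up_start First year offset at which coverage moves (>= 1;
#'   the baseline year is never altered).
#' @param scale_up_end Year offset at which the target is reached.
#' @param shape Ramp shape; `"linear"` is the only shape in this version.
#' @return A list with class `ls_scenario`.
#' @export
scenario <- function(name, targets, scale_up_start, scale_up_end,
                     shape = "linear") {
  structure(list(schema_version = LS_SCHEMA_VERSION, name = name,
                 targets = unlist(targets),
                 scale_up_start = as.integer(scale_up_start),
                 scale_up_end = as.integer(scale_up_end), shape = shape),
            class = "ls_scenario")
}

# ---- validation ------------------------------------------------------------

near_one <- function(x, tol = 1e-9) abs(x - 1) <= tol

validate_demography <- function(d) {
  if (d$horizon < 1L)
    ls_validation_error(sprintf("demography.horizon must be >= 1, got %d",
                                d$horizon))
  n <- d$horizon + 1L
  for (f in c("live_births", "pregnancies")) {
    v <- d[[f]]
    if (length(v) != n)
      ls_validation_error(sprintf(
        "demography.%s must have length horizon + 1 = %d, got %d", f, n,
        length(v)))
    if (anyNA(v) || any(v < 0))
      ls_validation_error(sprintf("demography.%s must be non-negative", f))
  }
  if (any(d$pregnancies < d$live_births - 1e-9))
    ls_validation_error(
      "demography.pregnancies must be >= live_births in every year")
  invisible(d)
}

validate_envelope <- function(e) {
  ls_rate_scale(e$group)
  if (is.na(e$base_rate) || e$base_rate < 0)
    ls_validation_error(sprintf("envelope[%s].base_rate must be >= 0", e$group))
  cf <- e$cause_fractions
  if (length(cf) == 0 || is.null(names(cf)) || any(names(cf) == ""))
    ls_validation_error(sprintf(
      "envelope[%s].cause_fractions must be a named map", e$group))
  if (anyNA(cf) || any(cf < 0) || any(cf > 1))
    ls_validation_error(sprintf(
      "envelope[%s].cause_fractions must lie in [0, 1]", e$group))
  if (!near_one(sum(cf)))
    ls_validation_error(sprintf(
      "envelope[%s].cause_fractions: fractions sum to %g, must sum to 1",
      e$group, sum(cf)))
  if (anyDuplicated(names(cf)))
    ls_validation_error(sprintf(
      "envelope[%s].cause_fractions has duplicated cause names", e$group))
  invisible(e)
}

validate_risk_factor <- function(rf) {
  if (length(rf$states) < 2)
    ls_validation_error(sprintf(
      "risk_factor[%s] needs at least two states (harmful + reference)", rf$id))
  p <- rf$baseline_prevalence
  if (length(p) != length(rf$states) || anyNA(p) ||
      !setequal(names(p), rf$states))
    ls_validation_error(sprintf(
      "risk_factor[%s].baseline_prevalence must cover exactly the states",
      rf$id))
  if (any(p < 0) || any(p > 1))
    ls_validation_error(sprintf(
      "risk_factor[%s].baseline_prevalence must lie in [0, 1]", rf$id))
  if (!near_one(sum(p)))
    ls_validation_error(sprintf(
      "risk_factor[%s].baseline_prevalence: prevalences sum to %g, must sum to 1",
      rf$id, sum(p)))
  rr <- rf$relative_risks
  need <- c("state", "group", "cause", "rr")
  if (!all(need %in% names(rr)))
    ls_validation_error(sprintf(
      "risk_factor[%s].relative_risks must have columns state, group, cause, rr",
      rf$id))
  if (nrow(rr) > 0) {
    if (any(!rr$state %in% rf$states))
      ls_validation_error(sprintf(
        "risk_factor[%s].relative_risks references unknown state '%s'",
        rf$id, setdiff(rr$state, rf$states)[1]))
    if (anyNA(rr$rr) || any(rr$rr < 0))
      ls_validation_error(sprintf(
        "risk_factor[%s].relative_risks: rr must be >= 0", rf$id))
    ref <- rf$states[length(rf$states)]
    bad <- rr$state == ref & !near_one(rr$rr)
    if (any(bad))
      ls_validation_error(sprintf(
        "risk_factor[%s]: reference state '%s' must have rr = 1 (got %g)",
        rf$id, ref, rr$rr[bad][1]))
  }
  invisible(rf)
}

validate_intervention <- function(iv, profile) {
  check_proportion(iv$baseline_coverage,
                   sprintf("intervention[%s].baseline_coverage", iv$id))
  n <- profile$demography$horizon + 1L
  for (f in c("utilization", "readiness")) {
    v <- iv[[f]]
    if (is.null(v)) next
    if (length(v) != n)
      ls_validation_error(sprintf(
        "intervention[%s].%s must have length horizon + 1 = %d, got %d",
        iv$id, f, n, length(v)))
    check_proportion(v, sprintf("intervention[%s].%s", iv$id, f))
  }
  if (length(iv$effects) < 1)
    ls_validation_error(sprintf(
      "intervention[%s] must declare at least one effect", iv$id))
  for (ef in iv$effects) {
    tag <- sprintf("intervention[%s].effect on '%s'", iv$id, ef$target)
    if (!ef$target_kind %in% c("cause", "risk_factor"))
      ls_validation_error(sprintf(
        "%s: target_kind must be 'cause' or 'risk_factor'", tag))
    check_proportion(ef$efficacy, paste0(tag, ": efficacy"))
    check_proportion(ef$affected_fraction, paste0(tag, ": affected_fraction"))
    if (ef$target_kind == "cause") {
      if (is.null(ef$group) || !ef$group %in% names(profile$envelopes))
        ls_validation_error(sprintf(
          "%s: outcome group '%s' has no mortality envelope in this profile",
          tag, ef$group %||% "<missing>"))
      causes <- names(profile$envelopes[[ef$group]]$cause_fractions)
      if (!ef$target %in% causes)
        ls_validation_error(sprintf(
          "%s: cause '%s' not found in group '%s' (has: %s)",
          tag, ef$target, ef$group, paste(causes, collapse = ", ")))
    } else {
      if (!ef$target %in% names(profile$risk_factors))
        ls_validation_error(sprintf(
          "%s: risk factor '%s' not defined in this profile", tag, ef$target))
    }
  }
  invisible(iv)
}

#' Validate a country profile
#'
#' Checks every structural invariant: series lengths, rate and proportion
#' ranges, cause fractions summing to one, prevalence simplexes, reference
#' relative risks of one, unique ids, and referential integrity of every
#' effect target.  Raises a classed `ls_validation_error` naming the failing
#' field and rule; returns the profile invisibly when valid.
#'
#' @param profile An `ls_profile`.
#' @return The profile, invisibly.
#' @export
validate_profile <- function(profile) {
  if (!inherits(profile, "ls_profile"))
    ls_validation_error("not an ls_profile object")
  validate_demography(profile$demography)
  if (length(profile$envelopes) == 0)
    ls_validation_error("profile must contain at least one mortality envelope")
  groups <- vapply(profile$envelopes, `[[`, "", "group")
  if (anyDuplicated(groups))
    ls_validation_error("duplicate mortality envelope for a group")
  for (e in profile$envelopes) validate_envelope(e)
  ids <- vapply(profile$risk_factors, `[[`, "", "id")
  if (anyDuplicated(ids))
    ls_validation_error(sprintf("duplicated risk factor id '%s'",
                                ids[duplicated(ids)][1]))
  for (rf in profile$risk_factors) {
    validate_risk_factor(rf)
    rr <- rf$relative_risks
    if (nrow(rr) > 0) {
      for (k in seq_len(nrow(rr))) {
        g <- rr$group[k]
        if (!g %in% names(profile$envelopes))
          ls_validation_error(sprintf(
            "risk_factor[%s].relative_risks: group '%s' has no envelope",
            rf$id, g))
        if (!rr$cause[k] %in% names(profile$envelopes[[g]]$cause_fractions))
          ls_validation_error(sprintf(
            "risk_factor[%s].relative_risks: cause '%s' not in group '%s'",
            rf$id, rr$cause[k], g))
      }
    }
  }
  ids <- vapply(profile$interventions, `[[`, "", "id")
  if (anyDuplicated(ids))
    ls_validation_error(sprintf("duplicated intervention id '%s'",
                                ids[duplicated(ids)][1]))
  for (iv in profile$interventions) validate_intervention(iv, profile)
  invisible(profile)
}

validate_scenario <- function(scn, profile) {
  if (!inherits(scn, "ls_scenario"))
    ls_validation_error("not an ls_scenario object")
  H <- profile$demography$horizon
  if (scn$scale_up_start < 1L)
    ls_validation_error(sprintf(
      "scenario.scale_up_start must be >= 1 (baseline year is fixed), got %d",
      scn$scale_up_start))
  if (scn$scale_up_end < scn$scale_up_start)
    ls_schedule_error(sprintf(
      "scenario.scale_up_end (%d) before scale_up_start (%d)",
      scn$scale_up_end, scn$scale_up_start))
  if (scn$scale_up_end > H)
    ls_validation_error(sprintf(
      "scenario.scale_up_end (%d) exceeds the profile horizon (%d)",
      scn$scale_up_end, H))
  if (!identical(scn$shape, "linear"))
    ls_validation_error(sprintf(
      "scenario.shape '%s' not supported; only 'linear'", scn$shape))
  tg <- scn$targets
  if (length(tg) > 0) {
    if (is.null(names(tg)) || any(names(tg) == ""))
      ls_validation_error("scenario.targets must be a named map of coverages")
    unknown <- setdiff(names(tg), names(profile$interventions))
    if (length(unknown) > 0)
      ls_validation_error(sprintf(
        "scenario.targets references unknown intervention '%s'", unknown[1]))
    check_proportion(tg, "scenario.targets")
  }
  invisible(scn)
}

# ---- document readers / writers -------------------------------------------

read_yaml_doc <- function(path, kind) {
  if (!file.exists(path))
    ls_io_error(sprintf("file not found: %s", path))
  doc <- tryCatch(yaml::read_yaml(path), error = function(e)
    ls_format_error(sprintf("cannot parse %s: %s", path, conditionMessage(e))))
  if (!is.list(doc))
    ls_format_error(sprintf("%s: document is not a key/value mapping", path))
  if (!is.null(doc$kind) && !identical(doc$kind, kind))
    ls_format_error(sprintf("%s: expected a %s document, found kind '%s'",
                            path, kind, doc$kind))
  doc
}

field <- function(doc, name, where) {
  if (is.null(doc[[name]]))
    ls_format_error(sprintf("missing required field '%s' in %s", name, where))
  doc[[name]]
}

#' Read and validate a country profile document
#'
#' Profiles are stored as human-readable YAML with an explicit
#' `schema_version` field; see the packaged example under
#' `system.file("extdata", "demo-country.yaml", package = "livessaved")`.
#'
#' @param path Path to a profile document.
#' @return A validated `ls_profile`.
#' @export
load_profile <- function(path) {
  doc <- read_yaml_doc(path, "profile")
  dem <- field(doc, "demography", "profile")
  d <- demography(
    base_year = field(dem, "base_year", "demography"),
    horizon = field(dem, "horizon", "demography"),
    live_births = field(dem, "live_births", "demography"),
    pregnancies = dem$pregnancies
  )
  envs <- lapply(field(doc, "envelopes", "profile"), function(e)
    mortality_envelope(field(e, "group", "envelope"),
                       field(e, "base_rate", "envelope"),
                       field(e, "cause_fractions", "envelope")))
  rfs <- lapply(doc$risk_factors %||% list(), function(r) {
    rr <- do.call(rbind, lapply(r$relative_risks %||% list(), as.data.frame))
    if (is.null(rr)) rr <- data.frame(state = character(), group = character(),
                                      cause = character(), rr = numeric())
    risk_factor(field(r, "id", "risk_factor"),
                field(r, "states", "risk_factor"),
                field(r, "baseline_prevalence", "risk_factor"), rr)
  })
  ivs <- lapply(doc$interventions %||% list(), function(i) {
    effs <- lapply(field(i, "effects", sprintf("intervention '%s'",
                                               i$id %||% "?")), function(ef)
      effect(field(ef, "target_kind", "effect"),
             field(ef, "target", "effect"),
             field(ef, "efficacy", "effect"),
             field(ef, "affected_fraction", "effect"),
             group = ef$group))
    intervention(field(i, "id", "intervention"), i$name %||% i$id,
                 field(i, "baseline_coverage", "intervention"), effs,
                 utilization = i$utilization, readiness = i$readiness)
  })
  country_profile(doc$region %||% "unnamed", d, envs,
                  interventions = ivs, risk_factors = rfs)
}

#' Write a country profile document
#'
#' @param profile A validated `ls_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_profile <- function(profile, path) {
  validate_profile(profile)
  doc <- list(
    schema_version = profile$schema_version,
    kind = "profile",
    region = profile$region,
    demography = list(base_year = profile$demography$base_year,
                      horizon = profile$demography$horizon,
                      live_births = profile$demography$live_births,
                      pregnancies = profile$demography$pregnancies),
    envelopes = unname(lapply(profile$envelopes, function(e)
      list(group = e$group, base_rate = e$base_rate,
           cause_fractions = as.list(e$cause_fractions)))),
    risk_factors = unname(lapply(profile$risk_factors, function(r)
      list(id = r$id, states = r$states,
           baseline_prevalence = as.list(r$baseline_prevalence),
           relative_risks = lapply(seq_len(nrow(r$relative_risks)), function(k)
             as.list(r$relative_risks[k, c("state", "group", "cause", "rr")]))))),
    interventions = unname(lapply(profile$interventions, function(i) {
      out <- list(id = i$id, name = i$name,
                  baseline_coverage = i$baseline_coverage)
      if (!is.null(i$utilization)) out$utilization <- i$utilization
      if (!is.null(i$readiness)) out$readiness <- i$readiness
      out$effects <- lapply(i$effects, function(ef) {
        e <- list(target_kind = ef$target_kind, target = ef$target,
                  efficacy = ef$efficacy,
                  affected_fraction = ef$affected_fraction)
        if (!is.null(ef$group)) e$group <- ef$group
        e
      })
      out
    }))
  )
  write_yaml_checked(doc, path)
}

#' Read a scenario document
#'
#' @param path Path to a scenario document.
#' @param profile Optional `ls_profile`; when given, the scenario is
#'   validated against it (referential integrity, schedule within horizon).
#' @return An `ls_scenario`.
#' @export
load_scenario <- function(path, profile = NULL) {
  doc <- read_yaml_doc(path, "scenario")
  scn <- scenario(doc$name %||% "unnamed",
                  unlist(field(doc, "targets", "scenario")),
                  field(doc, "scale_up_start", "scenario"),
                  field(doc, "scale_up_end", "scenario"),
                  doc$shape %||% "linear")
  if (!is.null(profile)) validate_scenario(scn, profile)
  scn
}

#' Write a scenario document
#'
#' @param scn An `ls_scenario`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_scenario <- function(scn, path) {
  write_yaml_checked(list(schema_version = scn$schema_version,
                          kind = "scenario", name = scn$name,
                          targets = as.list(scn$targets),
                          scale_up_start = scn$scale_up_start,
                          scale_up_end = scn$scale_up_end,
                          shape = scn$shape), path)
}

write_yaml_checked <- function(doc, path) {
  tryCatch(yaml::write_yaml(doc, path,
                            precision = 15L),
           error = function(e)
             ls_io_error(sprintf("cannot write %s: %s", path,
                                 conditionMessage(e))))
  invisible(path)
}

# ---- projection results ----------------------------------------------------

#' Write a projection result as a tidy table
#'
#' One row per year x group x cause x intervention (columns
#' `deaths_baseline` and `deaths_scenario` are carried on the totals rows,
#' marked `intervention = "ALL"`), written as CSV with full precision so
#' the table round-trips losslessly.
#'
#' @param result An `ls_projection` from [project()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_result <- function(result, path) {
  if (!inherits(result, "ls_projection"))
    ls_consistency_error("save_result expects an ls_projection")
  tab <- as.data.frame(result)
  con <- tryCatch(file(path, "w"), error = function(e)
    ls_io_error(sprintf("cannot open %s for writing: %s", path,
                        conditionMessage(e))))
  on.exit(close(con))
  # full double precision so load(save(x)) is exact to the last bit
  tab_chr <- tab
  for (col in c("deaths_baseline", "deaths_scenario", "lives_saved")) {
    v <- sprintf("%.17g", tab[[col]])
    v[is.na(tab[[col]])] <- ""
    tab_chr[[col]] <- v
  }
  utils::write.csv(tab_chr, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a projection-result table written by [save_result()]
#'
#' @param path Path to the CSV table.
#' @return A data frame with columns `year`, `group`, `cause`,
#'   `intervention`, `deaths_baseline`, `deaths_scenario`, `lives_saved`.
#' @export
load_result <- function(path) {
  if (!file.exists(path)) ls_io_error(sprintf("file not found: %s", path))
  tab <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(year = "integer", group = "character",
                                   cause = "character",
                                   intervention = "character",
                                   deaths_baseline = "numeric",
                                   deaths_scenario = "numeric",
                                   lives_saved = "numeric")),
    error = function(e)
      ls_format_error(sprintf("cannot parse %s: %s", path,
                              conditionMessage(e))))
  need <- c("year", "group", "cause", "intervention", "deaths_baseline",
            "deaths_scenario", "lives_saved")
  if (!identical(names(tab), need))
    ls_format_error(sprintf("%s: expected columns %s", path,
                            paste(need, collapse = ", ")))
  tab
}

#' Flatten a projection to its tidy long table
#'
#' @param x An `ls_projection`.
#' @param ... Unused.
#' @return Data frame with totals rows (`intervention = "ALL"`) followed by
#'   per-intervention attribution rows.
#' @export
as.data.frame.ls_projection <- function(x, ...) {
  tot <- x$deaths
  tot$intervention <- rep("ALL", nrow(tot))
  tot <- tot[, c("year", "group", "cause", "intervention", "deaths_baseline",
                 "deaths_scenario", "lives_saved")]
  by <- x$by_intervention
  if (nrow(by) > 0) {
    by$deaths_baseline <- NA_real_
    by$deaths_scenario <- NA_real_
    by <- by[, c("year", "group", "cause", "intervention", "deaths_baseline",
                 "deaths_scenario", "lives_saved")]
  } else {
    by <- tot[0, ]
  }
  out <- rbind(tot, by)
  out <- out[order(out$year, out$group, out$cause,
                   out$intervention != "ALL", out$intervention), ]
  rownames(out) <- NULL
  out
}

#' @export
print.ls_profile <- function(x, ...) {
  cat(sprintf("<country profile> %s (base year %d, horizon %d years)\n",
              x$region, x$demography$base_year, x$demography$horizon))
  for (e in x$envelopes)
    cat(sprintf("  %-12s rate %g per %s, %d causes\n", e$group, e$base_rate,
                format(ls_rate_scale(e$group), big.mark = ","),
                length(e$cause_fractions)))
  cat(sprintf("  %d intervention(s), %d risk factor(s)\n",
              length(x$interventions), length(x$risk_factors)))
  invisible(x)
}

#' @export
print.ls_scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s: %d target(s), ramp years %d-%d (%s)\n",
              x$name, length(x$targets), x$scale_up_start, x$scale_up_end,
              x$shape))
  invisible(x)
}

#' @export
print.ls_projection <- function(x, ...) {
  H <- max(x$deaths$year)
  cum <- sum(x$deaths$lives_saved)
  cat(sprintf(
    "<projection> %s | scenario '%s': %d years, cumulative lives saved %.1f\n",
    x$meta$region, x$meta$scenario, H, cum))
  invisible(x)
}
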