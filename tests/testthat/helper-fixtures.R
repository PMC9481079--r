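# Fixture builders used across the suite.  Everything is constructed in
# code; no fixture files.

# one-group, one-cause profile with a single cause-targeting intervention
single_intervention_profile <- function(efficacy = 0.5, af = 1,
                                        baseline_coverage = 0,
                                        base_rate = 60, births = 1e5,
                                        horizon = 5L) {
  country_profile(
    "fixture", demography(2020L, horizon, births),
    mortality_envelope("child_1_59m", base_rate, c(all = 1)),
    interventions = intervention(
      "iv", "fixture intervention", baseline_coverage,
      effect("cause", "all", efficacy, af, group = "child_1_59m")))
}

full_scaleup <- function(profile, target = 1) {
  H <- profile$demography$horizon
  scenario("full", stats::setNames(rep(target,
                                       length(profile$interventions)),
                                   names(profile$interventions)), 1L, H)
}

null_scenario <- function(profile) {
  H <- profile$demography$horizon
  scenario("null", stats::setNames(
    vapply(profile$interventions, `[[`, 0, "baseline_coverage"),
    names(profile$interventions)), 1L, H)
}

LS_GROUPS_FOR_TEST <- list("child_1_59m",
                           c("neonatal", "child_1_59m"),
                           c("maternal", "stillbirth", "neonatal",
                             "child_1_59m"))

# tiny random profile for oracle/property sweeps: one or two groups,
# <= 2 causes, <= 3 interventions, <= 3 years, optional risk factor
tiny_profile <- function(seed) {
  local({
    cfg <- generator_config(
      seed = seed,
      n_causes = 1L + seed %% 2L,
      n_interventions = seed %% 4L,
      n_risk_factors = seed %% 2L,
      horizon = 1L + seed %% 3L,
      groups = if (seed %% 3L == 0L) c("neonatal", "child_1_59m")
               else "child_1_59m")
    generate_profile(cfg)
  })
}
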