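# Seeded generator of plausible country profiles and scenarios, so the
# whole pipeline is testable without any external database, plus a fixed
# demo-country preset at the orders of magnitude typical of high-mortality
# settings.

local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  code
}

# symmetric flat simplex draw (Dirichlet with unit concentration)
rsimplex <- function(n) {
  x <- stats::rexp(n)
  x / sum(x)
}

#' Configuration for the synthetic-profile generator
#'
#' @param seed Integer seed; generation is a pure function of the config.
#' @param n_causes Causes per outcome group.
#' @param n_interventions Number of interventions.
#' @param n_risk_factors Number of categorical risk factors.
#' @param horizon Projected years beyond baseline.
#' @param births_per_year Annual live births (held constant over the
#'   horizon).
#' @param groups Outcome groups to include.
#' @param base_year Baseline calendar year.
#' @param quality_adjusted Attach utilization/readiness series to each
#'   intervention (default `FALSE`).
#' @return A list with class `ls_generator_config`.
#' @export
generator_config <- function(seed = 1L, n_causes = 3L, n_interventions = 4L,
                             n_risk_factors = 1L, horizon = 5L,
                             births_per_year = 1e5,
                             groups = c("neonatal", "child_1_59m"),
                             base_year = 2020L, quality_adjusted = FALSE) {
  cfg <- list(seed = as.integer(seed), n_causes = as.integer(n_causes),
              n_interventions = as.integer(n_interventions),
              n_risk_factors = as.integer(n_risk_factors),
              horizon = as.integer(horizon),
              births_per_year = as.numeric(births_per_year),
              groups = groups, base_year = as.integer(base_year),
              quality_adjusted = isTRUE(quality_adjusted))
  if (cfg$horizon < 1L) ls_validation_error("config.horizon must be >= 1")
  if (cfg$n_causes < 1L) ls_validation_error("config.n_causes must be >= 1")
  if (cfg$n_interventions < 0L || cfg$n_risk_factors < 0L)
    ls_validation_error("config counts must be >= 0")
  if (!all(cfg$groups %in% LS_GROUPS))
    ls_validation_error(sprintf("config.groups must be among: %s",
                                paste(LS_GROUPS, collapse = ", ")))
  structure(cfg, class = "ls_generator_config")
}

# plausible baseline rate ranges per group, in the group's units
rate_range <- function(group) {
  switch(group,
         maternal = c(100, 600),      # per 100,000 live births
         stillbirth = c(5, 30),       # per 1,000 pregnancies
         neonatal = c(10, 40),        # per 1,000 live births
         child_1_59m = c(20, 80))     # per 1,000 live births
}

#' Generate a synthetic country profile
#'
#' Deterministic given the config seed.  Cause fractions are drawn from a
#' symmetric flat simplex; efficacies are uniform on `[0.1, 0.9]`, affected
#' fractions uniform on `[0.3, 1.0]`, baseline coverages uniform on
#' `[0.05, 0.8]`; risk-factor relative risks are log-uniform on `[1, 4]`
#' with the reference state at 1.  Every generated profile passes
#' [validate_profile()].
#'
#' @param config An [generator_config()] (or the default one).
#' @return A validated `ls_profile`.
#' @export
generate_profile <- function(config = generator_config()) {
  if (!inherits(config, "ls_generator_config"))
    config <- do.call(generator_config, config)
  local_seed(config$seed, {
    H <- config$horizon
    dem <- demography(config$base_year, H,
                      rep(config$births_per_year, H + 1L))
    envs <- lapply(config$groups, function(g) {
      fr <- rsimplex(config$n_causes)
      names(fr) <- sprintf("%s_cause_%d", g, seq_len(config$n_causes))
      fr <- fr / sum(fr)
      mortality_envelope(g, stats::runif(1, rate_range(g)[1],
                                         rate_range(g)[2]), fr)
    })
    cause_pool <- do.call(rbind, lapply(envs, function(e)
      data.frame(group = e$group, cause = names(e$cause_fractions),
                 stringsAsFactors = FALSE)))
    rfs <- lapply(seq_len(config$n_risk_factors), function(j) {
      id <- sprintf("rf_%d", j)
      states <- c("exposed_high", "exposed_low", "reference")
      prev <- rsimplex(3)
      names(prev) <- states
      # each factor modulates 1-2 cause cells
      k <- sample(nrow(cause_pool), min(nrow(cause_pool), sample(1:2, 1)))
      rr <- do.call(rbind, lapply(k, function(i) {
        data.frame(state = states,
                   group = cause_pool$group[i], cause = cause_pool$cause[i],
                   rr = c(exp(stats::runif(2, 0, log(4))), 1),
                   stringsAsFactors = FALSE)
      }))
      risk_factor(id, states, prev, rr)
    })
    ivs <- lapply(seq_len(config$n_interventions), function(j) {
      id <- sprintf("iv_%d", j)
      target_rf <- config$n_risk_factors > 0 && stats::runif(1) < 0.25
      ef <- if (target_rf) {
        rf <- rfs[[sample(length(rfs), 1)]]
        effect("risk_factor", rf$id, stats::runif(1, 0.1, 0.9),
               stats::runif(1, 0.3, 1.0))
      } else {
        i <- sample(nrow(cause_pool), 1)
        effect("cause", cause_pool$cause[i], stats::runif(1, 0.1, 0.9),
               stats::runif(1, 0.3, 1.0), group = cause_pool$group[i])
      }
      util <- read <- NULL
      if (config$quality_adjusted) {
        util <- rep(stats::runif(1, 0.4, 0.9), H + 1L)
        read <- rep(stats::runif(1, 0.5, 0.95), H + 1L)
      }
      intervention(id, sprintf("Synthetic intervention %d", j),
                   stats::runif(1, 0.05, 0.8), list(ef),
                   utilization = util, readiness = read)
    })
    country_profile(sprintf("synthetic-%d", config$seed), dem, envs,
                    interventions = ivs, risk_factors = rfs)
  })
}

#' Generate a scale-up scenario for a profile
#'
#' Targets each intervention at a coverage drawn uniformly between its
#' baseline and `max_target`, ramping linearly from year 1 to the horizon.
#' Deterministic given `seed`.
#'
#' @param profile An `ls_profile`.
#' @param seed Integer seed.
#' @param max_target Upper bound for drawn targets.
#' @return An `ls_scenario`.
#' @export
generate_scenario <- function(profile, seed = 1L, max_target = 0.95) {
  local_seed(seed, {
    ids <- names(profile$interventions)
    tg <- vapply(profile$interventions, function(iv)
      stats::runif(1, iv$baseline_coverage, max_target), numeric(1))
    tg <- pmin(pmax(tg, 0), 1)
    scenario(sprintf("synthetic-scaleup-%d", seed),
             stats::setNames(as.numeric(tg), ids), 1L,
             profile$demography$horizon)
  })
}

#' The fixed demo-country profile
#'
#' A hand-written preset at the scale of a high-mortality setting: 100,000
#' live births per year over a 5-year horizon; neonatal and 1-59-month
#' envelopes, the child band anchored at an under-five-scale rate of 60
#' deaths per 1,000 live births; a breastfeeding risk factor with
#' none/partial/exclusive states; and a small intervention set including
#' promotion of exclusive breastfeeding.  All values other than the
#' 60-per-1,000 anchor are illustrative inventions.
#'
#' @return A validated `ls_profile`.
#' @export
demo_profile <- function() {
  dem <- demography(2020L, 5L, 1e5)
  child <- mortality_envelope("child_1_59m", 60, c(
    diarrhea = 0.20, pneumonia = 0.25, malaria = 0.15, measles = 0.05,
    other = 0.35))
  neo <- mortality_envelope("neonatal", 25, c(
    sepsis = 0.30, asphyxia = 0.30, prematurity = 0.30, other = 0.10))
  bf <- risk_factor(
    "breastfeeding",
    states = c("none", "partial", "exclusive"),
    baseline_prevalence = c(none = 0.20, partial = 0.45, exclusive = 0.35),
    relative_risks = data.frame(
      state = rep(c("none", "partial", "exclusive"), 2),
      group = "child_1_59m",
      cause = rep(c("diarrhea", "pneumonia"), each = 3),
      rr = c(2.4, 1.7, 1.0, 1.9, 1.4, 1.0)))
  ivs <- list(
    intervention("ebf_promotion", "Exclusive breastfeeding promotion", 0.30,
                 effect("risk_factor", "breastfeeding", 0.60, 0.90)),
    intervention("ors", "Oral rehydration solution", 0.40,
                 effect("cause", "diarrhea", 0.93, 0.90,
                        group = "child_1_59m")),
    intervention("pneumonia_abx", "Antibiotics for pneumonia", 0.35,
                 effect("cause", "pneumonia", 0.70, 0.85,
                        group = "child_1_59m")),
    intervention("clean_delivery", "Clean delivery practices", 0.45,
                 effect("cause", "sepsis", 0.25, 0.70, group = "neonatal")))
  country_profile("demo-country", dem, list(child, neo),
                  interventions = ivs, risk_factors = list(bf))
}
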