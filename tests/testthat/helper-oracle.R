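# Independent brute-force projection oracle: composes the declared formulas
# directly with nested loops, sharing no code with the engine.  Used to
# cross-check project() on tiny profiles.

oracle_project_deaths <- function(profile, scn) {
  H <- profile$demography$horizon
  start <- scn$scale_up_start
  end <- scn$scale_up_end

  # effective coverage per intervention per year, composed by hand
  cov <- list()
  for (iv in profile$interventions) {
    tgt <- if (iv$id %in% names(scn$targets)) scn$targets[[iv$id]]
           else iv$baseline_coverage
    v <- numeric(H + 1)
    for (t in 0:H) {
      v[t + 1] <-
        if (t < start) iv$baseline_coverage
        else if (t >= end) tgt
        else iv$baseline_coverage +
          (tgt - iv$baseline_coverage) * (t - start + 1) / (end - start + 1)
    }
    if (!is.null(iv$utilization)) v <- iv$utilization
    if (!is.null(iv$readiness)) v <- v * iv$readiness
    cov[[iv$id]] <- v
  }

  mult <- function(e, af, c0, ct) 1 - e * af * (ct - c0) / (1 - e * af * c0)

  rows <- list()
  for (env in profile$envelopes) {
    g <- env$group
    denom <- if (g == "stillbirth") profile$demography$pregnancies
             else profile$demography$live_births
    scale <- c(maternal = 1e5, stillbirth = 1e3, neonatal = 1e3,
               child_1_59m = 1e3)[[g]]
    for (cs in names(env$cause_fractions)) {
      for (t in 0:H) {
        base <- denom[t + 1] * env$base_rate / scale * env$cause_fractions[[cs]]
        m <- 1
        # direct effects
        for (iv in profile$interventions) {
          c0 <- cov[[iv$id]][1]
          ct <- cov[[iv$id]][t + 1]
          for (ef in iv$effects) {
            if (ef$target_kind == "cause" && ef$group == g &&
                ef$target == cs)
              m <- m * mult(ef$efficacy, ef$affected_fraction, c0, ct)
          }
        }
        # risk-factor paths
        for (rf in profile$risk_factors) {
          rr <- rf$relative_risks
          sub <- rr[rr$group == g & rr$cause == cs, ]
          if (nrow(sub) == 0) next
          q <- 1
          for (iv in profile$interventions) {
            c0 <- cov[[iv$id]][1]
            ct <- cov[[iv$id]][t + 1]
            for (ef in iv$effects) {
              if (ef$target_kind == "risk_factor" && ef$target == rf$id)
                q <- q * mult(ef$efficacy, ef$affected_fraction, c0, ct)
            }
          }
          f <- 1 - q
          p0 <- rf$baseline_prevalence
          nref <- length(p0)
          pt <- p0
          for (k in seq_len(nref - 1)) pt[k] <- p0[k] * (1 - f)
          pt[nref] <- p0[nref] + f * sum(p0[-nref])
          rrv <- rep(1, nref)
          names(rrv) <- names(p0)
          for (k in seq_len(nrow(sub))) rrv[[sub$state[k]]] <- sub$rr[k]
          m <- m * sum(pt * rrv) / sum(p0 * rrv)
        }
        rows[[length(rows) + 1]] <- data.frame(
          year = t, group = g, cause = cs,
          deaths_baseline = unname(base),
          deaths_scenario = unname(base * m), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$year, out$group, out$cause), ]
}

# compare engine output with the oracle, relative tolerance
expect_matches_oracle <- function(profile, scn, tol = 1e-9) {
  res <- project(profile, scn)
  eng <- res$deaths[order(res$deaths$year, res$deaths$group,
                          res$deaths$cause), ]
  ora <- oracle_project_deaths(profile, scn)
  expect_equal(eng$deaths_baseline, ora$deaths_baseline, tolerance = tol)
  expect_equal(eng$deaths_scenario, ora$deaths_scenario, tolerance = tol)
  invisible(res)
}
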