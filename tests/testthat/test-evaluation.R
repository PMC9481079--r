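# Attribution, ranking, explore summaries and modeled-vs-measured gaps.

two_intervention_profile <- function(e1 = 0.1, e2 = 0.2) {
  # rate 10/1,000 on 100,000 births = 1,000 baseline deaths per year;
  # with c0 = 0 and full coverage at the horizon the multipliers at the
  # final year are exactly 1 - e1 and 1 - e2
  country_profile(
    "attr", demography(2020L, 3L, 1e5),
    mortality_envelope("child_1_59m", 10, c(all = 1)),
    interventions = list(
      intervention("a", "a", 0, effect("cause", "all", e1, 1,
                                       group = "child_1_59m")),
      intervention("b", "b", 0, effect("cause", "all", e2, 1,
                                       group = "child_1_59m"))))
}

test_that("a sole contributor receives all of a cause's lives saved", {
  p <- single_intervention_profile()
  s <- full_scaleup(p, 0.9)
  res <- project(p, s)
  att <- attribute_lives_saved(p, s, res)
  merged <- merge(att, res$deaths, by = c("year", "group", "cause"))
  expect_equal(merged$lives_saved.x, merged$lives_saved.y)
})

test_that("proportional shares follow the 1 - m rule and conserve totals", {
  p <- two_intervention_profile(0.1, 0.2)
  s <- full_scaleup(p, 1)
  res <- project(p, s)
  att <- attribute_lives_saved(p, s, res)
  final <- att[att$year == 3, ]
  # multipliers 0.9 and 0.8 on 1,000 deaths: total averted 280, split 1:2
  expect_equal(sum(final$lives_saved), 280)
  expect_equal(final$lives_saved[final$intervention == "a"], 280 / 3)
  expect_equal(final$lives_saved[final$intervention == "b"], 2 * 280 / 3)
})

test_that("attribution conserves the per-cell total on random profiles", {
  for (seed in c(3L, 10L, 14L)) {
    p <- tiny_profile(seed)
    if (length(p$interventions) == 0) next
    s <- generate_scenario(p, seed = seed)
    res <- project(p, s)
    att <- attribute_lives_saved(p, s, res)
    agg <- aggregate(lives_saved ~ year + group + cause, att, sum)
    m <- merge(res$deaths, agg, by = c("year", "group", "cause"))
    expect_lt(max(abs(m$lives_saved.x - m$lives_saved.y)), 1e-6)
    expect_true(all(att$lives_saved >= -1e-9))
  }
})

test_that("null scenarios attribute nothing", {
  p <- demo_profile()
  s <- null_scenario(p)
  att <- attribute_lives_saved(p, s, project(p, s))
  expect_equal(att$lives_saved, rep(0, nrow(att)))
})

test_that("identical interventions receive identical attribution", {
  p <- country_profile(
    "twin", demography(2020L, 2L, 1e5),
    mortality_envelope("child_1_59m", 30, c(all = 1)),
    interventions = list(
      intervention("t1", "t1", 0.2, effect("cause", "all", 0.5, 0.8,
                                           group = "child_1_59m")),
      intervention("t2", "t2", 0.2, effect("cause", "all", 0.5, 0.8,
                                           group = "child_1_59m"))))
  s <- full_scaleup(p, 0.9)
  att <- attribute_lives_saved(p, s, project(p, s))
  a1 <- att$lives_saved[att$intervention == "t1"]
  a2 <- att$lives_saved[att$intervention == "t2"]
  expect_equal(a1, a2)
})

test_that("risk-factor paths are split among the interventions feeding them", {
  p <- demo_profile()
  s <- scenario("bf-only", c(ebf_promotion = 0.9), 1L, 5L)
  res <- project(p, s)
  att <- attribute_lives_saved(p, s, res)
  # only the breastfeeding promotion moved, so it owns every saved life
  other <- att[att$intervention != "ebf_promotion", ]
  expect_equal(other$lives_saved, rep(0, nrow(other)))
  mine <- aggregate(lives_saved ~ year + group + cause,
                    att[att$intervention == "ebf_promotion", ], sum)
  m <- merge(res$deaths, mine, by = c("year", "group", "cause"))
  expect_equal(m$lives_saved.x, m$lives_saved.y, tolerance = 1e-9)
})

test_that("missed-opportunity entries equal independent solo projections", {
  p <- demo_profile()
  rk <- rank_missed_opportunities(p, 0.9)
  expect_equal(nrow(rk), length(p$interventions))
  expect_true(all(diff(rk$deaths_averted) <= 1e-12))
  H <- p$demography$horizon
  for (k in seq_len(nrow(rk))) {
    id <- rk$intervention[k]
    target <- max(p$interventions[[id]]$baseline_coverage, 0.9)
    solo <- project(p, scenario("solo", stats::setNames(target, id), 1L, H))
    expect_equal(rk$deaths_averted[k],
                 sum(solo$deaths$lives_saved[solo$deaths$year == H]))
  }
})

test_that("ranking orders by impact with deterministic tie-breaks", {
  base <- function(id, e) intervention(
    id, id, 0.3, effect("cause", "all", e, 1, group = "child_1_59m"))
  p <- country_profile(
    "rank", demography(2020L, 3L, 1e5),
    mortality_envelope("child_1_59m", 40, c(all = 1)),
    interventions = list(base("weak", 0.3), base("strong", 0.6),
                         base("z_twin", 0.3), base("a_twin", 0.3)))
  rk <- rank_missed_opportunities(p)
  expect_equal(rk$intervention[1], "strong")
  twins <- rk$intervention[rk$intervention != "strong"]
  expect_equal(twins, sort(twins))
})

test_that("interventions without headroom or saturated at baseline score zero", {
  p <- country_profile(
    "flat", demography(2020L, 2L, 1e5),
    mortality_envelope("child_1_59m", 40, c(all = 1)),
    interventions = intervention("done", "done", 0.95,
                                 effect("cause", "all", 0.5, 1,
                                        group = "child_1_59m")))
  rk <- rank_missed_opportunities(p, 0.9)
  expect_equal(rk$deaths_averted, 0)

  sat <- country_profile(
    "sat", demography(2020L, 2L, 1e5),
    mortality_envelope("child_1_59m", 40, c(all = 1)),
    interventions = intervention("sat", "sat", 1,
                                 effect("cause", "all", 1, 1,
                                        group = "child_1_59m")))
  expect_warning(rk2 <- rank_missed_opportunities(sat), "saturated")
  expect_equal(rk2$deaths_averted, 0)
})

test_that("an empty intervention list yields an empty ranking", {
  p <- generate_profile(generator_config(seed = 2L, n_interventions = 0L,
                                         n_risk_factors = 0L))
  rk <- rank_missed_opportunities(p)
  expect_equal(nrow(rk), 0L)
})

test_that("explore summaries derive purely from the profile", {
  p <- country_profile(
    "sum", demography(2020L, 2L, 1e5),
    mortality_envelope("child_1_59m", 60, c(a = 0.4, b = 0.6)),
    interventions = intervention("v", "v", 0.5,
                                 effect("cause", "a", 0.5, 1,
                                        group = "child_1_59m")))
  s <- explore_summary(p)
  expect_equal(s$causes$baseline_deaths[s$causes$cause == "a"], 2400)
  expect_equal(s$causes$baseline_deaths[s$causes$cause == "b"], 3600)
  expect_equal(nrow(s$risk_factors), 0L)

  path <- withr::local_tempfile(fileext = ".yaml")
  save_profile(p, path)
  expect_equal(explore_summary(load_profile(path)), s, tolerance = 1e-12)
})

test_that("proportional reductions convert to absolute rate reductions", {
  expect_equal(proportional_to_absolute(60, 0.05), 3)
  expect_equal(proportional_to_absolute(123, 0), 0)
  expect_equal(proportional_to_absolute(0, 0.7), 0)
  expect_error(proportional_to_absolute(-1, 0.5), class = "ls_domain_error")
  expect_error(proportional_to_absolute(60, 1.5), class = "ls_domain_error")
})

test_that("modeled-vs-measured gaps align years and never interpolate", {
  p <- single_intervention_profile(efficacy = 0.5, baseline_coverage = 0,
                                   base_rate = 60, horizon = 5L)
  res <- project(p, full_scaleup(p, 1))
  modeled <- compare_to_measured(
    res, data.frame(year = 0:5, rate = res$deaths$deaths_scenario /
                      1e5 * 1e3), "child_1_59m")
  expect_equal(modeled$gap_absolute, rep(0, 6))
  expect_equal(modeled$gap_relative, rep(0, 6))

  # interior year missing from the measurement stays missing
  sparse <- compare_to_measured(
    res, data.frame(year = c(0, 1, 3), rate = c(60, 59, 57)), "child_1_59m")
  expect_equal(sparse$year, c(0, 1, 3))

  # no overlapping years at all is an alignment error
  expect_error(compare_to_measured(res, data.frame(year = 99, rate = 60),
                                   "child_1_59m"),
               class = "ls_alignment_error")
  expect_error(compare_to_measured(res, data.frame(year = 0, rate = 60),
                                   "neonatal"),
               class = "ls_alignment_error")

  # modeled 57 vs measured 60 per 1,000: gaps -3 and -5%
  p10 <- single_intervention_profile(efficacy = 0.5, baseline_coverage = 0,
                                     base_rate = 60, horizon = 10L)
  r10 <- project(p10, scenario("ramp", c(iv = 1), 1L, 10L))
  out <- compare_to_measured(r10, data.frame(year = 1, rate = 60),
                             "child_1_59m")
  expect_equal(out$modeled_rate, 57)   # 60 * (1 - 0.5 * 0.1)
  expect_equal(out$gap_absolute, -3)
  expect_equal(out$gap_relative, -0.05)
})

test_that("mismatched attribution inputs raise a consistency error", {
  p <- demo_profile()
  s <- null_scenario(p)
  res <- project(p, s)
  other <- single_intervention_profile()
  expect_error(attribute_lives_saved(other, full_scaleup(other, 1), res),
               class = "ls_consistency_error")
})
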