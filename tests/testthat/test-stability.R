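test_that("regime flags are a pure function of the regime label", {
  f <- regime_flags(c("a1", "a2", "a3", "a4"))
  expect_equal(f$flocculated, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(f$creams, c(TRUE, TRUE, FALSE, FALSE))
  expect_error(regime_flags("a5"), "regime")
})

test_that("guar classification reproduces the dilute-end observations and arrest", {
  pred <- classify_regime(solution_state(panel$guar, c(0.025, 0.05, 1.0)),
                          baseline_emulsion, defaults, arrest_multiplier = 2)
  expect_equal(pred$regime, c("a1", "a2", "a4"))
  expect_equal(pred$flocculated, c(FALSE, TRUE, FALSE))
  expect_equal(pred$creams, c(TRUE, TRUE, FALSE))
  b <- attr(pred, "boundaries")
  expect_equal(unname(b["arrest"]), 2 * unname(b["cvc"]))
})

test_that("boundaries are half-open with the lower bound in the higher regime", {
  b <- attr(classify_regime(solution_state(panel$bg2, 0.1)), "boundaries")
  at_bounds <- classify_regime(
    solution_state(panel$bg2, unname(c(b["cfc"], b["cvc"], b["arrest"]))))
  expect_equal(at_bounds$regime, c("a2", "a3", "a4"))
  just_below <- classify_regime(
    solution_state(panel$bg2, unname(c(b["cfc"], b["cvc"], b["arrest"])) * (1 - 1e-12)))
  expect_equal(just_below$regime, c("a1", "a2", "a3"))
})

test_that("regime is a non-decreasing step function of concentration", {
  set.seed(23)
  grid <- sort(exp(runif(60, log(1e-3), log(5))))
  for (i in 1:20) {
    p <- random_physical_polymer()
    idx <- match(classify_regime(solution_state(p, grid))$regime,
                 c("a1", "a2", "a3", "a4"))
    expect_true(all(diff(idx) >= 0))
  }
})

test_that("phase diagram covers the panel grid and matches per-cell classification", {
  grid <- c(0.025, 0.05, 0.1, 0.5, 1.0)
  pd <- phase_diagram(reference_polymer_table(), baseline_emulsion, grid)
  expect_equal(nrow(pd), 20L)
  # dilute-end cells: a1 at 0.025 for every polymer; a2 at 0.05 for all but
  # BG3, whose computed CFC (0.052 wt%) sits just above that concentration
  expect_true(all(pd$regime[pd$c_wtpct == 0.025] == "a1"))
  at05 <- pd[pd$c_wtpct == 0.05, ]
  expect_equal(at05$regime[at05$polymer != "BG3"], rep("a2", 3))
  expect_equal(at05$regime[at05$polymer == "BG3"], "a1")

  single <- phase_diagram(list(panel$bg1), baseline_emulsion, 0.3)
  direct <- classify_regime(solution_state(panel$bg1, 0.3), baseline_emulsion)
  expect_equal(single$regime, direct$regime)
  expect_equal(single$cfc, direct$cfc)

  expect_equal(nrow(phase_diagram(list(), baseline_emulsion, grid)), 0L)
  expect_error(phase_diagram(list(panel$bg1), baseline_emulsion, c(0.5, 0.1)),
               "increasing")
})

test_that("agreement scoring counts matches, mismatches and unknowns", {
  grid <- c(0.025, 0.05)
  pd <- phase_diagram(reference_polymer_table(), baseline_emulsion, grid)
  obs <- universal_observations()
  res <- compare_to_observations(pd, obs)
  expect_equal(res$n_scored, 8L)
  # 7/8: the BG3 cell at 0.05 wt% is predicted a1 from its computed CFC
  expect_equal(res$n_match, 7L)
  expect_equal(res$agreement, 7 / 8)
  miss <- res$detail[!res$detail$match, ]
  expect_equal(miss$name, "BG3")
  expect_equal(miss$c_wtpct, 0.05)

  # corrupting one matching observation drops the score by exactly one
  obs2 <- obs
  obs2$regime[obs2$name == "guar_gum" & obs2$c_wtpct == 0.025] <- "a2"
  expect_equal(compare_to_observations(pd, obs2)$n_match, 6L)

  obs3 <- rbind(obs, data.frame(name = "BG1", c_wtpct = 0.05, regime = "unknown"))
  res3 <- compare_to_observations(pd, obs3)
  expect_equal(res3$n_unknown, 1L)
  expect_equal(res3$n_scored, 8L)

  empty <- compare_to_observations(pd, obs[0, ])
  expect_true(is.na(empty$agreement))
  expect_error(
    compare_to_observations(pd, data.frame(name = "nope", c_wtpct = 0.05,
                                           regime = "a1")),
    "no prediction")
})

test_that("reproduction report lines computed values up against reported ones", {
  rep <- reproduction_report()
  expect_equal(rep$name, c("guar_gum", "BG1", "BG2", "BG3"))
  expect_equal(rep$cvc_table, c(0.11, 0.16, 0.24, 0.46))
  expect_equal(rep$cfc_table, c(0.037, 0.037, 0.044, 0.052))
  expect_equal(rep$cvc_match, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(rep$cfc_match, c(TRUE, FALSE, TRUE, FALSE))
  # full-precision columns are not the truncated ones
  expect_true(all(rep$cvc_computed >= rep$cvc_table))
})

test_that("extract report applies the mixing dilution and ranks flocculation tendency", {
  rep <- extract_stability_report()
  expect_equal(rep$c_mixture_wtpct, rep$c_extract_wtpct * 20 / 30.64,
               tolerance = 1e-12)

  flakes1 <- rep[rep$source == "flakes" & rep$incubation_h == 1, ]
  expect_equal(flakes1$regime_mixture, "a2")
  expect_true(flakes1$flocculated && flakes1$creams)

  bran72 <- rep[rep$source == "bran" & rep$incubation_h == 72, ]
  expect_true(bran72$regime_mixture %in% c("a3", "a4"))
  expect_false(bran72$creams)

  ctrl <- rep[rep$source == "control", ]
  expect_true(all(ctrl$regime_mixture == "a1"))

  # predicted flocculation tendency: bran > flour > flakes > control
  for (h in c(1, 72)) {
    at_h <- rep[rep$incubation_h == h, ]
    expect_equal(at_h$source[order(at_h$tendency_rank)],
                 c("bran", "flour", "flakes", "control"))
  }

  # the duodenal-digestion dilution is weaker polymer-wise than the mixing one
  dig <- extract_stability_report(dilution = 9 / 37.5)
  expect_equal(dig$c_mixture_wtpct, dig$c_extract_wtpct * 9 / 37.5,
               tolerance = 1e-12)
  expect_true(all(dig$c_mixture_wtpct <= rep$c_mixture_wtpct))
})
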