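test_that("contact depletion potential is zero without depletant and matches the oracle", {
  for (p in panel)
    expect_identical(
      depletion_potential_contact(solution_state(p, 0), baseline_emulsion), 0)
  # spot values against the independent direct evaluation in the helper
  for (cw in c(0.01, 0.0377, 0.2)) {
    w_pkg <- depletion_potential_contact(solution_state(panel$guar, cw),
                                         baseline_emulsion)
    expect_equal(w_pkg, oracle_w_contact(2490, 78, cw), tolerance = 1e-12)
    expect_lt(w_pkg, 0)
  }
  # at the solved CFC the attraction equals the threshold magnitude
  for (p in panel) {
    r <- cfc(p, baseline_emulsion)
    w_at_cfc <- depletion_potential_contact(solution_state(p, r$cfc),
                                            baseline_emulsion)
    expect_equal(w_at_cfc, -4, tolerance = 1e-9)
  }
})

test_that("depletion attraction strengthens with concentration, polymer size and droplet size", {
  cs <- seq(0.005, 0.5, length.out = 40)
  w_c <- depletion_potential_contact(solution_state(panel$bg2, cs),
                                     baseline_emulsion)
  expect_true(all(diff(w_c) < 0))

  set.seed(11)
  for (i in 1:25) {
    mw <- exp(runif(1, log(100), log(3000)))
    cw <- runif(1, 0.01, 0.3)
    rh_pair <- sort(exp(runif(2, log(10), log(100))))
    w_small <- depletion_potential_contact(
      solution_state(polymer_spec("s", mw, rh_pair[1]), cw), baseline_emulsion)
    w_large <- depletion_potential_contact(
      solution_state(polymer_spec("l", mw, rh_pair[2]), cw), baseline_emulsion)
    expect_lt(w_large, w_small)

    d_pair <- sort(runif(2, 0.5, 6))
    w_r1 <- depletion_potential_contact(
      solution_state(panel$bg1, cw), emulsion_spec(d_pair[1]))
    w_r2 <- depletion_potential_contact(
      solution_state(panel$bg1, cw), emulsion_spec(d_pair[2]))
    expect_lt(w_r2, w_r1)
  }
})

test_that("closed-form CFC reproduces frozen panel values and honours sign conventions", {
  # frozen from the bisection oracle run outside the package
  expect_equal(cfc(panel$guar)$cfc, 0.0377095285415, tolerance = 1e-9)
  expect_equal(cfc(panel$bg2)$cfc, 0.0443195923932, tolerance = 1e-9)
  expect_equal(cfc(panel$bg3)$cfc, 0.0520096618047, tolerance = 1e-9)

  r <- cfc(panel$guar)
  expect_lt(r$quad_b, 0)
  expect_lt(r$quad_a, 0)
  # a = b * (2 pi Rh^3 N_A / 3M), the osmotic non-ideality factor
  k_osm <- 2 * pi * (78e-9)^3 * 6.022e23 / (3 * 2490)
  expect_equal(r$quad_a, r$quad_b * k_osm, tolerance = 1e-12)
  expect_equal(r$w_contact, -4, tolerance = 1e-9)
  # the (1 + Kc) factor only strengthens attraction: root below linear estimate
  for (p in panel) {
    rr <- cfc(p)
    linear <- model_constants()$w_threshold / (-rr$quad_b) / 10
    expect_lte(rr$cfc, linear)
  }
})

test_that("bisection oracle and closed form agree on the panel and in limits", {
  for (p in panel)
    expect_equal(cfc_bisection(p), cfc(p)$cfc, tolerance = 1e-9)
  # vanishing threshold drives the root to zero
  tiny <- model_constants(w_threshold = 1e-8)
  expect_lt(cfc_bisection(panel$guar, constants = tiny), 1e-8)
  expect_lt(cfc(panel$guar, constants = tiny)$cfc, 1e-8)
})

test_that("CFC decreases as droplets grow", {
  d32 <- c(0.5, 1, 2, 4, 8)
  cfcs <- vapply(d32, function(d) cfc(panel$bg2, emulsion_spec(d))$cfc,
                 numeric(1))
  expect_true(all(diff(cfcs) < 0))
})

test_that("CVC/CFC window ratio widens monotonically from guar to BG3", {
  ratios <- vapply(panel, function(p) flocculation_window(p)$ratio, numeric(1))
  expect_equal(unname(ratios[c("guar", "bg3")]),
               c(2.92355282504, 9.03125022672), tolerance = 1e-8)
  expect_true(all(diff(ratios) > 0))
})
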