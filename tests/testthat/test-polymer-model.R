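test_that("mass-concentration conversion is linear and round-trips exactly", {
  expect_identical(to_mass_concentration(0), 0)
  expect_identical(to_mass_concentration(1), 10)
  expect_equal(to_mass_concentration(0.11), 1.1)
  x <- c(0, 0.025, 0.11, 1, 7.3)
  expect_equal(to_weight_percent(to_mass_concentration(x)), x,
               tolerance = 1e-15)
  expect_error(to_mass_concentration(-0.1), "non-negative")
  custom <- model_constants(wtpct_to_kgm3 = 12)
  expect_equal(to_mass_concentration(1, custom), 12)
})

test_that("effective volume fraction matches hand-evaluated values and is linear in c", {
  # frozen by direct evaluation of (4/3) pi Rh^3 c N_A / M outside the package
  phi <- effective_volume_fraction(solution_state(panel$guar, 0.1))
  expect_equal(phi, 0.480743943313, tolerance = 1e-10)
  expect_identical(effective_volume_fraction(solution_state(panel$bg2, 0)), 0)
  # the concentration given by the simplified CVC rule puts BG3 at phi_star
  expect_equal(effective_volume_fraction(solution_state(panel$bg3, 0.4695)),
               0.53, tolerance = 1e-2)
  cs <- c(0.01, 0.02, 0.05, 0.08)
  phis <- effective_volume_fraction(solution_state(panel$bg1, cs))
  expect_equal(phis / cs, rep(phis[1] / cs[1], 4), tolerance = 1e-12)
})

test_that("relative viscosity is 1 in solvent, rises strictly, diverges at packing", {
  expect_identical(relative_viscosity(0), 1)
  expect_equal(relative_viscosity(0.285), 4)
  phis <- seq(0, 0.56, length.out = 50)
  etas <- relative_viscosity(phis)
  expect_true(all(diff(etas) > 0))
  expect_error(relative_viscosity(0.57), "diverges")
  expect_error(relative_viscosity(0.8), "diverges")
})

test_that("solve_phi_star inverts the viscosity model in closed form", {
  expect_equal(solve_phi_star(100, 0.57), 0.513)
  expect_identical(solve_phi_star(1), 0)
  expect_equal(solve_phi_star(4, 0.57), 0.285)
  expect_error(solve_phi_star(0.5), ">= 1")
  for (r in c(1, 4, 25, 100, 400))
    expect_equal(relative_viscosity(solve_phi_star(r)), r, tolerance = 1e-10)
})

test_that("CVC reproduces the guar desk value and scales linearly with Mw", {
  expect_equal(round(cvc(panel$guar), 2), 0.11)
  expect_equal(cvc(panel$guar), 0.110245798698, tolerance = 1e-10)
  expect_equal(cvc(panel$bg3), 0.469712269966, tolerance = 1e-10)
  doubled <- polymer_spec("guar2", 2 * 2490, 78)
  expect_equal(cvc(doubled), 2 * cvc(panel$guar), tolerance = 1e-12)
  # the effective volume fraction at the CVC is phi_star by construction
  for (p in panel)
    expect_equal(effective_volume_fraction(solution_state(p, cvc(p))),
                 defaults$phi_star, tolerance = 1e-12)
})

test_that("full CVC formula agrees with the 21*M/Rh^3 desk rule within 0.5%", {
  expect_equal(round(cvc_prefactor()), 21)
  set.seed(7)
  mw <- exp(runif(1e4, log(50), log(5000)))
  rh <- exp(runif(1e4, log(5), log(150)))
  full <- vapply(seq_along(mw), function(i)
    cvc(polymer_spec("p", mw[i], rh[i])), numeric(1))
  simple <- 21 * mw / rh^3
  expect_true(all(abs(full / simple - 1) < 0.005))
})

test_that("Rh-Mw scaling fit recovers the panel power law and exact special cases", {
  fit <- fit_rh_scaling(reference_polymer_table())
  # frozen from an independent log-log least squares outside the package
  expect_equal(fit$nu, 0.555378347333, tolerance = 1e-9)
  expect_equal(fit$k, 1.04096901695, tolerance = 1e-9)
  expect_equal(fit$residual_se, 0.0386410653311, tolerance = 1e-8)
  expect_equal(fit$n, 4L)

  # two points: exact interpolating power law, zero residual
  two <- fit_rh_scaling(list(polymer_spec("a", 100, 10),
                             polymer_spec("b", 400, 20)))
  expect_equal(two$nu, 0.5, tolerance = 1e-12)
  expect_equal(two$k, 10 / 100^0.5, tolerance = 1e-12)
  expect_equal(two$residual_se, 0, tolerance = 1e-10)

  # noiseless synthetic family is closed under the model
  clean <- lapply(1:6, function(i)
    polymer_spec(paste0("p", i), 100 * 2^i, 2.5 * (100 * 2^i)^0.58))
  refit <- fit_rh_scaling(clean)
  expect_equal(refit$nu, 0.58, tolerance = 1e-10)
  expect_equal(refit$k, 2.5, tolerance = 1e-8)

  expect_error(fit_rh_scaling(list(panel$guar)), "at least two")
  expect_error(fit_rh_scaling(list(polymer_spec("a", 100, 10),
                                   polymer_spec("b", 100, 12))),
               "unidentifiable")
})

test_that("type constructors enforce their invariants", {
  expect_error(polymer_spec("x", -1, 10), "mw")
  expect_error(polymer_spec("x", 100, 0), "rh")
  expect_error(polymer_spec("x", 100, 10, purity = 1.2), "purity")
  expect_error(model_constants(phi_star = 0.6, phi_c = 0.57), "strictly less")
  expect_error(model_constants(eta_ratio_criterion = 0.5), "exceed 1")
  expect_error(solution_state(panel$guar, -0.1), "non-negative")
  e <- emulsion_spec(2.0)
  expect_equal(e$sauter_diameter, 2 * e$droplet_radius * 1e6, tolerance = 1e-9)
})

test_that("polymer table reader enforces schema and numeric columns", {
  tab <- reference_polymer_table()
  expect_equal(tab$name, c("guar_gum", "BG1", "BG2", "BG3"))
  expect_equal(tab$mw_kg_per_mol, c(2490, 1020, 650, 272))
  expect_equal(tab$rh_nm, c(78, 51, 38, 23))

  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,mw_kg_per_mol,rh_nm", 'x,"2490,5",78'), p)
  expect_error(read_polymer_table(p), "decimal commas")
  writeLines(c("name,mw", "x,1"), p)
  expect_error(read_polymer_table(p), "columns")

  fam <- list(polymer_spec("a", 100, 10, 0.9), polymer_spec("b", 200, 15))
  out <- withr::local_tempfile(fileext = ".csv")
  write_polymer_table(fam, out)
  back <- read_polymer_table(out)
  expect_equal(back$mw_kg_per_mol, c(100, 200))
  expect_equal(back$purity, c(0.9, NA))
})
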