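test_that("homeostatic modifiers reproduce their defining arithmetic", {
  p <- tcell_params(s_bar = 0.48, np_bar = 387, b = 3.4, constant_g = FALSE)

  # thymic export modifier s
  expect_identical(export_modifier_s(0, p), 1)
  expect_equal(export_modifier_s(387, p), 1 / 1.48)
  p0 <- tcell_params(s_bar = 0, np_bar = 713)
  expect_identical(export_modifier_s(500, p0), 1)
  expect_error(export_modifier_s(-1, p), "non-negative")

  # naive death modifier g
  expect_identical(death_modifier_g(0, p), 1)
  expect_equal(death_modifier_g(387, p), 4.4 / 2)
  expect_error(death_modifier_g(-1, p), "non-negative")

  # g held constant when b = 0 (the no-homeostatic-death scenarios)
  pg <- tcell_params(b = 0, np_bar = 713)
  expect_true(pg$constant_g)
  expect_identical(death_modifier_g(1000, pg), 1)
  # raw formula stays available for sensitivity work
  expect_equal(death_modifier_g(713, pg, raw = TRUE), 1 / 2)

  # dilution modifier h
  ph <- tcell_params(np_bar = 378)
  expect_identical(dilution_modifier_h(0, 0, ph), 1)
  expect_equal(dilution_modifier_h(0, 378, ph), 0.5)
  expect_equal(dilution_modifier_h(756, 378, ph), 0.25)
  expect_error(dilution_modifier_h(-1, 0, ph), "non-negative")
})

test_that("modifiers are bounded and monotone over their domain", {
  for (id in 1:5) {
    p <- scenario_parameters(id)$parameters
    np <- c(0, 10^(0:5))
    s <- export_modifier_s(np, p)
    g <- death_modifier_g(np, p)
    h <- dilution_modifier_h(np, rev(np), p)
    expect_true(all(s > 0 & s <= 1))
    expect_true(all(g > 0 & g <= max(1, p$b)))
    expect_true(all(h > 0 & h <= 1))
    if (p$s_bar > 0) expect_true(all(diff(s) < 0))
    expect_true(all(diff(dilution_modifier_h(np, 0, p)) < 0))
  }
})

test_that("thymic output halves every 15.7 years and respects modifiers", {
  p <- tcell_params()
  expect_equal(thymic_output_rate(0, 0, p), 56615)
  expect_equal(thymic_output_rate(15.7, 0, p), 56615 / 2)
  expect_equal(thymic_output_rate(31.4, 0, p), 56615 / 4)
  p_off <- tcell_params(s0 = 0)
  expect_identical(thymic_output_rate(40, 123, p_off), 0)
  expect_error(thymic_output_rate(-1, 0, p), "non-negative")
})

test_that("scenario registry returns the study design exactly", {
  tab <- list(
    `1` = list(lambda_n = 0.22, lambda_mn = 0.05, np_bar = 387,
               s_bar = 0.48, b = 3.4, mu_np = 0.13),
    `2` = list(lambda_n = 2.1, lambda_mn = 0, np_bar = 713,
               s_bar = 0, b = 0, mu_np = 4.4),
    `3` = list(lambda_n = 0.003, lambda_mn = 0, np_bar = 392,
               s_bar = 0, b = 4.2, mu_np = 4.4),
    `4` = list(lambda_n = 0.005, lambda_mn = 0, np_bar = 378,
               s_bar = 2.4, b = 0, mu_np = 4.4),
    `5` = list(lambda_n = 0.005, lambda_mn = 0, np_bar = 378,
               s_bar = 2.2, b = 0.13, mu_np = 4.4))
  for (id in 1:5) {
    sc <- scenario_parameters(id)
    expect_identical(sc$id, as.integer(id))
    p <- sc$parameters
    for (nm in names(tab[[as.character(id)]]))
      expect_identical(p[[nm]], tab[[as.character(id)]][[nm]])
    # shared constants
    expect_identical(p$s0, 56615)
    expect_equal(p$lambda_t, log(2) / 15.7)
    expect_identical(p$mu_n, 4.4)
    expect_identical(p$mu_m, 0.05)
    expect_identical(p$lambda_a, 1)
    expect_identical(p$constant_g, p$b == 0)
  }
  expect_error(scenario_parameters(0), "1\\.\\.5")
  expect_error(scenario_parameters(6), "1\\.\\.5")
  expect_error(scenario_parameters("a"), "1\\.\\.5")
})

test_that("proliferation coefficient is zero only without proliferation", {
  expect_identical(proliferation_coefficient(1), 0)
  expect_equal(proliferation_coefficient(2), 4.4 * (1 + 300 / 713))
  expect_equal(proliferation_coefficient(5), 4.4 * (1 + 300 / 378))
  for (id in 2:5) expect_gt(proliferation_coefficient(id), 0)
})

test_that("derivatives match hand arithmetic and conserve transfers", {
  actives <- fixture_actives()
  a_fun <- function(t) active_at(actives, t)

  # scenario 2 at birth: s = g = 1, Np = M = 0
  d <- derivatives(tcell_state(0, 3673, 0, 0),
                   scenario_parameters(2)$parameters, a_fun)
  expect_equal(unname(d["dN"]), 56615 - (2.1 + 4.4) * 3673)
  expect_equal(unname(d["dNp"]), 2.1 * 3673)
  expect_equal(unname(d["dM"]), a_fun(0))

  # null system
  d0 <- derivatives(tcell_state(3, 10, 20, 30),
                    null_scenario()$parameters, function(t) 0)
  expect_equal(unname(d0), c(0, 0, 0))

  # mass balance of the transfer terms at random states: the lambda_n*N
  # flux leaves N and enters Np; the lambda_mn*M flux leaves M and
  # enters Np
  set.seed(11)
  for (i in 1:20) {
    st <- tcell_state(runif(1, 0, 100), runif(1, 0, 5000),
                      runif(1, 0, 5000), runif(1, 0, 5000))
    p <- scenario_parameters(sample(1:5, 1))$parameters
    d <- derivatives(st, p, a_fun)
    p_noconv <- p; p_noconv$lambda_n <- 0
    d_noconv <- derivatives(st, p_noconv, a_fun)
    flux_n <- p$lambda_n * st$N
    expect_equal(unname(d["dN"] - d_noconv["dN"]), -flux_n)
    expect_equal(unname(d["dNp"] - d_noconv["dNp"]), flux_n)
    p_norev <- p; p_norev$lambda_mn <- 0
    d_norev <- derivatives(st, p_norev, a_fun)
    flux_m <- p$lambda_mn * st$M
    expect_equal(unname(d["dM"] - d_norev["dM"]), -flux_m)
    expect_equal(unname(d["dNp"] - d_norev["dNp"]), flux_m)
  }

  expect_error(derivatives(tcell_state(5, 1, 1, 1),
                           scenario_parameters(1)$parameters,
                           function(t) NA_real_), "undefined")
})

test_that("scenario configs round-trip through JSON with key overrides", {
  path <- withr::local_tempfile(fileext = ".json")
  for (id in 1:5) {
    sc <- scenario_parameters(id)
    write_scenario_json(sc, path)
    back <- read_scenario_json(path)
    expect_identical(back$id, sc$id)
    expect_identical(back$description, sc$description)
    expect_equal(unclass(back$parameters), unclass(sc$parameters))
  }
  over <- read_scenario_json(path, overrides = list(s0 = 100))
  expect_identical(over$parameters$s0, 100)
  expect_error(read_scenario_json(path, overrides = list(nope = 1)),
               "unknown override")
})

test_that("parameter and state validation rejects bad inputs", {
  expect_error(tcell_params(mu_n = -1), "non-negative")
  expect_error(tcell_params(np_bar = 0), "np_bar")
  expect_error(tcell_state(-1, 0, 0, 0), "non-negative")
  expect_error(tcell_state(0, -5, 0, 0), "non-negative")
})
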