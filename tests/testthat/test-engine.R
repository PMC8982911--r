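# Stock-flow engine: validation, expression grammar, lookups, Euler stepping.

test_that("validation accepts a minimal model and reports violations as data", {
  ok <- sd_model("minimal", horizon = list(start = 2015, end = 2050, dt = 1),
                 stocks = list(sd_stock("P", 10)))
  expect_s3_class(validate_model(ok), "sd_validation")
  expect_identical(nrow(validate_model(ok)), 0L)

  undeclared <- sd_model("bad", stocks = list(sd_stock("P", 10)),
                         flows = list(sd_flow("f", "0.1*xyz", sink = "P",
                                              signs = c(xyz = 1))))
  v <- validate_model(undeclared)
  expect_identical(nrow(v), 1L)
  expect_identical(v$rule, "undeclared-reference")
  expect_identical(v$variable, "xyz")

  algebraic <- sd_model("loop", auxiliaries = list(
    sd_aux("a", "b + 1", signs = c(b = 1)),
    sd_aux("b", "a + 1", signs = c(a = 1))))
  v <- validate_model(algebraic)
  expect_identical(nrow(v), 1L)
  expect_identical(v$rule, "algebraic-cycle")
  expect_identical(v$variable, "a, b")

  dup <- sd_model("dup", stocks = list(sd_stock("x", 1)),
                  auxiliaries = list(sd_aux("x", "1")))
  expect_true("duplicate-name" %in% validate_model(dup)$rule)

  bad_h <- sd_model("h", horizon = list(start = 2020, end = 2015, dt = 1),
                    stocks = list(sd_stock("P", 1)))
  expect_true("bad-horizon" %in% validate_model(bad_h)$rule)
  frac <- sd_model("h2", horizon = list(start = 2015, end = 2020, dt = 0.3),
                   stocks = list(sd_stock("P", 1)))
  expect_true("bad-horizon" %in% validate_model(frac)$rule)
})

test_that("expression evaluation is deterministic and matches hand values", {
  expect_identical(eval_expression("max(0, goal - current)/at",
                                   list(goal = 5, current = 3, at = 2)), 1.0)
  expect_identical(eval_expression("if_then_else(t >= 2020, 1, 0)", t = 2019), 0)
  expect_identical(eval_expression("if_then_else(t >= 2020, 1, 0)", t = 2020), 1)
  ramp <- sd_lookup("ramp", c(2015, 2030), c(27.8, 25))
  # hand linear interpolation: 27.8 + (25 - 27.8) * 5/15
  expect_equal(eval_expression("lookup(ramp, 2020)", lookups = list(ramp = ramp)),
               27.8 + (25 - 27.8) * 5 / 15, tolerance = 1e-12)
})

test_that("expression errors name the offending symbol and the grammar is closed", {
  expect_error(eval_expression("a + b", list(a = 1)), "b")
  expect_error(eval_expression("1 / x", list(x = 0)), "division by zero")
  expect_error(eval_expression("exp(1)"), "grammar")
  expect_error(eval_expression("system('true')"), "grammar")
  expect_error(eval_expression("x ^ 2", list(x = 2)), "grammar")
})

test_that("lookup interpolation hits knots, interpolates, and clamps", {
  expect_identical(apply_lookup(sd_lookup("a", 2020, 0.5), 2020), 0.5)
  tab <- sd_lookup("b", c(0, 10), c(0, 10))
  expect_identical(apply_lookup(tab, 5), 5)
  expect_identical(apply_lookup(tab, 25), 10)
  expect_identical(apply_lookup(tab, -5), 0)
  empty <- structure(list(name = "e", x = numeric(0), y = numeric(0)),
                     class = "sd_lookup")
  expect_error(apply_lookup(empty, 1), "empty")
})

test_that("Euler stepping: conservation, constant rates, decay closed form", {
  still <- sd_model("still", horizon = list(start = 2015, end = 2050, dt = 1),
                    stocks = list(sd_stock("S", 10)))
  tr <- simulate_model(still)
  expect_identical(trajectory_value(tr, "S", 2050), 10)

  filling <- sd_model("fill", horizon = list(start = 0, end = 5, dt = 1),
                      stocks = list(sd_stock("S", 0)),
                      flows = list(sd_flow("inflow", "2", sink = "S")))
  expect_identical(trajectory_value(simulate_model(filling), "S", 5), 10)

  tr <- simulate_model(decay_model(k = 0.1, s0 = 100))
  expect_equal(trajectory_value(tr, "S", 10),
               euler_decay_closed_form(100, 0.1, 1, 10), tolerance = 1e-9)
  expect_equal(trajectory_value(tr, "S", 10), 34.8678440100, tolerance = 1e-6)
})

test_that("Euler matches the closed-form recurrence for any k*dt < 1", {
  for (k in c(0.02, 0.1, 0.45, 0.9)) {
    for (dt in c(1, 0.5, 0.25)) {
      n <- as.integer(10 / dt)
      tr <- simulate_model(decay_model(k = k, horizon = list(start = 0, end = 10, dt = dt)))
      expect_equal(tr$series$S[[n + 1L]], euler_decay_closed_form(100, k, dt, n),
                   tolerance = 1e-9)
    }
  }
})

test_that("halving dt shows first-order convergence on the decay model", {
  exact <- 100 * exp(-0.1 * 10)
  err <- vapply(c(0.5, 0.25, 0.125), function(dt) {
    tr <- simulate_model(decay_model(horizon = list(start = 0, end = 10, dt = dt)))
    abs(tr$series$S[[length(tr$series$S)]] - exact)
  }, numeric(1))
  ratios <- err[-length(err)] / err[-1L]
  expect_true(all(ratios > 1.7 & ratios < 2.3))
})

test_that("flows between two stocks conserve their sum", {
  tr <- simulate_model(two_stock_model())
  total <- tr$series$A + tr$series$B
  expect_equal(total, rep(100, length(tr$times)), tolerance = 1e-12)
})

test_that("identical inputs give bitwise-identical trajectories", {
  m <- two_stock_model()
  expect_identical(simulate_model(m), simulate_model(m))
})

test_that("non-negative stocks are floored at zero with a logged warning", {
  m <- sd_model("drain", horizon = list(start = 0, end = 10, dt = 1),
                stocks = list(sd_stock("S", 3, non_negative = TRUE)),
                flows = list(sd_flow("out", "2", source = "S")))
  expect_warning(tr <- simulate_model(m), "floored")
  expect_true(all(tr$series$S >= 0))
  expect_true(nrow(tr$metadata$floored) > 0)
  expect_identical(tr$metadata$floored$stock[[1L]], "S")
})

test_that("simulation refuses invalid models and undeclared overrides", {
  bad <- sd_model("bad", stocks = list(sd_stock("P", 10)),
                  flows = list(sd_flow("f", "0.1*xyz", sink = "P",
                                       signs = c(xyz = 1))))
  expect_error(simulate_model(bad), "refusing")
  ok <- decay_model()
  expect_error(simulate_model(ok, overrides = list(zzz = 1)), "zzz")
})

test_that("overrides: parameter constants, stock initials and time overlays", {
  m <- decay_model(k = 0.1)
  tr <- simulate_model(m, overrides = list(k = 0))
  expect_identical(trajectory_value(tr, "S", 10), 100)
  tr <- simulate_model(m, overrides = list(S = 50))
  expect_equal(trajectory_value(tr, "S", 10),
               euler_decay_closed_form(50, 0.1, 1, 10), tolerance = 1e-12)
  # overlay pins the flow itself to a time function
  tr <- simulate_model(m, overrides = list(outflow = make_step(0, 5, 10)))
  expect_identical(trajectory_value(tr, "S", 5), 50)
  expect_identical(trajectory_value(tr, "S", 10), 50)
})

test_that("model YAML files round-trip identically", {
  m <- two_stock_model()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_yaml(m, path)
  expect_identical(read_model_yaml(path), m)
  # and the shipped Egypt fixture reproduces the built model
  fixture <- system.file("extdata", "coviam_egypt.yaml", package = "coviam")
  expect_identical(read_model_yaml(fixture),
                   build_coviam(egypt_baseline(), coviam_parameters()))
})
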