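test_that("scatter search solves a toy mixed-integer problem to the oracle", {
  bounds <- toy_mi_bounds()
  # brute-force oracle: closed form in x for each integer z
  oracle <- min(vapply(0:5, function(z) (z - 2)^2, numeric(1)))
  fit <- scatter_search(toy_mi_objective, bounds,
                        scatter_settings(max_eval = 1500, seed = 4,
                                         local_freq = 2,
                                         local_budget = 200))
  expect_equal(fit$best_value, oracle, tolerance = 1e-6)
  expect_equal(fit$best_x[1], 0.3, tolerance = 1e-3)
  expect_identical(fit$best_x[2], 2)
})

test_that("every evaluated point is feasible and integral", {
  bounds <- make_bounds(c(-2, -2, 0, 0), c(2, 2, 3, 1),
                        c(FALSE, FALSE, TRUE, TRUE))
  seen <- new.env(); seen$bad <- 0L
  obj <- function(x) {
    if (any(x < bounds$lower - 1e-12) || any(x > bounds$upper + 1e-12) ||
        any(x[3:4] != round(x[3:4]))) {
      seen$bad <- seen$bad + 1L
    }
    sum(x[1:2]^2) + (x[3] - 1)^2 + x[4]
  }
  fit <- scatter_search(obj, bounds,
                        scatter_settings(max_eval = 600, seed = 2))
  expect_identical(seen$bad, 0L)
  expect_lte(fit$n_eval, 600)
})

test_that("traces are monotone and seed-reproducible", {
  bounds <- toy_mi_bounds()
  a <- scatter_search(toy_mi_objective, bounds,
                      scatter_settings(max_eval = 400, seed = 9))
  b <- scatter_search(toy_mi_objective, bounds,
                      scatter_settings(max_eval = 400, seed = 9))
  expect_true(all(diff(a$trace$best) <= 0))
  expect_identical(a$trace, b$trace)
  expect_identical(a$best_x, b$best_x)
  expect_equal(min(a$trace$best), a$best_value)
})

test_that("local refinement is a descent method", {
  bounds <- toy_mi_bounds()
  # from the oracle optimum it must return the start
  x_star <- c(0.3, 2)
  r0 <- local_refine(x_star, toy_mi_objective, bounds, budget = 200)
  expect_identical(r0$x[2], 2)
  expect_equal(r0$value, 0, tolerance = 1e-9)
  # convex quadratic with integers fixed reaches the analytic minimizer
  set.seed(8)
  for (i in 1:3) {
    x0 <- c(runif(1, -5, 5), sample(0:5, 1))
    r <- local_refine(x0, toy_mi_objective, bounds, budget = 400)
    expect_lte(r$value, toy_mi_objective(x0))
    expect_equal(r$x[1], 0.3, tolerance = 1e-4)
  }
  # repair-enabled integer moves escape a structure mismatch
  r2 <- local_refine(c(-4, 0), toy_mi_objective, bounds, budget = 800,
                     repair_budget = 50)
  expect_identical(r2$x[2], 2)
})

test_that("multistart returns one final value per start", {
  bounds <- make_bounds(c(-3, -3), c(3, 3), c(FALSE, FALSE))
  convex <- function(x) sum((x - 0.5)^2)
  ms <- multistart(convex, n_starts = 6, bounds, seed = 3, budget = 300)
  expect_identical(nrow(ms), 6L)
  expect_true(all(is.finite(ms$value)))
  # strictly convex: all runs agree
  expect_lt(max(ms$value) - min(ms$value), 1e-6)
  # determinism
  ms2 <- multistart(convex, n_starts = 6, bounds, seed = 3, budget = 300)
  expect_identical(ms, ms2)
})

test_that("decision-vector encoding round-trips and respects bounds", {
  nomf <- nominal_fixture()
  bounds <- decision_bounds()
  x <- encode_decision(nomf$parameters, nomf$structure)
  expect_length(x, 25)
  expect_true(all(x >= bounds$lower & x <= bounds$upper))
  dec <- decode_decision(x, bounds)
  expect_equal(unclass(dec$parameters), unclass(nomf$parameters),
               tolerance = 1e-12)
  expect_identical(unclass(dec$structure), unclass(nomf$structure))
  # the full decision space has 17 reals + 5 integer exponents + 3 binaries
  expect_identical(sum(!bounds$is_int), 17L)
  expect_identical(sum(bounds$is_int), 8L)
})
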