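nom <- nominal_fixture()
cst <- kdp_constants()

test_that("log-likelihood matches its closed forms", {
  one <- kdp_dataset(tibble::tibble(
    experiment_id = "e1", strain = "wild", K_mM = 10, variable = "mRNA",
    time_h = 0.1, value = 2, sigma = 1))
  # perfect fit, sigma = 1: -0.5 log(2 pi)
  expect_equal(log_likelihood(one, 2), -0.5 * log(2 * pi),
               tolerance = 1e-12)
  # a residual of k sigma lowers the value by k^2/2
  for (k in c(0.5, 1, 3)) {
    expect_equal(log_likelihood(one, 2 + k) - log_likelihood(one, 2),
                 -k^2 / 2, tolerance = 1e-12)
  }
  # additivity: duplicating the dataset doubles the value
  two <- kdp_dataset(dplyr::bind_rows(one, one))
  expect_equal(log_likelihood(two, c(2.4, 2.4)),
               2 * log_likelihood(one, 2.4), tolerance = 1e-12)
  expect_error(log_likelihood(one, c(1, 2)), "one-to-one")
})

test_that("AIC identity and monotonicity", {
  expect_identical(aic(0, 0), 0)
  expect_identical(aic(-10, 3), 26)
  for (np in 0:5) expect_equal(aic(-3.3, np), -2 * -3.3 + 2 * np)
  expect_equal(aic(-3.3, 4) - aic(-3.3, 3), 2)
})

test_that("objective at the generating truth reduces to the sigma term", {
  ds <- generate_dataset(generation_protocol(
    strains = "wild", K_levels = 10, t_grid = seq(0, 1, length.out = 5),
    noise = 0, seed = 3))
  v <- objective_evaluate(nom$structure, nom$parameters, ds, cst)
  expect_true(v$feasible)
  sigma_term <- sum(log(1 / sqrt(2 * pi * ds$sigma^2)))
  expect_equal(v$Jml, sigma_term, tolerance = 1e-6)
  expect_equal(v$aic, -2 * v$Jml + 2 * v$Np, tolerance = 1e-12)
})

test_that("mutant-only objective is invariant to bin3", {
  ds <- mutant_dataset(seed = 5)
  s0 <- nom$structure
  s1 <- kdp_structure(bin1 = 1, bin2 = 1, bin3 = 1, n1 = 3, n2 = 1,
                      n3 = 2, n4 = 1, n5 = 3)
  v0 <- objective_evaluate(s0, nom$parameters, ds, cst)
  v1 <- objective_evaluate(s1, nom$parameters, ds, cst)
  expect_equal(v0$Jml, v1$Jml, tolerance = 1e-12)
  # the AICs differ only through the parameter count
  expect_equal(v1$aic - v0$aic, 2 * (v1$Np - v0$Np), tolerance = 1e-12)
})

test_that("penalized evaluations order strictly after feasible ones", {
  ds <- tiny_dataset(seed = 9)
  good <- objective_evaluate(nom$structure, nom$parameters, ds, cst)
  p_bad <- unclass(nom$parameters)
  p_bad["ktr"] <- 1e30; p_bad["kz"] <- 1e-30
  bad <- silence_solver(
    objective_evaluate(nom$structure, do.call(kdp_parameters,
                                              as.list(p_bad)), ds, cst))
  expect_false(bad$feasible)
  expect_true(is.finite(bad$search_value))
  expect_gt(bad$search_value, good$search_value)
  # even a catastrophically bad feasible fit orders before the penalty
  p_off <- unclass(nom$parameters)
  p_off["ktr"] <- nom$parameters[["ktr"]] * 50
  off <- objective_evaluate(nom$structure,
                            do.call(kdp_parameters, as.list(p_off)), ds,
                            cst)
  if (off$feasible) expect_lt(off$search_value, bad$search_value)
})

test_that("residual summary arithmetic and zero handling", {
  d2 <- kdp_dataset(tibble::tibble(
    experiment_id = "e1", strain = "wild", K_mM = 10, variable = "mRNA",
    time_h = c(0.1, 0.2), value = c(2, 4), sigma = c(1, 1)))
  expect_equal(as.numeric(residual_summary(d2, c(2, 4))), 0)
  expect_equal(as.numeric(residual_summary(d2, c(1, 4))), 25)  # 50%/2
  dz <- kdp_dataset(tibble::tibble(
    experiment_id = "e1", strain = "wild", K_mM = 10, variable = "mRNA",
    time_h = c(0.1, 0.2), value = c(0, 2), sigma = c(1, 1)))
  expect_warning(r <- residual_summary(dz, c(0.5, 1)), "zero-valued")
  expect_equal(as.numeric(r), 50)
  expect_identical(attr(r, "n_excluded"), 1L)
})

test_that("residuals of noisy data at the truth match the Gaussian mean", {
  # |y~ - y| / |y~| has mean ~ noise * sqrt(2/pi) for small noise
  set.seed(1)
  reps <- purrr::map_dbl(1:6, function(i) {
    ds <- tiny_dataset(seed = 100 + i)
    pred <- predict_dataset(nom$structure, nom$parameters, ds, cst)
    as.numeric(residual_summary(pred))
  })
  expect_equal(mean(reps), 5 * sqrt(2 / pi), tolerance = 0.25)
})

test_that("dataset round-trips through CSV", {
  ds <- tiny_dataset(seed = 77)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(as.data.frame(back), as.data.frame(ds), tolerance = 1e-12,
               ignore_attr = TRUE)
})
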