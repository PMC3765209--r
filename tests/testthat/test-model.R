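nom <- nominal_fixture()
cst <- kdp_constants()

test_that("translation regulation factor follows its closed form", {
  p <- nom$parameters
  s_off <- kdp_structure(bin1 = 0)
  expect_equal(regulation_translation(c(0, 1, 50), s_off, p), rep(1, 3))
  s_on <- kdp_structure(bin1 = 1, n1 = 3)
  expect_equal(regulation_translation(0, s_on, p), 1 / 0.974,
               tolerance = 1e-12)
  # strictly decreasing in F, vanishing at large F
  Fs <- c(0.5, 1, 2, 10, 1e3)
  r <- regulation_translation(Fs, s_on, p)
  expect_true(all(diff(r) < 0))
  expect_lt(regulation_translation(1e6, s_on, p), 1e-15)
  expect_error(regulation_translation(NaN, s_on, p), "finite")
})

test_that("proteolysis regulation factor follows its closed form", {
  p <- nom$parameters
  expect_equal(regulation_proteolysis(7, kdp_structure(bin2 = 0), p), 1)
  s_on <- kdp_structure(bin2 = 1, n2 = 1, n3 = 2)
  expect_equal(regulation_proteolysis(1, s_on, p), 1 / 1.136,
               tolerance = 1e-12)
  # n2 = n3 and kdeg -> 0 pushes the factor to 1
  p_small <- unclass(p); p_small["kdeg"] <- 1e-12
  s_eq <- kdp_structure(bin2 = 1, n2 = 2, n3 = 2)
  expect_equal(
    regulation_proteolysis(0.7, s_eq, do.call(kdp_parameters,
                                              as.list(p_small))),
    1, tolerance = 1e-10)
})

test_that("stimulus counteraction distinguishes strains and hypotheses", {
  p <- nom$parameters
  F <- c(0, 0.3, 2)
  # mutant value is invariant to every feedback-loop coordinate
  base <- stimulus_counteraction(F, "mutant", kdp_structure(), p, 50, cst)
  for (s in list(kdp_structure(bin3 = 1, n4 = 3, n5 = 2),
                 kdp_structure(bin3 = 0, n4 = 1))) {
    expect_identical(stimulus_counteraction(F, "mutant", s, p, 50, cst),
                     base)
  }
  # wild with khy -> 0 collapses to the mutant expression
  p0 <- unclass(p); p0["khy"] <- 1e-300
  expect_equal(
    stimulus_counteraction(F, "wild", kdp_structure(n4 = 2),
                           do.call(kdp_parameters, as.list(p0)), 50, cst),
    base, tolerance = 1e-10)
  # n5 = 0 makes the saturable form a 1/(1+Khy) rescaling of the linear one
  s0 <- kdp_structure(bin3 = 0, n4 = 3)
  s1 <- kdp_structure(bin3 = 1, n4 = 3, n5 = 0)
  lin <- stimulus_counteraction(F, "wild", s0, p, 50, cst) -
    p[["k3"]] * stimulus(50, cst)
  sat <- stimulus_counteraction(F, "wild", s1, p, 50, cst) -
    p[["k3"]] * stimulus(50, cst)
  expect_equal(sat, lin / (1 + p[["Khy"]]), tolerance = 1e-12)
  expect_error(stimulus_counteraction(F, "hybrid", s0, p, 50, cst),
               "strain")
})

test_that("promoter algebra is solved to tight residuals", {
  p <- nom$parameters
  # zero phospho-regulator: closed form
  z <- solve_algebraic(0, p)
  expect_identical(z$KdpEfP, 0)
  expect_equal(z$DNAf, p[["DNA0"]] / (1 + 1 / p[["K"]]), tolerance = 1e-14)
  # random positive inputs: residuals below 1e-10 and agreement with the
  # independent bisection oracle to 1e-8
  set.seed(11)
  for (EP in c(1e-9, 10^runif(8, -8, 1))) {
    sol <- solve_algebraic(EP, p)
    expect_true(sol$KdpEfP >= 0 && sol$KdpEfP <= EP)
    expect_true(sol$DNAf > 0 && sol$DNAf <= p[["DNA0"]])
    res <- algebraic_residuals(EP, sol$KdpEfP, sol$DNAf, p)
    expect_lt(max(abs(res)) / max(EP, p[["DNA0"]]), 1e-10)
    oracle <- bisect_algebraic(EP, p)
    expect_equal(sol$KdpEfP, oracle$KdpEfP, tolerance = 1e-8)
  }
  expect_error(solve_algebraic(-1, p), "non-negative")
})

test_that("simulated trajectories satisfy the model invariants", {
  des <- kdp_design("wild", 10, t_grid = seq(0, 1, length.out = 6))
  tr <- simulate_kdp(nom$structure, nom$parameters, des, cst)
  expect_true(trajectory_ok(tr))
  states <- c("mRNA", "KdpD0", "KdpE0", "KdpEP", "KdpFABC")
  expect_true(all(as.matrix(tr[states]) >= 0))
  # DNAf conservation and algebraic consistency at every output time
  expect_true(all(tr$DNAf > 0 & tr$DNAf <= nom$parameters[["DNA0"]]))
  for (i in seq_len(nrow(tr))) {
    res <- algebraic_residuals(tr$KdpEP[i], tr$KdpEfP[i], tr$DNAf[i],
                               nom$parameters)
    expect_lt(max(abs(res)), 1e-8)
  }
})

test_that("mutant trajectories are invariant to the wild-only coordinates", {
  des <- kdp_design("mutant", 50, t_grid = seq(0, 1, length.out = 5))
  p2 <- unclass(nom$parameters)
  p2["khy"] <- 123.4; p2["Khy"] <- 0.5
  a <- simulate_kdp(nom$structure, nom$parameters, des, cst)
  b <- simulate_kdp(kdp_structure(bin1 = 1, bin2 = 1, bin3 = 1,
                                  n1 = 3, n2 = 1, n3 = 2, n4 = 1, n5 = 2),
                    do.call(kdp_parameters, as.list(p2)), des, cst)
  expect_identical(as.matrix(a[-1]), as.matrix(b[-1]))
})

test_that("nestedness: inactive coordinates never affect the output", {
  des <- kdp_design("wild", 10, t_grid = seq(0, 0.5, length.out = 4))
  s_a <- kdp_structure(bin1 = 0, bin2 = 1, bin3 = 0, n1 = 0, n2 = 1,
                       n3 = 2, n4 = 3, n5 = 0)
  s_b <- kdp_structure(bin1 = 0, bin2 = 1, bin3 = 0, n1 = 3, n2 = 1,
                       n3 = 2, n4 = 3, n5 = 2)
  p2 <- unclass(nom$parameters)
  p2["ktrans"] <- 99; p2["Khy"] <- 42  # inactive reals under bin1=0, bin3=0
  a <- simulate_kdp(s_a, nom$parameters, des, cst)
  b <- simulate_kdp(s_b, do.call(kdp_parameters, as.list(p2)), des, cst)
  expect_identical(as.matrix(a[-1]), as.matrix(b[-1]))
})

test_that("compiled and reference right-hand sides agree", {
  des <- kdp_design("wild", 10, t_grid = seq(0, 1, length.out = 9))
  tr <- simulate_kdp(nom$structure, nom$parameters, des, cst)
  # central finite difference of the trajectory matches rhs() mid-grid
  states <- c("mRNA", "KdpD0", "KdpE0", "KdpEP", "KdpFABC")
  h <- diff(tr$time)[1]
  for (i in c(3, 5, 7)) {
    fd <- (as.numeric(tr[i + 1, states]) - as.numeric(tr[i - 1, states])) /
      (2 * h)
    d <- kdp_rhs(tr$time[i], stats::setNames(as.numeric(tr[i, states]),
                                             states),
                 nom$structure, nom$parameters, des, cst)$derivatives
    expect_equal(fd, as.numeric(d), tolerance = 5e-2)
  }
})

test_that("integration self-converges under tolerance tightening", {
  des <- kdp_design("mutant", 50, t_grid = seq(0, 1, length.out = 5))
  y0 <- initial_state(nom$structure, nom$parameters, cst, strain = "mutant")
  a <- simulate_kdp(nom$structure, nom$parameters, des, cst, init = y0,
                    rtol = 1e-8, atol = 1e-12)
  b <- simulate_kdp(nom$structure, nom$parameters, des, cst, init = y0,
                    rtol = 1e-9, atol = 1e-13)
  states <- c("mRNA", "KdpD0", "KdpE0", "KdpEP", "KdpFABC")
  rel <- abs(as.matrix(a[states]) - as.matrix(b[states])) /
    (abs(as.matrix(b[states])) + 1e-12)
  expect_lt(max(rel), 1e-4)
})

test_that("initial state: pass-through, steady state and idempotence", {
  y_user <- c(mRNA = 0.01, KdpD0 = 1, KdpE0 = 1, KdpEP = 1e-6,
              KdpFABC = 0.5)
  expect_identical(
    initial_state(nom$structure, nom$parameters, cst, state0 = y_user),
    y_user)
  y <- initial_state(nom$structure, nom$parameters, cst, strain = "wild")
  des <- kdp_design("wild", cst$prestim_K, t_grid = 1)
  d <- kdp_rhs(0, y, nom$structure, nom$parameters, des, cst)$derivatives
  expect_lt(max(abs(d) / (abs(y) + 1e-12)), 1e-6)
  # re-equilibrating from the steady state returns it
  des2 <- kdp_design("wild", cst$prestim_K,
                     t_grid = seq(0, 50, length.out = 3))
  tr <- simulate_kdp(nom$structure, nom$parameters, des2, cst, init = y)
  states <- c("mRNA", "KdpD0", "KdpE0", "KdpEP", "KdpFABC")
  expect_equal(as.numeric(tr[nrow(tr), states]), as.numeric(y),
               tolerance = 1e-6)
})

test_that("trajectories export to long-format CSV", {
  tr <- simulate_kdp(nom$structure, nom$parameters,
                     kdp_design("wild", 10, t_grid = c(0, 0.5, 1)), cst)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path, experiment_id = "wild_K10")
  back <- utils::read.csv(path)
  expect_identical(names(back), c("time", "state", "value",
                                  "experiment_id"))
  expect_identical(nrow(back), nrow(tr) * (ncol(tr) - 1L))
  expect_true(all(back$experiment_id == "wild_K10"))
})

test_that("integration failure is flagged, not raised", {
  # absurd parameters provoke integrator breakdown
  p_bad <- unclass(nom$parameters)
  p_bad["ktr"] <- 1e30; p_bad["kz"] <- 1e-30
  tr <- silence_solver(
    simulate_kdp(nom$structure, do.call(kdp_parameters, as.list(p_bad)),
                 kdp_design("wild", 10), cst,
                 init = c(mRNA = 1, KdpD0 = 1, KdpE0 = 1, KdpEP = 1,
                          KdpFABC = 1)))
  expect_false(trajectory_ok(tr))
})
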