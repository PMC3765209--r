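nom <- nominal_fixture()
cst <- kdp_constants()

test_that("relative sensitivities: structural zeros and self-convergence", {
  ds <- mutant_dataset(seed = 21, K_levels = 50)
  S <- relative_sensitivities(nom$structure, nom$parameters, ds, cst,
                              parameters = c("khy", "kz", "kd2"))
  # mutant dynamics do not depend on khy: an exact zero column
  expect_true(all(S[, "khy"] == 0))
  expect_gt(max(abs(S[, "kz"])), 0)
  # halving the step barely changes the entries (central differences);
  # checked away from the induction switch, where the response is smooth
  ds_mild <- mutant_dataset(seed = 21, K_levels = 500)
  Sa <- relative_sensitivities(nom$structure, nom$parameters, ds_mild, cst,
                               parameters = c("kz", "kd2"), step = 1e-4)
  Sb <- relative_sensitivities(nom$structure, nom$parameters, ds_mild, cst,
                               parameters = c("kz", "kd2"), step = 5e-5)
  # scale-relative: entries that are numerical zeros carry no information
  expect_lt(max(abs(Sa - Sb)) / max(abs(Sb)), 1e-4)
})

test_that("sensitivity ranking index follows its definition", {
  S <- matrix(c(0, 0, 0, 2, 1, -1), nrow = 3,
              dimnames = list(NULL, c("a", "b")))
  idx <- msqr_index(S)
  expect_equal(unname(idx), c(0, 6))
  # single entry S = 2 gives 4 under the sum-of-squares convention
  expect_equal(unname(msqr_index(matrix(2, 1, 1,
                                        dimnames = list(NULL, "p")))), 4)
  # rms variant
  expect_equal(unname(msqr_index(S, rms = TRUE)), sqrt(c(0, 2)))
  # duplicating the data doubles every index and preserves the ranking
  idx2 <- msqr_index(rbind(S, S))
  expect_equal(unname(idx2), 2 * unname(idx))
  r <- msqr_ranking(rbind(S, S))
  expect_identical(r$parameter[1], "b")
})

test_that("Fisher information: scalar case, rank deficiency, identity", {
  # scalar case: FIM = sum (dy/dp)^2 / sigma^2
  D <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(NULL, "p"))
  sig <- c(1, 2, 1)
  f <- fisher_information(D, sig)
  expect_equal(as.numeric(f), 1 + 1 + 9)
  # exactly duplicated column: rank 1
  D2 <- cbind(a = c(1, 2, 3), b = c(1, 2, 3))
  f2 <- fisher_information(D2, rep(1, 3))
  r <- fim_rank(f2)
  expect_identical(r$rank, 1L)
  expect_false(r$full_rank)
  expect_error(correlation_from_fim(f2), "not identifiable")
  # algebraic identity: FIM from the sensitivity object equals the one
  # rebuilt from de-normalized relative sensitivities
  ds <- tiny_dataset(seed = 13)
  S <- relative_sensitivities(nom$structure, nom$parameters, ds, cst,
                              parameters = c("kz", "kd", "kd2"))
  fim <- fisher_information(S, scale = "natural")
  y0 <- attr(S, "y0"); p0 <- attr(S, "p0")
  D_manual <- sweep(unclass(S) * y0, 2, p0, "/")
  fim_manual <- crossprod(D_manual / attr(S, "sigma"))
  expect_equal(unclass(fim), fim_manual, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("correlation from the FIM matches hand inversion", {
  f <- matrix(c(2, 1, 1, 2), 2, 2)
  C <- correlation_from_fim(f)
  expect_equal(C, matrix(c(1, -0.5, -0.5, 1), 2, 2), tolerance = 1e-12)
  # diagonal FIM: identity correlation
  expect_equal(correlation_from_fim(diag(c(3, 7, 0.1))), diag(3),
               tolerance = 1e-12)
  # always unit diagonal and entries in [-1, 1]
  set.seed(2)
  A <- matrix(rnorm(16), 4)
  C2 <- correlation_from_fim(crossprod(A) + diag(4))
  expect_equal(diag(C2), rep(1, 4))
  expect_true(all(C2 >= -1 & C2 <= 1))
})

test_that("pseudo-global analysis weights and degenerate averaging", {
  ds <- tiny_dataset(seed = 31)
  rep <- pseudo_global_analysis(nom$structure, ds, n_points = 8, seed = 3)
  w <- rep$weights
  expect_equal(sum(w$weight), 1, tolerance = 1e-12)
  expect_true(all(w$weight[!w$ok] == 0))
  # equal weights reduce to the unweighted mean of per-point indices
  rep_eq <- pseudo_global_analysis(nom$structure, ds, n_points = 8,
                                   seed = 3, equal_weights = TRUE)
  expect_equal(sum(rep_eq$weights$weight > 0), sum(rep_eq$weights$ok))
  if (any(rep_eq$weights$ok)) {
    expect_equal(unique(round(rep_eq$weights$weight[rep_eq$weights$ok], 12)),
                 round(1 / sum(rep_eq$weights$ok), 12))
  }
  # correlation average is a valid correlation matrix when available
  if (!is.null(rep$correlation)) {
    expect_equal(diag(rep$correlation), rep(1, ncol(rep$correlation)),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_true(all(rep$correlation >= -1 - 1e-9 &
                      rep$correlation <= 1 + 1e-9))
  }
  expect_s3_class(tidy(rep), "tbl_df")
})
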