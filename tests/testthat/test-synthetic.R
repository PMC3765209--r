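test_that("default protocol reproduces the study layout", {
  ds <- generate_dataset(generation_protocol(seed = 1))
  expect_identical(length(unique(ds$experiment_id)), 10L)  # 2 strains x 5 K
  expect_identical(sort(unique(ds$K_mM)), c(1, 10, 50, 100, 500))
  expect_identical(sort(unique(ds$strain)), c("mutant", "wild"))
  expect_identical(sort(unique(ds$variable)), c("KdpFABC", "mRNA"))
  # rows = experiments x variables x grid points
  expect_identical(nrow(ds), 10L * 2L * 15L)
  expect_true(all(ds$sigma > 0))
})

test_that("zero noise returns the simulated truth exactly", {
  ds <- generate_dataset(generation_protocol(
    strains = "wild", K_levels = c(10, 100),
    t_grid = seq(0, 1, length.out = 4), noise = 0, seed = 8))
  expect_identical(ds$value, attr(ds, "truth"))
})

test_that("generation is deterministic given the seed", {
  a <- generate_dataset(generation_protocol(seed = 12))
  b <- generate_dataset(generation_protocol(seed = 12))
  c <- generate_dataset(generation_protocol(seed = 13))
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(a$value, c$value))
  # and the generator does not disturb the caller's RNG stream
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generate_dataset(generation_protocol(seed = 12)))
  expect_identical(runif(3), before)
})

test_that("relative noise has the configured moments", {
  # pool relative errors across seeds: mean ~ 0, sd ~ 0.05
  rel <- unlist(purrr::map(1:12, function(i) {
    ds <- generate_dataset(generation_protocol(
      strains = "mutant", K_levels = 500,
      t_grid = seq(0, 1, length.out = 8), seed = 1000 + i))
    ds$value / attr(ds, "truth") - 1
  }))
  n <- length(rel)
  se_mean <- 0.05 / sqrt(n)
  expect_lt(abs(mean(rel)), 4 * se_mean)
  se_sd <- 0.05 / sqrt(2 * (n - 1))
  expect_lt(abs(sd(rel) - 0.05), 4 * se_sd)
})

test_that("mutant data are invariant to the wild-only generator settings", {
  s_alt <- kdp_structure(bin1 = 1, bin2 = 1, bin3 = 1, n1 = 3, n2 = 1,
                         n3 = 2, n4 = 0, n5 = 1)
  a <- mutant_dataset(seed = 4)
  b <- mutant_dataset(seed = 4, structure = s_alt)
  expect_identical(a$value, b$value)
  expect_identical(a$sigma, b$sigma)
})

test_that("the fixture suite writes byte-identical files per seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- make_fixture_suite(seed = 2, dir = d1)
  p2 <- make_fixture_suite(seed = 2, dir = d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  }
  # noise-free fixture evaluated at the generating truth: zero residuals
  clean <- read_dataset(p1[["noisefree"]])
  nomf <- nominal_fixture()
  pred <- predict_dataset(nomf$structure, nomf$parameters, clean)
  expect_lt(max(abs(pred$value - pred$.pred) / (abs(pred$value) + 1e-12)),
            1e-5)
  tiny <- read_dataset(p1[["tiny"]])
  expect_identical(nrow(tiny), 2L * 5L)
  full <- read_dataset(p1[["full"]])
  expect_identical(nrow(full), 300L)
})
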