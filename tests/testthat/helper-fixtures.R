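# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; no data files.

nominal_fixture <- function() nominal_parameters()

# tiny dataset: one wild-strain experiment, five time points
tiny_dataset <- function(seed = 42L, noise = 0.05) {
  generate_dataset(generation_protocol(
    strains = "wild", K_levels = 10,
    t_grid = seq(0, 1, length.out = 5), noise = noise, seed = seed))
}

# mutant-only dataset, used for the strain-invariance properties
mutant_dataset <- function(seed = 42L, structure = NULL, noise = 0.05,
                           K_levels = c(10, 500)) {
  proto <- generation_protocol(strains = "mutant", K_levels = K_levels,
                               t_grid = seq(0, 0.5, length.out = 4),
                               noise = noise, seed = seed)
  if (!is.null(structure)) proto$structure <- as_kdp_structure(structure)
  generate_dataset(proto)
}

# independent brute-force oracle for the promoter algebra: eliminate DNAf
# from the DNA balance and scan/bisect the KdpE-P balance on [0, EP]
bisect_algebraic <- function(EP, p, tol = 1e-14) {
  beta <- (1 + 1 / (p[["alpha"]] * p[["K"]])) / p[["Ka"]]
  gamma <- 1 + 1 / p[["K"]]
  g <- function(E) EP - E - 2 * beta * E^2 * p[["DNA0"]] / (gamma + beta * E^2)
  lo <- 0; hi <- EP
  while (hi - lo > tol * EP) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  E <- (lo + hi) / 2
  list(KdpEfP = E, DNAf = p[["DNA0"]] / (gamma + beta * E^2))
}

# algebraic residuals of the two promoter constraints at a candidate pair
algebraic_residuals <- function(EP, E, DNAf, p) {
  fac <- 1 + 1 / (p[["alpha"]] * p[["K"]])
  r1 <- EP - E - 2 * E^2 * DNAf / p[["Ka"]] * fac
  r2 <- p[["DNA0"]] - DNAf * (1 + 1 / p[["K"]]) - E^2 * DNAf / p[["Ka"]] * fac
  c(r1, r2)
}

# toy mixed-integer objective with a brute-force-verifiable optimum
toy_mi_objective <- function(x) (x[1] - 0.3)^2 + (x[2] - 2)^2
toy_mi_bounds <- function() {
  make_bounds(lower = c(-5, 0), upper = c(5, 5), is_int = c(FALSE, TRUE))
}

# one-dimensional star discrepancy of a point set in [0, 1]
star_discrepancy_1d <- function(x) {
  n <- length(x)
  x <- sort(x)
  max(pmax(abs(seq_len(n) / n - x), abs(x - (seq_len(n) - 1) / n)))
}
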