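#' Generation protocol for the in-silico dataset
#'
#' Encodes the conditions of the in-silico study: both strains, five
#' extracellular K+ levels (1, 10, 50, 100, 500 mM), only mRNA and
#' KdpFABC observed, multiplicative Gaussian (heteroscedastic) noise with
#' relative level 5%, trajectories simulated from the nominal structure and
#' parameters. The observation grid defaults to 15 equispaced points on
#' [0, 1] hours.
#'
#' @param structure Generating structure (default: nominal).
#' @param parameters Generating parameters (default: nominal).
#' @param constants A [kdp_constants()].
#' @param strains Character vector of strains.
#' @param K_levels K+ levels, mM.
#' @param observed Observed variables.
#' @param noise Relative noise level (standard deviation of the
#'   multiplicative error), default 0.05.
#' @param t_grid Observation times, hours.
#' @param seed Integer seed (mandatory for reproducibility).
#' @return A list of class `"generation_protocol"`.
#' @export
generation_protocol <- function(structure = nominal_parameters()$structure,
                                parameters = nominal_parameters()$parameters,
                                constants = kdp_constants(),
                                strains = c("wild", "mutant"),
                                K_levels = c(1, 10, 50, 100, 500),
                                observed = c("mRNA", "KdpFABC"),
                                noise = 0.05,
                                t_grid = seq(0, 1, length.out = 15),
                                seed = 1L) {
  stopifnot(noise >= 0, length(strains) >= 1, length(K_levels) >= 1,
            length(observed) >= 1)
  structure(list(structure = as_kdp_structure(structure),
                 parameters = as_kdp_parameters(parameters),
                 constants = constants, strains = strains,
                 K_levels = K_levels, observed = observed, noise = noise,
                 t_grid = t_grid, seed = as.integer(seed)),
            class = "generation_protocol")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate an in-silico dataset
#'
#' Simulates every strain-by-K+ experiment of the protocol from its
#' pre-stimulus steady state, samples the observation grid, and perturbs
#' each observed value with multiplicative Gaussian noise:
#' `y_obs = y (1 + noise * eps)`, `eps ~ N(0, 1)`. The recorded standard
#' deviation is `sigma = noise * |y|`, floored per variable at
#' `1e-12 + noise * median(|y|) * 1e-6` so the likelihood never sees a
#' zero variance where a trajectory crosses zero. Deterministic given the
#' protocol seed.
#'
#' @param protocol A [generation_protocol()].
#' @return A [kdp_dataset()] with the generating truth in column `.truth`
#'   preserved as attribute `truth` (noise-free values).
#' @export
generate_dataset <- function(protocol = generation_protocol()) {
  s <- protocol$structure; p <- protocol$parameters
  cst <- protocol$constants
  inits <- purrr::map(
    stats::setNames(protocol$strains, protocol$strains),
    function(st) initial_state(s, p, cst, strain = st)
  )
  grid <- tidyr::expand_grid(strain = protocol$strains,
                             K_mM = protocol$K_levels)
  rows <- purrr::pmap(grid, function(strain, K_mM) {
    des <- kdp_design(strain = strain, Kplus = K_mM,
                      t_grid = protocol$t_grid,
                      observed = protocol$observed)
    tr <- simulate_kdp(s, p, des, cst, init = inits[[strain]])
    if (!trajectory_ok(tr)) {
      stop(sprintf("simulation failed for strain=%s K=%g mM", strain, K_mM),
           call. = FALSE)
    }
    tr |>
      dplyr::select(dplyr::all_of(c("time", protocol$observed))) |>
      tidyr::pivot_longer(-"time", names_to = "variable",
                          values_to = "truth") |>
      dplyr::mutate(strain = strain, K_mM = K_mM,
                    experiment_id = sprintf("%s_K%g", strain, K_mM))
  })
  df <- dplyr::bind_rows(rows) |>
    dplyr::rename(time_h = "time") |>
    dplyr::arrange(.data$experiment_id, .data$variable, .data$time_h)
  df <- with_seed(protocol$seed, {
    eps <- stats::rnorm(nrow(df))
    dplyr::mutate(df, value = .data$truth * (1 + protocol$noise * eps))
  })
  df <- df |>
    dplyr::group_by(.data$variable) |>
    dplyr::mutate(
      sigma = pmax(protocol$noise * abs(.data$truth),
                   1e-12 + protocol$noise * stats::median(abs(.data$truth)) *
                     1e-6)
    ) |>
    dplyr::ungroup()
  truth <- df$truth
  out <- kdp_dataset(df[c("experiment_id", "strain", "K_mM", "variable",
                          "time_h", "value", "sigma")])
  attr(out, "truth") <- truth
  attr(out, "protocol") <- protocol
  out
}

#' Write the deterministic fixture suite
#'
#' Produces the small datasets used by the test suite: a tiny single
#' experiment with five time points, the full two-strain five-level set,
#' and a noise-free copy of the full set. Files are byte-identical for a
#' given seed.
#'
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return Named character vector of the written file paths, invisibly.
#' @export
make_fixture_suite <- function(seed = 1L, dir = tempdir()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tiny <- generate_dataset(generation_protocol(
    strains = "wild", K_levels = 10, t_grid = seq(0, 1, length.out = 5),
    seed = seed))
  full <- generate_dataset(generation_protocol(seed = seed))
  clean <- generate_dataset(generation_protocol(noise = 0, seed = seed))
  paths <- c(tiny = file.path(dir, "dataset_tiny.csv"),
             full = file.path(dir, "dataset_full.csv"),
             noisefree = file.path(dir, "dataset_noisefree.csv"))
  write_dataset(tiny, paths[["tiny"]])
  write_dataset(full, paths[["full"]])
  write_dataset(clean, paths[["noisefree"]])
  invisible(paths)
}
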