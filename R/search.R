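#' Decision-variable bounds
#'
#' Builds the box constraints of the mixed-integer problem. Real
#' parameters are searched in log10 space (they span nine orders of
#' magnitude); the default box is the nominal value divided and multiplied
#' by `factor` (100). Integer bounds are 0..1 for the binaries and
#' 0..`n_max` for the exponents.
#'
#' @param nominal Named vector of nominal real parameters
#'   (default: [nominal_parameters()]).
#' @param factor Multiplicative half-width of the real box.
#' @param n_max Upper bound of the integer exponents.
#' @return A list of class `"decision_bounds"` with `lower`, `upper`,
#'   `names`, `is_int`.
#' @export
decision_bounds <- function(nominal = nominal_parameters()$parameters,
                            factor = 100, n_max = 3) {
  p <- as_kdp_parameters(nominal)
  lp <- log10(unclass(p)[parameter_names()])
  lower <- c(lp - log10(factor),
             stats::setNames(rep(0, 8), structure_names()))
  upper <- c(lp + log10(factor),
             stats::setNames(c(1, 1, 1, rep(n_max, 5)), structure_names()))
  structure(list(lower = lower, upper = upper,
                 names = names(lower),
                 is_int = c(rep(FALSE, 17), rep(TRUE, 8))),
            class = "decision_bounds")
}

#' Generic box bounds for a mixed-integer problem
#'
#' @param lower,upper Numeric bound vectors (equal length).
#' @param is_int Logical vector flagging integer coordinates.
#' @return A `"decision_bounds"` object.
#' @export
make_bounds <- function(lower, upper, is_int) {
  stopifnot(length(lower) == length(upper), length(is_int) == length(lower),
            all(lower <= upper))
  nm <- names(lower)
  if (is.null(nm)) nm <- paste0("x", seq_along(lower))
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 names = nm, is_int = as.logical(is_int)),
            class = "decision_bounds")
}

#' Decode a decision vector of the case study
#'
#' Maps a 25-entry decision vector (17 log10 reals followed by the 8
#' structure integers) back to natural-scale parameters and a structure.
#'
#' @param x Numeric decision vector.
#' @param bounds A [decision_bounds()] for the case study.
#' @return List with `parameters` and `structure`.
#' @export
decode_decision <- function(x, bounds) {
  stopifnot(length(x) == 25)
  p <- 10^x[1:17]
  names(p) <- parameter_names()
  q <- as.integer(round(x[18:25]))
  names(q) <- structure_names()
  list(parameters = do.call(kdp_parameters, as.list(p)),
       structure = do.call(kdp_structure, as.list(q)))
}

#' Encode parameters and structure as a decision vector
#'
#' @param p A [kdp_parameters()].
#' @param s A [kdp_structure()].
#' @return Numeric vector of length 25.
#' @export
encode_decision <- function(p, s) {
  c(log10(unclass(as_kdp_parameters(p))[parameter_names()]),
    as.numeric(unclass(as_kdp_structure(s))[structure_names()]))
}

#' Search settings for the scatter-search metaheuristic
#'
#' @param max_eval Evaluation budget.
#' @param n_diverse Size of the initial space-filling sample
#'   (default 10 x dimension, set when the search starts).
#' @param refset_size Reference-set size (half quality, half diversity).
#' @param local_freq Run a local refinement every `local_freq` combination
#'   sweeps (0 disables local search).
#' @param local_budget Evaluation budget of each local refinement.
#' @param repair_budget Evaluations for the real-coordinate repair of each
#'   trial integer move inside local refinements (see [local_refine()]).
#' @param stagnation_window Stop after this many sweeps without an
#'   improvement larger than `stagnation_tol` (0 disables).
#' @param stagnation_tol Improvement threshold for stagnation.
#' @param seed Mandatory integer seed.
#' @return A list of class `"scatter_settings"`.
#' @export
scatter_settings <- function(max_eval = 2000, n_diverse = NULL,
                             refset_size = 10, local_freq = 5,
                             local_budget = 250, repair_budget = 0,
                             stagnation_window = 0,
                             stagnation_tol = 1e-8, seed = 1L) {
  stopifnot(max_eval >= 1, refset_size >= 4, is.numeric(seed))
  structure(list(max_eval = max_eval, n_diverse = n_diverse,
                 refset_size = refset_size, local_freq = local_freq,
                 local_budget = local_budget, repair_budget = repair_budget,
                 stagnation_window = stagnation_window,
                 stagnation_tol = stagnation_tol, seed = as.integer(seed)),
            class = "scatter_settings")
}

# round-half-away-from-zero, applied to integer coordinates after every
# combination/perturbation so trial points are always feasible
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

snap_to_bounds <- function(x, bounds) {
  x <- pmin(pmax(x, bounds$lower), bounds$upper)
  x[bounds$is_int] <- round_half_away(x[bounds$is_int])
  # rounding can only move within the integer bounds since they are integers
  x
}

# stratified (latin hypercube) sample of n points in the box; binary
# coordinates are additionally cycled through their full factorial so
# every switch combination is represented early in the diversification
diverse_sample <- function(n, bounds) {
  d <- length(bounds$lower)
  u <- vapply(seq_len(d), function(j) {
    (sample.int(n) - stats::runif(n)) / n
  }, numeric(n))
  if (n == 1) u <- matrix(u, nrow = 1)
  x <- sweep(sweep(u, 2, bounds$upper - bounds$lower, "*"), 2,
             bounds$lower, "+")
  x <- t(apply(x, 1, snap_to_bounds, bounds = bounds))
  bin <- which(bounds$is_int & (bounds$upper - bounds$lower == 1))
  if (length(bin) > 0 && length(bin) <= 10 && n >= 2^length(bin)) {
    combos <- as.matrix(expand.grid(rep(list(0:1), length(bin))))
    x[, bin] <- bounds$lower[bin] +
      combos[(seq_len(n) - 1) %% nrow(combos) + 1, , drop = FALSE]
  }
  x
}

#' Mixed-integer scatter search
#'
#' Global search over a box-bounded mixed-integer space, built on the
#' scatter-search template: a space-filling diversification sample, a small
#' reference set maintained half by quality and half by max-min diversity,
#' pairwise combination of reference solutions by path relinking
#' (directed line segments including extrapolation beyond both endpoints),
#' a rounding operator that keeps integer coordinates integral after every
#' move, and periodic local refinement of the incumbent. Deterministic for
#' a fixed seed; never exceeds the evaluation budget; always returns the
#' best point found.
#'
#' @param objective Function mapping a decision vector to a finite scalar
#'   (penalty-encode failures).
#' @param bounds A [decision_bounds()] or [make_bounds()] object.
#' @param settings A [scatter_settings()].
#' @return A list of class `"minlp_fit"`: `best_x`, `best_value`, `trace`
#'   (tibble `eval`, `value`, `best`), `n_eval`, `seed`, `settings`.
#' @export
scatter_search <- function(objective, bounds, settings = scatter_settings()) {
  set.seed(settings$seed)
  d <- length(bounds$lower)
  n_div <- settings$n_diverse %||% (10 * d)
  budget <- settings$max_eval

  env <- new.env()
  env$n <- 0L
  env$values <- numeric(0)
  env$best <- Inf
  env$best_x <- NULL
  fn <- function(x) {
    if (env$n >= budget) return(NA_real_)
    v <- objective(x)
    if (!is.finite(v)) v <- 1e12
    env$n <- env$n + 1L
    env$values[env$n] <- v
    if (v < env$best) {
      env$best <- v
      env$best_x <- x
    }
    v
  }

  # diversification
  P <- diverse_sample(min(n_div, budget), bounds)
  vals <- apply(P, 1, fn)
  keep <- !is.na(vals)
  P <- P[keep, , drop = FALSE]; vals <- vals[keep]

  b <- min(settings$refset_size, nrow(P))
  b_q <- ceiling(b / 2)
  scale <- pmax(bounds$upper - bounds$lower, 1e-12)
  ord <- order(vals)
  ref_idx <- ord[seq_len(min(b_q, length(ord)))]
  # diversity half: greedy max-min distance in the scaled box
  cand <- setdiff(seq_len(nrow(P)), ref_idx)
  while (length(ref_idx) < b && length(cand) > 0) {
    dmin <- vapply(cand, function(i) {
      min(vapply(ref_idx, function(j) {
        sqrt(sum(((P[i, ] - P[j, ]) / scale)^2))
      }, numeric(1)))
    }, numeric(1))
    pick <- cand[which.max(dmin)]
    ref_idx <- c(ref_idx, pick)
    cand <- setdiff(cand, pick)
  }
  R <- P[ref_idx, , drop = FALSE]
  Rv <- vals[ref_idx]

  sweep_i <- 0L
  last_best <- env$best
  stagnant <- 0L
  while (env$n < budget) {
    sweep_i <- sweep_i + 1L
    nb <- nrow(R)
    improved <- FALSE
    for (i in seq_len(nb - 1)) {
      for (j in (i + 1):nb) {
        if (env$n >= budget) break
        delta <- (R[j, ] - R[i, ]) / 2
        trials <- list(
          R[i, ] - stats::runif(1) * delta,
          R[i, ] + stats::runif(1) * 2 * delta,
          R[j, ] + stats::runif(1) * delta
        )
        for (x in trials) {
          if (env$n >= budget) break
          x <- snap_to_bounds(x, bounds)
          v <- fn(x)
          if (is.na(v)) break
          worst <- which.max(Rv)
          if (v < Rv[worst] &&
              !any(apply(R, 1, function(r) all(abs(r - x) < 1e-12)))) {
            R[worst, ] <- x
            Rv[worst] <- v
            improved <- TRUE
          }
        }
      }
      if (env$n >= budget) break
    }
    # periodic local refinement of the incumbent
    if (settings$local_freq > 0 && sweep_i %% settings$local_freq == 0 &&
        env$n < budget) {
      res <- local_refine(env$best_x, fn, bounds,
                          budget = min(settings$local_budget,
                                       budget - env$n),
                          repair_budget = settings$repair_budget %||% 0)
      worst <- which.max(Rv)
      if (res$value < Rv[worst]) {
        R[worst, ] <- res$x
        Rv[worst] <- res$value
      }
    }
    # diversification restart of the diverse half when a sweep stalls
    if (!improved && env$n < budget) {
      n_new <- max(1L, floor(nrow(R) / 2))
      keep_q <- order(Rv)[seq_len(nrow(R) - n_new)]
      fresh <- diverse_sample(n_new, bounds)
      fv <- apply(fresh, 1, fn)
      ok <- !is.na(fv)
      R <- rbind(R[keep_q, , drop = FALSE], fresh[ok, , drop = FALSE])
      Rv <- c(Rv[keep_q], fv[ok])
    }
    if (settings$stagnation_window > 0) {
      if (last_best - env$best > settings$stagnation_tol) {
        stagnant <- 0L
        last_best <- env$best
      } else {
        stagnant <- stagnant + 1L
        if (stagnant >= settings$stagnation_window) break
      }
    }
  }

  vals_all <- env$values[seq_len(env$n)]
  trace <- tibble::tibble(eval = seq_len(env$n), value = vals_all,
                          best = cummin(vals_all))
  structure(list(best_x = env$best_x, best_value = env$best, trace = trace,
                 n_eval = env$n, seed = settings$seed, settings = settings,
                 bounds = bounds),
            class = "minlp_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Local mixed-integer refinement
#'
#' Descent from a starting point: Nelder-Mead on the real coordinates
#' (run in box-normalized coordinates) with the integer coordinates held
#' fixed, followed by greedy unit-neighborhood integer moves (ties broken
#' by lower coordinate index), iterated until no move improves. The
#' returned point is never worse than the start.
#'
#' With `repair_budget > 0` each trial integer move is "repaired" by a
#' short real-coordinate descent before it is accepted or rejected. A bare
#' integer move is almost always rejected on a mixed-integer landscape
#' because the reals are tuned to the old integer values; the repair step
#' lets the refinement hop between neighboring integer assignments.
#'
#' @param x Start decision vector (within bounds).
#' @param objective Objective function (finite scalar).
#' @param bounds Bounds object.
#' @param budget Maximum number of objective evaluations.
#' @param repair_budget Evaluations allowed for the real-coordinate repair
#'   of each trial integer move (0 = plain greedy moves).
#' @return List with `x` and `value`.
#' @export
local_refine <- function(x, objective, bounds, budget = 300,
                         repair_budget = 0) {
  env <- new.env(); env$n <- 0L
  fn <- function(z) {
    if (env$n >= budget) return(1e15)
    env$n <- env$n + 1L
    v <- objective(z)
    if (is.na(v) || !is.finite(v)) 1e12 else v
  }
  x <- snap_to_bounds(x, bounds)
  v0 <- fn(x)
  if (is.na(v0)) return(list(x = x, value = Inf))
  best_x <- x; best_v <- v0
  ri <- which(!bounds$is_int)
  ii <- which(bounds$is_int)

  repeat {
    improved <- FALSE
    if (length(ri) > 0 && env$n < budget) {
      # optimize in box-normalized coordinates so the simplex steps are
      # commensurate across parameters spanning many orders of magnitude
      lo <- bounds$lower[ri]; span <- pmax(bounds$upper[ri] - lo, 1e-12)
      wrap <- function(u) {
        z <- best_x
        z[ri] <- lo + pmin(pmax(u, 0), 1) * span
        fn(z)
      }
      maxit <- max(10, budget - env$n)
      opt <- suppressWarnings(stats::optim((best_x[ri] - lo) / span, wrap,
                                           method = "Nelder-Mead",
                                           control = list(maxit = maxit)))
      if (opt$value < best_v - 1e-12) {
        best_x[ri] <- lo + pmin(pmax(opt$par, 0), 1) * span
        best_v <- opt$value
        improved <- TRUE
      }
    }
    nm_reals <- function(x0, v0, nm_budget) {
      if (length(ri) == 0 || nm_budget < 10) return(list(x = x0, value = v0))
      lo <- bounds$lower[ri]; span <- pmax(bounds$upper[ri] - lo, 1e-12)
      wrap <- function(u) {
        z <- x0
        z[ri] <- lo + pmin(pmax(u, 0), 1) * span
        fn(z)
      }
      opt <- suppressWarnings(
        stats::optim((x0[ri] - lo) / span, wrap, method = "Nelder-Mead",
                     control = list(maxit = nm_budget)))
      if (opt$value < v0) {
        x0[ri] <- lo + pmin(pmax(opt$par, 0), 1) * span
        v0 <- opt$value
      }
      list(x = x0, value = v0)
    }
    moved <- TRUE
    while (moved && length(ii) > 0 && env$n < budget) {
      moved <- FALSE
      for (k in ii) {
        for (step in c(-1, 1)) {
          z <- best_x
          z[k] <- z[k] + step
          if (z[k] < bounds$lower[k] || z[k] > bounds$upper[k]) next
          v <- fn(z)
          if (repair_budget > 0 && env$n < budget) {
            rep <- nm_reals(z, v, min(repair_budget, budget - env$n))
            z <- rep$x; v <- rep$value
          }
          if (v < best_v - 1e-12) {
            best_x <- z; best_v <- v
            moved <- TRUE; improved <- TRUE
            break
          }
        }
        if (moved) break
      }
    }
    if (!improved || env$n >= budget) break
  }
  list(x = best_x, value = best_v)
}

#' Multistart local baseline
#'
#' The traditional multimodality check: `n_starts` independent local
#' refinements from uniform random feasible starting points. Returns every
#' final objective value so the distribution can be histogrammed against
#' the global search result.
#'
#' @param objective Objective function.
#' @param n_starts Number of local runs (>= 1).
#' @param bounds Bounds object.
#' @param seed Integer seed.
#' @param budget Evaluation budget per local run.
#' @return A tibble of class `"multistart_result"` with columns `start`
#'   and `value`.
#' @export
multistart <- function(objective, n_starts, bounds, seed = 1L,
                       budget = 300) {
  stopifnot(n_starts >= 1)
  set.seed(seed)
  d <- length(bounds$lower)
  starts <- matrix(stats::runif(n_starts * d, rep(bounds$lower, each = n_starts),
                                rep(bounds$upper, each = n_starts)),
                   nrow = n_starts)
  starts <- t(apply(starts, 1, snap_to_bounds, bounds = bounds))
  vals <- purrr::map_dbl(seq_len(n_starts), function(i) {
    local_refine(starts[i, ], objective, bounds, budget = budget)$value
  })
  out <- tibble::tibble(start = seq_len(n_starts), value = vals)
  class(out) <- c("multistart_result", class(out))
  out
}
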