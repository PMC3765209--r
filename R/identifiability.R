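#' Relative (normalized) parameter sensitivities
#'
#' Central finite-difference sensitivities of every prediction with respect
#' to each active real parameter, normalized by parameter and state:
#' `S = (p/y) dy/dp`, computed as the symmetric difference quotient on the
#' log-parameter (`p` multiplied by `exp(+-h)`). Predictions with
#' magnitude below `y_floor` cannot be normalized and yield 0 (counted in
#' attribute `n_floored`). If a perturbed simulation fails the step is
#' halved once before erroring.
#'
#' @param s A [kdp_structure()].
#' @param p A [kdp_parameters()].
#' @param dataset A [kdp_dataset()].
#' @param constants A [kdp_constants()].
#' @param parameters Character vector of parameters to perturb
#'   (default: the active reals of `s`).
#' @param step Relative log-step `h` (default 1e-4).
#' @param y_floor Absolute floor below which predictions count as zero.
#' @param rtol,atol Integrator tolerances.
#' @return A matrix of class `"sensitivity_matrix"`, rows = measurements
#'   (labels `experiment/variable/time`), columns = parameters. Attributes:
#'   `y0` (baseline predictions), `p0` (parameter values), `sigma`,
#'   `derivatives` (unnormalized `dy/dp`), `n_floored`.
#' @export
relative_sensitivities <- function(s, p, dataset,
                                   constants = kdp_constants(),
                                   parameters = NULL, step = 1e-4,
                                   y_floor = 1e-12,
                                   rtol = 1e-10, atol = 1e-14) {
  s <- as_kdp_structure(s); p <- as_kdp_parameters(p)
  if (is.null(parameters)) parameters <- active_parameters(s)$reals
  stopifnot(all(parameters %in% parameter_names()))
  base <- predict_dataset(s, p, dataset, constants, rtol = rtol, atol = atol)
  if (!isTRUE(attr(base, "ok"))) {
    stop("baseline simulation failed; sensitivities undefined", call. = FALSE)
  }
  y0 <- base$.pred
  predict_at <- function(pv) {
    out <- predict_dataset(s, pv, dataset, constants, rtol = rtol,
                           atol = atol)
    if (!isTRUE(attr(out, "ok"))) return(NULL)
    out$.pred
  }
  n_floored <- 0L
  cols <- purrr::map(parameters, function(nm) {
    h <- step
    for (attempt in 1:2) {
      p_hi <- p; p_hi[[nm]] <- p[[nm]] * exp(h)
      p_lo <- p; p_lo[[nm]] <- p[[nm]] * exp(-h)
      y_hi <- predict_at(p_hi)
      y_lo <- predict_at(p_lo)
      if (!is.null(y_hi) && !is.null(y_lo)) {
        dy_dlnp <- (y_hi - y_lo) / (2 * h)
        S <- ifelse(abs(y0) < y_floor, 0, dy_dlnp / y0)
        n_floored <<- n_floored + sum(abs(y0) < y_floor & dy_dlnp != 0)
        return(list(S = S, D = dy_dlnp / p[[nm]]))
      }
      h <- h / 2
    }
    stop(sprintf("perturbed simulation failed for parameter %s", nm),
         call. = FALSE)
  })
  S <- do.call(cbind, purrr::map(cols, "S"))
  D <- do.call(cbind, purrr::map(cols, "D"))
  colnames(S) <- colnames(D) <- parameters
  rownames(S) <- rownames(D) <-
    paste(dataset$experiment_id, dataset$variable, dataset$time_h, sep = "/")
  attr(S, "y0") <- y0
  attr(S, "p0") <- stats::setNames(as.numeric(unclass(p)[parameters]),
                                   parameters)
  attr(S, "sigma") <- dataset$sigma
  attr(S, "derivatives") <- D
  attr(S, "n_floored") <- n_floored
  class(S) <- c("sensitivity_matrix", class(S))
  S
}

#' Sensitivity ranking index (sum of squared relative sensitivities)
#'
#' Aggregates the relative sensitivity of one parameter over all
#' experiments, variables and time points as the plain sum of squares
#' (the printed convention); `rms = TRUE` uses the root-mean-square
#' variant instead. Ranking is by descending index.
#'
#' @param S A [relative_sensitivities()] matrix (or any numeric matrix with
#'   parameters in columns).
#' @param rms Use the root-mean-square variant.
#' @return Named numeric vector of indices, one per parameter.
#' @export
msqr_index <- function(S, rms = FALSE) {
  stopifnot(all(is.finite(S)))
  idx <- colSums(unclass(S)^2)
  if (rms) idx <- sqrt(idx / nrow(S))
  idx
}

#' Ranking table from sensitivity indices
#'
#' @param S A sensitivity matrix.
#' @param rms Passed to [msqr_index()].
#' @return Tibble with `parameter`, `msqr`, `rank` (1 = most influential).
#' @export
msqr_ranking <- function(S, rms = FALSE) {
  idx <- msqr_index(S, rms = rms)
  tibble::tibble(parameter = names(idx), msqr = as.numeric(idx)) |>
    dplyr::arrange(dplyr::desc(.data$msqr)) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' Fisher information matrix
#'
#' `FIM = sum_i (1/sigma_i^2) (dy_i/dp)^T (dy_i/dp)` over all
#' measurements. Accepts either a [relative_sensitivities()] object (whose
#' unnormalized derivatives and sigmas are carried as attributes) or a
#' plain derivative matrix plus `sigma`.
#'
#' With `scale = "log"` (the default for sensitivity objects) the
#' derivatives are taken with respect to the log-parameters,
#' `dy/dln p = p dy/dp`. The kinetic parameters span nine orders of
#' magnitude, so the natural-scale FIM is numerically rank deficient by
#' construction; the log-scale FIM is the scale-free object on which rank
#' and correlation statements are meaningful, and its inverse diagonal is
#' the squared relative (fractional) parameter uncertainty.
#'
#' @param S A `"sensitivity_matrix"`, or a numeric matrix of derivatives
#'   `dy/dp` (rows = measurements).
#' @param sigma Per-measurement standard deviations (ignored when `S`
#'   carries them).
#' @param scale `"log"` or `"natural"` parameter scale (plain matrices are
#'   used as given).
#' @return A symmetric positive semi-definite matrix of class
#'   `"fim_matrix"`.
#' @export
fisher_information <- function(S, sigma = NULL,
                               scale = c("log", "natural")) {
  scale <- match.arg(scale)
  if (inherits(S, "sensitivity_matrix")) {
    D <- attr(S, "derivatives")
    sigma <- attr(S, "sigma")
    if (scale == "log") D <- sweep(D, 2, attr(S, "p0"), "*")
  } else {
    D <- unclass(S)
    if (is.null(sigma)) stop("sigma required for a plain derivative matrix",
                             call. = FALSE)
  }
  stopifnot(length(sigma) == nrow(D), all(sigma > 0))
  W <- D / sigma
  fim <- crossprod(W)
  fim <- (fim + t(fim)) / 2
  class(fim) <- c("fim_matrix", class(fim))
  fim
}

#' Numerical rank of a Fisher information matrix
#'
#' Singular values below `rtol` times the largest are counted as zero; the
#' tolerance used is reported with the result.
#'
#' @param fim A matrix.
#' @param rtol Relative singular-value tolerance.
#' @return List with `rank`, `full_rank`, `singular_values`, `tolerance`.
#' @export
fim_rank <- function(fim, rtol = 1e-10) {
  sv <- svd(unclass(fim), nu = 0, nv = 0)$d
  tol <- rtol * max(sv)
  list(rank = sum(sv > tol), full_rank = sum(sv > tol) == ncol(fim),
       singular_values = sv, tolerance = tol)
}

#' Parameter correlation matrix from the Fisher information
#'
#' Inverts the FIM (the asymptotic parameter covariance) and rescales it to
#' unit diagonal. Requires local identifiability: a rank-deficient FIM
#' cannot be inverted and signals a non-identifiability error.
#'
#' @param fim A [fisher_information()] matrix.
#' @param rtol Rank tolerance.
#' @return Correlation matrix (unit diagonal, entries in `[-1, 1]`).
#' @export
correlation_from_fim <- function(fim, rtol = 1e-10) {
  r <- fim_rank(fim, rtol)
  if (!r$full_rank) {
    stop(sprintf(paste0("FIM is rank deficient (rank %d of %d at tolerance ",
                        "%.2e): parameters are not identifiable, ",
                        "correlation analysis requires an invertible FIM"),
                 r$rank, ncol(fim), r$tolerance), call. = FALSE)
  }
  V <- solve(unclass(fim))
  C <- stats::cov2cor(V)
  pmin(pmax(C, -1), 1)
}

#' Likelihood-weighted pseudo-global identifiability analysis
#'
#' Removes the dependence of local sensitivity/correlation analysis on a
#' single nominal point: parameter sets are sampled from the (log10-scaled)
#' search box with a scrambled Sobol' sequence; at each set the relative
#' sensitivities, ranking indices and FIM-based correlation matrix are
#' computed, and the results are averaged with weights proportional to the
#' likelihood of each set given the data (computed with a max-log shift
#' before exponentiation), so parameter sets unlikely to fit the data
#' contribute negligibly. Sampling points whose simulation fails receive
#' zero weight; points with a rank-deficient FIM are excluded from the
#' correlation average (their count is reported).
#'
#' @param s A [kdp_structure()].
#' @param dataset A [kdp_dataset()].
#' @param bounds A [decision_bounds()] (only the real box is used).
#' @param constants A [kdp_constants()].
#' @param n_points Number of Sobol' points (the full protocol uses 2^10;
#'   smaller values keep exploratory runs cheap).
#' @param seed Mandatory integer seed (Sobol' scrambling).
#' @param equal_weights Force equal likelihood weights (reduces the result
#'   to the unweighted mean over feasible points).
#' @param step Finite-difference step for the sensitivities.
#' @param rtol,atol Integrator tolerances.
#' @return A list of class `"correlation_report"`: `correlation` (weighted
#'   average matrix), `msqr` (weighted indices), `ranking` (tibble),
#'   `weights` (tibble per point: `point`, `Jml`, `weight`, `ok`,
#'   `fim_ok`), `n_failed`, `n_rank_deficient`, `n_points`, `seed`.
#' @export
pseudo_global_analysis <- function(s, dataset, bounds = decision_bounds(),
                                   constants = kdp_constants(),
                                   n_points = 2^10, seed = 1L,
                                   equal_weights = FALSE, step = 1e-4,
                                   rtol = 1e-8, atol = 1e-12) {
  s <- as_kdp_structure(s)
  act <- active_parameters(s)$reals
  idx <- match(act, bounds$names)
  lo <- bounds$lower[idx]; hi <- bounds$upper[idx]
  u <- sobol_sequence(n_points, length(act), seed = seed)
  pts <- scale_to_bounds(u, lo, hi)
  nominal <- nominal_parameters()$parameters

  per_point <- silence_solver(purrr::map(seq_len(n_points), function(i) {
    pv <- unclass(nominal)
    pv[act] <- 10^pts[i, ]
    p_i <- do.call(kdp_parameters, as.list(pv))
    pred <- predict_dataset(s, p_i, dataset, constants, rtol = rtol,
                            atol = atol)
    if (!isTRUE(attr(pred, "ok"))) {
      return(list(ok = FALSE, Jml = -Inf, msqr = NULL, corr = NULL,
                  fim_ok = FALSE))
    }
    Jml <- log_likelihood(pred, pred$.pred)
    Smat <- tryCatch(
      relative_sensitivities(s, p_i, dataset, constants, parameters = act,
                             step = step, rtol = rtol, atol = atol),
      error = function(e) NULL
    )
    if (is.null(Smat)) {
      return(list(ok = FALSE, Jml = Jml, msqr = NULL, corr = NULL,
                  fim_ok = FALSE))
    }
    fim <- fisher_information(Smat)
    corr <- tryCatch(correlation_from_fim(fim), error = function(e) NULL)
    list(ok = TRUE, Jml = Jml, msqr = msqr_index(Smat), corr = corr,
         fim_ok = !is.null(corr))
  }))

  ok <- purrr::map_lgl(per_point, "ok")
  Jml <- purrr::map_dbl(per_point, "Jml")
  w <- rep(0, n_points)
  if (any(ok)) {
    if (equal_weights) {
      w[ok] <- 1 / sum(ok)
    } else {
      lw <- Jml[ok] - max(Jml[ok])  # max-log shift against overflow
      w[ok] <- exp(lw) / sum(exp(lw))
    }
  }
  msqr_w <- NULL
  if (any(ok)) {
    M <- do.call(rbind, purrr::map(per_point[ok], "msqr"))
    msqr_w <- colSums(M * w[ok])
  }
  corr_ok <- ok & purrr::map_lgl(per_point, "fim_ok")
  corr_w <- NULL
  if (any(corr_ok)) {
    wc <- w[corr_ok]
    if (sum(wc) <= 0) wc <- rep(1 / sum(corr_ok), sum(corr_ok))
    else wc <- wc / sum(wc)
    arr <- purrr::map(per_point[corr_ok], "corr")
    corr_w <- Reduce(`+`, purrr::map2(arr, wc, `*`))
  }
  ranking <- if (!is.null(msqr_w)) {
    tibble::tibble(parameter = names(msqr_w), msqr = as.numeric(msqr_w)) |>
      dplyr::arrange(dplyr::desc(.data$msqr)) |>
      dplyr::mutate(rank = dplyr::row_number())
  } else NULL
  structure(list(
    correlation = corr_w, msqr = msqr_w, ranking = ranking,
    weights = tibble::tibble(point = seq_len(n_points), Jml = Jml,
                             weight = w, ok = ok, fim_ok = corr_ok),
    n_failed = sum(!ok), n_rank_deficient = sum(ok & !corr_ok),
    n_points = n_points, seed = seed
  ), class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> %d Sobol' points (%d failed, %d rank deficient)\n",
              x$n_points, x$n_failed, x$n_rank_deficient))
  if (!is.null(x$ranking)) {
    cat("top of sensitivity ranking:\n")
    print(utils::head(x$ranking, 5))
  }
  invisible(x)
}

#' Tidy a pseudo-global analysis report
#'
#' @param x A `"correlation_report"`.
#' @param ... Unused.
#' @return The ranking tibble.
#' @export
tidy.correlation_report <- function(x, ...) x$ranking
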