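#' Build a dataset tibble
#'
#' Validates and normalizes a measurement table into the canonical dataset
#' layout: one row per measurement with columns `experiment_id`, `strain`,
#' `K_mM`, `variable`, `time_h`, `value` and `sigma`. Every standard
#' deviation must be strictly positive.
#'
#' @param df A data frame with the columns above.
#' @return A tibble of class `"kdp_dataset"`.
#' @export
kdp_dataset <- function(df) {
  need <- c("experiment_id", "strain", "K_mM", "variable", "time_h",
            "value", "sigma")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("dataset is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::as_tibble(df)[need]
  if (any(!is.finite(df$sigma)) || any(df$sigma <= 0)) {
    stop("all measurement standard deviations must be > 0", call. = FALSE)
  }
  if (!all(df$strain %in% c("wild", "mutant"))) {
    stop("strain must be 'wild' or 'mutant'", call. = FALSE)
  }
  if (!all(df$variable %in% c("mRNA", "KdpFABC"))) {
    stop("variable must be 'mRNA' or 'KdpFABC'", call. = FALSE)
  }
  class(df) <- c("kdp_dataset", class(df))
  df
}

#' Experiment designs contained in a dataset
#'
#' @param dataset A [kdp_dataset()].
#' @return Named list of [kdp_design()] objects, one per `experiment_id`.
#' @export
dataset_designs <- function(dataset) {
  split(dataset, dataset$experiment_id) |>
    purrr::map(function(d) {
      kdp_design(strain = d$strain[1], Kplus = d$K_mM[1],
                 t_grid = sort(unique(d$time_h)),
                 observed = unique(d$variable))
    })
}

#' Log-likelihood of predictions against a dataset
#'
#' Gaussian log-likelihood with known, per-measurement standard deviations:
#' `sum(log(1/sqrt(2 pi sigma^2))) - 0.5 * sum(((y_obs - y_pred)/sigma)^2)`,
#' additive over experiments, variables and time points.
#'
#' @param dataset A [kdp_dataset()].
#' @param predictions Numeric vector aligned row-by-row with `dataset`.
#' @return The log-likelihood value.
#' @export
log_likelihood <- function(dataset, predictions) {
  if (length(predictions) != nrow(dataset)) {
    stop("predictions must align one-to-one with dataset rows", call. = FALSE)
  }
  sum(log(1 / sqrt(2 * pi * dataset$sigma^2))) -
    0.5 * sum(((dataset$value - predictions) / dataset$sigma)^2)
}

#' Akaike information criterion
#'
#' `AIC = -2 Jml + 2 Np`; smaller is better. Used as the cost function of
#' the mixed-integer search so that model fit and structural complexity are
#' traded off within a single objective.
#'
#' @param Jml Maximized log-likelihood.
#' @param Np Number of estimated parameters.
#' @return The AIC value.
#' @export
aic <- function(Jml, Np) {
  stopifnot(is.finite(Jml), Np >= 0, Np == round(Np))
  -2 * Jml + 2 * Np
}

#' Row index of a dataset for fast repeated prediction
#'
#' Precomputes, per experiment, the dataset rows, the observed variable of
#' each row and its position on the design time grid, so that an optimizer
#' can map simulated trajectories onto measurement rows without any joins.
#'
#' @param dataset A [kdp_dataset()].
#' @return A list of per-experiment index entries (`design`, `rows`,
#'   `var_col`, `t_idx`).
#' @export
dataset_index <- function(dataset) {
  designs <- dataset_designs(dataset)
  purrr::imap(designs, function(des, id) {
    rows <- which(dataset$experiment_id == id)
    list(design = des, rows = rows,
         var_col = match(dataset$variable[rows], des$observed),
         t_idx = match(dataset$time_h[rows], des$t_grid))
  })
}

#' Model predictions for every measurement of a dataset
#'
#' Simulates each experiment once and matches the trajectory to the
#' measurement rows by variable and time. Initial steady states are
#' computed once per strain and reused across K+ levels.
#'
#' @param s A [kdp_structure()].
#' @param p A [kdp_parameters()].
#' @param dataset A [kdp_dataset()].
#' @param constants A [kdp_constants()].
#' @param rtol,atol Integrator tolerances.
#' @param index Optional precomputed [dataset_index()] (computed on the
#'   fly otherwise); supply it when calling in a tight loop.
#' @return The dataset with a `.pred` column appended; attribute `ok` is
#'   `FALSE` if any simulation failed (failed rows carry `NA`).
#' @export
predict_dataset <- function(s, p, dataset, constants = kdp_constants(),
                            rtol = 1e-8, atol = 1e-12, index = NULL) {
  s <- as_kdp_structure(s); p <- as_kdp_parameters(p)
  if (is.null(index)) index <- dataset_index(dataset)
  strains <- unique(vapply(index, function(e) e$design$strain, character(1)))
  inits <- lapply(stats::setNames(strains, strains), function(st) {
    tryCatch(initial_state(s, p, constants, strain = st,
                           rtol = min(rtol, 1e-8), atol = min(atol, 1e-12)),
             error = function(e) NULL)
  })
  pred <- rep(NA_real_, nrow(dataset))
  failed <- character(0)
  for (id in names(index)) {
    e <- index[[id]]
    des <- e$design
    y0 <- inits[[des$strain]]
    out <- NULL
    if (!is.null(y0)) {
      parms <- pack_parms(s, p, constants, des$strain, des$Kplus)
      tg <- des$t_grid
      times <- if (tg[1] > 0) c(0, tg) else tg
      out <- run_lsoda(y0, times, parms, rtol, atol)
      if (!is.null(out) && tg[1] > 0) out <- out[-1, , drop = FALSE]
    }
    if (is.null(out)) {
      failed <- c(failed, id)
      next
    }
    pred[e$rows] <- out[, des$observed, drop = FALSE][cbind(e$t_idx,
                                                            e$var_col)]
  }
  out <- dataset
  out$.pred <- pred
  attr(out, "ok") <- length(failed) == 0 && !anyNA(pred)
  attr(out, "failed_experiments") <- failed
  class(out) <- c("kdp_dataset", setdiff(class(out), "kdp_dataset"))
  out
}

#' Evaluate the MINLP objective for one decision vector
#'
#' Simulates every experiment of the dataset under the given structure and
#' real parameters, computes the log-likelihood and the AIC. All failures
#' (integration breakdown, non-finite states) are encoded in the returned
#' value as an infeasible evaluation with a large finite penalty, so that a
#' metaheuristic always receives a totally ordered objective.
#'
#' @param s A [kdp_structure()].
#' @param p A [kdp_parameters()].
#' @param dataset A [kdp_dataset()].
#' @param constants A [kdp_constants()].
#' @param counting Parameter-counting convention, see
#'   [count_active_parameters()].
#' @param rtol,atol Integrator tolerances.
#' @param index Optional precomputed [dataset_index()].
#' @return A list of class `"objective_value"` with `Jml`, `Np`, `aic`,
#'   `search_value` (the totally ordered value seen by an optimizer:
#'   the AIC when feasible, a penalty strictly worse than every feasible
#'   value otherwise), `feasible` and `penalty_reason`.
#' @export
objective_evaluate <- function(s, p, dataset, constants = kdp_constants(),
                               counting = "all", rtol = 1e-8, atol = 1e-12,
                               index = NULL) {
  s <- as_kdp_structure(s)
  Np <- count_active_parameters(s, counting)
  pred <- predict_dataset(s, p, dataset, constants, rtol = rtol, atol = atol,
                          index = index)
  if (!isTRUE(attr(pred, "ok"))) {
    n_fail <- length(attr(pred, "failed_experiments")) + anyNA(pred$.pred)
    return(structure(
      list(Jml = NA_real_, Np = Np, aic = NA_real_,
           search_value = penalty_value(n_fail), feasible = FALSE,
           penalty_reason = paste("simulation failure in experiments:",
                                  paste(attr(pred, "failed_experiments"),
                                        collapse = ", "))),
      class = "objective_value"))
  }
  Jml <- log_likelihood(pred, pred$.pred)
  a <- aic(Jml, Np)
  if (!is.finite(a) || a >= 1e100) {
    # predictions so absurd that the likelihood overflows: treat as failure
    return(structure(
      list(Jml = Jml, Np = Np, aic = a, search_value = penalty_value(0L),
           feasible = FALSE, penalty_reason = "objective overflow"),
      class = "objective_value"))
  }
  structure(list(Jml = Jml, Np = Np, aic = a, search_value = a,
                 feasible = TRUE, penalty_reason = NULL),
            class = "objective_value")
}

# Penalty encoding for infeasible decision vectors: a finite value that is
# strictly worse than every feasible search value (feasible AICs are capped
# below 1e100), keeping the metaheuristic's ordering total.
penalty_value <- function(n_fail) 1e100 * (1 + 1e-6 * n_fail)

#' @export
print.objective_value <- function(x, ...) {
  if (x$feasible) {
    cat(sprintf("<objective_value> AIC = %.4f (Jml = %.4f, Np = %d)\n",
                x$aic, x$Jml, x$Np))
  } else {
    cat(sprintf("<objective_value> infeasible (penalty %.4g): %s\n",
                x$aic, x$penalty_reason))
  }
  invisible(x)
}

#' Mean relative residual of a fit, in percent
#'
#' `mean(|y_obs - y_pred| / |y_obs|) * 100` over all measurements.
#' Measurements with value exactly zero cannot be normalized and are
#' excluded with a warning count (attribute `n_excluded`).
#'
#' @param dataset A [kdp_dataset()].
#' @param predictions Numeric vector aligned with `dataset` rows, or `NULL`
#'   if `dataset` already carries a `.pred` column.
#' @return Mean relative residual (percent).
#' @export
residual_summary <- function(dataset, predictions = NULL) {
  if (is.null(predictions)) {
    if (!".pred" %in% names(dataset)) {
      stop("no predictions supplied and no .pred column present",
           call. = FALSE)
    }
    predictions <- dataset$.pred
  }
  if (length(predictions) != nrow(dataset)) {
    stop("predictions must align one-to-one with dataset rows", call. = FALSE)
  }
  nz <- dataset$value != 0
  n_excl <- sum(!nz)
  if (n_excl > 0) {
    warning(sprintf("%d zero-valued measurements excluded from residuals",
                    n_excl))
  }
  r <- mean(abs(dataset$value[nz] - predictions[nz]) /
              abs(dataset$value[nz])) * 100
  attr(r, "n_excluded") <- n_excl
  r
}

#' Write / read a dataset CSV
#'
#' Plain CSV with the canonical dataset columns.
#'
#' @param dataset A [kdp_dataset()].
#' @param path File path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns
#'   a [kdp_dataset()].
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  kdp_dataset(utils::read.csv(path, stringsAsFactors = FALSE))
}
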