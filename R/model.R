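#' Experiment design
#'
#' One stimulus-response experiment: a strain (wild type or K+-uptake
#' mutant), an extracellular K+ level, an observation time grid, and the
#' set of observed state variables.
#'
#' @param strain `"wild"` or `"mutant"`.
#' @param Kplus Extracellular K+ concentration, mM (> 0).
#' @param t_grid Strictly increasing observation times, hours.
#' @param observed Character subset of `c("mRNA", "KdpFABC")`.
#' @return A list of class `"kdp_design"`.
#' @export
kdp_design <- function(strain = c("wild", "mutant"), Kplus = 10,
                       t_grid = seq(0, 1, length.out = 15),
                       observed = c("mRNA", "KdpFABC")) {
  strain <- match.arg(strain)
  if (!is.numeric(Kplus) || length(Kplus) != 1 || !is.finite(Kplus) ||
      Kplus <= 0) {
    stop("Kplus must be a single positive number (mM)", call. = FALSE)
  }
  if (length(t_grid) < 1 || any(!is.finite(t_grid)) || t_grid[1] < 0 ||
      any(diff(t_grid) <= 0)) {
    stop("t_grid must be non-empty, non-negative and strictly increasing",
         call. = FALSE)
  }
  observed <- match.arg(observed, c("mRNA", "KdpFABC"), several.ok = TRUE)
  structure(list(strain = strain, Kplus = Kplus, t_grid = as.numeric(t_grid),
                 observed = observed),
            class = "kdp_design")
}

state_names <- function() c("mRNA", "KdpD0", "KdpE0", "KdpEP", "KdpFABC")

int_pow <- function(x, n) {
  # x^0 == 1 by convention, including at x = 0
  if (n == 0) rep(1, length(x)) else x^n
}

#' Stimulus function
#'
#' Maps the extracellular K+ concentration to the dimensionless stimulus S
#' driving the dephosphorylation of KdpE-P. The default ratio form is
#' S = K+/K0; the saturating alternative is S = K+/(K+ + K0).
#'
#' @param Kplus Extracellular K+ (mM).
#' @param constants A [kdp_constants()].
#' @return Stimulus value (dimensionless).
#' @export
stimulus <- function(Kplus, constants = kdp_constants()) {
  if (constants$s_form == "ratio") Kplus / constants$K0
  else Kplus / (Kplus + constants$K0)
}

#' Regulation of translation (R1)
#'
#' Feedback factor multiplying KdpFABC translation. Inactive
#' (`bin1 = 0`) it equals 1; active, it is `1 / (F^n1 + ktrans)` —
#' strictly decreasing in the KdpFABC concentration `F` for `n1 >= 1`.
#'
#' @param F KdpFABC concentration (>= 0).
#' @param s A [kdp_structure()].
#' @param p A [kdp_parameters()].
#' @return Positive regulation factor, vectorized over `F`.
#' @export
regulation_translation <- function(F, s, p) {
  if (any(!is.finite(F))) stop("non-finite KdpFABC state", call. = FALSE)
  if (any(F < 0)) stop("negative KdpFABC state", call. = FALSE)
  s <- as_kdp_structure(s); p <- as_kdp_parameters(p)
  if (s[["bin1"]] == 0L) return(rep(1, length(F)))
  1 / (int_pow(F, s[["n1"]]) + p[["ktrans"]])
}

#' Regulation of proteolysis (R2)
#'
#' Feedback factor multiplying the `kd2` degradation of KdpFABC. Inactive
#' (`bin2 = 0`) it equals 1; active, it is `F^n2 / (F^n3 + kdeg)`.
#'
#' @inheritParams regulation_translation
#' @return Positive regulation factor, vectorized over `F`.
#' @export
regulation_proteolysis <- function(F, s, p) {
  if (any(!is.finite(F))) stop("non-finite KdpFABC state", call. = FALSE)
  if (any(F < 0)) stop("negative KdpFABC state", call. = FALSE)
  s <- as_kdp_structure(s); p <- as_kdp_parameters(p)
  if (s[["bin2"]] == 0L) return(rep(1, length(F)))
  int_pow(F, s[["n2"]]) / (int_pow(F, s[["n3"]]) + p[["kdeg"]])
}

#' Stimulus counteraction rate k3f
#'
#' Effective dephosphorylation rate of KdpE-P. The mutant strain, defective
#' in K+ uptake through KdpFABC, has no feedback: `k3f = k3 * S(K+)`. For
#' the wild strain a feedback term is added, either `khy * F^n4`
#' (`bin3 = 0`) or the saturable form `khy * F^n4 / (F^n5 + Khy)`
#' (`bin3 = 1`).
#'
#' @inheritParams regulation_translation
#' @param strain `"wild"` or `"mutant"`.
#' @param Kplus Extracellular K+ (mM).
#' @param constants A [kdp_constants()].
#' @return Non-negative rate (per hour), vectorized over `F`.
#' @export
stimulus_counteraction <- function(F, strain, s, p, Kplus,
                                   constants = kdp_constants()) {
  if (!strain %in% c("wild", "mutant")) {
    stop("strain must be 'wild' or 'mutant'", call. = FALSE)
  }
  if (any(!is.finite(F)) || any(F < 0)) {
    stop("KdpFABC state must be finite and non-negative", call. = FALSE)
  }
  s <- as_kdp_structure(s); p <- as_kdp_parameters(p)
  base <- p[["k3"]] * stimulus(Kplus, constants)
  if (strain == "mutant") return(rep(base, length(F)))
  if (s[["bin3"]] == 0L) {
    base + p[["khy"]] * int_pow(F, s[["n4"]])
  } else {
    base + p[["khy"]] * int_pow(F, s[["n4"]]) /
      (int_pow(F, s[["n5"]]) + p[["Khy"]])
  }
}

#' Solve the promoter-binding algebraic subsystem
#'
#' Given the total phosphorylated response regulator, solves the two
#' algebraic constraints — the KdpE-P balance over free and DNA-bound dimer
#' and the DNA balance over free, non-specifically bound and complex-bound
#' promoter — for the free regulator `KdpEfP` and the free DNA `DNAf`.
#' `DNAf` is eliminated from the DNA balance (linear in `DNAf`) and the
#' resulting scalar equation in `KdpEfP` is solved by safeguarded Newton on
#' the bracket `[0, KdpEP_total]`.
#'
#' @param KdpEP_total Total phosphorylated KdpE concentration (>= 0).
#' @param p A [kdp_parameters()].
#' @return List with `KdpEfP` and `DNAf`; both algebraic residuals are
#'   satisfied to a relative tolerance below 1e-10.
#' @export
solve_algebraic <- function(KdpEP_total, p) {
  p <- as_kdp_parameters(p)
  if (!is.finite(KdpEP_total) || KdpEP_total < 0) {
    stop("KdpEP_total must be finite and non-negative", call. = FALSE)
  }
  beta <- (1 + 1 / (p[["alpha"]] * p[["K"]])) / p[["Ka"]]
  gamma <- 1 + 1 / p[["K"]]
  DNA0 <- p[["DNA0"]]
  if (KdpEP_total == 0) {
    return(list(KdpEfP = 0, DNAf = DNA0 / gamma))
  }
  g <- function(E) {
    KdpEP_total - E - 2 * beta * E^2 * DNA0 / (gamma + beta * E^2)
  }
  lo <- 0; hi <- KdpEP_total; E <- KdpEP_total
  for (it in 1:200) {
    den <- gamma + beta * E^2
    gE <- g(E)
    if (gE > 0) lo <- E else hi <- E
    if (abs(gE) < 1e-14 * KdpEP_total ||
        (hi - lo) < 1e-16 * KdpEP_total) break
    dg <- -1 - 4 * beta * DNA0 * E * gamma / den^2
    En <- E - gE / dg
    E <- if (En <= lo || En >= hi) (lo + hi) / 2 else En
  }
  DNAf <- DNA0 / (gamma + beta * E^2)
  if (!is.finite(E) || !is.finite(DNAf) || DNAf <= 0) {
    stop(sprintf("algebraic solve failed (KdpEP_total = %g)", KdpEP_total),
         call. = FALSE)
  }
  list(KdpEfP = E, DNAf = DNAf)
}

#' Right-hand side of the reduced DAE model (reference implementation)
#'
#' Time derivatives of the five differential states, with the promoter
#' algebra solved inline and the phosphorylated sensor held at its constant
#' reduced-model level. This pure-R implementation mirrors the compiled
#' derivative function used by [simulate_kdp()] and serves for diagnostics
#' and cross-checking.
#'
#' @param t Time (unused; the system is autonomous).
#' @param state Named numeric vector of the five states
#'   (`mRNA`, `KdpD0`, `KdpE0`, `KdpEP`, `KdpFABC`).
#' @param s A [kdp_structure()].
#' @param p A [kdp_parameters()].
#' @param design A [kdp_design()].
#' @param constants A [kdp_constants()].
#' @return Named list with `derivatives` (length 5), `KdpEfP`, `DNAf`, `k3f`.
#' @export
kdp_rhs <- function(t, state, s, p, design, constants = kdp_constants()) {
  s <- as_kdp_structure(s); p <- as_kdp_parameters(p)
  y <- state[state_names()]
  if (any(!is.finite(y))) stop("non-finite state", call. = FALSE)
  EPc <- max(y[["KdpEP"]], 0)
  Fc <- max(y[["KdpFABC"]], 0)
  alg <- solve_algebraic(EPc, p)
  k3f <- stimulus_counteraction(Fc, design$strain, s, p, design$Kplus,
                                constants)
  R1 <- regulation_translation(Fc, s, p)
  R2 <- regulation_proteolysis(Fc, s, p)
  act <- 1 + alg$KdpEfP^2 / (p[["alpha"]] * p[["Ka"]] * p[["DNA0"]])
  KdpDu <- max(y[["KdpD0"]] - constants$KdpDP_const, 0)
  mu <- constants$mu
  d <- c(
    mRNA = p[["ktr"]] * alg$DNAf / (p[["K"]] * p[["DNA0"]]) * act -
      (p[["kz"]] + mu) * y[["mRNA"]],
    KdpD0 = p[["ktl"]] * y[["mRNA"]] - (p[["kd"]] + mu) * y[["KdpD0"]],
    KdpE0 = p[["ktl2"]] * y[["mRNA"]] - (p[["kd"]] + mu) * y[["KdpE0"]],
    KdpEP = p[["k2"]] * constants$KdpDP_const * (y[["KdpE0"]] - y[["KdpEP"]]) -
      (p[["kd"]] + k3f + constants$kminus2 * KdpDu) * y[["KdpEP"]],
    KdpFABC = p[["ktl3"]] * y[["mRNA"]] * R1 -
      (p[["kd2"]] * R2 + mu) * y[["KdpFABC"]]
  )
  list(derivatives = d, KdpEfP = alg$KdpEfP, DNAf = alg$DNAf, k3f = k3f)
}

pack_parms <- function(s, p, constants, strain, Kplus) {
  s <- as_kdp_structure(s); p <- as_kdp_parameters(p)
  c(unclass(p)[parameter_names()],
    mu = constants$mu, kminus2 = constants$kminus2,
    KdpDP = constants$KdpDP_const, K0 = constants$K0,
    s_form = if (constants$s_form == "ratio") 0 else 1,
    unclass(s)[c("bin1", "bin2", "bin3")],
    unclass(s)[c("n1", "n2", "n3", "n4", "n5")],
    strain = if (strain == "wild") 0 else 1,
    Kplus = Kplus)
}

run_lsoda <- function(y0, times, parms, rtol, atol) {
  out <- tryCatch(
    suppressWarnings(deSolve::lsoda(
      y = y0, times = times, func = "kdp_derivs", parms = parms,
      dllname = "minlpselect", initfunc = "kdp_init", nout = 3,
      outnames = c("KdpEfP", "DNAf", "k3f"),
      rtol = rtol, atol = atol, maxsteps = 20000
    )),
    error = function(e) NULL
  )
  if (is.null(out) || nrow(out) < length(times) || any(!is.finite(out))) {
    return(NULL)
  }
  out
}

#' Evaluate an expression with solver console chatter suppressed
#'
#' The Fortran solver core prints step-size diagnostics directly to the
#' console on failed integrations; inside an optimizer run, where failures
#' are simply penalized, that output would flood the console. This helper
#' redirects standard output while `code` is evaluated.
#'
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
silence_solver <- function(code) {
  con <- file(nullfile(), open = "wt")
  sink(con)
  on.exit({
    sink()
    close(con)
  })
  force(code)
}

#' Simulate a nested model for one experiment
#'
#' Integrates the reduced DAE (five ODE states plus the promoter algebra)
#' with a stiff solver (`lsoda`, compiled derivative core) over the
#' observation grid of an experiment design. Integration failures never
#' raise: a trajectory object flagged `ok = FALSE` is returned so that an
#' optimizer can penalize the decision vector and continue.
#'
#' @param s A [kdp_structure()].
#' @param p A [kdp_parameters()].
#' @param design A [kdp_design()].
#' @param constants A [kdp_constants()].
#' @param init Initial state: `NULL` (default) computes the pre-stimulus
#'   steady state via [initial_state()], otherwise a named numeric vector
#'   of the five states.
#' @param rtol,atol Integrator tolerances.
#' @return A tibble (class `"kdp_trajectory"`) with columns `time`, the
#'   five states, `KdpEfP` and `DNAf`; attribute `ok` flags success.
#' @export
simulate_kdp <- function(s, p, design, constants = kdp_constants(),
                         init = NULL, rtol = 1e-8, atol = 1e-12) {
  s <- as_kdp_structure(s); p <- as_kdp_parameters(p)
  if (is.null(init)) {
    init <- tryCatch(
      initial_state(s, p, constants, strain = design$strain),
      error = function(e) NULL
    )
    if (is.null(init)) return(failed_trajectory(design, "initial state"))
  }
  y0 <- as.numeric(init[state_names()])
  names(y0) <- state_names()
  parms <- pack_parms(s, p, constants, design$strain, design$Kplus)
  tg <- design$t_grid
  times <- if (tg[1] > 0) c(0, tg) else tg
  out <- run_lsoda(y0, times, parms, rtol, atol)
  if (is.null(out)) return(failed_trajectory(design, "integration"))
  keep <- if (tg[1] > 0) -1 else seq_along(times)
  df <- tibble::as_tibble(as.data.frame(out[keep, , drop = FALSE]))
  attr(df, "ok") <- TRUE
  attr(df, "design") <- design
  class(df) <- c("kdp_trajectory", class(df))
  df
}

failed_trajectory <- function(design, reason) {
  df <- tibble::tibble(time = numeric(0))
  attr(df, "ok") <- FALSE
  attr(df, "reason") <- reason
  attr(df, "design") <- design
  class(df) <- c("kdp_trajectory", class(df))
  df
}

#' Did a simulation succeed?
#' @param x A trajectory returned by [simulate_kdp()].
#' @return Logical flag.
#' @export
trajectory_ok <- function(x) isTRUE(attr(x, "ok"))

#' Export a trajectory as long-format CSV
#'
#' One row per time point and state, with columns `time`, `state`,
#' `value` and `experiment_id`.
#'
#' @param trajectory A [simulate_kdp()] result.
#' @param path Output CSV path.
#' @param experiment_id Identifier recorded with every row.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, experiment_id = "exp1") {
  if (!trajectory_ok(trajectory)) {
    stop("cannot export a failed trajectory", call. = FALSE)
  }
  long <- trajectory |>
    tidyr::pivot_longer(-"time", names_to = "state", values_to = "value") |>
    dplyr::mutate(experiment_id = experiment_id)
  utils::write.csv(as.data.frame(long), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Pre-stimulus initial state
#'
#' Returns either a user-supplied state vector (pass-through) or the
#' pre-stimulus steady state, computed by integrating the model at the
#' pre-stimulus K+ level until the largest relative derivative falls below
#' `tol`. The steady state is strain-specific because the wild-strain
#' stimulus-counteraction feedback also acts before the stimulus.
#'
#' @param s A [kdp_structure()].
#' @param p A [kdp_parameters()].
#' @param constants A [kdp_constants()].
#' @param strain `"wild"` or `"mutant"`.
#' @param state0 Optional user-supplied named state vector (returned as is).
#' @param tol Relative-derivative convergence tolerance.
#' @param t_max Time cap (hours) for the equilibration.
#' @param rtol,atol Integrator tolerances for the equilibration runs.
#' @return Named numeric vector of the five states.
#' @export
initial_state <- function(s, p, constants = kdp_constants(),
                          strain = "wild", state0 = NULL,
                          tol = 1e-8, t_max = 3200,
                          rtol = 1e-10, atol = 1e-14) {
  if (!is.null(state0)) {
    y <- as.numeric(state0[state_names()])
    if (any(!is.finite(y))) stop("state0 has non-finite entries", call. = FALSE)
    names(y) <- state_names()
    return(y)
  }
  s <- as_kdp_structure(s); p <- as_kdp_parameters(p)
  parms <- pack_parms(s, p, constants, strain, constants$prestim_K)
  design <- kdp_design(strain = strain, Kplus = constants$prestim_K,
                       t_grid = 1)
  y <- stats::setNames(rep(1e-8, 5), state_names())
  t_done <- 0
  span <- 200
  repeat {
    out <- run_lsoda(y, c(0, span), parms, rtol = rtol, atol = atol)
    if (is.null(out)) {
      stop("equilibration failed during pre-stimulus integration",
           call. = FALSE)
    }
    y <- stats::setNames(as.numeric(out[2, 1 + seq_len(5)]), state_names())
    t_done <- t_done + span
    d <- kdp_rhs(0, y, s, p, design, constants)$derivatives
    rel <- max(abs(d) / (abs(y) + 1e-12))
    if (rel < tol) break
    if (t_done >= t_max) {
      stop(sprintf(paste0("no steady state within %g h (max relative ",
                          "derivative %.3g)"), t_max, rel), call. = FALSE)
    }
  }
  y
}
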