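#' Kinetic parameters of the KdpD/KdpE superstructure
#'
#' The 17 real decision variables of the mixed-integer estimation problem.
#' Thirteen core rate constants govern transcription, translation,
#' phosphotransfer, degradation and promoter binding; `khy`, `ktrans`,
#' `kdeg` and `Khy` are the feedback-loop constants of the hypothesized
#' regulation terms. Rates are per hour; concentrations are in the source
#' model's concentration unit.
#'
#' @param k2 Phosphotransfer rate KdpD-P to KdpE.
#' @param k3 Stimulus-counteraction (dephosphorylation) base rate.
#' @param alpha Promoter activation factor of the bound complex.
#' @param ktr Transcription rate constant.
#' @param ktl,ktl2,ktl3 Translation rate constants for KdpD, KdpE, KdpFABC.
#' @param kz mRNA degradation rate.
#' @param kd2 KdpFABC degradation rate.
#' @param DNA0 Total promoter DNA concentration.
#' @param Ka Specific (activating) DNA-binding constant of the KdpE-P dimer.
#' @param K Non-specific DNA-binding constant.
#' @param kd Protein degradation rate.
#' @param khy Stimulus-counteraction feedback gain (K+ uptake via KdpFABC).
#' @param ktrans Half-saturation constant of the translation-regulation loop.
#' @param kdeg Half-saturation constant of the proteolysis-regulation loop.
#' @param Khy Half-saturation constant of the saturable counteraction form
#'   (active only with `bin3 = 1`).
#' @return A named numeric vector of class `"kdp_parameters"`.
#' @export
kdp_parameters <- function(k2, k3, alpha, ktr, ktl, ktl2, ktl3, kz, kd2,
                           DNA0, Ka, K, kd, khy, ktrans, kdeg, Khy = 1.0) {
  p <- c(k2 = k2, k3 = k3, alpha = alpha, ktr = ktr, ktl = ktl,
         ktl2 = ktl2, ktl3 = ktl3, kz = kz, kd2 = kd2, DNA0 = DNA0,
         Ka = Ka, K = K, kd = kd, khy = khy, ktrans = ktrans,
         kdeg = kdeg, Khy = Khy)
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("all kinetic parameters must be strictly positive and finite",
         call. = FALSE)
  }
  structure(p, class = "kdp_parameters")
}

parameter_names <- function() {
  c("k2", "k3", "alpha", "ktr", "ktl", "ktl2", "ktl3", "kz", "kd2",
    "DNA0", "Ka", "K", "kd", "khy", "ktrans", "kdeg", "Khy")
}

#' Fixed model constants
#'
#' Constants of the reduced model that are never decision variables of the
#' MINLP: the dilution rate `mu` (0.5 per hour, fixed to its experimental
#' value), the reverse phosphotransfer rate `kminus2` (fixed after the
#' sensitivity-based model reduction), the constant phosphorylated-sensor
#' level `KdpDP_const` that replaces the eliminated KdpD-P balance, the
#' stimulus reference concentration `K0` (mM), the functional form of the
#' stimulus, and the pre-stimulus extracellular K+ level used to compute
#' the initial steady state.
#'
#' @param mu Specific growth (dilution) rate, per hour.
#' @param kminus2 Reverse phosphotransfer rate constant.
#' @param KdpDP_const Constant KdpD-P concentration of the reduced model.
#' @param K0 Stimulus reference K+ concentration, mM.
#' @param s_form `"ratio"` for S = K+/K0 (default) or `"saturating"` for
#'   S = K+/(K+ + K0).
#' @param prestim_K Pre-stimulus extracellular K+, mM.
#' @return A list of class `"kdp_constants"`.
#' @export
kdp_constants <- function(mu = 0.5, kminus2 = 100, KdpDP_const = 1e-9,
                          K0 = 0.1, s_form = c("ratio", "saturating"),
                          prestim_K = 1000) {
  s_form <- match.arg(s_form)
  vals <- c(mu = mu, kminus2 = kminus2, KdpDP_const = KdpDP_const, K0 = K0,
            prestim_K = prestim_K)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("model constants must be strictly positive and finite", call. = FALSE)
  }
  structure(list(mu = mu, kminus2 = kminus2, KdpDP_const = KdpDP_const,
                 K0 = K0, s_form = s_form, prestim_K = prestim_K),
            class = "kdp_constants")
}

#' Nominal parameter set and structure of the in-silico study
#'
#' The nominal column of the case-study parameter table: regulation of
#' translation and of proteolysis active (`bin1 = bin2 = 1`), linear
#' stimulus counteraction with kinetic order three for KdpFABC
#' (`bin3 = 0`, `n4 = 3`). `Khy` is inactive under this structure (no
#' nominal value exists); a placeholder of 1 is carried so the full real
#' vector is always well defined.
#'
#' @return A list with components `structure` ([kdp_structure()]) and
#'   `parameters` ([kdp_parameters()]).
#' @export
nominal_parameters <- function() {
  list(
    structure = kdp_structure(bin1 = 1, bin2 = 1, bin3 = 0,
                              n1 = 3, n2 = 1, n3 = 2, n4 = 3, n5 = 0),
    parameters = kdp_parameters(
      k2 = 5.18e+07, k3 = 9.76e+01, alpha = 5.79e-02, ktr = 1.00e+03,
      ktl = 4.96e+03, ktl2 = 1.03e+03, ktl3 = 2.05e+03, kz = 4.99e+01,
      kd2 = 1.00e+01, DNA0 = 6.16e-04, Ka = 1.82e-07, K = 1.00e+03,
      kd = 1.18e+00, khy = 2.00e+06, ktrans = 9.74e-01, kdeg = 1.36e-01,
      Khy = 1.0
    )
  )
}

as_kdp_parameters <- function(p) {
  if (inherits(p, "kdp_parameters")) return(p)
  if (is.numeric(p) && all(parameter_names() %in% names(p))) {
    return(do.call(kdp_parameters, as.list(p[parameter_names()])))
  }
  stop("cannot interpret object as kdp_parameters", call. = FALSE)
}
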