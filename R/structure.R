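#' Structure vector of the KdpD/KdpE superstructure
#'
#' A structure vector selects one nested model out of the superstructure:
#' three binary switches and five integer (Hill-type) exponents.
#' `bin1` switches the regulation-of-translation loop on, `bin2` the
#' regulation-of-proteolysis loop, and `bin3` chooses between the two
#' hypothesized expressions for the stimulus-counteraction feedback of the
#' wild strain. Exponents are restricted to moderately steep Hill
#' coefficients, 0 to 3.
#'
#' The activity rule makes nested models well defined: `n1` matters only
#' when `bin1 = 1`; `n2`, `n3` only when `bin2 = 1`; `n5` and the
#' half-saturation constant `Khy` only when `bin3 = 1`; `n4` and `khy`
#' always act for the wild strain.
#'
#' @param bin1,bin2,bin3 Binary flags (0 or 1).
#' @param n1,n2,n3,n4,n5 Integer exponents in 0..3.
#' @return A named integer vector of class `"kdp_structure"`.
#' @examples
#' kdp_structure(bin1 = 1, bin2 = 1, bin3 = 0, n1 = 3, n2 = 1, n3 = 2, n4 = 3)
#' @export
kdp_structure <- function(bin1 = 0, bin2 = 0, bin3 = 0,
                          n1 = 0, n2 = 0, n3 = 0, n4 = 0, n5 = 0) {
  s <- c(bin1 = bin1, bin2 = bin2, bin3 = bin3,
         n1 = n1, n2 = n2, n3 = n3, n4 = n4, n5 = n5)
  if (any(!is.finite(s)) || any(s != round(s))) {
    stop("structure entries must be finite integers", call. = FALSE)
  }
  s <- as.integer(round(s))
  names(s) <- c("bin1", "bin2", "bin3", "n1", "n2", "n3", "n4", "n5")
  if (any(s[1:3] < 0L | s[1:3] > 1L)) {
    stop("binary flags must be 0 or 1", call. = FALSE)
  }
  if (any(s[4:8] < 0L | s[4:8] > 3L)) {
    stop("integer exponents must lie in 0..3", call. = FALSE)
  }
  structure(s, class = "kdp_structure")
}

#' @export
print.kdp_structure <- function(x, ...) {
  cat("<kdp_structure> bins:", x[["bin1"]], x[["bin2"]], x[["bin3"]],
      " exponents:", x[["n1"]], x[["n2"]], x[["n3"]], x[["n4"]], x[["n5"]], "\n")
  invisible(x)
}

structure_names <- function() c("bin1", "bin2", "bin3", "n1", "n2", "n3", "n4", "n5")

#' Names of active decision variables for a structure
#'
#' Applies the activity rule: 13 core rate constants plus `khy` are always
#' estimated; `ktrans` only with the translation loop (`bin1 = 1`), `kdeg`
#' only with the proteolysis loop (`bin2 = 1`), `Khy` only with the
#' saturable stimulus-counteraction form (`bin3 = 1`). Exponents follow the
#' loop they belong to; `n4` is always active (wild-strain feedback).
#'
#' @param s A [kdp_structure()].
#' @return List with components `reals` and `integers` (character vectors).
#' @export
active_parameters <- function(s) {
  s <- as_kdp_structure(s)
  reals <- c("k2", "k3", "alpha", "ktr", "ktl", "ktl2", "ktl3", "kz",
             "kd2", "DNA0", "Ka", "K", "kd", "khy")
  ints <- "n4"
  if (s[["bin1"]] == 1L) {
    reals <- c(reals, "ktrans")
    ints <- c(ints, "n1")
  }
  if (s[["bin2"]] == 1L) {
    reals <- c(reals, "kdeg")
    ints <- c(ints, "n2", "n3")
  }
  if (s[["bin3"]] == 1L) {
    reals <- c(reals, "Khy")
    ints <- c(ints, "n5")
  }
  list(reals = reals, integers = ints)
}

#' Number of estimated parameters of a nested model
#'
#' Counts the decision variables that are active under a given structure.
#' By default active integer exponents and the three binary switches are
#' counted as estimated parameters alongside the active reals, since all of
#' them are decision variables of the mixed-integer program and the AIC must
#' penalize structural complexity; `counting = "reals_only"` restricts the
#' count to the active real parameters.
#'
#' @param s A [kdp_structure()].
#' @param counting `"all"` (default) or `"reals_only"`.
#' @return Integer count.
#' @examples
#' count_active_parameters(kdp_structure(bin1 = 1, bin2 = 1, bin3 = 1)) # 25
#' @export
count_active_parameters <- function(s, counting = c("all", "reals_only")) {
  counting <- match.arg(counting)
  a <- active_parameters(s)
  if (counting == "reals_only") {
    return(length(a$reals))
  }
  length(a$reals) + length(a$integers) + 3L
}

as_kdp_structure <- function(s) {
  if (inherits(s, "kdp_structure")) return(s)
  if (is.numeric(s) && all(structure_names() %in% names(s))) {
    return(do.call(kdp_structure, as.list(s[structure_names()])))
  }
  if (is.list(s)) {
    return(do.call(kdp_structure, s[structure_names()]))
  }
  stop("cannot interpret object as a kdp_structure", call. = FALSE)
}

#' Canonical form of a structure vector
#'
#' Inactive exponents are forced to 0 so that structures that differ only in
#' coordinates without effect on the dynamics map to the same representative.
#'
#' @param s A [kdp_structure()].
#' @return A [kdp_structure()] in canonical form.
#' @export
canonical_structure <- function(s) {
  s <- as_kdp_structure(s)
  if (s[["bin1"]] == 0L) s[["n1"]] <- 0L
  if (s[["bin2"]] == 0L) s[["n2"]] <- s[["n3"]] <- 0L
  if (s[["bin3"]] == 0L) s[["n5"]] <- 0L
  structure(s, class = "kdp_structure")
}

#' Enumerate all distinct nested model structures
#'
#' Generates every structure vector within the exponent bounds and
#' deduplicates by the activity rule (structures differing only in inactive
#' exponents describe the same model). With the default exponent range 0..3
#' the superstructure contains 1700 distinct nested models.
#'
#' @param n_values Integer vector of admissible exponent values
#'   (default `0:3`).
#' @return A tibble with one row per distinct structure, columns
#'   `bin1..bin3`, `n1..n5`, and `n_params` (active-parameter count).
#' @examples
#' nrow(enumerate_structures()) # 1700
#' @export
enumerate_structures <- function(n_values = 0:3) {
  n_values <- sort(unique(as.integer(n_values)))
  if (any(n_values < 0L | n_values > 3L)) {
    stop("exponent values must lie in 0..3", call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    bin1 = 0:1, bin2 = 0:1, bin3 = 0:1,
    n1 = n_values, n2 = n_values, n3 = n_values,
    n4 = n_values, n5 = n_values
  )
  canon <- grid |>
    dplyr::mutate(
      n1 = ifelse(bin1 == 0L, 0L, n1),
      n2 = ifelse(bin2 == 0L, 0L, n2),
      n3 = ifelse(bin2 == 0L, 0L, n3),
      n5 = ifelse(bin3 == 0L, 0L, n5)
    ) |>
    dplyr::distinct()
  canon$n_params <- purrr::pmap_int(canon, function(bin1, bin2, bin3, ...) {
    count_active_parameters(kdp_structure(bin1 = bin1, bin2 = bin2,
                                          bin3 = bin3, ...))
  })
  canon
}
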