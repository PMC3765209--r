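# FNV-1a 32-bit hash of the serialized configuration; stamps every artifact
# so reruns can be matched to their exact configuration.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(utils::capture.output(utils::str(x)),
                                      collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)  # keep within int range
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Read and validate a run configuration
#'
#' YAML configuration with sections `paths` (`dataset`, `output`),
#' `model` (`s_form`, `K0`, `kminus2`, `KdpDP_const`, `prestim_K`,
#' `n_max`, `bound_factor`, `counting`), `search`
#' (fields of [scatter_settings()]), `analysis` (`n_points`, `step`),
#' `generate` (fields of [generation_protocol()] scalars), and a top-level
#' `seed`. Unknown keys are rejected; a seed is mandatory.
#'
#' @param path YAML file path, or a list already in memory.
#' @return Validated configuration list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  known <- c("paths", "model", "search", "analysis", "generate", "seed",
             "stages")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cfg$seed)) stop("configuration must set a seed", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  cfg$paths$output <- cfg$paths$output %||% "minlpselect_out"
  cfg$stages <- cfg$stages %||% c("generate", "fit", "analyze")
  structure(cfg, class = c("run_config", "list"))
}

config_constants <- function(cfg) {
  m <- cfg$model %||% list()
  kdp_constants(
    mu = m$mu %||% 0.5, kminus2 = m$kminus2 %||% 100,
    KdpDP_const = m$KdpDP_const %||% 1e-9, K0 = m$K0 %||% 0.1,
    s_form = m$s_form %||% "ratio", prestim_K = m$prestim_K %||% 1000
  )
}

#' Run the generate / fit / analyze pipeline
#'
#' Executes the requested stages of the model-selection workflow on one
#' configuration: dataset generation (or loading), the MINLP fit, and the
#' pseudo-global identifiability analysis. All artifacts (dataset CSV, fit
#' JSON, convergence-trace CSV, correlation and ranking CSVs, and a
#' human-readable report with the selected structure and a parameter table
#' against the nominal values) are written to the output directory and
#' stamped with the seed and a configuration hash.
#'
#' @param config Path to a YAML configuration or a configuration list.
#' @return Invisibly, a list with the fitted object, the analysis report
#'   and the artifact paths.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  out_dir <- cfg$paths$output
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cst <- config_constants(cfg)
  # hash the scientific configuration only, not the filesystem paths
  stamp <- list(seed = cfg$seed,
                config_hash = fnv1a_hash(unclass(cfg)[setdiff(names(cfg),
                                                              "paths")]))
  artifacts <- character(0)
  message(sprintf("[%s] pipeline start (seed %d, config %s)",
                  format(Sys.time(), "%H:%M:%S"), cfg$seed,
                  stamp$config_hash))

  # --- generate or load -----------------------------------------------
  gen <- cfg$generate %||% list()
  if ("generate" %in% cfg$stages) {
    proto <- generation_protocol(
      constants = cst,
      noise = gen$noise %||% 0.05,
      t_grid = seq(gen$t_min %||% 0, gen$t_max %||% 1,
                   length.out = gen$n_times %||% 15),
      seed = cfg$seed
    )
    dataset <- generate_dataset(proto)
    ds_path <- file.path(out_dir, "dataset.csv")
    write_dataset(dataset, ds_path)
    jsonlite::write_json(
      c(stamp, list(protocol = list(noise = proto$noise,
                                    K_levels = proto$K_levels,
                                    strains = proto$strains,
                                    n_times = length(proto$t_grid)))),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE)
    artifacts <- c(artifacts, ds_path)
  } else {
    dataset <- read_dataset(cfg$paths$dataset)
  }

  fit <- NULL
  if ("fit" %in% cfg$stages) {
    sc <- cfg$search %||% list()
    settings <- scatter_settings(
      max_eval = sc$max_eval %||% 2000,
      refset_size = sc$refset_size %||% 10,
      local_freq = sc$local_freq %||% 5,
      local_budget = sc$local_budget %||% 250,
      seed = cfg$seed
    )
    bounds <- decision_bounds(factor = cfg$model$bound_factor %||% 100,
                              n_max = cfg$model$n_max %||% 3)
    fit <- fit_kdp_model(dataset, bounds, settings, cst,
                         counting = cfg$model$counting %||% "all")
    utils::write.csv(fit$search$trace, file.path(out_dir, "trace.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      c(stamp, list(structure = as.list(unclass(fit$structure)),
                    parameters = as.list(unclass(fit$parameters)),
                    Jml = fit$objective$Jml, Np = fit$objective$Np,
                    aic = fit$objective$aic,
                    feasible = fit$objective$feasible,
                    residual_pct = fit$residual_pct,
                    n_eval = fit$search$n_eval)),
      file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA)
    write_report(fit, file.path(out_dir, "report.txt"), stamp)
    artifacts <- c(artifacts, file.path(out_dir, c("trace.csv", "fit.json",
                                                   "report.txt")))
    message(sprintf("[%s] fit done: AIC %.2f after %d evaluations",
                    format(Sys.time(), "%H:%M:%S"), fit$objective$aic,
                    fit$search$n_eval))
  }

  report <- NULL
  if ("analyze" %in% cfg$stages) {
    an <- cfg$analysis %||% list()
    s_use <- if (!is.null(fit)) fit$structure else nominal_parameters()$structure
    report <- pseudo_global_analysis(
      s_use, dataset, decision_bounds(), cst,
      n_points = an$n_points %||% 2^10, seed = cfg$seed,
      step = an$step %||% 1e-4
    )
    if (!is.null(report$correlation)) {
      utils::write.csv(report$correlation,
                       file.path(out_dir, "correlation.csv"))
    }
    if (!is.null(report$ranking)) {
      utils::write.csv(report$ranking, file.path(out_dir, "ranking.csv"),
                       row.names = FALSE)
    }
    artifacts <- c(artifacts, file.path(out_dir, c("correlation.csv",
                                                   "ranking.csv")))
  }

  invisible(list(fit = fit, analysis = report, dataset = dataset,
                 artifacts = artifacts, stamp = stamp))
}

write_report <- function(fit, path, stamp) {
  nom <- nominal_parameters()
  tab <- tidy(fit, nominal = unclass(nom$parameters))
  act <- tab[tab$type == "real" & tab$active, ]
  lines <- c(
    "minlpselect fit report",
    sprintf("seed: %d   config: %s", stamp$seed, stamp$config_hash),
    "",
    sprintf("selected structure: bin1=%d bin2=%d bin3=%d n1=%d n2=%d n3=%d n4=%d n5=%d",
            fit$structure[["bin1"]], fit$structure[["bin2"]],
            fit$structure[["bin3"]], fit$structure[["n1"]],
            fit$structure[["n2"]], fit$structure[["n3"]],
            fit$structure[["n4"]], fit$structure[["n5"]]),
    sprintf("AIC: %.4f   log-likelihood: %.4f   Np: %d",
            fit$objective$aic, fit$objective$Jml, fit$objective$Np),
    sprintf("mean relative residual: %.2f %%", fit$residual_pct),
    "",
    "active real parameters (estimate vs nominal):",
    sprintf("  %-8s %12.4g %12.4g %8.1f%%", act$term, act$estimate,
            act$nominal, act$deviation_pct)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Structure census report
#'
#' Enumerates the distinct nested structures within the exponent bounds and
#' writes the census as a CSV.
#'
#' @param n_values Admissible exponent values (default `0:3`).
#' @param path Optional CSV output path.
#' @return The census tibble (invisibly if written to file).
#' @export
enumerate_report <- function(n_values = 0:3, path = NULL) {
  census <- enumerate_structures(n_values)
  if (!is.null(path)) {
    utils::write.csv(as.data.frame(census), path, row.names = FALSE)
    message(sprintf("%d distinct nested structures written to %s",
                    nrow(census), path))
    return(invisible(census))
  }
  census
}
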