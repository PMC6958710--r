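#' @title Configuration, presets and the command-line interface
#' @description
#' Experiments are described by flat YAML configuration files (a `RunSpec`):
#' an experiment kind, a model, parameters, an initial state, a seed and
#' stopping caps. Derived parameters (`lam = lam0 / K`,
#' `comp_rate = b_H / K`) are resolved at load time and echoed back, so
#' every output is re-runnable from its own metadata. Named presets ship
#' the reference parameter sets.
#' @name interface
NULL

rq_experiments <- c("simulate", "ensemble", "exact-dt", "ode", "sweep",
                    "diversity")

preset_dir <- function() system.file("extdata", "presets", package = "redqueen")

#' List the shipped presets
#' @return character vector of preset names.
#' @export
preset_list <- function() {
  sub("\\.yaml$", "", list.files(preset_dir(), pattern = "\\.yaml$"))
}

#' Load a named preset
#'
#' @param name preset name (see [preset_list()]).
#' @return list with `name`, `n`, optional `N_H`/`N_P`, resolved `params`
#'   (a [model_params()]), and any extra preset fields.
#' @export
preset <- function(name) {
  path <- file.path(preset_dir(), paste0(name, ".yaml"))
  if (!file.exists(path)) {
    stop(sprintf("unknown preset '%s' (available: %s)", name,
                 paste(preset_list(), collapse = ", ")), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  raw$params <- do.call(model_params, raw$params)
  raw
}

known_spec_keys <- c("experiment", "model", "preset", "n", "seed", "reps",
                     "params", "init", "stop", "t_grid", "N_P_targets",
                     "models", "with_mutation", "out_csv", "out_json",
                     "name", "N_H", "N_P", "b_H_grid")

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, optionally merges a named `preset`, resolves
#' all derived parameters, and validates the result before any computation.
#' Unknown keys are rejected; a missing seed is an error (the
#' reproducibility contract demands an explicit one); an interaction rate
#' given both directly and as `lam0 / K` must be consistent.
#'
#' @param path YAML file.
#' @return an object of class `rq_run_spec`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config '%s' not found", path),
                               call. = FALSE)
  validate_run_spec(yaml::read_yaml(path))
}

#' Validate a run-specification list
#'
#' @param spec named list of configuration values (see [load_config()]).
#' @return an `rq_run_spec`.
#' @export
validate_run_spec <- function(spec) {
  unknown <- setdiff(names(spec), known_spec_keys)
  if (length(unknown)) {
    stop(sprintf("unknown configuration keys: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(spec$preset)) {
    pre <- preset(spec$preset)
    for (k in c("n", "N_H", "N_P")) {
      if (is.null(spec[[k]]) && !is.null(pre[[k]])) spec[[k]] <- pre[[k]]
    }
    merged <- unclass(pre$params)
    merged <- merged[!vapply(merged, is.na, logical(1))]
    merged[names(spec$params)] <- spec$params
    spec$params <- merged
  }
  if (is.null(spec$experiment) || !spec$experiment %in% rq_experiments) {
    stop(sprintf("`experiment` must be one of: %s",
                 paste(rq_experiments, collapse = ", ")), call. = FALSE)
  }
  if (is.null(spec$seed)) {
    stop("an explicit integer `seed` is required for reproducibility",
         call. = FALSE)
  }
  all_models <- c(ct_models, dt_models)
  if (!is.null(spec$model) && !spec$model %in% all_models) {
    stop(sprintf("unknown model '%s' (use %s)", spec$model,
                 paste(all_models, collapse = ", ")), call. = FALSE)
  }
  if (spec$experiment != "sweep" && is.null(spec$model)) {
    stop("`model` is required", call. = FALSE)
  }
  if (is.null(spec$n)) spec$n <- 2L
  spec$n <- as.integer(spec$n)
  # resolve the parameters once; conflicts error here
  spec$params <- unclass(do.call(model_params,
                                 if (is.null(spec$params)) list()
                                 else spec$params))
  stop_keys <- c("t_max", "event_max", "n_max", "stop_on_genotype_loss")
  if (!is.null(spec$stop)) {
    bad <- setdiff(names(spec$stop), stop_keys)
    if (length(bad)) stop(sprintf("unknown stop keys: %s",
                                  paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(spec, class = "rq_run_spec")
}

#' Serialise a run specification
#'
#' Writing then [load_config()]-ing a spec reproduces it exactly.
#'
#' @param spec an `rq_run_spec`.
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
save_config <- function(spec, path) {
  stopifnot(inherits(spec, "rq_run_spec"))
  out <- unclass(spec)
  out$params <- out$params[!vapply(out$params, is.na, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

spec_params <- function(spec) {
  do.call(model_params, spec$params[!vapply(spec$params, is.na, logical(1))])
}

spec_init <- function(spec) {
  if (!is.null(spec$init)) {
    if (!is.null(spec$init$H)) {
      return(population_state(spec$init$H, spec$init$P))
    }
    return(uniform_init(spec$init$N_H, spec$init$N_P, spec$n))
  }
  if (!is.null(spec$N_H) && !is.null(spec$N_P)) {
    return(uniform_init(spec$N_H, spec$N_P, spec$n))
  }
  stop("no initial state: give `init` or `N_H`/`N_P`", call. = FALSE)
}

spec_stop <- function(spec, default_t_max = 1e6) {
  s <- spec$stop
  stop_condition(
    t_max = if (is.null(s$t_max)) default_t_max else s$t_max,
    event_max = if (is.null(s$event_max)) Inf else s$event_max,
    n_max = if (is.null(s$n_max)) Inf else s$n_max,
    stop_on_genotype_loss = if (is.null(s$stop_on_genotype_loss)) TRUE
                            else s$stop_on_genotype_loss)
}

spec_grid <- function(spec, default) {
  g <- spec$t_grid
  if (is.null(g)) return(default)
  seq(g$from, g$to, by = g$by)
}

write_outputs <- function(df, spec, summary = NULL) {
  meta <- unclass(spec)
  if (!is.null(spec$out_csv)) {
    write.csv(df, spec$out_csv, row.names = FALSE)
    jsonlite::write_json(meta, paste0(spec$out_csv, ".spec.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  if (!is.null(spec$out_json)) {
    jsonlite::write_json(list(spec = meta, summary = summary), spec$out_json,
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  invisible(df)
}

#' Execute a validated run specification
#'
#' @param spec an `rq_run_spec`.
#' @return the experiment's tidy result data.frame, invisibly; outputs are
#'   written to `out_csv` / `out_json` when set (each with a JSON sidecar
#'   embedding the resolved spec).
#' @export
run_experiment <- function(spec) {
  stopifnot(inherits(spec, "rq_run_spec"))
  params <- spec_params(spec)
  switch(spec$experiment,
    "simulate" = {
      init <- spec_init(spec)
      if (spec$model %in% dt_models) {
        A <- matching_matrix(2, params$alpha, params$beta)
        stop <- spec_stop(spec)
        res <- simulate_discrete(spec$model, init, A, params$w_H, params$w_P,
                                 seed = spec$seed,
                                 max_steps = min(stop$event_max, 1e8))
        write_outputs(res$trajectory, spec,
                      summary = unclass(res$record))
      } else {
        sys <- build_model(spec$model, spec$n, params,
                           with_mutation = isTRUE(spec$with_mutation))
        res <- simulate_ct(sys, init, spec_stop(spec, 1000),
                           seed = spec$seed)
        write_outputs(res$trajectory, spec,
                      summary = list(record = unclass(res$record),
                                     n_events = res$n_events))
      }
    },
    "ensemble" = {
      reps <- if (is.null(spec$reps)) 100L else as.integer(spec$reps)
      ens <- extinction_ensemble(spec$model, params, spec_init(spec),
                                 n_reps = reps, seed = spec$seed,
                                 stop = spec_stop(spec))
      write_outputs(as.data.frame(ens), spec,
                    summary = list(mean = ens$mean, median = ens$median,
                                   se = ens$se,
                                   censored = ens$censored_count))
    },
    "exact-dt" = {
      init <- spec_init(spec)
      A <- matching_matrix(2, params$alpha, params$beta)
      tau <- exact_mean_extinction_time(spec$model, A, params$w_H,
                                        params$w_P, N_H = sum(init$H),
                                        N_P = sum(init$P))
      df <- as.data.frame(tau)
      central <- tau[as.character(init$H[1]), as.character(init$P[1])]
      write_outputs(df, spec, summary = list(central_start = central))
    },
    "ode" = {
      fp <- interior_fixed_point(spec$model, params, spec$n)
      init <- if (!is.null(spec$init$y)) as.numeric(spec$init$y) else {
        y <- fp; y[1] <- y[1] * 1.2; y[2] <- y[2] - (y[1] - fp[1]); y
      }
      tr <- integrate_ode(spec$model, init, params,
                          spec_grid(spec, seq(0, 50, by = 0.05)), spec$n)
      kind <- if (spec$model %in% c("EcoEvo", "EcoEvoPlus")) "abundance"
              else "frequency"
      write_outputs(cbind(model = spec$model, kind = kind, tr), spec)
    },
    "sweep" = {
      models <- if (is.null(spec$models)) c("EvoPlus", "Evo", "Hybrid",
                                            "EcoEvoPlus", "EcoEvo")
                else unlist(spec$models)
      targets <- if (is.null(spec$N_P_targets)) c(30, 60, 100)
                 else unlist(spec$N_P_targets)
      cells <- fig3_sweep_spec(N_P = targets, models = models)
      reps <- if (is.null(spec$reps)) 100L else as.integer(spec$reps)
      df <- population_size_sweep(cells, n_reps = reps, seed = spec$seed,
                                  stop = spec_stop(spec))
      write_outputs(df, spec)
    },
    "diversity" = {
      reps <- if (is.null(spec$reps)) 100L else as.integer(spec$reps)
      dv <- diversity_time_series(model = spec$model, n = spec$n,
                                  n_reps = reps, seed = spec$seed,
                                  t_grid = spec_grid(spec,
                                                     seq(0, 150, by = 1)),
                                  with_mutation = isTRUE(spec$with_mutation))
      fit <- fit_exponential_decay(dv)
      df <- data.frame(t = dv$t, host_mean = dv$host_mean,
                       parasite_mean = dv$parasite_mean)
      write_outputs(df, spec,
                    summary = list(decay_rate = fit$rate,
                                   r_squared = fit$r_squared))
    })
}

cli_options <- function() {
  list(
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "YAML run configuration"),
    optparse::make_option("--preset", type = "character", default = NULL),
    optparse::make_option("--model", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--reps", type = "integer", default = NULL),
    optparse::make_option("--n", type = "integer", default = NULL),
    optparse::make_option("--NH", type = "integer", default = NULL),
    optparse::make_option("--NP", type = "integer", default = NULL),
    optparse::make_option("--t-max", type = "double", default = NULL,
                          dest = "t_max"),
    optparse::make_option("--mutation", action = "store_true",
                          default = FALSE),
    optparse::make_option("--out", type = "character", default = NULL,
                          help = "output CSV"),
    optparse::make_option("--json", type = "character", default = NULL,
                          help = "output JSON summary"))
}

#' Command-line entry point
#'
#' `Rscript -e 'redqueen::run_cli(...)'` or the shipped launcher
#' `inst/cli/redqueen.R` run one experiment per invocation:
#' `simulate`, `ensemble`, `exact-dt`, `ode`, `sweep`, `diversity`, or
#' `preset-list`. Flags override configuration-file values (with a logged
#' notice). All parameters, the seed and the resolved specification are
#' echoed next to every output file.
#'
#' @param argv character vector of arguments (subcommand first), e.g.
#'   `c("ensemble", "--preset", "fig1", "--model", "EcoEvoPlus", "--reps",
#'   "100", "--seed", "7", "--out", "runs.csv")`.
#' @return integer exit code: 0 on success, 1 on a runtime or validation
#'   error, 2 on a usage error.
#' @export
run_cli <- function(argv) {
  usage <- function() {
    message("usage: redqueen <simulate|ensemble|exact-dt|ode|sweep|",
            "diversity|preset-list> [options]")
    2L
  }
  if (length(argv) < 1L) return(usage())
  cmd <- argv[1]
  if (cmd == "preset-list") {
    cat(paste(preset_list(), collapse = "\n"), "\n", sep = "")
    return(0L)
  }
  if (!cmd %in% rq_experiments) return(usage())
  tryCatch({
    opts <- optparse::parse_args(
      optparse::OptionParser(option_list = cli_options()), argv[-1])
    spec <- if (!is.null(opts$config)) {
      unclass(load_config(opts$config))
    } else list()
    spec$experiment <- cmd
    override <- function(key, value) {
      if (is.null(value)) return()
      if (!is.null(spec[[key]])) {
        message(sprintf("note: flag overrides config value for `%s`", key))
      }
      spec[[key]] <<- value
    }
    override("preset", opts$preset)
    override("model", opts$model)
    override("seed", opts$seed)
    override("reps", opts$reps)
    override("n", opts$n)
    override("N_H", opts$NH)
    override("N_P", opts$NP)
    if (!is.null(opts$t_max)) spec$stop <- c(spec$stop, list(t_max = opts$t_max))
    if (isTRUE(opts$mutation)) spec$with_mutation <- TRUE
    override("out_csv", opts$out)
    override("json", NULL)  # placeholder keeps ordering stable
    if (!is.null(opts$json)) spec$out_json <- opts$json
    spec <- validate_run_spec(spec)
    message(sprintf("running %s (model %s, seed %s)", spec$experiment,
                    if (is.null(spec$model)) "-" else spec$model, spec$seed))
    run_experiment(spec)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
}
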