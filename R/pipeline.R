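#' Write / read BIDS-style events tables
#'
#' Tab-delimited events files with columns `onset`, `duration`,
#' `trial_type`, `scene_id`, `response_time` (seconds; `n/a` when the
#' trial has no assigned response, following the BIDS missing-value
#' convention).
#'
#' @param x a `trial_stream` or `rt_series`; streams are written with
#'   `response_time = n/a` throughout.
#' @param path file path.
#' @return `write_events` returns `path` invisibly; `read_events` returns
#'   a data.frame with numeric `onset`/`duration`/`response_time`.
#' @export
write_events <- function(x, path) {
  isi <- attr(x, "isi")
  df <- data.frame(
    onset = x$onset,
    duration = isi,
    trial_type = x$category,
    scene_id = if (!is.null(x$scene_id)) x$scene_id else NA,
    response_time = if (!is.null(x$rt)) ifelse(is.na(x$rt), "n/a", format(x$rt, digits = 10)) else "n/a",
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(response_time = "character"))
  df$response_time <- suppressWarnings(as.numeric(ifelse(df$response_time == "n/a",
                                                         NA, df$response_time)))
  df
}

default_config <- function() {
  list(
    seed = 1L,
    n_participants = 16L,
    n_runs = 3L,
    n_trials_per_run = 600L,
    isi = 0.8,
    p_mountain = 0.10,
    tr = 2.0,
    volumes_per_run = NULL,       # auto: cover run duration + lag
    hemodynamic_lag = 5,
    dwell_control = 10L,
    amplitude = 1,
    coupling = 1.6,
    sigma_ratio = 1.5,            # State2 sigma / State1 sigma
    mu_ratio = 1,
    tau_ratio = 1,
    omission_state1 = 0.03, omission_state2 = 0.06,
    commission_state1 = 0.25, commission_state2 = 0.35,
    population_means = c(mu = 0.80, sigma = 0.08, tau = 0.05),
    population_sds = c(mu = 0.06, sigma = 0.02, tau = 0.015),
    ambiguous_press_rate = 0.01,
    multipress_rate = 0.01,
    min_trials = 10L
  )
}

validate_config <- function(config) {
  cfg <- utils::modifyList(default_config(), config %||% list())
  check_pos <- function(field, strict = TRUE) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) ||
        (strict && v <= 0) || (!strict && v < 0)) {
      stop(structure(
        class = c("gradstate_config_error", "error", "condition"),
        list(message = sprintf("config field '%s' invalid (%s)", field,
                               paste(v, collapse = ",")), call = sys.call())
      ))
    }
  }
  for (f in c("n_participants", "n_runs", "n_trials_per_run", "isi", "tr",
              "dwell_control", "sigma_ratio", "mu_ratio", "tau_ratio")) check_pos(f)
  for (f in c("p_mountain", "omission_state1", "omission_state2",
              "commission_state1", "commission_state2",
              "ambiguous_press_rate", "multipress_rate")) {
    check_pos(f, strict = FALSE)
    if (cfg[[f]] > 1) stop(structure(
      class = c("gradstate_config_error", "error", "condition"),
      list(message = sprintf("config field '%s' must be a probability", f),
           call = sys.call())
    ))
  }
  if (is.null(cfg$volumes_per_run)) {
    cfg$volumes_per_run <-
      ceiling((cfg$n_trials_per_run * cfg$isi + cfg$hemodynamic_lag) / cfg$tr) + 1L
  }
  cfg
}

#' Simulate a full multi-participant gradCPT + fMRI dataset
#'
#' Co-simulates behavior and network activity under a planted two-state
#' Ising model: per participant, exGaussian parameters are drawn from the
#' population model and modulated by brain state (by default only sigma
#' changes, State2 = `sigma_ratio` x State1), binary network dynamics are
#' sampled by Metropolis from the planted model, and button presses are
#' generated conditional on the lagged state at each trial. Ground truth
#' (generating states, per-trial RTs, the planted model) is retained.
#'
#' @param config named list overriding the default configuration (see the
#'   package vignette for the schema); `config$seed` drives all
#'   randomness through hierarchical seed derivation.
#' @param dir optional directory; when given, events tables, network
#'   series, ground truth and the configuration are written under
#'   `dir/sub-XX/`.
#' @return list of class `gradstate_sim`: `model`, `landscape`,
#'   `templates`, `population`, `participants` (list of runs with
#'   `stream`, `presses`, `truth`, `binary`, `values`, `true_states`),
#'   `config`.
#' @export
simulate_dataset <- function(config = list(), dir = NULL) {
  cfg <- validate_config(config)
  model <- planted_two_state_model(cfg$coupling)
  landscape <- energy_landscape(model)
  templates <- attr(model, "templates")
  pop <- gen_population(
    cfg$n_participants, means = cfg$population_means, sds = cfg$population_sds,
    seed = derive_seed(cfg$seed, 0L)
  )
  participants <- vector("list", cfg$n_participants)
  for (i in seq_len(cfg$n_participants)) {
    p <- pop[i, ]
    state_params <- list()
    state_params[[as.character(templates["state1"])]] <- list(
      mu = p$mu, sigma = p$sigma, tau = p$tau,
      omission_rate = cfg$omission_state1, commission_rate = cfg$commission_state1
    )
    state_params[[as.character(templates["state2"])]] <- list(
      mu = p$mu * cfg$mu_ratio, sigma = p$sigma * cfg$sigma_ratio,
      tau = p$tau * cfg$tau_ratio,
      omission_rate = cfg$omission_state2, commission_rate = cfg$commission_state2
    )
    runs <- vector("list", cfg$n_runs)
    for (r in seq_len(cfg$n_runs)) {
      stream <- gen_trial_stream(cfg$n_trials_per_run, cfg$isi, cfg$p_mountain,
                                 seed = derive_seed(cfg$seed, i, r, 1L))
      net <- gen_network_series(model, cfg$volumes_per_run, cfg$dwell_control,
                                seed = derive_seed(cfg$seed, i, r, 2L),
                                amplitude = cfg$amplitude)
      true_states <- landscape$basin[patterns_to_codes(net$binary) + 1L]
      beh <- gen_behavior(stream, true_states, state_params, cfg$tr,
                          lag = cfg$hemodynamic_lag,
                          ambiguous_press_rate = cfg$ambiguous_press_rate,
                          multipress_rate = cfg$multipress_rate,
                          seed = derive_seed(cfg$seed, i, r, 3L))
      runs[[r]] <- list(stream = stream, presses = beh$presses,
                        truth = beh$truth, binary = net$binary,
                        values = net$values, true_states = true_states)
    }
    participants[[i]] <- runs
  }
  sim <- structure(list(
    model = model, landscape = landscape, templates = templates,
    population = pop, participants = participants, config = cfg
  ), class = "gradstate_sim")
  if (!is.null(dir)) write_sim(sim, dir)
  sim
}

write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- sim$config
  jsonlite::write_json(
    cfg[!vapply(cfg, is.null, logical(1))],
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA
  )
  for (i in seq_along(sim$participants)) {
    sub <- file.path(dir, sprintf("sub-%02d", i))
    dir.create(sub, showWarnings = FALSE)
    for (r in seq_along(sim$participants[[i]])) {
      run <- sim$participants[[i]][[r]]
      base <- file.path(sub, sprintf("sub-%02d_run-%02d", i, r))
      write_events(run$stream, paste0(base, "_events.tsv"))
      utils::write.table(
        data.frame(press = run$presses),
        paste0(base, "_presses.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
      )
      utils::write.table(
        run$values, paste0(base, "_networks.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      utils::write.table(
        run$truth,
        paste0(base, "_truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
      )
    }
  }
  invisible(dir)
}

#' Run the full analysis pipeline
#'
#' simulate (or accept) a dataset, assign presses to trials, fit the group
#' pairwise maximum-entropy model on the concatenated binarized network
#' series, extract the energy landscape and its named states, pool
#' correct-commission RTs by lag-aligned brain state, and compare the
#' exGaussian parameters between State1 and State2.
#'
#' @param config a configuration list (see [simulate_dataset()]), or a
#'   path to a JSON/YAML configuration file.
#' @param out_dir optional report directory; when given, result tables,
#'   a JSON report and a manifest with file checksums are written there.
#' @param sim optionally, an existing `gradstate_sim` to analyze (the
#'   simulation stage is then skipped and `config` ignored).
#' @return object of class `gradstate_report` (see [make_report()]).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, sim = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (is.character(config)) config <- read_config(config)
  if (is.null(sim)) sim <- simulate_dataset(config)
  cfg <- sim$config
  timings <- c(simulate = proc.time()[["elapsed"]] - t0)

  # behavior stage
  t1 <- proc.time()[["elapsed"]]
  rts_by_run <- lapply(sim$participants, function(runs) {
    lapply(runs, function(run) assign_presses(run$stream, run$presses))
  })
  timings["behavior"] <- proc.time()[["elapsed"]] - t1

  # group MEM on concatenated standardized series
  t2 <- proc.time()[["elapsed"]]
  values_all <- do.call(rbind, unlist(lapply(sim$participants, function(runs) {
    lapply(runs, `[[`, "values")
  }), recursive = FALSE))
  binary_all <- binarize(values_all)
  fitted_model <- fit_mem(binary_all, networks = colnames(binary_all))
  fitted_landscape <- energy_landscape(fitted_model)
  quality <- fit_quality(binary_all, fitted_model)
  state_labels <- label_named_states(fitted_landscape)
  timings["mem"] <- proc.time()[["elapsed"]] - t2

  # state series + pooling (group binarization threshold, per-run labels)
  t3 <- proc.time()[["elapsed"]]
  thresholds <- colMeans(values_all)
  pools <- vector("list", length(sim$participants))
  for (i in seq_along(sim$participants)) {
    merged <- list()
    for (r in seq_along(sim$participants[[i]])) {
      run <- sim$participants[[i]][[r]]
      bin <- matrix(0L, nrow(run$values), ncol(run$values))
      bin[sweep(run$values, 2, thresholds, ">")] <- 1L
      ss <- state_series(bin, fitted_landscape, cfg$tr, cfg$hemodynamic_lag)
      pr <- pool_rts(rts_by_run[[i]][[r]], ss)
      for (nm in names(pr$pools)) merged[[nm]] <- c(merged[[nm]], pr$pools[[nm]])
    }
    pools[[i]] <- merged
  }
  timings["pooling"] <- proc.time()[["elapsed"]] - t3

  # comparison between the two named states
  t4 <- proc.time()[["elapsed"]]
  code1 <- names(state_labels)[state_labels == "State1"]
  code2 <- names(state_labels)[state_labels == "State2"]
  comparison <- NULL
  comparison_error <- NULL
  if (length(code1) == 1 && length(code2) == 1) {
    comparison <- tryCatch(
      compare_states(pools, code1, code2, min_trials = cfg$min_trials),
      gradstate_no_result = function(e) {
        comparison_error <<- conditionMessage(e); NULL
      }
    )
  } else {
    comparison_error <- "named states State1/State2 not both present among minima"
  }
  timings["comparison"] <- proc.time()[["elapsed"]] - t4

  report <- make_report(list(
    config = cfg, model = fitted_model, landscape = fitted_landscape,
    quality = quality, state_labels = state_labels,
    comparison = comparison, comparison_error = comparison_error,
    rts_by_run = rts_by_run, timings = timings
  ))
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configurations")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Assemble the pipeline report
#'
#' Collects the stage outputs into a machine-readable summary: model fit
#' quality, the minima table with named-state labels, the per-parameter
#' state comparison (state means, t, df, p, Hedges' g) and all exclusion
#' counts. Missing stages are reported, not fatal.
#'
#' @param stages named list of stage outputs (as built by
#'   [run_pipeline()]).
#' @return object of class `gradstate_report`.
#' @export
make_report <- function(stages) {
  ls <- stages[["landscape"]]
  minima_table <- if (!is.null(ls)) {
    data.frame(
      code = ls$minima,
      label = unname(stages[["state_labels"]][as.character(ls$minima)]),
      energy = ls$energies[ls$minima + 1L],
      basin_probability = vapply(
        ls$minima, function(m) sum(ls$probabilities[ls$basin == m]), numeric(1)
      ),
      active_networks = vapply(ls$minima, function(m) {
        act <- ls$networks[decode_pattern(m, ls$N) == 1]
        if (length(act)) paste(act, collapse = "+") else ""
      }, character(1)),
      stringsAsFactors = FALSE
    )
  } else NULL
  accuracy <- if (!is.null(stages[["rts_by_run"]])) {
    do.call(rbind, lapply(seq_along(stages[["rts_by_run"]]), function(i) {
      runs <- stages[["rts_by_run"]][[i]]
      cnt <- lapply(runs, error_counts)
      data.frame(
        participant = i,
        omission_rate = mean(vapply(cnt, `[[`, numeric(1), "omission_rate")),
        commission_rate = mean(vapply(cnt, `[[`, numeric(1), "commission_rate")),
        tuneout = any(vapply(runs, exclude_tuneouts, logical(1)))
      )
    }))
  } else NULL
  structure(list(
    config = stages[["config"]],
    fit_quality = stages[["quality"]],
    mem_iterations = stages[["model"]]$meta$iterations %||% NA,
    mem_mismatch = stages[["model"]]$meta$mismatch %||% NA,
    minima = minima_table,
    comparison = stages[["comparison"]],
    comparison_error = stages[["comparison_error"]],
    accuracy = accuracy,
    timings = stages[["timings"]]
  ), class = "gradstate_report")
}

#' @export
print.gradstate_report <- function(x, ...) {
  cat("gradstate pipeline report\n")
  cat(sprintf("  MEM fit: r(empirical, model pattern probabilities) = %.4f; %d iterations, moment mismatch %.1e\n",
              x$fit_quality, x$mem_iterations, x$mem_mismatch))
  if (is.null(x$minima) || nrow(x$minima) == 0) {
    cat("  no states found: the energy landscape has no local minima table\n")
  } else {
    cat(sprintf("  %d local minima:\n", nrow(x$minima)))
    print(x$minima, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$comparison)) {
    cat("  exGaussian parameters by state:\n")
    print(x$comparison$table, row.names = FALSE, digits = 4)
    cat(sprintf("  included %d participants, excluded %d\n",
                x$comparison$n_included, nrow(x$comparison$exclusions)))
  } else {
    cat("  state comparison unavailable:", x$comparison_error %||% "not run", "\n")
  }
  invisible(x)
}

report_to_list <- function(report) {
  out <- list(
    fit_quality = report$fit_quality,
    mem_iterations = report$mem_iterations,
    mem_mismatch = report$mem_mismatch,
    minima = report$minima,
    comparison = if (!is.null(report$comparison)) list(
      table = report$comparison$table,
      n_included = report$comparison$n_included,
      n_excluded = nrow(report$comparison$exclusions),
      exclusion_reasons = as.list(table(report$comparison$exclusions$reason))
    ) else NULL,
    comparison_error = report$comparison_error
  )
  # timings stay in the R object only: serialized reports must be
  # byte-identical across reruns of the same seed
  out[!vapply(out, is.null, logical(1))]
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  jpath <- file.path(out_dir, "report.json")
  jsonlite::write_json(report_to_list(report), jpath, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  paths <- c(paths, jpath)
  if (!is.null(report$minima)) {
    p <- file.path(out_dir, "minima.tsv")
    utils::write.table(report$minima, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(report$comparison)) {
    p <- file.path(out_dir, "state_comparison.tsv")
    utils::write.table(report$comparison$table, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(report$accuracy)) {
    p <- file.path(out_dir, "accuracy.tsv")
    utils::write.table(report$accuracy, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest <- data.frame(
    file = basename(paths),
    md5 = unname(tools::md5sum(paths)),
    stringsAsFactors = FALSE
  )
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
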