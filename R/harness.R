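#' Optimization and orchestration harness
#'
#' CMA-ES driver with the shipped optimizer settings and stopping rules,
#' the belt-speed ramp protocol, configuration files, run manifests, and a
#' command-line front end.
#'
#' @name harness
NULL

#' Optimizer settings
#'
#' @param lambda population size (default 16).
#' @param sigma initial step size (default 1).
#' @param max_generations generation budget; 200 is a desk-scale default
#'   (full-dynamics runs use far larger budgets).
#' @param stop_window moving-average stopping window, generations.
#' @param stop_tol stopping improvement threshold.
#' @param seed integer RNG seed.
#' @return named list of settings.
#' @export
optimizer_settings <- function(lambda = 16, sigma = 1, max_generations = 200,
                               stop_window = 500, stop_tol = 1e-4,
                               seed = 1L) {
  stopifnot(lambda >= 2, sigma > 0)
  list(lambda = lambda, sigma = sigma, max_generations = max_generations,
       stop_window = stop_window, stop_tol = stop_tol, seed = as.integer(seed))
}

#' Optimize a parameter registry with CMA-ES
#'
#' Runs [cma_es()] over the registry's genotype vector within its bounds.
#' The objective receives a registry (the candidate vector applied via
#' [apply_vector()]) and must return a finite cost; non-finite costs are
#' penalized inside the optimizer.
#'
#' @param objective_fn function(registry) -> scalar cost.
#' @param registry a [build_parameter_registry()] result (defines the
#'   genotype layout, start values, and bounds).
#' @param settings an [optimizer_settings()].
#' @return list with `registry` (best parameters applied), `f_best`,
#'   `history`, `generations`, `stopped_by`.
#' @export
run_cmaes <- function(objective_fn, registry,
                      settings = optimizer_settings()) {
  set.seed(settings$seed)
  fn <- function(x) {
    reg <- suppressWarnings(apply_vector(registry, x))
    objective_fn(reg)
  }
  res <- cma_es(fn, x0 = extract_vector(registry),
                sigma = settings$sigma, lambda = settings$lambda,
                max_generations = settings$max_generations,
                stop_window = settings$stop_window,
                stop_tol = settings$stop_tol,
                lower = registry$lower, upper = registry$upper)
  best <- suppressWarnings(apply_vector(registry, res$x_best))
  list(registry = best, f_best = res$f_best, history = res$history,
       generations = res$generations, stopped_by = res$stopped_by)
}

#' Belt-speed ramp protocol
#'
#' Stages optimizations from tied belts to the full split: the slow-belt
#' speed is lowered from `start_speeds[2]` to `end_speeds[2]` in `step`
#' increments, and each stage is warm-started from the previous stage's
#' best registry.
#'
#' @param start_speeds `c(v_fast, v_slow)` of the first stage (m/s),
#'   typically `c(1, 1)`.
#' @param end_speeds `c(v_fast, v_slow)` of the final stage, typically
#'   `c(1, 0.5)`.
#' @param step decrement, m/s (must divide the speed gap).
#' @param optimize_fn function(speeds, registry) -> list with elements
#'   `registry` and `f_best` (e.g. a wrapper around [run_cmaes()]).
#' @param registry initial registry for the first stage.
#' @return list of per-stage results (`speeds`, `registry`, `f_best`).
#' @export
ramp_protocol <- function(start_speeds, end_speeds, step, optimize_fn,
                          registry) {
  gap <- start_speeds[2] - end_speeds[2]
  if (step <= 0) stop("step must be positive")
  k <- gap / step
  if (abs(k - round(k)) > 1e-9) stop("step must divide the belt-speed gap")
  slow_speeds <- seq(start_speeds[2], end_speeds[2], by = -step)
  stages <- vector("list", length(slow_speeds))
  for (i in seq_along(slow_speeds)) {
    speeds <- c(start_speeds[1], slow_speeds[i])
    res <- optimize_fn(speeds, registry)
    if (is.null(res$f_best) || !is.finite(res$f_best)) {
      stop(sprintf("ramp stage %d (v_slow = %.2f) produced no finite-cost solution",
                   i, slow_speeds[i]))
    }
    registry <- res$registry
    stages[[i]] <- list(speeds = speeds, registry = res$registry,
                        f_best = res$f_best)
  }
  stages
}

#' Read/write sectioned key-value configuration files
#'
#' Plain-text configuration with `[section]` headers and `key = value`
#' lines; values are parsed as numeric when possible. Sections used by the
#' tools: model, controller, cerebellum, plant, objective, optimizer.
#'
#' @param path file path.
#' @return nested named list (section -> key -> value).
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cfg <- list()
  section <- "global"
  for (ln in lines) {
    ln <- sub("[#;].*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    m <- regmatches(ln, regexec("^\\[(.+)\\]$", ln))[[1]]
    if (length(m) == 2L) {
      section <- m[2]
      next
    }
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(kv) != 3L) stop(sprintf("malformed configuration line: '%s'", ln))
    key <- trimws(kv[2])
    val <- trimws(kv[3])
    num <- suppressWarnings(as.numeric(val))
    cfg[[section]][[key]] <- if (!is.na(num)) num else val
  }
  cfg
}

#' @rdname read_config
#' @param cfg nested named list.
#' @export
write_config <- function(cfg, path) {
  out <- character(0)
  for (section in names(cfg)) {
    out <- c(out, sprintf("[%s]", section))
    for (key in names(cfg[[section]])) {
      out <- c(out, sprintf("%s = %s", key, format(cfg[[section]][[key]],
                                                   digits = 15)))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Run manifest
#'
#' Snapshot that makes a run reproducible: the configuration, the seed(s),
#' a content hash of the serialized configuration, and the output paths.
#'
#' @param cfg configuration list.
#' @param seed integer seed.
#' @param outputs named character vector of output paths.
#' @return object of class `run_manifest`.
#' @export
run_manifest <- function(cfg, seed, outputs = character(0)) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(list(cfg = cfg, seed = seed), tmp)
  hash <- unname(tools::md5sum(tmp))
  structure(list(config = cfg, seed = as.integer(seed),
                 content_hash = hash, outputs = outputs),
            class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path file path for the plain-text manifest.
#' @export
write_manifest <- function(manifest, path) {
  lines <- c(sprintf("seed = %d", manifest$seed),
             sprintf("content_hash = %s", manifest$content_hash))
  for (nm in names(manifest$outputs)) {
    lines <- c(lines, sprintf("output.%s = %s", nm, manifest$outputs[[nm]]))
  }
  lines <- c(lines, "")
  for (section in names(manifest$config)) {
    lines <- c(lines, sprintf("[%s]", section))
    sec <- manifest$config[[section]]
    for (key in names(sec)) {
      lines <- c(lines, sprintf("%s = %s", key, format(sec[[key]], digits = 15)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

parse_cli_flags <- function(argv) {
  flags <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop(sprintf("unexpected argument '%s'", a))
    key <- sub("^--", "", a)
    if (i == length(argv) || startsWith(argv[i + 1L], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      val <- argv[i + 1L]
      num <- suppressWarnings(as.numeric(val))
      flags[[key]] <- if (!is.na(num)) num else val
      i <- i + 2L
    }
  }
  flags
}

cli_usage <- function() {
  paste(
    "usage: splitbeltsim <subcommand> [--flag value ...]",
    "subcommands:",
    "  simulate  open-loop surrogate strides",
    "            [--strides N] [--seed S] [--out DIR] [--v-fast V] [--v-slow V]",
    "  adapt     closed-loop strides with the cerebellum",
    "            [--alpha A] [--beta B] [--strides N] [--seed S] [--out DIR]",
    "  optimize  CMA-ES over the surrogate thresholds",
    "            [--generations G] [--lambda L] [--sigma S] [--seed S] [--out DIR]",
    "  analyze   stride table -> asymmetry series + exponential fits",
    "            --table FILE [--out DIR]",
    "  fixtures  synthetic datasets",
    "            --kind symmetric_gait|splitbelt_gait|noisy_exponential_series",
    "            [--strides N] [--seed S] [--out DIR]",
    sep = "\n")
}

#' Command-line entry point
#'
#' Thin front end over the package functions; see `inst/cli/splitbeltsim`
#' for the executable wrapper. Every run writes its outputs plus a
#' plain-text run manifest into `--out` (default `"."`).
#'
#' @param argv character vector of arguments (subcommand first).
#' @return exit status, invisibly (0 on success).
#' @export
gait_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0L) {
    message(cli_usage())
    return(invisible(1L))
  }
  sub <- argv[1]
  flags <- tryCatch(parse_cli_flags(argv[-1]),
                    error = function(e) e)
  if (inherits(flags, "error")) {
    message(conditionMessage(flags), "\n", cli_usage())
    return(invisible(1L))
  }
  out_dir <- flags[["out"]] %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(flags[["seed"]] %||% 1L)
  p <- function(f) file.path(out_dir, f)

  write_run <- function(cfg, outputs) {
    write_manifest(run_manifest(cfg, seed, outputs), p("manifest.txt"))
  }

  status <- tryCatch({
    if (sub == "simulate" || sub == "adapt") {
      plant <- plant_parameters(
        v_fast = flags[["v-fast"]] %||% 1.0,
        v_slow = flags[["v-slow"]] %||% 0.5,
        noise_sd = flags[["noise-sd"]] %||% 0)
      alpha <- if (sub == "simulate") 0 else flags[["alpha"]] %||% 0.002
      beta <- if (sub == "simulate") 0 else flags[["beta"]] %||% 0.02
      n <- as.integer(flags[["strides"]] %||% 80L)
      sim <- run_closed_loop(plant, cerebellar_state(alpha = alpha, beta = beta),
                             n_strides = n, seed = seed)
      write_stride_table(sim$table, p("strides.tsv"))
      utils::write.table(sim$trace, p("cerebellar_trace.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_run(list(plant = unclass(plant),
                     cerebellum = list(alpha = alpha, beta = beta),
                     run = list(subcommand = sub, n_strides = n)),
                c(strides = p("strides.tsv"), trace = p("cerebellar_trace.tsv")))
      0L
    } else if (sub == "optimize") {
      plant <- plant_parameters()
      cfg <- default_controller_config()
      cfg$reflex <- cfg$reflex[0, ]      # surrogate: thresholds only
      registry <- build_parameter_registry(cfg, cerebellum_enabled = FALSE)
      settings <- optimizer_settings(
        lambda = as.integer(flags[["lambda"]] %||% 16L),
        sigma = flags[["sigma"]] %||% 1,
        max_generations = as.integer(flags[["generations"]] %||% 50L),
        seed = seed)
      target <- flags[["target-sla"]] %||% 0
      obj <- function(reg) {
        v <- extract_vector(reg)
        sim <- try(run_closed_loop(plant,
                                   cerebellar_state(alpha = 0, beta = 0,
                                                    t_fast = v[["t_fast"]],
                                                    t_slow = v[["t_slow"]]),
                                   n_strides = 10, seed = seed), silent = TRUE)
        if (inherits(sim, "try-error")) return(1e6)
        mean((sim$records$sla - target)^2)
      }
      res <- run_cmaes(obj, registry, settings)
      write_registry(res$registry, p("best_registry.tsv"))
      utils::write.table(res$history, p("fitness_history.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_run(list(optimizer = settings,
                     run = list(subcommand = sub, f_best = res$f_best)),
                c(registry = p("best_registry.tsv"),
                  history = p("fitness_history.tsv")))
      0L
    } else if (sub == "analyze") {
      tab_path <- flags[["table"]]
      if (is.null(tab_path)) stop("analyze requires --table FILE")
      tab <- read_stride_table(tab_path)
      fast <- tab[tab$side == "fast", ]
      slow <- tab[tab$side == "slow", ]
      strides <- sort(intersect(fast$stride, slow$stride))
      lf <- fast$step_length_m[match(strides, fast$stride)]
      ls <- slow$step_length_m[match(strides, slow$stride)]
      df <- fast$step_time_s[match(strides, fast$stride)]
      ds <- slow$step_time_s[match(strides, slow$stride)]
      series <- data.frame(stride = strides,
                           sla = sla(lf, ls),
                           sva = step_velocity_asymmetry(lf / df, ls / ds))
      utils::write.table(series, p("asymmetry_series.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      fits <- list(fast = fit_exponential(lf), slow = fit_exponential(ls),
                   sla = fit_exponential(series$sla))
      fit_tab <- do.call(rbind, lapply(names(fits), function(nm) {
        f <- fits[[nm]]
        data.frame(series = nm, a = f$a, b = f$b, c = f$c,
                   residual_norm = f$residual_norm, converged = f$converged)
      }))
      utils::write.table(fit_tab, p("exponential_fits.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_run(list(run = list(subcommand = sub, table = tab_path)),
                c(series = p("asymmetry_series.tsv"),
                  fits = p("exponential_fits.tsv")))
      0L
    } else if (sub == "fixtures") {
      kind <- flags[["kind"]]
      if (is.null(kind)) stop("fixtures requires --kind KIND")
      params <- list()
      if (!is.null(flags[["strides"]])) params$n_strides <- as.integer(flags[["strides"]])
      fx <- make_fixtures(kind, params, seed = seed)
      if (is.data.frame(fx)) {
        utils::write.table(fx, p("series.tsv"), sep = "\t", quote = FALSE,
                           row.names = FALSE)
        outs <- c(series = p("series.tsv"))
      } else {
        write_stride_table(fx$table, p("strides.tsv"))
        utils::write.table(fx$events, p("events.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        outs <- c(strides = p("strides.tsv"), events = p("events.tsv"))
      }
      write_run(list(run = list(subcommand = sub, kind = kind)), outs)
      0L
    } else {
      message(sprintf("unknown subcommand '%s'\n%s", sub, cli_usage()))
      1L
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e), "\n", cli_usage())
    1L
  })
  invisible(status)
}
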