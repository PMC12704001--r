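test_that("CMA-ES solves the 4-D sphere to 1e-6 within 200 generations", {
  set.seed(11)
  res <- cma_es(function(x) sum(x^2), x0 = rep(3, 4), sigma = 1, lambda = 16,
                max_generations = 200)
  expect_lt(res$f_best, 1e-6)
})

test_that("generation budget and window stopping rule are honored", {
  set.seed(1)
  one <- cma_es(function(x) sum(x^2), x0 = c(1, 1), sigma = 1, lambda = 8,
                max_generations = 1)
  expect_equal(one$generations, 1)
  expect_equal(one$stopped_by, "max_generations")

  # flat objective: zero improvement triggers the moving-window rule
  set.seed(1)
  flat <- cma_es(function(x) 7, x0 = c(0, 0), sigma = 1, lambda = 4,
                 max_generations = 1000, stop_window = 5, stop_tol = 1e-4)
  expect_equal(flat$stopped_by, "window")
  expect_lte(flat$generations, 3 * 5)
})

test_that("non-finite candidate costs are penalized, not fatal", {
  set.seed(3)
  res <- cma_es(function(x) if (x[1] > 0) NaN else sum(x^2),
                x0 = c(0.5, 0.5), sigma = 0.5, lambda = 8,
                max_generations = 30)
  expect_gt(res$n_nonfinite, 0)
  expect_true(is.finite(res$f_best))
})

test_that("run_cmaes optimizes a registry within its bounds", {
  cfg <- default_controller_config()
  cfg$reflex <- cfg$reflex[0, ]   # two threshold parameters only
  reg <- build_parameter_registry(cfg, cerebellum_enabled = FALSE)
  target <- c(t_fast = 0.25, t_slow = 0.4)
  obj <- function(r) sum((extract_vector(r) - target)^2)
  res <- run_cmaes(obj, reg, optimizer_settings(lambda = 8, sigma = 0.3,
                                                max_generations = 60, seed = 5))
  expect_lt(res$f_best, 1e-4)
  v <- extract_vector(res$registry)
  expect_equal(unname(v["t_fast"]), 0.25, tolerance = 0.05)
  expect_equal(unname(v["t_slow"]), 0.40, tolerance = 0.05)
  expect_true(all(v >= reg$lower & v <= reg$upper))
})

test_that("the belt-speed ramp stages from tied to 2:1 belts", {
  cfg <- default_controller_config()
  cfg$reflex <- cfg$reflex[0, ]
  reg <- build_parameter_registry(cfg, FALSE)
  seen <- list()
  opt <- function(speeds, registry) {
    seen[[length(seen) + 1L]] <<- speeds
    list(registry = registry, f_best = 1)
  }
  stages <- ramp_protocol(c(1, 1), c(1, 0.5), 0.1, opt, reg)
  expect_length(stages, 6)
  expect_equal(vapply(seen, `[`, 0, 2), seq(1, 0.5, by = -0.1))

  expect_length(ramp_protocol(c(1, 1), c(1, 0.5), 0.5, opt, reg), 2)
  expect_error(ramp_protocol(c(1, 1), c(1, 0.5), 0.3, opt, reg), "divide")
  expect_error(
    ramp_protocol(c(1, 1), c(1, 0.5), 0.5,
                  function(speeds, registry) list(registry = registry,
                                                  f_best = NaN), reg),
    "stage 1")
})

test_that("sectioned configuration files round-trip", {
  cfg <- list(plant = list(v_fast = 1, v_slow = 0.5, noise_sd = 0.005),
              cerebellum = list(alpha = 0.002, beta = 0.02,
                                convention = "analytic"))
  path <- withr::local_tempfile(fileext = ".ini")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$plant$v_slow, 0.5)
  expect_equal(back$cerebellum$alpha, 0.002)
  expect_equal(back$cerebellum$convention, "analytic")
  expect_error(read_config(withr::local_tempfile(lines = "no equals sign here")),
               "malformed")
})

test_that("manifests hash their configuration deterministically", {
  cfg <- list(plant = list(v_fast = 1))
  m1 <- run_manifest(cfg, seed = 3)
  m2 <- run_manifest(cfg, seed = 3)
  expect_equal(m1$content_hash, m2$content_hash)
  m3 <- run_manifest(cfg, seed = 4)
  expect_false(m1$content_hash == m3$content_hash)
  path <- withr::local_tempfile()
  write_manifest(m1, path)
  expect_true(any(grepl("content_hash", readLines(path))))
})

test_that("the CLI runs adapt/analyze/fixtures and reports usage errors", {
  out1 <- withr::local_tempdir()
  status <- gait_cli(c("adapt", "--alpha", "0.002", "--beta", "0.02",
                       "--strides", "12", "--seed", "1", "--out", out1))
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(out1, "strides.tsv")))
  expect_true(file.exists(file.path(out1, "cerebellar_trace.tsv")))
  expect_true(file.exists(file.path(out1, "manifest.txt")))

  # no-cerebellum analogue: SLA is constant
  out2 <- withr::local_tempdir()
  gait_cli(c("adapt", "--alpha", "0", "--beta", "0",
             "--strides", "10", "--seed", "1", "--out", out2))
  tab <- read_stride_table(file.path(out2, "strides.tsv"))
  fast <- tab[tab$side == "fast", ]
  slow <- tab[tab$side == "slow", ]
  s <- sla(fast$step_length_m, slow$step_length_m)
  expect_equal(diff(s), rep(0, length(s) - 1), tolerance = 1e-9)

  # analyze a symmetric fixture table: SLA column all zeros
  out3 <- withr::local_tempdir()
  fx <- symmetric_fixture(6)
  tpath <- file.path(out3, "sym.tsv")
  write_stride_table(fx$table, tpath)
  expect_equal(gait_cli(c("analyze", "--table", tpath, "--out", out3)), 0L)
  series <- utils::read.table(file.path(out3, "asymmetry_series.tsv"),
                              header = TRUE, sep = "\t")
  expect_equal(series$sla, rep(0, nrow(series)), tolerance = 1e-9)

  # fixtures subcommand writes a series
  out4 <- withr::local_tempdir()
  expect_equal(gait_cli(c("fixtures", "--kind", "noisy_exponential_series",
                          "--out", out4)), 0L)
  expect_true(file.exists(file.path(out4, "series.tsv")))

  expect_equal(suppressMessages(gait_cli(c("frobnicate"))), 1L)
  expect_equal(suppressMessages(gait_cli(character(0))), 1L)
})

test_that("identical seeds and flags give byte-identical stride tables", {
  o1 <- withr::local_tempdir()
  o2 <- withr::local_tempdir()
  args <- c("adapt", "--strides", "10", "--seed", "7", "--noise-sd", "0.005")
  gait_cli(c(args, "--out", o1))
  gait_cli(c(args, "--out", o2))
  expect_identical(readLines(file.path(o1, "strides.tsv")),
                   readLines(file.path(o2, "strides.tsv")))
})

test_that("the rate grid runs as one batch and stays ordered", {
  # the four (alpha, beta) cells run as a simple batch loop
  grid <- expand.grid(alpha = c(0.01, 0.05), beta = c(0.01, 0.04))
  runs <- lapply(seq_len(nrow(grid)), function(i) {
    run_closed_loop(plant_parameters(),
                    cerebellar_state(alpha = grid$alpha[i], beta = grid$beta[i]),
                    n_strides = 20, seed = 1)$records$sla
  })
  expect_length(runs, 4)
  avg <- average_stride_series(runs)
  expect_equal(nrow(avg), 20)
  expect_true(all(avg$n == 4))
})
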