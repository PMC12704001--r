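#' Musculoskeletal model descriptor and free-parameter registry
#'
#' The descriptor is a declarative registry of the planar walker: a
#' pelvis-trunk segment and two legs (thigh, shank, foot), six pin joints
#' (hip/knee/ankle per side), a planar 3-DOF pelvis-ground joint, a locked
#' lumbar joint, and seven Hill-type muscle groups per leg. It carries
#' counts and names only -- no inertia, geometry, or contact -- so parameter
#' layouts are testable without a dynamics engine.
#'
#' @name model_registry
NULL

MUSCLE_GROUPS <- c("HAM", "GLU", "IL", "VAS", "GAS", "SOL", "TA")

#' Default model configuration
#'
#' @return nested list naming the shipped default planar layout.
#' @export
default_model_config <- function() {
  list(
    segments = c("pelvis_trunk",
                 "thigh_left", "shank_left", "foot_left",
                 "thigh_right", "shank_right", "foot_right"),
    joints = list(
      list(name = "pelvis_ground", kind = "planar-3dof", dof_count = 3L),
      list(name = "hip_left",    kind = "pin", dof_count = 1L),
      list(name = "knee_left",   kind = "pin", dof_count = 1L),
      list(name = "ankle_left",  kind = "pin", dof_count = 1L),
      list(name = "hip_right",   kind = "pin", dof_count = 1L),
      list(name = "knee_right",  kind = "pin", dof_count = 1L),
      list(name = "ankle_right", kind = "pin", dof_count = 1L),
      list(name = "lumbar", kind = "locked", dof_count = 0L)
    ),
    muscles_per_leg = MUSCLE_GROUPS,
    lumbar_angle_deg = 8.5
  )
}

#' Build the model descriptor
#'
#' Validates a model configuration against the structural invariants
#' (exactly two legs, the seven named muscle groups per leg, 3 DOF at the
#' pelvis-ground joint, 1 DOF per hip/knee/ankle, 0 for locked joints) and
#' returns a `model_descriptor`.
#'
#' @param config a configuration list as from [default_model_config()].
#' @return object of class `model_descriptor`.
#' @export
build_default_descriptor <- function(config = default_model_config()) {
  for (f in c("segments", "joints", "muscles_per_leg", "lumbar_angle_deg")) {
    if (is.null(config[[f]])) stop(sprintf("configuration error: missing field '%s'", f))
  }
  if (!setequal(config$muscles_per_leg, MUSCLE_GROUPS)) {
    missing <- setdiff(MUSCLE_GROUPS, config$muscles_per_leg)
    extra <- setdiff(config$muscles_per_leg, MUSCLE_GROUPS)
    stop(sprintf("configuration error: field 'muscles_per_leg' invalid (missing: %s; unknown: %s)",
                 paste(missing, collapse = ","), paste(extra, collapse = ",")))
  }
  kinds <- vapply(config$joints, `[[`, "", "kind")
  dofs <- vapply(config$joints, function(j) as.integer(j$dof_count), 1L)
  if (!all(kinds %in% c("pin", "planar-3dof", "locked"))) {
    stop("configuration error: field 'joints' has an unknown joint kind")
  }
  expected <- c(pin = 1L, `planar-3dof` = 3L, locked = 0L)
  bad <- which(dofs != expected[kinds])
  if (length(bad)) {
    stop(sprintf("configuration error: joint '%s' has dof_count %d, expected %d",
                 config$joints[[bad[1]]]$name, dofs[bad[1]], expected[kinds[bad[1]]]))
  }
  if (sum(kinds == "pin") != 6L) {
    stop("configuration error: field 'joints' must list six pin joints (hip/knee/ankle per side)")
  }
  if (sum(kinds == "planar-3dof") != 1L) {
    stop("configuration error: field 'joints' must list one planar-3dof pelvis-ground joint")
  }
  muscles <- rbind(
    data.frame(name = config$muscles_per_leg, side = "left",
               stringsAsFactors = FALSE),
    data.frame(name = config$muscles_per_leg, side = "right",
               stringsAsFactors = FALSE)
  )
  structure(list(segments = config$segments,
                 joints = config$joints,
                 muscles = muscles,
                 lumbar_angle_deg = config$lumbar_angle_deg),
            class = "model_descriptor")
}

#' Total degrees of freedom of a descriptor
#'
#' @param descriptor a `model_descriptor`.
#' @return integer sum of all joint DOF counts (9 for the default layout).
#' @export
count_dofs <- function(descriptor) {
  stopifnot(inherits(descriptor, "model_descriptor"))
  sum(vapply(descriptor$joints, function(j) as.integer(j$dof_count), 1L))
}

#' @export
print.model_descriptor <- function(x, ...) {
  cat("Planar walker descriptor\n")
  cat(sprintf("  segments: %d; joints: %d (%d DOF); lumbar locked at %.1f deg\n",
              length(x$segments), length(x$joints), count_dofs(x),
              x$lumbar_angle_deg))
  cat(sprintf("  muscles: %d per leg (%s)\n",
              sum(x$muscles$side == "left"),
              paste(unique(x$muscles$name), collapse = ", ")))
  invisible(x)
}

# One leg's reflex-law template: each row is one free scalar of the spinal
# controller. 31 rows per leg -> 62 reflex parameters for the biped. The
# grouping into laws (column `law`) drives muscle_excitations(); `param`
# says which slot of the law the scalar fills. Values are plausible
# Geyer-style placeholders (the published enumeration lives in supplementary
# material not reproduced here) and are free parameters of the optimizer.
leg_reflex_template <- function() {
  r <- function(law, target, kind, sign, source, phases, param, value)
    data.frame(law = law, target = target, kind = kind, sign = sign,
               source = source, phases = phases, param = param,
               value = value, stringsAsFactors = FALSE)
  rbind(
    r("SOL_F_st",  "SOL", "F",  1L, "SOL", "ES,MS,PS", "gain",     1.20),
    r("TA_L_all",  "TA",  "L",  1L, "TA",  "ES,MS,PS,SW,LP", "gain",   1.10),
    r("TA_L_all",  "TA",  "L",  1L, "TA",  "ES,MS,PS,SW,LP", "offset", 0.60),
    r("TA_Fsol_st","TA",  "F", -1L, "SOL", "ES,MS,PS", "gain",     0.40),
    r("GAS_F_st",  "GAS", "F",  1L, "GAS", "ES,MS,PS", "gain",     1.10),
    r("VAS_F_st",  "VAS", "F",  1L, "VAS", "ES,MS",    "gain",     1.00),
    r("VAS_C_es",  "VAS", "C",  1L, NA,    "ES",       "constant", 0.09),
    r("HAM_PD_st", "HAM", "PD", 1L, NA,    "ES,MS,PS", "kp",       1.90),
    r("HAM_PD_st", "HAM", "PD", 1L, NA,    "ES,MS,PS", "kd",       0.25),
    r("HAM_PD_st", "HAM", "PD", 1L, NA,    "ES,MS,PS", "theta_ref", 0.105),
    r("GLU_PD_st", "GLU", "PD", 1L, NA,    "ES,MS,PS", "kp",       1.10),
    r("GLU_PD_st", "GLU", "PD", 1L, NA,    "ES,MS,PS", "kd",       0.25),
    r("IL_PD_st",  "IL",  "PD", -1L, NA,   "ES,MS,PS", "kp",       1.90),
    r("IL_PD_st",  "IL",  "PD", -1L, NA,   "ES,MS,PS", "kd",       0.25),
    r("IL_L_sw",   "IL",  "L",  1L, "IL",  "PS,SW",    "gain",     0.35),
    r("IL_L_sw",   "IL",  "L",  1L, "IL",  "PS,SW",    "offset",   0.55),
    r("IL_C_sw",   "IL",  "C",  1L, NA,    "SW",       "constant", 0.05),
    r("HAM_F_sw",  "HAM", "F",  1L, "HAM", "SW,LP",    "gain",     0.65),
    r("IL_Lham_sw","IL",  "L", -1L, "HAM", "SW",       "gain",     4.00),
    r("IL_Lham_sw","IL",  "L", -1L, "HAM", "SW",       "offset",   0.85),
    r("GLU_C_sw",  "GLU", "C",  1L, NA,    "SW",       "constant", 0.05),
    r("HAM_C_lp",  "HAM", "C",  1L, NA,    "LP",       "constant", 0.05),
    r("GLU_F_lp",  "GLU", "F",  1L, "GLU", "LP",       "gain",     0.40),
    r("VAS_F_lp",  "VAS", "F",  1L, "VAS", "LP",       "gain",     0.60),
    r("GAS_C_ps",  "GAS", "C",  1L, NA,    "PS",       "constant", 0.03),
    r("TA_C_sw",   "TA",  "C",  1L, NA,    "SW",       "constant", 0.25),
    r("HAM_L_lp",  "HAM", "L",  1L, "HAM", "LP",       "gain",     0.65),
    r("HAM_L_lp",  "HAM", "L",  1L, "HAM", "LP",       "offset",   0.85),
    r("GLU_L_lp",  "GLU", "L",  1L, "GLU", "LP",       "gain",     0.40),
    r("GLU_L_lp",  "GLU", "L",  1L, "GLU", "LP",       "offset",   0.70),
    r("VAS_C_lp",  "VAS", "C",  1L, NA,    "LP",       "constant", 0.08)
  )
}

#' Default spinal controller configuration
#'
#' Enumerates the reflex laws of the shipped controller (force, length,
#' constant and pelvis-PD laws, phase-gated per the five-phase state
#' machine), duplicated for the two legs: 31 free scalars per leg, 62 in
#' total. Also carries the initial swing-initiation thresholds and the
#' per-channel neural delays (5--20 ms by anatomical distance).
#'
#' @param t_fast,t_slow initial swing-initiation thresholds, seconds.
#' @return nested configuration list with elements `reflex` (data frame,
#'   one row per free scalar), `thresholds`, `delays_s`.
#' @export
default_controller_config <- function(t_fast = 0.35, t_slow = 0.35) {
  tpl <- leg_reflex_template()
  reflex <- do.call(rbind, lapply(c("fast", "slow"), function(side) {
    d <- tpl
    d$side <- side
    d$name <- paste(side, d$law, d$param, sep = ".")
    d
  }))
  rownames(reflex) <- NULL
  list(
    reflex = reflex,
    thresholds = c(t_fast = t_fast, t_slow = t_slow),
    delays_s = c(SOL = 0.020, GAS = 0.020, TA = 0.020, VAS = 0.010,
                 HAM = 0.010, GLU = 0.005, IL = 0.005, pelvis = 0.005)
  )
}

default_bounds <- function(group, value) {
  if (group == "timing_threshold") return(c(0, 1))
  if (group == "cerebellar_rate") return(c(1e-5, 1))
  # gains/offsets/constants: one order of magnitude around the default
  v <- abs(value)
  if (v == 0) return(c(-1, 1))
  sort(c(value / 10, value * 10))
}

#' Build the free-parameter registry
#'
#' Lays out the optimizer genotype: the reflex scalars of the controller
#' configuration (62 for the shipped default), the two swing-initiation
#' thresholds, and -- when the cerebellum is enabled -- the learning rate
#' `alpha` and adaptation rate `beta`. Ordering is deterministic (the
#' enumeration order of the configuration), so two registries built from the
#' same configuration have identical genotype layouts.
#'
#' @param controller_config as from [default_controller_config()].
#' @param cerebellum_enabled logical; append `alpha`, `beta`?
#' @param alpha,beta initial cerebellar rates used when enabled.
#' @return object of class `parameter_registry`: data frame with columns
#'   `name`, `group`, `value`, `lower`, `upper` plus attribute
#'   `cerebellum_enabled`.
#' @export
build_parameter_registry <- function(controller_config = default_controller_config(),
                                     cerebellum_enabled = FALSE,
                                     alpha = 0.002, beta = 0.02) {
  rows <- list()
  rf <- controller_config$reflex
  if (!is.null(rf) && nrow(rf)) {
    for (i in seq_len(nrow(rf))) {
      b <- default_bounds("reflex", rf$value[i])
      rows[[length(rows) + 1L]] <-
        data.frame(name = rf$name[i], group = "reflex", value = rf$value[i],
                   lower = b[1], upper = b[2], stringsAsFactors = FALSE)
    }
  }
  th <- controller_config$thresholds
  for (nm in names(th)) {
    b <- default_bounds("timing_threshold", th[[nm]])
    rows[[length(rows) + 1L]] <-
      data.frame(name = nm, group = "timing_threshold", value = th[[nm]],
                 lower = b[1], upper = b[2], stringsAsFactors = FALSE)
  }
  if (cerebellum_enabled) {
    for (nm in c("alpha", "beta")) {
      v <- if (nm == "alpha") alpha else beta
      b <- default_bounds("cerebellar_rate", v)
      rows[[length(rows) + 1L]] <-
        data.frame(name = nm, group = "cerebellar_rate", value = v,
                   lower = b[1], upper = b[2], stringsAsFactors = FALSE)
    }
  }
  reg <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(), group = character(), value = numeric(),
               lower = numeric(), upper = numeric(), stringsAsFactors = FALSE)
  if (anyDuplicated(reg$name)) {
    stop(sprintf("duplicate parameter name: %s",
                 reg$name[duplicated(reg$name)][1]))
  }
  if (any(reg$value < reg$lower | reg$value > reg$upper)) {
    stop("registry invariant violated: value outside [lower, upper]")
  }
  structure(reg, class = c("parameter_registry", "data.frame"),
            cerebellum_enabled = cerebellum_enabled)
}

#' @export
print.parameter_registry <- function(x, ...) {
  counts <- table(x$group)
  cat(sprintf("Parameter registry: %d free parameters (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(counts), counts), collapse = ", ")))
  cat(sprintf("  cerebellum %s\n",
              if (isTRUE(attr(x, "cerebellum_enabled"))) "enabled" else "disabled"))
  invisible(x)
}

#' Extract the genotype vector from a registry
#'
#' @param registry a `parameter_registry`.
#' @return named numeric vector in registry order.
#' @export
extract_vector <- function(registry) {
  stopifnot(inherits(registry, "parameter_registry"))
  stats::setNames(registry$value, registry$name)
}

#' Write a genotype vector into a registry
#'
#' Out-of-bound entries are clipped to the registry bounds; the names of
#' clipped parameters are recorded in the `clipped` attribute and a warning
#' is raised.
#'
#' @param registry a `parameter_registry`.
#' @param vector numeric vector of length `nrow(registry)`.
#' @return updated registry.
#' @export
apply_vector <- function(registry, vector) {
  stopifnot(inherits(registry, "parameter_registry"))
  if (length(vector) != nrow(registry)) {
    stop(sprintf("vector length %d does not match registry size %d",
                 length(vector), nrow(registry)))
  }
  clipped <- as.numeric(pmin(pmax(vector, registry$lower), registry$upper))
  hit <- which(clipped != vector)
  if (length(hit)) {
    warning(sprintf("%d parameter(s) clipped to bounds: %s", length(hit),
                    paste(registry$name[hit], collapse = ", ")))
  }
  registry$value <- clipped
  attr(registry, "clipped") <- registry$name[hit]
  registry
}

#' Export / import a registry as two-column text
#'
#' @param registry a `parameter_registry`.
#' @param path file path for the tab-separated (name, value) table.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "parameter_registry"))
  utils::write.table(registry[, c("name", "value")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_registry
#' @param template registry providing grouping and bounds for the values
#'   read back in.
#' @export
read_registry <- function(path, template) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("name", "value") %in% names(tab)))
  idx <- match(template$name, tab$name)
  if (anyNA(idx)) stop("registry file is missing parameters of the template")
  apply_vector(template, tab$value[idx])
}
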