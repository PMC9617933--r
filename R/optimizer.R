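# The two-stage algorithm-guided programming loop: predefined seed points,
# acquisition-driven suggestions, distance-threshold convergence.

#' Algorithm configuration
#'
#' Defaults follow the published workflow where stated (three ring and
#' four directional predefined points, 130 Hz, 60 us pulse width, 0.1 mA
#' amplitude step, 30 s wash-in logged per step) and this package's own
#' documented choices elsewhere: predefined point coordinates, amplitude
#' bounds 0.5-5.5 mA, convergence threshold 0.08 normalized units, and an
#' acquisition schedule (`beta0`, `beta_decay`) that trades exploration
#' for exploitation as steps accumulate.
#'
#' @param amp_range amplitude bounds in mA.
#' @param amp_step amplitude resolution in mA.
#' @param predefined_ring list of exactly 3 ring-stage points.
#' @param predefined_directional list of exactly 4 directional-stage points.
#' @param convergence_distance normalized distance threshold.
#' @param beta0,beta_decay exploration bonus schedule beta(t) = beta0 *
#'   beta_decay^t, t = suggestions already made in the stage.
#' @param max_steps_per_stage hard step cap per exploration stage.
#' @param n_coord1_ring,n_coord1_directional,n_amp lattice resolutions.
#' @param frequency,pulse_width,wash_in_s logged stimulation constants.
#' @return an object of class `algorithm_config`.
#' @export
algorithm_config <- function(amp_range = c(0.5, 5.5),
                             amp_step = 0.1,
                             predefined_ring = list(
                               exploration_point("ring", 0.5, 1.5),
                               exploration_point("ring", 1.5, 2.5),
                               exploration_point("ring", 2.5, 1.5)),
                             predefined_directional = list(
                               exploration_point("directional", 0, 3.0),
                               exploration_point("directional", 90, 3.0),
                               exploration_point("directional", 180, 3.0),
                               exploration_point("directional", 270, 3.0)),
                             convergence_distance = 0.08,
                             beta0 = 4, beta_decay = 0.9,
                             max_steps_per_stage = 20L,
                             n_coord1_ring = 31L,
                             n_coord1_directional = 30L,
                             n_amp = 26L,
                             frequency = 130, pulse_width = 60,
                             wash_in_s = 30) {
  if (length(predefined_ring) != 3L) stop("exactly 3 predefined ring points required")
  if (length(predefined_directional) != 4L) stop("exactly 4 predefined directional points required")
  if (amp_step <= 0) stop("amplitude step must be positive")
  cfg <- list(amp_range = amp_range, amp_step = amp_step,
              predefined_ring = predefined_ring,
              predefined_directional = predefined_directional,
              convergence_distance = convergence_distance,
              beta0 = beta0, beta_decay = beta_decay,
              max_steps_per_stage = as.integer(max_steps_per_stage),
              n_coord1_ring = as.integer(n_coord1_ring),
              n_coord1_directional = as.integer(n_coord1_directional),
              n_amp = as.integer(n_amp),
              frequency = frequency, pulse_width = pulse_width,
              wash_in_s = wash_in_s)
  class(cfg) <- "algorithm_config"
  cfg
}

new_stage_map <- function(stage, config) {
  score_map(stage, amp_range = config$amp_range,
            n_coord1 = if (stage == "ring") config$n_coord1_ring
                       else config$n_coord1_directional,
            n_amp = config$n_amp, amp_step = config$amp_step)
}

#' Predefined seed points of an exploration stage
#'
#' The same fixed points for every subject: three for the ring stage,
#' four for the directional stage.
#'
#' @param stage `"ring"` or `"directional"`.
#' @param config an [algorithm_config()].
#' @return list of [exploration_point()]s in fixed order.
#' @export
init_stage <- function(stage, config = algorithm_config()) {
  stage <- match.arg(stage, c("ring", "directional"))
  if (stage == "ring") config$predefined_ring else config$predefined_directional
}

# nearest-explored normalized distance for each lattice query
.nearest_explored_dist <- function(map, c1v, av) {
  dmin <- rep(Inf, length(c1v))
  for (k in seq_len(nrow(map$obs))) {
    d2 <- .map_dist2(map, c1v, av, map$obs$coord1[k], map$obs$amplitude[k])
    dmin <- pmin(dmin, sqrt(d2))
  }
  dmin
}

#' Suggest the next point to explore
#'
#' Minimizes, over admissible lattice nodes, the acquisition
#' `predicted_score(x) - beta(t) * dist_to_nearest_explored(x)` with
#' `beta(t) = beta0 * beta_decay^t`: early suggestions favor regions far
#' from everything explored, later ones the regions with best predicted
#' scores. Ties go to the lower amplitude, then lower first coordinate.
#'
#' @param map the stage's [score_map()] (all predefined points explored).
#' @param step_index t, number of suggestions already made this stage.
#' @param config an [algorithm_config()].
#' @return an [exploration_point()] on the lattice.
#' @export
suggest_next <- function(map, step_index, config = algorithm_config()) {
  if (!nrow(map$obs)) stop("no explored points yet")
  nc <- length(map$coord1_grid); na_ <- length(map$amp_grid)
  c1v <- rep(map$coord1_grid, times = na_)
  av <- rep(map$amp_grid, each = nc)
  adm <- as.vector(outer(map$caps, map$amp_grid,
                         function(cap, a) a < cap - 1e-9))
  if (!any(adm)) stop("stimulation space exhausted")
  pred <- .predict_many(map, c1v, av)
  dist <- .nearest_explored_dist(map, c1v, av)
  beta <- config$beta0 * config$beta_decay^step_index
  acq <- pred - beta * dist
  acq[!adm] <- Inf
  # ties: lower amplitude, then lower coord1
  best <- order(acq, av, c1v)[1]
  exploration_point(map$stage, c1v[best], av[best])
}

#' Convergence check
#'
#' The loop converges when the suggested point lies within the
#' normalized-distance threshold of the nearest already-explored point.
#'
#' @param suggested an [exploration_point()].
#' @param map the stage's [score_map()] (holds the explored points).
#' @param config an [algorithm_config()].
#' @return logical.
#' @export
check_convergence <- function(suggested, map, config = algorithm_config()) {
  if (!nrow(map$obs)) stop("no explored points yet")
  d <- .nearest_explored_dist(map, suggested$coord1, suggested$amplitude)
  d < config$convergence_distance
}

point_to_setting <- function(point, config, base_vertical = NULL,
                             geometry = lead_geometry()) {
  if (point$stage == "ring") {
    ring_point_to_setting(point, geometry, a_max = config$amp_range[2])
  } else {
    directional_point_to_setting(point, base_vertical, geometry,
                                 a_max = config$amp_range[2])
  }
}

#' Run one exploration stage
#'
#' Explores the predefined points, then iterates suggest / respond /
#' update until convergence or the step cap. The responder is any
#' function mapping a [stim_setting()] to
#' `list(scores = <named 0-4 vector>, side_effect = <logical>)` — a
#' synthetic patient via [patient_responder()], or a clinician at the
#' keyboard.
#'
#' @param responder responder function.
#' @param stage `"ring"` or `"directional"`.
#' @param spec the hemisphere's [select_symptoms()] result.
#' @param config an [algorithm_config()].
#' @param base_vertical vertical position carried from the ring stage
#'   (directional stage only).
#' @param step_offset step index of the last step recorded before this
#'   stage (session step indices stay contiguous).
#' @param geometry a [lead_geometry()].
#' @return list with `steps` (data.frame), `settings` (list), `map`,
#'   `converged`, `best` (list: point, setting, score, step) or NULL when
#'   every explored point was inadmissible.
#' @export
run_stage <- function(responder, stage, spec, config = algorithm_config(),
                      base_vertical = NULL, step_offset = 0L,
                      geometry = lead_geometry()) {
  stage <- match.arg(stage, c("ring", "directional"))
  if (stage == "directional" && is.null(base_vertical)) {
    stop("directional stage needs the base vertical position")
  }
  map <- new_stage_map(stage, config)
  steps <- data.frame(step = integer(0), stage = character(0),
                      coord1 = numeric(0), amplitude = numeric(0),
                      total_score = numeric(0), side_effect = logical(0),
                      electrode_configuration = character(0),
                      wash_in_s = numeric(0))
  settings <- list()

  explore <- function(point) {
    setting <- point_to_setting(point, config, base_vertical, geometry)
    resp <- tryCatch(responder(setting), error = function(e) {
      stop(sprintf("responder failed at step %d (%s stage): %s",
                   nrow(steps) + 1L, stage, conditionMessage(e)))
    })
    s_tot <- total_weighted_score(spec, resp$scores, resp$side_effect)
    steps[nrow(steps) + 1L, ] <<- list(
      step = step_offset + nrow(steps) + 1L, stage = stage,
      coord1 = point$coord1, amplitude = point$amplitude,
      total_score = as.numeric(s_tot),
      side_effect = isTRUE(resp$side_effect),
      electrode_configuration = format_electrode_config(setting),
      wash_in_s = config$wash_in_s)
    settings[[length(settings) + 1L]] <<- setting
    map <<- update_map(map, point, as.numeric(s_tot), resp$side_effect)
  }

  for (pt in init_stage(stage, config)) explore(pt)

  converged <- FALSE
  t <- 0L
  while (nrow(steps) < config$max_steps_per_stage) {
    sug <- tryCatch(suggest_next(map, t, config), error = function(e) e)
    if (inherits(sug, "error")) {
      if (grepl("exhausted", conditionMessage(sug))) stop(sug) else stop(sug)
    }
    if (check_convergence(sug, map, config)) { converged <- TRUE; break }
    explore(sug)
    t <- t + 1L
  }

  # best admissible explored step: no side effect, and not under a cap
  # learned later in the stage; ties to lower amplitude
  caps <- map$caps
  cap_at <- vapply(steps$coord1, function(c1) {
    caps[which.min(.coord1_dist(map, c1, map$coord1_grid))]
  }, numeric(1))
  ok <- !steps$side_effect & steps$amplitude < cap_at - 1e-9
  best <- NULL
  if (any(ok)) {
    cand <- which(ok)
    cand <- cand[order(steps$total_score[cand], steps$amplitude[cand])]
    b <- cand[1]
    best <- list(point = exploration_point(stage, steps$coord1[b],
                                           steps$amplitude[b]),
                 setting = settings[[b]], score = steps$total_score[b],
                 step = steps$step[b])
  }
  list(steps = steps, settings = settings, map = map,
       converged = converged, best = best)
}

#' Run the full two-stage loop for one hemisphere
#'
#' Stage 1 explores ring settings along the lead axis. If the best ring
#' setting puts cathodic current on any segmented electrode (E2-E7), the
#' directional stage explores rotation angles at that vertical position;
#' otherwise the loop stops after stage 1. The final recommendation is
#' the admissible explored setting with the lowest total weighted score
#' across both stages (ties to lower amplitude).
#'
#' @inheritParams run_stage
#' @return an object of class `session_record`: `steps`, `settings`,
#'   `stages` (per-stage convergence and best), `final` (point, setting,
#'   score, step), `spec`, `config`.
#' @export
run_hemisphere <- function(responder, spec, config = algorithm_config(),
                           geometry = lead_geometry()) {
  ring <- run_stage(responder, "ring", spec, config, geometry = geometry)
  if (is.null(ring$best)) stop("no admissible ring-stage setting found")
  steps <- ring$steps
  settings <- ring$settings
  stages <- list(ring = list(converged = ring$converged, best = ring$best))

  pct <- ring$best$setting$percents
  directional_trigger <- any(pct[2:7] > 0)
  dir_res <- NULL
  if (directional_trigger) {
    base_p <- setting_to_point(ring$best$setting, geometry)$p
    dir_res <- run_stage(responder, "directional", spec, config,
                         base_vertical = base_p,
                         step_offset = nrow(steps), geometry = geometry)
    steps <- rbind(steps, dir_res$steps)
    settings <- c(settings, dir_res$settings)
    stages$directional <- list(converged = dir_res$converged,
                               best = dir_res$best, base_vertical = base_p)
  }

  cands <- Filter(Negate(is.null), list(ring$best,
                                        if (!is.null(dir_res)) dir_res$best))
  ord <- order(vapply(cands, `[[`, numeric(1), "score"),
               vapply(cands, function(b) b$setting$amplitude, numeric(1)))
  final <- cands[[ord[1]]]

  rec <- list(steps = steps, settings = settings, stages = stages,
              final = final, directional_stage = directional_trigger,
              spec = spec, config = config)
  class(rec) <- "session_record"
  rec
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf(paste0("<session_record> %d steps (%s), final score %.2f at ",
                     "%.1f mA [%s]\n"),
              nrow(x$steps),
              if (x$directional_stage) "ring + directional" else "ring only",
              x$final$score, x$final$setting$amplitude,
              format_electrode_config(x$final$setting)))
  invisible(x)
}

#' Convergence and optimization burden of a session
#'
#' @param record a [run_hemisphere()] result.
#' @return list with `steps_to_convergence` (total steps recorded) and
#'   `steps_to_best` (step index at which the final best setting was
#'   explored).
#' @export
burden_report <- function(record) {
  stopifnot(inherits(record, "session_record"))
  if (!nrow(record$steps)) stop("empty session record")
  list(steps_to_convergence = nrow(record$steps),
       steps_to_best = record$final$step)
}
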