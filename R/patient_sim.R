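# In-silico patients: ground-truth symptom response fields and side-effect
# thresholds over the stimulation space, so the programming loop can be
# exercised and validated without clinical data.

# Run code under a temporary RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

quantize_score <- function(s) round(pmin(pmax(s, 0), 4) * 10) / 10

# Saturating amplitude response anchored at zero: 0 at A = 0, -> 1 for
# A >> a50.
amp_response <- function(a, a50, slope) {
  sig <- function(x) 1 / (1 + exp(-(x - a50) / slope))
  (sig(a) - sig(0)) / (1 - sig(0))
}

circ_dist_deg <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

# Mean angular attenuation seen by ring-mode (angularly symmetric)
# stimulation: the circular average of the wrapped Gaussian kernel,
# independent of the sweet angle.
ring_angular_factor <- function(sigma_theta) {
  ang <- seq(0, 359, by = 1)
  mean(exp(-circ_dist_deg(ang, 0)^2 / (2 * sigma_theta^2)))
}

#' A ground-truth symptom response field
#'
#' Severity over the stimulation space is a Gaussian spatial kernel
#' (vertical x angular) times a saturating amplitude response:
#' `score = baseline_off - max_improvement * G_p * G_theta * f(A) + noise`,
#' clipped to [0, 4] and quantized to 0.1. Ring-mode (angularly
#' symmetric) stimulation sees the circular average of the angular kernel
#' instead of a point evaluation.
#'
#' @param symptom,laterality,source as in [symptom_assessment()].
#' @param baseline_off severity at zero stimulation.
#' @param baseline_on severity under a reference therapy (drives the
#'   weight, not the field).
#' @param max_improvement best achievable score reduction (score points).
#' @param sweet_p,sweet_theta sweet-spot coordinates (level units, deg).
#' @param sigma_p,sigma_theta spatial kernel scales (level units, deg).
#' @param a50,slope amplitude-response midpoint and slope (mA).
#' @param noise_sd additive Gaussian noise (score points; truncated by
#'   clipping).
#' @return an object of class `symptom_field`.
#' @export
symptom_field <- function(symptom, laterality = "left", source = "clinician",
                          baseline_off, baseline_on, max_improvement,
                          sweet_p, sweet_theta, sigma_p = 0.8,
                          sigma_theta = 60, a50 = 2.0, slope = 0.5,
                          noise_sd = 0) {
  f <- list(symptom = symptom, laterality = laterality, source = source,
            symptom_id = paste(symptom, laterality, sep = "_"),
            baseline_off = baseline_off, baseline_on = baseline_on,
            max_improvement = max_improvement,
            sweet_p = sweet_p, sweet_theta = sweet_theta %% 360,
            sigma_p = sigma_p, sigma_theta = sigma_theta,
            a50 = a50, slope = slope, noise_sd = noise_sd,
            ring_factor = ring_angular_factor(sigma_theta))
  class(f) <- "symptom_field"
  f
}

# Noise-free field severity at stimulation-space coordinates.
# theta = NA means angularly symmetric (ring-mode) stimulation; seg_frac
# is the share of cathodic current on segmented electrodes: only that
# share is angularly steered, the rest sees the ring average.
field_score <- function(field, p, theta, a, seg_frac = 1) {
  gp <- exp(-(p - field$sweet_p)^2 / (2 * field$sigma_p^2))
  k <- ifelse(is.na(theta), field$ring_factor,
              exp(-circ_dist_deg(theta, field$sweet_theta)^2 /
                    (2 * field$sigma_theta^2)))
  gt <- seg_frac * k + (1 - seg_frac) * field$ring_factor
  field$baseline_off - field$max_improvement * gp * gt *
    amp_response(a, field$a50, field$slope)
}

# share of cathodic current on the segmented levels for a directional
# point at vertical position p (the E1/E8 remainder is unsteered)
seg_frac_of_p <- function(p) pmin(p, 1, 3 - p)

#' A side-effect threshold surface
#'
#' The side-effect threshold is lowest near one sector of the lead
#' (emulating e.g. current spread towards the internal capsule):
#' `T(p, theta) = t_base - t_depth * exp(-dp^2/2sp^2 - dtheta^2/2st^2)`.
#' A setting triggers the side effect when its amplitude reaches T at its
#' effective coordinate; angularly symmetric stimulation is evaluated at
#' the worst (lowest-threshold) angle.
#'
#' @param p_se,theta_se location of the sensitive sector.
#' @param t_base baseline threshold (mA) far from the sector.
#' @param t_depth threshold reduction at the sector center (mA).
#' @param sigma_p,sigma_theta extent of the sector.
#' @return an object of class `side_effect_field`.
#' @export
side_effect_field <- function(p_se, theta_se, t_base = 5.0, t_depth = 2.0,
                              sigma_p = 0.5, sigma_theta = 40) {
  f <- list(p_se = p_se, theta_se = theta_se %% 360, t_base = t_base,
            t_depth = t_depth, sigma_p = sigma_p, sigma_theta = sigma_theta)
  class(f) <- "side_effect_field"
  f
}

se_threshold <- function(field, p, theta) {
  if (is.null(field)) return(rep(Inf, length(p)))
  dth <- ifelse(is.na(theta), 0, circ_dist_deg(theta, field$theta_se))
  field$t_base - field$t_depth *
    exp(-(p - field$p_se)^2 / (2 * field$sigma_p^2) -
          dth^2 / (2 * field$sigma_theta^2))
}

#' Generate a synthetic patient hemisphere
#'
#' Difficulty presets: `"easy"` draws 2-4 symptoms sharing one sweet spot
#' with no noise and no side effects (unimodal ground truth, used for
#' oracle-agreement checks); `"clinical"` jitters sweet spots, adds
#' quantized assessment noise (clinician symptoms noisier than sensor
#' ones) and a side-effect sector; `"adversarial"` places at least two
#' symptoms' sweet spots >= 1 level unit apart so the best compromise
#' setting differs from every single-symptom optimum.
#'
#' @param seed integer; the patient is fully reproducible from it.
#' @param preset `"easy"`, `"clinical"` or `"adversarial"`.
#' @return an object of class `synthetic_patient` with `fields`,
#'   `side_effects`, `assessments`, `seed`, `preset`.
#' @export
make_patient <- function(seed, preset = c("easy", "clinical", "adversarial")) {
  preset <- match.arg(preset)
  with_seed(seed, {
    pool <- data.frame(
      symptom = c("rigidity", "bradykinesia", "tremor_rest",
                  "finger_tapping", "hand_grasp"),
      source = c("clinician", "clinician", "clinician", "sensor", "sensor"),
      stringsAsFactors = FALSE)
    n_sym <- sample(2:4, 1)
    # rigidity is always assessed in the emulated workflow
    take <- c(1L, sample(2:5, n_sym - 1L))
    center_p <- runif(1, 0.8, 2.2)
    center_th <- runif(1, 0, 360)
    # adversarial preset: two well-separated vertical spots shared by all
    # symptoms (alternating), fixed per patient
    adv_sep <- runif(1, 1.2, 1.8)
    adv_base <- runif(1, 0.4, 2.6 - adv_sep)
    adv_dth <- runif(1, 90, 270)
    fields <- vector("list", n_sym)
    for (i in seq_len(n_sym)) {
      b_off <- sample(seq(2, 4, by = 0.5), 1)
      improve <- runif(1, 0.5, 0.9)
      b_on <- quantize_score(b_off * (1 - improve))
      max_imp <- runif(1, 0.6, 0.95) * b_off
      if (preset == "easy") {
        sp <- center_p; st <- center_th
        noise <- 0
      } else if (preset == "clinical") {
        sp <- min(max(center_p + runif(1, -0.4, 0.4), 0.2), 2.8)
        st <- center_th + runif(1, -40, 40)
        noise <- if (pool$source[take[i]] == "sensor") 0.15 else 0.3
      } else {
        sp <- if (i %% 2 == 1) adv_base else adv_base + adv_sep
        st <- (center_th + if (i %% 2 == 1) 0 else adv_dth) %% 360
        noise <- if (pool$source[take[i]] == "sensor") 0.15 else 0.3
      }
      fields[[i]] <- symptom_field(
        symptom = pool$symptom[take[i]], laterality = "left",
        source = pool$source[take[i]],
        baseline_off = b_off, baseline_on = b_on, max_improvement = max_imp,
        sweet_p = sp, sweet_theta = st,
        sigma_p = runif(1, 0.6, 1.0), sigma_theta = runif(1, 50, 80),
        a50 = runif(1, 1.5, 2.5), slope = 0.5, noise_sd = noise)
    }
    se <- NULL
    if (preset != "easy") {
      se <- side_effect_field(p_se = runif(1, 0, 3),
                              theta_se = runif(1, 0, 360),
                              t_base = 5.0, t_depth = runif(1, 1.0, 2.5))
    }
    assessments <- lapply(fields, function(f) {
      symptom_assessment(f$symptom, f$laterality, f$source,
                         f$baseline_off, f$baseline_on)
    })
    p <- list(fields = fields, side_effects = se, assessments = assessments,
              seed = seed, preset = preset)
    class(p) <- "synthetic_patient"
    p
  })
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf("<synthetic_patient> seed %d, preset %s, %d symptom field(s)%s\n",
              x$seed, x$preset, length(x$fields),
              if (is.null(x$side_effects)) "" else ", side-effect sector"))
  invisible(x)
}

#' Evaluate a patient's response to a stimulation setting
#'
#' The setting's effective coordinate is its cathodic-share-weighted
#' vertical centroid and recovered steering angle (angle `NA` for
#' angularly symmetric settings); each field is evaluated there, noise is
#' added when `noise` is supplied, and scores are clipped to [0, 4] and
#' quantized to 0.1. The side-effect flag is raised when the amplitude
#' reaches the threshold surface at the effective coordinate.
#'
#' @param patient a [make_patient()] result.
#' @param setting a [stim_setting()].
#' @param noise optional numeric vector of standard-normal draws, one per
#'   field (scaled by each field's `noise_sd`); omit for noise-free.
#' @return list with `scores` (named by symptom id) and `side_effect`.
#' @export
respond <- function(patient, setting, noise = NULL) {
  stopifnot(inherits(patient, "synthetic_patient"),
            inherits(setting, "stim_setting"))
  if (setting$amplitude == 0) {
    scores <- vapply(patient$fields, function(f) f$baseline_off, numeric(1))
    names(scores) <- vapply(patient$fields, `[[`, character(1), "symptom_id")
    return(list(scores = quantize_score(scores), side_effect = FALSE))
  }
  coord <- setting_to_point(setting)
  fr <- setting$fractions[paste0("E", 1:8)]
  shares <- pmax(-fr, 0)
  sf <- if (is.na(coord$theta)) 0 else sum(shares[2:7]) / sum(shares)
  scores <- vapply(seq_along(patient$fields), function(i) {
    f <- patient$fields[[i]]
    s <- field_score(f, coord$p, coord$theta, setting$amplitude, sf)
    if (!is.null(noise) && f$noise_sd > 0) s <- s + noise[i] * f$noise_sd
    s
  }, numeric(1))
  names(scores) <- vapply(patient$fields, `[[`, character(1), "symptom_id")
  thr <- se_threshold(patient$side_effects, coord$p, coord$theta)
  list(scores = quantize_score(scores),
       side_effect = setting$amplitude >= thr)
}

#' Responder closure for the optimization loop
#'
#' Wraps [respond()] with a private noise stream so that a session is
#' fully reproducible from `(patient, seed)` while leaving the caller's
#' RNG untouched.
#'
#' @param patient a [make_patient()] result.
#' @param seed noise-stream seed (defaults to the patient's own).
#' @return function mapping a [stim_setting()] to the [respond()] output.
#' @export
patient_responder <- function(patient, seed = patient$seed) {
  counter <- 0L
  n_fields <- length(patient$fields)
  function(setting) {
    counter <<- counter + 1L
    z <- with_seed(seed + counter, stats::rnorm(n_fields))
    respond(patient, setting, noise = z)
  }
}

#' Weighted-score specification of a synthetic patient
#'
#' @param patient a [make_patient()] result.
#' @param max_n maximum symptoms kept.
#' @return a [select_symptoms()] result.
#' @export
patient_spec <- function(patient, max_n = 4L) {
  select_symptoms(patient$assessments, max_n = max_n)
}

#' Brute-force grid optimum of the total weighted score
#'
#' Exhaustive, noise-free evaluation of the total weighted score over the
#' full (vertical position x angle x amplitude) lattice plus the
#' angularly symmetric (ring) sub-lattice, restricted to points below the
#' side-effect threshold. Serves as the independent oracle for optimizer
#' validation. Ties go to the lower amplitude.
#'
#' @param patient a [make_patient()] result.
#' @param spec a [select_symptoms()] result for that patient.
#' @param config an [algorithm_config()] (defines the lattice).
#' @return list with `p`, `theta` (`NA` for a ring optimum), `amplitude`
#'   and `score`.
#' @export
brute_force_optimum <- function(patient, spec, config = algorithm_config()) {
  p_grid <- seq(0, 3, length.out = config$n_coord1_ring)
  th_grid <- seq(0, 360, length.out = config$n_coord1_directional + 1L)
  th_grid <- th_grid[seq_len(config$n_coord1_directional)]
  a_grid <- seq(config$amp_range[1], config$amp_range[2],
                length.out = config$n_amp)
  grid <- rbind(
    expand.grid(p = p_grid, theta = th_grid, a = a_grid),
    expand.grid(p = p_grid, theta = NA_real_, a = a_grid)
  )
  thr <- se_threshold(patient$side_effects, grid$p, grid$theta)
  grid <- grid[grid$a < thr, , drop = FALSE]
  if (!nrow(grid)) stop("stimulation space exhausted")
  sf <- ifelse(is.na(grid$theta), 0, seg_frac_of_p(grid$p))
  total <- numeric(nrow(grid))
  for (f in patient$fields) {
    if (!f$symptom_id %in% spec$symptom_id) next
    w <- spec$weight[match(f$symptom_id, spec$symptom_id)]
    total <- total + w * quantize_score(field_score(f, grid$p, grid$theta,
                                                    grid$a, sf))
  }
  best <- order(total, grid$a)[1]
  list(p = grid$p[best], theta = grid$theta[best], amplitude = grid$a[best],
       score = total[best])
}
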