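# Configuration loading, session / patient serialization, settings
# tables in the published dialect, and the command-line surface.

SESSION_SCHEMA_VERSION <- "1.0"

.config_scalar_keys <- c("amp_step", "convergence_distance", "beta0",
                         "beta_decay", "max_steps_per_stage",
                         "n_coord1_ring", "n_coord1_directional", "n_amp",
                         "frequency", "pulse_width", "wash_in_s")

#' Load a run configuration from JSON
#'
#' Unknown keys are rejected; omitted keys take the [algorithm_config()]
#' defaults (130 Hz, 60 us pulse width, 0.1 mA step, 30 s wash-in).
#' Predefined points are given as two-element `[coord1, amplitude]`
#' arrays under `predefined_ring` / `predefined_directional`.
#'
#' @param path JSON file; an empty object (`{}`) yields all defaults.
#' @return an [algorithm_config()].
#' @export
load_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(raw)) raw <- list()
  known <- c(.config_scalar_keys, "amp_range", "predefined_ring",
             "predefined_directional")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  args <- raw[intersect(names(raw), .config_scalar_keys)]
  if (!is.null(raw$amp_range)) {
    if (length(raw$amp_range) != 2L || raw$amp_range[1] >= raw$amp_range[2]) {
      stop("amp_range must be [min, max] with min < max")
    }
    args$amp_range <- as.numeric(raw$amp_range)
  }
  for (k in c("amp_step", "convergence_distance", "beta0")) {
    if (!is.null(args[[k]]) && args[[k]] <= 0) stop(k, " must be positive")
  }
  mk_points <- function(m, stage) {
    m <- as.matrix(m)
    lapply(seq_len(nrow(m)), function(i) {
      exploration_point(stage, m[i, 1], m[i, 2])
    })
  }
  if (!is.null(raw$predefined_ring)) {
    args$predefined_ring <- mk_points(raw$predefined_ring, "ring")
  }
  if (!is.null(raw$predefined_directional)) {
    args$predefined_directional <- mk_points(raw$predefined_directional,
                                             "directional")
  }
  do.call(algorithm_config, args)
}

serialize_setting <- function(s) {
  list(amplitude = s$amplitude, fractions = as.list(s$fractions),
       frequency = s$frequency, pulse_width = s$pulse_width, mode = s$mode,
       percents = if (is.null(s$percents)) NULL else as.list(s$percents))
}

deserialize_setting <- function(x) {
  fr <- unlist(x$fractions)
  s <- stim_setting(x$amplitude, fr, x$frequency, x$pulse_width, x$mode)
  if (!is.null(x$percents)) {
    s$percents <- stats::setNames(as.integer(unlist(x$percents)),
                                  names(x$percents))
  }
  s
}

#' Write a session record to JSON
#'
#' @param record a [run_hemisphere()] result.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_session <- function(record, path) {
  stopifnot(inherits(record, "session_record"))
  cfg <- record$config
  out <- list(
    schema_version = SESSION_SCHEMA_VERSION,
    steps = record$steps,
    settings = lapply(record$settings, serialize_setting),
    stages = lapply(record$stages, function(st) {
      list(converged = st$converged, best_step = st$best$step,
           base_vertical = st$base_vertical)
    }),
    final_step = record$final$step,
    directional_stage = record$directional_stage,
    spec = list(symptom_id = record$spec$symptom_id,
                source = record$spec$source,
                raw_weight = record$spec$raw_weight,
                weight = record$spec$weight,
                baseline_off = record$spec$baseline_off),
    config = c(cfg[.config_scalar_keys],
               list(amp_range = cfg$amp_range,
                    predefined_ring = lapply(cfg$predefined_ring, function(p)
                      c(p$coord1, p$amplitude)),
                    predefined_directional =
                      lapply(cfg$predefined_directional, function(p)
                        c(p$coord1, p$amplitude))))
  )
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE), path)
  invisible(path)
}

#' Read a session record from JSON
#'
#' @param path file written by [write_session()].
#' @return a `session_record`.
#' @export
read_session <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  if (!identical(x$schema_version, SESSION_SCHEMA_VERSION)) {
    stop("unsupported session schema version: ", x$schema_version)
  }
  cfgl <- x$config
  # jsonlite simplifies the list of [coord1, amplitude] pairs to a matrix
  as_points <- function(m, stage) {
    if (is.matrix(m)) m <- lapply(seq_len(nrow(m)), function(i) m[i, ])
    lapply(m, function(p) exploration_point(stage, p[1], p[2]))
  }
  cfg <- algorithm_config(
    amp_range = as.numeric(cfgl$amp_range),
    amp_step = cfgl$amp_step,
    predefined_ring = as_points(cfgl$predefined_ring, "ring"),
    predefined_directional = as_points(cfgl$predefined_directional,
                                       "directional"),
    convergence_distance = cfgl$convergence_distance,
    beta0 = cfgl$beta0, beta_decay = cfgl$beta_decay,
    max_steps_per_stage = cfgl$max_steps_per_stage,
    n_coord1_ring = cfgl$n_coord1_ring,
    n_coord1_directional = cfgl$n_coord1_directional, n_amp = cfgl$n_amp,
    frequency = cfgl$frequency, pulse_width = cfgl$pulse_width,
    wash_in_s = cfgl$wash_in_s)
  # jsonlite flattens the settings list into parallel columns; rebuild
  settings <- lapply(seq_len(nrow(x$steps)), function(i) {
    s <- stim_setting(x$settings$amplitude[i],
                      unlist(x$settings$fractions[i, ]),
                      x$settings$frequency[i], x$settings$pulse_width[i],
                      x$settings$mode[i])
    if (!is.null(x$settings$percents)) {
      s$percents <- stats::setNames(as.integer(x$settings$percents[i, ]),
                                    colnames(x$settings$percents))
    }
    s
  })
  steps <- x$steps
  spec <- structure(list(symptom_id = x$spec$symptom_id,
                         source = x$spec$source,
                         raw_weight = x$spec$raw_weight,
                         weight = x$spec$weight,
                         baseline_off = x$spec$baseline_off),
                    class = "weighted_score_spec")
  mk_best <- function(step_idx) {
    i <- match(step_idx, steps$step)
    list(point = exploration_point(steps$stage[i], steps$coord1[i],
                                   steps$amplitude[i]),
         setting = settings[[i]], score = steps$total_score[i],
         step = steps$step[i])
  }
  stages <- lapply(x$stages, function(st) {
    out <- list(converged = st$converged, best = mk_best(st$best_step))
    if (!is.null(st$base_vertical)) out$base_vertical <- st$base_vertical
    out
  })
  rec <- list(steps = steps, settings = settings, stages = stages,
              final = mk_best(x$final_step),
              directional_stage = x$directional_stage,
              spec = spec, config = cfg)
  class(rec) <- "session_record"
  rec
}

#' Write / read a synthetic patient for exact replay
#'
#' @param patient a [make_patient()] result.
#' @param path JSON file.
#' @return `path` invisibly / the reconstructed `synthetic_patient`.
#' @export
write_patient <- function(patient, path) {
  stopifnot(inherits(patient, "synthetic_patient"))
  field_keys <- c("symptom", "laterality", "source", "baseline_off",
                  "baseline_on", "max_improvement", "sweet_p", "sweet_theta",
                  "sigma_p", "sigma_theta", "a50", "slope", "noise_sd")
  out <- list(
    schema_version = SESSION_SCHEMA_VERSION,
    seed = patient$seed, preset = patient$preset,
    fields = lapply(patient$fields, function(f) f[field_keys]),
    side_effects = if (is.null(patient$side_effects)) NULL else
      patient$side_effects[c("p_se", "theta_se", "t_base", "t_depth",
                             "sigma_p", "sigma_theta")]
  )
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_patient
#' @export
read_patient <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE)
  if (!identical(x$schema_version, SESSION_SCHEMA_VERSION)) {
    stop("unsupported patient schema version: ", x$schema_version)
  }
  fields <- lapply(x$fields, function(f) do.call(symptom_field, f))
  se <- if (is.null(x$side_effects)) NULL else
    do.call(side_effect_field, x$side_effects)
  assessments <- lapply(fields, function(f) {
    symptom_assessment(f$symptom, f$laterality, f$source,
                       f$baseline_off, f$baseline_on)
  })
  p <- list(fields = fields, side_effects = se, assessments = assessments,
            seed = x$seed, preset = x$preset)
  class(p) <- "synthetic_patient"
  p
}

#' Read a settings table in the published dialect
#'
#' Expects CSV columns `subject`, `hemisphere`, `amplitude_mA`,
#' `frequency_Hz`, `pulse_width_us`, `electrode_configuration`,
#' `stimulation_mode` (a `condition` column is carried through when
#' present).
#'
#' @param path CSV file.
#' @return data.frame with an extra list-column `setting` of
#'   [stim_setting()] objects.
#' @export
read_settings_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "hemisphere", "amplitude_mA", "frequency_Hz",
            "pulse_width_us", "electrode_configuration", "stimulation_mode")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("settings table lacks column(s): ",
                         paste(miss, collapse = ", "))
  df$setting <- lapply(seq_len(nrow(df)), function(i) {
    setting_from_config(df$electrode_configuration[i], df$amplitude_mA[i],
                        df$frequency_Hz[i], df$pulse_width_us[i],
                        mode = tolower(df$stimulation_mode[i]))
  })
  df
}

#' Compare two settings tables hemisphere by hemisphere
#'
#' Rows are matched on (subject, hemisphere); each pair yields amplitude
#' ratio, normalized configuration distance, setting similarity and the
#' VTA-stand-in Jaccard index.
#'
#' @param table1,table2 [read_settings_table()] results (or paths).
#' @return data.frame, one row per matched hemisphere.
#' @export
compare_settings_tables <- function(table1, table2) {
  if (is.character(table1)) table1 <- read_settings_table(table1)
  if (is.character(table2)) table2 <- read_settings_table(table2)
  key <- function(d) paste(d$subject, d$hemisphere)
  common <- intersect(key(table1), key(table2))
  if (!length(common)) stop("no matching (subject, hemisphere) rows")
  do.call(rbind, lapply(common, function(k) {
    i <- match(k, key(table1)); j <- match(k, key(table2))
    rep_ <- similarity_report(table1$setting[[i]], table2$setting[[j]])
    data.frame(subject = table1$subject[i],
               hemisphere = table1$hemisphere[i],
               amp_ratio = rep_$amp_ratio,
               norm_elec_conf_dist = rep_$norm_elec_conf_dist,
               set_sim = rep_$set_sim,
               jaccard_index = rep_$jaccard_index)
  }))
}

rebuild_stage_map <- function(record, stage) {
  map <- new_stage_map(stage, record$config)
  rows <- which(record$steps$stage == stage)
  if (!length(rows)) stop("session has no ", stage, "-stage steps")
  for (i in rows) {
    map <- update_map(map,
                      exploration_point(stage, record$steps$coord1[i],
                                        record$steps$amplitude[i]),
                      record$steps$total_score[i],
                      record$steps$side_effect[i])
  }
  map
}

cli_fail <- function(msg) {
  message(msg)
  1L
}

.cli_opt <- function(args, name, default = NULL) {
  i <- which(args == paste0("--", name))
  if (!length(i)) return(default)
  if (i[1] == length(args)) stop("missing value for --", name)
  args[i[1] + 1L]
}

#' Command-line entry point
#'
#' Subcommands: `simulate --seed S [--preset P] --out patient.json`;
#' `optimize --patient patient.json [--config cfg.json] [--seed S]
#' --out session.json`; `compare soc.csv agp.csv --out report.csv`;
#' `export --session session.json [--stage ring] --out map.csv`;
#' `report --session session.json [--out report.json]`. Runs are
#' deterministic given `--seed`.
#'
#' @param args character vector of arguments (as from
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit status (0 on success), invisibly.
#' @export
dbs_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) stop("usage: dbsteer <simulate|optimize|compare|export|report> ...")
    cmd <- args[1]; rest <- args[-1]
    switch(
      cmd,
      simulate = {
        seed <- as.integer(.cli_opt(rest, "seed"))
        if (is.na(seed)) stop("simulate needs an integer --seed")
        preset <- .cli_opt(rest, "preset", "clinical")
        out <- .cli_opt(rest, "out")
        if (is.null(out)) stop("simulate needs --out")
        write_patient(make_patient(seed, preset), out)
        message("wrote patient to ", out)
      },
      optimize = {
        pfile <- .cli_opt(rest, "patient")
        if (is.null(pfile)) stop("optimize needs --patient")
        patient <- read_patient(pfile)
        cfg <- if (is.null(.cli_opt(rest, "config"))) algorithm_config()
               else load_config(.cli_opt(rest, "config"))
        seed <- as.integer(.cli_opt(rest, "seed", patient$seed))
        out <- .cli_opt(rest, "out")
        if (is.null(out)) stop("optimize needs --out")
        spec <- patient_spec(patient)
        rec <- run_hemisphere(patient_responder(patient, seed), spec, cfg)
        write_session(rec, out)
        b <- burden_report(rec)
        message(sprintf("converged in %d steps (best at step %d); wrote %s",
                        b$steps_to_convergence, b$steps_to_best, out))
      },
      compare = {
        files <- rest[!startsWith(rest, "--")]
        if (length(files) < 2) stop("compare needs two settings tables")
        out <- .cli_opt(rest, "out")
        rep_ <- compare_settings_tables(files[1], files[2])
        if (is.null(out)) {
          print(rep_)
        } else {
          utils::write.csv(rep_, out, row.names = FALSE)
          message("wrote comparison to ", out)
        }
      },
      export = {
        sfile <- .cli_opt(rest, "session")
        out <- .cli_opt(rest, "out")
        if (is.null(sfile) || is.null(out)) stop("export needs --session and --out")
        stage <- .cli_opt(rest, "stage", "ring")
        export_map(rebuild_stage_map(read_session(sfile), stage), out)
        message("wrote score map to ", out)
      },
      report = {
        sfile <- .cli_opt(rest, "session")
        if (is.null(sfile)) stop("report needs --session")
        rec <- read_session(sfile)
        b <- burden_report(rec)
        out <- .cli_opt(rest, "out")
        txt <- jsonlite::toJSON(
          list(steps_to_convergence = b$steps_to_convergence,
               steps_to_best = b$steps_to_best,
               final_score = rec$final$score,
               final_amplitude = rec$final$setting$amplitude,
               final_configuration =
                 format_electrode_config(rec$final$setting)),
          auto_unbox = TRUE, digits = NA, pretty = TRUE)
        if (is.null(out)) cat(txt, "\n") else writeLines(txt, out)
      },
      stop("unknown subcommand: ", cmd)
    )
    0L
  }, error = function(e) cli_fail(conditionMessage(e)))
  invisible(status)
}
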