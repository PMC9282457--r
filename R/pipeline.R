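#' End-to-end pipeline configuration
#'
#' Exactly one of `inputs` (paths to questionnaire and sobriety CSVs) or
#' `simulate` (a [synth_config()]) must be given. Biomarker definitions are
#' either `"discover"` (PCA + varimax + assignment on complete days) or a
#' list of two [biomarker_definition()]s named `motsc` and `webe` (default:
#' the published groupings).
#'
#' @param inputs `NULL` or list with `questionnaire` and `sobriety` paths.
#' @param simulate `NULL` or a [synth_config()].
#' @param definitions `"discover"` or list(motsc =, webe =) of
#'   [biomarker_definition()]s.
#' @param alpha Smoothing factor for both questionnaire biomarkers.
#' @param feature_set One of `"biomarker2"`, `"avg4"`, `"raw22"`.
#' @param look_ahead Integer pair `c(1, 3)` or `c(5, 7)`.
#' @param split_fractions Patient-level partition fractions.
#' @param split_counts Optional exact partition counts.
#' @param forecaster A [forecaster_config()].
#' @param ami_min,startup_days,min_hist,max_hist Eligibility and windowing
#'   parameters (see [eligibility_mask()], [make_samples()]).
#' @param seed Master seed: governs the patient split and, unless the
#'   forecaster config sets its own, model training.
#' @param out_dir Artifact directory (created if absent).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(inputs = NULL, simulate = NULL,
                            definitions = NULL, alpha = 0.32,
                            feature_set = c("biomarker2", "avg4", "raw22"),
                            look_ahead = c(1L, 3L),
                            split_fractions = c(0.70, 0.15, 0.15),
                            split_counts = NULL,
                            forecaster = NULL,
                            ami_min = 40, startup_days = 7L,
                            min_hist = 7L, max_hist = 93L,
                            seed = 1L, out_dir = tempfile("dbmarker_run_")) {
  if (is.null(inputs) == is.null(simulate)) {
    stop("give exactly one of 'inputs' (file paths) or 'simulate' ",
         "(a synth_config)", call. = FALSE)
  }
  smoothing_params(alpha)  # validates
  feature_set <- match.arg(feature_set)
  if (is.null(definitions)) {
    definitions <- list(
      motsc = biomarker_definition("MotSC-i", motsc_questions),
      webe = biomarker_definition("WeBe-i", webe_questions)
    )
  }
  if (is.null(forecaster)) {
    forecaster <- forecaster_config(seed = seed)
  }
  structure(list(inputs = inputs, simulate = simulate,
                 definitions = definitions, alpha = alpha,
                 feature_set = feature_set,
                 look_ahead = as.integer(look_ahead),
                 split_fractions = split_fractions,
                 split_counts = split_counts,
                 forecaster = forecaster, ami_min = ami_min,
                 startup_days = as.integer(startup_days),
                 min_hist = as.integer(min_hist),
                 max_hist = as.integer(max_hist),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

stage_msg <- function(...) message("[dbmarker] ", ...)

#' Prepare one patient's forecasting ingredients
#'
#' Library-level building block of [run_pipeline()]: panel, the two
#' biomarkers, event calendar, AMI (recorded where present, otherwise the
#' [sobriety_index()] approximation), labels, eligibility and windowed
#' samples for one patient.
#'
#' @param q_table,s_table Validated input tables.
#' @param patient One patient id.
#' @param config A [pipeline_config()].
#' @return List with `panel`, `biomarkers`, `calendar`, `ami`, `labels`,
#'   `eligible`, `samples`.
#' @export
prepare_patient <- function(q_table, s_table, patient, config) {
  panel <- build_day_grid(q_table, s_table, patient)
  params <- smoothing_params(config$alpha)
  bm <- list(
    motsc = build_biomarker(panel, config$definitions$motsc$questions,
                            params, name = config$definitions$motsc$name),
    webe = build_biomarker(panel, config$definitions$webe$questions,
                           params, name = config$definitions$webe$name)
  )
  calendar <- detect_exacerbation_events(panel$status)
  ami <- panel$ami
  approx_idx <- is.na(ami)
  if (any(approx_idx)) {
    ami[approx_idx] <- sobriety_index(panel$status)[approx_idx]
  }
  labels <- make_labels(calendar, config$look_ahead)
  eligible <- eligibility_mask(calendar, ami, config$ami_min,
                               config$startup_days)
  feats <- build_feature_rows(panel, bm, config$feature_set)
  samples <- make_samples(feats, labels, eligible, patient_id = patient,
                          min_hist = config$min_hist,
                          max_hist = config$max_hist)
  list(panel = panel, biomarkers = bm, calendar = calendar, ami = ami,
       labels = labels, eligible = eligible, samples = samples)
}

#' Run the full forecasting pipeline
#'
#' Simulates or reads the cohort, builds the digital biomarkers, detects
#' exacerbation events, assembles eligible windowed samples, splits by
#' patient, trains the LSTM, and evaluates on the held-out test patients at
#' the MCC-maximizing threshold. All artifacts (tidy CSVs, the metrics
#' table and a JSON run manifest with seed and config hash) land in
#' `config$out_dir`. Identical config + seed reproduces the run exactly.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `report` (the test-set
#'   [metrics_report()]), `reports` (test and validation), `partition`,
#'   `samples` per partition, `model`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$simulate)) {
    stage_msg("simulate: ", config$simulate$n_patients, " patients x ",
              config$simulate$days, " days")
    cohort <- simulate_cohort(config$simulate)
    q_table <- cohort$questionnaire
    s_table <- cohort$sobriety
  } else {
    stage_msg("read: ", config$inputs$questionnaire)
    q_table <- read_questionnaire(config$inputs$questionnaire)
    s_table <- read_sobriety(config$inputs$sobriety)
  }
  stage_msg("inputs: ", nrow(q_table), " answers, ", nrow(s_table),
            " sobriety days")

  if (identical(config$definitions, "discover")) {
    m <- select_complete_days(q_table)
    stage_msg("factors: ", nrow(m), " complete days")
    pc <- principal_components(m)
    rot <- varimax_rotate(pc, max(2L, pc$k))
    defs <- assign_questions(rot)
    config$definitions <- list(
      motsc = defs[["MotSC-i"]], webe = defs[["WeBe-i"]]
    )
    utils::write.csv(data.frame(question = rownames(rot$loadings),
                                round(rot$loadings, 4)),
                     file.path(config$out_dir, "loadings.csv"),
                     row.names = FALSE)
  }

  patients <- sort(unique(c(q_table$patient_id, s_table$patient_id)))
  per <- lapply(patients, function(p) {
    prepare_patient(q_table, s_table, p, config)
  })
  names(per) <- patients
  samples <- bind_samples(lapply(per, `[[`, "samples"))
  stage_msg("samples: ", length(samples$windows), " (",
            sum(samples$meta$label), " positive) from ", length(patients),
            " patients")

  partition <- split_patients(patients, config$split_fractions,
                              config$split_counts, seed = config$seed)
  part_of <- partition[samples$meta$patient_id]
  subset_samples <- function(keep) {
    structure(list(windows = samples$windows[keep],
                   meta = samples$meta[keep, , drop = FALSE],
                   n_features = samples$n_features),
              class = "forecast_samples")
  }
  sets <- lapply(c(train = "train", validation = "validation", test = "test"),
                 function(p) subset_samples(which(part_of == p)))
  stage_msg("split: ", paste(names(sets), vapply(sets, function(s)
    length(s$windows), integer(1)), sep = "=", collapse = ", "))

  model <- train_forecaster(sets$train, sets$validation, config$forecaster)
  stage_msg("train: ", model$epochs_run, " epochs, best at ",
            model$best_epoch)

  reports <- list()
  for (nm in c("test", "validation")) {
    p <- predict(model, sets[[nm]])
    reports[[nm]] <- best_mcc_threshold(p, sets[[nm]]$meta$label)
    pred <- data.frame(sets[[nm]]$meta, probability = p,
                       partition = nm)
    utils::write.csv(pred,
                     file.path(config$out_dir,
                               paste0("predictions_", nm, ".csv")),
                     row.names = FALSE)
  }
  stage_msg(sprintf("evaluate: test AUC %.3f, MCC %.3f at threshold %.3f",
                    reports$test$auc, reports$test$mcc,
                    reports$test$threshold))

  # artifacts
  write_biomarkers(unlist(lapply(per, `[[`, "biomarkers"), recursive = FALSE),
                   file.path(config$out_dir, "biomarkers.csv"))
  events <- do.call(rbind, lapply(patients, function(p) {
    ev <- per[[p]]$calendar$events
    if (!nrow(ev)) return(NULL)
    data.frame(patient_id = p,
               start_date = per[[p]]$panel$date[ev$start + 1L],
               end_date = per[[p]]$panel$date[ev$end + 1L])
  }))
  utils::write.csv(events %||% data.frame(),
                   file.path(config$out_dir, "events.csv"),
                   row.names = FALSE)
  labels_df <- do.call(rbind, lapply(patients, function(p) {
    data.frame(patient_id = p, date = per[[p]]$panel$date,
               label = per[[p]]$labels$label,
               eligible = per[[p]]$eligible)
  }))
  utils::write.csv(labels_df, file.path(config$out_dir, "labels.csv"),
                   row.names = FALSE)

  info <- data.frame(
    input = config$feature_set,
    n_features = samples$n_features,
    look_ahead = paste(config$look_ahead, collapse = "-"),
    n_patients = length(unique(sets$test$meta$patient_id)),
    n_days = length(sets$test$windows)
  )
  mt <- metrics_table(reports["test"], info)
  utils::write.csv(mt, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)

  cfg_json <- jsonlite::toJSON(config_manifest(config), auto_unbox = TRUE,
                               digits = NA, null = "null")
  cfg_path <- file.path(config$out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  manifest <- list(
    created = format(t0, "%Y-%m-%dT%H:%M:%S"),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("dbmarker")),
    r_version = R.version.string,
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_samples = length(samples$windows),
    partition_sizes = as.list(table(partition)),
    best_epoch = model$best_epoch
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(config$out_dir, "manifest.json"))
  stage_msg(sprintf("done in %.1fs -> %s",
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    config$out_dir))

  invisible(list(report = reports$test, reports = reports,
                 partition = partition, samples = sets, model = model,
                 definitions = config$definitions,
                 out_dir = config$out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_manifest <- function(config) {
  list(
    source = if (is.null(config$simulate)) config$inputs else
      config$simulate[setdiff(names(config$simulate), "start_date")],
    definitions = lapply(config$definitions, function(d)
      list(name = d$name, questions = d$questions)),
    alpha = config$alpha, feature_set = config$feature_set,
    look_ahead = config$look_ahead,
    split_fractions = config$split_fractions,
    split_counts = config$split_counts,
    forecaster = unclass(config$forecaster),
    ami_min = config$ami_min, startup_days = config$startup_days,
    min_hist = config$min_hist, max_hist = config$max_hist,
    seed = config$seed
  )
}

#' Clinical-course plot for one patient
#'
#' Stacked time-series panels over treatment day: wellbeing (raw daily
#' average and WeBe-i), motivation/self-confidence (raw and MotSC-i) and
#' the sobriety index, with day markers for no-alcohol, alcohol-detected
#' and all-tests-omitted days.
#'
#' @param panel A [build_day_grid()] panel.
#' @param biomarkers List with `motsc` and `webe` series.
#' @param out_path Output image path (`.png`, `.pdf` or `.svg`).
#' @param ami Optional AMI series; defaults to [sobriety_index()] of the
#'   panel's status column.
#' @return The output path, invisibly; the ggplot object as attribute
#'   `"plot"`.
#' @export
plot_patient <- function(panel, biomarkers, out_path, ami = NULL) {
  if (!nrow(panel)) {
    stop("panel is empty", call. = FALSE)
  }
  if (is.null(ami)) {
    ami <- sobriety_index(panel$status)
  }
  day <- panel$day
  series <- rbind(
    data.frame(day = day, value = raw_daily_series(panel, webe_questions),
               panel_name = "Wellbeing", kind = "daily average"),
    data.frame(day = day, value = biomarkers$webe$value,
               panel_name = "Wellbeing", kind = "digital biomarker"),
    data.frame(day = day, value = raw_daily_series(panel, motsc_questions),
               panel_name = "Motivation/Self-confidence",
               kind = "daily average"),
    data.frame(day = day, value = biomarkers$motsc$value,
               panel_name = "Motivation/Self-confidence",
               kind = "digital biomarker"),
    data.frame(day = day, value = ami, panel_name = "Sobriety index",
               kind = "digital biomarker")
  )
  series$panel_name <- factor(series$panel_name,
                              levels = c("Wellbeing",
                                         "Motivation/Self-confidence",
                                         "Sobriety index"))
  marks <- data.frame(day = day, status = panel$status)
  marks <- marks[!is.na(marks$status), , drop = FALSE]
  marks$status <- factor(marks$status,
                         levels = c("no_alcohol", "alcohol_detected",
                                    "all_omitted"),
                         labels = c("no alcohol detected",
                                    "alcohol detected",
                                    "all breathalyzer tests omitted"))
  marks$panel_name <- factor("Sobriety index", levels = levels(series$panel_name))

  g <- ggplot2::ggplot(series, ggplot2::aes(x = day, y = value)) +
    ggplot2::geom_line(ggplot2::aes(linetype = kind), na.rm = TRUE) +
    ggplot2::geom_point(
      data = marks,
      ggplot2::aes(x = day, y = -6, shape = status, colour = status),
      inherit.aes = FALSE, size = 1.6, na.rm = TRUE) +
    ggplot2::scale_shape_manual(values = c(
      "no alcohol detected" = 16, "alcohol detected" = 15,
      "all breathalyzer tests omitted" = 18), drop = FALSE) +
    ggplot2::scale_colour_manual(values = c(
      "no alcohol detected" = "forestgreen", "alcohol detected" = "firebrick",
      "all breathalyzer tests omitted" = "black"), drop = FALSE) +
    ggplot2::facet_wrap(~panel_name, ncol = 1) +
    ggplot2::coord_cartesian(ylim = c(-10, 100),
                             xlim = range(day)) +
    ggplot2::labs(x = "Treatment day", y = "Index value (0-100)",
                  linetype = NULL, shape = NULL, colour = NULL,
                  title = paste("Patient", attr(panel, "patient_id"))) +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(legend.position = "bottom")

  ggplot2::ggsave(out_path, g, width = 8, height = 6, dpi = 150)
  out <- invisible(out_path)
  attr(out, "plot") <- g
  out
}
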