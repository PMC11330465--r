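#' Demo pipeline configuration
#'
#' Three simulated ventilation scenarios that together produce all three
#' cycle types: a gentle pattern with a generous leak (type I: peak
#' expiratory flow stays below the EPAP bias flow), an intermediate
#' pattern (type II: CO2 enters the ventilator limb but is flushed before
#' the next inspiration) and a fast, large-tidal-volume pattern against a
#' small leak (type III: CO2 persists at inspiration onset and is
#' re-inhaled).
#'
#' @param duration seconds of signal per scenario.
#' @param seed integer master seed; scenario seeds derive from it.
#' @param noise logical: add channel noise.
#' @return A pipeline configuration list for [run_pipeline()].
#' @export
demo_pipeline_config <- function(duration = 120, seed = 1L, noise = TRUE) {
  nd <- if (noise) list(pressure = 0.2, flow = 5, co2 = 0.02)
        else list(pressure = 0, flow = 0, co2 = 0)
  list(
    seed = as.integer(seed),
    scenarios = list(
      list(name = "gentle_highleak",
           patient = patient_config(respiratory_rate = 12, tidal_volume = 300,
                                    ti_fraction = 0.4, exp_flow_tau = 0.5,
                                    noise_sd = nd, seed = seed),
           circuit = circuit_config(leak_conductance = 160),
           interface = "noninvasive", duration = duration),
      list(name = "intermediate",
           patient = patient_config(respiratory_rate = 15, tidal_volume = 450,
                                    ti_fraction = 0.4, exp_flow_tau = 0.4,
                                    noise_sd = nd, seed = seed + 1L),
           circuit = circuit_config(leak_conductance = 90),
           interface = "invasive", duration = duration),
      list(name = "fast_lowleak",
           patient = patient_config(respiratory_rate = 30, tidal_volume = 700,
                                    ti_fraction = 0.4, exp_flow_tau = 0.35,
                                    noise_sd = nd, seed = seed + 2L),
           circuit = circuit_config(leak_conductance = 40),
           interface = "invasive", duration = duration)),
    segmentation = segmentation_config(),
    labeler = labeler_config(),
    mlp = mlp_config(seed = seed),
    run_stats = TRUE, run_classifier = TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of [patient_config()], [circuit_config()],
#' [segmentation_config()], [labeler_config()] and [mlp_config()] may be
#' given per scenario under their constructor-argument names; omitted
#' fields keep their defaults.
#'
#' @param path YAML file.
#' @param seed optional integer overriding the file's seed.
#' @return A pipeline configuration list for [run_pipeline()].
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  seed <- as.integer(seed %||% y$seed %||% 1L)
  scenarios <- lapply(seq_along(y$scenarios), function(i) {
    sc <- y$scenarios[[i]]
    pat <- do.call(patient_config,
                   c(sc$patient %||% list(), list(seed = seed + i - 1L)))
    cir <- do.call(circuit_config, sc$circuit %||% list())
    list(name = sc$name %||% paste0("scenario", i), patient = pat,
         circuit = cir, interface = sc$interface %||% "invasive",
         duration = sc$duration %||% 120)
  })
  list(seed = seed, scenarios = scenarios,
       segmentation = do.call(segmentation_config, y$segmentation %||% list()),
       labeler = do.call(labeler_config, y$labeler %||% list()),
       mlp = do.call(mlp_config, c(y$mlp %||% list(), list(seed = seed))),
       run_stats = y$run_stats %||% TRUE,
       run_classifier = y$run_classifier %||% TRUE)
}

#' Run the full analysis pipeline
#'
#' simulate -> capnometer-delay alignment -> segmentation -> feature
#' extraction -> CO2-based labelling -> statistics -> CO2-free MLP
#' cross-validation. Every simulated scenario is aligned with the delay of
#' its own circuit configuration, so the CO2 channels are back in phase
#' with pressure and flow before anything downstream runs.
#'
#' @param config list from [demo_pipeline_config()] or
#'   [read_pipeline_config()].
#' @param out_dir optional directory; if given, the feature, label, truth
#'   and per-fold tables are written there as CSV.
#' @param verbose narrate cycle counts and exclusions.
#' @return A report bundle: `features` (with `cycle_type` from the
#'   labeler), `labels`, `truth`, `composition`, `anova`, `cda`, `cv`,
#'   `seed`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  all_feat <- list(); all_lab <- list(); all_truth <- list()
  for (sc in config$scenarios) {
    sim <- simulate_recording(sc$patient, sc$circuit, duration = sc$duration,
                              interface = sc$interface,
                              subject_id = sc$name)
    rec <- align_capnogram(sim$recording,
                           line_volume = sc$circuit$sample_line_volume,
                           pump_flow = sc$circuit$pump_flow)
    cycles <- segment_recording(rec, config$segmentation)
    if (nrow(cycles) == 0)
      stop_invalid("segmentation found no cycles in scenario ", sc$name)
    feat <- extract_feature_table(rec, cycles)
    lab <- label_cycles(rec, cycles, config$labeler)
    say(sprintf("%s: %d cycles, types %s", sc$name, nrow(cycles),
                paste(names(table(lab$type)), table(lab$type),
                      sep = "=", collapse = " ")))
    feat$scenario <- sc$name; lab$scenario <- sc$name
    tr <- sim$truth; tr$scenario <- sc$name
    all_feat[[sc$name]] <- feat
    all_lab[[sc$name]] <- lab
    all_truth[[sc$name]] <- tr
  }
  features <- do.call(rbind, all_feat)
  labels <- do.call(rbind, all_lab)
  truth <- do.call(rbind, all_truth)
  rownames(features) <- rownames(labels) <- rownames(truth) <- NULL
  features$cycle_type <- labels$type
  analyzable <- features$cycle_type %in% c("I", "II", "III")
  say(sprintf("%d/%d analyzable cycles (%d borderline/excluded)",
              sum(analyzable), nrow(features), sum(!analyzable)))
  fa <- features[analyzable, , drop = FALSE]
  fa$cycle_type <- factor(fa$cycle_type, levels = c("I", "II", "III"))
  fa$cycle_type <- droplevels(fa$cycle_type)
  composition <- summarize_labels(labels)
  anova <- cda <- cv <- NULL
  vars <- setdiff(names(fa), c("cycle", "scenario", "cycle_type"))
  if (isTRUE(config$run_stats) && nlevels(fa$cycle_type) >= 2) {
    keep <- vars[vapply(vars, function(v) var(fa[[v]]) > 0, logical(1))]
    anova <- feature_anova_table(fa, vars = keep)
    cda_vars <- intersect(co2_free_predictors(), keep)
    cda <- cda_fit(fa[, cda_vars], fa$cycle_type)
  }
  if (isTRUE(config$run_classifier)) {
    preds <- intersect(co2_free_predictors(), vars)
    cv <- run_cv(fa, predictors = preds, config = config$mlp)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)
    write.csv(labels, file.path(out_dir, "labels.csv"), row.names = FALSE)
    write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
    if (!is.null(cv))
      write.csv(cv$per_fold, file.path(out_dir, "cv_folds.csv"),
                row.names = FALSE)
  }
  list(features = features, labels = labels, truth = truth,
       composition = composition, anova = anova, cda = cda, cv = cv,
       seed = config$seed)
}
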