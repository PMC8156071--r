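# End-to-end orchestration: synth -> extract -> split -> train ->
# qc_grid -> saliency, under one config, with a JSON run manifest that
# records per-stage outputs and their digests. Stage seeds are derived
# from the global seed and the stage name, so re-running a stage does not
# depend on execution order.

PIPELINE_STAGES <- c("synth", "extract", "split", "train", "qc_grid",
                     "saliency")

#' Default pipeline configuration
#'
#' A plain nested list; override any entry, or load one from YAML with
#' [load_pipeline_config()]. The defaults describe a desk-scale run: a
#' three-class cohort rendered at 1 um/px, the base family member
#' (phi = 0), a short learning-rate screen, and the published 5 x 5
#' QC-threshold grid.
#'
#' @param workdir working directory for all stage outputs.
#' @param seed global seed; every stage seed is derived from it.
#' @return nested configuration list.
#' @export
pipeline_config <- function(workdir = "lymphopatch_run", seed = 1L) {
  list(
    workdir = workdir,
    seed = as.integer(seed),
    synth = list(cases_per_class = 15L, patches_per_case = c(12L, 24L),
                 um_per_px = 1.0,
                 classes = c("SLL_CLL", "DLBCL", "LN_LUNG")),
    extract = list(patch_size_um = 100),
    split = list(fractions = c(0.6, 0.2, 0.2), stratify_by_class = TRUE),
    train = list(phi = 0L, candidate_lrs = c(1e-2, 3e-3),
                 screen_epochs = 4L, epochs = 16L, batch_size = 32L,
                 patience = 10L),
    qc = list(pqc_thresholds = seq(0.5, 0.9, by = 0.1),
              cqc_thresholds = seq(0.5, 0.9, by = 0.1)),
    saliency = list(noise_fraction = 0.005, n_samples = 50L,
                    n_examples = 3L)
  )
}

#' Load a pipeline configuration from YAML
#'
#' Entries in the file override the defaults of [pipeline_config()].
#' `${VAR}` references in character values are interpolated from the
#' environment.
#'
#' @param path YAML file.
#' @return nested configuration list.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config file: ", path)
  user <- yaml::read_yaml(path)
  interp <- function(x) {
    if (is.character(x) && length(x) == 1L) {
      for (var in unique(unlist(regmatches(x, gregexpr("\\$\\{[^}]+\\}", x))))) {
        x <- gsub(var, Sys.getenv(substr(var, 3, nchar(var) - 1)), x,
                  fixed = TRUE)
      }
      x
    } else if (is.list(x)) lapply(x, interp) else x
  }
  user <- interp(user)
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        merge_lists(base[[nm]], over[[nm]])
      } else over[[nm]]
    }
    base
  }
  merge_lists(pipeline_config(), user)
}

#' Validate a pipeline configuration
#'
#' Checks are reported as messages, not exceptions, so a driver can print
#' all of them at once.
#'
#' @param config configuration list ([pipeline_config()]).
#' @return character vector of violations; empty when the config is valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  fr <- config$split$fractions
  if (length(fr) != 3L || abs(sum(fr) - 1) > 1e-9) {
    v <- c(v, sprintf("split fractions must sum to 1 (got %s = %g)",
                      paste(fr, collapse = " + "), sum(fr)))
  }
  if (any(fr < 0 | fr > 1)) v <- c(v, "split fractions must lie in [0, 1]")
  b <- config$train$batch_size
  if (b < 1 || bitwAnd(as.integer(b), as.integer(b) - 1L) != 0L) {
    v <- c(v, sprintf("batch_size must be a power of two (got %s", b))
  }
  if (config$synth$um_per_px <= 0) v <- c(v, "um_per_px must be positive")
  if (config$extract$patch_size_um <= 0) {
    v <- c(v, "patch_size_um must be positive")
  }
  ppc <- config$synth$patches_per_case
  if (ppc[1] < 1 || ppc[2] < ppc[1]) {
    v <- c(v, "patches_per_case must be an increasing range with lower bound >= 1")
  }
  for (thr in c(config$qc$pqc_thresholds, config$qc$cqc_thresholds)) {
    if (thr < 0 || thr > 1) {
      v <- c(v, sprintf("QC threshold %g outside [0, 1]", thr))
    }
  }
  if (config$saliency$noise_fraction < 0) {
    v <- c(v, "saliency noise_fraction must be >= 0")
  }
  if (config$saliency$n_samples < 1) {
    v <- c(v, "saliency n_samples must be >= 1")
  }
  v
}

stage_dir <- function(config, stage) file.path(config$workdir, stage)

pipeline_log <- function(stage, seed, ...) {
  message(sprintf("[%s seed=%d] %s", stage, seed, paste0(...)))
}

digest_files <- function(paths) {
  paths <- paths[file.exists(paths)]
  md5 <- tools::md5sum(paths)
  lapply(seq_along(paths), function(i) {
    list(path = unname(paths[i]), md5 = unname(md5[i]))
  })
}

require_stage_output <- function(config, stage, path) {
  if (!file.exists(path)) {
    stop("stage dependency missing: '", path, "' (produced by stage '",
         stage, "'); run that stage first")
  }
  path
}

#' Run the pipeline
#'
#' Executes the requested stages in canonical order. Each stage writes its
#' outputs under `workdir/<stage>/` and an entry (outputs + md5 digests +
#' stage seed) into the run manifest, which is also written to
#' `workdir/manifest.json`. A failed stage halts the run; completed
#' stages' outputs remain on disk, so the run is resumable by naming the
#' remaining stages.
#'
#' @param config configuration list ([pipeline_config()]).
#' @param stages subset of `c("synth", "extract", "split", "train",
#'   "qc_grid", "saliency")`; default all.
#' @return the run manifest (list), invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = PIPELINE_STAGES) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  bad <- validate_config(config)
  if (length(bad)) stop("invalid config:\n  ", paste(bad, collapse = "\n  "))
  dir.create(config$workdir, recursive = TRUE, showWarnings = FALSE)

  cfg_path <- file.path(config$workdir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA)
  manifest_path <- file.path(config$workdir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else list()
  manifest$config_hash <- unname(tools::md5sum(cfg_path))
  manifest$package_version <-
    as.character(utils::packageVersion("lymphopatch"))
  manifest$stages <- manifest$stages %||% list()

  for (stage in stages) {
    seed <- stage_seed(config$seed, stage)
    t0 <- Sys.time()
    outputs <- switch(stage,
      synth = run_stage_synth(config, seed),
      extract = run_stage_extract(config, seed),
      split = run_stage_split(config, seed),
      train = run_stage_train(config, seed),
      qc_grid = run_stage_qc(config, seed),
      saliency = run_stage_saliency(config, seed))
    manifest$stages[[stage]] <- list(
      seed = seed,
      started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      outputs = digest_files(outputs))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(manifest)
}

run_stage_synth <- function(config, seed) {
  out <- stage_dir(config, "synth")
  cohort <- generate_cohort(synthetic_cohort_config(
    cases_per_class = config$synth$cases_per_class,
    patches_per_case = config$synth$patches_per_case,
    um_per_px = config$synth$um_per_px,
    patch_size_um = config$extract$patch_size_um,
    classes = config$synth$classes, seed = seed))
  manifest <- write_cohort(cohort, out)
  pipeline_log("synth", seed, nrow(manifest), " cases written to ", out)
  c(file.path(out, "manifest.csv"), manifest$image_path,
    manifest$annotation_path)
}

run_stage_extract <- function(config, seed) {
  synth_manifest <- require_stage_output(
    config, "synth", file.path(stage_dir(config, "synth"), "manifest.csv"))
  man <- utils::read.csv(synth_manifest)
  out <- stage_dir(config, "extract")
  tile_dir <- file.path(out, "patches")
  dir.create(tile_dir, recursive = TRUE, showWarnings = FALSE)
  index <- list(); reports <- list()
  for (i in seq_len(nrow(man))) {
    im <- read_annotated_image(man$image_path[i], man$annotation_path[i])
    ex <- extract_patches(im, config$extract$patch_size_um)
    reports[[i]] <- ex$report
    for (r in ex$records) {
      path <- file.path(tile_dir, sprintf("%s_%s_tile%s.png", r$case_id,
                                          r$true_class,
                                          sub(".*tile", "", r$patch_id)))
      write_image_png(r$tile, path)
      index[[length(index) + 1L]] <- data.frame(
        patch_id = r$patch_id, case_id = r$case_id,
        true_class = r$true_class, x = r$origin_px[["x"]],
        y = r$origin_px[["y"]], side_px = r$side_px, path = path)
    }
  }
  index <- do.call(rbind, index)
  report <- do.call(rbind, reports)
  low <- flag_low_patch_cases(report)
  if (length(low)) {
    pipeline_log("extract", seed, "cases below the 10-patch minimum: ",
                 paste(low, collapse = ", "))
  }
  utils::write.csv(index, file.path(out, "patch_index.csv"),
                   row.names = FALSE)
  utils::write.csv(report, file.path(out, "report.csv"), row.names = FALSE)
  pipeline_log("extract", seed, nrow(index), " patches from ",
               nrow(report), " cases")
  c(file.path(out, "patch_index.csv"), file.path(out, "report.csv"),
    index$path)
}

run_stage_split <- function(config, seed) {
  report_path <- require_stage_output(
    config, "extract", file.path(stage_dir(config, "extract"), "report.csv"))
  report <- utils::read.csv(report_path)
  out <- stage_dir(config, "split")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cohort <- data.frame(case_id = report$case_id, class = report$true_class,
                       n_patches = report$n_patches)
  cohort <- split_cases(cohort, split_config(
    fractions = config$split$fractions,
    stratify_by_class = config$split$stratify_by_class, seed = seed))
  utils::write.csv(cohort, file.path(out, "cohort.csv"), row.names = FALSE)
  summ <- summarize_subsets(cohort)
  utils::write.csv(summ, file.path(out, "subset_summary.csv"),
                   row.names = FALSE)
  writeLines(format_subset_summary(summ),
             file.path(out, "subset_summary.txt"))
  pipeline_log("split", seed, "subset sizes: ",
               paste(names(table(cohort$subset)), table(cohort$subset),
                     sep = "=", collapse = ", "))
  file.path(out, c("cohort.csv", "subset_summary.csv", "subset_summary.txt"))
}

#' Render a subset summary as a fixed-width text table
#' @param summ data.frame from [summarize_subsets()].
#' @return character vector of text lines.
#' @export
format_subset_summary <- function(summ) {
  lines <- "Number of extracted image patches per group"
  for (s in unique(summ$subset)) {
    lines <- c(lines, "", paste0(s, " set"))
    sub <- summ[summ$subset == s, ]
    lines <- c(lines, sprintf(
      "  %-14s cases=%-4d total=%-6d min=%-4d max=%-4d mean=%-7.1f median=%g",
      sub$class, sub$n_cases, sub$total, sub$min, sub$max, sub$mean,
      sub$median))
  }
  lines
}

load_patch_records <- function(index) {
  lapply(seq_len(nrow(index)), function(i) {
    list(patch_id = index$patch_id[i], case_id = index$case_id[i],
         true_class = index$true_class[i],
         tile = read_image_png(index$path[i]))
  })
}

run_stage_train <- function(config, seed) {
  index_path <- require_stage_output(
    config, "extract",
    file.path(stage_dir(config, "extract"), "patch_index.csv"))
  cohort_path <- require_stage_output(
    config, "split", file.path(stage_dir(config, "split"), "cohort.csv"))
  index <- utils::read.csv(index_path)
  cohort <- utils::read.csv(cohort_path)
  out <- stage_dir(config, "train")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  index$subset <- cohort$subset[match(index$case_id, cohort$case_id)]
  leaks <- assert_single_subset(index, cohort)
  if (length(leaks)) {
    stop("case-level leak check failed for: ", paste(leaks, collapse = ", "))
  }
  classes <- sort(unique(index$true_class))
  scaling <- scaling_spec(phi = config$train$phi)
  sets <- lapply(c(TRAIN = "TRAIN", VAL = "VAL", TEST = "TEST"),
                 function(s) {
    rows <- index[index$subset == s, , drop = FALSE]
    build_patch_dataset(load_patch_records(rows), classes,
                        scaling$resolution)
  })

  lrs <- config$train$candidate_lrs
  if (length(lrs) > 1L) {
    sweep <- lr_sweep(sets$TRAIN, sets$VAL, scaling, lrs,
                      screen_epochs = config$train$screen_epochs,
                      seed = seed, batch_size = config$train$batch_size,
                      class_list = classes)
    utils::write.csv(sweep$curves, file.path(out, "sweep_curves.csv"),
                     row.names = FALSE)
    lr <- sweep$chosen_lr
    pipeline_log("train", seed, "chosen learning rate: ", lr)
  } else lr <- lrs

  fit <- train(sets$TRAIN, sets$VAL,
               train_config(scaling, learning_rate = lr,
                            batch_size = config$train$batch_size,
                            epochs = config$train$epochs,
                            patience = config$train$patience,
                            seed = seed, class_list = classes))
  utils::write.csv(fit$curves, file.path(out, "curves.csv"),
                   row.names = FALSE)
  saveRDS(fit, file.path(out, "model.rds"))
  for (s in c("VAL", "TEST")) {
    preds <- predict_patches(fit, sets[[s]])
    utils::write.csv(preds,
                     file.path(out, sprintf("predictions_%s.csv",
                                            tolower(s))),
                     row.names = FALSE)
  }
  pipeline_log("train", seed, sprintf(
    "best val acc %.3f at epoch %d", fit$best_val_acc, fit$best_epoch))
  file.path(out, c("curves.csv", "model.rds", "predictions_val.csv",
                   "predictions_test.csv"))
}

run_stage_qc <- function(config, seed) {
  preds_path <- require_stage_output(
    config, "train",
    file.path(stage_dir(config, "train"), "predictions_test.csv"))
  preds <- utils::read.csv(preds_path)
  out <- stage_dir(config, "qc_grid")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  classes_present <- sub("^p_", "", grep("^p_", names(preds), value = TRUE))
  map <- default_class_map(classes_present)
  grid <- qc_grid(preds, config$qc$pqc_thresholds, config$qc$cqc_thresholds,
                  map = map)
  utils::write.csv(grid, file.path(out, "grid_long.csv"), row.names = FALSE)
  utils::write.csv(format_qc_grid(grid), file.path(out, "grid_wide.csv"),
                   row.names = FALSE)
  agg <- aggregate_probs(preds, map)
  classes <- attr(agg, "classes")
  patch_cb <- confusion_and_bacc(agg$true_class, patch_argmax(agg, classes),
                                 classes)
  votes <- do.call(rbind, lapply(split(agg, agg$case_id), vote_case,
                                 cqc_threshold = 0, classes = classes))
  case_cb <- confusion_and_bacc(votes$true_class, votes$predicted_class,
                                classes)
  utils::write.csv(as.data.frame(patch_cb$normalized),
                   file.path(out, "confusion_patch.csv"))
  utils::write.csv(as.data.frame(case_cb$normalized),
                   file.path(out, "confusion_case.csv"))
  pipeline_log("qc_grid", seed, sprintf(
    "patch BACC %.2f%%, case BACC %.2f%% (no QC); grid max %.2f%%",
    100 * patch_cb$bacc, 100 * case_cb$bacc, max(grid$bacc_pct)))
  file.path(out, c("grid_long.csv", "grid_wide.csv", "confusion_patch.csv",
                   "confusion_case.csv"))
}

run_stage_saliency <- function(config, seed) {
  model_path <- require_stage_output(
    config, "train", file.path(stage_dir(config, "train"), "model.rds"))
  index_path <- require_stage_output(
    config, "extract",
    file.path(stage_dir(config, "extract"), "patch_index.csv"))
  fit <- readRDS(model_path)
  index <- utils::read.csv(index_path)
  out <- stage_dir(config, "saliency")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  classes <- fit$config$class_list
  res <- fit$model$resolution
  outputs <- character(0)
  k <- 0L
  for (cls in classes) {
    rows <- index[index$true_class == cls, , drop = FALSE]
    if (nrow(rows) == 0L) next
    k <- k + 1L
    if (k > config$saliency$n_examples) break
    row <- rows[1L, ]
    tile <- read_image_png(row$path)
    x <- resize_bilinear(tile / 255, res)
    sm <- smoothgrad(fit$model, x, match(cls, classes),
                     saliency_config(config$saliency$noise_fraction,
                                     config$saliency$n_samples,
                                     seed = seed))
    heat_path <- file.path(out, paste0(row$patch_id, "_heatmap.png"))
    over_path <- file.path(out, paste0(row$patch_id, "_overlay.png"))
    side_path <- file.path(out, paste0(row$patch_id, ".json"))
    png::writePNG(sm$heatmap, heat_path)
    write_image_png(overlay(x, sm), over_path)
    jsonlite::write_json(
      list(patch_id = row$patch_id, target_class = cls,
           noise_fraction = config$saliency$noise_fraction,
           n_samples = config$saliency$n_samples, seed = seed),
      side_path, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, heat_path, over_path, side_path)
  }
  pipeline_log("saliency", seed, k - (k > config$saliency$n_examples),
               " heatmaps written")
  outputs
}
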