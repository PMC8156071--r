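# A small trained classifier and its cohort, built once per test run and
# shared across trainer, saliency and acceptance tests.

.trained_cache <- new.env(parent = emptyenv())

demo_classes <- c("SLL_CLL", "DLBCL", "LN_LUNG")

# cohort -> records + case table, at 1 um/px desk scale
build_demo_cohort <- function(seed, cases_per_class = 10,
                              patches_per_case = c(10, 16),
                              classes = demo_classes) {
  co <- generate_cohort(synthetic_cohort_config(
    cases_per_class = cases_per_class, patches_per_case = patches_per_case,
    um_per_px = 1, classes = classes, seed = seed))
  recs <- list(); rep_rows <- list()
  for (cid in names(co$images)) {
    ex <- extract_patches(co$images[[cid]])
    recs <- c(recs, ex$records)
    rep_rows[[cid]] <- ex$report
  }
  report <- do.call(rbind, rep_rows)
  rownames(report) <- NULL
  list(records = recs,
       cases = data.frame(case_id = report$case_id,
                          class = report$true_class,
                          n_patches = report$n_patches))
}

# split records into model-ready datasets by the case-level subset table
demo_datasets <- function(demo, seed, classes = demo_classes,
                          resolution = 32) {
  cohort <- split_cases(demo$cases, split_config(seed = seed))
  sub_of <- stats::setNames(cohort$subset, cohort$case_id)
  sets <- lapply(c(TRAIN = "TRAIN", VAL = "VAL", TEST = "TEST"),
                 function(s) {
    rr <- demo$records[vapply(demo$records,
                              function(r) sub_of[[r$case_id]] == s, TRUE)]
    build_patch_dataset(rr, classes, resolution)
  })
  sets$cohort <- cohort
  sets
}

# memoised fitted model at the demo cohort scale (~30 s once per run)
demo_fit <- function() {
  if (is.null(.trained_cache$fit)) {
    demo <- build_demo_cohort(seed = 11, cases_per_class = 15,
                              patches_per_case = c(12, 24))
    sets <- demo_datasets(demo, seed = 11)
    .trained_cache$fit <- train(
      sets$TRAIN, sets$VAL,
      train_config(scaling_spec(0), learning_rate = 1e-2, epochs = 16,
                   seed = 11, class_list = demo_classes))
    .trained_cache$sets <- sets
  }
  list(fit = .trained_cache$fit, sets = .trained_cache$sets)
}
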