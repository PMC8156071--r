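# Patient-level subset assignment and cohort summaries.
#
# The unit of splitting is the patient (case): all patches of a case follow
# the case into its subset, and a hard checkpoint verifies that no case
# leaks across subsets.

SUBSETS <- c("TRAIN", "VAL", "TEST")

#' Split configuration for patient-level subset assignment
#'
#' @param fractions numeric length-3 vector `(train, val, test)` summing
#'   to 1 (default `c(0.6, 0.2, 0.2)`).
#' @param stratify_by_class split within each class stratum (default TRUE).
#' @param seed integer seed.
#' @return an object of class `split_config`.
#' @export
split_config <- function(fractions = c(0.6, 0.2, 0.2),
                         stratify_by_class = TRUE, seed = 1L) {
  stopifnot(length(fractions) == 3L, all(fractions >= 0), all(fractions <= 1))
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("split fractions must sum to 1 (got ", sum(fractions), ")")
  }
  structure(list(fractions = fractions,
                 stratify_by_class = isTRUE(stratify_by_class),
                 seed = as.integer(seed)),
            class = "split_config")
}

# Largest-remainder apportionment of n items to fractions.
# Deterministic: remainder ties are broken in subset order (train, val, test).
apportion <- function(n, fractions) {
  quota <- n * fractions
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    rem <- quota - base
    ord <- order(-rem, seq_along(rem))  # largest remainder, then subset order
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Assign cases to training, validation and test subsets
#'
#' Randomly assigns whole cases (patients) to TRAIN/VAL/TEST with
#' largest-remainder apportionment of the requested fractions, optionally
#' stratified by class so that every class is represented in every subset.
#' Assignment shuffles the sorted case ids under the seed, so the result is
#' independent of the input row order.
#'
#' @param cohort data.frame with columns `case_id`, `class` and optionally
#'   `n_patches`.
#' @param config a [split_config()].
#' @return the cohort data.frame with a `subset` column added.
#' @export
split_cases <- function(cohort, config = split_config()) {
  stopifnot(is.data.frame(cohort), all(c("case_id", "class") %in% names(cohort)))
  if (anyDuplicated(cohort$case_id)) stop("case_id values must be unique")
  if (nrow(cohort) < 3L) stop("need at least 3 cases to form three subsets")

  cohort$subset <- NA_character_
  strata <- if (config$stratify_by_class) split(seq_len(nrow(cohort)), cohort$class)
            else list(all = seq_len(nrow(cohort)))

  withr::with_seed(config$seed, {
    for (rows in strata) {
      ids <- sort(cohort$case_id[rows])
      ids <- sample(ids)
      sizes <- apportion(length(ids), config$fractions)
      lab <- rep(SUBSETS, times = sizes)
      cohort$subset[match(ids, cohort$case_id)] <- lab
    }
  })
  cohort
}

#' Checkpoint: every case's patches live in exactly one subset
#'
#' Compares a patch index against the case-level subset table and reports
#' any case whose patches span more than one subset, disagree with the
#' case's assigned subset, or reference an unknown case.
#'
#' @param patch_index data.frame with columns `case_id` and `subset`
#'   (one row per patch).
#' @param cohort data.frame with columns `case_id` and `subset`
#'   (one row per case).
#' @return character vector of violating case ids (empty when clean).
#' @export
assert_single_subset <- function(patch_index, cohort) {
  stopifnot(all(c("case_id", "subset") %in% names(patch_index)),
            all(c("case_id", "subset") %in% names(cohort)))
  bad <- character(0)
  unknown <- setdiff(unique(patch_index$case_id), cohort$case_id)
  bad <- c(bad, unknown)
  known <- patch_index[patch_index$case_id %in% cohort$case_id, , drop = FALSE]
  if (nrow(known)) {
    per_case <- split(known$subset, known$case_id)
    assigned <- cohort$subset[match(names(per_case), cohort$case_id)]
    viol <- vapply(seq_along(per_case), function(i) {
      s <- unique(per_case[[i]])
      length(s) > 1L || !identical(s, assigned[i])
    }, logical(1))
    bad <- c(bad, names(per_case)[viol])
  }
  sort(unique(bad))
}

#' Summarize patch counts per class and subset
#'
#' Produces the cohort summary table: for every class x subset cell, the
#' number of cases and the total, minimum, maximum, mean and median of
#' per-case patch counts. Empty strata are emitted as zero rows with a flag.
#'
#' @param cohort data.frame with columns `case_id`, `class`, `n_patches`,
#'   `subset`.
#' @return data.frame with one row per class x subset combination.
#' @export
summarize_subsets <- function(cohort) {
  stopifnot(nrow(cohort) > 0,
            all(c("case_id", "class", "n_patches", "subset") %in% names(cohort)))
  classes <- sort(unique(cohort$class))
  out <- expand.grid(class = classes, subset = SUBSETS,
                     stringsAsFactors = FALSE)
  stats <- lapply(seq_len(nrow(out)), function(i) {
    n <- cohort$n_patches[cohort$class == out$class[i] &
                          cohort$subset == out$subset[i]]
    if (length(n) == 0L) {
      data.frame(n_cases = 0L, total = 0L, min = 0L, max = 0L,
                 mean = 0, median = 0, empty = TRUE)
    } else {
      data.frame(n_cases = length(n), total = sum(n), min = min(n),
                 max = max(n), mean = round(mean(n), 1),
                 median = median(n), empty = FALSE)
    }
  })
  cbind(out, do.call(rbind, stats))
}
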