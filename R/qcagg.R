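# Patch-to-case aggregation with two-level quality control.
#
# The evaluation chain is: aggregate training-class probabilities to
# evaluation classes -> patch-level quality control (PQC: drop patches whose
# top probability is below a threshold) -> per-case majority vote ->
# case-level quality control (CQC: abstain on cases whose winning vote
# fraction is below a threshold) -> row-normalized confusion matrix and
# balanced accuracy (BACC), the mean of per-class recalls.

UNCLASSIFIED <- "UNCLASSIFIED"

#' Default training and evaluation class vocabularies
#'
#' Five training classes: two B-cell lymphoma entities and tumor-free
#' lymph nodes from three resection origins. For evaluation the three
#' tumor-free origins are aggregated into one "tumor-free reference LN"
#' class.
#' @export
TRAINING_CLASSES <- c("SLL_CLL", "DLBCL", "LN_LUNG", "LN_COLON", "LN_PANCREAS")

#' @rdname TRAINING_CLASSES
#' @export
EVAL_CLASSES <- c("SLL_CLL", "DLBCL", "TUMOR_FREE_LN")

#' Class map from training classes to evaluation classes
#'
#' A named character vector mapping every training class to its evaluation
#' class. The default maps the three tumor-free lymph-node origins to the
#' aggregated `TUMOR_FREE_LN` class and is the identity elsewhere. The map
#' must be total over the classes it is applied to.
#'
#' @param training character vector of training classes.
#' @param eval_of named character vector of overrides
#'   (`training class -> evaluation class`).
#' @return named character vector (names = training classes).
#' @export
default_class_map <- function(training = TRAINING_CLASSES,
                              eval_of = c(LN_LUNG = "TUMOR_FREE_LN",
                                          LN_COLON = "TUMOR_FREE_LN",
                                          LN_PANCREAS = "TUMOR_FREE_LN")) {
  map <- stats::setNames(training, training)
  map[names(eval_of)[names(eval_of) %in% training]] <-
    eval_of[names(eval_of) %in% training]
  map
}

# p_<class> columns of a prediction table, in the given class order
prob_columns <- function(records, classes) paste0("p_", classes)

prob_matrix <- function(records, classes) {
  cols <- prob_columns(records, classes)
  missing <- setdiff(cols, names(records))
  if (length(missing)) {
    stop("prediction table lacks probability columns: ",
         paste(missing, collapse = ", "))
  }
  as.matrix(records[, cols, drop = FALSE])
}

#' Aggregate training-class probabilities to evaluation classes
#'
#' Each evaluation-class probability is the sum of the probabilities of the
#' training classes mapped to it, so the vector sum is preserved. True
#' labels are mapped through the same class map into `true_class`.
#' Aggregation happens before the patch argmax, so a patch that is
#' confidently "some tumor-free origin" keeps its confidence even when the
#' probability is split across the three origins.
#'
#' @param records prediction table: columns `patch_id`, `case_id`,
#'   `true_class` and one `p_<class>` column per training class.
#' @param map named character vector from [default_class_map()].
#' @return prediction table over evaluation classes.
#' @export
aggregate_probs <- function(records, map = default_class_map()) {
  train_classes <- sub("^p_", "", grep("^p_", names(records), value = TRUE))
  unmapped <- setdiff(union(train_classes, unique(records$true_class)),
                      names(map))
  if (length(unmapped)) {
    stop("class map does not cover: ", paste(unmapped, collapse = ", "))
  }
  eval_classes <- unique(unname(map[train_classes]))
  p <- prob_matrix(records, train_classes)
  out <- records[, setdiff(names(records), prob_columns(records, train_classes)),
                 drop = FALSE]
  for (ec in eval_classes) {
    src <- train_classes[map[train_classes] == ec]
    out[[paste0("p_", ec)]] <- rowSums(p[, match(src, train_classes),
                                         drop = FALSE])
  }
  out$true_class <- unname(map[records$true_class])
  attr(out, "classes") <- eval_classes
  out
}

#' Patch-level quality control (PQC)
#'
#' A patch survives iff its maximum class probability is at least the
#' threshold; a probability strictly less than the threshold fails.
#'
#' @param records prediction table (typically after [aggregate_probs()]).
#' @param pqc_threshold numeric in `[0, 1]`.
#' @param classes class vocabulary of the table (defaults to its `p_`
#'   columns).
#' @return list with `records` (survivors) and `pqc_not_met_pct`
#'   (percentage of input patches removed).
#' @export
apply_pqc <- function(records, pqc_threshold,
                      classes = sub("^p_", "", grep("^p_", names(records),
                                                    value = TRUE))) {
  if (!is.numeric(pqc_threshold) || pqc_threshold < 0 || pqc_threshold > 1) {
    stop("pqc_threshold must lie in [0, 1]")
  }
  maxp <- apply(prob_matrix(records, classes), 1L, max)
  keep <- maxp >= pqc_threshold
  list(records = records[keep, , drop = FALSE],
       pqc_not_met_pct = 100 * mean(!keep))
}

# per-patch predicted class: argmax over probability columns,
# first-in-class-order tie-break
patch_argmax <- function(records, classes) {
  p <- prob_matrix(records, classes)
  classes[max.col(p, ties.method = "first")]
}

#' Case-level majority vote with CQC abstention
#'
#' Assigns a case the modal predicted class of its (PQC-surviving) patches.
#' The vote fraction is the modal count divided by the number of surviving
#' patches. The case is UNCLASSIFIED when no patch survives or when the
#' vote fraction is strictly below the CQC threshold. Modal ties are broken
#' by the larger summed class probability over the surviving patches, then
#' by class order.
#'
#' @param case_records prediction table rows of a single case.
#' @param cqc_threshold numeric in `[0, 1]`.
#' @param classes class vocabulary.
#' @param n_total_patches total patches of the case before PQC (defaults to
#'   the rows given).
#' @return one-row data.frame: `case_id`, `true_class`, `predicted_class`,
#'   `vote_fraction`, `n_surviving`, `n_total`.
#' @export
vote_case <- function(case_records, cqc_threshold,
                      classes = sub("^p_", "", grep("^p_", names(case_records),
                                                    value = TRUE)),
                      n_total_patches = nrow(case_records)) {
  if (!is.numeric(cqc_threshold) || cqc_threshold < 0 || cqc_threshold > 1) {
    stop("cqc_threshold must lie in [0, 1]")
  }
  ids <- unique(case_records$case_id)
  if (length(ids) > 1L) stop("vote_case received records of multiple cases")
  n <- nrow(case_records)
  if (n == 0L) {
    return(data.frame(case_id = if (length(ids)) ids else NA_character_,
                      true_class = NA_character_,
                      predicted_class = UNCLASSIFIED,
                      vote_fraction = NA_real_,
                      n_surviving = 0L, n_total = n_total_patches))
  }
  pred <- patch_argmax(case_records, classes)
  votes <- table(factor(pred, levels = classes))
  top <- max(votes)
  tied <- names(votes)[votes == top]
  if (length(tied) > 1L) {
    sums <- colSums(prob_matrix(case_records, tied))
    tied <- tied[sums == max(sums)]  # then class order: first survivor wins
  }
  winner <- tied[1L]
  frac <- as.numeric(top) / n
  decided <- frac >= cqc_threshold
  data.frame(case_id = ids,
             true_class = case_records$true_class[1L],
             predicted_class = if (decided) winner else UNCLASSIFIED,
             vote_fraction = frac,
             n_surviving = n, n_total = n_total_patches)
}

#' Confusion matrix and balanced accuracy
#'
#' Builds the confusion matrix (rows = true class, columns = predicted
#' class) over classified items only — UNCLASSIFIED predictions are
#' excluded — and computes the balanced accuracy as the arithmetic mean of
#' per-class recalls. Classes with no classified true instances are dropped
#' from the mean with a warning. Works identically for patch-level records
#' and case-level decisions.
#'
#' @param true character vector of true classes.
#' @param predicted character vector of predicted classes (may contain
#'   UNCLASSIFIED).
#' @param classes class order for the matrix.
#' @return list: `counts` (matrix), `normalized` (row-normalized matrix),
#'   `recalls` (named numeric), `bacc` (numeric, NA when nothing is
#'   classified), `n_classified`.
#' @export
confusion_and_bacc <- function(true, predicted, classes) {
  stopifnot(length(true) == length(predicted))
  keep <- predicted != UNCLASSIFIED & !is.na(predicted)
  true <- true[keep]; predicted <- predicted[keep]
  counts <- table(factor(true, levels = classes),
                  factor(predicted, levels = classes))
  counts <- unclass(counts)
  rs <- rowSums(counts)
  normalized <- counts / ifelse(rs == 0, 1, rs)
  if (sum(keep) == 0L) {
    return(list(counts = counts, normalized = normalized,
                recalls = stats::setNames(rep(NA_real_, length(classes)),
                                          classes),
                bacc = NA_real_, n_classified = 0L))
  }
  present <- rs > 0
  if (!all(present)) {
    warning("no classified true instances for: ",
            paste(classes[!present], collapse = ", "),
            "; dropped from the BACC mean")
  }
  recalls <- diag(normalized)
  recalls[!present] <- NA_real_
  list(counts = counts, normalized = normalized,
       recalls = stats::setNames(recalls, classes),
       bacc = mean(recalls[present]), n_classified = sum(keep))
}

#' Quality-control threshold grid
#'
#' For every (PQC, CQC) threshold pair: apply patch-level QC, vote each
#' case, apply case-level QC, and record the case-level balanced accuracy
#' together with the two rejection percentages. `pqc_not_met` is the
#' percentage of patches removed by PQC (patch-denominated); `cqc_not_met`
#' is the percentage of cases left UNCLASSIFIED (case-denominated,
#' including cases whose patches were all removed by PQC).
#'
#' @param records prediction table over training classes.
#' @param pqc_thresholds,cqc_thresholds numeric vectors (defaults
#'   `seq(0.5, 0.9, 0.1)`, the published 5 x 5 grid).
#' @param map class map applied before the patch argmax
#'   ([default_class_map()]).
#' @param cqc_denominator `"survivors"` (default): the vote fraction is
#'   computed over PQC survivors; `"all"`: over all patches of the case.
#' @param aggregate_first aggregate probabilities before the patch argmax
#'   (default TRUE); FALSE takes the argmax over training classes first and
#'   maps it afterwards.
#' @return data.frame with columns `pqc`, `cqc`, `bacc_pct`,
#'   `pqc_not_met_pct`, `cqc_not_met_pct` (one row per grid cell,
#'   PQC-major order).
#' @export
qc_grid <- function(records,
                    pqc_thresholds = seq(0.5, 0.9, by = 0.1),
                    cqc_thresholds = seq(0.5, 0.9, by = 0.1),
                    map = default_class_map(),
                    cqc_denominator = c("survivors", "all"),
                    aggregate_first = TRUE) {
  stopifnot(length(pqc_thresholds) > 0, length(cqc_thresholds) > 0)
  cqc_denominator <- match.arg(cqc_denominator)

  agg <- aggregate_probs(records, map)
  classes <- attr(agg, "classes")
  if (!aggregate_first) {
    # argmax over training classes, then map: encode the mapped argmax as a
    # degenerate one-hot table so the voting code path is shared
    train_classes <- sub("^p_", "", grep("^p_", names(records), value = TRUE))
    pred_train <- patch_argmax(records, train_classes)
    maxp <- apply(prob_matrix(records, train_classes), 1L, max)
    onehot <- matrix(0, nrow(records), length(classes),
                     dimnames = list(NULL, paste0("p_", classes)))
    onehot[cbind(seq_len(nrow(records)),
                 match(unname(map[pred_train]), classes))] <- maxp
    for (cl in classes) agg[[paste0("p_", cl)]] <- onehot[, paste0("p_", cl)]
  }

  all_cases <- unique(agg$case_id)
  n_cases <- length(all_cases)
  total_per_case <- table(factor(agg$case_id, levels = all_cases))
  maxp <- apply(prob_matrix(agg, classes), 1L, max)
  true_of_case <- agg$true_class[match(all_cases, agg$case_id)]

  out <- list()
  for (pqc in pqc_thresholds) {
    keep <- maxp >= pqc
    pqc_pct <- 100 * mean(!keep)
    surv <- agg[keep, , drop = FALSE]
    # vote each case once per pqc; cqc only thresholds the vote fraction
    votes <- lapply(all_cases, function(cid) {
      cr <- surv[surv$case_id == cid, , drop = FALSE]
      denom_total <- as.integer(total_per_case[[cid]])
      v <- vote_case(cr, cqc_threshold = 0, classes = classes,
                     n_total_patches = denom_total)
      if (cqc_denominator == "all" && v$n_surviving > 0L) {
        v$vote_fraction <- v$vote_fraction * v$n_surviving / denom_total
      }
      v$case_id <- cid
      v$true_class <- true_of_case[match(cid, all_cases)]
      v
    })
    votes <- do.call(rbind, votes)
    for (cqc in cqc_thresholds) {
      classified <- votes$n_surviving > 0L &
        !is.na(votes$vote_fraction) & votes$vote_fraction >= cqc
      pred <- ifelse(classified, votes$predicted_class, UNCLASSIFIED)
      cb <- suppressWarnings(
        confusion_and_bacc(votes$true_class, pred, classes))
      out[[length(out) + 1L]] <- data.frame(
        pqc = pqc, cqc = cqc,
        bacc_pct = 100 * cb$bacc,
        pqc_not_met_pct = pqc_pct,
        cqc_not_met_pct = 100 * sum(!classified) / n_cases)
    }
  }
  do.call(rbind, out)
}

#' Format a QC grid as the published wide table
#'
#' One row per PQC threshold; per CQC threshold three columns (BACC, PQC
#' not met, CQC not met), percentages rounded to 2 decimals.
#'
#' @param grid long-format grid from [qc_grid()].
#' @return wide-format data.frame.
#' @export
format_qc_grid <- function(grid) {
  pqcs <- sort(unique(grid$pqc))
  cqcs <- sort(unique(grid$cqc))
  rows <- lapply(pqcs, function(p) {
    row <- list(pqc_pct = 100 * p,
                pqc_not_met = round(grid$pqc_not_met_pct[grid$pqc == p][1], 2))
    for (q in cqcs) {
      cell <- grid[grid$pqc == p & grid$cqc == q, ]
      row[[sprintf("bacc_cqc%d", round(100 * q))]] <- round(cell$bacc_pct, 2)
      row[[sprintf("cqc_not_met_cqc%d", round(100 * q))]] <-
        round(cell$cqc_not_met_pct, 2)
    }
    as.data.frame(row)
  })
  do.call(rbind, rows)
}
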