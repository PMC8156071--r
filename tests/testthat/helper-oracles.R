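# Independent brute-force oracles. These deliberately share no code with
# the package: plain loops, direct arithmetic, first-principles geometry.

# Tile count by rasterized containment: grid squares (anchored at the
# polygon bounding-box top-left, stride = side) whose 4 corners and centre
# all fall inside the rasterized region mask. `inside_fun(x, y)` defines
# the region analytically (e.g. a circle equation).
oracle_tile_count <- function(inside_fun, bbox, side) {
  x0 <- ceiling(bbox[1]); y0 <- ceiling(bbox[2])
  count <- 0L
  yy <- y0
  while (yy + side <= bbox[4]) {
    xx <- x0
    while (xx + side <= bbox[3]) {
      pts <- rbind(c(xx, yy), c(xx + side, yy), c(xx, yy + side),
                   c(xx + side, yy + side), c(xx + side / 2, yy + side / 2))
      ok <- TRUE
      for (i in 1:5) if (!inside_fun(pts[i, 1], pts[i, 2])) { ok <- FALSE; break }
      if (ok) count <- count + 1L
      xx <- xx + side
    }
    yy <- yy + side
  }
  count
}

# Nested-loop re-implementation of the whole QC grid evaluation.
oracle_qc_grid <- function(records, pqcs, cqcs, map) {
  train_classes <- sub("^p_", "", grep("^p_", names(records), value = TRUE))
  eval_classes <- unique(unname(map[train_classes]))
  n <- nrow(records)
  P <- matrix(0, n, length(eval_classes))
  for (j in seq_along(eval_classes)) {
    src <- train_classes[unname(map[train_classes]) == eval_classes[j]]
    for (cl in src) P[, j] <- P[, j] + records[[paste0("p_", cl)]]
  }
  true_eval <- unname(map[records$true_class])
  cases <- unique(records$case_id)
  case_rows <- split(seq_len(n), factor(records$case_id, levels = cases))
  out <- NULL
  for (pqc in pqcs) {
    maxp <- numeric(n)
    for (i in seq_len(n)) maxp[i] <- max(P[i, ])
    surv <- maxp >= pqc
    pqc_pct <- 100 * sum(!surv) / n
    for (cqc in cqcs) {
      true_v <- character(0); pred_v <- character(0); uncls <- 0L
      for (cid in cases) {
        rows <- case_rows[[cid]]
        tr <- true_eval[rows[1]]
        rows <- rows[surv[rows]]
        if (length(rows) == 0L) { uncls <- uncls + 1L; next }
        votes <- integer(length(eval_classes))
        for (r in rows) {
          k <- which.max(P[r, ])
          votes[k] <- votes[k] + 1L
        }
        top <- max(votes)
        cand <- which(votes == top)
        if (length(cand) > 1L) {
          ssum <- vapply(cand, function(k) sum(P[rows, k]), 0)
          cand <- cand[ssum == max(ssum)]
        }
        if (top / length(rows) < cqc) { uncls <- uncls + 1L; next }
        true_v <- c(true_v, tr)
        pred_v <- c(pred_v, eval_classes[cand[1]])
      }
      recalls <- numeric(0)
      for (ec in eval_classes) {
        idx <- true_v == ec
        if (sum(idx) > 0) recalls <- c(recalls, mean(pred_v[idx] == ec))
      }
      out <- rbind(out, data.frame(
        pqc = pqc, cqc = cqc,
        bacc_pct = if (length(recalls)) 100 * mean(recalls) else NA_real_,
        pqc_not_met_pct = pqc_pct,
        cqc_not_met_pct = 100 * uncls / length(cases)))
    }
  }
  out
}

# manifest of n cases cycling through the class list
fixture_manifest <- function(n_cases, classes = TRAINING_CLASSES) {
  data.frame(case_id = sprintf("case%03d", seq_len(n_cases)),
             class = rep(classes, length.out = n_cases))
}
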