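#' Evaluation configuration
#'
#' @param fp_rates the seven operating points, false positives per scan.
#' @param n_folds folds for cross-validated evaluation.
#' @param extra_hits_are_fp score extra detections on an already-credited
#'   nodule as false positives instead of ignoring them (the free-response
#'   convention is to ignore them).
#' @return An `eval_config` list.
#' @export
eval_config <- function(fp_rates = c(0.125, 0.25, 0.5, 1, 2, 4, 8),
                        n_folds = 10L, extra_hits_are_fp = FALSE) {
  if (is.unsorted(fp_rates)) stop("fp_rates must be sorted ascending")
  structure(list(fp_rates = fp_rates, n_folds = as.integer(n_folds),
                 extra_hits_are_fp = isTRUE(extra_hits_are_fp)),
            class = "eval_config")
}

#' Match detections to ground-truth nodules
#'
#' A detection is a hit when its centre lies within the nodule radius
#' (`diameter_mm / 2`) of a ground-truth centre, the standard
#' centre-within-radius criterion of the LUNA16 protocol. Detections are
#' visited in descending probability; each nodule is credited once, to the
#' highest-probability hit. Later detections hitting an already-credited
#' nodule are ignored (neither TP nor FP) unless `extra_hits_are_fp`;
#' everything else is a false positive.
#'
#' @param dets detections data frame (`seriesuid`, `coordX/Y/Z`,
#'   `probability`).
#' @param gts annotations data frame (`seriesuid`, `coordX/Y/Z`,
#'   `diameter_mm`).
#' @param extra_hits_are_fp see [eval_config()].
#' @return List: `dets` with a `match` column (`"TP"`, `"FP"`, `"ignored"`)
#'   and `gt_index`, and `gt_hit_prob` — per ground truth, the probability
#'   of its crediting detection (`-Inf` when missed).
#' @export
match_detections <- function(dets, gts, extra_hits_are_fp = FALSE) {
  dets <- dets[order(-dets$probability), , drop = FALSE]
  n <- nrow(dets)
  match <- character(n)
  gt_index <- rep(NA_integer_, n)
  gt_hit_prob <- rep(-Inf, nrow(gts))
  credited <- rep(FALSE, nrow(gts))
  for (i in seq_len(n)) {
    g <- which(gts$seriesuid == dets$seriesuid[i])
    if (length(g) > 0L) {
      dist <- sqrt((gts$coordX[g] - dets$coordX[i])^2 +
                     (gts$coordY[g] - dets$coordY[i])^2 +
                     (gts$coordZ[g] - dets$coordZ[i])^2)
      within <- dist <= gts$diameter_mm[g] / 2
    } else within <- logical(0)
    hit <- g[within]
    open <- hit[!credited[hit]]
    if (length(open) > 0L) {
      # credit the nearest still-open nodule
      j <- open[which.min(dist[match(open, g)])]
      credited[j] <- TRUE
      gt_hit_prob[j] <- dets$probability[i]
      match[i] <- "TP"; gt_index[i] <- j
    } else if (length(hit) > 0L) {
      match[i] <- if (extra_hits_are_fp) "FP" else "ignored"
    } else {
      match[i] <- "FP"
    }
  }
  dets$match <- match
  dets$gt_index <- gt_index
  list(dets = dets, gt_hit_prob = gt_hit_prob)
}

#' Build a free-response ROC curve
#'
#' Sweeps the confidence threshold over every distinct detection
#' probability; at each threshold, sensitivity is the fraction of nodules
#' credited and the false-positive rate is FP count divided by the number
#' of scans.
#'
#' @inheritParams match_detections
#' @param n_scans number of scans evaluated (scans without detections still
#'   count in the FP denominator).
#' @return A `froc_curve`: data frame of operating points (`threshold`,
#'   `fp_per_scan`, `sensitivity`) with attributes `n_scans`, `n_nodules`.
#' @export
froc_curve <- function(dets, gts, n_scans, extra_hits_are_fp = FALSE) {
  if (n_scans < 1) stop("n_scans must be >= 1")
  if (nrow(gts) == 0L) stop("sensitivity is undefined with zero nodules")
  m <- match_detections(dets, gts, extra_hits_are_fp)
  fp_probs <- m$dets$probability[m$dets$match == "FP"]
  thresholds <- sort(unique(m$dets$probability), decreasing = TRUE)
  pts <- data.frame(threshold = thresholds,
                    fp_per_scan = vapply(thresholds, function(t)
                      sum(fp_probs >= t) / n_scans, 0),
                    sensitivity = vapply(thresholds, function(t)
                      sum(m$gt_hit_prob >= t) / nrow(gts), 0))
  structure(pts, n_scans = n_scans, n_nodules = nrow(gts),
            class = c("froc_curve", "data.frame"))
}

#' Sensitivity at given false-positive rates
#'
#' Linear interpolation of sensitivity against FP/scan between adjacent
#' operating points; below the smallest achieved rate the curve is
#' interpolated towards `(0, 0)`, and beyond the largest it is held at the
#' rightmost sensitivity.
#'
#' @param curve a [froc_curve()].
#' @param fp_rates query rates (default the seven CPM points).
#' @return Named numeric vector of sensitivities.
#' @export
sensitivity_at <- function(curve, fp_rates = c(0.125, 0.25, 0.5, 1, 2, 4, 8)) {
  fp <- c(0, curve$fp_per_scan)
  se <- c(0, curve$sensitivity)
  # collapse duplicate fp values to their best sensitivity
  best <- tapply(se, fp, max)
  fp_u <- as.numeric(names(best)); se_u <- as.numeric(best)
  o <- order(fp_u); fp_u <- fp_u[o]; se_u <- se_u[o]
  out <- vapply(fp_rates, function(r) {
    if (r >= fp_u[length(fp_u)]) return(se_u[length(se_u)])
    approx(fp_u, se_u, xout = r, ties = max)$y
  }, 0)
  names(out) <- as.character(fp_rates)
  out
}

#' Competition performance metric
#'
#' The arithmetic mean of the sensitivities at 0.125, 0.25, 0.5, 1, 2, 4
#' and 8 false positives per scan.
#'
#' @param sensitivities exactly 7 values in `[0, 1]` (or percent in
#'   `[0, 100]`, returned on the same scale).
#' @return Their mean.
#' @export
cpm <- function(sensitivities) {
  if (length(sensitivities) != 7L)
    stop("CPM is defined over exactly 7 sensitivities, got ",
         length(sensitivities))
  mean(sensitivities)
}

#' Evaluate detections against annotations
#'
#' Convenience wrapper: FROC curve, the seven per-rate sensitivities and
#' their CPM.
#'
#' @inheritParams froc_curve
#' @param cfg an [eval_config()].
#' @return A `cpm_result` list: `curve`, `sensitivities`, `cpm`.
#' @export
evaluate_detections <- function(dets, gts, n_scans, cfg = eval_config()) {
  curve <- froc_curve(dets, gts, n_scans, cfg$extra_hits_are_fp)
  sens <- sensitivity_at(curve, cfg$fp_rates)
  structure(list(curve = curve, sensitivities = sens, cpm = cpm(sens)),
            class = "cpm_result")
}

#' @export
print.cpm_result <- function(x, ...) {
  cat("FROC sensitivities (FP/scan):\n")
  print(round(x$sensitivities, 4))
  cat(sprintf("CPM: %.4f\n", x$cpm))
  invisible(x)
}

#' Aggregate per-fold evaluation results
#'
#' @param fold_results list of `cpm_result` objects (>= 1).
#' @return List with `mean` and `sd` (sample SD across folds; `NA` with a
#'   single fold) for each per-rate sensitivity and the CPM, plus the
#'   per-fold CPMs.
#' @export
crossval_aggregate <- function(fold_results) {
  if (length(fold_results) < 1L) stop("need at least one fold")
  sens <- do.call(rbind, lapply(fold_results, `[[`, "sensitivities"))
  cpms <- vapply(fold_results, `[[`, 0, "cpm")
  one <- length(fold_results) == 1L
  list(mean = c(colMeans(sens), cpm = mean(cpms)),
       sd = if (one) rep(NA_real_, ncol(sens) + 1L)
       else c(apply(sens, 2, sd), cpm = sd(cpms)),
       fold_cpms = cpms)
}

#' Split scans into cross-validation folds
#'
#' Folds are by scan, never by nodule, so no scan leaks across folds.
#'
#' @param scan_ids character vector of scan identifiers.
#' @param n_folds number of folds.
#' @param seed shuffle seed.
#' @return Integer fold id per scan, names = scan ids.
#' @export
assign_folds <- function(scan_ids, n_folds = 10L, seed = 1L) {
  set.seed(as.integer(seed))
  ids <- unique(scan_ids)
  fold <- rep(seq_len(n_folds), length.out = length(ids))[sample(length(ids))]
  setNames(fold, ids)
}
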