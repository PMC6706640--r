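#' Extract scores and known/unknown labels from a matrix + reference
#'
#' @param im An interaction matrix (see [build_matrix()]).
#' @param reference A [reference_set()] (entries must lie within the rosters).
#' @param missing How to treat unquantifiable cells: `"exclude"` drops them
#'   from both positives and negatives (default); `"nondetect"` keeps them as
#'   never-detected.
#' @return List with numeric `score`, logical `known`, and `n_missing`.
#' @keywords internal
score_labels <- function(im, reference, missing = c("exclude", "nondetect")) {
  missing <- match.arg(missing)
  if (any(!(reference$protein_id %in% im$proteins)) ||
      any(!(reference$metabolite_id %in% im$metabolites)))
    stop("reference entry outside the matrix rosters", call. = FALSE)
  known <- matrix(FALSE, length(im$proteins), length(im$metabolites),
                  dimnames = list(im$proteins, im$metabolites))
  known[cbind(match(reference$protein_id, im$proteins),
              match(reference$metabolite_id, im$metabolites))] <- TRUE
  score <- as.vector(im$delta_rf)
  known <- as.vector(known)
  n_missing <- sum(is.na(score))
  if (missing == "exclude") {
    keep <- !is.na(score)
    score <- score[keep]; known <- known[keep]
  } else {
    score[is.na(score)] <- -Inf
  }
  list(score = score, known = known, n_missing = n_missing)
}

#' Confusion counts at one relaxation-factor cutoff
#'
#' A pair is detected iff its relaxation factor is strictly greater than the
#' cutoff. True positives are detected known interactions, false negatives
#' undetected known ones; false positives and true negatives are the detected
#' and undetected pairs not in the reference. `TP + FN` always equals the
#' number of (evaluable) known pairs and `FP + TN` the number of (evaluable)
#' unknown pairs.
#'
#' @inheritParams score_labels
#' @param cutoff Relaxation-factor detection cutoff.
#' @return List of class `confusion_counts`: `cutoff`, `tp`, `fp`, `tn`,
#'   `fn`, `tpr`, `fpr`, `n_missing`.
#' @export
confusion_at_cutoff <- function(im, reference, cutoff,
                                missing = c("exclude", "nondetect")) {
  sl <- score_labels(im, reference, missing)
  det <- sl$score > cutoff
  tp <- sum(det & sl$known); fn <- sum(!det & sl$known)
  fp <- sum(det & !sl$known); tn <- sum(!det & !sl$known)
  structure(list(cutoff = cutoff, tp = tp, fp = fp, tn = tn, fn = fn,
                 tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
                 n_missing = sl$n_missing),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("cutoff %.4g: TP=%d FP=%d TN=%d FN=%d  TPR=%.3f FPR=%.3f (%d missing cells)\n",
              x$cutoff, x$tp, x$fp, x$tn, x$fn, x$tpr, x$fpr, x$n_missing))
  invisible(x)
}

#' Receiver operating characteristic over relaxation-factor cutoffs
#'
#' Computes the true- and false-positive rate of recovering the known
#' interactions at every candidate cutoff. By default the candidates are all
#' observed relaxation-factor values plus `{0, 0.5}` (an exact ROC); a fixed
#' grid, e.g. `seq(0, 0.5, by = 0.0005)`, may be supplied for parity with
#' grid-swept calibrations.
#'
#' @inheritParams score_labels
#' @param cutoffs Optional numeric vector of candidate cutoffs.
#' @return Data.frame of class `rf_roc` with columns `cutoff`, `tpr`, `fpr`,
#'   sorted by increasing cutoff.
#' @export
roc_curve <- function(im, reference, cutoffs = NULL,
                      missing = c("exclude", "nondetect")) {
  sl <- score_labels(im, reference, missing)
  n_pos <- sum(sl$known); n_neg <- sum(!sl$known)
  if (n_pos == 0L || n_neg == 0L)
    stop("degenerate reference: need at least one known and one unknown evaluable pair",
         call. = FALSE)
  if (is.null(cutoffs))
    cutoffs <- sort(unique(c(sl$score[is.finite(sl$score)], 0, 0.5)))
  cutoffs <- sort(unique(cutoffs))
  tpr <- vapply(cutoffs, function(ct) sum(sl$score > ct & sl$known) / n_pos,
                numeric(1))
  fpr <- vapply(cutoffs, function(ct) sum(sl$score > ct & !sl$known) / n_neg,
                numeric(1))
  structure(data.frame(cutoff = cutoffs, tpr = tpr, fpr = fpr),
            class = c("rf_roc", "data.frame"),
            n_pos = n_pos, n_neg = n_neg, n_missing = sl$n_missing)
}

#' Select the detection cutoff at a target false-positive rate
#'
#' Returns the smallest candidate cutoff whose FPR does not exceed the
#' target — since TPR and FPR are non-increasing in the cutoff, this
#' maximises the TPR subject to the FPR bound.
#'
#' @param roc An [roc_curve()] result.
#' @param target_fpr Highest acceptable false-positive rate.
#' @return List with `cutoff` and the achieved `tpr` and `fpr`.
#' @export
select_cutoff <- function(roc, target_fpr) {
  ok <- which(roc$fpr <= target_fpr)
  if (!length(ok)) {   # only possible on a fixed grid missing the top corner
    i <- which.min(roc$fpr)
    return(list(cutoff = roc$cutoff[i], tpr = roc$tpr[i], fpr = roc$fpr[i],
                met_target = FALSE))
  }
  i <- ok[which.min(roc$cutoff[ok])]
  list(cutoff = roc$cutoff[i], tpr = roc$tpr[i], fpr = roc$fpr[i],
       met_target = TRUE)
}

#' Area under the ROC curve
#'
#' Trapezoidal area over `fpr` in \[0, 1\], with the (0, 0) and (1, 1)
#' corners appended if the candidate cutoffs did not reach them. Equals the
#' probability that a random known pair outscores a random unknown pair
#' (ties counting one half) when the curve was built from all observed
#' values.
#'
#' @param roc An [roc_curve()] result.
#' @return Area in \[0, 1\].
#' @export
roc_auc <- function(roc) {
  fpr <- c(roc$fpr, 0, 1)
  tpr <- c(roc$tpr, 0, 1)
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' @export
plot.rf_roc <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "false-positive rate", ylab = "true-positive rate",
                 ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Calibrate the detection cutoff against the known interactions
#'
#' Convenience wrapper: builds the exact ROC and selects the cutoff at the
#' target false-positive rate.
#'
#' @inheritParams score_labels
#' @param target_fpr Highest acceptable false-positive rate.
#' @param cutoffs Optional fixed cutoff grid (see [roc_curve()]).
#' @return List with `cutoff`, `tpr`, `fpr`, `auc` and the `roc` curve.
#' @export
calibrate_cutoff <- function(im, reference, target_fpr = 0.05,
                             cutoffs = NULL,
                             missing = c("exclude", "nondetect")) {
  roc <- roc_curve(im, reference, cutoffs = cutoffs, missing = missing)
  sel <- select_cutoff(roc, target_fpr)
  c(sel, list(auc = roc_auc(roc), roc = roc))
}

#' Screen-level summary arithmetic from printed counts
#'
#' Derives the internal-consistency quantities of a screen from its headline
#' counts alone: the total pair space, the confusion counts of the known-
#' interaction recovery, the recovery (true-positive) rate, the implied
#' false-positive rate, the number of novel detections, and the mean number
#' of binding partners per interacting metabolite.
#'
#' @param n_proteins,n_metabolites Roster sizes.
#' @param n_known Number of known (reference) interactions in the pair space.
#' @param n_detected Total detections at the working cutoff.
#' @param n_known_detected Detections that are known interactions.
#' @param n_interacting_metabolites Number of metabolites with at least one
#'   detection (optional; enables the mean-partners summary).
#' @return List of class `recovery_summary`.
#' @export
recovery_summary <- function(n_proteins, n_metabolites, n_known, n_detected,
                             n_known_detected,
                             n_interacting_metabolites = NULL) {
  total <- n_proteins * n_metabolites
  tp <- n_known_detected
  fn <- n_known - tp
  fp <- n_detected - tp
  tn <- total - n_known - fp
  out <- list(total_pairs = total, tp = tp, fp = fp, tn = tn, fn = fn,
              tpr = tp / (tp + fn), fpr = fp / (fp + tn),
              n_novel = fp,
              mean_partners_per_interacting_metabolite =
                if (is.null(n_interacting_metabolites)) NA_real_
                else n_detected / n_interacting_metabolites)
  class(out) <- "recovery_summary"
  out
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("%d possible pairs; recovery TPR %.1f%% (TP=%d/%d), implied FPR %.2f%% (FP=%d/%d); %d novel\n",
              x$total_pairs, 100 * x$tpr, x$tp, x$tp + x$fn,
              100 * x$fpr, x$fp, x$fp + x$tn, x$n_novel))
  if (!is.na(x$mean_partners_per_interacting_metabolite))
    cat(sprintf("mean partners per interacting metabolite: %.2f\n",
                x$mean_partners_per_interacting_metabolite))
  invisible(x)
}
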