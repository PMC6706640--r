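#' Classify detected interactions as putative allosteric or competitive
#'
#' A detected binder chemically dissimilar to every substrate/product of its
#' target enzyme (maximum similarity strictly below the threshold, 0.5 by
#' default) is unlikely to sit in the active site and is labelled an
#' allosteric candidate; similar binders (at or above the threshold) are
#' competitive candidates. Pairs without a similarity value stay
#' `unclassified`.
#'
#' @param detections Data.frame with columns `protein_id`, `metabolite_id`
#'   and optionally `delta_rf` (e.g. the detected rows of an interaction
#'   table).
#' @param similarity Similarity table ([read_similarity_table()] format).
#' @param threshold Similarity boundary; allosteric means `< threshold`.
#' @return The detections with added `max_similarity` and `mode` columns,
#'   plus a `"summary"` attribute (mode counts and mean similarity).
#' @export
classify_binding_mode <- function(detections, similarity, threshold = 0.5) {
  key <- function(p, m) paste(p, m, sep = "\r")
  i <- match(key(detections$protein_id, detections$metabolite_id),
             key(similarity$protein_id, similarity$metabolite_id))
  sim <- similarity$max_similarity[i]
  mode <- ifelse(is.na(sim), "unclassified",
                 ifelse(sim < threshold, "allosteric_candidate",
                        "competitive_candidate"))
  out <- detections
  out$max_similarity <- sim
  out$mode <- mode
  attr(out, "summary") <- list(
    n = nrow(out),
    n_allosteric = sum(mode == "allosteric_candidate"),
    n_competitive = sum(mode == "competitive_candidate"),
    n_unclassified = sum(mode == "unclassified"),
    mean_similarity = if (all(is.na(sim))) NA_real_ else
      mean(sim, na.rm = TRUE))
  out
}

#' Detections of an interaction matrix at a cutoff
#'
#' @param im An interaction matrix (see [build_matrix()]).
#' @param cutoff Detection cutoff (strictly-greater rule).
#' @return Long data.frame of detected pairs with their relaxation factors.
#' @export
detections_at_cutoff <- function(im, cutoff) {
  long <- as.data.frame(im)
  long <- long[!is.na(long$delta_rf) & long$delta_rf > cutoff, , drop = FALSE]
  rownames(long) <- NULL
  long
}

#' Mean detections per enzyme, by pathway
#'
#' Counts detections per enzyme (optionally after removing detections whose
#' reference annotation is purely catalytic — substrate/product binding says
#' nothing about regulation) and averages within pathway groups.
#'
#' @param detections Data.frame with `protein_id`, `metabolite_id`.
#' @param pathways Data.frame with columns `protein_id`, `pathway`, covering
#'   every screened protein (also fixes which proteins count as
#'   zero-detection enzymes).
#' @param reference Optional [reference_set()], required when
#'   `exclude_catalytic = TRUE`.
#' @param exclude_catalytic Drop detections whose known type is exactly
#'   `catalytic`; `both` (catalytic and regulatory) is retained.
#' @return List with `per_protein` (data.frame `protein_id`, `pathway`,
#'   `n_detections`) and `per_pathway` (data.frame `pathway`, `n_proteins`,
#'   `mean_detections`).
#' @export
pathway_summary <- function(detections, pathways, reference = NULL,
                            exclude_catalytic = FALSE) {
  det_prot <- unique(detections$protein_id)
  un <- setdiff(det_prot, pathways$protein_id)
  if (length(un))
    stop(sprintf("unannotated protein(s): %s", paste(un, collapse = ", ")),
         call. = FALSE)
  if (exclude_catalytic) {
    if (is.null(reference))
      stop("exclude_catalytic requires a reference set", call. = FALSE)
    key <- function(p, m) paste(p, m, sep = "\r")
    cat_only <- reference[reference$type == "catalytic", , drop = FALSE]
    drop <- key(detections$protein_id, detections$metabolite_id) %in%
      key(cat_only$protein_id, cat_only$metabolite_id)
    detections <- detections[!drop, , drop = FALSE]
  }
  counts <- table(factor(detections$protein_id,
                         levels = pathways$protein_id))
  per_protein <- data.frame(protein_id = pathways$protein_id,
                            pathway = pathways$pathway,
                            n_detections = as.integer(counts),
                            stringsAsFactors = FALSE)
  agg <- split(per_protein$n_detections, per_protein$pathway)
  per_pathway <- data.frame(pathway = names(agg),
                            n_proteins = lengths(agg),
                            mean_detections = vapply(agg, mean, numeric(1)),
                            stringsAsFactors = FALSE)
  rownames(per_pathway) <- NULL
  list(per_protein = per_protein, per_pathway = per_pathway)
}

#' Welch's unequal-variance t test on two groups of counts
#'
#' Thin wrapper around the unequal-variance t test with Welch-Satterthwaite
#' degrees of freedom, as used to compare interaction counts between enzyme
#' groups (e.g. one pathway against all others).
#'
#' @param group_a,group_b Numeric vectors (each of length >= 2).
#' @param tails `"two"` or `"one"` (one-tailed: alternative `group_a` less
#'   than `group_b`).
#' @return List with `t`, `df` and `p`.
#' @export
welch_t_test <- function(group_a, group_b, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least two values", call. = FALSE)
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0)
    stop("degenerate groups: zero variance in both", call. = FALSE)
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE,
                      alternative = if (tails == "two") "two.sided" else "less")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Squared Pearson correlation of two count vectors
#'
#' @param x,y Numeric vectors of equal length (>= 3), each with positive
#'   variance.
#' @return R squared.
#' @export
correlate_counts <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal-length vectors of at least 3 values", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance", call. = FALSE)
  stats::cor(x, y)^2
}
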