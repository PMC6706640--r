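#' Relaxation factor difference for one peak
#'
#' The relaxation factor of a signal is its long-to-short spin-lock intensity
#' ratio; the interaction metric is the difference between the free-metabolite
#' ratio and the ratio in the protein's presence after protein-signal
#' subtraction:
#' \deqn{\Delta RF = \frac{M_{long}}{M_{short}} -
#'       \frac{PM_{long} - P_{long}}{PM_{short} - P_{short}}}
#' Positive values mean the metabolite relaxes faster when the protein is
#' present, i.e. binding. The ratio structure makes the value invariant under
#' a common rescaling of all six intensities. Vectorised; peaks with a
#' non-positive `M_short` or `PM_short - P_short` are unevaluable and return
#' `NA` (never a propagated `NaN`).
#'
#' @param m_short,m_long Window maxima of the metabolite-only spectra.
#' @param p_short,p_long Window maxima of the protein-only spectra.
#' @param pm_short,pm_long Window maxima of the protein + metabolites spectra.
#' @return Numeric vector of relaxation factor differences (`NA` =
#'   unevaluable).
#' @export
delta_rf <- function(m_short, m_long, p_short, p_long, pm_short, pm_long) {
  denom <- pm_short - p_short
  ok <- is.finite(m_short) & m_short > 0 & is.finite(denom) & denom > 0
  out <- rep(NA_real_, length(denom))
  out[ok] <- m_long[ok] / m_short[ok] - (pm_long[ok] - p_long[ok]) / denom[ok]
  out
}

#' Aggregate peak-level relaxation factors to one value per pair
#'
#' Only peaks free of quality flags (`unstable`, `gained`, `low_snr`) and with
#' an evaluable relaxation factor qualify. The default policy averages the
#' qualifying peaks; `median` and `max` are available and recorded in the
#' result.
#'
#' @param delta_rfs Numeric vector of peak-level values (may contain `NA`).
#' @param flags Character vector of `;`-separated flag strings, same length.
#' @param policy `"mean"`, `"median"` or `"max"`.
#' @return List with `delta_rf` (`NA` when no peak qualifies), `n_peaks_used`,
#'   `qc` (summary string) and `policy`.
#' @export
aggregate_pair <- function(delta_rfs, flags = rep("", length(delta_rfs)),
                           policy = c("mean", "median", "max")) {
  policy <- match.arg(policy)
  ok <- !is.na(delta_rfs) & !nzchar(flags)
  if (!any(ok)) {
    qc <- if (length(delta_rfs) == 0L) "no_peaks" else "no_valid_peaks"
    return(list(delta_rf = NA_real_, n_peaks_used = 0L, qc = qc,
                policy = policy))
  }
  v <- delta_rfs[ok]
  val <- switch(policy, mean = mean(v), median = stats::median(v),
                max = max(v))
  list(delta_rf = val, n_peaks_used = sum(ok), qc = "ok", policy = policy)
}

#' Assemble the protein x metabolite interaction matrix
#'
#' @param pair_values Data.frame with columns `protein_id`, `metabolite_id`,
#'   `delta_rf` and optionally `n_peaks_used`, `qc_flags`. One row per pair;
#'   duplicates are an error. Pairs absent from the input are missing cells.
#' @param proteins,metabolites Character rosters fixing the grid dimensions
#'   and order.
#' @return An object of class `interaction_matrix`: matrices `delta_rf` and
#'   `n_peaks` (proteins in rows, metabolites in columns) plus the long table.
#' @export
build_matrix <- function(pair_values, proteins, metabolites) {
  key <- paste(pair_values$protein_id, pair_values$metabolite_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (protein, metabolite) pair submitted", call. = FALSE)
  outside <- !(pair_values$protein_id %in% proteins) |
    !(pair_values$metabolite_id %in% metabolites)
  if (any(outside))
    stop("pair value outside the rosters", call. = FALSE)
  drf <- matrix(NA_real_, length(proteins), length(metabolites),
                dimnames = list(proteins, metabolites))
  npk <- matrix(0L, length(proteins), length(metabolites),
                dimnames = list(proteins, metabolites))
  ij <- cbind(match(pair_values$protein_id, proteins),
              match(pair_values$metabolite_id, metabolites))
  drf[ij] <- pair_values$delta_rf
  if ("n_peaks_used" %in% names(pair_values)) npk[ij] <- pair_values$n_peaks_used
  qc <- matrix("absent", length(proteins), length(metabolites),
               dimnames = list(proteins, metabolites))
  qc[ij] <- if ("qc_flags" %in% names(pair_values))
    as.character(pair_values$qc_flags) else
      ifelse(is.na(pair_values$delta_rf), "no_valid_peaks", "ok")
  structure(list(delta_rf = drf, n_peaks = npk, qc = qc,
                 proteins = proteins, metabolites = metabolites),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("<interaction_matrix> %d proteins x %d metabolites (%d cells, %d missing)\n",
              length(x$proteins), length(x$metabolites),
              length(x$delta_rf), sum(is.na(x$delta_rf))))
  invisible(x)
}

#' @export
as.data.frame.interaction_matrix <- function(x, ...) {
  data.frame(
    protein_id = rep(x$proteins, times = length(x$metabolites)),
    metabolite_id = rep(x$metabolites, each = length(x$proteins)),
    delta_rf = as.vector(x$delta_rf),
    n_peaks_used = as.vector(x$n_peaks),
    qc_flags = as.vector(x$qc),
    stringsAsFactors = FALSE)
}

#' Interaction counts per protein and per metabolite at a cutoff
#'
#' @param im An interaction matrix (see [build_matrix()]).
#' @param cutoff Detection cutoff (strictly-greater rule).
#' @return List with `per_protein`, `per_metabolite` (named integer vectors)
#'   and `total`.
#' @export
matrix_marginals <- function(im, cutoff) {
  det <- !is.na(im$delta_rf) & im$delta_rf > cutoff
  list(per_protein = rowSums(det), per_metabolite = colSums(det),
       total = sum(det))
}

#' Aggregate a peak table into an interaction matrix
#'
#' Convenience wrapper: applies [aggregate_pair()] to every (protein,
#' metabolite) group of a [process_study()] peak table and builds the matrix
#' over the given rosters.
#'
#' @param peaks Peak table from [process_study()].
#' @param proteins,metabolites Rosters (default: ids present in `peaks`).
#' @param policy Aggregation policy, see [aggregate_pair()].
#' @return An interaction matrix (see [build_matrix()]).
#' @export
aggregate_study <- function(peaks, proteins = unique(peaks$protein_id),
                            metabolites = unique(peaks$metabolite_id),
                            policy = "mean") {
  sp <- split(peaks, list(peaks$protein_id, peaks$metabolite_id),
              drop = TRUE)
  rows <- lapply(sp, function(g) {
    a <- aggregate_pair(g$delta_rf, g$flags, policy = policy)
    data.frame(protein_id = g$protein_id[1], metabolite_id = g$metabolite_id[1],
               delta_rf = a$delta_rf, n_peaks_used = a$n_peaks_used,
               qc_flags = a$qc, stringsAsFactors = FALSE)
  })
  build_matrix(do.call(rbind, rows), proteins, metabolites)
}
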