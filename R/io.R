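#' Read a per-metabolite reference peak list
#'
#' CSV with columns `metabolite_id, ppm, rel_intensity`. Relative intensities
#' are re-normalised so that each metabolite's strongest peak has
#' `rel_intensity == 1` (peak lists from pure-compound spectra are recorded on
#' arbitrary intensity scales).
#'
#' @param path CSV path.
#' @return A data.frame with columns `metabolite_id`, `ppm`, `rel_intensity`.
#' @export
read_peak_list <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("metabolite_id", "ppm", "rel_intensity")
  if (!all(need %in% names(df)))
    stop("peak list must have columns metabolite_id, ppm, rel_intensity",
         call. = FALSE)
  df <- df[need]
  validate_peak_list(df)
}

#' Validate (and re-normalise) a peak-list data.frame
#'
#' @param df Data.frame with columns `metabolite_id`, `ppm`, `rel_intensity`.
#' @return The validated data.frame, max-normalised per metabolite.
#' @export
validate_peak_list <- function(df) {
  if (nrow(df) == 0L) stop("peak list is empty", call. = FALSE)
  if (any(!is.finite(df$ppm)) || any(!is.finite(df$rel_intensity)) ||
      any(df$rel_intensity < 0))
    stop("peak list has non-finite ppm or negative intensity", call. = FALSE)
  for (m in unique(df$metabolite_id)) {
    i <- df$metabolite_id == m
    mx <- max(df$rel_intensity[i])
    if (mx <= 0) stop(sprintf("metabolite %s has no positive peak", m),
                      call. = FALSE)
    df$rel_intensity[i] <- df$rel_intensity[i] / mx
  }
  df
}

#' Read the known-interaction reference set
#'
#' CSV with columns `protein_id, metabolite_id, type`, where `type` is
#' `catalytic` (metabolite is substrate or product), `regulatory` (metabolite
#' modulates activity) or `both`. Duplicate (protein, metabolite) rows are
#' collapsed; a pair listed as both catalytic and regulatory becomes
#' `type = "both"`.
#'
#' @param path CSV path.
#' @return A data.frame of class `reference_set` with one row per unique pair.
#' @export
read_reference_set <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "metabolite_id", "type")
  if (!all(need %in% names(df)))
    stop("reference set must have columns protein_id, metabolite_id, type",
         call. = FALSE)
  reference_set(df[need])
}

#' Build a reference set from a data.frame of known interactions
#'
#' @param df Data.frame with columns `protein_id`, `metabolite_id`, `type`.
#' @return Deduplicated data.frame of class `reference_set`.
#' @export
reference_set <- function(df) {
  ok <- c("catalytic", "regulatory", "both")
  bad <- setdiff(unique(df$type), ok)
  if (length(bad))
    stop(sprintf("unknown interaction type label(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  if (nrow(df) == 0L) {
    out <- data.frame(protein_id = character(), metabolite_id = character(),
                      type = character(), stringsAsFactors = FALSE)
    class(out) <- c("reference_set", "data.frame")
    return(out)
  }
  key <- paste(df$protein_id, df$metabolite_id, sep = "\r")
  agg <- tapply(df$type, key, function(tt) {
    tt <- unique(tt)
    if ("both" %in% tt || all(c("catalytic", "regulatory") %in% tt)) "both"
    else tt
  })
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- data.frame(protein_id = vapply(parts, `[`, "", 1L),
                    metabolite_id = vapply(parts, `[`, "", 2L),
                    type = unname(unlist(agg)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$protein_id, out$metabolite_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("reference_set", "data.frame")
  out
}

#' Read a precomputed chemical-similarity table
#'
#' CSV with columns `protein_id, metabolite_id, max_similarity`: for every
#' pair, the maximum global chemical similarity between the metabolite and any
#' substrate/product of the protein, on \[0, 1\]. The similarity computation
#' itself (maximal-common-substructure methods) is upstream of this package;
#' the table is consumed as given.
#'
#' @param path CSV path.
#' @return A validated data.frame with one row per pair.
#' @export
read_similarity_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "metabolite_id", "max_similarity")
  if (!all(need %in% names(df)))
    stop("similarity table must have columns protein_id, metabolite_id, max_similarity",
         call. = FALSE)
  df <- df[need]
  if (any(!is.finite(df$max_similarity)) ||
      any(df$max_similarity < 0 | df$max_similarity > 1))
    stop("max_similarity values must lie in [0, 1]", call. = FALSE)
  key <- paste(df$protein_id, df$metabolite_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (protein, metabolite) pair in similarity table",
         call. = FALSE)
  df
}

#' Write an interaction matrix to disk
#'
#' Writes a long-format CSV (`protein_id, metabolite_id, delta_rf,
#' n_peaks_used, qc_flags, detected_at_cutoff`) and optionally a wide
#' protein x metabolite matrix CSV. Unquantifiable pairs get an empty
#' `delta_rf` and the flag `no_valid_peaks`. `read_interaction_table()`
#' round-trips the long file to full precision.
#'
#' @param im An interaction matrix (see [build_matrix()]).
#' @param path Path for the long-format CSV.
#' @param wide_path Optional path for the wide matrix CSV.
#' @param cutoff Optional detection cutoff used to fill `detected_at_cutoff`.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(im, path, wide_path = NULL, cutoff = NULL) {
  stopifnot(inherits(im, "interaction_matrix"))
  long <- as.data.frame(im)
  long$detected_at_cutoff <-
    if (is.null(cutoff)) NA else !is.na(long$delta_rf) & long$delta_rf > cutoff
  fmt <- long
  fmt$delta_rf <- ifelse(is.na(long$delta_rf), "",
                         sprintf("%.17g", long$delta_rf))
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  if (!is.null(wide_path))
    utils::write.csv(im$delta_rf, wide_path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read back a long-format interaction table
#'
#' @param path Path written by [write_interaction_table()].
#' @return An interaction matrix (see [build_matrix()]).
#' @export
read_interaction_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(delta_rf = "character"))
  df$delta_rf <- suppressWarnings(as.numeric(df$delta_rf))
  build_matrix(df, proteins = unique(df$protein_id),
               metabolites = unique(df$metabolite_id))
}
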