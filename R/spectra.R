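#' Construct a 1D NMR spectrum
#'
#' A `spectrum1d` holds a calibratable 1D \eqn{^1}H intensity trace on a ppm
#' axis, plus the acquisition metadata the screening pipeline needs: the sample
#' role (metabolite mix alone `"M"`, protein alone `"P"`, protein + mix `"PM"`),
#' the experiment slot within the acquisition scheme, and the spin-lock
#' (relaxation) delay. The ppm axis is always stored strictly descending
#' (high field left, the NMR plotting convention); inputs in ascending order
#' are re-sorted together with their intensities.
#'
#' @param ppm Numeric vector of chemical shifts (ppm), strictly monotone.
#' @param intensity Numeric vector of signal intensities (arbitrary units),
#'   same length as `ppm`, all finite.
#' @param sample_id Sample identifier.
#' @param role One of `"M"`, `"P"`, `"PM"`.
#' @param experiment One of `"t1rho_short_a"`, `"t1rho_short_b"`,
#'   `"t1rho_long"`, `"spin_echo"`.
#' @param spin_lock_ms Spin-lock delay in milliseconds; must be 10, 200 or 400.
#' @param protein_id,mix_id Identifiers; empty string when not applicable
#'   (an M sample has no protein, a P sample no mix).
#' @return An object of class `spectrum1d`.
#' @export
spectrum1d <- function(ppm, intensity, sample_id, role, experiment,
                       spin_lock_ms, protein_id = "", mix_id = "") {
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity))
    stop("ppm and intensity must have the same length", call. = FALSE)
  if (length(ppm) < 2L)
    stop("a spectrum needs at least two points", call. = FALSE)
  d <- diff(ppm)
  if (all(d > 0)) {            # ascending input: flip to the stored convention
    o <- rev(seq_along(ppm))
    ppm <- ppm[o]; intensity <- intensity[o]
  } else if (!all(d < 0)) {
    stop("ppm axis must be strictly monotone", call. = FALSE)
  }
  if (!all(is.finite(intensity)))
    stop("all intensities must be finite", call. = FALSE)
  role <- match.arg(role, c("M", "P", "PM"))
  experiment <- match.arg(experiment,
                          c("t1rho_short_a", "t1rho_short_b", "t1rho_long",
                            "spin_echo"))
  if (!is.numeric(spin_lock_ms) || length(spin_lock_ms) != 1L ||
      !spin_lock_ms %in% c(10, 200, 400))
    stop("invalid spin lock delay (must be 10, 200 or 400 ms)", call. = FALSE)
  structure(
    list(sample_id = as.character(sample_id), role = role,
         experiment = experiment, spin_lock_ms = as.numeric(spin_lock_ms),
         protein_id = as.character(protein_id), mix_id = as.character(mix_id),
         ppm = ppm, intensity = intensity),
    class = "spectrum1d")
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf("<spectrum1d> %s  role=%s  %s  spin_lock=%g ms\n",
              x$sample_id, x$role, x$experiment, x$spin_lock_ms))
  cat(sprintf("  %d points, %0.3f .. %0.3f ppm\n",
              length(x$ppm), x$ppm[1], x$ppm[length(x$ppm)]))
  invisible(x)
}

#' Read a spectrum from a plain-text file
#'
#' The file format is UTF-8 text: a header block of `#key: value` lines
#' (`sample_id`, `role`, `experiment`, `spin_lock_ms`, optional `protein_id`
#' and `mix_id`), followed by TAB-separated `ppm<TAB>intensity` rows.
#' Row order in the file is irrelevant; the returned axis is descending.
#'
#' @param path Path to the spectrum file.
#' @return A [spectrum1d()].
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_hdr <- grepl("^#", lines)
  hdr <- lines[is_hdr]
  body_idx <- which(!is_hdr & nzchar(trimws(lines)))
  kv <- regmatches(hdr, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", hdr))
  keys <- vapply(kv, function(m) if (length(m) == 3L) m[2] else NA_character_,
                 character(1))
  vals <- vapply(kv, function(m) if (length(m) == 3L) trimws(m[3]) else NA_character_,
                 character(1))
  meta <- stats::setNames(as.list(vals), keys)
  for (req in c("sample_id", "role", "experiment", "spin_lock_ms"))
    if (is.null(meta[[req]]) || is.na(meta[[req]]))
      stop(sprintf("missing header field '%s' in %s", req, path), call. = FALSE)
  sl <- suppressWarnings(as.numeric(meta$spin_lock_ms))
  if (is.na(sl)) stop("invalid spin lock delay (non-numeric)", call. = FALSE)
  parts <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  bad_ncol <- which(lengths(parts) != 2L)
  if (length(bad_ncol))
    stop(sprintf("parse error at line %d of %s: expected 2 tab-separated fields",
                 body_idx[bad_ncol[1]], path), call. = FALSE)
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 2, byrow = TRUE)
  bad_num <- which(!stats::complete.cases(m))
  if (length(bad_num))
    stop(sprintf("parse error at line %d of %s: non-numeric value",
                 body_idx[bad_num[1]], path), call. = FALSE)
  spectrum1d(m[, 1], m[, 2],
             sample_id = meta$sample_id, role = meta$role,
             experiment = meta$experiment, spin_lock_ms = sl,
             protein_id = if (is.null(meta$protein_id)) "" else meta$protein_id,
             mix_id = if (is.null(meta$mix_id)) "" else meta$mix_id)
}

#' Write a spectrum to the plain-text format read by [read_spectrum()]
#'
#' @param spec A [spectrum1d()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum1d"))
  hdr <- c(sprintf("#sample_id: %s", spec$sample_id),
           sprintf("#role: %s", spec$role),
           sprintf("#experiment: %s", spec$experiment),
           sprintf("#spin_lock_ms: %g", spec$spin_lock_ms),
           sprintf("#protein_id: %s", spec$protein_id),
           sprintf("#mix_id: %s", spec$mix_id))
  rows <- sprintf("%.10g\t%.10g", spec$ppm, spec$intensity)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Bundle the spectrum triple of one sample measurement
#'
#' One measurement of one sample (an M, P or PM tube) consists of two
#' short-spin-lock (10 ms) replicates recorded before and after one
#' long-spin-lock spectrum (200 ms, or 400 ms for small proteins below
#' 40 kDa whose relaxation enhancement is weaker).
#'
#' @param short_a,short_b The two 10 ms replicates ([spectrum1d()]).
#' @param long The long-delay spectrum.
#' @param sample_id,role,protein_id,mix_id Metadata; defaults taken from
#'   `short_a`.
#' @return An object of class `sample_measurement`.
#' @export
sample_measurement <- function(short_a, long, short_b,
                               sample_id = short_a$sample_id,
                               role = short_a$role,
                               protein_id = short_a$protein_id,
                               mix_id = short_a$mix_id) {
  for (s in list(short_a, long, short_b))
    stopifnot(inherits(s, "spectrum1d"))
  if (short_a$spin_lock_ms != 10 || short_b$spin_lock_ms != 10)
    stop("short replicates must use a 10 ms spin lock", call. = FALSE)
  if (!long$spin_lock_ms %in% c(200, 400))
    stop("long spectrum must use a 200 or 400 ms spin lock", call. = FALSE)
  role <- match.arg(role, c("M", "P", "PM"))
  if (role == "M" && nzchar(protein_id))
    stop("an M measurement has no protein_id", call. = FALSE)
  if (role == "P" && nzchar(mix_id))
    stop("a P measurement has no mix_id", call. = FALSE)
  structure(
    list(sample_id = sample_id, role = role, protein_id = protein_id,
         mix_id = mix_id, short_a = short_a, short_b = short_b, long = long,
         long_delay_ms = long$spin_lock_ms),
    class = "sample_measurement")
}

#' @export
print.sample_measurement <- function(x, ...) {
  cat(sprintf("<sample_measurement> %s role=%s protein=%s mix=%s long=%g ms\n",
              x$sample_id, x$role,
              if (nzchar(x$protein_id)) x$protein_id else "-",
              if (nzchar(x$mix_id)) x$mix_id else "-", x$long_delay_ms))
  invisible(x)
}
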