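#' Quality-filter and quantification thresholds
#'
#' The three peak-level quality gates and the detection settings, with the
#' screen's defaults: a peak is dropped when its two short-spin-lock
#' replicates differ by more than 5% (instability in the protein's presence),
#' when it gains intensity in the protein's presence (reference-minus-residual
#' below -0.05 on the normalised scale), or when its signal-to-noise ratio in
#' the protein-and-metabolite difference spectrum is not above 2.
#'
#' @param stability_max Maximum allowed relative difference between the two
#'   short-delay replicates (fraction).
#' @param gain_min Lower bound on `M - (PM - P)` at short delay (normalised
#'   units); smaller values flag an intensity gain.
#' @param snr_min Signal-to-noise ratio a peak must exceed.
#' @param noise_region ppm interval free of catalogued peaks used for noise
#'   estimation.
#' @param reference_window ppm interval containing the DSS reference peak.
#' @param target_fpr Target false-positive rate for cutoff calibration.
#' @param similarity_threshold Chemical-similarity boundary between putative
#'   allosteric (below) and competitive (at or above) binding.
#' @param aggregate Peak-to-pair aggregation policy: `"mean"`, `"median"` or
#'   `"max"`.
#' @return A list of class `screen_thresholds`.
#' @export
screen_thresholds <- function(stability_max = 0.05, gain_min = -0.05,
                              snr_min = 2, noise_region = c(10.5, 11.0),
                              reference_window = c(-0.2, 0.2),
                              target_fpr = 0.05, similarity_threshold = 0.5,
                              aggregate = c("mean", "median", "max")) {
  aggregate <- match.arg(aggregate)
  if (stability_max < 0) stop("stability_max must be >= 0", call. = FALSE)
  if (snr_min < 0) stop("snr_min must be >= 0", call. = FALSE)
  if (target_fpr < 0 || target_fpr > 1)
    stop("target_fpr must lie in [0, 1]", call. = FALSE)
  structure(list(stability_max = stability_max, gain_min = gain_min,
                 snr_min = snr_min, noise_region = noise_region,
                 reference_window = reference_window,
                 target_fpr = target_fpr,
                 similarity_threshold = similarity_threshold,
                 aggregate = aggregate),
            class = "screen_thresholds")
}

#' Calibrate a spectrum to its DSS reference peak
#'
#' Shifts the ppm axis so that the maximum inside the reference window sits at
#' exactly 0 ppm. Calibration against the internal DSS signal is what makes
#' the later difference spectra (PM - P - M) free of subtraction artefacts.
#'
#' @param spec A [spectrum1d()].
#' @param reference_window ppm interval expected to contain only the DSS peak.
#' @return The calibrated spectrum; the applied shift (ppm) is stored in
#'   attribute `"calibration_shift"`.
#' @export
calibrate <- function(spec, reference_window = c(-0.2, 0.2)) {
  idx <- which(spec$ppm >= reference_window[1] &
               spec$ppm <= reference_window[2])
  if (length(idx) < 3L)
    stop("reference window outside spectrum axis", call. = FALSE)
  noise <- stats::mad(spec$intensity)
  peak_height <- max(spec$intensity[idx]) - stats::median(spec$intensity)
  if (!(peak_height > 3 * noise) || peak_height <= 0)
    stop("calibration failure: no peak above 3x noise in reference window",
         call. = FALSE)
  shift <- spec$ppm[idx[which.max(spec$intensity[idx])]]
  out <- spec
  out$ppm <- spec$ppm - shift
  attr(out, "calibration_shift") <- shift
  out
}

#' Interpolate a spectrum onto a reference ppm grid
#'
#' Linear interpolation; used to bring calibrated spectra (whose axes differ
#' by their calibration shifts) onto a shared grid before summing or
#' subtracting.
#'
#' @param spec A [spectrum1d()].
#' @param ppm_ref Target descending ppm grid.
#' @return The spectrum resampled on `ppm_ref`.
#' @export
interp_spectrum <- function(spec, ppm_ref) {
  y <- stats::approx(spec$ppm, spec$intensity, xout = ppm_ref, rule = 2)$y
  out <- spec
  out$ppm <- ppm_ref
  out$intensity <- y
  out
}

#' Sum the two short-delay replicate spectra
#'
#' The two 10 ms spin-lock replicates (recorded before and after the long
#' spectrum) are summed point-wise, averaging time-dependent intensity changes
#' and matching the scan count of the long spectrum.
#'
#' @param a,b Calibrated replicates on the same ppm grid.
#' @return Their point-wise sum, marked `experiment = "t1rho_short_a"` with a
#'   `"combined"` attribute.
#' @export
sum_short_replicates <- function(a, b) {
  if (a$spin_lock_ms != 10 || b$spin_lock_ms != 10)
    stop("both replicates must use a 10 ms spin lock", call. = FALSE)
  if (length(a$ppm) != length(b$ppm) ||
      max(abs(a$ppm - b$ppm)) > 1e-9)
    stop("axis mismatch between replicates", call. = FALSE)
  out <- a
  out$intensity <- a$intensity + b$intensity
  attr(out, "combined") <- TRUE
  out
}

#' Relative difference between replicate window maxima (stability filter)
#'
#' Returns `|max_a - max_b| / mean(max_a, max_b)` over a peak window. Values
#' above the stability threshold (default 5%) mark a metabolite signal as
#' unstable over the acquisition and exclude it from analysis.
#'
#' @param a,b Calibrated replicate spectra.
#' @param window Numeric `c(ppm_lo, ppm_hi)` or a peak-window row.
#' @return The relative difference (fraction; 0 when both maxima are 0).
#' @export
stability_reldiff <- function(a, b, window) {
  w <- as_window(window)
  ma <- window_max(a, w[1], w[2])
  mb <- window_max(b, w[1], w[2])
  mid <- (ma + mb) / 2
  if (mid == 0) return(0)
  abs(ma - mb) / mid
}

#' Intensity-gain check at short delay
#'
#' Computes `I_M - (I_PM - I_P)` on intensities normalised to the
#' free-metabolite short-delay window maximum. Markedly negative values
#' (below -0.05 by default) mean the peak gained intensity in the protein's
#' presence — an artefact, not relaxation — and the peak is excluded.
#'
#' @param i_m_short,i_pm_short,i_p_short Normalised short-delay window maxima.
#' @return The gain value (negative = apparent gain).
#' @export
gain_check <- function(i_m_short, i_pm_short, i_p_short) {
  i_m_short - (i_pm_short - i_p_short)
}

#' Estimate the spectral noise level
#'
#' Standard deviation of the intensities in a signal-free ppm region after
#' removing a linear baseline.
#'
#' @param spec A [spectrum1d()].
#' @param noise_region ppm interval containing no catalogued peaks.
#' @return Noise standard deviation.
#' @export
estimate_noise <- function(spec, noise_region = c(10.5, 11.0)) {
  idx <- which(spec$ppm >= noise_region[1] & spec$ppm <= noise_region[2])
  if (length(idx) < 10L)
    stop("noise region outside axis or narrower than 10 grid points",
         call. = FALSE)
  noise_sd_vec(spec$ppm[idx], spec$intensity[idx])
}

noise_sd_vec <- function(x, y) {
  if (all(y == 0)) return(0)
  fit <- stats::lm.fit(cbind(1, x), y)
  stats::sd(fit$residuals)
}

# accept c(lo, hi) or a window data.frame row with ppm_lo/ppm_hi
as_window <- function(window) {
  if (is.data.frame(window)) c(window$ppm_lo[1], window$ppm_hi[1])
  else as.numeric(window[1:2])
}

#' Maximum intensity within a ppm window
#'
#' @param spec A [spectrum1d()].
#' @param lo,hi Window bounds, ppm (closed interval).
#' @return The window-maximum intensity.
#' @export
window_max <- function(spec, lo, hi) {
  idx <- which(spec$ppm >= lo & spec$ppm <= hi)
  if (!length(idx)) stop("window outside spectrum axis", call. = FALSE)
  max(spec$intensity[idx])
}

# Calibrate the three spectra of a measurement and return intensity vectors on
# a shared grid, plus the summed short spectrum.
process_measurement_grid <- function(meas, grid = NULL,
                                     reference_window = c(-0.2, 0.2)) {
  a <- calibrate(meas$short_a, reference_window)
  b <- calibrate(meas$short_b, reference_window)
  l <- calibrate(meas$long, reference_window)
  if (is.null(grid)) grid <- a$ppm
  a <- interp_spectrum(a, grid); b <- interp_spectrum(b, grid)
  l <- interp_spectrum(l, grid)
  list(grid = grid, short_a = a$intensity, short_b = b$intensity,
       short = a$intensity + b$intensity, long = l$intensity,
       long_delay_ms = meas$long_delay_ms)
}

# Processed (M, P, PM) triple for one protein x mix, on the M grid.
process_triple <- function(m_meas, p_meas, pm_meas, thresholds) {
  if (m_meas$role != "M" || p_meas$role != "P" || pm_meas$role != "PM")
    stop("missing or misassigned spectrum role", call. = FALSE)
  if (m_meas$long_delay_ms != pm_meas$long_delay_ms ||
      p_meas$long_delay_ms != pm_meas$long_delay_ms)
    stop("long spin-lock delays differ between M/P/PM; matched references required",
         call. = FALSE)
  M <- process_measurement_grid(m_meas, NULL, thresholds$reference_window)
  P <- process_measurement_grid(p_meas, M$grid, thresholds$reference_window)
  PM <- process_measurement_grid(pm_meas, M$grid, thresholds$reference_window)
  # protein-subtracted difference spectra: the PM quantities of the relaxation
  # factor are window maxima of PM - P, not differences of separate maxima
  d_short <- PM$short - P$short
  d_long <- PM$long - P$long
  diff_long <- d_long - M$long
  nr <- thresholds$noise_region
  idx <- which(M$grid >= nr[1] & M$grid <= nr[2])
  if (length(idx) < 10L)
    stop("noise region outside axis or narrower than 10 grid points",
         call. = FALSE)
  noise_sd <- noise_sd_vec(M$grid[idx], diff_long[idx])
  list(grid = M$grid, M = M, P = P, PM = PM, d_short = d_short,
       d_long = d_long, diff_long = diff_long,
       noise_sd = noise_sd, long_delay_ms = PM$long_delay_ms)
}

quantify_window <- function(tr, window, thresholds) {
  w <- as_window(window)
  idx <- which(tr$grid >= w[1] & tr$grid <= w[2])
  if (!length(idx)) stop("window outside spectrum axis", call. = FALSE)
  wmax <- function(v) max(v[idx])
  i_m_s <- wmax(tr$M$short);  i_m_l <- wmax(tr$M$long)
  i_p_s <- wmax(tr$P$short);  i_p_l <- wmax(tr$P$long)
  i_d_s <- wmax(tr$d_short);  i_d_l <- wmax(tr$d_long)
  if (i_m_s <= 0) stop("zero normaliser: free-metabolite short-delay maximum",
                       call. = FALSE)
  stab <- {
    ma <- max(tr$PM$short_a[idx]); mb <- max(tr$PM$short_b[idx])
    mid <- (ma + mb) / 2
    if (mid == 0) 0 else abs(ma - mb) / mid
  }
  norm <- i_m_s
  gain <- 1 - i_d_s / norm
  resid <- max(abs(tr$diff_long[idx]))
  snr <- if (tr$noise_sd > 0) resid / tr$noise_sd
         else if (resid > 1e-12) Inf else 0
  flags <- character()
  if (stab > thresholds$stability_max) flags <- c(flags, "unstable")
  if (gain < thresholds$gain_min) flags <- c(flags, "gained")
  if (!(snr > thresholds$snr_min)) flags <- c(flags, "low_snr")
  data.frame(
    i_m_short = 1, i_m_long = i_m_l / norm,
    i_p_short = i_p_s / norm, i_p_long = i_p_l / norm,
    i_d_short = i_d_s / norm, i_d_long = i_d_l / norm,
    noise_sd = tr$noise_sd / norm, snr = snr,
    stability_reldiff = stab, gain_value = gain,
    flags = paste(flags, collapse = ";"),
    long_delay_ms = tr$long_delay_ms)
}

#' Quantify one metabolite peak window for one protein
#'
#' Calibrates the M, P and PM measurements, sums the short replicates, brings
#' everything onto the M grid, and fills the window-maximum intensities that
#' enter the relaxation factor. The protein-bound quantities (`i_d_short`,
#' `i_d_long`) are quantified on the protein-subtracted difference spectra
#' `PM - P`, the form in which the processing pipeline holds them (the DSS
#' reference and the broad protein signal cancel there exactly); `i_p_*` are
#' kept for provenance. Quality-filter quantities accompany them: the
#' replicate stability difference (PM short replicates), the intensity-gain
#' value `1 - i_d_short` on the normalised scale, and the signal-to-noise
#' ratio of the residual difference spectrum `PM - P - M` at long delay.
#' Intensities are normalised to the free-metabolite short-delay window
#' maximum. Flags (`unstable`, `gained`, `low_snr`) are deterministic
#' functions of the stored numbers and the thresholds.
#'
#' @param m_meas,p_meas,pm_meas The M, P and PM [sample_measurement()]s.
#' @param window `c(ppm_lo, ppm_hi)` or a peak-window row.
#' @param thresholds A [screen_thresholds()].
#' @return One-row data.frame (the peak quantification record).
#' @export
quantify_peak <- function(m_meas, p_meas, pm_meas, window,
                          thresholds = screen_thresholds()) {
  tr <- process_triple(m_meas, p_meas, pm_meas, thresholds)
  out <- quantify_window(tr, window, thresholds)
  out$protein_id <- pm_meas$protein_id
  w <- as_window(window)
  out$ppm_lo <- w[1]; out$ppm_hi <- w[2]
  out
}

#' Run the spectral pipeline over a whole study
#'
#' For every protein and every compiled peak window, quantifies the window
#' from the matching (M, P, PM) measurement triple and evaluates the
#' relaxation factor where the denominators permit.
#'
#' @param study A [generate_study()] result, or a list with elements
#'   `measurements` (named `M_mix<k>`, `P_<protein>`, `PM_<protein>_mix<k>`),
#'   `proteins` and `mix_assignment`.
#' @param windows Peak windows as returned by [compile_peak_windows()]
#'   (columns `metabolite_id`, `mix`, `ppm_lo`, `ppm_hi`); compiled from the
#'   study's peak lists when `NULL`.
#' @param thresholds A [screen_thresholds()].
#' @param overlap_range Window half-width / exclusion range (ppm) used when
#'   `windows` is `NULL`.
#' @return Data.frame with one row per (protein, window): intensities, QC
#'   quantities, flags, and `delta_rf` (`NA` when unevaluable).
#' @export
process_study <- function(study, windows = NULL,
                          thresholds = screen_thresholds(),
                          overlap_range = 0.025) {
  if (is.null(windows))
    windows <- compile_peak_windows(study$mix_assignment, study$peak_lists,
                                    overlap_range = overlap_range)
  meas <- study$measurements
  out <- vector("list", 0L)
  for (pid in study$proteins$protein_id) {
    p_meas <- meas[[sprintf("P_%s", pid)]]
    for (mx in unique(windows$mix)) {
      pm_meas <- meas[[sprintf("PM_%s_mix%s", pid, mx)]]
      # the M reference recorded at the same long delay as this PM sample
      m_meas <- if (is.null(pm_meas)) NULL else
        meas[[m_measurement_id(mx, pm_meas$long_delay_ms)]]
      if (is.null(m_meas) || is.null(p_meas) || is.null(pm_meas))
        stop(sprintf("missing measurement for protein %s, mix %s", pid, mx),
             call. = FALSE)
      tr <- process_triple(m_meas, p_meas, pm_meas, thresholds)
      wmix <- windows[windows$mix == mx, , drop = FALSE]
      for (i in seq_len(nrow(wmix))) {
        q <- quantify_window(tr, wmix[i, ], thresholds)
        q$protein_id <- pid
        q$metabolite_id <- wmix$metabolite_id[i]
        q$mix <- mx
        q$ppm_lo <- wmix$ppm_lo[i]; q$ppm_hi <- wmix$ppm_hi[i]
        out[[length(out) + 1L]] <- q
      }
    }
  }
  pk <- do.call(rbind, out)
  zero <- numeric(nrow(pk))  # protein already subtracted in the i_d_* maxima
  pk$delta_rf <- delta_rf(pk$i_m_short, pk$i_m_long, zero, zero,
                          pk$i_d_short, pk$i_d_long)
  front <- c("protein_id", "metabolite_id", "mix", "ppm_lo", "ppm_hi")
  pk[, c(front, setdiff(names(pk), front))]
}
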