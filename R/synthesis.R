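#' Ground-truth binding model for a synthetic screen
#'
#' Defines which protein-metabolite pairs bind (and how tightly) in a
#' generated study, together with the concentrations and the free/bound
#' relaxation rates of the fast-exchange model. Defaults mirror the screening
#' conditions: 15 uM protein monomer, 200 uM of each metabolite.
#'
#' @param pairs Data.frame with columns `protein_id`, `metabolite_id`, `kd`
#'   (dissociation constant, uM). Pairs not listed are non-binders
#'   (`kd = Inf`).
#' @param protein_conc Protein monomer concentration, uM.
#' @param metabolite_conc Per-metabolite concentration, uM.
#' @param r_free Spin-lock relaxation rate of free metabolite signals, 1/s.
#' @param r_bound Relaxation rate of protein-bound metabolite signals, 1/s.
#' @return An object of class `binding_truth`.
#' @export
binding_truth <- function(pairs = NULL, protein_conc = 15,
                          metabolite_conc = 200, r_free = 1, r_bound = 60) {
  if (is.null(pairs))
    pairs <- data.frame(protein_id = character(), metabolite_id = character(),
                        kd = numeric())
  stopifnot(all(c("protein_id", "metabolite_id", "kd") %in% names(pairs)))
  if (any(pairs$kd <= 0)) stop("kd must be positive", call. = FALSE)
  if (protein_conc <= 0 || metabolite_conc <= 0)
    stop("concentrations must be positive", call. = FALSE)
  if (!(r_bound >= r_free && r_free > 0))
    stop("need r_bound >= r_free > 0", call. = FALSE)
  structure(list(pairs = pairs, protein_conc = protein_conc,
                 metabolite_conc = metabolite_conc,
                 r_free = r_free, r_bound = r_bound),
            class = "binding_truth")
}

m_measurement_id <- function(mix, long_delay_ms) {
  if (long_delay_ms == 200) sprintf("M_mix%s", mix)
  else sprintf("M_mix%s_%dms", mix, long_delay_ms)
}

truth_kd <- function(truth, protein_id, metabolite_id) {
  i <- which(truth$pairs$protein_id == protein_id &
             truth$pairs$metabolite_id == metabolite_id)
  if (length(i)) truth$pairs$kd[i[1]] else Inf
}

#' Nuisance (noise and artefact) model for synthetic spectra
#'
#' Bundles everything a real acquisition adds on top of the ideal signal:
#' additive per-point noise, a per-spectrum chemical-shift calibration offset
#' (corrected downstream against the DSS reference), first-order metabolite
#' degradation across the acquisition sequence, and a broad protein baseline
#' hump in P and PM samples that makes protein-signal subtraction non-trivial.
#'
#' @param noise_sd Additive Gaussian noise sd per point, as a fraction of a
#'   unit peak amplitude.
#' @param shift_offset_sd Sd of the per-spectrum ppm calibration offset.
#' @param degradation_rates Named numeric vector, metabolite_id -> first-order
#'   loss rate per acquisition stage (the three spectra of a measurement are
#'   recorded in the order short_a, long, short_b).
#' @param protein_baseline_amplitude Amplitude of the broad protein hump.
#' @param seed Integer; fixes the generated study byte-for-byte.
#' @return An object of class `nuisance_model`.
#' @export
nuisance_model <- function(noise_sd = 0.005, shift_offset_sd = 0.003,
                           degradation_rates = NULL,
                           protein_baseline_amplitude = 0.3, seed = 1L) {
  if (noise_sd < 0 || shift_offset_sd < 0 || protein_baseline_amplitude < 0)
    stop("nuisance parameters must be non-negative", call. = FALSE)
  if (!is.null(degradation_rates)) {
    if (is.null(names(degradation_rates)) || any(degradation_rates < 0))
      stop("degradation_rates must be a named non-negative vector",
           call. = FALSE)
  }
  structure(list(noise_sd = noise_sd, shift_offset_sd = shift_offset_sd,
                 degradation_rates = degradation_rates,
                 protein_baseline_amplitude = protein_baseline_amplitude,
                 seed = as.integer(seed)),
            class = "nuisance_model")
}

#' An all-zero nuisance model (ideal, noiseless acquisition)
#' @param seed Seed (unused when nothing is random, kept for uniformity).
#' @return A `nuisance_model` with every nuisance switched off.
#' @export
null_nuisance <- function(seed = 1L) {
  nuisance_model(noise_sd = 0, shift_offset_sd = 0, degradation_rates = NULL,
                 protein_baseline_amplitude = 0, seed = seed)
}

#' Default ppm axis for synthetic spectra
#'
#' Spans -0.7 to 11.2 ppm (descending), covering the DSS reference at 0 ppm,
#' the metabolite region, and the 10.5-11.0 ppm signal-free region used for
#' noise estimation.
#'
#' @param ppm_min,ppm_max Axis limits, ppm.
#' @param step Grid step, ppm.
#' @return Descending numeric ppm vector.
#' @export
default_axis <- function(ppm_min = -0.7, ppm_max = 11.2, step = 0.002) {
  seq(ppm_max, ppm_min, by = -step)
}

# fixed synthetic lineshape / reference constants
.synth <- list(lorentz_hwhm = 0.005,   # ppm, half width at half maximum
               dss_ppm = 0, dss_amplitude = 1, dss_rate = 1,    # 1/s
               baseline_center = 2.5, baseline_width = 2.0,     # ppm
               baseline_rate = 20,     # 1/s, protein signals relax fast
               long_scan_scale = 2,    # 512 vs 256 scans
               tail_cut = 0.5)         # ppm, truncate far Lorentzian tails

# Lorentzian line with tails truncated beyond tail_cut ppm: at that distance
# the tail is 1e-4 of the peak, far below any realistic noise floor, and the
# truncation keeps synthetic spectra exactly local (a peak influences no
# window further than tail_cut away).
lorentzian <- function(ppm, center, amplitude, hwhm = .synth$lorentz_hwhm) {
  d <- ppm - center
  amplitude * (hwhm^2 / (hwhm^2 + d^2)) * (abs(d) <= .synth$tail_cut)
}

#' Render one synthetic T1rho spectrum
#'
#' Each peak is a Lorentzian of fixed base width whose amplitude is attenuated
#' by `exp(-rate * spin_lock_s)` (spin-lock relaxation) and by per-stage
#' first-order degradation (stages in acquisition order: `short_a` = 0,
#' `long` = 1, `short_b` = 2). A DSS reference peak at 0 ppm is always added
#' and is exempt from degradation. A global ppm offset and additive Gaussian
#' noise emulate miscalibration and thermal noise; both are drawn from the
#' caller's RNG stream so a study is reproducible under its seed.
#'
#' @param peaks Data.frame with columns `ppm`, `amplitude`, `rate` (1/s) and
#'   optionally `degradation` (per-stage loss rate, default 0). May have zero
#'   rows (pure-protein sample).
#' @param spin_lock_ms Spin-lock delay, ms (10, 200 or 400).
#' @param axis Descending ppm axis, e.g. [default_axis()].
#' @param nuisance A [nuisance_model()].
#' @param stage `"short_a"`, `"long"` or `"short_b"`.
#' @param baseline_amplitude Protein hump amplitude for this sample (0 for M).
#' @param scale Overall scan-count scale (the long spectrum is acquired with
#'   twice the scans of each short replicate).
#' @param sample_id,role,protein_id,mix_id Metadata for the returned spectrum.
#' @return A [spectrum1d()].
#' @export
render_spectrum <- function(peaks, spin_lock_ms, axis, nuisance,
                            stage = c("short_a", "long", "short_b"),
                            baseline_amplitude = 0, scale = 1,
                            sample_id = "synthetic", role = "M",
                            protein_id = "", mix_id = "") {
  stage <- match.arg(stage)
  stage_idx <- c(short_a = 0, long = 1, short_b = 2)[[stage]]
  t_sl <- spin_lock_ms / 1000
  if (nrow(peaks) > 0 &&
      (max(peaks$ppm) > max(axis) || min(peaks$ppm) < min(axis)))
    stop("peak outside axis range", call. = FALSE)
  y <- numeric(length(axis))
  offset <- if (nuisance$shift_offset_sd > 0)
    stats::rnorm(1, 0, nuisance$shift_offset_sd) else 0
  if (nrow(peaks) > 0) {
    degr <- if ("degradation" %in% names(peaks)) peaks$degradation else
      rep(0, nrow(peaks))
    amp <- peaks$amplitude * exp(-peaks$rate * t_sl) * exp(-degr * stage_idx)
    for (i in seq_len(nrow(peaks)))
      y <- y + lorentzian(axis, peaks$ppm[i] + offset, amp[i])
  }
  y <- y + lorentzian(axis, .synth$dss_ppm + offset,
                      .synth$dss_amplitude * exp(-.synth$dss_rate * t_sl))
  if (baseline_amplitude > 0)
    y <- y + baseline_amplitude * exp(-.synth$baseline_rate * t_sl) *
      exp(-((axis - (.synth$baseline_center + offset)) /
              .synth$baseline_width)^2)
  y <- y * scale
  if (nuisance$noise_sd > 0)
    y <- y + stats::rnorm(length(y), 0, nuisance$noise_sd)
  exp_name <- switch(stage, short_a = "t1rho_short_a",
                     short_b = "t1rho_short_b", long = "t1rho_long")
  spectrum1d(axis, y, sample_id = sample_id, role = role,
             experiment = exp_name, spin_lock_ms = spin_lock_ms,
             protein_id = protein_id, mix_id = mix_id)
}

render_measurement <- function(peaks, long_delay_ms, axis, nuisance,
                               baseline_amplitude, sample_id, role,
                               protein_id = "", mix_id = "") {
  mk <- function(stage, sl, sc)
    render_spectrum(peaks, sl, axis, nuisance, stage = stage,
                    baseline_amplitude = baseline_amplitude, scale = sc,
                    sample_id = sample_id, role = role,
                    protein_id = protein_id, mix_id = mix_id)
  # acquisition order: short_a, long, short_b
  a <- mk("short_a", 10, 1)
  l <- mk("long", long_delay_ms, .synth$long_scan_scale)
  b <- mk("short_b", 10, 1)
  sample_measurement(a, l, b, sample_id = sample_id, role = role,
                     protein_id = protein_id, mix_id = mix_id)
}

#' Generate a complete synthetic screening study
#'
#' Emits, per mix, one metabolite-only (M) measurement; per protein, one
#' protein-only (P) measurement; and per (protein, mix), one protein +
#' metabolites (PM) measurement — each a (short_a, long, short_b) spectrum
#' triple. In PM samples, metabolite peak relaxation rates follow the
#' two-state fast-exchange model: the bound fraction from the binding
#' quadratic at the study concentrations, the observed rate the population
#' average of `r_free` and `r_bound`. Proteins flagged `small` (below 40 kDa,
#' weaker relaxation enhancement) use a 400 ms long delay, others 200 ms.
#'
#' @param proteins Data.frame with columns `protein_id` and optionally
#'   `small` (logical), or a character vector of ids.
#' @param peak_lists Peak-list data.frame ([read_peak_list()] format).
#' @param mix_assignment Data.frame with columns `metabolite_id`, `mix`
#'   (integer or id); every catalogued metabolite in exactly one mix.
#' @param truth A [binding_truth()].
#' @param nuisance A [nuisance_model()]; its seed fixes the study.
#' @param axis Descending ppm axis.
#' @return An object of class `t1rho_study`: named list of measurements plus
#'   the echoed truth, rosters and axis.
#' @export
generate_study <- function(proteins, peak_lists, mix_assignment, truth,
                           nuisance = nuisance_model(),
                           axis = default_axis()) {
  if (is.character(proteins))
    proteins <- data.frame(protein_id = proteins, small = FALSE)
  if (!"small" %in% names(proteins)) proteins$small <- FALSE
  peak_lists <- validate_peak_list(peak_lists)
  if (is.numeric(mix_assignment) && !is.null(names(mix_assignment)))
    mix_assignment <- data.frame(metabolite_id = names(mix_assignment),
                                 mix = unname(mix_assignment))
  mets <- unique(peak_lists$metabolite_id)
  if (!setequal(mets, mix_assignment$metabolite_id) ||
      anyDuplicated(mix_assignment$metabolite_id))
    stop("every catalogued metabolite must be assigned to exactly one mix",
         call. = FALSE)
  extra <- setdiff(unique(truth$pairs$metabolite_id), mets)
  extra_p <- setdiff(unique(truth$pairs$protein_id), proteins$protein_id)
  if (length(extra) || length(extra_p))
    stop("binding truth names proteins/metabolites outside the rosters",
         call. = FALSE)
  mix_ids <- sort(unique(mix_assignment$mix))
  degr_of <- function(m) {
    r <- nuisance$degradation_rates
    if (!is.null(r) && m %in% names(r)) unname(r[[m]]) else 0
  }

  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  })
  set.seed(nuisance$seed)

  measurements <- list()
  mix_peaks <- list()
  # pure-mix references must share the long delay of the PM samples they are
  # compared with, so one M measurement is recorded per delay in use
  delays_needed <- sort(unique(ifelse(proteins$small, 400, 200)))
  for (mx in mix_ids) {
    in_mix <- mix_assignment$metabolite_id[mix_assignment$mix == mx]
    pk <- peak_lists[peak_lists$metabolite_id %in% in_mix, , drop = FALSE]
    pk$degradation <- vapply(pk$metabolite_id, degr_of, numeric(1))
    mix_peaks[[as.character(mx)]] <- pk
    peaks_m <- data.frame(ppm = pk$ppm, amplitude = pk$rel_intensity,
                          rate = truth$r_free, degradation = pk$degradation)
    for (ld in delays_needed) {
      sid <- m_measurement_id(mx, ld)
      measurements[[sid]] <- render_measurement(
        peaks_m, ld, axis, nuisance, baseline_amplitude = 0,
        sample_id = sid, role = "M", mix_id = as.character(mx))
    }
  }
  for (i in seq_len(nrow(proteins))) {
    pid <- proteins$protein_id[i]
    ld <- if (isTRUE(proteins$small[i])) 400 else 200
    sid <- sprintf("P_%s", pid)
    measurements[[sid]] <- render_measurement(
      data.frame(ppm = numeric(), amplitude = numeric(), rate = numeric()),
      ld, axis, nuisance,
      baseline_amplitude = nuisance$protein_baseline_amplitude,
      sample_id = sid, role = "P", protein_id = pid)
  }
  for (i in seq_len(nrow(proteins))) {
    pid <- proteins$protein_id[i]
    ld <- if (isTRUE(proteins$small[i])) 400 else 200
    for (mx in mix_ids) {
      pk <- mix_peaks[[as.character(mx)]]
      kd <- vapply(pk$metabolite_id, function(m) truth_kd(truth, pid, m),
                   numeric(1))
      pb <- bound_fraction(truth$protein_conc, truth$metabolite_conc, kd)
      r_obs <- observed_relaxation(pb, truth$r_free, truth$r_bound)
      peaks_pm <- data.frame(ppm = pk$ppm, amplitude = pk$rel_intensity,
                             rate = r_obs, degradation = pk$degradation)
      sid <- sprintf("PM_%s_mix%s", pid, mx)
      measurements[[sid]] <- render_measurement(
        peaks_pm, ld, axis, nuisance,
        baseline_amplitude = nuisance$protein_baseline_amplitude,
        sample_id = sid, role = "PM", protein_id = pid,
        mix_id = as.character(mx))
    }
  }
  structure(list(measurements = measurements, truth = truth,
                 nuisance = nuisance, proteins = proteins,
                 peak_lists = peak_lists, mix_assignment = mix_assignment,
                 axis = axis),
            class = "t1rho_study")
}

#' @export
print.t1rho_study <- function(x, ...) {
  roles <- vapply(x$measurements, `[[`, "", "role")
  cat(sprintf("<t1rho_study> %d proteins x %d metabolites in %d mixes\n",
              nrow(x$proteins), length(unique(x$peak_lists$metabolite_id)),
              length(unique(x$mix_assignment$mix))))
  cat(sprintf("  measurements: %d M, %d P, %d PM (%d spectra)\n",
              sum(roles == "M"), sum(roles == "P"), sum(roles == "PM"),
              3L * length(x$measurements)))
  invisible(x)
}

#' Closed-form relaxation factor expected for a synthetic binder
#'
#' For a noiseless synthetic study the pipeline's relaxation factor reduces to
#' `exp(-r_free * dt) - exp(-r_obs * dt)` with `dt` the difference between the
#' long and short spin-lock delays and `r_obs` the fast-exchange
#' population-averaged rate at the study concentrations. Used as the ground
#' truth against which the spectral pipeline is validated.
#'
#' @param kd Dissociation constant, uM (vectorised; `Inf` = non-binder).
#' @param truth A [binding_truth()].
#' @param long_delay_ms Long spin-lock delay, ms.
#' @return Expected relaxation factor difference.
#' @export
expected_delta_rf <- function(kd, truth, long_delay_ms = 200) {
  dt <- (long_delay_ms - 10) / 1000
  pb <- bound_fraction(truth$protein_conc, truth$metabolite_conc, kd)
  r_obs <- observed_relaxation(pb, truth$r_free, truth$r_bound)
  exp(-truth$r_free * dt) - exp(-r_obs * dt)
}

#' Draw a random synthetic metabolite peak library
#'
#' Peak positions are uniform over the metabolite region and relative
#' intensities uniform on (0.3, 1\] with the strongest peak normalised to 1 —
#' a rough stand-in for real compound peak lists, adequate for exercising mix
#' design and window compilation.
#'
#' @param n_metabolites Number of metabolites.
#' @param n_peaks Range (min, max) of peaks per metabolite.
#' @param ppm_range Region in which peaks fall, ppm.
#' @param seed RNG seed.
#' @return Peak-list data.frame (`metabolite_id`, `ppm`, `rel_intensity`).
#' @export
synthetic_peak_library <- function(n_metabolites, n_peaks = c(1, 4),
                                   ppm_range = c(0.8, 9.2), seed = 1L) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  })
  set.seed(seed)
  rows <- lapply(seq_len(n_metabolites), function(i) {
    k <- sample(seq(n_peaks[1], n_peaks[2]), 1)
    data.frame(metabolite_id = sprintf("met%02d", i),
               ppm = round(stats::runif(k, ppm_range[1], ppm_range[2]), 3),
               rel_intensity = stats::runif(k, 0.3, 1))
  })
  validate_peak_list(do.call(rbind, rows))
}
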