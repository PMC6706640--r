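#' Simulate a complete synthetic screen with known ground truth
#'
#' Convenience front end to the generator: draws a synthetic metabolite peak
#' library, designs low-overlap mixes by simulated annealing, plants a random
#' set of binders with dissociation constants in `kd_range`, and renders the
#' full set of M, P and PM measurements. All randomness derives from `seed`
#' (library, mix design, binder draw and nuisance draws use fixed offsets of
#' it), so the whole screen is reproducible.
#'
#' @param n_proteins,n_metabolites Roster sizes.
#' @param n_mixes Number of metabolite mixes.
#' @param binder_fraction Fraction of protein x metabolite pairs that bind.
#' @param kd_range Range (uM) from which binder dissociation constants are
#'   drawn uniformly.
#' @param nuisance Optional [nuisance_model()]; default uses
#'   `noise_sd = 0.01` and seed derived from `seed`.
#' @param truth Optional [binding_truth()] overriding the random binder draw.
#' @param schedule Optional [anneal_schedule()] for the mix design.
#' @param small_proteins Optional character vector of protein ids measured
#'   with the 400 ms long delay.
#' @param seed Master seed.
#' @return List of class `synthetic_screen`: `study`, `design`,
#'   `reference` (the planted binders as a known-interaction set), `truth`.
#' @export
simulate_screen <- function(n_proteins = 20, n_metabolites = 20, n_mixes = 2,
                            binder_fraction = 0.1, kd_range = c(10, 500),
                            nuisance = NULL, truth = NULL, schedule = NULL,
                            small_proteins = character(), seed = 1L) {
  seed <- as.integer(seed)
  if (is.null(nuisance))
    nuisance <- nuisance_model(noise_sd = 0.01, seed = seed + 2L)
  peak_lists <- synthetic_peak_library(n_metabolites, seed = seed)
  if (is.null(schedule))
    schedule <- anneal_schedule(
      n_mixes = n_mixes,
      max_mix_size = ceiling(n_metabolites / n_mixes),
      max_steps = 5000, iterations = 2, seed = seed + 1L)
  design <- anneal_mixes(peak_lists, schedule)
  proteins <- data.frame(protein_id = sprintf("prot%02d", seq_len(n_proteins)),
                         stringsAsFactors = FALSE)
  proteins$small <- proteins$protein_id %in% small_proteins
  mets <- unique(peak_lists$metabolite_id)
  if (is.null(truth)) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed + 3L)
    all_pairs <- expand.grid(protein_id = proteins$protein_id,
                             metabolite_id = mets,
                             KEEP.OUT.ATTRS = FALSE,
                             stringsAsFactors = FALSE)
    n_bind <- round(binder_fraction * nrow(all_pairs))
    pick <- sample(nrow(all_pairs), n_bind)
    pairs <- all_pairs[pick, , drop = FALSE]
    pairs$kd <- stats::runif(n_bind, kd_range[1], kd_range[2])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
    truth <- binding_truth(pairs)
  }
  study <- generate_study(proteins, peak_lists, design$assignment, truth,
                          nuisance = nuisance)
  reference <- if (nrow(truth$pairs))
    reference_set(data.frame(protein_id = truth$pairs$protein_id,
                             metabolite_id = truth$pairs$metabolite_id,
                             type = "regulatory")) else
    reference_set(data.frame(protein_id = character(),
                             metabolite_id = character(),
                             type = character()))
  structure(list(study = study, design = design, reference = reference,
                 truth = truth, seed = seed),
            class = "synthetic_screen")
}

#' Validate a run configuration
#'
#' Schema validation with collected (not first-fail) messages. A valid config
#' is a list with blocks `thresholds` (see [screen_thresholds()]),
#' optionally `synthesis` (roster sizes, binder fraction, kd range, nuisance
#' settings), optionally `annealing`, optional input paths (`similarity`,
#' `pathways`), and a mandatory `seed` whenever any stochastic stage
#' (synthesis or annealing) is configured.
#'
#' @param config A list (e.g. from [read_run_config()]).
#' @return List with `config` (normalised, defaults filled) and `errors`
#'   (character vector; empty when valid).
#' @export
validate_config <- function(config) {
  errors <- character()
  add <- function(msg) errors <<- c(errors, msg)
  if (!is.list(config)) return(list(config = NULL,
                                    errors = "config must be a list"))
  th <- config$thresholds
  if (is.null(th)) th <- list()
  def <- list(stability_max = 0.05, gain_min = -0.05, snr_min = 2,
              target_fpr = 0.05, similarity_threshold = 0.5)
  for (k in names(def)) if (is.null(th[[k]])) th[[k]] <- def[[k]]
  if (!is.numeric(th$stability_max) || th$stability_max < 0)
    add("stability_max must be >= 0")
  if (!is.numeric(th$snr_min) || th$snr_min < 0)
    add("snr_min must be >= 0")
  if (!is.numeric(th$target_fpr) || th$target_fpr < 0 || th$target_fpr > 1)
    add("target_fpr must lie in [0, 1]")
  if (!is.numeric(th$similarity_threshold) ||
      th$similarity_threshold < 0 || th$similarity_threshold > 1)
    add("similarity_threshold must lie in [0, 1]")
  config$thresholds <- th
  if (is.null(config$aggregate)) config$aggregate <- "mean"
  if (!config$aggregate %in% c("mean", "median", "max"))
    add("aggregate must be one of mean, median, max")
  stochastic <- !is.null(config$synthesis) || !is.null(config$annealing)
  if (stochastic && (is.null(config$seed) ||
                     !is.numeric(config$seed) || is.na(config$seed)))
    add("seed is required when a stochastic stage (synthesis/annealing) is configured")
  syn <- config$synthesis
  if (!is.null(syn)) {
    sdef <- list(n_proteins = 20, n_metabolites = 20, n_mixes = 2,
                 binder_fraction = 0.1, kd_range = c(10, 500),
                 noise_sd = 0.01, shift_offset_sd = 0.003,
                 protein_baseline_amplitude = 0.3)
    for (k in names(sdef)) if (is.null(syn[[k]])) syn[[k]] <- sdef[[k]]
    if (syn$n_proteins < 1 || syn$n_metabolites < 2)
      add("synthesis roster sizes too small")
    if (syn$binder_fraction < 0 || syn$binder_fraction > 1)
      add("binder_fraction must lie in [0, 1]")
    if (length(syn$kd_range) != 2 || any(syn$kd_range <= 0) ||
        syn$kd_range[1] > syn$kd_range[2])
      add("kd_range must be an increasing positive pair")
    if (syn$noise_sd < 0) add("noise_sd must be >= 0")
    config$synthesis <- syn
  }
  an <- config$annealing
  if (!is.null(an)) {
    if (!is.null(an$start_temp) && !is.null(an$final_temp) &&
        !(an$start_temp > an$final_temp && an$final_temp > 0))
      add("annealing temperatures must satisfy start > final > 0")
  }
  list(config = config, errors = errors)
}

#' Read a YAML run configuration
#'
#' @param path YAML file.
#' @return The parsed, unvalidated list (pass to [validate_config()]).
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

# small stable polynomial rolling hash of the config for provenance
# fingerprints (not cryptographic; collision resistance is irrelevant here)
config_fingerprint <- function(config) {
  s <- paste(deparse(config[sort(names(config))]), collapse = "")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full screening pipeline from one configuration
#'
#' Executes the stages in order — simulate (when a `synthesis` block is
#' present), design mixes, process spectra, quantify the relaxation factor,
#' calibrate the detection cutoff by ROC against the known/planted
#' interactions, classify detections by chemical similarity (skipped without
#' a similarity table) — writes all intermediate artifacts under `out_dir`,
#' and returns (and writes) a JSON run report. Identical config + seed gives
#' identical reports.
#'
#' @param config Run configuration (list, already or not yet validated).
#' @param out_dir Output directory; created if needed. `NULL` skips writing.
#' @return The run report, invisibly a list.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  v <- validate_config(config)
  if (length(v$errors))
    stop(paste(c("invalid config:", v$errors), collapse = "\n  "),
         call. = FALSE)
  config <- v$config
  if (is.null(config$synthesis))
    stop("stage simulate: this build runs on synthetic studies; provide a synthesis block",
         call. = FALSE)
  th <- do.call(screen_thresholds, c(config$thresholds,
                                     list(aggregate = config$aggregate)))
  syn <- config$synthesis
  nuisance <- nuisance_model(
    noise_sd = syn$noise_sd, shift_offset_sd = syn$shift_offset_sd,
    protein_baseline_amplitude = syn$protein_baseline_amplitude,
    seed = as.integer(config$seed) + 2L)
  scr <- simulate_screen(n_proteins = syn$n_proteins,
                         n_metabolites = syn$n_metabolites,
                         n_mixes = syn$n_mixes,
                         binder_fraction = syn$binder_fraction,
                         kd_range = syn$kd_range, nuisance = nuisance,
                         seed = as.integer(config$seed))
  peaks <- process_study(scr$study, windows = scr$design$windows,
                         thresholds = th)
  im <- aggregate_study(peaks,
                        proteins = scr$study$proteins$protein_id,
                        metabolites = unique(scr$study$peak_lists$metabolite_id),
                        policy = config$aggregate)
  cal <- calibrate_cutoff(im, scr$reference, target_fpr = th$target_fpr)
  det <- detections_at_cutoff(im, cal$cutoff)
  classification <- NULL
  class_skipped <- TRUE
  if (!is.null(config$similarity)) {
    sim <- if (is.character(config$similarity))
      read_similarity_table(config$similarity) else config$similarity
    classification <- classify_binding_mode(det, sim,
                                            threshold = th$similarity_threshold)
    class_skipped <- FALSE
  }
  flag_count <- function(f) sum(grepl(f, peaks$flags, fixed = TRUE))
  report <- list(
    config_fingerprint = config_fingerprint(config),
    seed = as.integer(config$seed),
    n_proteins = nrow(scr$study$proteins),
    n_metabolites = length(unique(scr$study$peak_lists$metabolite_id)),
    n_mixes = length(unique(scr$design$assignment$mix)),
    mix_overlap_score = scr$design$score,
    n_peak_windows = nrow(scr$design$windows),
    n_peaks_quantified = nrow(peaks),
    n_flagged_unstable = flag_count("unstable"),
    n_flagged_gained = flag_count("gained"),
    n_flagged_low_snr = flag_count("low_snr"),
    n_missing_pairs = sum(is.na(im$delta_rf)),
    selected_cutoff = cal$cutoff,
    calibration_tpr = cal$tpr,
    calibration_fpr = cal$fpr,
    auc = cal$auc,
    n_detections = nrow(det),
    classification = if (class_skipped) "skipped" else
      attr(classification, "summary"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(scr$design$assignment,
                     file.path(out_dir, "mix_assignment.csv"),
                     row.names = FALSE)
    utils::write.csv(scr$design$windows,
                     file.path(out_dir, "peak_windows.csv"),
                     row.names = FALSE)
    utils::write.csv(peaks, file.path(out_dir, "peak_quant.csv"),
                     row.names = FALSE)
    write_interaction_table(im, file.path(out_dir, "interactions_long.csv"),
                            wide_path = file.path(out_dir, "interactions_wide.csv"),
                            cutoff = cal$cutoff)
    utils::write.csv(cal$roc, file.path(out_dir, "roc.csv"),
                     row.names = FALSE)
    utils::write.csv(det, file.path(out_dir, "detections.csv"),
                     row.names = FALSE)
    if (!class_skipped)
      utils::write.csv(classification,
                       file.path(out_dir, "classified.csv"),
                       row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(c(report, list(matrix = im, detections = det,
                           classification = classification,
                           peaks = peaks, screen = scr, roc = cal$roc)))
}
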