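# Shared builders for synthetic fixtures. Everything is generated in code;
# no stored data files.

# A minimal valid spectrum: flat baseline with one sharp triangular peak.
toy_spectrum <- function(peak_ppm = 0, peak_height = 1, ppm = seq(11, -0.5, by = -0.01),
                         sample_id = "S1", role = "M", experiment = "t1rho_short_a",
                         spin_lock_ms = 10, noise = 0) {
  y <- numeric(length(ppm))
  i <- which.min(abs(ppm - peak_ppm))
  y[i] <- peak_height
  if (i > 1) y[i - 1] <- peak_height / 2
  if (i < length(y)) y[i + 1] <- peak_height / 2
  if (noise > 0) y <- y + rnorm(length(y), 0, noise)
  spectrum1d(ppm, y, sample_id = sample_id, role = role,
             experiment = experiment, spin_lock_ms = spin_lock_ms)
}

# Two-metabolite, one-protein roster used across processing tests.
tiny_rosters <- function() {
  list(proteins = data.frame(protein_id = "prot01", small = FALSE),
       peak_lists = data.frame(metabolite_id = c("met01", "met02"),
                               ppm = c(3.0, 7.0), rel_intensity = c(1, 1)),
       mix = data.frame(metabolite_id = c("met01", "met02"), mix = c(1, 1)))
}

tiny_study <- function(kd = Inf, nuisance = null_nuisance(), r_free = 1,
                       r_bound = 60) {
  r <- tiny_rosters()
  pairs <- if (is.finite(kd))
    data.frame(protein_id = "prot01", metabolite_id = "met01", kd = kd)
  else NULL
  truth <- binding_truth(pairs, r_free = r_free, r_bound = r_bound)
  generate_study(r$proteins, r$peak_lists, r$mix, truth, nuisance = nuisance)
}

# Synthetic stand-in for a curated known-interaction file: 43 catalytic and
# 40 regulatory rows over a 29 x 55 roster, with 11 pairs listed under both
# types, giving 72 unique interactions.
synthetic_reference_rows <- function() {
  prot <- sprintf("enz%02d", 1:29)
  met <- sprintf("met%02d", 1:55)
  pairs <- expand.grid(protein_id = prot, metabolite_id = met,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cat_rows <- pairs[seq_len(43), ]
  cat_rows$type <- "catalytic"
  reg_rows <- pairs[seq(33, by = 1, length.out = 40), ]  # rows 33..43 overlap
  reg_rows$type <- "regulatory"
  rbind(cat_rows, reg_rows)
}

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}

# Independent equilibrium oracle: solve [P][L]/[PL] = KD by root finding,
# without using the closed-form quadratic.
bound_fraction_oracle <- function(p_tot, l_tot, kd) {
  if (!is.finite(kd)) return(0)
  f <- function(pl) (p_tot - pl) * (l_tot - pl) - kd * pl
  pl <- uniroot(f, c(0, min(p_tot, l_tot)), tol = 1e-12)$root
  pl / l_tot
}

# Brute-force confusion counts by threshold enumeration.
brute_roc <- function(scores, known, cutoffs) {
  do.call(rbind, lapply(cutoffs, function(ct) {
    det <- scores > ct
    data.frame(cutoff = ct,
               tpr = sum(det & known) / sum(known),
               fpr = sum(det & !known) / sum(!known))
  }))
}
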