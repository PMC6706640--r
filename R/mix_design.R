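#' Annealing schedule for metabolite mix design
#'
#' Settings of the simulated-annealing mix optimiser. `published = TRUE` returns
#' the full published schedule (4 mixes of at most 15, linear
#' cooling 10,000 to 25 over 500,000 steps, mix rate 2, 10 restarts, plus an
#' exponential 50-to-25 refinement over 1,000 steps); the default is a
#' desk-scale schedule (20,000 steps, 3 restarts) that reaches the same
#' zero-overlap designs on libraries of this size in seconds.
#'
#' @param n_mixes Number of mixes.
#' @param max_mix_size Maximum metabolites per mix.
#' @param cooling `"linear"` or `"exponential"`.
#' @param start_temp,final_temp Temperature bounds (`start > final > 0`).
#' @param max_steps Annealing steps per restart.
#' @param mix_rate Metabolites relocated per step.
#' @param iterations Independent restarts; the best design wins.
#' @param overlap_range Peaks closer than this (ppm) clash.
#' @param score_scaling Penalty per clash.
#' @param use_intensity_scoring Scale each clash by the product of the two
#'   peaks' relative intensities.
#' @param refine Run the refinement phase after the main anneal.
#' @param refine_start_temp,refine_final_temp,refine_max_steps Refinement
#'   phase settings (exponential cooling).
#' @param seed RNG seed; fixes the returned design.
#' @param published Use the full published schedule.
#' @return A list of class `anneal_schedule`.
#' @export
anneal_schedule <- function(n_mixes = 4, max_mix_size = 15,
                            cooling = c("linear", "exponential"),
                            start_temp = 10000, final_temp = 25,
                            max_steps = 20000, mix_rate = 2, iterations = 3,
                            overlap_range = 0.025, score_scaling = 100,
                            use_intensity_scoring = TRUE, refine = TRUE,
                            refine_start_temp = 50, refine_final_temp = 25,
                            refine_max_steps = 1000, seed = 1L,
                            published = FALSE) {
  cooling <- match.arg(cooling)
  if (published) { max_steps <- 500000; iterations <- 10 }
  if (!(start_temp > final_temp && final_temp > 0))
    stop("need start_temp > final_temp > 0", call. = FALSE)
  structure(list(n_mixes = n_mixes, max_mix_size = max_mix_size,
                 cooling = cooling, start_temp = start_temp,
                 final_temp = final_temp, max_steps = max_steps,
                 mix_rate = mix_rate, iterations = iterations,
                 overlap_range = overlap_range, score_scaling = score_scaling,
                 use_intensity_scoring = use_intensity_scoring,
                 refine = refine, refine_start_temp = refine_start_temp,
                 refine_final_temp = refine_final_temp,
                 refine_max_steps = refine_max_steps,
                 seed = as.integer(seed)),
            class = "anneal_schedule")
}

# Symmetric metabolite x metabolite clash-penalty matrix.
clash_matrix <- function(peak_lists, overlap_range, score_scaling,
                         use_intensity) {
  mets <- unique(peak_lists$metabolite_id)
  n <- length(mets)
  pm <- matrix(0, n, n, dimnames = list(mets, mets))
  pk <- split(peak_lists, factor(peak_lists$metabolite_id, levels = mets))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- pk[[i]]; b <- pk[[j]]
    d <- abs(outer(a$ppm, b$ppm, "-"))
    clash <- d < overlap_range
    if (any(clash)) {
      w <- if (use_intensity) outer(a$rel_intensity, b$rel_intensity) else
        array(1, dim(d))
      pm[i, j] <- pm[j, i] <- score_scaling * sum(w[clash])
    }
  }
  pm
}

#' Spectral-overlap penalty of a mix assignment
#'
#' Sums, over every same-mix pair of peaks belonging to different metabolites
#' and closer than `overlap_range` ppm, a penalty of `score_scaling` scaled by
#' the product of the two relative intensities when intensity scoring is on.
#' Zero iff the assignment has no clashes.
#'
#' @param assignment Named integer vector, metabolite_id -> mix index, or a
#'   data.frame with columns `metabolite_id`, `mix`.
#' @param peak_lists Peak-list data.frame.
#' @param overlap_range Clash distance, ppm.
#' @param score_scaling Penalty per clash.
#' @param use_intensity Scale by intensity products.
#' @return Total penalty (>= 0).
#' @export
overlap_score <- function(assignment, peak_lists, overlap_range = 0.025,
                          score_scaling = 100, use_intensity = TRUE) {
  assignment <- as_assignment(assignment)
  mets <- unique(peak_lists$metabolite_id)
  if (!all(mets %in% names(assignment)))
    stop("metabolite without mix assignment", call. = FALSE)
  if (!all(names(assignment) %in% mets))
    stop("assigned metabolite without peak list", call. = FALSE)
  pm <- clash_matrix(peak_lists, overlap_range, score_scaling, use_intensity)
  a <- assignment[mets]
  same <- outer(a, a, "==")
  sum(pm[same & upper.tri(pm)])
}

as_assignment <- function(x) {
  if (is.data.frame(x)) stats::setNames(x$mix, x$metabolite_id)
  else x
}

score_of <- function(assign, pm) {
  same <- outer(assign, assign, "==")
  sum(pm[same & upper.tri(pm)])
}

#' Partition a metabolite library into low-overlap mixes
#'
#' Simulated annealing over mix assignments: each step relocates `mix_rate`
#' random metabolites to random other mixes with free capacity, accepting any
#' score decrease and score increases with probability `exp(-delta / T)`.
#' Must-separate constraints (e.g. metabolites that would react
#' enzymatically) and forced assignments (manual curation) are honoured at
#' every step, never just repaired at the end. The best design over
#' `iterations` restarts is returned, with ties broken towards the
#' lexicographically smallest assignment in metabolite-id order.
#'
#' @param peak_lists Peak-list data.frame.
#' @param schedule An [anneal_schedule()].
#' @param must_separate Optional data.frame with columns `a`, `b`: pairs that
#'   may not share a mix.
#' @param forced Optional named vector metabolite_id -> mix index, fixed
#'   throughout.
#' @return List of class `mix_design`: `assignment` (data.frame
#'   `metabolite_id`, `mix`), `score`, `windows` (see
#'   [compile_peak_windows()]) and `schedule`.
#' @export
anneal_mixes <- function(peak_lists, schedule = anneal_schedule(),
                         must_separate = NULL, forced = NULL) {
  mets <- sort(unique(peak_lists$metabolite_id))
  n <- length(mets)
  if (n == 0L) stop("empty metabolite library", call. = FALSE)
  K <- schedule$n_mixes
  if (K * schedule$max_mix_size < n)
    stop("n_mixes * max_mix_size smaller than the library", call. = FALSE)
  sep_a <- sep_b <- integer()
  if (!is.null(must_separate) && nrow(must_separate)) {
    sep_a <- match(must_separate$a, mets)
    sep_b <- match(must_separate$b, mets)
    if (anyNA(sep_a) || anyNA(sep_b))
      stop("must-separate pair names unknown metabolite", call. = FALSE)
  }
  fixed <- logical(n)
  base <- rep(NA_integer_, n)
  if (!is.null(forced)) {
    i <- match(names(forced), mets)
    if (anyNA(i)) stop("forced assignment names unknown metabolite",
                       call. = FALSE)
    base[i] <- as.integer(forced)
    fixed[i] <- TRUE
  }
  pm <- clash_matrix(peak_lists, schedule$overlap_range,
                     schedule$score_scaling, schedule$use_intensity_scoring)
  pm <- pm[mets, mets, drop = FALSE]

  sep_ok <- function(assign, i) {
    # TRUE iff metabolite i violates no must-separate constraint
    viol <- c(sep_b[sep_a == i], sep_a[sep_b == i])
    !any(assign[viol] == assign[i], na.rm = TRUE)
  }
  random_feasible <- function() {
    for (try in 1:200) {
      assign <- base
      ord <- sample(which(!fixed))
      ok <- TRUE
      for (i in ord) {
        sizes <- tabulate(assign[!is.na(assign)], K)
        cand <- sample(which(sizes < schedule$max_mix_size))
        placed <- FALSE
        for (k in cand) {
          assign[i] <- k
          if (sep_ok(assign, i)) { placed <- TRUE; break }
          assign[i] <- NA_integer_
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) {
        viol <- any(vapply(seq_along(sep_a), function(s)
          assign[sep_a[s]] == assign[sep_b[s]], logical(1)))
        if (!length(sep_a) || !viol) return(assign)
      }
    }
    stop("infeasible constraints: no valid initial assignment found",
         call. = FALSE)
  }
  temp_at <- function(step, n_steps, t0, t1, cooling) {
    f <- (step - 1) / max(n_steps - 1, 1)
    if (cooling == "linear") t0 + (t1 - t0) * f else t0 * (t1 / t0)^f
  }
  anneal_phase <- function(assign, score, n_steps, t0, t1, cooling) {
    movable <- which(!fixed)
    if (!length(movable) || score == 0)
      return(list(assign = assign, score = score))
    for (step in seq_len(n_steps)) {
      temp <- temp_at(step, n_steps, t0, t1, cooling)
      picks <- sample(movable, min(schedule$mix_rate, length(movable)))
      for (i in picks) {
        old <- assign[i]
        k <- if (K == 2L) (3L - old) else sample(setdiff(seq_len(K), old), 1)
        sizes <- tabulate(assign, K)
        if (sizes[k] < schedule$max_mix_size) {
          # relocate i into mix k
          delta <- sum(pm[i, assign == k]) - sum(pm[i, assign == old])
          assign[i] <- k
          if (!sep_ok(assign, i)) { assign[i] <- old; next }
          if (delta <= 0 || stats::runif(1) < exp(-delta / temp)) {
            score <- score + delta
          } else {
            assign[i] <- old
          }
        } else {
          # mix k full: swap i with a random movable member of k
          in_k <- intersect(which(assign == k), movable)
          if (!length(in_k)) next
          j <- if (length(in_k) == 1L) in_k else sample(in_k, 1)
          delta <- sum(pm[i, assign == k]) - sum(pm[i, assign == old]) +
            sum(pm[j, assign == old]) - sum(pm[j, assign == k]) -
            2 * pm[i, j]   # i and j stay in different mixes
          assign[i] <- k; assign[j] <- old
          if (!sep_ok(assign, i) || !sep_ok(assign, j)) {
            assign[i] <- old; assign[j] <- k; next
          }
          if (delta <= 0 || stats::runif(1) < exp(-delta / temp)) {
            score <- score + delta
          } else {
            assign[i] <- old; assign[j] <- k
          }
        }
      }
      if (score <= 0) break   # zero overlap is the global minimum
    }
    list(assign = assign, score = score)
  }

  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  })
  set.seed(schedule$seed)

  best <- NULL
  for (it in seq_len(schedule$iterations)) {
    a0 <- random_feasible()
    s0 <- score_of(a0, pm)
    res <- anneal_phase(a0, s0, schedule$max_steps, schedule$start_temp,
                        schedule$final_temp, schedule$cooling)
    if (schedule$refine)
      res <- anneal_phase(res$assign, res$score, schedule$refine_max_steps,
                          schedule$refine_start_temp,
                          schedule$refine_final_temp, "exponential")
    res$score <- score_of(res$assign, pm)   # guard against drift
    if (is.null(best) || res$score < best$score ||
        (res$score == best$score && lex_less(res$assign, best$assign)))
      best <- res
  }
  assignment <- data.frame(metabolite_id = mets, mix = best$assign,
                           stringsAsFactors = FALSE)
  windows <- compile_peak_windows(assignment, peak_lists,
                                  overlap_range = schedule$overlap_range)
  structure(list(assignment = assignment, score = best$score,
                 windows = windows, schedule = schedule),
            class = "mix_design")
}

lex_less <- function(a, b) {
  d <- a - b
  i <- which(d != 0)
  length(i) > 0 && d[i[1]] < 0
}

#' @export
print.mix_design <- function(x, ...) {
  sizes <- table(x$assignment$mix)
  cat(sprintf("<mix_design> %d metabolites in %d mixes (sizes: %s), overlap score %.4g\n",
              nrow(x$assignment), length(sizes),
              paste(sizes, collapse = ", "), x$score))
  invisible(x)
}

#' Compile per-mix metabolite peak windows
#'
#' For every metabolite, a window of half-width `overlap_range` is placed
#' around each of its peaks whose distance to every other metabolite's peak in
#' the same mix exceeds `overlap_range`; overlapping-peak regions are
#' excluded. Adjacent surviving windows are trimmed at the midpoint between
#' their source peaks so that windows within a mix are pairwise disjoint.
#' Metabolites left without any window are reported in attribute
#' `"uncovered"` — they remain in the mix but cannot be quantified.
#'
#' @param mix_assignment Data.frame (`metabolite_id`, `mix`) or named vector.
#' @param peak_lists Peak-list data.frame.
#' @param overlap_range Exclusion distance and window half-width, ppm.
#' @return Data.frame with columns `metabolite_id`, `mix`, `ppm_lo`,
#'   `ppm_hi`, `source_peak_ppm`.
#' @export
compile_peak_windows <- function(mix_assignment, peak_lists,
                                 overlap_range = 0.025) {
  assignment <- as_assignment(mix_assignment)
  peak_lists <- validate_peak_list(peak_lists)
  out <- list()
  uncovered <- character()
  for (mx in sort(unique(assignment))) {
    in_mix <- names(assignment)[assignment == mx]
    pk <- peak_lists[peak_lists$metabolite_id %in% in_mix, , drop = FALSE]
    keep <- logical(nrow(pk))
    for (i in seq_len(nrow(pk))) {
      others <- pk$ppm[pk$metabolite_id != pk$metabolite_id[i]]
      keep[i] <- !length(others) ||
        min(abs(others - pk$ppm[i])) > overlap_range
    }
    uncovered <- c(uncovered,
                   setdiff(in_mix, unique(pk$metabolite_id[keep])))
    pk <- pk[keep, , drop = FALSE]
    if (!nrow(pk)) next
    pk <- pk[order(pk$ppm), , drop = FALSE]
    lo <- pk$ppm - overlap_range
    hi <- pk$ppm + overlap_range
    if (nrow(pk) > 1) {
      mid <- (pk$ppm[-nrow(pk)] + pk$ppm[-1]) / 2
      hi[-nrow(pk)] <- pmin(hi[-nrow(pk)], mid)
      lo[-1] <- pmax(lo[-1], mid + .Machine$double.eps * abs(mid))
    }
    ok <- hi > lo
    out[[length(out) + 1L]] <-
      data.frame(metabolite_id = pk$metabolite_id[ok], mix = mx,
                 ppm_lo = lo[ok], ppm_hi = hi[ok],
                 source_peak_ppm = pk$ppm[ok], stringsAsFactors = FALSE)
  }
  win <- if (length(out)) do.call(rbind, out) else
    data.frame(metabolite_id = character(), mix = integer(),
               ppm_lo = numeric(), ppm_hi = numeric(),
               source_peak_ppm = numeric())
  rownames(win) <- NULL
  attr(win, "uncovered") <- unique(uncovered)
  win
}
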