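#' Bound ligand fraction under two-state equilibrium binding
#'
#' Solves the binding quadratic \eqn{[PL]^2 - (P_t + L_t + K_D)[PL] +
#' P_t L_t = 0} for the complex concentration (the smaller root) and returns
#' the fraction of total ligand that is protein-bound. `kd = Inf` denotes a
#' non-binder and returns 0.
#'
#' @param p_tot Total protein (monomer) concentration, uM.
#' @param l_tot Total ligand (metabolite) concentration, uM.
#' @param kd Dissociation constant, uM; `Inf` for no binding. Vectorised.
#' @return Fraction of ligand bound, in \[0, 1\].
#' @export
bound_fraction <- function(p_tot, l_tot, kd) {
  if (any(p_tot <= 0) || any(l_tot <= 0))
    stop("concentrations must be positive", call. = FALSE)
  if (any(kd <= 0)) stop("kd must be positive (use Inf for non-binders)",
                         call. = FALSE)
  n <- max(length(p_tot), length(l_tot), length(kd))
  p_tot <- rep_len(p_tot, n); l_tot <- rep_len(l_tot, n); kd <- rep_len(kd, n)
  out <- numeric(n)
  fin <- is.finite(kd)
  if (any(fin)) {
    b <- p_tot[fin] + l_tot[fin] + kd[fin]
    pl <- (b - sqrt(b^2 - 4 * p_tot[fin] * l_tot[fin])) / 2
    out[fin] <- pmin(pmax(pl / l_tot[fin], 0), 1)
  }
  out
}

#' Population-averaged relaxation rate under fast exchange
#'
#' In the fast-exchange regime the observed spin-lock relaxation rate of a
#' ligand signal is the population-weighted average of its free and bound
#' rates; protein-bound small molecules relax far faster, which is what the
#' spin-lock experiment detects.
#'
#' @param p_bound Fraction of ligand bound, in \[0, 1\]. Vectorised.
#' @param r_free Relaxation rate of the free ligand, 1/s.
#' @param r_bound Relaxation rate of the bound ligand, 1/s
#'   (`r_bound >= r_free`).
#' @return Observed relaxation rate, 1/s.
#' @export
observed_relaxation <- function(p_bound, r_free, r_bound) {
  if (any(p_bound < 0 | p_bound > 1))
    stop("p_bound must lie in [0, 1]", call. = FALSE)
  if (any(r_free <= 0) || any(r_bound < r_free))
    stop("rates must satisfy r_bound >= r_free > 0", call. = FALSE)
  (1 - p_bound) * r_free + p_bound * r_bound
}
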