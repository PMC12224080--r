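# IAM structure factors with symmetry summation and Debye-Waller damping:
#   F(h) = sum_ops sum_atoms occ * f(s) * T(h; op, U) * exp(2 pi i h.(R r + t))
# Anisotropic T = exp(-2 pi^2 h'^T N U N h') with h' = R^T h and
# N = diag(a*, b*, c*) (CIF Uij convention).

#' Calculate structure factors
#'
#' @param structure A \code{\link{crystal_structure}} with occupancies and
#'   ADPs (anisotropic Uij where present, otherwise Uiso).
#' @param hkl n x 3 integer matrix of Miller indices.
#' @param default_uiso Fallback Uiso for sites with no ADP at all;
#'   \code{NULL} means a missing ADP is an error. (A Uiso of 0 is a valid
#'   ADP, not a missing one.)
#' @return Complex vector of F(h), one per row of \code{hkl}.
#' @export
calc_structure_factors <- function(structure, hkl, default_uiso = NULL) {
  h <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3)
  cell <- structure$cell
  sites <- structure$sites
  n_at <- nrow(sites)
  frac <- site_frac(structure)
  gstar <- reciprocal_metric_tensor(cell)
  nstar <- sqrt(diag(gstar))

  if (any(is.na(sites$uiso) & is.na(sites$u11))) {
    if (is.null(default_uiso))
      stop("calc_structure_factors: site(s) with no ADP and no default_uiso")
    sites$uiso[is.na(sites$uiso)] <- default_uiso
  }

  s2 <- rowSums((h %*% gstar) * h) / 4   # (sin theta / lambda)^2 = 1/(4 d^2)
  f_el <- matrix(0, nrow(h), n_at)
  for (el in unique(sites$element)) {
    idx <- sites$element == el
    f_el[, idx] <- form_factor(el, sqrt(s2))
  }

  aniso <- !is.na(sites$u11)
  # per-atom scaled Uij matrices (beta / (2 pi^2) = N U N) for aniso atoms
  beta_list <- vector("list", n_at)
  for (a in which(aniso)) {
    u <- matrix(c(sites$u11[a], sites$u12[a], sites$u13[a],
                  sites$u12[a], sites$u22[a], sites$u23[a],
                  sites$u13[a], sites$u23[a], sites$u33[a]), 3, 3)
    beta_list[[a]] <- diag(nstar) %*% u %*% diag(nstar)
  }

  fvec <- complex(length.out = nrow(h))
  for (op in structure$spacegroup$operations) {
    hp <- h %*% op$rotation                      # rows are (R^T h)^T
    phase_t <- as.numeric(h %*% symop_translation(op))
    phase <- hp %*% t(frac) + phase_t            # n_hkl x n_at (cycles)
    dw <- matrix(1, nrow(h), n_at)
    iso <- which(!aniso)
    if (length(iso) > 0)
      dw[, iso] <- exp(-8 * pi^2 * outer(s2, sites$uiso[iso]))
    for (a in which(aniso)) {
      q <- rowSums((hp %*% beta_list[[a]]) * hp)
      dw[, a] <- exp(-2 * pi^2 * q)
    }
    contrib <- (matrix(sites$occ, nrow(h), n_at, byrow = TRUE) * f_el * dw) *
      exp(2i * pi * phase)
    fvec <- fvec + rowSums(contrib)
  }
  fvec
}

#' Least-squares scale factor on intensities
#'
#' k minimizing sum (Fo^2 - k Fc^2)^2, i.e.
#' k = sum(Fo^2 Fc^2) / sum(Fc^4).
#'
#' @param fo_sq,fc_sq Observed and calculated intensities (equal length).
#' @export
scale_factor <- function(fo_sq, fc_sq) {
  stopifnot(length(fo_sq) == length(fc_sq))
  denom <- sum(fc_sq^2)
  if (denom == 0) stop("scale_factor: all calculated intensities are zero")
  sum(fo_sq * fc_sq) / denom
}

#' Conventional R1 agreement factor on amplitudes
#'
#' R1 = sum | |Fo| - |Fc| | / sum |Fo|.
#'
#' @param fo,fc Observed and (scaled) calculated structure-factor
#'   amplitudes.
#' @export
r1_factor <- function(fo, fc) {
  if (length(fo) == 0) stop("r1_factor: empty input")
  stopifnot(length(fo) == length(fc))
  sum(abs(abs(fo) - abs(fc))) / sum(abs(fo))
}
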