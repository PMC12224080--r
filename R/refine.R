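# Restrained / unrestrained positional least squares against Fo^2
# (SHELXL convention), reporting R1 on |F|. Gauss-Newton with analytic
# derivatives, damped steps and a shift/esd convergence test. Minimizes
#   sum_h w_h (Fo^2 - k Fc^2)^2 + sum_r w_r (D_model - T_target)^2
# over the fractional coordinates of the refined atoms plus the overall
# scale k. ADPs are held fixed; riding hydrogens follow their parent shifts
# and never contribute parameters.

#' Refinement options
#'
#' @param mode "auto" (restrained iff restraints are supplied),
#'   "unrestrained" (ignore any supplied restraints) or "restrained".
#' @param max_cycles Maximum Gauss-Newton cycles.
#' @param convergence_tol Stop when max |shift|/esd falls below this.
#' @param damping Step multiplier in (0, 1].
#' @param weight_a,weight_b Constants of the sigma-based weighting scheme
#'   w = 1/[sigma^2 + (aP)^2 + bP], P = (max(Fo^2,0) + 2 Fc^2)/3.
#' @param restraint_weight_scale Multiplier on the restraint weights
#'   w_r = scale / su^2; the knob that makes "tight" tight.
#' @param riding_h Ride hydrogens on their parent atoms (positions shift
#'   with the parent, Uiso = multiplier x Ueq(parent))?
#' @param h_u_multiplier Uiso multiplier for riding hydrogens (2.4, or 3.0
#'   for hydroxyl/methyl-type hydrogens).
#' @export
refinement_options <- function(mode = c("auto", "unrestrained", "restrained"),
                               max_cycles = 50, convergence_tol = 0.01,
                               damping = 1.0, weight_a = 0.1, weight_b = 0,
                               restraint_weight_scale = 1.0,
                               riding_h = TRUE, h_u_multiplier = 2.4) {
  mode <- match.arg(mode)
  if (damping <= 0 || damping > 1) stop("refinement_options: damping must be in (0, 1]")
  if (max_cycles < 1) stop("refinement_options: max_cycles must be >= 1")
  list(mode = mode, max_cycles = max_cycles, convergence_tol = convergence_tol,
       damping = damping, weight_a = weight_a, weight_b = weight_b,
       restraint_weight_scale = restraint_weight_scale,
       riding_h = riding_h, h_u_multiplier = h_u_multiplier)
}

# structure factors plus analytic derivatives wrt fractional coordinates of
# parameter groups (group = refined atom index owning each atom's shifts)
sf_and_derivs <- function(structure, h, group, want_derivs = TRUE) {
  cell <- structure$cell
  sites <- structure$sites
  n_at <- nrow(sites)
  frac <- site_frac(structure)
  gstar <- reciprocal_metric_tensor(cell)
  nstar <- sqrt(diag(gstar))
  s2 <- rowSums((h %*% gstar) * h) / 4
  f_el <- matrix(0, nrow(h), n_at)
  for (el in unique(sites$element)) {
    idx <- sites$element == el
    f_el[, idx] <- form_factor(el, sqrt(s2))
  }
  aniso <- !is.na(sites$u11)
  beta_list <- vector("list", n_at)
  for (a in which(aniso)) {
    u <- matrix(c(sites$u11[a], sites$u12[a], sites$u13[a],
                  sites$u12[a], sites$u22[a], sites$u23[a],
                  sites$u13[a], sites$u23[a], sites$u33[a]), 3, 3)
    beta_list[[a]] <- diag(nstar) %*% u %*% diag(nstar)
  }
  ngroups <- max(c(0L, group), na.rm = TRUE)
  fvec <- complex(length.out = nrow(h))
  dF <- if (want_derivs && ngroups > 0)
    matrix(complex(length.out = nrow(h) * 3 * ngroups), nrow(h), 3 * ngroups)
  else NULL
  occ_row <- matrix(sites$occ, nrow(h), n_at, byrow = TRUE)
  for (op in structure$spacegroup$operations) {
    hp <- h %*% op$rotation
    phase_t <- as.numeric(h %*% symop_translation(op))
    phase <- hp %*% t(frac) + phase_t
    dw <- matrix(1, nrow(h), n_at)
    iso <- which(!aniso)
    if (length(iso) > 0)
      dw[, iso] <- exp(-8 * pi^2 * outer(s2, sites$uiso[iso]))
    for (a in which(aniso))
      dw[, a] <- exp(-2 * pi^2 * rowSums((hp %*% beta_list[[a]]) * hp))
    contrib <- (occ_row * f_el * dw) * exp(2i * pi * phase)
    fvec <- fvec + rowSums(contrib)
    if (!is.null(dF)) {
      for (a in seq_len(n_at)) {
        g <- group[a]
        if (is.na(g)) next
        for (m in 1:3) {
          col <- 3 * (g - 1) + m
          dF[, col] <- dF[, col] + 2i * pi * hp[, m] * contrib[, a]
        }
      }
    }
  }
  list(f = fvec, dF = dF)
}

#' Refine a structure against Bragg intensities
#'
#' @param structure Starting \code{\link{crystal_structure}}.
#' @param reflections A \code{\link{reflection_set}}.
#' @param restraints Optional \code{\link{restraint_set}} of bond / 1-3
#'   distance restraints.
#' @param options A \code{\link{refinement_options}} list.
#' @return A \code{refinement_result}: refined structure, \code{r1},
#'   \code{wr2}, \code{scale}, \code{cycles_used},
#'   \code{max_shift_over_esd}, \code{restraint_rms}, \code{converged}.
#' @export
refine <- function(structure, reflections, restraints = NULL,
                   options = refinement_options()) {
  stopifnot(inherits(structure, "xtal_structure"),
            inherits(reflections, "reflection_set"))
  if (options$mode == "unrestrained") restraints <- NULL
  if (options$mode == "restrained" && is.null(restraints))
    stop("refine: restrained mode requested but no restraints supplied")
  sites <- structure$sites
  n_at <- nrow(sites)
  m_orth <- orthogonalization_matrix(structure$cell)
  gmat <- t(m_orth) %*% m_orth

  # parameter groups: every non-riding atom owns its 3 coordinates;
  # riding hydrogens map onto their parent's group
  riding_parent <- rep(NA_integer_, n_at)
  if (options$riding_h && any(sites$is_h)) {
    graph <- perceive_bonds(sites$element, site_cart(structure))
    parents <- h_parents(graph)
    for (i in which(sites$is_h)) {
      if (length(parents[[i]]) > 0) riding_parent[i] <- parents[[i]][1]
    }
    # riding-H Uiso from the parent's equivalent U
    for (i in which(sites$is_h & !is.na(riding_parent))) {
      p <- riding_parent[i]
      ueq <- if (!is.na(sites$u11[p])) u_equiv(structure$cell, site_u_cif(structure, p))
             else sites$uiso[p]
      sites$uiso[i] <- options$h_u_multiplier * ueq
      sites[i, c("u11", "u22", "u33", "u23", "u13", "u12")] <- NA_real_
    }
  }
  refined_atom <- which(!(sites$is_h & options$riding_h))
  group <- rep(NA_integer_, n_at)
  group[refined_atom] <- seq_along(refined_atom)
  for (i in which(!is.na(riding_parent)))
    group[i] <- group[riding_parent[i]]
  npar_xyz <- 3 * length(refined_atom)

  # restraint bookkeeping; weights w_r = scale * s / su^2 with the data
  # normalization s = mean(w_h Fo^4) fixed from the first cycle, so a
  # "tight" s.u. really is enforced at the data's own scale
  r_i <- r_j <- integer(0); r_t <- r_su <- r_w <- numeric(0)
  if (!is.null(restraints) && nrow(restraints$restraints) > 0) {
    rr <- restraints$restraints
    r_i <- match(toupper(rr$atom1), toupper(sites$label))
    r_j <- match(toupper(rr$atom2), toupper(sites$label))
    if (anyNA(r_i) || anyNA(r_j))
      stop(sprintf("refine: restraint label(s) not in structure: %s",
                   paste(unique(c(rr$atom1[is.na(r_i)], rr$atom2[is.na(r_j)])),
                         collapse = ", ")))
    r_t <- rr$target
    r_su <- rr$su
  }

  st <- structure
  st$sites <- sites
  h <- reflections$hkl
  fo_sq <- reflections$f_sq
  sig <- reflections$sigma

  frac_cur <- site_frac(st)
  frac_start <- frac_cur
  polar <- polar_directions(structure$spacegroup)
  n_polar <- if (npar_xyz > 0) ncol(polar) else 0L
  k <- NULL
  cycles <- 0L
  max_sh_esd <- Inf
  converged <- FALSE

  objective <- function(frac, kval, w) {
    st$sites[, c("x", "y", "z")] <- frac
    fc <- Mod(sf_and_derivs(st, h, group, want_derivs = FALSE)$f)^2
    obj <- sum(w * (fo_sq - kval * fc)^2)
    if (length(r_i) > 0) {
      d <- restraint_distances(frac, r_i, r_j, gmat)
      obj <- obj + sum(r_w * (d - r_t)^2)
    }
    obj
  }

  for (cyc in seq_len(options$max_cycles)) {
    cycles <- cyc
    st$sites[, c("x", "y", "z")] <- frac_cur
    sf <- sf_and_derivs(st, h, group, want_derivs = TRUE)
    fc_sq <- Mod(sf$f)^2
    if (is.null(k)) k <- scale_factor(fo_sq, fc_sq)
    p_half <- (pmax(fo_sq, 0) + 2 * k * fc_sq) / 3
    w <- 1 / (sig^2 + (options$weight_a * p_half)^2 + options$weight_b * p_half)
    if (length(r_i) > 0 && length(r_w) == 0)
      r_w <- options$restraint_weight_scale * mean(w * fo_sq^2) / r_su^2

    # residuals and Jacobian: data part
    sw <- sqrt(w)
    e <- sw * (fo_sq - k * fc_sq)
    # d(k Fc^2)/dxyz = k * 2 Re(conj(F) dF); d/dk = Fc^2
    jac <- matrix(0, length(e) + length(r_i) + n_polar, npar_xyz + 1)
    if (npar_xyz > 0)
      jac[seq_along(e), seq_len(npar_xyz)] <-
        sw * (2 * k * Re(Conj(sf$f) * sf$dF))
    jac[seq_along(e), npar_xyz + 1] <- sw * fc_sq

    if (length(r_i) > 0) {
      d <- restraint_distances(frac_cur, r_i, r_j, gmat)
      swr <- sqrt(r_w)
      e <- c(e, swr * (r_t - d))
      for (n in seq_along(r_i)) {
        dfij <- frac_cur[r_i[n], ] - frac_cur[r_j[n], ]
        grad <- as.numeric(gmat %*% dfij) / d[n]   # dD/dfrac_i
        gi <- group[r_i[n]]; gj <- group[r_j[n]]
        row <- length(fo_sq) + n
        if (!is.na(gi))
          jac[row, 3 * (gi - 1) + 1:3] <- jac[row, 3 * (gi - 1) + 1:3] + swr[n] * grad
        if (!is.na(gj))
          jac[row, 3 * (gj - 1) + 1:3] <- jac[row, 3 * (gj - 1) + 1:3] - swr[n] * grad
      }
    }

    # fix the floating origin of polar space groups: pin the mean refined
    # coordinate along each polar direction to its starting value
    if (n_polar > 0) {
      w0 <- sqrt(max(colSums(jac[seq_along(fo_sq), , drop = FALSE]^2)))
      if (w0 == 0) w0 <- 1
      drift <- colMeans(frac_start[refined_atom, , drop = FALSE] -
                          frac_cur[refined_atom, , drop = FALSE])
      for (p in seq_len(n_polar)) {
        v <- polar[, p]
        row <- length(fo_sq) + length(r_i) + p
        for (gidx in seq_along(refined_atom))
          jac[row, 3 * (gidx - 1) + 1:3] <- w0 * v / length(refined_atom)
        e <- c(e, w0 * sum(drift * v))
      }
    }

    nm <- crossprod(jac)
    g <- crossprod(jac, e)
    ch <- tryCatch(chol(nm), error = function(err) NULL)
    if (is.null(ch))
      stop("refine: singular normal matrix (consider damping, fewer parameters or more data)")
    shift <- backsolve(ch, forwardsolve(t(ch), g))
    nobs <- length(e); npar <- length(shift)
    gof2 <- if (nobs > npar) sum(e^2) / (nobs - npar) else sum(e^2)
    esd <- sqrt(pmax(diag(chol2inv(ch)), 0) * max(gof2, .Machine$double.eps))

    step <- options$damping * shift
    # backtracking keeps the objective non-increasing
    obj0 <- sum(e^2)
    accepted <- FALSE
    for (try in 0:8) {
      frac_try <- frac_cur
      if (npar_xyz > 0) {
        dxyz <- matrix(step[seq_len(npar_xyz)], ncol = 3, byrow = TRUE)
        for (a in seq_len(n_at)) {
          if (!is.na(group[a]))
            frac_try[a, ] <- frac_try[a, ] + dxyz[group[a], ]
        }
      }
      k_try <- k + step[npar_xyz + 1]
      obj1 <- objective(frac_try, k_try, w)
      if (obj1 <= obj0 + 1e-12 * (1 + abs(obj0))) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) {
      max_sh_esd <- 0
      converged <- TRUE
      break
    }
    frac_cur <- frac_try
    k <- k_try
    sh_ratio <- ifelse(esd > 0, abs(step) / esd, 0)
    max_sh_esd <- max(c(sh_ratio, 0))
    if (max_sh_esd < options$convergence_tol) { converged <- TRUE; break }
  }

  st$sites[, c("x", "y", "z")] <- frac_cur
  fc_sq <- Mod(sf_and_derivs(st, h, group, want_derivs = FALSE)$f)^2
  p_half <- (pmax(fo_sq, 0) + 2 * k * fc_sq) / 3
  w <- 1 / (sig^2 + (options$weight_a * p_half)^2 + options$weight_b * p_half)
  fo_amp <- sqrt(pmax(fo_sq, 0))
  fc_amp <- sqrt(pmax(k, 0) * fc_sq)
  restraint_rms <- NA_real_
  if (length(r_i) > 0) {
    d <- restraint_distances(frac_cur, r_i, r_j, gmat)
    restraint_rms <- sqrt(mean((d - r_t)^2))
  }
  structure(list(structure = st,
                 r1 = r1_factor(fo_amp, fc_amp),
                 wr2 = sqrt(sum(w * (fo_sq - k * fc_sq)^2) / sum(w * fo_sq^2)),
                 scale = k,
                 cycles_used = cycles,
                 max_shift_over_esd = max_sh_esd,
                 restraint_rms = restraint_rms,
                 converged = converged,
                 mode = if (length(r_i) > 0) "restrained" else "unrestrained",
                 reflections = reflections),
            class = "refinement_result")
}

restraint_distances <- function(frac, i, j, gmat) {
  df <- frac[i, , drop = FALSE] - frac[j, , drop = FALSE]
  sqrt(rowSums((df %*% gmat) * df))
}

# directions v with R v = v for every rotation: along these the structure
# can float freely (|F| is origin-independent), so the origin must be fixed
polar_directions <- function(spacegroup) {
  stack <- do.call(rbind, lapply(spacegroup$operations,
                                 function(op) op$rotation - diag(3L)))
  sv <- svd(stack, nu = 0, nv = 3)
  null_idx <- which(sv$d < 1e-9)
  if (length(sv$d) < 3) null_idx <- union(null_idx, (length(sv$d) + 1):3)
  sv$v[, null_idx, drop = FALSE]
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf("%s refinement: R1 = %.5f, wR2 = %.5f, %d cycle(s), %s\n",
              x$mode, x$r1, x$wr2, x$cycles_used,
              if (x$converged) "converged" else "NOT converged"))
  if (!is.na(x$restraint_rms))
    cat(sprintf("  restraint rms deviation: %.5f A\n", x$restraint_rms))
  invisible(x)
}

#' R-factor penalty of tight restraints
#'
#' Delta R1 = R1(restrained) - R1(unrestrained), both refined against the
#' same reflection set. Near zero (or slightly positive) for accurate
#' restraint targets; grows with target error.
#'
#' @param restrained,unrestrained \code{refinement_result} objects for the
#'   same data.
#' @export
delta_r1 <- function(restrained, unrestrained) {
  stopifnot(inherits(restrained, "refinement_result"),
            inherits(unrestrained, "refinement_result"))
  same <- identical(dim(restrained$reflections$hkl),
                    dim(unrestrained$reflections$hkl)) &&
    all(restrained$reflections$hkl == unrestrained$reflections$hkl) &&
    isTRUE(all.equal(restrained$reflections$f_sq, unrestrained$reflections$f_sq))
  if (!same)
    stop("delta_r1: the two refinements used different reflection sets")
  restrained$r1 - unrestrained$r1
}
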