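# TLS rigid-body analysis of anisotropic displacement parameters and the
# resulting libration correction of bond lengths, plus the Busing-Levy
# riding correction. All tensors here are Cartesian.

#' TLS rigid-body model
#'
#' @param T 3x3 symmetric translation tensor (Angstrom^2).
#' @param L 3x3 symmetric libration tensor (rad^2).
#' @param S 3x3 screw tensor (Angstrom rad) with trace 0 by convention.
#' @param origin Cartesian origin (Angstrom), typically the molecular
#'   centroid.
#' @export
tls_model <- function(T, L, S = matrix(0, 3, 3), origin = c(0, 0, 0)) {
  stopifnot(all(dim(T) == c(3, 3)), all(dim(L) == c(3, 3)), all(dim(S) == c(3, 3)))
  if (max(abs(T - t(T))) > 1e-10 || max(abs(L - t(L))) > 1e-10)
    stop("tls_model: T and L must be symmetric")
  if (abs(sum(diag(S))) > 1e-8)
    stop("tls_model: trace(S) must be 0 (origin convention)")
  structure(list(T = T, L = L, S = S, origin = as.numeric(origin)),
            class = "tls_model")
}

skew_cross <- function(d) {
  # A such that A %*% omega = omega x d
  matrix(c(0, -d[3], d[2],
           d[3], 0, -d[1],
           -d[2], d[1], 0), 3, 3, byrow = TRUE)
}

#' Rigid-body ADPs predicted by a TLS model
#'
#' U(r) = T + A L A' + A S + S' A' with A the cross-product matrix of
#' (r - origin); linear in (T, L, S).
#'
#' @param cart n x 3 Cartesian coordinates (Angstrom).
#' @param tls A \code{\link{tls_model}}.
#' @return n x 6 matrix of Cartesian Uij, columns U11,U22,U33,U23,U13,U12.
#' @export
rigid_body_adps <- function(cart, tls) {
  cart <- if (is.matrix(cart)) cart else matrix(cart, ncol = 3)
  out <- matrix(0, nrow(cart), 6)
  colnames(out) <- c("u11", "u22", "u33", "u23", "u13", "u12")
  for (i in seq_len(nrow(cart))) {
    a <- skew_cross(cart[i, ] - tls$origin)
    u <- tls$T + a %*% tls$L %*% t(a) + a %*% tls$S + t(tls$S) %*% t(a)
    out[i, ] <- c(u[1, 1], u[2, 2], u[3, 3], u[2, 3], u[1, 3], u[1, 2])
  }
  out
}

u6_to_mat <- function(u6) {
  matrix(c(u6[1], u6[6], u6[5],
           u6[6], u6[2], u6[4],
           u6[5], u6[4], u6[3]), 3, 3)
}

#' Fit a TLS model to anisotropic ADPs
#'
#' Linear least squares of the 20 independent TLS parameters (S is made
#' unique by trace(S) = 0) against the observed Cartesian Uij of the fitted
#' atoms. The origin is the centroid of the fitted atoms. Following common
#' thermal-motion-analysis practice, molecules with six or fewer atoms are
#' refused.
#'
#' @param structure A \code{\link{crystal_structure}} whose fitted sites
#'   carry anisotropic ADPs, or a list with \code{cart} (n x 3) and
#'   \code{u_cart} (n x 6, columns U11,U22,U33,U23,U13,U12).
#' @param non_h_only Fit non-hydrogen atoms only?
#' @return List with \code{tls} (a \code{tls_model}), \code{residual}
#'   (RMS misfit over Uij components, Angstrom^2), and \code{n_atoms}.
#' @export
fit_tls <- function(structure, non_h_only = TRUE) {
  if (inherits(structure, "xtal_structure")) {
    sel <- if (non_h_only) !structure$sites$is_h else rep(TRUE, nrow(structure$sites))
    sel <- sel & !is.na(structure$sites$u11)
    if (sum(sel) < 7)
      stop("fit_tls: need more than six atoms with anisotropic ADPs for a TLS fit")
    cart <- site_cart(structure)[sel, , drop = FALSE]
    u_obs <- t(vapply(which(sel), function(i) {
      u <- u_cif_to_cart(structure$cell, site_u_cif(structure, i))
      c(u[1, 1], u[2, 2], u[3, 3], u[2, 3], u[1, 3], u[1, 2])
    }, numeric(6)))
  } else {
    cart <- structure$cart
    u_obs <- structure$u_cart
    if (nrow(cart) < 7)
      stop("fit_tls: need more than six atoms with anisotropic ADPs for a TLS fit")
  }
  origin <- colMeans(cart)

  # design matrix: columns = basis elements of (T, L, S|trace 0)
  basis <- tls_parameter_basis()
  n <- nrow(cart)
  design <- matrix(0, 6 * n, length(basis))
  for (p in seq_along(basis)) {
    pred <- rigid_body_adps(cart, tls_from_params(basis[[p]], origin))
    design[, p] <- as.numeric(t(pred))
  }
  y <- as.numeric(t(u_obs))
  qrd <- qr(design)
  if (qrd$rank < length(basis))
    stop("fit_tls: rank-deficient TLS design (degenerate geometry, e.g. a linear molecule)")
  coef <- qr.coef(qrd, y)
  fitted <- design %*% coef
  resid <- sqrt(mean((y - fitted)^2))
  params <- list(T = matrix(0, 3, 3), L = matrix(0, 3, 3), S = matrix(0, 3, 3))
  for (p in seq_along(basis)) {
    params$T <- params$T + coef[p] * basis[[p]]$T
    params$L <- params$L + coef[p] * basis[[p]]$L
    params$S <- params$S + coef[p] * basis[[p]]$S
  }
  list(tls = tls_from_params(params, origin), residual = resid, n_atoms = n)
}

tls_parameter_basis <- function() {
  sym6 <- function(i, j) { m <- matrix(0, 3, 3); m[i, j] <- m[j, i] <- 1; m }
  basis <- list()
  for (idx in list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3)))
    basis[[length(basis) + 1]] <- list(T = sym6(idx[1], idx[2]),
                                       L = matrix(0, 3, 3), S = matrix(0, 3, 3))
  for (idx in list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3)))
    basis[[length(basis) + 1]] <- list(T = matrix(0, 3, 3),
                                       L = sym6(idx[1], idx[2]), S = matrix(0, 3, 3))
  # 8 traceless S elements: off-diagonals + (S11-S33), (S22-S33)
  soff <- list(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))
  for (idx in soff) {
    m <- matrix(0, 3, 3); m[idx[1], idx[2]] <- 1
    basis[[length(basis) + 1]] <- list(T = matrix(0, 3, 3),
                                       L = matrix(0, 3, 3), S = m)
  }
  m1 <- diag(c(1, 0, -1)); m2 <- diag(c(0, 1, -1))
  basis[[length(basis) + 1]] <- list(T = matrix(0, 3, 3), L = matrix(0, 3, 3), S = m1)
  basis[[length(basis) + 1]] <- list(T = matrix(0, 3, 3), L = matrix(0, 3, 3), S = m2)
  basis
}

tls_from_params <- function(p, origin) {
  tls_model(p$T, p$L, p$S, origin)
}

#' Libration-corrected bond lengths
#'
#' Applies the rigid-body libration correction
#' delta_r = 1/2 (trace(L) I - L) (r - origin) to every atom and recomputes
#' the bond lengths; libration systematically shortens apparent distances,
#' so the correction elongates them.
#'
#' @param structure A \code{\link{crystal_structure}}.
#' @param tls A \code{\link{tls_model}} (e.g. from \code{\link{fit_tls}}).
#' @param graph Optional \code{bond_graph}; perceived when omitted.
#' @return A \code{tma_report}: per-bond table (uncorrected, corrected,
#'   delta) and \code{mean_delta} over non-hydrogen bonds.
#' @export
libration_corrected_bonds <- function(structure, tls, graph = NULL) {
  cart <- site_cart(structure)
  if (is.null(graph)) graph <- perceive_bonds(structure$sites$element, cart)
  corr <- 0.5 * (sum(diag(tls$L)) * diag(3) - tls$L)
  cart_c <- cart + t(corr %*% t(sweep(cart, 2, tls$origin)))
  e <- graph$edges
  d0 <- sqrt(rowSums((cart[e$i, , drop = FALSE] - cart[e$j, , drop = FALSE])^2))
  d1 <- sqrt(rowSums((cart_c[e$i, , drop = FALSE] - cart_c[e$j, , drop = FALSE])^2))
  labels <- structure$sites$label
  non_h <- !(graph$nodes$is_h[e$i] | graph$nodes$is_h[e$j])
  tab <- data.frame(atom1 = labels[e$i], atom2 = labels[e$j],
                    d_uncorrected = d0, d_corrected = d1, delta = d1 - d0,
                    non_h = non_h, stringsAsFactors = FALSE)
  structure(list(bonds = tab,
                 mean_delta = mean(tab$delta[tab$non_h])),
            class = "tma_report")
}

#' @export
print.tma_report <- function(x, ...) {
  cat(sprintf("TMA libration correction: %d bonds, mean non-H delta = %.5f A\n",
              nrow(x$bonds), x$mean_delta))
  invisible(x)
}

#' Busing-Levy riding correction of a bond length
#'
#' d_corr = d + (<u2_perp>_rider - <u2_perp>_parent) / (2 d), where
#' <u2_perp> = trace(U) - n' U n is the mean-square displacement
#' perpendicular to the bond (sum of the two perpendicular components).
#'
#' @param d Uncorrected bond length (Angstrom), > 0.
#' @param u_parent,u_rider 3x3 Cartesian U tensors (Angstrom^2).
#' @param bond_unit_vector Unit vector along the bond.
#' @return Corrected distance in Angstrom (the correction may be negative).
#' @export
riding_correction <- function(d, u_parent, u_rider, bond_unit_vector) {
  if (d <= 0) stop("riding_correction: bond length must be positive")
  n <- bond_unit_vector / sqrt(sum(bond_unit_vector^2))
  perp <- function(u) sum(diag(u)) - as.numeric(t(n) %*% u %*% n)
  d + (perp(u_rider) - perp(u_parent)) / (2 * d)
}
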