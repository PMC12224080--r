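# Crystal structures: asymmetric-unit atom sites in fractional coordinates
# plus cell and space group. Coordinates are fractional everywhere inside
# the package; Cartesian only at API boundaries.

#' Atom site table
#'
#' Builds the atom-site data frame used inside \code{\link{crystal_structure}}.
#' Anisotropic displacement parameters follow the CIF convention (Uij in
#' Angstrom^2, referred to the reciprocal-axis basis); sites without aniso
#' values carry \code{NA} in the six Uij columns and are treated as
#' isotropic with \code{uiso}.
#'
#' @param label Unique atom labels (e.g. "C1").
#' @param element Chemical symbols.
#' @param frac n x 3 matrix of fractional coordinates.
#' @param occ Occupancies in (0, 1].
#' @param uiso Isotropic U in Angstrom^2.
#' @param uaniso Optional n x 6 matrix with columns U11,U22,U33,U23,U13,U12.
#' @param charge Optional point charges (dimensionless).
#' @export
atom_sites <- function(label, element, frac, occ = 1, uiso = 0.01,
                       uaniso = NULL, charge = NA_real_) {
  frac <- if (is.matrix(frac)) frac else matrix(frac, ncol = 3)
  n <- length(label)
  stopifnot(nrow(frac) == n, length(element) == n)
  df <- data.frame(label = as.character(label),
                   element = as.character(element),
                   x = frac[, 1], y = frac[, 2], z = frac[, 3],
                   occ = rep_len(occ, n),
                   uiso = rep_len(uiso, n),
                   u11 = NA_real_, u22 = NA_real_, u33 = NA_real_,
                   u23 = NA_real_, u13 = NA_real_, u12 = NA_real_,
                   charge = rep_len(charge, n),
                   stringsAsFactors = FALSE)
  if (!is.null(uaniso)) {
    uaniso <- if (is.matrix(uaniso)) uaniso else matrix(uaniso, ncol = 6)
    stopifnot(nrow(uaniso) == n)
    df[, c("u11", "u22", "u33", "u23", "u13", "u12")] <- uaniso
  }
  df$is_h <- toupper(df$element) %in% c("H", "D")
  df
}

#' Crystal structure (asymmetric unit)
#'
#' @param cell A \code{\link{unit_cell}}.
#' @param spacegroup A \code{\link{space_group}}.
#' @param sites Atom-site data frame from \code{\link{atom_sites}}.
#' @return Object of class \code{xtal_structure}.
#' @export
crystal_structure <- function(cell, spacegroup, sites) {
  stopifnot(inherits(cell, "unit_cell"), inherits(spacegroup, "space_group"))
  if (nrow(sites) < 1) stop("crystal_structure: at least one atom site required")
  if (anyDuplicated(toupper(sites$label)))
    stop("crystal_structure: atom labels must be unique (case-insensitive)")
  if (any(!nzchar(sites$label)))
    stop("crystal_structure: empty atom label")
  if (any(!is.finite(as.matrix(sites[, c("x", "y", "z")]))))
    stop("crystal_structure: non-finite fractional coordinates")
  if (any(sites$occ <= 0 | sites$occ > 1 + 1e-9))
    stop("crystal_structure: occupancies must lie in (0, 1]")
  structure(list(cell = cell, spacegroup = spacegroup, sites = sites),
            class = "xtal_structure")
}

#' @export
print.xtal_structure <- function(x, ...) {
  cat(sprintf("crystal structure: %d sites, space group %s\n",
              nrow(x$sites), x$spacegroup$name))
  print(x$cell)
  invisible(x)
}

#' Fractional coordinates of a structure's sites as a matrix
#' @param structure A \code{xtal_structure}.
#' @export
site_frac <- function(structure) {
  as.matrix(structure$sites[, c("x", "y", "z")])
}

#' Cartesian coordinates of a structure's sites (Angstrom)
#' @param structure A \code{xtal_structure}.
#' @export
site_cart <- function(structure) {
  frac_to_cart(structure$cell, site_frac(structure))
}

#' CIF Uij tensor for one site, NA-free (isotropic promoted to the CIF basis)
#' @noRd
site_u_cif <- function(structure, i) {
  s <- structure$sites[i, ]
  if (!is.na(s$u11)) {
    u <- matrix(c(s$u11, s$u12, s$u13,
                  s$u12, s$u22, s$u23,
                  s$u13, s$u23, s$u33), 3, 3)
    return(u)
  }
  # isotropic U: U_cif = uiso * N^-1 G* N^-1 ... for the CIF convention an
  # isotropic atom has U_cart = uiso * I; transform back to the CIF basis.
  cart_to_u_cif(structure$cell, diag(rep(s$uiso, 3)))
}

# a*-scaled transformation between CIF Uij and Cartesian U:
#   U_cart = (M N) U_cif (M N)^T,  N = diag(a*, b*, c*)
u_cif_to_cart <- function(cell, u_cif) {
  m <- orthogonalization_matrix(cell)
  n <- diag(sqrt(diag(reciprocal_metric_tensor(cell))))
  a <- m %*% n
  a %*% u_cif %*% t(a)
}

cart_to_u_cif <- function(cell, u_cart) {
  m <- orthogonalization_matrix(cell)
  n <- diag(sqrt(diag(reciprocal_metric_tensor(cell))))
  a <- solve(m %*% n)
  a %*% u_cart %*% t(a)
}

# Transform a CIF-convention Uij under a symmetry rotation R (fractional
# basis). The quadratic Debye-Waller form beta = 2 pi^2 N U N transforms as
# beta' = R beta R^T.
transform_u_cif <- function(cell, rotation, u_cif) {
  n <- diag(sqrt(diag(reciprocal_metric_tensor(cell))))
  beta <- n %*% u_cif %*% n
  beta2 <- rotation %*% beta %*% t(rotation)
  ninv <- solve(n)
  ninv %*% beta2 %*% ninv
}

u_equiv <- function(cell, u_cif) {
  sum(diag(u_cif_to_cart(cell, u_cif))) / 3
}

#' Expand an asymmetric unit to the full P1 cell
#'
#' Replicates every site by every space-group operation, wraps coordinates
#' into [0, 1), rotates anisotropic ADPs accordingly, and merges duplicates
#' closer than \code{tol} (fractional) arising from special positions. On a
#' merge the occupancies of the merged copies are summed, so a structure
#' factor computed from the expanded cell in P1 equals the symmetry-summed
#' one.
#'
#' @param structure A \code{xtal_structure}.
#' @param tol Merge tolerance in fractional units.
#' @return Atom-site data frame for the full cell (labels suffixed by
#'   operation index).
#' @export
expand_to_p1 <- function(structure, tol = 1e-4) {
  ops <- structure$spacegroup$operations
  frac <- site_frac(structure)
  out <- NULL
  for (k in seq_along(ops)) {
    op <- ops[[k]]
    f <- wrap_frac(apply_symmetry(op, frac))
    s <- structure$sites
    s$x <- f[, 1]; s$y <- f[, 2]; s$z <- f[, 3]
    aniso <- !is.na(s$u11)
    if (any(aniso) && k > 1) {
      for (i in which(aniso)) {
        u <- transform_u_cif(structure$cell, op$rotation, site_u_cif(structure, i))
        s[i, c("u11", "u22", "u33", "u23", "u13", "u12")] <-
          c(u[1, 1], u[2, 2], u[3, 3], u[2, 3], u[1, 3], u[1, 2])
      }
    }
    s$label <- paste0(s$label, "_", k)
    s$orig <- structure$sites$label
    out <- rbind(out, s)
  }
  # merge special-position duplicates of the same original atom
  keep <- rep(TRUE, nrow(out))
  fr <- as.matrix(out[, c("x", "y", "z")])
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(out))) {
      if (j <= i || !keep[j] || out$orig[j] != out$orig[i]) next
      d <- fr[j, ] - fr[i, ]
      d <- d - round(d)
      if (max(abs(d)) < tol) {
        keep[j] <- FALSE
        out$occ[i] <- out$occ[i] + out$occ[j]
      }
    }
  }
  out <- out[keep, ]
  rownames(out) <- NULL
  out
}

#' Full-cell structure in P1 (reference representation)
#'
#' Convenience wrapper returning a \code{xtal_structure} in space group P1
#' whose sites are \code{\link{expand_to_p1}} of the input.
#' @param structure A \code{xtal_structure}.
#' @param tol Merge tolerance passed to \code{expand_to_p1}.
#' @export
as_p1_structure <- function(structure, tol = 1e-4) {
  s <- expand_to_p1(structure, tol)
  s$orig <- NULL
  crystal_structure(structure$cell, lookup_space_group("P1"), s)
}
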