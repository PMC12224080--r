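#' Unit cell
#'
#' Construct a validated unit cell from lengths (Angstrom) and angles
#' (degrees).
#'
#' @param a,b,c Cell lengths in Angstrom, all > 0.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class \code{unit_cell}.
#' @examples
#' unit_cell(5, 5, 5, 90, 90, 90)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  vals <- c(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(vals)))
    stop("unit_cell: all cell parameters must be finite numbers")
  if (any(vals[1:3] <= 0))
    stop("unit_cell: cell lengths must be positive")
  if (any(vals[4:6] <= 0 | vals[4:6] >= 180))
    stop("unit_cell: cell angles must lie in (0, 180) degrees")
  cell <- structure(as.list(vals), class = "unit_cell")
  # volume check catches impossible angle combinations (e.g. 170/170/170)
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180); cg <- cos(gamma * pi / 180)
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 1e-12)
    stop("unit_cell: degenerate cell (non-positive volume)")
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.4f b=%.4f c=%.4f  alpha=%.3f beta=%.3f gamma=%.3f  V=%.3f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, cell_volume(x)))
  invisible(x)
}

#' Fractional-to-Cartesian orthogonalization matrix
#'
#' Returns the 3x3 matrix \code{M} such that \code{cart = M \%*\% frac}.
#' Convention: the a axis lies along Cartesian x and b lies in the x-y
#' plane, so \code{t(M) \%*\% M} equals the direct metric tensor.
#'
#' @param cell A \code{unit_cell}.
#' @return 3x3 numeric matrix (Angstrom).
#' @export
orthogonalization_matrix <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta  * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  sg <- sin(cell$gamma * pi / 180)
  v  <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  matrix(c(cell$a, cell$b * cg, cell$c * cb,
           0,      cell$b * sg, cell$c * (ca - cb * cg) / sg,
           0,      0,           cell$c * v / sg),
         nrow = 3, byrow = TRUE)
}

#' Unit-cell volume in cubic Angstrom
#' @param cell A \code{unit_cell}.
#' @export
cell_volume <- function(cell) {
  abs(det(orthogonalization_matrix(cell)))
}

#' Direct metric tensor G = t(M) M
#' @param cell A \code{unit_cell}.
#' @export
metric_tensor <- function(cell) {
  m <- orthogonalization_matrix(cell)
  t(m) %*% m
}

#' Reciprocal metric tensor (inverse of the direct metric)
#' @param cell A \code{unit_cell}.
#' @export
reciprocal_metric_tensor <- function(cell) {
  solve(metric_tensor(cell))
}

#' Resolution d of one or more reflections
#'
#' @param cell A \code{unit_cell}.
#' @param hkl Integer 3-vector or n x 3 matrix of Miller indices.
#' @return d-spacings in Angstrom (one per row of \code{hkl}).
#' @export
d_spacing <- function(cell, hkl) {
  h <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3)
  if (any(rowSums(h != 0) == 0))
    stop("d_spacing: (0,0,0) has no d-spacing")
  gstar <- reciprocal_metric_tensor(cell)
  inv_d2 <- rowSums((h %*% gstar) * h)
  1 / sqrt(inv_d2)
}

#' Convert fractional to Cartesian coordinates
#' @param cell A \code{unit_cell}.
#' @param frac n x 3 matrix (or 3-vector) of fractional coordinates.
#' @return n x 3 matrix of Cartesian coordinates in Angstrom.
#' @export
frac_to_cart <- function(cell, frac) {
  f <- if (is.matrix(frac)) frac else matrix(frac, ncol = 3)
  f %*% t(orthogonalization_matrix(cell))
}

#' Convert Cartesian to fractional coordinates
#' @param cell A \code{unit_cell}.
#' @param cart n x 3 matrix (or 3-vector) of Cartesian coordinates (Angstrom).
#' @return n x 3 matrix of fractional coordinates.
#' @export
cart_to_frac <- function(cell, cart) {
  x <- if (is.matrix(cart)) cart else matrix(cart, ncol = 3)
  x %*% t(solve(orthogonalization_matrix(cell)))
}

cells_equal <- function(a, b, rel_tol = 1e-4) {
  pa <- unlist(a[c("a", "b", "c", "alpha", "beta", "gamma")])
  pb <- unlist(b[c("a", "b", "c", "alpha", "beta", "gamma")])
  all(abs(pa - pb) <= rel_tol * pmax(abs(pa), 1))
}
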