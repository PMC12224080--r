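# RMSCD scoring and geometry tables for optimized-vs-experimental
# structure comparison at a fixed unit cell.

#' Root mean square Cartesian displacement between two structures
#'
#' RMSCD = sqrt( (1/n) sum_i |M (r1_i - r2_i)|^2 ) over mapped atoms, with
#' M the fractional-to-Cartesian matrix and each fractional difference
#' component wrapped to the nearest periodic image (into [-1/2, 1/2)).
#' Hydrogens are omitted by default.
#'
#' @param a,b \code{\link{crystal_structure}} objects sharing a unit cell.
#' @param mapping Optional \code{atom_mapping} from
#'   \code{\link{match_atoms}}; by default atoms are matched by label.
#' @param include_hydrogen Include hydrogen atoms?
#' @param remove_rigid_shift Subtract the mean Cartesian displacement
#'   before taking the RMS (reports a pure deformation measure)?
#' @param cell_tol Relative tolerance for the cell-identity check.
#' @return RMSCD in Angstrom.
#' @export
rmscd <- function(a, b, mapping = NULL, include_hydrogen = FALSE,
                  remove_rigid_shift = FALSE, cell_tol = 1e-4) {
  compare_structures(a, b, mapping = mapping,
                     include_hydrogen = include_hydrogen,
                     remove_rigid_shift = remove_rigid_shift,
                     cell_tol = cell_tol)$rmscd
}

#' Full structure comparison report
#'
#' @inheritParams rmscd
#' @return List of class \code{comparison_report}: \code{rmscd},
#'   \code{per_atom} (label -> displacement in Angstrom),
#'   \code{n_atoms_compared}, \code{rigid_shift_removed}.
#' @export
compare_structures <- function(a, b, mapping = NULL, include_hydrogen = FALSE,
                               remove_rigid_shift = FALSE, cell_tol = 1e-4) {
  stopifnot(inherits(a, "xtal_structure"), inherits(b, "xtal_structure"))
  if (!cells_equal(a$cell, b$cell, cell_tol))
    stop("compare_structures: unit cells differ beyond tolerance (RMSCD is defined at a fixed cell)")
  if (is.null(mapping)) {
    idx_b <- match(toupper(a$sites$label), toupper(b$sites$label))
    if (anyNA(idx_b))
      stop("compare_structures: labels do not correspond; supply a mapping from match_atoms()")
  } else {
    idx_b <- mapping$pairs
  }
  sel <- if (include_hydrogen) rep(TRUE, nrow(a$sites)) else !a$sites$is_h
  sel <- sel & !is.na(idx_b)
  if (!include_hydrogen && any(is.na(idx_b) & !a$sites$is_h))
    stop("compare_structures: mapping does not cover all non-hydrogen atoms")
  fa <- site_frac(a)[sel, , drop = FALSE]
  fb <- site_frac(b)[idx_b[sel], , drop = FALSE]
  dfrac <- fa - fb
  dfrac <- dfrac - round(dfrac)          # nearest periodic image
  m <- orthogonalization_matrix(a$cell)
  dcart <- dfrac %*% t(m)
  if (remove_rigid_shift)
    dcart <- sweep(dcart, 2, colMeans(dcart))
  disp <- sqrt(rowSums(dcart^2))
  names(disp) <- a$sites$label[sel]
  structure(list(rmscd = sqrt(mean(disp^2)),
                 per_atom = disp,
                 n_atoms_compared = length(disp),
                 rigid_shift_removed = remove_rigid_shift),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("RMSCD = %.5f A over %d atoms%s\n", x$rmscd, x$n_atoms_compared,
              if (x$rigid_shift_removed) " (rigid shift removed)" else ""))
  invisible(x)
}

#' Bond and 1-3 distance tables of a structure
#'
#' @param structure A \code{\link{crystal_structure}}.
#' @param graph Optional \code{bond_graph}; perceived when omitted.
#' @return List with \code{bonds} and \code{angles_13} data frames
#'   (labels and distances in Angstrom, deterministically sorted).
#' @export
geometry_tables <- function(structure, graph = NULL) {
  cart <- site_cart(structure)
  labels <- structure$sites$label
  if (is.null(graph)) graph <- perceive_bonds(structure$sites$element, cart)
  if (nrow(graph$nodes) != nrow(cart))
    stop("geometry_tables: graph does not match the structure")
  e <- graph$edges
  bonds <- data.frame(atom1 = labels[e$i], atom2 = labels[e$j],
                      d = sqrt(rowSums((cart[e$i, , drop = FALSE] -
                                        cart[e$j, , drop = FALSE])^2)),
                      stringsAsFactors = FALSE)
  bonds <- bonds[order(bonds$atom1, bonds$atom2), , drop = FALSE]
  ap <- angle_pairs(graph, exclude_h = FALSE)
  angles <- data.frame(atom1 = labels[ap$i], apex = labels[ap$apex],
                       atom2 = labels[ap$k],
                       d13 = sqrt(rowSums((cart[ap$i, , drop = FALSE] -
                                           cart[ap$k, , drop = FALSE])^2)),
                       stringsAsFactors = FALSE)
  angles <- angles[order(angles$atom1, angles$atom2, angles$apex), , drop = FALSE]
  rownames(bonds) <- rownames(angles) <- NULL
  list(bonds = bonds, angles_13 = angles)
}
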