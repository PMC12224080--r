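# Molecule-in-cluster generation: the asymmetric unit as free atoms inside
# a fixed shell of symmetry-generated whole-ASU copies. A copy enters the
# environment iff any of its atoms lies within the contact threshold of any
# free atom; complete ASU images are always included as a whole.

#' Build a molecule-in-cluster system
#'
#' Enumerates candidate ASU images over all space-group operations and a
#' guaranteed-sufficient range of lattice translations, and keeps every
#' image with at least one atom within \code{threshold} of a free (ASU)
#' atom. The identity image with zero lattice translation is the free part
#' itself and is excluded from the environment.
#'
#' @param structure A \code{\link{crystal_structure}}.
#' @param threshold Contact distance in Angstrom (default 3.75).
#' @param include_h Use hydrogen atoms in the minimum-distance rule?
#' @param overlap_tol Environment atoms closer than this to a free atom
#'   (special-position overlap) are dropped with a warning.
#' @return A \code{cluster}: list with \code{free} (data frame: label,
#'   element, is_h, Cartesian xyz), \code{env} (same plus \code{op},
#'   \code{shift} columns identifying the generator), and \code{threshold}.
#' @export
build_cluster <- function(structure, threshold = 3.75, include_h = TRUE,
                          overlap_tol = 0.2) {
  if (threshold < 0) stop("build_cluster: threshold must be non-negative")
  cell <- structure$cell
  m <- orthogonalization_matrix(cell)
  frac <- site_frac(structure)
  cart_free <- frac %*% t(m)
  sel_free <- if (include_h) rep(TRUE, nrow(frac)) else !structure$sites$is_h

  # translation search range per axis from perpendicular cell thicknesses
  diam <- max(0, max_pair_distance(cart_free))
  gstar <- reciprocal_metric_tensor(cell)
  thick <- 1 / sqrt(diag(gstar))          # perpendicular thickness per axis
  range_i <- ceiling((threshold + diam) / thick) + 1

  ops <- structure$spacegroup$operations
  env_rows <- list()
  for (k in seq_along(ops)) {
    op <- ops[[k]]
    base <- apply_symmetry(op, frac)
    for (n1 in -range_i[1]:range_i[1]) for (n2 in -range_i[2]:range_i[2])
      for (n3 in -range_i[3]:range_i[3]) {
        if (k == 1 && n1 == 0 && n2 == 0 && n3 == 0) next
        shifted <- sweep(base, 2, c(n1, n2, n3), `+`)
        cart <- shifted %*% t(m)
        sel_env <- if (include_h) rep(TRUE, nrow(cart)) else !structure$sites$is_h
        dmin <- min_cross_distance(cart_free[sel_free, , drop = FALSE],
                                   cart[sel_env, , drop = FALSE])
        if (dmin <= threshold) {
          env_rows[[length(env_rows) + 1]] <-
            list(op = k, shift = c(n1, n2, n3), cart = cart)
        }
      }
  }

  env <- NULL
  for (e in env_rows) {
    df <- data.frame(label = structure$sites$label,
                     element = structure$sites$element,
                     is_h = structure$sites$is_h,
                     x = e$cart[, 1], y = e$cart[, 2], z = e$cart[, 3],
                     op = e$op, s1 = e$shift[1], s2 = e$shift[2], s3 = e$shift[3],
                     stringsAsFactors = FALSE)
    # special-position overlap: drop duplicated atoms sitting on free atoms
    dmin_atom <- apply(as.matrix(df[, c("x", "y", "z")]), 1, function(p)
      min(sqrt(rowSums(sweep(cart_free, 2, p)^2))))
    if (any(dmin_atom < overlap_tol)) {
      warning(sprintf("build_cluster: dropping %d overlapping atom(s) from image (op %d, shift %d %d %d)",
                      sum(dmin_atom < overlap_tol), e$op,
                      e$shift[1], e$shift[2], e$shift[3]))
      df <- df[dmin_atom >= overlap_tol, , drop = FALSE]
    }
    env <- rbind(env, df)
  }

  free <- data.frame(label = structure$sites$label,
                     element = structure$sites$element,
                     is_h = structure$sites$is_h,
                     x = cart_free[, 1], y = cart_free[, 2], z = cart_free[, 3],
                     stringsAsFactors = FALSE)
  structure(list(free = free, env = env, threshold = threshold,
                 n_images = length(env_rows)),
            class = "cluster")
}

#' @export
print.cluster <- function(x, ...) {
  cat(sprintf("cluster: %d free atoms + %d environment atoms in %d ASU images (threshold %.2f A)\n",
              nrow(x$free), if (is.null(x$env)) 0 else nrow(x$env),
              x$n_images, x$threshold))
  invisible(x)
}

max_pair_distance <- function(cart) {
  if (nrow(cart) < 2) return(0)
  max(stats::dist(cart))
}

min_cross_distance <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(Inf)
  # min over pairs without forming the full n x m matrix for large b
  mins <- apply(b, 1, function(p) min(rowSums(sweep(a, 2, p)^2)))
  sqrt(min(mins))
}

#' Export a cluster as XYZ with a free-atom index list
#'
#' Free atoms come first, then environment atoms; the accompanying index
#' vector (1-based positions of the free atoms) is the fixed-atom contract
#' for an external optimizer.
#'
#' @param cluster A \code{cluster}.
#' @return List with \code{xyz} (character lines) and \code{free_indices}.
#' @export
export_cluster_xyz <- function(cluster) {
  all_el <- c(cluster$free$element,
              if (!is.null(cluster$env)) cluster$env$element)
  all_xyz <- rbind(as.matrix(cluster$free[, c("x", "y", "z")]),
                   if (!is.null(cluster$env)) as.matrix(cluster$env[, c("x", "y", "z")]))
  list(xyz = write_xyz(all_el, all_xyz,
                       comment = sprintf("cluster: %d free atoms, threshold %.2f A",
                                         nrow(cluster$free), cluster$threshold)),
       free_indices = seq_len(nrow(cluster$free)))
}

#' Brute-force cluster enumeration over a supercell (oracle)
#'
#' Reference implementation used to validate \code{\link{build_cluster}}:
#' enumerates every ASU image in a (2r+1)^3 supercell and applies the same
#' inclusion rule directly.
#'
#' @param structure A \code{\link{crystal_structure}}.
#' @param threshold Contact distance in Angstrom.
#' @param r Supercell half-width in unit cells.
#' @param include_h Use hydrogens in the distance rule?
#' @return Data frame of included images (op, s1, s2, s3), sorted.
#' @export
cluster_images_bruteforce <- function(structure, threshold, r = 3,
                                      include_h = TRUE) {
  m <- orthogonalization_matrix(structure$cell)
  frac <- site_frac(structure)
  cart_free <- frac %*% t(m)
  sel <- if (include_h) rep(TRUE, nrow(frac)) else !structure$sites$is_h
  ops <- structure$spacegroup$operations
  rows <- list()
  for (k in seq_along(ops)) {
    base <- apply_symmetry(ops[[k]], frac)
    for (n1 in -r:r) for (n2 in -r:r) for (n3 in -r:r) {
      if (k == 1 && n1 == 0 && n2 == 0 && n3 == 0) next
      cart <- sweep(base, 2, c(n1, n2, n3), `+`) %*% t(m)
      if (min_cross_distance(cart_free[sel, , drop = FALSE],
                             cart[sel, , drop = FALSE]) <= threshold)
        rows[[length(rows) + 1]] <- c(k, n1, n2, n3)
    }
  }
  if (length(rows) == 0)
    return(data.frame(op = integer(0), s1 = integer(0),
                      s2 = integer(0), s3 = integer(0)))
  mm <- do.call(rbind, rows)
  df <- data.frame(op = mm[, 1], s1 = mm[, 2], s2 = mm[, 3], s3 = mm[, 4])
  df[order(df$op, df$s1, df$s2, df$s3), , drop = FALSE]
}

#' Image list of a built cluster in oracle-comparable form
#' @param cluster A \code{cluster}.
#' @export
cluster_images <- function(cluster) {
  if (is.null(cluster$env))
    return(data.frame(op = integer(0), s1 = integer(0),
                      s2 = integer(0), s3 = integer(0)))
  df <- unique(cluster$env[, c("op", "s1", "s2", "s3")])
  df <- df[order(df$op, df$s1, df$s2, df$s3), , drop = FALSE]
  rownames(df) <- NULL
  df
}
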