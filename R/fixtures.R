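# Deterministic toy crystal structures, rigid-body ADPs and simulated
# Bragg intensities: every pipeline stage is testable with no external
# data. Emulates the regime of very low temperature organic structures
# (small ADPs, d_min around 0.5-1 Angstrom), not real chemistry.

#' Default rigid-body motion for fixture ADPs
#'
#' Translation 0.01 Angstrom^2, libration 0.0012 rad^2 (about 2 degrees
#' RMS) with a small anisotropy and screw component: the magnitude regime
#' of organic molecules near 20 K.
#' @param origin Cartesian origin.
#' @export
default_fixture_tls <- function(origin = c(0, 0, 0)) {
  T <- diag(c(0.010, 0.012, 0.009))
  T[1, 2] <- T[2, 1] <- 0.001
  L <- diag(c(0.0012, 0.0009, 0.0015))
  L[1, 3] <- L[3, 1] <- 0.0002
  S <- matrix(c(0.0002, 0.0001, 0,
                0, -0.0001, 0.0002,
                0.0001, 0, -0.0001), 3, 3, byrow = TRUE)
  tls_model(T, L, S, origin)
}

#' Generate a deterministic toy crystal structure
#'
#' Builds a connected molecule with bond lengths sampled in 1.2-1.6
#' Angstrom and no intramolecular nonbonded contact below 2.0 Angstrom,
#' places it at a general position of the requested space group in a cell
#' large enough to avoid intermolecular clashes, and assigns anisotropic
#' ADPs from a rigid-body TLS model. The same seed always returns the same
#' structure.
#'
#' @param seed Integer seed fixing all randomness.
#' @param spacegroup Symbol accepted by \code{\link{lookup_space_group}} or
#'   a \code{space_group} object.
#' @param n_heavy Number of non-hydrogen atoms.
#' @param n_h Number of hydrogen atoms to attach (at ~1.0 Angstrom).
#' @param elements Palette of heavy-atom element symbols.
#' @param cell_margin Extra cell length beyond the molecular extent
#'   (Angstrom), controls intermolecular spacing.
#' @param tls TLS model for ADP generation (origin is overridden by the
#'   molecular centroid); \code{NULL} for isotropic ADPs only.
#' @param max_tries Packing retries before giving up.
#' @return A \code{\link{crystal_structure}}.
#' @export
make_toy_structure <- function(seed, spacegroup = "P21/c", n_heavy = 6,
                               n_h = 0, elements = c("C", "N", "O"),
                               cell_margin = 3.5, tls = default_fixture_tls(),
                               max_tries = 200) {
  sg <- if (inherits(spacegroup, "space_group")) spacegroup
        else lookup_space_group(spacegroup)
  set.seed(seed)
  for (attempt in seq_len(max_tries)) {
    mol <- grow_molecule(n_heavy, elements)
    if (is.null(mol)) next
    if (n_h > 0) mol <- attach_hydrogens(mol, n_h)
    if (is.null(mol)) next
    st <- place_in_cell(mol, sg, cell_margin)
    if (!is.null(st)) {
      if (!is.null(tls)) st <- assign_rigid_body_adps(st, tls)
      return(st)
    }
  }
  stop("make_toy_structure: packing failed; try a larger cell_margin or fewer atoms")
}

grow_molecule <- function(n_heavy, elements) {
  cart <- matrix(0, n_heavy, 3)
  parent <- integer(n_heavy)
  for (i in 2:n_heavy) {
    placed <- FALSE
    for (try in 1:50) {
      p <- sample.int(i - 1, 1)
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      pos <- cart[p, ] + stats::runif(1, 1.2, 1.6) * dir
      d <- sqrt(rowSums(sweep(cart[seq_len(i - 1), , drop = FALSE], 2, pos)^2))
      ok <- d[p] >= 1.2 && all(d[-p] >= 2.0)
      if (ok) { cart[i, ] <- pos; parent[i] <- p; placed <- TRUE; break }
    }
    if (!placed) return(NULL)
  }
  el <- sample(elements, n_heavy, replace = TRUE)
  list(element = el, cart = cart, is_h = rep(FALSE, n_heavy))
}

attach_hydrogens <- function(mol, n_h) {
  for (k in seq_len(n_h)) {
    placed <- FALSE
    for (try in 1:50) {
      p <- sample(which(!mol$is_h), 1)
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      pos <- mol$cart[p, ] + 1.0 * dir
      d <- sqrt(rowSums(sweep(mol$cart, 2, pos)^2))
      if (all(d[-p] >= 1.5) && d[p] >= 0.95) {
        mol$cart <- rbind(mol$cart, pos)
        mol$element <- c(mol$element, "H")
        mol$is_h <- c(mol$is_h, TRUE)
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  mol
}

place_in_cell <- function(mol, sg, cell_margin) {
  # random orientation
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  rot <- quaternion_rotation(q)
  cart <- mol$cart %*% t(rot)
  extent <- apply(cart, 2, function(v) diff(range(v)))
  n_ops <- length(sg$operations)
  # scale the cell with symmetry content so images do not collide
  lengths <- extent + cell_margin * (1 + 0.25 * (n_ops - 1))
  angles <- c(90, 90, 90)
  mono <- any(vapply(sg$operations, function(o)
    !identical(o$rotation, diag(3L)) && o$rotation[2, 2] == 1L, logical(1)))
  tric <- n_ops <= 2 && !mono
  if (mono) angles[2] <- stats::runif(1, 95, 110)
  if (tric) angles <- stats::runif(3, 85, 95)
  cell <- unit_cell(lengths[1], lengths[2], lengths[3],
                    angles[1], angles[2], angles[3])
  m <- orthogonalization_matrix(cell)
  # centroid at a general position away from symmetry elements
  target <- c(0.23, 0.31, 0.17) + stats::runif(3, -0.03, 0.03)
  shift <- as.numeric(m %*% target) - colMeans(cart)
  cart <- sweep(cart, 2, shift, `+`)
  frac <- cart %*% t(solve(m))
  heavy_n <- sum(!mol$is_h)
  labels <- character(length(mol$element))
  counts <- list()
  for (i in seq_along(mol$element)) {
    e <- mol$element[i]
    counts[[e]] <- (counts[[e]] %||% 0L) + 1L
    labels[i] <- sprintf("%s%d", e, counts[[e]])
  }
  st <- crystal_structure(cell, sg,
                          atom_sites(labels, mol$element, frac, occ = 1, uiso = 0.01))
  # verify no intermolecular contact below 2.0 A among symmetry images
  imgs <- cluster_images_bruteforce(st, threshold = 2.0, r = 1)
  if (nrow(imgs) > 0) return(NULL)
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

quaternion_rotation <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Assign anisotropic ADPs from a rigid-body TLS model
#'
#' The TLS origin is moved to the molecular centroid; Cartesian rigid-body
#' Uij are generated and converted to the CIF convention. Uiso is set to
#' the equivalent isotropic value.
#'
#' @param structure A \code{\link{crystal_structure}}.
#' @param tls A \code{\link{tls_model}}.
#' @export
assign_rigid_body_adps <- function(structure, tls, h_u_multiplier = 2.4) {
  cart <- site_cart(structure)
  tls2 <- tls_model(tls$T, tls$L, tls$S, colMeans(cart))
  u6 <- rigid_body_adps(cart, tls2)
  for (i in seq_len(nrow(cart))) {
    u_cif <- cart_to_u_cif(structure$cell, u6_to_mat(u6[i, ]))
    structure$sites[i, c("u11", "u22", "u33", "u23", "u13", "u12")] <-
      c(u_cif[1, 1], u_cif[2, 2], u_cif[3, 3],
        u_cif[2, 3], u_cif[1, 3], u_cif[1, 2])
    structure$sites$uiso[i] <- sum(diag(u6_to_mat(u6[i, ]))) / 3
  }
  # hydrogens follow the riding convention: isotropic U tied to the parent
  if (any(structure$sites$is_h)) {
    graph <- perceive_bonds(structure$sites$element, cart)
    parents <- h_parents(graph)
    for (i in which(structure$sites$is_h)) {
      p <- if (length(parents[[i]]) > 0) parents[[i]][1] else i
      structure$sites$uiso[i] <- h_u_multiplier * structure$sites$uiso[p]
      structure$sites[i, c("u11", "u22", "u33", "u23", "u13", "u12")] <- NA_real_
    }
  }
  structure
}

#' Enumerate symmetry-unique reflections to a resolution limit
#'
#' @param structure A \code{\link{crystal_structure}} (cell and symmetry).
#' @param d_min Resolution limit in Angstrom.
#' @return n x 3 integer matrix of Laue-unique Miller indices with
#'   d >= d_min.
#' @export
unique_hkl <- function(structure, d_min) {
  if (d_min <= 0) stop("unique_hkl: d_min must be positive")
  cell <- structure$cell
  hmax <- ceiling(c(cell$a, cell$b, cell$c) / d_min)
  grid <- as.matrix(expand.grid(h = -hmax[1]:hmax[1],
                                k = -hmax[2]:hmax[2],
                                l = -hmax[3]:hmax[3]))
  grid <- grid[rowSums(grid != 0) > 0, , drop = FALSE]
  d <- d_spacing(cell, grid)
  grid <- grid[d >= d_min, , drop = FALSE]
  # Laue-unique representative: lexicographic maximum over +/- R^T h
  rots <- lapply(structure$spacegroup$operations, function(o) o$rotation)
  keys <- apply(grid, 1, function(h) {
    cands <- NULL
    for (r in rots) {
      hp <- as.integer(h %*% r)
      cands <- rbind(cands, hp, -hp)
    }
    best <- cands[order(-cands[, 1], -cands[, 2], -cands[, 3])[1], ]
    paste(best, collapse = ",")
  })
  uniq <- t(vapply(strsplit(unique(keys), ","), as.integer, integer(3)))
  storage.mode(uniq) <- "integer"
  uniq
}

#' Simulate a reflection set from a structure
#'
#' Fo^2 = |F_calc|^2 (1 + eps) with eps ~ Normal(0, noise_fraction), and
#' sigma = noise_fraction * |F_calc|^2 + floor. Indices are the Laue-unique
#' set with d >= d_min.
#'
#' @param structure A \code{\link{crystal_structure}}.
#' @param d_min Resolution limit (Angstrom).
#' @param noise_fraction Relative Gaussian noise on intensities (0 for
#'   noiseless data).
#' @param seed Integer seed.
#' @param sigma_floor_frac Sigma floor as a fraction of the median
#'   intensity.
#' @return A \code{\link{reflection_set}}.
#' @export
simulate_reflections <- function(structure, d_min = 0.8, noise_fraction = 0,
                                 seed = 1, sigma_floor_frac = 1e-4) {
  hkl <- unique_hkl(structure, d_min)
  fc <- Mod(calc_structure_factors(structure, hkl))^2
  set.seed(seed)
  eps <- if (noise_fraction > 0) stats::rnorm(length(fc), 0, noise_fraction) else 0
  fo <- fc * (1 + eps)
  floor_val <- sigma_floor_frac * stats::median(fc[fc > 0])
  sigma <- noise_fraction * fc + floor_val
  reflection_set(hkl, fo, sigma)
}

#' Perturb a structure by Gaussian Cartesian displacements
#'
#' Non-hydrogen atoms receive isotropic Gaussian displacements with
#' standard deviation \code{amplitude} per Cartesian axis; hydrogens ride
#' on their bonded parent atoms (identical shift).
#'
#' @param structure A \code{\link{crystal_structure}}.
#' @param amplitude Per-axis displacement standard deviation (Angstrom).
#' @param seed Integer seed.
#' @export
perturb_structure <- function(structure, amplitude, seed = 1) {
  if (amplitude < 0) stop("perturb_structure: amplitude must be non-negative")
  if (amplitude == 0) return(structure)
  set.seed(seed)
  n <- nrow(structure$sites)
  shift <- matrix(stats::rnorm(3 * n, 0, amplitude), n, 3)
  if (any(structure$sites$is_h)) {
    graph <- perceive_bonds(structure$sites$element, site_cart(structure))
    parents <- h_parents(graph)
    for (i in which(structure$sites$is_h)) {
      if (length(parents[[i]]) > 0) shift[i, ] <- shift[parents[[i]][1], ]
    }
  }
  minv <- solve(orthogonalization_matrix(structure$cell))
  frac_shift <- shift %*% t(minv)
  structure$sites[, c("x", "y", "z")] <-
    site_frac(structure) + frac_shift
  structure
}

#' The shipped toy-set profile
#'
#' Five deterministic fixtures spanning P1, P-1, P21, P21/c and a
#' two-molecule asymmetric unit, mirroring the diversity of a small
#' organic test set.
#'
#' @param seed Base seed.
#' @return Named list of \code{crystal_structure} objects.
#' @export
toy_fixture_set <- function(seed = 42) {
  two_mol <- make_toy_structure(seed + 4, "P-1", n_heavy = 4, cell_margin = 7)
  # append a second, shifted copy of the molecule as an independent unit
  s2 <- two_mol$sites
  s2$label <- paste0(s2$label, "B")
  s2[, c("x", "y", "z")] <- s2[, c("x", "y", "z")] + 0.45
  two_mol$sites <- rbind(two_mol$sites, s2)
  list(
    p1 = make_toy_structure(seed, "P1", n_heavy = 5),
    p1bar = make_toy_structure(seed + 1, "P-1", n_heavy = 5),
    p21 = make_toy_structure(seed + 2, "P21", n_heavy = 5),
    p21c = make_toy_structure(seed + 3, "P21/c", n_heavy = 5),
    two_molecule = two_mol
  )
}
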