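# Space-group symmetry operations with exact rational translations.
# Rotations act on fractional coordinates; translations are stored as
# integer numerator/denominator pairs so closure checks are exact.

#' Symmetry operation
#'
#' @param rotation Integer 3x3 matrix (entries in -1,0,1) acting on
#'   fractional coordinates.
#' @param tr_num,tr_den Integer 3-vectors: translation components
#'   \code{tr_num/tr_den}.
#' @return Object of class \code{symop}.
#' @export
symop <- function(rotation, tr_num = c(0L, 0L, 0L), tr_den = c(1L, 1L, 1L)) {
  rotation <- matrix(as.integer(round(rotation)), 3, 3)
  if (abs(det(rotation)) != 1L)
    stop("symop: rotation must have determinant +/-1")
  tr_num <- as.integer(tr_num); tr_den <- as.integer(tr_den)
  if (any(tr_den <= 0L)) stop("symop: translation denominators must be positive")
  g <- mapply(gcd_int, abs(tr_num), tr_den)
  g[g == 0L] <- 1L
  structure(list(rotation = rotation,
                 tr_num = as.integer(tr_num / g),
                 tr_den = as.integer(tr_den / g)),
            class = "symop")
}

gcd_int <- function(a, b) {
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

symop_translation <- function(op) op$tr_num / op$tr_den

#' @export
print.symop <- function(x, ...) {
  cat(format_symop(x), "\n")
  invisible(x)
}

symop_identity <- function() symop(diag(3))

#' Compose two symmetry operations (op1 then applied after op2)
#'
#' Returns the operation equivalent to applying \code{op2} first and
#' \code{op1} second. Translations are combined with exact rational
#' arithmetic and reduced modulo 1 when \code{mod1 = TRUE}.
#'
#' @param op1,op2 \code{symop} objects.
#' @param mod1 Reduce the resulting translation into [0, 1)?
#' @export
symop_compose <- function(op1, op2, mod1 = TRUE) {
  rot <- op1$rotation %*% op2$rotation
  den <- op1$tr_den
  num <- op1$tr_num
  # t = R1 t2 + t1, componentwise over rationals
  out_num <- integer(3); out_den <- integer(3)
  for (i in 1:3) {
    # sum_j R1[i,j] * t2[j] + t1[i]
    n <- num[i]; d <- den[i]
    for (j in 1:3) {
      r <- op1$rotation[i, j]
      if (r != 0L) {
        n2 <- r * op2$tr_num[j]; d2 <- op2$tr_den[j]
        n <- n * d2 + n2 * d
        d <- d * d2
        g <- gcd_int(abs(n), d); if (g > 1L) { n <- n %/% g; d <- d %/% g }
      }
    }
    if (mod1) n <- ((n %% d) + d) %% d
    out_num[i] <- n; out_den[i] <- d
  }
  symop(rot, out_num, out_den)
}

symop_equal <- function(a, b) {
  identical(a$rotation, b$rotation) &&
    all(a$tr_num == b$tr_num) && all(a$tr_den == b$tr_den)
}

#' Apply a symmetry operation to fractional coordinates
#'
#' Computes \code{rotation \%*\% frac + translation}. No wrapping into the
#' unit cell is performed; wrapping is a separate explicit step
#' (\code{\link{wrap_frac}}).
#'
#' @param op A \code{symop}.
#' @param frac 3-vector or n x 3 matrix of fractional coordinates.
#' @export
apply_symmetry <- function(op, frac) {
  f <- if (is.matrix(frac)) frac else matrix(frac, ncol = 3)
  out <- f %*% t(op$rotation) +
    matrix(symop_translation(op), nrow(f), 3, byrow = TRUE)
  if (is.matrix(frac)) out else drop(out)
}

#' Wrap fractional coordinates into [0, 1)
#' @param frac 3-vector or n x 3 matrix.
#' @export
wrap_frac <- function(frac) frac - floor(frac)

#' Space group
#'
#' A space group is a named, closed set of symmetry operations (modulo
#' lattice translations) containing the identity.
#'
#' @param name Hermann-Mauguin label (free text; taken from the input file).
#' @param operations List of \code{symop}, identity included.
#' @param check Verify identity membership and closure modulo 1.
#' @export
space_group <- function(name, operations, check = TRUE) {
  if (length(operations) < 1) stop("space_group: needs at least one operation")
  ops <- lapply(operations, function(o) {
    # normalize translations into [0,1)
    symop(o$rotation, ((o$tr_num %% o$tr_den) + o$tr_den) %% o$tr_den, o$tr_den)
  })
  if (check) {
    has_id <- any(vapply(ops, function(o) symop_equal(o, symop_identity()), logical(1)))
    if (!has_id) stop("space_group: identity operation missing")
    for (a in ops) for (b in ops) {
      ab <- symop_compose(a, b, mod1 = TRUE)
      if (!any(vapply(ops, symop_equal, logical(1), b = ab)))
        stop(sprintf("space_group '%s': not closed under composition (%s o %s)",
                     name, format_symop(a), format_symop(b)))
    }
  }
  structure(list(name = name, operations = ops), class = "space_group")
}

#' @export
print.space_group <- function(x, ...) {
  cat(sprintf("space group %s (%d operations)\n", x$name, length(x$operations)))
  for (op in x$operations) cat(" ", format_symop(op), "\n")
  invisible(x)
}

#' Look up a small built-in space group by symbol
#'
#' Covers the settings used by the synthetic fixtures: P1, P-1, P21
#' (unique axis b) and P21/c. Any other group must be supplied through its
#' operator list (e.g. from a CIF symmetry loop).
#'
#' @param name One of "P1", "P-1", "P21", "P21/c".
#' @export
lookup_space_group <- function(name) {
  key <- toupper(gsub("[ ()]", "", name))
  xyz <- switch(key,
    "P1"    = c("x,y,z"),
    "P-1"   = c("x,y,z", "-x,-y,-z"),
    "P21"   = c("x,y,z", "-x,y+1/2,-z"),
    "P21/C" = c("x,y,z", "-x,y+1/2,-z+1/2", "-x,-y,-z", "x,-y+1/2,z+1/2"),
    stop(sprintf("lookup_space_group: unknown symbol '%s' (supply operators explicitly)", name))
  )
  space_group(name, lapply(xyz, parse_symop_xyz))
}
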