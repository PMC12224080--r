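# Parsing and formatting of "x, y+1/2, -z" symmetry operator strings.

#' Parse a symmetry operator in xyz notation
#'
#' Accepts the CIF/SHELX triplet notation, e.g. \code{"-x, y+1/2, -z+1/2"}.
#' Rational offsets are kept exact (numerator/denominator); decimal offsets
#' such as 0.5 are converted to the nearest small rational.
#'
#' @param text Operator string: three comma-separated components in x, y, z.
#' @return A \code{\link{symop}}.
#' @examples
#' parse_symop_xyz("-x, y+1/2, -z+1/2")
#' @export
parse_symop_xyz <- function(text) {
  parts <- strsplit(text, ",", fixed = TRUE)[[1]]
  if (length(parts) != 3)
    stop(sprintf("parse_symop_xyz: expected 3 comma-separated components in '%s'", text))
  rot <- matrix(0L, 3, 3)
  num <- integer(3); den <- rep(1L, 3)
  for (i in 1:3) {
    comp <- tolower(gsub("[[:space:]]", "", parts[i]))
    if (!nzchar(comp))
      stop(sprintf("parse_symop_xyz: empty component %d in '%s'", i, text))
    # split into signed terms
    terms <- regmatches(comp, gregexpr("[+-]?[^+-]+", comp))[[1]]
    for (term in terms) {
      sign <- if (startsWith(term, "-")) -1L else 1L
      body <- sub("^[+-]", "", term)
      if (body %in% c("x", "y", "z")) {
        j <- match(body, c("x", "y", "z"))
        rot[i, j] <- rot[i, j] + sign
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        pq <- as.integer(strsplit(body, "/", fixed = TRUE)[[1]])
        r <- add_rational(num[i], den[i], sign * pq[1], pq[2])
        num[i] <- r[1]; den[i] <- r[2]
      } else if (grepl("^[0-9]*\\.?[0-9]+$", body)) {
        pq <- decimal_to_rational(as.numeric(body))
        r <- add_rational(num[i], den[i], sign * pq[1], pq[2])
        num[i] <- r[1]; den[i] <- r[2]
      } else {
        stop(sprintf("parse_symop_xyz: cannot parse term '%s' in '%s'", term, text))
      }
    }
  }
  symop(rot, num, den)
}

add_rational <- function(n1, d1, n2, d2) {
  n <- n1 * d2 + n2 * d1
  d <- d1 * d2
  g <- gcd_int(abs(n), d)
  if (g > 1L) c(n %/% g, d %/% g) else c(n, d)
}

decimal_to_rational <- function(x, max_den = 24L) {
  for (d in 1:max_den) {
    n <- round(x * d)
    if (abs(x - n / d) < 1e-9) return(c(as.integer(n), as.integer(d)))
  }
  stop(sprintf("decimal_to_rational: %g is not a small crystallographic fraction", x))
}

#' Format a symmetry operation in xyz notation
#'
#' Inverse of \code{\link{parse_symop_xyz}}: \code{parse_symop_xyz(format_symop(op))}
#' reproduces \code{op} exactly.
#'
#' @param op A \code{symop}.
#' @export
format_symop <- function(op) {
  axes <- c("x", "y", "z")
  comps <- character(3)
  for (i in 1:3) {
    s <- ""
    for (j in 1:3) {
      r <- op$rotation[i, j]
      if (r != 0L) {
        sgn <- if (r < 0L) "-" else if (nzchar(s)) "+" else ""
        s <- paste0(s, sgn, axes[j])
      }
    }
    n <- op$tr_num[i]; d <- op$tr_den[i]
    if (n != 0L) {
      sgn <- if (n < 0L) "-" else if (nzchar(s)) "+" else ""
      frac <- if (d == 1L) sprintf("%d", abs(n)) else sprintf("%d/%d", abs(n), d)
      s <- paste0(s, sgn, frac)
    }
    if (!nzchar(s)) s <- "0"
    comps[i] <- s
  }
  paste(comps, collapse = ", ")
}
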