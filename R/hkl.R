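# SHELX HKLF-4 reflection files: 3I4 Miller indices, two F8.2 fields with
# Fo^2 and sigma(Fo^2), terminated by the 0 0 0 record.

#' Reflection set
#'
#' @param hkl n x 3 integer matrix of Miller indices.
#' @param f_sq Observed intensities Fo^2 (arbitrary scale).
#' @param sigma Standard uncertainties sigma(Fo^2), all > 0.
#' @param wavelength Optional wavelength in Angstrom.
#' @export
reflection_set <- function(hkl, f_sq, sigma, wavelength = NA_real_) {
  hkl <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3)
  storage.mode(hkl) <- "integer"
  stopifnot(nrow(hkl) == length(f_sq), length(f_sq) == length(sigma))
  if (nrow(hkl) == 0) stop("reflection_set: empty reflection list")
  if (any(rowSums(hkl != 0) == 0)) stop("reflection_set: (0,0,0) is not a reflection")
  if (any(sigma <= 0)) stop("reflection_set: all sigmas must be positive")
  structure(list(hkl = hkl, f_sq = as.numeric(f_sq), sigma = as.numeric(sigma),
                 wavelength = wavelength),
            class = "reflection_set")
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("reflection set: %d reflections, <Fo^2>=%.3g\n",
              nrow(x$hkl), mean(x$f_sq)))
  invisible(x)
}

#' Read a SHELX HKLF-4 reflection file
#'
#' Fixed-format lines (3I4, 2F8); parsing stops at the 0 0 0 terminator.
#' Non-positive sigmas are replaced by \code{sigma_floor_frac} times the
#' median positive sigma, with a warning.
#'
#' @param text File path, single string, or character vector of lines.
#' @param sigma_floor_frac Replacement floor for non-positive sigmas, as a
#'   fraction of the median positive sigma.
#' @return A \code{\link{reflection_set}}.
#' @export
read_shelx_hkl <- function(text, sigma_floor_frac = 0.01) {
  lines <- as_lines(text)
  hkl <- matrix(0L, 0, 3); fo <- numeric(0); sig <- numeric(0)
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) next
    if (nchar(line) < 28) {
      # tolerate trailing short junk only after the terminator
      stop(sprintf("read_shelx_hkl: line %d too short for HKLF-4 (need 28 chars): '%s'",
                   ln, line))
    }
    h <- suppressWarnings(as.integer(substr(line, 1, 4)))
    k <- suppressWarnings(as.integer(substr(line, 5, 8)))
    l <- suppressWarnings(as.integer(substr(line, 9, 12)))
    if (anyNA(c(h, k, l)))
      stop(sprintf("read_shelx_hkl: unparsable indices on line %d: '%s'", ln, line))
    if (h == 0L && k == 0L && l == 0L) break
    f <- as.numeric(substr(line, 13, 20))
    s <- as.numeric(substr(line, 21, 28))
    hkl <- rbind(hkl, c(h, k, l)); fo <- c(fo, f); sig <- c(sig, s)
  }
  if (nrow(hkl) == 0) stop("read_shelx_hkl: no reflections before terminator")
  bad <- sig <= 0
  if (any(bad)) {
    floor_val <- sigma_floor_frac * stats::median(sig[!bad])
    warning(sprintf("read_shelx_hkl: %d non-positive sigma(s) replaced by floor %.4g",
                    sum(bad), floor_val))
    sig[bad] <- floor_val
  }
  reflection_set(hkl, fo, sig)
}

#' Write a reflection set in SHELX HKLF-4 format
#' @param refl A \code{\link{reflection_set}}.
#' @return Character vector of lines including the 0 0 0 terminator.
#' @export
write_shelx_hkl <- function(refl) {
  stopifnot(inherits(refl, "reflection_set"))
  c(sprintf("%4d%4d%4d%8.2f%8.2f",
            refl$hkl[, 1], refl$hkl[, 2], refl$hkl[, 3], refl$f_sq, refl$sigma),
    sprintf("%4d%4d%4d%8.2f%8.2f", 0L, 0L, 0L, 0, 0))
}
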