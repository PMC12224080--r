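# Minimal XYZ reader/writer (cluster export and optimizer output import).

#' Write Cartesian coordinates as XYZ text
#' @param element Chemical symbols.
#' @param cart n x 3 Cartesian coordinates (Angstrom).
#' @param comment Second-line comment.
#' @return Character vector of lines.
#' @export
write_xyz <- function(element, cart, comment = "") {
  cart <- if (is.matrix(cart)) cart else matrix(cart, ncol = 3)
  stopifnot(length(element) == nrow(cart))
  c(sprintf("%d", nrow(cart)), comment,
    sprintf("%-2s %14.6f %14.6f %14.6f", element, cart[, 1], cart[, 2], cart[, 3]))
}

#' Read an XYZ file
#' @param text File path, single string, or character vector of lines.
#' @return List with \code{element} and \code{cart} (n x 3 matrix).
#' @export
read_xyz <- function(text) {
  lines <- as_lines(text)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || n < 1) stop("read_xyz: first line must be the atom count")
  if (length(lines) < n + 2) stop("read_xyz: fewer coordinate lines than declared")
  rows <- strsplit(trimws(lines[3:(n + 2)]), "[[:space:]]+")
  element <- vapply(rows, `[`, character(1), 1)
  cart <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  if (any(!is.finite(cart))) stop("read_xyz: non-numeric coordinates")
  list(element = element, cart = cart)
}
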