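# SHELXL-dialect auxiliary restraint file ("+filename.rests"): free-format
# DFIX (1-2 bonds) and DANG (1-3 angle-as-distance) instruction lines.

#' Write a restraint set as a SHELXL-dialect restraint file
#'
#' One instruction per line: \code{DFIX target su atom1 atom2} for bond
#' restraints, \code{DANG target su atom1 atom2} for 1-3 distances. Targets
#' are printed to 4 decimals.
#'
#' @param restraints A \code{\link{restraint_set}}.
#' @param structure Optional companion \code{crystal_structure}; when given,
#'   every restraint label must resolve in it.
#' @return Character vector of lines.
#' @export
write_restraint_file <- function(restraints, structure = NULL) {
  stopifnot(inherits(restraints, "restraint_set"))
  r <- restraints$restraints
  header <- sprintf("REM structure-specific restraints (%s), %d entries",
                    restraints$source_tag, nrow(r))
  if (nrow(r) == 0) return(header)
  if (!is.null(structure)) {
    labs <- unique(c(r$atom1, r$atom2))
    miss <- labs[!toupper(labs) %in% toupper(structure$sites$label)]
    if (length(miss) > 0)
      stop(sprintf("write_restraint_file: label(s) not in structure: %s",
                   paste(miss, collapse = ", ")))
  }
  instr <- ifelse(r$kind == "bond_12", "DFIX", "DANG")
  su_txt <- vapply(r$su, function(s) format(s, trim = TRUE, scientific = FALSE),
                   character(1))
  c(header, sprintf("%s %.4f %s %s %s", instr, r$target, su_txt,
                    r$atom1, r$atom2))
}

#' Read a restraint file (DFIX/DANG lines)
#' @param text File path, single string, or character vector of lines.
#' @param source_tag Provenance string attached to the result.
#' @return A \code{\link{restraint_set}}.
#' @export
read_restraint_file <- function(text, source_tag = "file") {
  lines <- as_lines(text)
  rows <- list()
  for (line in lines) {
    toks <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    if (length(toks) < 5) next
    kw <- toupper(toks[1])
    if (!kw %in% c("DFIX", "DANG")) next
    rows[[length(rows) + 1]] <- data.frame(
      kind = if (kw == "DFIX") "bond_12" else "angle_13",
      atom1 = toks[4], atom2 = toks[5],
      target = as.numeric(toks[2]), su = as.numeric(toks[3]),
      stringsAsFactors = FALSE)
  }
  restraint_set(do.call(rbind, rows), source_tag = source_tag)
}
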