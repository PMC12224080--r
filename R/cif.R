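# Reader/writer for the CIF core-dictionary subset used by small-molecule
# depositions: cell, symmetry operator loop, atom_site loop, aniso loop.

strip_su <- function(x) as.numeric(sub("\\(.*\\)$", "", x))

cif_tokens <- function(line) {
  # whitespace-split respecting single/double quoted strings
  out <- character(0)
  rest <- line
  repeat {
    rest <- sub("^[[:space:]]+", "", rest)
    if (!nzchar(rest) || startsWith(rest, "#")) break
    ch <- substr(rest, 1, 1)
    if (ch %in% c("'", '"')) {
      end <- regexpr(paste0(ch, "([[:space:]]|$)"), substring(rest, 2))
      if (end < 0) { out <- c(out, substring(rest, 2)); break }
      out <- c(out, substr(rest, 2, end))
      rest <- substring(rest, end + 2)
    } else {
      m <- regexpr("^[^[:space:]]+", rest)
      out <- c(out, regmatches(rest, m))
      rest <- substring(rest, attr(m, "match.length") + 1)
    }
  }
  out
}

parse_cif_blocks <- function(lines) {
  # returns list(items = named scalar values, loops = list of data frames)
  items <- list(); loops <- list()
  i <- 1; n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#") || startsWith(line, "data_")) {
      i <- i + 1; next
    }
    if (tolower(line) == "loop_") {
      i <- i + 1
      tags <- character(0)
      while (i <= n && grepl("^_", trimws(lines[i]))) {
        tags <- c(tags, tolower(trimws(lines[i]))); i <- i + 1
      }
      rows <- list(); buf <- character(0)
      while (i <= n) {
        l <- trimws(lines[i])
        if (!nzchar(l) || grepl("^(_|loop_|data_|#)", l, ignore.case = TRUE)) break
        buf <- c(buf, cif_tokens(lines[i]))
        while (length(buf) >= length(tags)) {
          rows[[length(rows) + 1]] <- buf[seq_along(tags)]
          buf <- buf[-seq_along(tags)]
        }
        i <- i + 1
      }
      if (length(rows) > 0) {
        df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
        names(df) <- tags
        loops[[length(loops) + 1]] <- df
      }
    } else if (startsWith(line, "_")) {
      toks <- cif_tokens(line)
      if (length(toks) >= 2) {
        items[[tolower(toks[1])]] <- paste(toks[-1], collapse = " ")
      } else if (i < n) {
        # value on the following line (possibly a ; text field, not needed here)
        items[[tolower(toks[1])]] <- trimws(lines[i + 1])
        i <- i + 1
      }
      i <- i + 1
    } else {
      i <- i + 1
    }
  }
  list(items = items, loops = loops)
}

find_loop <- function(loops, tag) {
  for (df in loops) if (tag %in% names(df)) return(df)
  NULL
}

#' Read a crystal structure from CIF text
#'
#' Parses the core-dictionary subset: cell parameters, the symmetry operator
#' loop (either \code{_space_group_symop_operation_xyz} or the legacy
#' \code{_symmetry_equiv_pos_as_xyz}), the atom_site loop (fractional
#' coordinates, occupancy, Uiso or Biso) and the optional aniso loop
#' (\code{_atom_site_aniso_U_*} or \code{_atom_site_aniso_B_*}).
#'
#' @param text CIF content as a single string, character vector of lines, or
#'   a file path.
#' @return A \code{\link{crystal_structure}}.
#' @export
read_cif <- function(text) {
  lines <- as_lines(text)
  p <- parse_cif_blocks(lines)
  need <- c("_cell_length_a", "_cell_length_b", "_cell_length_c",
            "_cell_angle_alpha", "_cell_angle_beta", "_cell_angle_gamma")
  miss <- need[!need %in% names(p$items)]
  if (length(miss) > 0)
    stop(sprintf("read_cif: missing cell item(s): %s", paste(miss, collapse = ", ")))
  cell <- unit_cell(strip_su(p$items[["_cell_length_a"]]),
                    strip_su(p$items[["_cell_length_b"]]),
                    strip_su(p$items[["_cell_length_c"]]),
                    strip_su(p$items[["_cell_angle_alpha"]]),
                    strip_su(p$items[["_cell_angle_beta"]]),
                    strip_su(p$items[["_cell_angle_gamma"]]))

  symloop <- find_loop(p$loops, "_space_group_symop_operation_xyz")
  symtag <- "_space_group_symop_operation_xyz"
  if (is.null(symloop)) {
    symloop <- find_loop(p$loops, "_symmetry_equiv_pos_as_xyz")
    symtag <- "_symmetry_equiv_pos_as_xyz"
  }
  if (is.null(symloop)) {
    ops <- list(symop_identity())
    sgname <- "P1"
  } else {
    ops <- lapply(symloop[[symtag]], parse_symop_xyz)
    sgname <- p$items[["_space_group_name_h-m_alt"]]
    if (is.null(sgname)) sgname <- p$items[["_symmetry_space_group_name_h-m"]]
    if (is.null(sgname)) sgname <- sprintf("(%d ops)", length(ops))
  }
  sg <- space_group(sgname, ops)

  at <- find_loop(p$loops, "_atom_site_fract_x")
  if (is.null(at))
    stop("read_cif: missing atom_site loop (_atom_site_fract_x)")
  label <- at[["_atom_site_label"]]
  if (is.null(label)) stop("read_cif: atom_site loop lacks _atom_site_label")
  element <- at[["_atom_site_type_symbol"]]
  if (is.null(element)) element <- gsub("[0-9'\"*]+$", "", label)
  frac <- cbind(strip_su(at[["_atom_site_fract_x"]]),
                strip_su(at[["_atom_site_fract_y"]]),
                strip_su(at[["_atom_site_fract_z"]]))
  occ <- if (!is.null(at[["_atom_site_occupancy"]]))
    strip_su(at[["_atom_site_occupancy"]]) else rep(1, nrow(at))
  occ[is.na(occ)] <- 1
  uiso <- rep(0, nrow(at))
  if (!is.null(at[["_atom_site_u_iso_or_equiv"]])) {
    uiso <- strip_su(at[["_atom_site_u_iso_or_equiv"]])
  } else if (!is.null(at[["_atom_site_b_iso_or_equiv"]])) {
    uiso <- strip_su(at[["_atom_site_b_iso_or_equiv"]]) / (8 * pi^2)
  }
  uiso[is.na(uiso)] <- 0
  sites <- atom_sites(label, element, frac, occ = occ, uiso = uiso)

  an <- find_loop(p$loops, "_atom_site_aniso_label")
  if (!is.null(an)) {
    utags <- paste0("_atom_site_aniso_u_", c("11", "22", "33", "23", "13", "12"))
    btags <- paste0("_atom_site_aniso_b_", c("11", "22", "33", "23", "13", "12"))
    scale <- 1
    if (!all(utags %in% names(an))) {
      if (all(btags %in% names(an))) { utags <- btags; scale <- 1 / (8 * pi^2) }
      else stop("read_cif: aniso loop lacks the six Uij (or Bij) items")
    }
    idx <- match(toupper(an[["_atom_site_aniso_label"]]), toupper(sites$label))
    if (anyNA(idx))
      stop(sprintf("read_cif: aniso label(s) with no matching atom site: %s",
                   paste(an[["_atom_site_aniso_label"]][is.na(idx)], collapse = ", ")))
    for (k in seq_along(idx)) {
      sites[idx[k], c("u11", "u22", "u33", "u23", "u13", "u12")] <-
        vapply(utags, function(t) strip_su(an[[t]][k]), numeric(1)) * scale
    }
  }
  crystal_structure(cell, sg, sites)
}

#' Write a crystal structure as CIF text
#'
#' Coordinates are printed to 6 decimals and displacement parameters to 5,
#' so \code{read_cif(write_cif(s))} reproduces \code{s} to print precision.
#'
#' @param structure A \code{\link{crystal_structure}}.
#' @param data_name Name for the data block.
#' @return Character vector of CIF lines.
#' @export
write_cif <- function(structure, data_name = "xtalbench") {
  s <- structure$sites
  if (any(!nzchar(s$label))) stop("write_cif: empty atom label")
  cell <- structure$cell
  out <- c(sprintf("data_%s", data_name),
           sprintf("_cell_length_a     %.6f", cell$a),
           sprintf("_cell_length_b     %.6f", cell$b),
           sprintf("_cell_length_c     %.6f", cell$c),
           sprintf("_cell_angle_alpha  %.5f", cell$alpha),
           sprintf("_cell_angle_beta   %.5f", cell$beta),
           sprintf("_cell_angle_gamma  %.5f", cell$gamma),
           sprintf("_symmetry_space_group_name_H-M '%s'", structure$spacegroup$name),
           "loop_",
           "_space_group_symop_operation_xyz")
  out <- c(out, vapply(structure$spacegroup$operations,
                       function(op) sprintf("'%s'", format_symop(op)), character(1)))
  out <- c(out,
           "loop_",
           "_atom_site_label",
           "_atom_site_type_symbol",
           "_atom_site_fract_x",
           "_atom_site_fract_y",
           "_atom_site_fract_z",
           "_atom_site_occupancy",
           "_atom_site_U_iso_or_equiv",
           sprintf("%s %s %.6f %.6f %.6f %.5f %.5f",
                   s$label, s$element, s$x, s$y, s$z, s$occ, s$uiso))
  aniso <- which(!is.na(s$u11))
  if (length(aniso) > 0) {
    out <- c(out,
             "loop_",
             "_atom_site_aniso_label",
             "_atom_site_aniso_U_11",
             "_atom_site_aniso_U_22",
             "_atom_site_aniso_U_33",
             "_atom_site_aniso_U_23",
             "_atom_site_aniso_U_13",
             "_atom_site_aniso_U_12",
             sprintf("%s %.5f %.5f %.5f %.5f %.5f %.5f",
                     s$label[aniso], s$u11[aniso], s$u22[aniso], s$u33[aniso],
                     s$u23[aniso], s$u13[aniso], s$u12[aniso]))
  }
  out
}

as_lines <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    return(readLines(text, warn = FALSE))
  if (length(text) == 1) return(strsplit(text, "\n", fixed = TRUE)[[1]])
  text
}
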