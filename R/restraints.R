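# Structure-specific distance restraints: one tight bond restraint per
# bonded pair and one softer 1-3 restraint per angle not involving
# hydrogen, with targets taken from an optimized geometry.

#' Restraint set
#'
#' @param restraints Data frame with columns \code{kind} ("bond_12" or
#'   "angle_13"), \code{atom1}, \code{atom2}, \code{target} (Angstrom),
#'   \code{su} (Angstrom).
#' @param source_tag Provenance string (e.g. the optimizer name).
#' @export
restraint_set <- function(restraints, source_tag = "unknown") {
  if (is.null(restraints))
    restraints <- data.frame(kind = character(0), atom1 = character(0),
                             atom2 = character(0), target = numeric(0),
                             su = numeric(0), stringsAsFactors = FALSE)
  if (nrow(restraints) > 0) {
    stopifnot(all(restraints$kind %in% c("bond_12", "angle_13")))
    if (any(restraints$target <= 0)) stop("restraint_set: targets must be positive")
    if (any(restraints$su <= 0)) stop("restraint_set: restraint s.u. must be positive")
    if (any(toupper(restraints$atom1) == toupper(restraints$atom2)))
      stop("restraint_set: restraint between an atom and itself")
    key <- paste(pmin(toupper(restraints$atom1), toupper(restraints$atom2)),
                 pmax(toupper(restraints$atom1), toupper(restraints$atom2)))
    if (anyDuplicated(key))
      stop("restraint_set: duplicate restraint on an atom pair")
  }
  structure(list(restraints = restraints, source_tag = source_tag),
            class = "restraint_set")
}

#' @export
print.restraint_set <- function(x, ...) {
  r <- x$restraints
  cat(sprintf("restraint set (%s): %d bond, %d angle-as-distance\n",
              x$source_tag, sum(r$kind == "bond_12"), sum(r$kind == "angle_13")))
  invisible(x)
}

#' Restraint s.u. profiles
#'
#' The \code{tight} profile (0.0005 / 0.002 Angstrom) enforces targets
#' essentially exactly and turns the R factor into a diagnostic of target
#' accuracy; the \code{practical} profile (0.01 / 0.03) is the scale one
#' would use to actually improve a refinement.
#'
#' @param name "tight" or "practical".
#' @return Named vector with \code{su_bond} and \code{su_angle}.
#' @export
restraint_profile <- function(name = c("tight", "practical")) {
  name <- match.arg(name)
  switch(name,
         tight = c(su_bond = 0.0005, su_angle = 0.002),
         practical = c(su_bond = 0.01, su_angle = 0.03))
}

#' Generate distance restraints from an optimized geometry
#'
#' Every bonded pair gets a bond restraint whose target is the optimized
#' distance; every 1-3 pair (angle expressed as a distance) not involving
#' hydrogen gets an angle restraint, unless \code{restrain_h_angles}. A 1-3
#' pair that is also bonded (three-membered ring) keeps only the bond
#' restraint.
#'
#' @param element Chemical symbols of the optimized atoms.
#' @param cart n x 3 optimized Cartesian coordinates (Angstrom).
#' @param labels Atom labels used in the restraint file (must match the
#'   experimental structure the restraints will be applied to).
#' @param graph Optional \code{bond_graph}; perceived from the coordinates
#'   when omitted.
#' @param su_bond,su_angle Restraint standard uncertainties in Angstrom.
#' @param restrain_h_bonds Restrain bonds to hydrogen? (Inert under riding
#'   hydrogens, but recorded.)
#' @param restrain_h_angles Restrain angles involving hydrogen?
#' @param source_tag Provenance string.
#' @return A \code{\link{restraint_set}}.
#' @export
generate_restraints <- function(element, cart, labels = NULL, graph = NULL,
                                su_bond = 0.0005, su_angle = 0.002,
                                restrain_h_bonds = TRUE,
                                restrain_h_angles = FALSE,
                                source_tag = "optimizer") {
  cart <- if (is.matrix(cart)) cart else matrix(cart, ncol = 3)
  if (is.null(labels)) labels <- sprintf("%s%d", element, seq_along(element))
  if (is.null(graph)) graph <- perceive_bonds(element, cart)
  if (nrow(graph$nodes) != nrow(cart))
    stop("generate_restraints: bond graph does not match the atom list")
  is_h <- graph$nodes$is_h
  rows <- list()
  for (e in seq_len(nrow(graph$edges))) {
    i <- graph$edges$i[e]; j <- graph$edges$j[e]
    if (!restrain_h_bonds && (is_h[i] || is_h[j])) next
    rows[[length(rows) + 1]] <- data.frame(
      kind = "bond_12", atom1 = labels[i], atom2 = labels[j],
      target = sqrt(sum((cart[i, ] - cart[j, ])^2)), su = su_bond,
      stringsAsFactors = FALSE)
  }
  bonded_key <- paste(pmin(graph$edges$i, graph$edges$j),
                      pmax(graph$edges$i, graph$edges$j))
  ap <- angle_pairs(graph, exclude_h = !restrain_h_angles)
  for (r in seq_len(nrow(ap))) {
    i <- ap$i[r]; k <- ap$k[r]
    if (paste(min(i, k), max(i, k)) %in% bonded_key) next  # 3-ring
    rows[[length(rows) + 1]] <- data.frame(
      kind = "angle_13", atom1 = labels[i], atom2 = labels[k],
      target = sqrt(sum((cart[i, ] - cart[k, ])^2)), su = su_angle,
      stringsAsFactors = FALSE)
  }
  df <- if (length(rows) > 0) do.call(rbind, rows) else NULL
  if (!is.null(df)) df <- unique(df)
  rs <- restraint_set(df, source_tag = source_tag)
  attr(rs, "apex") <- ap
  rs
}

#' Thermal-motion scaling of restraint targets
#'
#' Shifts every bond target by \code{delta} (the mean thermal-motion
#' elongation) and propagates the per-bond elongation through the law of
#' cosines to the 1-3 targets: for an angle with bond lengths d1, d2 and
#' apex angle theta, the first-order 1-3 shift is
#' \code{[(d1 - d2 cos(theta)) + (d2 - d1 cos(theta))] * delta / D13}.
#'
#' @param restraints A \code{\link{restraint_set}}.
#' @param delta Bond elongation in Angstrom (may be negative).
#' @param element,cart,labels Reference geometry supplying the two bond
#'   lengths and apex angle of every 1-3 restraint.
#' @param graph Optional \code{bond_graph} of the reference geometry.
#' @return A new \code{\link{restraint_set}} with shifted targets.
#' @export
apply_tma_correction <- function(restraints, delta, element, cart,
                                 labels = NULL, graph = NULL) {
  cart <- if (is.matrix(cart)) cart else matrix(cart, ncol = 3)
  if (is.null(labels)) labels <- sprintf("%s%d", element, seq_along(element))
  if (is.null(graph)) graph <- perceive_bonds(element, cart)
  ap <- angle_pairs(graph, exclude_h = FALSE)
  r <- restraints$restraints
  for (n in seq_len(nrow(r))) {
    if (r$kind[n] == "bond_12") {
      r$target[n] <- r$target[n] + delta
    } else {
      i <- match(toupper(r$atom1[n]), toupper(labels))
      k <- match(toupper(r$atom2[n]), toupper(labels))
      hit <- which((ap$i == i & ap$k == k) | (ap$i == k & ap$k == i))
      if (length(hit) == 0)
        stop(sprintf("apply_tma_correction: no apex found for 1-3 restraint %s...%s",
                     r$atom1[n], r$atom2[n]))
      j <- ap$apex[hit[1]]
      d1 <- sqrt(sum((cart[i, ] - cart[j, ])^2))
      d2 <- sqrt(sum((cart[k, ] - cart[j, ])^2))
      v1 <- cart[i, ] - cart[j, ]; v2 <- cart[k, ] - cart[j, ]
      costh <- sum(v1 * v2) / (d1 * d2)
      d13 <- sqrt(d1^2 + d2^2 - 2 * d1 * d2 * costh)
      r$target[n] <- r$target[n] +
        ((d1 - d2 * costh) + (d2 - d1 * costh)) * delta / d13
    }
  }
  restraint_set(r, source_tag = paste0(restraints$source_tag,
                                       sprintf(" (TMA %+0.5f A)", delta)))
}

#' Evaluate restraint residuals on a structure
#'
#' @param restraints A \code{\link{restraint_set}}.
#' @param structure A \code{\link{crystal_structure}} carrying the labels
#'   the restraints refer to.
#' @return Data frame with the model distance, target, and residual
#'   (model - target) per restraint.
#' @export
evaluate_restraints <- function(restraints, structure) {
  r <- restraints$restraints
  cart <- site_cart(structure)
  i <- match(toupper(r$atom1), toupper(structure$sites$label))
  j <- match(toupper(r$atom2), toupper(structure$sites$label))
  if (anyNA(i) || anyNA(j))
    stop("evaluate_restraints: restraint label not found in structure")
  d <- sqrt(rowSums((cart[i, , drop = FALSE] - cart[j, , drop = FALSE])^2))
  data.frame(kind = r$kind, atom1 = r$atom1, atom2 = r$atom2,
             model = d, target = r$target, residual = d - r$target,
             su = r$su, stringsAsFactors = FALSE)
}
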