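# Atom-sequence matching between two representations of the same molecule
# (e.g. experimental ASU vs optimizer output) by a combined figure of merit:
# extended-connectivity equivalence, positional similarity, atomic mass and
# point charge.

#' Match atoms of two structures
#'
#' Establishes a bijection between the non-hydrogen atoms of A and B using a
#' greedy assignment on a combined figure of merit (weighted sum of
#' extended-connectivity class disagreement, Cartesian distance after an
#' optional best-fit superposition, absolute mass difference and absolute
#' charge difference). Hydrogens are mapped afterwards through their parent
#' atoms, not by the figure of merit. Elements of mapped atoms always agree.
#'
#' @param a,b Lists with \code{element}, \code{cart} (n x 3), optional
#'   \code{charge} and \code{label}; a \code{crystal_structure} is accepted
#'   and converted.
#' @param weights Named numeric vector with components \code{ec},
#'   \code{pos}, \code{mass}, \code{charge}.
#' @param superpose Remove the rigid-body difference (Kabsch best fit on
#'   non-H atoms) before measuring positional similarity?
#' @return An \code{atom_mapping}: list with \code{pairs} (integer vector,
#'   \code{pairs[i]} = index in B matched to atom i of A) and \code{score}.
#' @export
match_atoms <- function(a, b, weights = c(ec = 100, pos = 10, mass = 1, charge = 1),
                        superpose = FALSE) {
  a <- as_match_input(a); b <- as_match_input(b)
  na <- length(a$element); nb <- length(b$element)
  ha <- toupper(normalize_element(a$element)) %in% c("H", "D")
  hb <- toupper(normalize_element(b$element)) %in% c("H", "D")
  fa <- sort(table(normalize_element(a$element)[!ha]))
  fb <- sort(table(normalize_element(b$element)[!hb]))
  if (!identical(names(fa), names(fb)) || !identical(as.integer(fa), as.integer(fb)))
    stop(sprintf("match_atoms: element composition differs (A: %s; B: %s)",
                 paste(names(fa), as.integer(fa), collapse = " "),
                 paste(names(fb), as.integer(fb), collapse = " ")))
  if (sum(ha) != sum(hb))
    stop("match_atoms: hydrogen counts differ")

  ga <- perceive_bonds(a$element, a$cart)
  gb <- perceive_bonds(b$element, b$cart)
  # extended connectivity on the disjoint union makes classes comparable
  nodes <- rbind(ga$nodes, gb$nodes)
  edges <- rbind(ga$edges,
                 transform(gb$edges, i = i + na, j = j + na))
  ec <- extended_connectivity(bond_graph(nodes, edges))
  eca <- ec[seq_len(na)]; ecb <- ec[na + seq_len(nb)]

  carta <- a$cart; cartb <- b$cart
  if (superpose) {
    fit <- kabsch_fit(carta[!ha, , drop = FALSE], cartb[!hb, , drop = FALSE])
    cartb <- sweep(cartb, 2, fit$center_b) %*% fit$rotation
    cartb <- sweep(cartb, 2, fit$center_a, `+`)
  }

  ia <- which(!ha); ib <- which(!hb)
  cost <- matrix(Inf, length(ia), length(ib))
  dist_ab <- matrix(Inf, length(ia), length(ib))
  for (p in seq_along(ia)) for (q in seq_along(ib)) {
    i <- ia[p]; j <- ib[q]
    if (normalize_element(a$element[i]) != normalize_element(b$element[j])) next
    dpos <- sqrt(sum((carta[i, ] - cartb[j, ])^2))
    dist_ab[p, q] <- dpos
    dchg <- if (!is.null(a$charge) && !is.null(b$charge) &&
                is.finite(a$charge[i]) && is.finite(b$charge[j]))
      abs(a$charge[i] - b$charge[j]) else 0
    cost[p, q] <- weights["ec"] * (eca[i] != ecb[j]) +
      weights["pos"] * dpos +
      weights["mass"] * abs(atomic_mass(a$element[i]) - atomic_mass(b$element[j])) +
      weights["charge"] * dchg
  }

  pairs <- rep(NA_integer_, na)
  score <- rep(NA_real_, na)
  free_a <- rep(TRUE, length(ia)); free_b <- rep(TRUE, length(ib))
  for (step in seq_along(ia)) {
    sub <- cost
    sub[!free_a, ] <- Inf; sub[, !free_b] <- Inf
    best <- min(sub)
    if (!is.finite(best))
      stop("match_atoms: no feasible assignment for remaining atoms")
    cand <- which(sub == best, arr.ind = TRUE)
    if (nrow(cand) > 1) {
      # tie-break: smallest Cartesian distance, then label sort
      dd <- dist_ab[cand]
      cand <- cand[order(dd, a$label[ia[cand[, 1]]], b$label[ib[cand[, 2]]]), ,
                   drop = FALSE]
    }
    p <- cand[1, 1]; q <- cand[1, 2]
    pairs[ia[p]] <- ib[q]; score[ia[p]] <- best
    free_a[p] <- FALSE; free_b[q] <- FALSE
  }

  # hydrogens: by parent correspondence, nearest available rider
  if (any(ha)) {
    parent_a <- h_parents(ga); parent_b <- h_parents(gb)
    used_b <- rep(FALSE, nb)
    for (i in which(ha)) {
      pa <- parent_a[[i]]
      cand <- which(hb & !used_b &
                      vapply(seq_len(nb), function(j)
                        length(parent_b[[j]]) > 0 && length(pa) > 0 &&
                          pairs[pa[1]] %in% parent_b[[j]], logical(1)))
      if (length(cand) == 0) cand <- which(hb & !used_b)
      d <- vapply(cand, function(j) sqrt(sum((carta[i, ] - cartb[j, ])^2)), numeric(1))
      j <- cand[which.min(d)]
      pairs[i] <- j; used_b[j] <- TRUE
      score[i] <- 0
    }
  }
  structure(list(pairs = pairs, score = score,
                 label_a = a$label, label_b = b$label),
            class = "atom_mapping")
}

h_parents <- function(graph) {
  adj <- graph_adjacency(graph)
  lapply(seq_along(adj), function(i) {
    if (!graph$nodes$is_h[i]) return(integer(0))
    adj[[i]][!graph$nodes$is_h[adj[[i]]]]
  })
}

as_match_input <- function(x) {
  if (inherits(x, "xtal_structure")) {
    return(list(element = x$sites$element, cart = site_cart(x),
                charge = x$sites$charge, label = x$sites$label))
  }
  if (is.null(x$label)) x$label <- sprintf("A%d", seq_along(x$element))
  if (is.null(x$charge)) x$charge <- rep(NA_real_, length(x$element))
  x$cart <- if (is.matrix(x$cart)) x$cart else matrix(x$cart, ncol = 3)
  x
}

kabsch_fit <- function(pa, pb) {
  ca <- colMeans(pa); cb <- colMeans(pb)
  h <- t(sweep(pb, 2, cb)) %*% sweep(pa, 2, ca)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(rotation = rot, center_a = ca, center_b = cb)
}
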