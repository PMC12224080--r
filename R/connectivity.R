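# Bond perception, 1-3 pair enumeration and Morgan-style extended
# connectivity on molecular graphs.

#' Perceive covalent bonds from Cartesian coordinates
#'
#' Atoms i and j are bonded iff their distance is at most
#' \code{tol_factor * (r_cov(i) + r_cov(j))} and above 0.3 Angstrom.
#' Hydrogen atoms are kept monovalent: only the nearest eligible partner is
#' retained.
#'
#' @param element Chemical symbols.
#' @param cart n x 3 Cartesian coordinates (Angstrom).
#' @param tol_factor Multiplier on the covalent-radius sum.
#' @return A \code{bond_graph}: list with \code{nodes} (element, is_h) and
#'   \code{edges} (i, j, length) data frames.
#' @export
perceive_bonds <- function(element, cart, tol_factor = 1.15) {
  cart <- if (is.matrix(cart)) cart else matrix(cart, ncol = 3)
  n <- nrow(cart)
  if (n < 2) stop("perceive_bonds: need at least 2 atoms")
  rcov <- covalent_radius(element)
  is_h <- toupper(normalize_element(element)) %in% c("H", "D")
  d <- as.matrix(stats::dist(cart))
  cut <- tol_factor * outer(rcov, rcov, `+`)
  bonded <- d <= cut & d > 0.3
  bonded[lower.tri(bonded, diag = TRUE)] <- FALSE
  idx <- which(bonded, arr.ind = TRUE)
  edges <- data.frame(i = idx[, 1], j = idx[, 2],
                      length = d[idx], stringsAsFactors = FALSE)
  # enforce monovalent hydrogens: keep only the nearest partner
  for (a in which(is_h)) {
    mine <- which(edges$i == a | edges$j == a)
    if (length(mine) > 1) {
      keep <- mine[which.min(edges$length[mine])]
      edges <- edges[-setdiff(mine, keep), , drop = FALSE]
    }
  }
  rownames(edges) <- NULL
  bond_graph(data.frame(element = element, is_h = is_h, stringsAsFactors = FALSE),
             edges)
}

#' Bond graph constructor
#' @param nodes Data frame with columns \code{element}, \code{is_h}.
#' @param edges Data frame with columns \code{i}, \code{j}, \code{length}.
#' @export
bond_graph <- function(nodes, edges) {
  if (nrow(edges) > 0) {
    if (any(edges$i == edges$j)) stop("bond_graph: self-loop")
    key <- paste(pmin(edges$i, edges$j), pmax(edges$i, edges$j))
    if (anyDuplicated(key)) stop("bond_graph: duplicate edge")
    if (any(edges$length <= 0.3)) stop("bond_graph: edge length must exceed 0.3 A")
  }
  structure(list(nodes = nodes, edges = edges), class = "bond_graph")
}

#' @export
print.bond_graph <- function(x, ...) {
  cat(sprintf("bond graph: %d atoms, %d bonds\n", nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

graph_adjacency <- function(graph) {
  n <- nrow(graph$nodes)
  adj <- vector("list", n)
  for (k in seq_len(nrow(graph$edges))) {
    i <- graph$edges$i[k]; j <- graph$edges$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

#' Enumerate 1-3 (angle) pairs of a bond graph
#'
#' One pair per distinct bonded path i-j-k with i < k; the apex j is
#' reported alongside. With \code{exclude_h = TRUE} any pair whose angle
#' involves a hydrogen atom (terminal or apex) is dropped.
#'
#' @param graph A \code{bond_graph}.
#' @param exclude_h Drop angles involving hydrogen?
#' @return Data frame with columns \code{i}, \code{apex}, \code{k}.
#' @export
angle_pairs <- function(graph, exclude_h = TRUE) {
  adj <- graph_adjacency(graph)
  is_h <- graph$nodes$is_h
  rows <- list()
  for (j in seq_along(adj)) {
    nb <- sort(adj[[j]])
    if (length(nb) < 2) next
    if (exclude_h && is_h[j]) next
    cmb <- utils::combn(nb, 2)
    for (c_ in seq_len(ncol(cmb))) {
      i <- cmb[1, c_]; k <- cmb[2, c_]
      if (exclude_h && (is_h[i] || is_h[k])) next
      rows[[length(rows) + 1]] <- c(i, j, k)
    }
  }
  if (length(rows) == 0)
    return(data.frame(i = integer(0), apex = integer(0), k = integer(0)))
  m <- do.call(rbind, rows)
  df <- data.frame(i = m[, 1], apex = m[, 2], k = m[, 3])
  df[order(df$i, df$k, df$apex), , drop = FALSE]
}

#' Extended-connectivity atom invariants
#'
#' Morgan-style iterative neighbourhood refinement seeded by
#' (element, degree, hydrogen flag). Each round appends the sorted multiset
#' of neighbour invariants, so the partition only ever refines. Iteration
#' stops when the number of classes is stable. The result is invariant
#' under atom permutation; topologically equivalent atoms share a class.
#'
#' @param graph A \code{bond_graph}.
#' @return Integer vector of class indices (1..n_classes), plus the stable
#'   invariant strings as attribute \code{"key"}.
#' @export
extended_connectivity <- function(graph) {
  n <- nrow(graph$nodes)
  adj <- graph_adjacency(graph)
  deg <- vapply(adj, length, integer(1))
  key <- sprintf("%s|%d|%d", normalize_element(graph$nodes$element), deg,
                 as.integer(graph$nodes$is_h))
  n_classes <- length(unique(key))
  for (iter in seq_len(n + 1)) {
    newkey <- vapply(seq_len(n), function(i) {
      nb <- key[adj[[i]]]
      paste(key[i], paste(sort(nb), collapse = ","), sep = ";")
    }, character(1))
    # compress to short canonical codes to keep strings bounded
    codes <- match(newkey, sort(unique(newkey)))
    key <- sprintf("%d", codes)
    nc <- length(unique(codes))
    if (nc == n_classes) break
    n_classes <- nc
  }
  out <- match(key, sort(unique(key)))
  attr(out, "key") <- key
  out
}
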