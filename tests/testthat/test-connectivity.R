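test_that("bond perception follows covalent-radius sums and keeps H monovalent", {
  two_c <- matrix(c(0, 0, 0, 1.54, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(nrow(perceive_bonds(c("C", "C"), two_c)$edges), 1)
  far <- matrix(c(0, 0, 0, 3.0, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(nrow(perceive_bonds(c("C", "C"), far)$edges), 0)

  # water: two O-H bonds, no H-H bond even though H...H is only 1.51 A
  ang <- 104.5 * pi / 180
  water <- matrix(c(0, 0, 0,
                    0.96, 0, 0,
                    0.96 * cos(ang), 0.96 * sin(ang), 0), 3, 3, byrow = TRUE)
  g <- perceive_bonds(c("O", "H", "H"), water)
  expect_equal(nrow(g$edges), 2)
  expect_true(all(g$edges$i == 1))
  expect_error(perceive_bonds(c("C", "Xx"), two_c), "unknown element")
})

test_that("bond perception is invariant under rotation, translation and atom order", {
  set.seed(14)
  cart <- matrix(c(0, 0, 0, 1.5, 0, 0, 1.5, 1.4, 0, 3.0, 1.4, 0), 4, 3, byrow = TRUE)
  el <- c("C", "C", "N", "O")
  ref <- perceive_bonds(el, cart)$edges
  q <- rnorm(4); rot <- xtalbench:::quaternion_rotation(q / sqrt(sum(q^2)))
  moved <- sweep(cart %*% t(rot), 2, c(5, -3, 2), `+`)
  expect_equal(perceive_bonds(el, moved)$edges[, c("i", "j")], ref[, c("i", "j")])

  perm <- c(3, 1, 4, 2)
  gp <- perceive_bonds(el[perm], cart[perm, ])$edges
  remap <- order(perm)
  keys_ref <- sort(paste(pmin(ref$i, ref$j), pmax(ref$i, ref$j)))
  keys_perm <- sort(paste(pmin(perm[gp$i], perm[gp$j]), pmax(perm[gp$i], perm[gp$j])))
  expect_equal(keys_perm, keys_ref)
})

test_that("angle pairs enumerate 1-3 paths and honour the hydrogen rule", {
  chain3 <- perceive_bonds(c("C", "C", "C"),
                           matrix(c(0, 0, 0, 1.5, 0, 0, 3.0, 0.6, 0), 3, 3, byrow = TRUE))
  expect_equal(nrow(angle_pairs(chain3)), 1)
  expect_equal(angle_pairs(chain3)$apex, 2)

  chain4 <- perceive_bonds(c("C", "C", "C", "C"),
                           matrix(c(0, 0, 0, 1.5, 0, 0, 2.2, 1.3, 0, 3.7, 1.4, 0),
                                  4, 3, byrow = TRUE))
  expect_equal(nrow(angle_pairs(chain4)), 2)

  # methane: every angle involves H, so the exclusion empties the list
  td <- rbind(c(0, 0, 0), 1.09 / sqrt(3) * rbind(c(1, 1, 1), c(1, -1, -1),
                                                 c(-1, 1, -1), c(-1, -1, 1)))
  methane <- perceive_bonds(c("C", "H", "H", "H", "H"), td)
  expect_equal(nrow(angle_pairs(methane, exclude_h = TRUE)), 0)
  expect_equal(nrow(angle_pairs(methane, exclude_h = FALSE)), 6)
})

test_that("extended connectivity classes capture topological equivalence", {
  ring <- t(vapply(0:5, function(k) 1.4 * c(cos(k * pi / 3), sin(k * pi / 3), 0),
                   numeric(3)))
  benzene <- perceive_bonds(rep("C", 6), ring)
  expect_equal(length(unique(extended_connectivity(benzene))), 1)

  butane <- bond_graph(data.frame(element = rep("C", 4), is_h = rep(FALSE, 4)),
                       data.frame(i = 1:3, j = 2:4, length = 1.53))
  ec <- extended_connectivity(butane)
  expect_equal(length(unique(ec)), 2)
  expect_equal(ec[1], ec[4])
  expect_equal(ec[2], ec[3])
})

test_that("extended connectivity is invariant under atom permutation", {
  set.seed(4)
  for (trial in 1:10) {
    n <- 8
    edges <- NULL
    for (i in 2:n) edges <- rbind(edges, c(sample(i - 1, 1), i))
    el <- sample(c("C", "N", "O"), n, TRUE)
    g <- bond_graph(data.frame(element = el, is_h = rep(FALSE, n)),
                    data.frame(i = edges[, 1], j = edges[, 2], length = 1.5))
    perm <- sample(n)
    inv <- order(perm)
    g2 <- bond_graph(data.frame(element = el[perm], is_h = rep(FALSE, n)),
                     data.frame(i = pmin(inv[edges[, 1]], inv[edges[, 2]]),
                                j = pmax(inv[edges[, 1]], inv[edges[, 2]]),
                                length = 1.5))
    expect_equal(sort(table(extended_connectivity(g))),
                 sort(table(extended_connectivity(g2))), ignore_attr = TRUE)
  }
})
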