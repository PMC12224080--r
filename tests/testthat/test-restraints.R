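test_that("a right-angle chain yields two bond and one 1-3 restraint", {
  ch <- right_angle_chain()
  rs <- generate_restraints(ch$element, ch$cart, labels = ch$labels,
                            graph = ch$graph)
  r <- rs$restraints
  expect_equal(sum(r$kind == "bond_12"), 2)
  expect_equal(sum(r$kind == "angle_13"), 1)
  expect_equal(sort(r$target[r$kind == "bond_12"]), c(1, 1))
  expect_equal(r$target[r$kind == "angle_13"], sqrt(2), tolerance = 1e-12)
  expect_equal(unique(r$su[r$kind == "bond_12"]), 0.0005)
  expect_equal(unique(r$su[r$kind == "angle_13"]), 0.002)
})

test_that("hydrogen angles are excluded by default, hydrogen bonds kept", {
  ang <- 104.5 * pi / 180
  water <- matrix(c(0, 0, 0,
                    0.96, 0, 0,
                    0.96 * cos(ang), 0.96 * sin(ang), 0), 3, 3, byrow = TRUE)
  rs <- generate_restraints(c("O", "H", "H"), water)
  expect_equal(sum(rs$restraints$kind == "bond_12"), 2)
  expect_equal(sum(rs$restraints$kind == "angle_13"), 0)
  rs2 <- generate_restraints(c("O", "H", "H"), water, restrain_h_angles = TRUE)
  expect_equal(sum(rs2$restraints$kind == "angle_13"), 1)
})

test_that("restraint count equals |edges| + |eligible 1-3 pairs|", {
  st <- make_toy_structure(91, "P1", n_heavy = 7, n_h = 2)
  cart <- site_cart(st)
  g <- perceive_bonds(st$sites$element, cart)
  rs <- generate_restraints(st$sites$element, cart, labels = st$sites$label,
                            graph = g)
  bonded <- paste(pmin(g$edges$i, g$edges$j), pmax(g$edges$i, g$edges$j))
  ap <- angle_pairs(g, exclude_h = TRUE)
  eligible <- sum(!(paste(pmin(ap$i, ap$k), pmax(ap$i, ap$k)) %in% bonded))
  expect_equal(nrow(rs$restraints), nrow(g$edges) + eligible)
})

test_that("a 1-3 pair that is also bonded keeps only the bond restraint", {
  # equilateral triangle: every pair bonded and every pair also 1-3
  tri <- 1.5 * rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  rs <- generate_restraints(c("C", "C", "C"), tri)
  expect_equal(nrow(rs$restraints), 3)
  expect_true(all(rs$restraints$kind == "bond_12"))
})

test_that("restraints evaluate to zero residual on their generating geometry", {
  st <- make_toy_structure(92, "P21", n_heavy = 6, n_h = 1)
  rs <- generate_restraints(st$sites$element, site_cart(st),
                            labels = st$sites$label)
  ev <- evaluate_restraints(rs, st)
  expect_lt(max(abs(ev$residual)), 1e-10)
})

test_that("thermal-motion scaling shifts bonds by delta and angles by the cosine rule", {
  ch <- right_angle_chain()
  rs <- generate_restraints(ch$element, ch$cart, labels = ch$labels,
                            graph = ch$graph)

  same <- apply_tma_correction(rs, 0, ch$element, ch$cart, labels = ch$labels,
                               graph = ch$graph)
  expect_equal(same$restraints$target, rs$restraints$target)

  delta <- 5e-4
  corr <- apply_tma_correction(rs, delta, ch$element, ch$cart,
                               labels = ch$labels, graph = ch$graph)
  r <- corr$restraints
  expect_equal(r$target[r$kind == "bond_12"],
               rs$restraints$target[rs$restraints$kind == "bond_12"] + delta)
  # exact recompute for d1 = d2 = 1, theta = 90: sqrt(2) * (1 + delta)
  exact <- sqrt(2 * (1 + delta)^2)
  expect_lt(abs(r$target[r$kind == "angle_13"] - exact), 1e-6)
})

test_that("first-order 1-3 scaling matches exact recomputation on random geometries", {
  set.seed(17)
  chain_graph <- bond_graph(data.frame(element = c("C", "C", "C"),
                                       is_h = rep(FALSE, 3)),
                            data.frame(i = c(1, 2), j = c(2, 3), length = 1.4))
  for (trial in 1:25) {
    d1 <- runif(1, 1.2, 1.6); d2 <- runif(1, 1.2, 1.6)
    th <- runif(1, 80, 140) * pi / 180
    cart <- rbind(c(d1, 0, 0), c(0, 0, 0), d2 * c(cos(th), sin(th), 0))
    rs <- generate_restraints(c("C", "C", "C"), cart,
                              labels = c("C1", "C2", "C3"),
                              graph = chain_graph)
    for (delta in c(-0.002, 0.0005, 0.002)) {
      corr <- apply_tma_correction(rs, delta, c("C", "C", "C"), cart,
                                   labels = c("C1", "C2", "C3"),
                                   graph = chain_graph)
      got <- corr$restraints$target[corr$restraints$kind == "angle_13"]
      exact <- sqrt((d1 + delta)^2 + (d2 + delta)^2 -
                      2 * (d1 + delta) * (d2 + delta) * cos(th))
      expect_lt(abs(got - exact), 1e-6)
    }
  }
})

test_that("the practical profile relaxes the s.u. values", {
  p <- restraint_profile("practical")
  expect_gt(p[["su_bond"]], restraint_profile("tight")[["su_bond"]])
  expect_equal(p[["su_angle"]], 0.03)
})

test_that("degenerate restraint sets are rejected", {
  expect_error(restraint_set(data.frame(kind = "bond_12", atom1 = "C1",
                                        atom2 = "C1", target = 1.5, su = 5e-4)),
               "itself")
  dup <- data.frame(kind = c("bond_12", "angle_13"),
                    atom1 = c("C1", "C2"), atom2 = c("C2", "C1"),
                    target = c(1.5, 2.4), su = c(5e-4, 2e-3))
  expect_error(restraint_set(dup), "duplicate")
})
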