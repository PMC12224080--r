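random_tls_fixture <- function(n = 9) {
  cart <- matrix(rnorm(3 * n, sd = 2), n, 3)
  a <- matrix(rnorm(9, sd = 0.05), 3, 3); T <- crossprod(a) + diag(0.008, 3)
  b <- matrix(rnorm(9, sd = 0.015), 3, 3); L <- crossprod(b) + diag(5e-4, 3)
  S <- matrix(rnorm(9, sd = 3e-4), 3, 3)
  diag(S) <- diag(S) - sum(diag(S)) / 3
  S[abs(S) < 1e-12] <- 0
  list(cart = cart, tls = tls_model(T, L, S, colMeans(cart)))
}

test_that("a pure-translation model gives every atom the same U", {
  T <- diag(c(0.01, 0.02, 0.015))
  tls <- tls_model(T, matrix(0, 3, 3), origin = c(1, 2, 3))
  u6 <- rigid_body_adps(matrix(rnorm(15), 5, 3), tls)
  for (i in 1:5)
    expect_equal(xtalbench:::u6_to_mat(u6[i, ]), T, tolerance = 1e-14)
})

test_that("rigid-body ADPs satisfy the Hirshfeld rigid-bond condition", {
  set.seed(55)
  fx <- random_tls_fixture(8)
  u6 <- rigid_body_adps(fx$cart, fx$tls)
  for (i in 1:7) for (j in (i + 1):8) {
    v <- fx$cart[j, ] - fx$cart[i, ]
    n <- v / sqrt(sum(v^2))
    msda_i <- as.numeric(t(n) %*% xtalbench:::u6_to_mat(u6[i, ]) %*% n)
    msda_j <- as.numeric(t(n) %*% xtalbench:::u6_to_mat(u6[j, ]) %*% n)
    expect_lt(abs(msda_i - msda_j), 1e-12)
  }
})

test_that("fit_tls inverts rigid_body_adps exactly", {
  set.seed(56)
  for (trial in 1:20) {
    fx <- random_tls_fixture(sample(7:12, 1))
    u6 <- rigid_body_adps(fx$cart, fx$tls)
    fit <- fit_tls(list(cart = fx$cart, u_cart = u6))
    expect_lt(fit$residual, 1e-10)
    expect_equal(fit$tls$T, fx$tls$T, tolerance = 1e-8)
    expect_equal(fit$tls$L, fx$tls$L, tolerance = 1e-8)
    expect_equal(fit$tls$S, fx$tls$S, tolerance = 1e-8)
  }
})

test_that("pure-translation ADPs fit back to L = 0, S = 0", {
  set.seed(57)
  cart <- matrix(rnorm(27, sd = 2), 9, 3)
  T <- diag(c(0.012, 0.01, 0.014))
  u6 <- rigid_body_adps(cart, tls_model(T, matrix(0, 3, 3), origin = colMeans(cart)))
  fit <- fit_tls(list(cart = cart, u_cart = u6))
  expect_equal(fit$tls$T, T, tolerance = 1e-10)
  expect_lt(max(abs(fit$tls$L)), 1e-10)
  expect_lt(max(abs(fit$tls$S)), 1e-10)
})

test_that("fit_tls enforces the more-than-six-atoms rule and catches degeneracy", {
  set.seed(58)
  fx <- random_tls_fixture(8)
  u6 <- rigid_body_adps(fx$cart, fx$tls)
  expect_error(fit_tls(list(cart = fx$cart[1:6, ], u_cart = u6[1:6, ])),
               "more than six")
  # linear molecule: libration about the axis is unobservable
  line <- cbind(seq(0, 7, 1), 0, 0)
  u6l <- rigid_body_adps(line, tls_model(diag(0.01, 3), matrix(0, 3, 3),
                                         origin = colMeans(line)))
  expect_error(fit_tls(list(cart = line, u_cart = u6l)), "rank-deficient")
})

test_that("fit_tls on a structure uses non-H aniso sites", {
  st <- make_toy_structure(59, "P21/c", n_heavy = 8, n_h = 2)
  fit <- fit_tls(st)
  expect_equal(fit$n_atoms, 8)
  expect_lt(fit$residual, 1e-8)   # fixture ADPs are exactly rigid-body
  expect_equal(fit$tls$L, default_fixture_tls()$L, tolerance = 1e-6)
})

test_that("libration corrections vanish for L = 0 and scale exactly for isotropic L", {
  st <- make_toy_structure(60, "P1", n_heavy = 6)
  cart <- site_cart(st)
  origin <- colMeans(cart)

  rep0 <- libration_corrected_bonds(st, tls_model(diag(0.01, 3), matrix(0, 3, 3),
                                                  origin = origin))
  expect_equal(rep0$bonds$delta, rep(0, nrow(rep0$bonds)), tolerance = 1e-14)

  lambda <- 2e-3
  repiso <- libration_corrected_bonds(st, tls_model(diag(0.01, 3), lambda * diag(3),
                                                    origin = origin))
  expect_equal(repiso$bonds$delta, lambda * repiso$bonds$d_uncorrected,
               tolerance = 1e-9)
  expect_equal(repiso$mean_delta,
               mean(repiso$bonds$delta[repiso$bonds$non_h]), tolerance = 1e-15)
})

test_that("libration correction is non-negative for PSD L at the centroid", {
  set.seed(61)
  for (trial in 1:10) {
    fx <- random_tls_fixture(8)
    st <- cartesian_p1(rep("C", 8), fx$cart)
    # bonds are irrelevant to the sign property; perceive what is there
    g <- bond_graph(data.frame(element = rep("C", 8), is_h = rep(FALSE, 8)),
                    data.frame(i = 1:7, j = 2:8,
                               length = sqrt(rowSums((fx$cart[1:7, ] - fx$cart[2:8, ])^2))))
    rep_ <- libration_corrected_bonds(st, fx$tls, graph = g)
    expect_true(all(rep_$bonds$delta >= -1e-12))
  }
})

test_that("the Busing-Levy riding correction follows the perpendicular excess", {
  u <- diag(0.02, 3)
  expect_equal(riding_correction(1.5, u, u, c(1, 0, 0)), 1.5)

  # isotropic excess 0.01 A^2: perpendicular excess 2 * 0.01
  u_rider <- u + diag(0.01, 3)
  expect_equal(riding_correction(1.5, u, u_rider, c(0, 0, 1)) - 1.5,
               2 * 0.01 / (2 * 1.5), tolerance = 1e-12)
  # negative excess gives a negative correction
  expect_lt(riding_correction(1.5, u_rider, u, c(0, 1, 0)), 1.5)
  expect_error(riding_correction(0, u, u, c(1, 0, 0)), "positive")
})
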