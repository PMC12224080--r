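test_that("form factors approach Z at s = 0 and decay with resolution", {
  for (el in c("H", "C", "N", "O", "S", "Cl", "Br")) {
    expect_lt(abs(form_factor(el, 0) - atomic_number(el)) / atomic_number(el),
              0.02)
  }
  s <- seq(0, 1.4, by = 0.02)
  for (el in c("C", "N", "O")) {
    f <- form_factor(el, s)
    expect_true(all(diff(f) < 0))
    expect_true(all(f > 0))
  }
  expect_error(form_factor("Xq", 0.1), "no coefficients")
  expect_error(form_factor("C", -0.1), "non-negative")
})

test_that("oxygen form factor at s = 0.5 matches a direct Gaussian-sum recompute", {
  a <- c(3.0485, 2.2868, 1.5463, 0.8670)
  b <- c(13.2771, 5.7011, 0.3239, 32.9089)
  cc <- 0.2508
  expect_equal(form_factor("O", 0.5), sum(a * exp(-b * 0.25)) + cc,
               tolerance = 1e-12)
})

test_that("a single atom in P1 reproduces textbook structure-factor limits", {
  cell <- unit_cell(6, 7, 8)
  at_origin <- crystal_structure(cell, lookup_space_group("P1"),
                                 atom_sites("C1", "C", c(0, 0, 0), uiso = 0))
  hkl <- rbind(c(1, 0, 0), c(0, 2, 0), c(1, 1, 1), c(3, -2, 1))
  f <- calc_structure_factors(at_origin, hkl)
  s <- 1 / (2 * d_spacing(cell, hkl))
  expect_equal(Mod(f), form_factor("C", s), tolerance = 1e-12)
  expect_equal(Arg(f), rep(0, 4), tolerance = 1e-12)

  at_half <- crystal_structure(cell, lookup_space_group("P1"),
                               atom_sites("C1", "C", c(0.5, 0, 0), uiso = 0))
  f100 <- calc_structure_factors(at_half, c(1, 0, 0))
  expect_equal(Re(f100), -form_factor("C", 1 / (2 * d_spacing(cell, c(1, 0, 0)))),
               tolerance = 1e-12)
  expect_equal(Im(f100), 0, tolerance = 1e-12)
})

test_that("the 2_1 screw axis extinguishes odd 0k0 reflections", {
  st <- make_toy_structure(13, "P21", n_heavy = 5, n_h = 1)
  k <- 1:8
  hkl <- cbind(0, k, 0)
  f <- Mod(calc_structure_factors(st, hkl))
  fmax <- max(Mod(calc_structure_factors(st, unique_hkl(st, 1.2))))
  expect_true(all(f[k %% 2 == 1] / fmax < 1e-10))
  expect_true(any(f[k %% 2 == 0] / fmax > 1e-6))
})

test_that("symmetry-summed structure factors equal the P1-expansion oracle", {
  set.seed(29)
  for (seed in 101:104) {
    sg <- c("P1", "P-1", "P21", "P21/c")[seed - 100]
    st <- make_toy_structure(seed, sg, n_heavy = 5, n_h = 1)
    hkl <- cbind(sample(-5:5, 40, TRUE), sample(-5:5, 40, TRUE),
                 sample(-5:5, 40, TRUE))
    hkl <- hkl[rowSums(hkl != 0) > 0, , drop = FALSE]
    f_sym <- calc_structure_factors(st, hkl)
    f_p1 <- calc_structure_factors(as_p1_structure(st), hkl)
    expect_lt(max(Mod(f_sym - f_p1)) / max(Mod(f_sym)), 1e-8)
  }
})

test_that("Friedel symmetry holds without anomalous scattering", {
  st <- make_toy_structure(15, "P21", n_heavy = 6)
  hkl <- unique_hkl(st, 1.2)
  expect_equal(Mod(calc_structure_factors(st, hkl)),
               Mod(calc_structure_factors(st, -hkl)), tolerance = 1e-12)
})

test_that("missing ADPs are an error unless a default is configured", {
  cell <- unit_cell(6, 7, 8)
  sites <- atom_sites("C1", "C", c(0.1, 0.2, 0.3))
  sites$uiso <- NA_real_
  st <- crystal_structure(cell, lookup_space_group("P1"), sites)
  expect_error(calc_structure_factors(st, c(1, 0, 0)), "no ADP")
  expect_silent(calc_structure_factors(st, c(1, 0, 0), default_uiso = 0.02))
})

test_that("the intensity scale factor is the least-squares ratio", {
  fc <- c(4, 9, 25)
  expect_equal(scale_factor(4 * fc, fc), 4)
  expect_equal(scale_factor(fc, fc), 1)
  expect_equal(scale_factor(fc, 2 * fc), scale_factor(fc, fc) / 2)
  expect_error(scale_factor(fc, c(0, 0, 0)), "zero")
})

test_that("R1 matches hand-computed sums", {
  expect_equal(r1_factor(c(10, 20), c(10, 20)), 0)
  expect_equal(r1_factor(c(10, 20), c(8, 22)), 4 / 30)
  expect_equal(r1_factor(c(10, 20), c(0, 0)), 1)
  expect_error(r1_factor(numeric(0), numeric(0)), "empty")
})
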