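test_that("refinement of the generating model on noiseless data is a fixed point", {
  res <- refine(shared_fix$structure, shared_fix$refl_clean)
  expect_lt(res$r1, 1e-6)
  expect_lte(res$cycles_used, 2)
  expect_true(res$converged)
})

test_that("unrestrained refinement recovers a perturbed structure from noiseless data", {
  pert <- perturb_structure(shared_fix$structure, 0.05, seed = 202)
  start_off <- rmscd(pert, shared_fix$structure)
  expect_gt(start_off, 0.05)
  res <- refine(pert, shared_fix$refl_clean)
  expect_true(res$converged)
  expect_lt(rmscd(res$structure, shared_fix$structure), 1e-3)
})

test_that("tight restraints with wrong targets are enforced and spoil R1", {
  ur <- refine(shared_fix$structure, shared_fix$refl_noisy)
  g <- ur$structure
  rs <- generate_restraints(g$sites$element, site_cart(g),
                            labels = g$sites$label)
  wrong <- rs$restraints
  wrong$target <- wrong$target + 0.05
  rr <- refine(shared_fix$structure, shared_fix$refl_noisy,
               restraints = restraint_set(wrong))
  # a uniform +0.05 A offset makes bond and 1-3 targets mutually
  # inconsistent, so the rms cannot vanish; the bulk of the offset is
  # nevertheless absorbed ...
  expect_lt(rr$restraint_rms, 0.6 * 0.05)
  # ... and the data agreement pays for it
  expect_gt(rr$r1, ur$r1)
})

test_that("restrained refinement with huge s.u. reproduces the unrestrained result", {
  pert <- perturb_structure(shared_fix$structure, 0.03, seed = 7)
  ur <- refine(pert, shared_fix$refl_noisy)
  g <- ur$structure
  rs <- generate_restraints(g$sites$element, site_cart(g),
                            labels = g$sites$label,
                            su_bond = 100, su_angle = 100)
  rr <- refine(pert, shared_fix$refl_noisy, restraints = rs)
  expect_lt(rmscd(rr$structure, ur$structure), 1e-5)
})

test_that("riding hydrogens follow their parents and keep the H geometry", {
  st <- shared_fix$structure
  g0 <- perceive_bonds(st$sites$element, site_cart(st))
  h_edges <- g0$edges[g0$nodes$is_h[g0$edges$i] | g0$nodes$is_h[g0$edges$j], ]
  pert <- perturb_structure(st, 0.04, seed = 31)
  res <- refine(pert, shared_fix$refl_clean)
  cart <- site_cart(res$structure)
  cart0 <- site_cart(pert)
  for (r in seq_len(nrow(h_edges))) {
    d_before <- sqrt(sum((cart0[h_edges$i[r], ] - cart0[h_edges$j[r], ])^2))
    d_after <- sqrt(sum((cart[h_edges$i[r], ] - cart[h_edges$j[r], ])^2))
    expect_equal(d_after, d_before, tolerance = 1e-9)
  }
  # riding Uiso ties to the parent equivalent U
  hu <- res$structure$sites$uiso[res$structure$sites$is_h]
  expect_true(all(hu > 0))
})

test_that("delta R1 is zero for identical results and demands matching data", {
  ur <- refine(shared_fix$structure, shared_fix$refl_noisy)
  expect_identical(delta_r1(ur, ur), 0)
  other <- simulate_reflections(shared_fix$structure, d_min = 1.1,
                                noise_fraction = 0.02, seed = 99)
  ur2 <- refine(shared_fix$structure, other)
  expect_error(delta_r1(ur, ur2), "different reflection sets")
})

test_that("restraints from the converged unrestrained geometry leave R1 unchanged", {
  ur <- refine(shared_fix$structure, shared_fix$refl_noisy)
  g <- ur$structure
  rs <- generate_restraints(g$sites$element, site_cart(g),
                            labels = g$sites$label)
  rr <- refine(shared_fix$structure, shared_fix$refl_noisy, restraints = rs)
  expect_lt(abs(delta_r1(rr, ur)), 1e-4)
  expect_lt(rr$restraint_rms, 1e-4)
})

test_that("refinement options are validated", {
  expect_error(refinement_options(damping = 0), "damping")
  expect_error(refinement_options(max_cycles = 0), "max_cycles")
  expect_error(refine(shared_fix$structure, shared_fix$refl_clean,
                      options = refinement_options(mode = "restrained")),
               "no restraints")
})
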