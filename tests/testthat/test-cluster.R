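single_atom_cubic <- function(a = 5) {
  crystal_structure(unit_cell(a, a, a), lookup_space_group("P1"),
                    atom_sites("C1", "C", c(0.1, 0.2, 0.3)))
}

test_that("threshold geometry of the single-atom cubic P1 cell is exact", {
  expect_equal(build_cluster(single_atom_cubic(), 0)$n_images, 0)
  # nearest images at 5.0 A: none within 3.75, the six axial ones within 5.2
  expect_equal(build_cluster(single_atom_cubic(), 3.75)$n_images, 0)
  cl <- build_cluster(single_atom_cubic(), 5.2)
  expect_equal(cl$n_images, 6)
  shifts <- cluster_images(cl)
  expect_true(all(rowSums(abs(shifts[, c("s1", "s2", "s3")])) == 1))
  expect_error(build_cluster(single_atom_cubic(), -1), "non-negative")
})

test_that("environment size is monotone in the threshold", {
  st <- make_toy_structure(41, "P21/c", n_heavy = 5)
  counts <- vapply(c(1.5, 2.5, 3.75, 5.0), function(th)
    build_cluster(st, th)$n_images, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("cluster contents agree with brute-force supercell enumeration", {
  for (seed in 51:54) {
    sg <- c("P1", "P-1", "P21", "P21/c")[(seed - 51) %% 4 + 1]
    st <- make_toy_structure(seed, sg, n_heavy = 5, n_h = 1)
    for (th in c(2.5, 3.75)) {
      expect_equal(cluster_images(build_cluster(st, th)),
                   cluster_images_bruteforce(st, th, r = 3),
                   ignore_attr = TRUE)
    }
  }
})

test_that("cluster size is unchanged when the ASU is replaced by a symmetry image", {
  st <- make_toy_structure(61, "P21/c", n_heavy = 5)
  n_ref <- build_cluster(st, 3.75)$n_images
  for (k in 2:4) {
    st2 <- st
    st2$sites[, c("x", "y", "z")] <-
      wrap_frac(apply_symmetry(st$spacegroup$operations[[k]], site_frac(st)))
    expect_equal(build_cluster(st2, 3.75)$n_images, n_ref)
  }
})

test_that("every included image has a contact within threshold and a full ASU", {
  st <- make_toy_structure(71, "P-1", n_heavy = 5, n_h = 1)
  cl <- build_cluster(st, 3.75)
  n_asu <- nrow(st$sites)
  imgs <- cluster_images(cl)
  free <- as.matrix(cl$free[, c("x", "y", "z")])
  for (r in seq_len(nrow(imgs))) {
    atoms <- cl$env[cl$env$op == imgs$op[r] & cl$env$s1 == imgs$s1[r] &
                      cl$env$s2 == imgs$s2[r] & cl$env$s3 == imgs$s3[r], ]
    expect_equal(nrow(atoms), n_asu)  # whole-ASU inclusion
    dmin <- min(apply(as.matrix(atoms[, c("x", "y", "z")]), 1, function(p)
      min(sqrt(rowSums(sweep(free, 2, p)^2)))))
    expect_lte(dmin, 3.75)
  }
})

test_that("XYZ export lists free atoms first with a matching index list", {
  st <- make_toy_structure(81, "P21", n_heavy = 5)
  cl <- build_cluster(st, 3.75)
  out <- export_cluster_xyz(cl)
  expect_equal(out$free_indices, seq_len(nrow(cl$free)))
  parsed <- read_xyz(out$xyz)
  n_total <- nrow(cl$free) + if (is.null(cl$env)) 0 else nrow(cl$env)
  expect_equal(length(parsed$element), n_total)
  expect_equal(parsed$cart[seq_len(nrow(cl$free)), ],
               as.matrix(cl$free[, c("x", "y", "z")]),
               tolerance = 1e-6, ignore_attr = TRUE)
})
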