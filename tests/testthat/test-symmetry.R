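test_that("xyz operator parsing handles identity, screw and permutation forms", {
  id <- parse_symop_xyz("x,y,z")
  expect_equal(id$rotation, diag(3L))
  expect_equal(id$tr_num, c(0L, 0L, 0L))

  sc <- parse_symop_xyz("-x, y+1/2, -z+1/2")
  expect_equal(sc$rotation, diag(c(-1L, 1L, -1L)))
  expect_equal(sc$tr_num / sc$tr_den, c(0, 0.5, 0.5))

  pm <- parse_symop_xyz("y,x,z")
  expect_equal(det(pm$rotation), -1)

  # decimal offsets and leading constants
  expect_true(symop_equal <- identical(parse_symop_xyz("0.5-x,y,z")$rotation,
                                       diag(c(-1L, 1L, 1L))))
  expect_equal(parse_symop_xyz("1/2+x,y,z")$tr_num[1] /
                 parse_symop_xyz("1/2+x,y,z")$tr_den[1], 0.5)
  expect_error(parse_symop_xyz("x,y"), "3 comma")
  expect_error(parse_symop_xyz("x,y,w+1/2"), "cannot parse")
})

test_that("format_symop and parse_symop_xyz are exact inverses on group operators", {
  for (sgname in c("P1", "P-1", "P21", "P21/c")) {
    sg <- lookup_space_group(sgname)
    for (op in sg$operations) {
      back <- parse_symop_xyz(format_symop(op))
      expect_identical(back$rotation, op$rotation)
      expect_identical(back$tr_num, op$tr_num)
      expect_identical(back$tr_den, op$tr_den)
    }
  }
})

test_that("space groups are closed and reject broken operator sets", {
  sg <- lookup_space_group("P21/c")
  expect_length(sg$operations, 4)
  # composing any two operations lands back in the group (checked at build);
  # removing one breaks closure
  expect_error(space_group("broken", sg$operations[c(1, 2, 3)]), "not closed")
  expect_error(space_group("no-id", sg$operations[2]), "identity")
})

test_that("apply_symmetry does not wrap and matches hand results", {
  expect_equal(apply_symmetry(parse_symop_xyz("x,y,z"), c(0.1, 0.2, 0.3)),
               c(0.1, 0.2, 0.3))
  expect_equal(apply_symmetry(parse_symop_xyz("-x,-y,-z"), c(0.1, 0.2, 0.3)),
               c(-0.1, -0.2, -0.3))
  expect_equal(apply_symmetry(parse_symop_xyz("-x,y+1/2,-z"), c(0.25, 0.0, 0.1)),
               c(-0.25, 0.5, -0.1))
})

test_that("P1 expansion replicates general positions and merges special ones", {
  cellp <- unit_cell(8, 9, 10, beta = 100)
  pbar <- crystal_structure(cellp, lookup_space_group("P-1"),
                            atom_sites(c("C1"), c("C"), c(0.1, 0.2, 0.3)))
  expect_equal(nrow(expand_to_p1(pbar)), 2)

  origin_atom <- crystal_structure(cellp, lookup_space_group("P-1"),
                                   atom_sites("N1", "N", c(0, 0, 0), occ = 0.5))
  merged <- expand_to_p1(origin_atom)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$occ, 1)  # merged copies sum their occupancies

  p21c <- crystal_structure(cellp, lookup_space_group("P21/c"),
                            atom_sites("O1", "O", c(0.13, 0.21, 0.34)))
  expect_equal(nrow(expand_to_p1(p21c)), 4)
})

test_that("P1 expansion is invariant under pre-applying a group operation", {
  st <- make_toy_structure(21, "P21/c", n_heavy = 4)
  ref <- expand_to_p1(st)
  ref_set <- ref[order(ref$x, ref$y, ref$z), c("x", "y", "z")]
  for (k in 2:4) {
    st2 <- st
    f2 <- wrap_frac(apply_symmetry(st$spacegroup$operations[[k]], site_frac(st)))
    st2$sites[, c("x", "y", "z")] <- f2
    alt <- expand_to_p1(st2)
    alt_set <- alt[order(alt$x, alt$y, alt$z), c("x", "y", "z")]
    expect_equal(as.matrix(alt_set), as.matrix(ref_set), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})
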