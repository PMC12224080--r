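# Shared fixtures, built once per test run.

# big-cell P1 container for purely Cartesian geometry tests
cartesian_p1 <- function(element, cart, cell_len = 30) {
  cell <- unit_cell(cell_len, cell_len, cell_len)
  frac <- cart_to_frac(cell, cart)
  labels <- sprintf("%s%d", element, seq_along(element))
  crystal_structure(cell, lookup_space_group("P1"),
                    atom_sites(labels, element, frac, uiso = 0.01))
}

# right-angle 3-atom chain: bonds 1.0 / 1.0, apex angle 90 degrees.
# The 1-3 distance (1.414 A) is short enough that distance-based perception
# would close the triangle, so the chain topology is supplied explicitly.
right_angle_chain <- function() {
  cart <- matrix(c(0, 0, 0,
                   1.0, 0, 0,
                   1.0, 1.0, 0), 3, 3, byrow = TRUE)
  graph <- bond_graph(data.frame(element = c("C", "C", "C"),
                                 is_h = rep(FALSE, 3)),
                      data.frame(i = c(1, 2), j = c(2, 3), length = c(1, 1)))
  list(element = c("C", "C", "C"), cart = cart,
       labels = c("C1", "C2", "C3"), graph = graph)
}

random_valid_cell <- function() {
  repeat {
    cl <- try(unit_cell(runif(1, 3, 20), runif(1, 3, 20), runif(1, 3, 20),
                        runif(1, 60, 120), runif(1, 60, 120), runif(1, 60, 120)),
              silent = TRUE)
    if (!inherits(cl, "try-error")) return(cl)
  }
}

# one moderately sized refinement fixture shared by several test files
shared_fix <- local({
  st <- make_toy_structure(7, "P21/c", n_heavy = 6, n_h = 2)
  list(structure = st,
       refl_clean = simulate_reflections(st, d_min = 0.9, noise_fraction = 0, seed = 7),
       refl_noisy = simulate_reflections(st, d_min = 0.9, noise_fraction = 0.02, seed = 7))
})
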