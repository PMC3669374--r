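# shared fixtures and independent oracles for the test suite

# straight chain along x at the given spacing (a valid conformation for
# spacing in {2, 3} under both excluded-volume modes)
straight_chain <- function(n, spacing = 2L, box = 64L, boundary = "closed",
                           excluded_volume = "cube", letters = "A") {
  co <- cbind(spacing * (seq_len(n) - 1L), 0L, 0L)
  lattice_conformation(co, residue_sequence(rep(letters, length.out = n)),
                       box, boundary, excluded_volume)
}

# independent O(N^2) pair-sum oracle for the total contact energy: explicit
# nested loops and the closed-form potential, no shared code with the package
oracle_total_energy <- function(conf, matrix, r_c = sqrt(8), sigma = 1) {
  co <- conf$coords
  L <- conf$box_size
  s <- unclass(conf$sequence)
  e <- 0
  n <- nrow(co)
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      d <- co[j, ] - co[i, ]
      if (conf$boundary == "periodic") d <- d - L * round(d / L)
      r <- sqrt(sum(d^2))
      if (r < r_c) {
        epsij <- unclass(matrix)[s[i], s[j]]
        e <- e + abs(epsij) * (sigma / r)^12 + epsij * (sigma / r)^6
      }
    }
  }
  e
}

# random valid conformations for property tests
random_conformations <- function(n_conf, n_res, box = 32L, seed0 = 100L,
                                 excluded_volume = "cube") {
  lapply(seq_len(n_conf), function(k)
    build_initial_conformation(random_sequence(n_res, seed = seed0 + k),
                               box, seed = seed0 + k,
                               excluded_volume = excluded_volume))
}
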