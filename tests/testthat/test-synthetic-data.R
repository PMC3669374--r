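test_that("random sequences are canonical, seeded and uniform", {
  s <- random_sequence(143, seed = 1)
  expect_length(s, 143)
  expect_true(all(unclass(s) %in% aa_alphabet()))
  expect_identical(unclass(random_sequence(143, seed = 1)), unclass(s))
  expect_false(identical(unclass(random_sequence(143, seed = 2)), unclass(s)))
  expect_error(random_sequence(1), ">= 2")

  # letter frequencies within 3 sigma of binomial at n = 1e5
  big <- unclass(random_sequence(1e5, seed = 2))
  counts <- table(factor(big, levels = aa_alphabet()))
  expt <- 1e5 / 20
  sd3 <- 3 * sqrt(1e5 * (1 / 20) * (19 / 20))
  expect_true(all(abs(counts - expt) <= sd3))
})

test_that("synthetic matrices have the promised structure", {
  m0 <- synthetic_matrix("null")
  expect_true(all(unclass(m0) == 0))
  conf <- random_conformations(1, 25, seed0 = 40)[[1]]
  expect_equal(total_energy(conf, m0), 0)

  mh <- synthetic_matrix("homopolymer", eps = -1)
  expect_true(all(unclass(mh) == -1))
  expect_identical(unclass(mh), t(unclass(mh)))

  hp <- synthetic_matrix("hp", eps = -2, hydrophobic = c("L", "V", "I", "F"))
  expect_equal(sum(unclass(hp) == -2), 16L)       # 4 x 4 hydrophobic block
  expect_equal(sum(unclass(hp) == 0), 400L - 16L)

  bl <- synthetic_matrix("block", groups = list(c("A", "G"), c("K", "R")),
                         block_eps = rbind(c(-1, 0.5), c(0.5, 2)))
  expect_equal(unclass(bl)["A", "G"], -1)
  expect_equal(unclass(bl)["K", "R"], 2)
  expect_equal(unclass(bl)["A", "K"], 0.5)
  expect_equal(unclass(bl)["A", "C"], 0)

  kd <- synthetic_matrix("hydropathy")
  expect_identical(unclass(kd), t(unclass(kd)))
  expect_lt(unclass(kd)["I", "I"], 0)             # hydrophobic pairs attract
  expect_gt(unclass(kd)["R", "K"], 0)             # charged pairs repel
  expect_equal(unclass(kd)["I", "I"], -(1 / 3) * 9)
})

test_that("matrix and sequence generators round-trip through the file formats", {
  kd <- synthetic_matrix("hydropathy")
  f <- withr::local_tempfile(fileext = ".csv")
  write_contact_matrix(kd, f)
  expect_equal(unclass(load_contact_matrix(f)), unclass(kd),
               ignore_attr = TRUE, tolerance = 1e-12)

  s <- histone_like_sequence(143, seed = 9)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_sequence(s, fa)
  expect_identical(unclass(read_fasta_sequence(fa)), unclass(s))
})

test_that("reference conformations carry their nominal mass dimension", {
  fit_de <- function(frames) {
    rg <- mean(vapply(frames, radius_of_gyration, numeric(1)))
    qs <- exp(seq(log(2 * pi / rg) - 0.6, log(2 * pi / rg) + 0.6,
                  length.out = 25))
    fit_effective_dimension(structure_factor(frames, qs, 200, seed = 4), rg)$D_e
  }
  rod <- reference_conformations("straight_rod", 100)
  expect_equal(fit_de(rod), 1, tolerance = 0.2)
  ball <- reference_conformations("compact_ball", 343)
  expect_equal(fit_de(ball), 3, tolerance = 0.1)
  walk <- reference_conformations("ideal_walk", 256, seed = 6,
                                  n_replicates = 20)
  expect_equal(fit_de(walk), 2, tolerance = 0.15)
})

test_that("exact enumeration is normalized and uniform for 2-mers", {
  m0 <- synthetic_matrix("null")
  en <- enumerate_boltzmann(residue_sequence("AC"), 5, m0, temperature = 1)
  expect_equal(sum(en$prob), 1, tolerance = 1e-12)
  # adjacent pairs carry no contact energy: exactly uniform
  expect_true(all(en$energy == 0))
  expect_equal(max(en$prob), min(en$prob))

  # independent nested-loop oracle for the same count (hash-free route)
  bv <- unclass(allowed_bond_vectors())
  count <- 0L
  for (x0 in 0:3) for (y0 in 0:3) for (z0 in 0:3)
    for (k in seq_len(nrow(bv))) {
      p <- c(x0, y0, z0) + bv[k, ]
      if (all(p >= 0 & p <= 3)) count <- count + 1L
    }
  expect_equal(nrow(en), count)
  expect_equal(length(unique(en$key)), nrow(en))
})

test_that("3-mer enumeration weights contacts by the Boltzmann factor", {
  mh <- synthetic_matrix("homopolymer", eps = -1)
  en <- enumerate_boltzmann(residue_sequence("AAA"), 6, mh, temperature = 0.5)
  expect_equal(sum(en$prob), 1, tolerance = 1e-12)
  # end pair at distance 2 (d2 = 4) is favoured over far states by
  # exp(+0.015380859375 / 0.5)
  p4 <- en$prob[en$d2_ends == 4][1]
  pfar <- en$prob[en$d2_ends >= 8][1]
  expect_equal(p4 / pfar, exp(0.015380859375 / 0.5), tolerance = 1e-12)
  # cube excluded volume: end pairs closer than 2 cannot occur
  expect_true(all(en$d2_ends >= 4))
  # site mode admits closer end pairs
  en_site <- enumerate_boltzmann(residue_sequence("AAA"), 6, mh,
                                 temperature = 0.5, excluded_volume = "site")
  expect_true(any(en_site$d2_ends < 4))
  expect_gt(nrow(en_site), nrow(en))

  expect_error(enumerate_boltzmann(residue_sequence("AAAA"), 6, mh,
                                   temperature = 1), "length 2 or 3")
  expect_error(enumerate_boltzmann(residue_sequence("AAA"), 40, mh,
                                   temperature = 1), "too large")
})

test_that("generated conformations all pass validation", {
  for (conf in random_conformations(5, 20, box = 16, seed0 = 60))
    expect_true(validate_conformation(conf)$valid)
  for (conf in random_conformations(3, 20, box = 16, seed0 = 70,
                                    excluded_volume = "site"))
    expect_true(validate_conformation(conf)$valid)
})
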