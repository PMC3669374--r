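test_that("pair energy follows the truncated generalized LJ closed form", {
  p <- interaction_params()
  expect_identical(pair_energy(0, 2, p), 0)
  expect_identical(pair_energy(-1, sqrt(8), p), 0)     # at the cutoff
  expect_identical(pair_energy(5, 10, p), 0)           # beyond the cutoff
  expect_equal(pair_energy(-1, 1, p), 0)               # core cancels well at r = sigma
  expect_equal(pair_energy(-1, 2, p), 1 / 4096 - 1 / 64)
  expect_equal(pair_energy(-1, 2, p), -0.015380859375)
  expect_equal(pair_energy(2, 2, p), 2 / 4096 + 2 / 64)
  # attractive minimum at r = 2^(1/6) sigma with depth |eps|/4
  expect_equal(pair_energy(-1, 2^(1 / 6), p), -0.25)
  rr <- seq(0.9, 1.6, by = 0.001)
  expect_equal(min(pair_energy(-1, rr, p)), -0.25, tolerance = 1e-5)
  expect_error(pair_energy(-1, 0, p), "r > 0")
  expect_error(interaction_params(r_c = 1, sigma = 2), "sigma")
})

test_that("interaction shell matches brute-force enumeration", {
  sh <- interaction_shell()
  expect_equal(nrow(sh), 92L)
  d2 <- rowSums(sh^2)
  expect_equal(as.vector(table(d2)), c(6L, 12L, 8L, 6L, 24L, 24L, 12L))
  expect_identical(sort(unique(d2)), c(1, 2, 3, 4, 5, 6, 8))
  # closed under sign flip
  key <- sort(paste(sh[, 1], sh[, 2], sh[, 3]))
  neg <- -sh
  expect_identical(sort(paste(neg[, 1], neg[, 2], neg[, 3])), key)
  expect_equal(nrow(interaction_shell(interaction_params(r_c = 2))), 32L)
})

test_that("contact matrix files load, validate and symmetrize", {
  aa <- aa_alphabet()
  m <- matrix(-1, 20, 20, dimnames = list(aa, aa))
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(m, f, quote = FALSE)
  cm <- load_contact_matrix(f)
  expect_s3_class(cm, "contact_matrix")
  expect_true(all(unclass(cm) == -1))

  # missing amino acid named in the error
  m19 <- m[-3, ]                                      # drop D
  utils::write.csv(m19, f, quote = FALSE)
  expect_error(load_contact_matrix(f), "D")

  # tiny asymmetry is averaged
  m2 <- m
  m2["A", "C"] <- -2
  m2["C", "A"] <- -2.0000001
  utils::write.csv(format(m2, digits = 12), f, quote = FALSE)
  cm2 <- load_contact_matrix(f)
  expect_equal(unclass(cm2)["A", "C"], -2.00000005)
  expect_equal(unclass(cm2)["C", "A"], -2.00000005)

  # gross asymmetry is rejected with the cell named
  m3 <- m
  m3["A", "C"] <- 5
  utils::write.csv(m3, f, quote = FALSE)
  expect_error(load_contact_matrix(f), "asymmetry.*\\(A,C\\)|asymmetry.*\\(C,A\\)")

  # whitespace-delimited tables are accepted too
  f2 <- withr::local_tempfile(fileext = ".txt")
  utils::write.table(m, f2, quote = FALSE)
  expect_true(all(unclass(load_contact_matrix(f2)) == -1))
})

test_that("contact matrices are remapped to the canonical alphabet order", {
  aa <- aa_alphabet()
  perm <- rev(aa)
  m <- outer(seq_along(aa), seq_along(aa), function(i, j) -(i + j) / 10)
  dimnames(m) <- list(perm, perm)
  cm <- contact_matrix(m, alphabet = perm)
  expect_identical(rownames(cm), aa)
  expect_equal(unclass(cm)["Y", "W"], m["Y", "W"])
  f <- withr::local_tempfile(fileext = ".csv")
  write_contact_matrix(cm, f)
  expect_equal(unclass(load_contact_matrix(f)), unclass(cm),
               ignore_attr = TRUE)
})

test_that("site energies realize the documented pair examples", {
  # 3-mer with end residues at distance 2 (non-adjacent pair in contact)
  co <- rbind(c(0, 0, 0), c(2, 2, 0), c(2, 0, 0))
  conf <- lattice_conformation(co, residue_sequence("AAA"), 16, "closed")
  expect_true(validate_conformation(conf)$valid)
  mH <- synthetic_matrix("homopolymer", eps = -1)
  expect_equal(site_energy(conf, 1, mH), -0.015380859375)
  expect_equal(site_energy(conf, 3, mH), -0.015380859375)
  expect_equal(site_energy(conf, 2, mH), 0)            # only adjacent partners
  expect_equal(total_energy(conf, mH), -0.015380859375)
  expect_error(site_energy(conf, 4, mH), "out of range")

  # straight chain at spacing 3: all non-adjacent pairs beyond the cutoff
  expect_equal(total_energy(straight_chain(10, spacing = 3, box = 32), mH), 0)
  # two-residue chain: only the adjacent pair exists
  expect_equal(total_energy(straight_chain(2, spacing = 2), mH), 0)
})

test_that("total energy agrees with an independent brute-force oracle", {
  mX <- synthetic_matrix("hydropathy")
  confs <- random_conformations(10, 40, box = 32, seed0 = 300)
  for (conf in confs) {
    e <- total_energy(conf, mX)
    expect_equal(e, oracle_total_energy(conf, mX), tolerance = 1e-9)
    # half the site-energy sum double-counts every pair
    prof <- residue_energy_profile(conf, mX)
    expect_equal(sum(prof) / 2, e, tolerance = 1e-9)
  }
})
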