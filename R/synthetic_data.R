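#' Random residue sequence
#'
#' Uniform i.i.d. draw over the 20-letter alphabet.
#'
#' @param n Length (at least 2).
#' @param seed Integer seed.
#' @return A [residue_sequence()].
#' @export
random_sequence <- function(n, seed = 1L) {
  if (n < 2L) stop("n must be >= 2")
  set.seed(seed)
  residue_sequence(sample(aa_alphabet(), n, replace = TRUE),
                   name = sprintf("random-%d-seed%d", n, seed))
}

# Kyte-Doolittle hydropathy scale (positive = hydrophobic)
kd_hydropathy <- function() {
  c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
    I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
    R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)[aa_alphabet()]
}

# approximate amino-acid composition of the histone H2A family: strongly
# basic (K+R ~ 22%) with an A/G/L/V-rich hydrophobic core
histone_composition <- function() {
  p <- c(A = 0.110, C = 0.005, D = 0.025, E = 0.055, F = 0.015, G = 0.095,
         H = 0.025, I = 0.035, K = 0.115, L = 0.085, M = 0.005, N = 0.025,
         P = 0.040, Q = 0.045, R = 0.100, S = 0.040, T = 0.040, V = 0.060,
         W = 0.000, Y = 0.020)[aa_alphabet()]
  p / sum(p)
}

#' Synthetic histone-like sequence
#'
#' A SYNTHETIC stand-in for a histone protein: residues drawn i.i.d. from an
#' approximate H2A-family composition (lysine/arginine-rich with a
#' hydrophobic core fraction). It emulates the composition, not the specific
#' residue order, of any real histone.
#'
#' @param n Length; default 143 (size of the H2A.X variant).
#' @param seed Integer seed.
#' @return A [residue_sequence()].
#' @export
histone_like_sequence <- function(n = 143L, seed = 1L) {
  set.seed(seed)
  residue_sequence(sample(aa_alphabet(), n, replace = TRUE,
                          prob = histone_composition()),
                   name = sprintf("synthetic-histone-like-%d-seed%d", n, seed))
}

#' Synthetic contact matrices with controlled attraction structure
#'
#' Test and study fixtures covering the interaction regimes the pipeline must
#' handle:
#' \describe{
#'   \item{`null`}{all zero — athermal chain, pure excluded volume.}
#'   \item{`homopolymer`}{all entries `eps` — uniform (homopolymer) coupling.}
#'   \item{`hp`}{`eps` for hydrophobic-hydrophobic pairs, 0 elsewhere.}
#'   \item{`block`}{block-structured: groups of residues with a k x k block
#'     strength matrix `block_eps`.}
#'   \item{`hydropathy`}{mixed-sign knowledge-based-like SYNTHETIC matrix,
#'     \eqn{\epsilon_{ij} = -s\,(h_i + h_j)} with \eqn{h} the Kyte-Doolittle
#'     hydropathy; hydrophobic pairs attract, polar/charged pairs repel.}
#' }
#'
#' @param kind Matrix kind.
#' @param eps Strength for `homopolymer`/`hp`; default -1.
#' @param hydrophobic Hydrophobic subset for `hp`.
#' @param groups For `block`: list of character vectors partitioning (part of)
#'   the alphabet; letters left out get zero couplings.
#' @param block_eps For `block`: k x k strengths between groups.
#' @param scale For `hydropathy`; default 1/3, giving entries up to about
#'   |3| (the magnitude range of published knowledge-based tables) and
#'   strongest-contact energies of roughly 4x the reduced temperature at the
#'   cold edge and 1x at the hot edge of the default 0.010-0.040 grid.
#' @return A [contact_matrix()].
#' @export
synthetic_matrix <- function(kind = c("null", "homopolymer", "hp", "block",
                                      "hydropathy"),
                             eps = -1,
                             hydrophobic = c("A", "V", "L", "I", "F", "M", "W", "C"),
                             groups = NULL, block_eps = NULL, scale = 1 / 3) {
  kind <- match.arg(kind)
  aa <- aa_alphabet()
  m <- matrix(0, 20L, 20L, dimnames = list(aa, aa))
  if (kind == "homopolymer") m[] <- eps
  else if (kind == "hp") m[hydrophobic, hydrophobic] <- eps
  else if (kind == "block") {
    if (is.null(groups) || is.null(block_eps))
      stop("block matrix needs 'groups' and 'block_eps'")
    block_eps <- as.matrix(block_eps)
    k <- length(groups)
    if (!all(dim(block_eps) == c(k, k)))
      stop("block_eps must be ", k, "x", k)
    for (a in seq_len(k))
      for (b in seq_len(k))
        m[groups[[a]], groups[[b]]] <- (block_eps[a, b] + block_eps[b, a]) / 2
  } else if (kind == "hydropathy") {
    h <- kd_hydropathy()
    m <- -scale * outer(h, h, `+`)
  }
  contact_matrix(m, label = paste0("synthetic-", kind))
}

#' Reference conformations with known mass dimension
#'
#' Off-lattice oracle geometries for structure-factor scaling tests:
#' `straight_rod` (collinear points, dimension 1), `ideal_walk` (Gaussian-step
#' chain, dimension 2), `compact_ball` (n sites filling a lattice sphere,
#' dimension 3).
#'
#' @param kind Geometry kind.
#' @param n Number of points (at least 8).
#' @param seed Seed (used by `ideal_walk`).
#' @param n_replicates Number of independent replicates; default 1.
#' @param step Bond length scale; default 2 (comparable to the lattice chain).
#' @return List of `n_replicates` numeric n x 3 matrices.
#' @export
reference_conformations <- function(kind = c("ideal_walk", "compact_ball",
                                             "straight_rod"),
                                    n, seed = 1L, n_replicates = 1L, step = 2) {
  kind <- match.arg(kind)
  if (n < 8L) stop("n must be >= 8")
  set.seed(seed)
  one <- function() {
    switch(kind,
      straight_rod = cbind(step * (seq_len(n) - 1), 0, 0),
      ideal_walk = apply(matrix(stats::rnorm(3L * n, sd = step / sqrt(3)),
                                n, 3L), 2L, cumsum),
      compact_ball = {
        m <- ceiling((3 * n / (4 * pi))^(1 / 3)) + 2L
        g <- as.matrix(expand.grid(x = -m:m, y = -m:m, z = -m:m))
        g[order(rowSums(g^2))[seq_len(n)], , drop = FALSE]
      })
  }
  lapply(seq_len(n_replicates), function(k) one())
}

# closed-box site grid as integer matrix
box_sites <- function(L) {
  as.matrix(expand.grid(x = 0:(L - 1L), y = 0:(L - 1L), z = 0:(L - 1L)))
}

#' Exact Boltzmann enumeration for tiny chains
#'
#' Brute-force enumeration of every valid conformation of a 2- or 3-residue
#' chain in a small closed box, with energies from [total_energy()]'s pair
#' rule and probabilities proportional to \eqn{e^{-E/T}}. Serves as the
#' independent oracle for the Metropolis engine: adjacent pairs carry no
#' contact energy, so the only energetic degree of freedom of a 3-mer is the
#' end-pair distance.
#'
#' @param sequence A [residue_sequence()] of length 2 or 3.
#' @param box_size Closed-box edge (at most 6 recommended).
#' @param matrix A [contact_matrix()].
#' @param params An [interaction_params()].
#' @param temperature Reduced temperature.
#' @param bond_set Allowed bond vectors.
#' @param excluded_volume `"cube"` (default) or `"site"`, matching the
#'   conformations being checked.
#' @param max_states Refusal threshold on the enumeration size; default 2e7.
#' @return Data frame, one row per valid state: `key` (site-index encoding of
#'   the coordinates), `d2_ends` (squared end-pair distance; `NA` for 2-mers),
#'   `energy`, `prob` (sums to 1).
#' @export
enumerate_boltzmann <- function(sequence, box_size, matrix,
                                params = interaction_params(), temperature,
                                bond_set = allowed_bond_vectors(),
                                excluded_volume = c("cube", "site"),
                                max_states = 2e7) {
  excluded_volume <- match.arg(excluded_volume)
  cube <- excluded_volume == "cube"
  n <- length(sequence)
  if (n > 3L) stop("enumeration supports chains of length 2 or 3")
  L <- as.integer(box_size)
  hi <- if (cube) L - 1L else L     # closed box: the cube must fit inside
  bv <- unclass(bond_set)
  est <- as.numeric(L^3) * nrow(bv)^(n - 1L)
  if (est > max_states)
    stop("state space too large to enumerate (~", format(est, digits = 3),
         " raw states)")
  sites <- box_sites(L)
  sites <- sites[sites[, 1L] < hi & sites[, 2L] < hi & sites[, 3L] < hi, ,
                 drop = FALSE]
  # state key: positional encoding sum_i idx_i * (L^3)^i, exact in doubles
  idx1 <- sites[, 1L] + L * sites[, 2L] + L^2 * sites[, 3L]

  rows <- list()
  for (s0 in seq_len(nrow(sites))) {
    p0 <- sites[s0, ]
    p1 <- sweep(bv, 2L, p0, `+`)
    ok1 <- p1[, 1L] >= 0L & p1[, 1L] < hi & p1[, 2L] >= 0L & p1[, 2L] < hi &
      p1[, 3L] >= 0L & p1[, 3L] < hi
    p1 <- p1[ok1, , drop = FALSE]
    if (nrow(p1) == 0L) next
    i0 <- idx1[s0]
    i1 <- p1[, 1L] + L * p1[, 2L] + L^2 * p1[, 3L]
    if (n == 2L) {
      rows[[length(rows) + 1L]] <- data.frame(
        key = i0 + as.numeric(L^3) * i1, d2_ends = NA_real_, energy = 0)
      next
    }
    # third residue: every bond from every valid second position
    nb <- nrow(bv)
    rep1 <- rep(seq_len(nrow(p1)), each = nb)
    p2 <- p1[rep1, , drop = FALSE] + bv[rep(seq_len(nb), times = nrow(p1)), , drop = FALSE]
    ok2 <- p2[, 1L] >= 0L & p2[, 1L] < hi & p2[, 2L] >= 0L & p2[, 2L] < hi &
      p2[, 3L] >= 0L & p2[, 3L] < hi
    i2 <- p2[, 1L] + L * p2[, 2L] + L^2 * p2[, 3L]
    ok2 <- ok2 & i2 != i0 & i2 != i1[rep1]          # excluded volume (anchors)
    if (cube) {
      # non-adjacent pair (1,3): cubes overlap unless some |delta| >= 2
      # (bonded pairs can never overlap: every bond has a component >= 2)
      dd <- abs(sweep(p2, 2L, p0))
      ok2 <- ok2 & (dd[, 1L] >= 2L | dd[, 2L] >= 2L | dd[, 3L] >= 2L)
    }
    if (!any(ok2)) next
    d2e <- rowSums(sweep(p2[ok2, , drop = FALSE], 2L, p0)^2)
    s <- unclass(sequence)
    epair <- unclass(matrix)[s[1L], s[3L]]
    en <- ifelse(d2e < params$r_c^2 - 1e-12,
                 pair_energy(epair, sqrt(d2e), params), 0)
    rows[[length(rows) + 1L]] <- data.frame(
      key = i0 + as.numeric(L^3) * i1[rep1[ok2]] +
        as.numeric(L^3)^2 * i2[ok2],
      d2_ends = d2e, energy = en)
  }
  st <- do.call(rbind, rows)
  w <- exp(-st$energy / temperature)
  st$prob <- w / sum(w)
  st
}
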