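#' Radius of gyration
#'
#' Root-mean-square distance of points from their centroid. Coordinates must
#' be unwrapped (no periodic folding).
#'
#' @param coords Numeric n x 3 matrix.
#' @return \eqn{R_g}.
#' @export
radius_of_gyration <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1L) stop("radius_of_gyration needs at least one point")
  c0 <- colMeans(coords)
  sqrt(mean(rowSums(sweep(coords, 2L, c0)^2)))
}

#' Residue contact map of a conformation
#'
#' All unordered pairs `(i, j)` with `|i - j| > 1` whose minimum-image
#' distance is below the interaction cutoff — the same criterion the energy
#' evaluation uses, so every listed contact carries pair energy unless its
#' \eqn{\epsilon_{ij} = 0}.
#'
#' @param conf A [lattice_conformation()].
#' @param params An [interaction_params()].
#' @return Object of class `contact_map`: data frame with columns `i`, `j`
#'   (`i < j`), plus attributes `n` (chain length) and `r_c`.
#' @export
contact_map <- function(conf, params = interaction_params()) {
  n <- nrow(conf$coords)
  pairs <- list()
  for (i in seq_len(max(0L, n - 2L))) {
    d2 <- conf_sq_dists(conf, i)
    j <- (i + 2L):n
    j <- j[d2[j] < params$r_c^2 - 1e-12]
    if (length(j)) pairs[[length(pairs) + 1L]] <- data.frame(i = i, j = j)
  }
  cm <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(i = integer(), j = integer())
  structure(cm, n = n, r_c = params$r_c, class = c("contact_map", "data.frame"))
}

#' Ensemble contact-frequency map
#'
#' Fraction of supplied conformations in which each non-adjacent pair is in
#' contact.
#'
#' @param confs List of [lattice_conformation()]s.
#' @param params An [interaction_params()].
#' @return Data frame `i`, `j`, `freq`.
#' @export
contact_frequency_map <- function(confs, params = interaction_params()) {
  maps <- lapply(confs, function(cf) contact_map(cf, params))
  all <- do.call(rbind, lapply(maps, function(m) as.data.frame(m)))
  if (nrow(all) == 0L)
    return(data.frame(i = integer(), j = integer(), freq = numeric()))
  ag <- stats::aggregate(list(count = rep(1L, nrow(all))),
                         by = all[c("i", "j")], FUN = sum)
  ag$freq <- ag$count / length(confs)
  ag[order(ag$i, ag$j), c("i", "j", "freq")]
}

# seeded unit directions, uniform on the sphere
sphere_directions <- function(n, seed) {
  set.seed(seed)
  d <- matrix(stats::rnorm(3L * n), n, 3L)
  d / sqrt(rowSums(d^2))
}

#' Spherically averaged single-chain structure factor
#'
#' \deqn{S(q) = \frac{1}{N}\left\langle \left|\sum_j e^{i q \cdot r_j}\right|^2
#' \right\rangle} averaged over seeded random unit directions per wave-vector
#' magnitude \eqn{|q| = 2\pi/\lambda} (and over frames when a list of
#' coordinate sets is given). Satisfies \eqn{S(q\to 0) = N} and, over the
#' window of wavelengths comparable to the chain size, the power law
#' \eqn{S(q) \propto q^{-D_e}} with \eqn{D_e} the effective dimension of the
#' mass distribution.
#'
#' @param coords Numeric n x 3 matrix of unwrapped positions, or a list of
#'   such matrices (frames) to average over.
#' @param q_magnitudes Positive wave-vector magnitudes.
#' @param n_directions Directions per magnitude; default 50.
#' @param seed Seed for the direction sample.
#' @param directions Optional matrix of unit direction vectors (one per row)
#'   overriding the random sample, e.g. a single axis for lattice-exact or
#'   analytic checks.
#' @return Object of class `sq_table`: data frame `q`, `s` with attributes
#'   `n` (chain length), `n_directions`, `n_frames`.
#' @export
structure_factor <- function(coords, q_magnitudes, n_directions = 50L,
                             seed = 1L, directions = NULL) {
  frames <- if (is.list(coords)) coords else list(coords)
  frames <- lapply(frames, as.matrix)
  if (any(q_magnitudes <= 0)) stop("q magnitudes must be positive")
  n <- nrow(frames[[1L]])
  dirs <- if (is.null(directions)) sphere_directions(n_directions, seed) else
    as.matrix(directions)
  n_directions <- nrow(dirs)
  s <- vapply(q_magnitudes, function(q) {
    mean(vapply(frames, function(r) {
      ph <- q * (dirs %*% t(r))          # n_directions x n phases
      mean(rowSums(cos(ph))^2 + rowSums(sin(ph))^2) / n
    }, numeric(1L)))
  }, numeric(1L))
  structure(data.frame(q = q_magnitudes, s = s),
            n = n, n_directions = n_directions, n_frames = length(frames),
            class = c("sq_table", "data.frame"))
}

#' Time-averaged mean-square displacement of the centre of mass
#'
#' @param traj A `trajectory_record` (its unwrapped COM series is used), or a
#'   numeric matrix of COM positions.
#' @param lag Lag in records (0 to series length - 1).
#' @return MSD at the given lag, lattice constants squared.
#' @export
com_msd <- function(traj, lag) {
  com <- if (inherits(traj, "trajectory_record"))
    as.matrix(traj$records[, c("com_x", "com_y", "com_z")]) else as.matrix(traj)
  m <- nrow(com)
  if (lag < 0L || lag >= m) stop("lag out of range")
  if (lag == 0L) return(0)
  idx <- seq_len(m - lag)
  mean(rowSums((com[idx + lag, , drop = FALSE] - com[idx, , drop = FALSE])^2))
}

#' Per-residue contact-energy profile
#'
#' [site_energy()] for every residue; sums to twice [total_energy()] because
#' each pair is counted from both ends.
#'
#' @inheritParams site_energy
#' @return Numeric vector of length N.
#' @export
residue_energy_profile <- function(conf, matrix, params = interaction_params()) {
  vapply(seq_len(nrow(conf$coords)), function(i)
    site_energy(conf, i, matrix, params), numeric(1L))
}

#' Export a contact map as sparse triplets
#'
#' @param map A [contact_map()].
#' @param path Output CSV path (`i,j,value`).
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path) {
  df <- as.data.frame(map)
  df$value <- rep(1L, nrow(df))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
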