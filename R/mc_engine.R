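#' Monte Carlo run configuration
#'
#' @param temperature Reduced temperature \eqn{T > 0} (units of the
#'   Boltzmann constant times the contact-energy scale).
#' @param n_mcs Number of Monte Carlo steps; one MCS is N attempted
#'   single-residue moves.
#' @param seed Integer seed making the whole run reproducible.
#' @param move_neighborhood `"6-axial"` unit displacements (default) or
#'   `"26-cell"`.
#' @param record_every Sweeps between observable records; default gives about
#'   200 records.
#' @param burn_in_fraction Leading fraction of sweeps flagged as equilibration
#'   and dropped from ensemble statistics; default 0.5.
#' @return Object of class `mc_config`.
#' @export
mc_config <- function(temperature = 1, n_mcs = 1000L, seed = 1L,
                      move_neighborhood = c("6-axial", "26-cell"),
                      record_every = NULL, burn_in_fraction = 0.5) {
  move_neighborhood <- match.arg(move_neighborhood)
  if (temperature <= 0) stop("temperature must be > 0")
  n_mcs <- as.integer(n_mcs)
  if (n_mcs < 1L) stop("n_mcs must be >= 1")
  if (burn_in_fraction < 0 || burn_in_fraction >= 1)
    stop("burn_in_fraction must be in [0, 1)")
  if (is.null(record_every)) record_every <- max(1L, n_mcs %/% 200L)
  structure(list(temperature = temperature, n_mcs = n_mcs,
                 seed = as.integer(seed),
                 move_neighborhood = move_neighborhood,
                 record_every = as.integer(record_every),
                 burn_in_fraction = burn_in_fraction),
            class = "mc_config")
}

#' Single Metropolis move attempt
#'
#' Reference implementation of one move: the proposal is rejected outright if
#' the target site is occupied, outside a closed box, or if either affected
#' bond leaves the allowed set; otherwise the local energy change is computed
#' and the move accepted iff `u < min(1, exp(-dE/T))`.
#'
#' @param conf A [lattice_conformation()].
#' @param i Residue index (1-based).
#' @param proposal Integer displacement 3-vector.
#' @param temperature Reduced temperature.
#' @param matrix A [contact_matrix()].
#' @param params An [interaction_params()].
#' @param u Uniform random number in `[0, 1)`.
#' @param bond_set Allowed bond vectors.
#' @return List: `accepted`, `delta_e` (`NA` on geometric rejection), and
#'   `conf` (mutated only on acceptance).
#' @export
attempt_move <- function(conf, i, proposal, temperature, matrix,
                         params = interaction_params(), u,
                         bond_set = allowed_bond_vectors()) {
  L <- conf$box_size
  new_pos <- conf$coords[i, ] + as.integer(proposal)
  if (conf$boundary == "periodic") new_pos <- new_pos %% L
  else if (any(new_pos < 0L | new_pos >= L))
    return(list(accepted = FALSE, delta_e = NA_real_, conf = conf))
  key <- function(p) p[1L] + as.numeric(L) * p[2L] + as.numeric(L)^2 * p[3L]
  occ_keys <- conf$coords[, 1L] + as.numeric(L) * conf$coords[, 2L] +
    as.numeric(L)^2 * conf$coords[, 3L]
  if (key(new_pos) %in% occ_keys[-i])
    return(list(accepted = FALSE, delta_e = NA_real_, conf = conf))
  if ((conf$excluded_volume %||% "cube") == "cube") {
    d <- min_image(sweep(conf$coords[-i, , drop = FALSE], 2L, new_pos),
                   L, conf$boundary)
    if (any(apply(abs(d), 1L, max) < 2L))
      return(list(accepted = FALSE, delta_e = NA_real_, conf = conf))
  }
  ok2 <- sort(unique(bond_sqlens(bond_set)))
  for (j in c(i - 1L, i + 1L)) {
    if (j < 1L || j > nrow(conf$coords)) next
    dv <- min_image(conf$coords[j, ] - new_pos, L, conf$boundary)
    if (!(sum(dv^2) %in% ok2))
      return(list(accepted = FALSE, delta_e = NA_real_, conf = conf))
  }
  e_old <- site_energy(conf, i, matrix, params)
  trial <- conf
  trial$coords[i, ] <- as.integer(new_pos)
  e_new <- site_energy(trial, i, matrix, params)
  de <- e_new - e_old
  acc <- u < min(1, exp(-de / temperature))
  list(accepted = acc, delta_e = de, conf = if (acc) trial else conf)
}

engine_call <- function(conf, matrix, config, params, n_mcs, record_every,
                        record_frames = FALSE, record_site_energy = FALSE,
                        bond_set = allowed_bond_vectors()) {
  cpp_run_mc(conf$coords, sequence_codes(conf$sequence), unclass(matrix),
             unclass(bond_set), config$temperature, as.integer(n_mcs),
             as.integer(record_every), conf$box_size,
             conf$boundary == "periodic", params$r_c, params$sigma,
             if (config$move_neighborhood == "26-cell") 26L else 6L,
             (conf$excluded_volume %||% "cube") == "cube",
             record_frames, record_site_energy)
}

#' Run Monte Carlo sweeps on a conformation
#'
#' Performs `n_mcs` sweeps of N attempted moves each (residues chosen
#' uniformly at random with replacement) and returns the updated conformation
#' with sweep statistics. Uses the current RNG stream; call `set.seed()`
#' first for reproducibility.
#'
#' @param conf A [lattice_conformation()].
#' @param matrix A [contact_matrix()].
#' @param config An [mc_config()] (its `seed` field is not consulted here).
#' @param params An [interaction_params()].
#' @param n_mcs Number of sweeps; default 1.
#' @param bond_set Allowed bond vectors.
#' @return List: `conf` (updated), `acceptance_rate`, `energy` (running total
#'   after the sweeps), `recomputed_energy` (full shell recompute).
#' @export
run_mcs <- function(conf, matrix, config, params = interaction_params(),
                    n_mcs = 1L, bond_set = allowed_bond_vectors()) {
  res <- engine_call(conf, matrix, config, params, n_mcs, as.integer(n_mcs),
                     bond_set = bond_set)
  newc <- lattice_conformation(res$final_coords, conf$sequence,
                               conf$box_size, conf$boundary,
                               conf$excluded_volume %||% "cube")
  list(conf = newc, acceptance_rate = res$acc_rate[length(res$acc_rate)],
       energy = res$final_energy, recomputed_energy = res$recomputed_energy)
}

#' Simulate a tethered chain at one temperature
#'
#' Builds a self-avoiding initial conformation from the seed, then runs
#' Metropolis dynamics, recording total energy, radius of gyration (from
#' unwrapped coordinates), unwrapped centre of mass and acceptance rate every
#' `record_every` sweeps. Fully reproducible for a fixed seed.
#'
#' @param sequence A [residue_sequence()].
#' @param matrix A [contact_matrix()].
#' @param config An [mc_config()].
#' @param params An [interaction_params()].
#' @param box_size Lattice edge; default 64.
#' @param boundary `"periodic"` or `"closed"`.
#' @param excluded_volume `"cube"` (default) or `"site"`, see
#'   [lattice_conformation()].
#' @param bond_set Allowed bond vectors.
#' @param record_frames Keep unwrapped coordinates at every record (needed for
#'   structure factors and contact statistics along the run).
#' @param record_site_energy Keep per-residue energies at every record.
#' @param init Optional starting [lattice_conformation()] (skips growth).
#' @return Object of class `trajectory_record`: `records` data frame (`time`,
#'   `energy`, `rg`, `com_x/y/z`, `acc_rate`, `burn_in`), `final` conformation,
#'   `final_unwrapped` coordinates, optional `frames` list, and metadata.
#' @export
simulate_chain <- function(sequence, matrix, config,
                           params = interaction_params(), box_size = 64L,
                           boundary = c("periodic", "closed"),
                           excluded_volume = c("cube", "site"),
                           bond_set = allowed_bond_vectors(),
                           record_frames = FALSE, record_site_energy = FALSE,
                           init = NULL) {
  boundary <- match.arg(boundary)
  excluded_volume <- match.arg(excluded_volume)
  set.seed(config$seed)
  conf <- if (is.null(init)) {
    build_initial_conformation(sequence, box_size, bond_set, seed = NULL,
                               boundary = boundary,
                               excluded_volume = excluded_volume)
  } else init
  res <- engine_call(conf, matrix, config, params, config$n_mcs,
                     config$record_every, record_frames, record_site_energy,
                     bond_set)
  n <- length(sequence)
  records <- data.frame(time = res$times, energy = res$energies,
                        rg = res$rg, com_x = res$com[, 1L],
                        com_y = res$com[, 2L], com_z = res$com[, 3L],
                        acc_rate = res$acc_rate)
  records$burn_in <- records$time <= config$burn_in_fraction * config$n_mcs
  frames <- NULL
  if (record_frames)
    frames <- lapply(seq_len(nrow(res$frames)), function(k)
      base::matrix(res$frames[k, ], n, 3L))
  out <- list(records = records,
              final = lattice_conformation(res$final_coords, sequence,
                                           box_size, boundary,
                                           conf$excluded_volume %||% "cube"),
              final_unwrapped = res$final_unwrapped,
              final_energy = res$final_energy,
              recomputed_energy = res$recomputed_energy,
              frames = frames,
              site_energies = if (record_site_energy) res$site_energies,
              config = config, params = params, box_size = box_size,
              boundary = boundary)
  class(out) <- "trajectory_record"
  out
}

#' @export
print.trajectory_record <- function(x, ...) {
  cat("trajectory_record:", nrow(x$records), "records over",
      x$config$n_mcs, "MCS at T =", x$config$temperature, "\n")
  invisible(x)
}

# deterministic, order-independent per-sample seed stream
derive_seeds <- function(master_seed, n) {
  p <- 2147483629
  as.integer((as.numeric(master_seed) %% p * 48271 + 66421 * seq_len(n)) %% p) + 1L
}

#' Run an ensemble of independent trajectories
#'
#' Per-sample seeds are derived deterministically from `master_seed`, so the
#' ensemble is reproducible as a set and independent of execution order.
#'
#' @inheritParams simulate_chain
#' @param n_samples Number of independent runs.
#' @param master_seed Integer master seed.
#' @param ... Passed to [simulate_chain()].
#' @return List of `trajectory_record`s with the seed vector as attribute
#'   `seeds`.
#' @export
run_ensemble <- function(sequence, matrix, config, n_samples, master_seed,
                         ...) {
  if (n_samples < 1L) stop("n_samples must be >= 1")
  seeds <- derive_seeds(master_seed, n_samples)
  out <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- s
    simulate_chain(sequence, matrix, cfg, ...)
  })
  attr(out, "seeds") <- seeds
  out
}
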