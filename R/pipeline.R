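#' Default run configuration
#'
#' Defaults mirror the full study conditions (64^3 lattice, 1e7 MCS, 150
#' samples, temperature grid 0.010-0.040 step 0.001); [desk_profile()] gives a
#' scaled-down profile for interactive work and tests.
#'
#' @return Named list of configuration defaults.
#' @export
default_run_config <- function() {
  list(sequence_path = NULL, matrix_path = NULL,
       synthetic_sequence = NULL,          # e.g. list(kind="histone_like", n=143)
       synthetic_matrix = NULL,            # e.g. list(kind="hydropathy")
       temperatures = seq(0.010, 0.040, by = 0.001),
       temperature = 1,
       n_mcs = 1e7, n_samples = 150L, box_size = 64L, seed = 1L,
       boundary = "periodic", excluded_volume = "cube",
       move_neighborhood = "6-axial",
       exclude_sqrt8 = FALSE, burn_in_fraction = 0.5, record_every = NULL,
       threshold = 0.25, n_directions = 50L, fit_width_decades = 0.5,
       output_dir = "latticefold-run", resume = FALSE)
}

#' Scaled-down "desk" configuration profile
#'
#' @return Named list overriding [default_run_config()] with sizes suited to
#'   a single CPU (32^3 box, 1e4 MCS, 8 samples, coarser grid).
#' @export
desk_profile <- function() {
  list(box_size = 32L, n_mcs = 1e4, n_samples = 8L,
       temperatures = seq(0.010, 0.040, by = 0.0025))
}

#' Load and validate a run configuration
#'
#' @param config Path to a YAML or JSON file, or a named list of overrides.
#' @param ... Further overrides applied last.
#' @return Validated configuration list.
#' @export
load_run_config <- function(config = list(), ...) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_run_config(), config)
  cfg <- utils::modifyList(cfg, list(...))
  for (p in c("sequence_path", "matrix_path"))
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop(p, " does not exist: ", cfg[[p]])
  if (cfg$n_mcs < 1 || cfg$n_samples < 1 || cfg$box_size < 4)
    stop("n_mcs, n_samples and box_size must be positive (box_size >= 4)")
  if (!cfg$boundary %in% c("periodic", "closed"))
    stop("boundary must be 'periodic' or 'closed'")
  cfg
}

config_sequence <- function(cfg) {
  if (!is.null(cfg$sequence_path)) return(read_fasta_sequence(cfg$sequence_path))
  sp <- cfg$synthetic_sequence %||% list(kind = "histone_like", n = 143L, seed = cfg$seed)
  switch(sp$kind %||% "histone_like",
         histone_like = histone_like_sequence(sp$n %||% 143L, sp$seed %||% cfg$seed),
         random = random_sequence(sp$n %||% 143L, sp$seed %||% cfg$seed),
         stop("unknown synthetic sequence kind: ", sp$kind))
}

config_matrix <- function(cfg) {
  if (!is.null(cfg$matrix_path)) return(load_contact_matrix(cfg$matrix_path))
  sp <- cfg$synthetic_matrix %||% list(kind = "hydropathy")
  do.call(synthetic_matrix, sp)
}

config_mc <- function(cfg, temperature = cfg$temperature, seed = cfg$seed) {
  mc_config(temperature = temperature, n_mcs = cfg$n_mcs, seed = seed,
            move_neighborhood = cfg$move_neighborhood,
            record_every = cfg$record_every,
            burn_in_fraction = cfg$burn_in_fraction)
}

write_metadata <- function(cfg, path, extra = list()) {
  meta <- c(cfg[!vapply(cfg, is.null, logical(1L))], extra,
            list(package_version = as.character(utils::packageVersion("latticefold"))))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run a single-temperature simulation job
#'
#' Runs one (sequence, matrix, T) trajectory and writes `trajectory.csv`,
#' `snapshot.txt` (final conformation) and `metadata.json` into the output
#' directory.
#'
#' @param config Configuration (path or list), see [load_run_config()].
#' @param ... Overrides.
#' @return Invisibly, named vector of the three file paths.
#' @export
run_simulation_job <- function(config = list(), ...) {
  cfg <- load_run_config(config, ...)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  seqn <- config_sequence(cfg)
  mat <- config_matrix(cfg)
  traj <- simulate_chain(seqn, mat, config_mc(cfg),
                         interaction_params(), cfg$box_size, cfg$boundary,
                         cfg$excluded_volume,
                         allowed_bond_vectors(cfg$exclude_sqrt8))
  paths <- c(trajectory = file.path(cfg$output_dir, "trajectory.csv"),
             snapshot = file.path(cfg$output_dir, "snapshot.txt"),
             metadata = file.path(cfg$output_dir, "metadata.json"))
  utils::write.csv(traj$records, paths["trajectory"], row.names = FALSE,
                   quote = FALSE)
  write_snapshot(traj$final, paths["snapshot"])
  write_metadata(cfg, paths["metadata"],
                 list(matrix_label = attr(mat, "label"),
                      sequence_name = attr(seqn, "name"),
                      final_energy = traj$final_energy))
  invisible(paths)
}

#' Run a full temperature-sweep job
#'
#' Ensemble sweep over the configured grid; per-temperature results are cached
#' as `sweep_T*.csv` so an interrupted job can resume (`resume = TRUE` skips
#' completed temperatures). Writes `sweep.csv` and `summary.json` containing
#' \eqn{T_c} and the response window when an interior peak exists.
#'
#' @inheritParams run_simulation_job
#' @return Invisibly, list with `sweep` (the table) and `summary`.
#' @export
run_sweep_job <- function(config = list(), ...) {
  cfg <- load_run_config(config, ...)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  seqn <- config_sequence(cfg)
  mat <- config_matrix(cfg)
  rows <- list()
  for (k in seq_along(cfg$temperatures)) {
    tt <- cfg$temperatures[k]
    cache <- file.path(cfg$output_dir, sprintf("sweep_T%0.6f.csv", tt))
    if (cfg$resume && file.exists(cache)) {
      rows[[k]] <- utils::read.csv(cache)
      next
    }
    ens <- run_ensemble(seqn, mat, config_mc(cfg, temperature = tt),
                        cfg$n_samples, cfg$seed + 104729 * (k - 1L),
                        box_size = cfg$box_size, boundary = cfg$boundary,
                        excluded_volume = cfg$excluded_volume,
                        bond_set = allowed_bond_vectors(cfg$exclude_sqrt8))
    rg <- vapply(ens, equilibrium_rg, numeric(1L))
    rows[[k]] <- data.frame(temperature = tt, rg_mean = mean(rg),
                            rg_sem = stats::sd(rg) / sqrt(length(rg)),
                            n_samples = length(rg))
    utils::write.csv(rows[[k]], cache, row.names = FALSE, quote = FALSE)
  }
  sweep <- structure(do.call(rbind, rows), label = attr(mat, "label"),
                     class = c("sweep_table", "data.frame"))
  write_sweep_table(sweep, file.path(cfg$output_dir, "sweep.csv"))
  summ <- tryCatch(response_window(sweep, cfg$threshold), error = function(e)
    list(error = conditionMessage(e)))
  jsonlite::write_json(c(unclass(summ), list(matrix_label = attr(mat, "label"))),
                       file.path(cfg$output_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(sweep = sweep, summary = summ))
}

#' Analyze snapshots: structure factor, effective dimension, contact map
#'
#' Takes one or more snapshot files written by [write_snapshot()], computes
#' the spherically averaged structure factor, fits the effective dimension on
#' the window around \eqn{q^* = 2\pi/R_g}, and writes the per-snapshot contact
#' maps.
#'
#' @param snapshot_paths Character vector of snapshot files.
#' @param config Configuration (path or list).
#' @param ... Overrides.
#' @return Invisibly, list with `sq` table, `D_e` fit, `rg`.
#' @export
run_analysis_job <- function(snapshot_paths, config = list(), ...) {
  cfg <- load_run_config(config, ...)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  missing <- snapshot_paths[!file.exists(snapshot_paths)]
  if (length(missing)) stop("snapshot file(s) not found: ",
                            paste(missing, collapse = ", "))
  confs <- lapply(snapshot_paths, read_snapshot)
  frames <- lapply(confs, function(cf) cf$coords)
  rg <- mean(vapply(frames, radius_of_gyration, numeric(1L)))
  qgrid <- exp(seq(log(2 * pi / rg) - 1.5, log(2 * pi / rg) + 1.5,
                   length.out = 40L))
  qgrid <- qgrid[qgrid <= pi * sqrt(3)]
  sq <- structure_factor(frames, qgrid, cfg$n_directions, cfg$seed)
  utils::write.csv(as.data.frame(sq), file.path(cfg$output_dir, "sq.csv"),
                   row.names = FALSE, quote = FALSE)
  de <- tryCatch(fit_effective_dimension(sq, rg, cfg$fit_width_decades),
                 error = function(e) list(error = conditionMessage(e)))
  jsonlite::write_json(c(de, list(rg = rg)),
                       file.path(cfg$output_dir, "effective_dimension.json"),
                       auto_unbox = TRUE, digits = NA)
  for (k in seq_along(confs))
    write_contact_map(contact_map(confs[[k]]),
                      file.path(cfg$output_dir,
                                sprintf("contact_map_%02d.csv", k)))
  invisible(list(sq = sq, D_e = de, rg = rg))
}
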