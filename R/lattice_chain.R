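#' Allowed bond vectors of the fluctuating-bond chain
#'
#' Consecutive residues are joined by a bond whose length fluctuates between
#' 2 and sqrt(10) lattice constants: every integer 3-vector with squared
#' length in \{4, 5, 6, 8, 9, 10\}. The sqrt(8) class (signed permutations of
#' (2,2,0)) can be excluded, which recovers the classical 108-vector
#' bond-fluctuation set that prevents chain crossing.
#'
#' @param exclude_sqrt8 Drop the \eqn{|v|^2 = 8} class? Default `FALSE`.
#' @return Integer matrix (one vector per row) of class `bond_vector_set`,
#'   closed under sign flips and coordinate permutations.
#' @export
allowed_bond_vectors <- function(exclude_sqrt8 = FALSE) {
  g <- as.matrix(expand.grid(x = -3:3, y = -3:3, z = -3:3))
  d2 <- rowSums(g^2)
  keep <- d2 >= 4 & d2 <= 10
  if (exclude_sqrt8) keep <- keep & d2 != 8
  v <- g[keep, , drop = FALSE]
  dimnames(v) <- list(NULL, c("x", "y", "z"))
  structure(v, exclude_sqrt8 = exclude_sqrt8, class = c("bond_vector_set", "matrix"))
}

# squared-length lookup used by validators
bond_sqlens <- function(bond_set) rowSums(unclass(bond_set)^2)

#' Construct a lattice conformation
#'
#' @param coords Integer N x 3 matrix of lattice sites, one residue per row,
#'   all coordinates in `[0, box_size)`.
#' @param sequence A [residue_sequence()] of matching length.
#' @param box_size Lattice edge L (e.g. 64).
#' @param boundary `"periodic"` (minimum-image distances) or `"closed"`.
#' @param excluded_volume `"cube"` (default): a residue occupies the 8 sites
#'   of the unit cube anchored at its coordinate, the classical
#'   bond-fluctuation excluded volume, under which chains show self-avoiding
#'   statistics already at short lengths; `"site"`: only the anchor site is
#'   excluded.
#' @return Object of class `lattice_conformation`.
#' @export
lattice_conformation <- function(coords, sequence, box_size,
                                 boundary = c("periodic", "closed"),
                                 excluded_volume = c("cube", "site")) {
  boundary <- match.arg(boundary)
  excluded_volume <- match.arg(excluded_volume)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  if (ncol(coords) != 3L) stop("coords must have 3 columns")
  if (nrow(coords) != length(sequence))
    stop("coords rows (", nrow(coords), ") != sequence length (", length(sequence), ")")
  structure(list(coords = coords, sequence = sequence,
                 box_size = as.integer(box_size), boundary = boundary,
                 excluded_volume = excluded_volume),
            class = "lattice_conformation")
}

#' @export
print.lattice_conformation <- function(x, ...) {
  cat("lattice_conformation:", nrow(x$coords), "residues in a",
      x$box_size, "^3", x$boundary, "box\n")
  invisible(x)
}

# displacement j - i under the conformation's boundary convention
min_image <- function(d, L, boundary) {
  if (boundary == "periodic") d - L * round(d / L) else d
}

#' Validate a lattice conformation
#'
#' Checks excluded volume (duplicate anchor sites and, in cube mode, any pair
#' of overlapping cubes), bond-set membership of every consecutive bond
#' vector, and box containment, and reports every violation found.
#'
#' @param conf A [lattice_conformation()].
#' @param bond_set Allowed bond vectors; default [allowed_bond_vectors()].
#' @return List with `valid` (logical) and `violations`, a data frame with
#'   columns `type`, `index`, `detail` (empty when valid).
#' @export
validate_conformation <- function(conf, bond_set = allowed_bond_vectors()) {
  co <- conf$coords
  L <- conf$box_size
  viol <- list()
  add <- function(type, index, detail)
    viol[[length(viol) + 1L]] <<- data.frame(type = type, index = index,
                                             detail = detail)
  out <- which(co < 0L | co >= L, arr.ind = TRUE)
  if (nrow(out) > 0L)
    for (k in unique(out[, 1L]))
      add("out_of_box", k, paste(co[k, ], collapse = ","))
  key <- co[, 1L] + as.numeric(L) * co[, 2L] + as.numeric(L)^2 * co[, 3L]
  dup <- which(duplicated(key))
  for (k in dup)
    add("duplicate_site", k, paste(co[k, ], collapse = ","))
  if ((conf$excluded_volume %||% "cube") == "cube" && nrow(co) >= 2L) {
    for (i in seq_len(nrow(co) - 1L)) {
      d <- min_image(sweep(co[(i + 1L):nrow(co), , drop = FALSE], 2L, co[i, ]),
                     L, conf$boundary)
      ov <- which(apply(abs(d), 1L, max) < 2L & rowSums(abs(d)) > 0L)
      for (k in ov)
        add("cube_overlap", i, sprintf("residues %d and %d", i, i + k))
    }
  }
  if (nrow(co) >= 2L) {
    dv <- min_image(diff(co), L, conf$boundary)
    ok_len2 <- sort(unique(bond_sqlens(bond_set)))
    d2 <- rowSums(dv^2)
    bad <- which(!(d2 %in% ok_len2))
    for (k in bad)
      add("bad_bond", k, sprintf("bond %d-%d |v|^2=%d", k, k + 1L, d2[k]))
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(type = character(), index = integer(), detail = character())
  list(valid = nrow(violations) == 0L, violations = violations)
}

#' Build an initial self-avoiding conformation
#'
#' Randomized growth with backtracking: residues are placed one after another
#' at a previously unoccupied site reachable by an allowed bond vector,
#' retreating on dead ends; after a bounded number of backtracking steps the
#' growth restarts from a fresh random origin.
#'
#' @param sequence A [residue_sequence()].
#' @param box_size Lattice edge L.
#' @param bond_set Allowed bond vectors.
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @param boundary `"periodic"` or `"closed"`.
#' @param excluded_volume `"cube"` (default) or `"site"`, see
#'   [lattice_conformation()].
#' @param max_restarts Growth restarts before giving up.
#' @return A valid [lattice_conformation()].
#' @export
build_initial_conformation <- function(sequence, box_size,
                                       bond_set = allowed_bond_vectors(),
                                       seed = NULL,
                                       boundary = c("periodic", "closed"),
                                       excluded_volume = c("cube", "site"),
                                       max_restarts = 100L) {
  boundary <- match.arg(boundary)
  excluded_volume <- match.arg(excluded_volume)
  if (!is.null(seed)) set.seed(seed)
  n <- length(sequence)
  L <- as.integer(box_size)
  if (L < 4L) stop("box_size too small to hold a bonded chain")
  bv <- unclass(bond_set)
  nb <- nrow(bv)
  cube <- excluded_volume == "cube"
  hi <- if (boundary == "closed" && cube) L - 1L else L
  # lattice sites claimed by a residue anchored at p (1 or 8 of them)
  claim <- function(p) {
    q <- if (cube) t(p + t(as.matrix(expand.grid(0:1, 0:1, 0:1)))) else
      matrix(p, 1L)
    if (boundary == "periodic") q <- q %% L
    q[, 1L] + L * q[, 2L] + L * L * q[, 3L] + 1L
  }

  for (restart in seq_len(max_restarts)) {
    occ <- logical(L^3)
    co <- matrix(0L, n, 3L)
    co[1L, ] <- as.integer(sample.int(hi, 3L, replace = TRUE) - 1L)
    occ[claim(co[1L, ])] <- TRUE
    # per-level shuffled candidate order and next candidate pointer
    ord <- matrix(0L, n, nb)
    ptr <- integer(n)
    i <- 2L
    ord[i, ] <- sample.int(nb)
    ptr[i] <- 1L
    steps <- 0L
    ok <- TRUE
    while (i <= n) {
      steps <- steps + 1L
      if (steps > 200L * n) { ok <- FALSE; break }
      placed <- FALSE
      while (ptr[i] <= nb) {
        v <- bv[ord[i, ptr[i]], ]
        ptr[i] <- ptr[i] + 1L
        p <- co[i - 1L, ] + v
        if (boundary == "periodic") p <- p %% L
        else if (any(p < 0L | p >= hi)) next
        cl <- claim(p)
        if (any(occ[cl])) next
        co[i, ] <- as.integer(p)
        occ[cl] <- TRUE
        placed <- TRUE
        break
      }
      if (placed) {
        i <- i + 1L
        if (i <= n) { ord[i, ] <- sample.int(nb); ptr[i] <- 1L }
      } else {
        if (i == 2L) { ok <- FALSE; break }       # cannot backtrack past origin
        i <- i - 1L
        occ[claim(co[i, ])] <- FALSE
      }
    }
    if (ok && i > n)
      return(lattice_conformation(co, sequence, L, boundary, excluded_volume))
  }
  stop("failed to grow a valid conformation after ", max_restarts, " restarts")
}

#' Write a conformation snapshot
#'
#' Plain-text format: comment lines starting with `#` carrying box size and
#' boundary, then one row per residue: `index code x y z`.
#'
#' @param conf A [lattice_conformation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(conf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# latticefold snapshot box_size=%d boundary=%s excluded_volume=%s",
                       conf$box_size, conf$boundary,
                       conf$excluded_volume %||% "cube"),
               "index res x y z"), con)
  df <- data.frame(index = seq_len(nrow(conf$coords)),
                   res = unclass(conf$sequence),
                   conf$coords)
  utils::write.table(df, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a conformation snapshot written by [write_snapshot()]
#'
#' @param path Snapshot path.
#' @return A [lattice_conformation()].
#' @export
read_snapshot <- function(path) {
  hdr <- readLines(path, n = 1L)
  L <- as.integer(sub(".*box_size=([0-9]+).*", "\\1", hdr))
  boundary <- sub(".*boundary=([a-z]+).*", "\\1", hdr)
  ev <- if (grepl("excluded_volume=", hdr))
    sub(".*excluded_volume=([a-z]+).*", "\\1", hdr) else "cube"
  df <- utils::read.table(path, skip = 2L,
                          col.names = c("index", "res", "x", "y", "z"))
  lattice_conformation(unname(as.matrix(df[, c("x", "y", "z")])),
                       residue_sequence(df$res), L, boundary, ev)
}
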