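#' Interaction parameters of the truncated pair potential
#'
#' @param r_c Cutoff distance in lattice constants; default `sqrt(8)`.
#' @param sigma Length scale of the potential; default 1.
#' @return Object of class `interaction_params`.
#' @export
interaction_params <- function(r_c = sqrt(8), sigma = 1) {
  if (!(sigma > 0 && sigma < r_c)) stop("need 0 < sigma < r_c")
  structure(list(r_c = r_c, sigma = sigma), class = "interaction_params")
}

#' Construct a residue contact matrix
#'
#' A 20x20 symmetric table of pair strengths \eqn{\epsilon_{ij}} in reduced
#' energy units over the canonical alphabet; negative entries are attractive,
#' positive repulsive. Knowledge-based matrices (MJ, BT, BFKV) are consumed
#' through this container; see [load_contact_matrix()].
#'
#' @param eps 20x20 numeric matrix, rows/columns ordered by `alphabet`.
#' @param alphabet Ordering of `eps`; remapped to [aa_alphabet()] internally.
#' @param label Free-text label (e.g. `"MJ"`, `"synthetic-HP"`).
#' @return Object of class `contact_matrix`: the matrix in canonical order
#'   with dimnames and a `label` attribute.
#' @export
contact_matrix <- function(eps, alphabet = aa_alphabet(), label = "") {
  eps <- as.matrix(eps)
  if (!all(dim(eps) == c(20L, 20L))) stop("eps must be 20x20")
  if (!all(is.finite(eps))) stop("non-finite entries in contact matrix")
  alphabet <- toupper(alphabet)
  missing <- setdiff(aa_alphabet(), alphabet)
  if (length(missing) > 0L)
    stop("alphabet is missing amino acid(s): ", paste(missing, collapse = ", "))
  ord <- match(aa_alphabet(), alphabet)
  eps <- eps[ord, ord, drop = FALSE]
  asym <- max(abs(eps - t(eps)))
  if (asym > 1e-12) stop("contact matrix asymmetric by ", format(asym))
  dimnames(eps) <- list(aa_alphabet(), aa_alphabet())
  structure(eps, label = as.character(label)[1L],
            class = c("contact_matrix", "matrix"))
}

#' Load a contact matrix from a delimited text file
#'
#' Expects a 21x21 table: a header row and first column of one-letter codes
#' framing the 20x20 numeric block; comma- or whitespace-delimited. Small
#' asymmetries (at most 1e-6, e.g. from truncated decimals) are symmetrized by
#' averaging; anything larger is rejected with the offending cell named.
#'
#' @param path File path.
#' @param label Label; default the file name without extension.
#' @return A [contact_matrix()].
#' @export
load_contact_matrix <- function(path, label = NULL) {
  if (!file.exists(path)) stop("contact matrix file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  tab <- utils::read.table(path, header = TRUE, row.names = 1L, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  rn <- toupper(rownames(tab)); cn <- toupper(colnames(tab))
  miss <- unique(c(setdiff(aa_alphabet(), rn), setdiff(aa_alphabet(), cn)))
  if (length(miss) > 0L)
    stop("contact matrix file is missing amino acid(s): ",
         paste(miss, collapse = ", "))
  m <- as.matrix(tab)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2L, as.numeric))), arr.ind = TRUE)
    cell <- if (nrow(bad)) paste0("(", rn[bad[1L, 1L]], ",", cn[bad[1L, 2L]], ")") else ""
    stop("non-numeric cell in contact matrix file ", cell)
  }
  rownames(m) <- rn; colnames(m) <- cn
  m <- m[aa_alphabet(), aa_alphabet()]
  asym <- abs(m - t(m))
  if (max(asym) > 1e-6) {
    w <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
    stop(sprintf("gross asymmetry %.3g at cell (%s,%s)", max(asym),
                 aa_alphabet()[w[1L]], aa_alphabet()[w[2L]]))
  }
  m <- (m + t(m)) / 2
  if (is.null(label))
    label <- tools::file_path_sans_ext(basename(path))
  contact_matrix(m, label = label)
}

#' Write a contact matrix as CSV
#'
#' @param matrix A [contact_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(matrix, path) {
  utils::write.csv(unclass(matrix)[, , drop = FALSE], path, quote = FALSE)
  invisible(path)
}

#' Truncated generalized Lennard-Jones pair energy
#'
#' \deqn{U(r) = |\epsilon_{ij}| (\sigma/r)^{12} + \epsilon_{ij} (\sigma/r)^6}
#' for \eqn{r < r_c} and exactly 0 at and beyond the cutoff (truncated, not
#' shifted). The \eqn{r^{-12}} core is repulsive for either sign of
#' \eqn{\epsilon_{ij}}; for attractive pairs the minimum sits at
#' \eqn{r = 2^{1/6}\sigma} with depth \eqn{|\epsilon_{ij}|/4}.
#'
#' @param eps_ij Pair strength(s).
#' @param r Distance(s), lattice constants; must be positive.
#' @param params An [interaction_params()].
#' @return Energy, vectorized over `eps_ij`/`r`.
#' @export
pair_energy <- function(eps_ij, r, params = interaction_params()) {
  if (any(r <= 0)) stop("pair_energy requires r > 0")
  s6 <- (params$sigma / r)^6
  u <- abs(eps_ij) * s6^2 + eps_ij * s6
  u[r >= params$r_c] <- 0
  u
}

#' Lattice offsets of the interaction shell
#'
#' All nonzero integer offsets with \eqn{0 < |d|^2 \le r_c^2}; for the default
#' cutoff \eqn{r_c=\sqrt 8} this is 92 sites (sites exactly at \eqn{r_c}
#' contribute zero energy but are included for simplicity).
#'
#' @param params An [interaction_params()].
#' @return Integer matrix, one offset per row.
#' @export
interaction_shell <- function(params = interaction_params()) {
  m <- floor(params$r_c)
  g <- as.matrix(expand.grid(x = -m:m, y = -m:m, z = -m:m))
  d2 <- rowSums(g^2)
  v <- g[d2 > 0 & d2 <= params$r_c^2 + 1e-9, , drop = FALSE]
  dimnames(v) <- list(NULL, c("x", "y", "z"))
  v
}

# minimum-image squared distances from residue i to all residues
conf_sq_dists <- function(conf, i) {
  d <- sweep(conf$coords, 2L, conf$coords[i, ])
  d <- min_image(d, conf$box_size, conf$boundary)
  rowSums(d^2)
}

#' Contact energy of one residue
#'
#' Sum of pair energies between residue `i` and every non-adjacent residue
#' within the interaction shell (minimum image under periodic boundaries).
#' Covalently bonded neighbours (`j = i-1, i+1`) are excluded from the
#' contact sum.
#'
#' @param conf A [lattice_conformation()].
#' @param i Residue index (1-based).
#' @param matrix A [contact_matrix()].
#' @param params An [interaction_params()].
#' @return Energy of residue `i`.
#' @export
site_energy <- function(conf, i, matrix, params = interaction_params()) {
  n <- nrow(conf$coords)
  if (i < 1L || i > n) stop("residue index out of range")
  d2 <- conf_sq_dists(conf, i)
  j <- setdiff(which(d2 < params$r_c^2 - 1e-12), c(i - 1L, i, i + 1L))
  if (length(j) == 0L) return(0)
  s <- unclass(conf$sequence)
  sum(pair_energy(unclass(matrix)[cbind(s[i], s[j])], sqrt(d2[j]), params))
}

#' Total contact energy of a conformation
#'
#' Brute-force sum over unordered non-adjacent pairs within the cutoff; equals
#' half the sum of [site_energy()] over all residues.
#'
#' @inheritParams site_energy
#' @return Total energy.
#' @export
total_energy <- function(conf, matrix, params = interaction_params()) {
  n <- nrow(conf$coords)
  if (n < 3L) return(0)
  e <- 0
  for (i in seq_len(n - 2L)) {
    d2 <- conf_sq_dists(conf, i)
    j <- (i + 2L):n
    j <- j[d2[j] < params$r_c^2 - 1e-12]
    if (length(j) == 0L) next
    s <- unclass(conf$sequence)
    e <- e + sum(pair_energy(unclass(matrix)[cbind(s[i], s[j])],
                             sqrt(d2[j]), params))
  }
  e
}
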