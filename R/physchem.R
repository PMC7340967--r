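# Property-based encoders: EIIP, PseEIIP, parallel-correlation
# pseudo-dinucleotide composition, one-hot (BE) and chemical-property +
# density (NCP+ND).

#' Electron-ion interaction pseudopotentials of the four nucleotides.
#'
#' Dimensionless EIIP values; U inherits the value of T.
#' @export
eiip_values <- c(A = 0.1260, C = 0.1340, G = 0.0806, U = 0.1335)

#' EIIP encoding
#'
#' Replaces each nucleotide by its electron-ion interaction pseudopotential,
#' giving an L-dimensional vector per window.
#'
#' @param x an [rna_windows] dataset or character vector of sequences.
#' @param values named EIIP table over A, C, G, U.
#' @return Numeric matrix, one position-labeled column per window position.
#' @export
encode_eiip <- function(x, values = eiip_values) {
  stopifnot(all(RNA_BASES %in% names(values)), all(values[RNA_BASES] > 0))
  idx <- seq_index_matrix(as_seq_strings(x))
  out <- matrix(values[RNA_BASES][idx], nrow = nrow(idx))
  colnames(out) <- sprintf("EIIP:p%+d", window_positions(ncol(idx)))
  out
}

#' PseEIIP encoding
#'
#' 64 components, one per trinucleotide XYZ: the normalized trinucleotide
#' frequency f_XYZ multiplied by EIIP_X + EIIP_Y + EIIP_Z.
#'
#' @inheritParams encode_eiip
#' @return Numeric matrix with 64 named columns.
#' @export
encode_pseeiip <- function(x, values = eiip_values) {
  tnc <- encode_kmer(x, k = 3L)
  v <- values[RNA_BASES]
  tri <- kmer_alphabet(3L)
  esum <- v[substr(tri, 1, 1)] + v[substr(tri, 2, 2)] + v[substr(tri, 3, 3)]
  out <- sweep(tnc, 2L, esum, `*`)
  colnames(out) <- paste0("PseEIIP:", tri)
  out
}

#' Load an RNA dinucleotide physicochemical property table
#'
#' Reads a TSV with one property per row and the 16 dinucleotides as
#' columns, then standardizes each property to mean 0 and variance 1
#' (population variance) across the 16 dinucleotides -- the convention under
#' which pseudo-composition correlations are computed. The bundled default
#' (`dinuc_properties_synthetic.tsv`) contains 22 scales: 8 exact
#' compositional properties derivable from dinucleotide identity and 14
#' synthetic stand-in scales, since the upstream 22-property values are not
#' redistributable here. Swap in your own table for production scales.
#'
#' @param path TSV file; default is the bundled synthetic table.
#' @param standardize standardize each property row.
#' @return Numeric matrix (properties x 16 dinucleotides) of class
#'   `dinuc_properties`, with attribute `standardized`.
#' @export
dinuc_property_table <- function(path = NULL, standardize = TRUE) {
  if (is.null(path))
    path <- system.file("extdata", "dinuc_properties_synthetic.tsv",
                        package = "rnam5c", mustWork = TRUE)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  din <- kmer_alphabet(2L)
  if (!all(din %in% colnames(m)))
    stop("property table must have one column per dinucleotide AA..UU")
  m <- m[, din, drop = FALSE]
  if (standardize) {
    mu <- rowMeans(m)
    sdev <- sqrt(rowMeans((m - mu)^2))
    if (any(sdev == 0)) stop("constant property row cannot be standardized")
    m <- (m - mu) / sdev
  }
  attr(m, "standardized") <- standardize
  class(m) <- c("dinuc_properties", class(m))
  m
}

#' Parallel-correlation pseudo-dinucleotide composition (PC-PseDNC)
#'
#' Type-1 pseudo-dinucleotide composition: the 16 normalized dinucleotide
#' frequencies plus `lambda` correlation tiers. The correlation between two
#' dinucleotides is the squared property difference averaged over the
#' property set, and tier g averages it over all dinucleotide pairs at lag
#' g. Components are jointly normalized so the full `16 + lambda` vector
#' sums to 1; `w` weights the correlation tail.
#'
#' @param x an [rna_windows] dataset or character vector of sequences.
#' @param lambda number of correlation tiers (1 <= lambda <= L - 2).
#' @param w tail weight in (0, 1].
#' @param table a [dinuc_property_table()]; the bundled default when `NULL`.
#' @return Numeric matrix with `16 + lambda` named columns per window.
#' @export
encode_pc_psednc <- function(x, lambda = 3L, w = 0.2, table = NULL) {
  seqs <- as_seq_strings(x)
  L <- unique(nchar(seqs))
  stopifnot(length(L) == 1L)
  if (lambda < 1L || lambda > L - 2L)
    stop("lambda must lie in 1..", L - 2L)
  if (w <= 0 || w > 1) stop("w must lie in (0, 1]")
  if (is.null(table)) table <- dinuc_property_table()
  if (!isTRUE(attr(table, "standardized")))
    stop("property table must be standardized")
  # 16 x 16 squared-difference correlation, averaged over properties
  theta_fun <- matrix(0, 16L, 16L)
  for (i in 1:16) for (j in 1:16)
    theta_fun[i, j] <- mean((table[, i] - table[, j])^2)
  codes <- kmer_code_matrix(seq_index_matrix(seqs), 2L)
  nd <- ncol(codes)                       # L - 1 dinucleotides
  f <- encode_kmer(x, k = 2L)
  theta <- matrix(0, nrow = length(seqs), ncol = lambda)
  for (g in seq_len(lambda)) {
    pairs <- seq_len(nd - g)
    acc <- numeric(length(seqs))
    for (i in pairs)
      acc <- acc + theta_fun[cbind(codes[, i], codes[, i + g])]
    theta[, g] <- acc / length(pairs)
  }
  denom <- 1 + w * rowSums(theta)
  out <- cbind(f / denom, w * theta / denom)
  colnames(out) <- c(paste0("PseDNC:f_", kmer_alphabet(2L)),
                     paste0("PseDNC:theta_", seq_len(lambda)))
  out
}

#' Binary one-hot encoding (BE)
#'
#' Position-major one-hot encoding: A, C, G, U map to (1,0,0,0), (0,1,0,0),
#' (0,0,1,0), (0,0,0,1), giving a 4L vector with exactly L ones.
#'
#' @param x an [rna_windows] dataset or character vector of sequences.
#' @return Numeric 0/1 matrix with `4 * L` columns.
#' @export
encode_be <- function(x) {
  idx <- seq_index_matrix(as_seq_strings(x))
  L <- ncol(idx)
  n <- nrow(idx)
  out <- matrix(0, nrow = n, ncol = 4L * L)
  for (j in seq_len(L))
    out[cbind(seq_len(n), (j - 1L) * 4L + idx[, j])] <- 1
  pos <- window_positions(L)
  colnames(out) <- sprintf("BE:p%+d_%s", rep(pos, each = 4L),
                           rep(RNA_BASES, times = L))
  out
}

#' Nucleotide chemical property + density encoding (NCP+ND)
#'
#' Per position, four components: the ring-structure indicator (1 for
#' purines A/G), the functional-group indicator (1 for amino bases A/C),
#' the hydrogen-bond indicator (1 for weak pairing A/U), and the cumulative
#' density -- the frequency of the current base within the prefix ending at
#' that position (always 1 at position 1, and in (0, 1] everywhere).
#'
#' @param x an [rna_windows] dataset or character vector of sequences.
#' @return Numeric matrix with `4 * L` columns, position-major.
#' @export
encode_ncp_nd <- function(x) {
  idx <- seq_index_matrix(as_seq_strings(x))
  L <- ncol(idx)
  n <- nrow(idx)
  ring <- c(1, 0, 1, 0)   # A,G purines
  func <- c(1, 1, 0, 0)   # A,C amino
  hbond <- c(1, 0, 0, 1)  # A,U weak (two hydrogen bonds)
  out <- matrix(0, nrow = n, ncol = 4L * L)
  prefix_counts <- matrix(0, nrow = n, ncol = 4L)
  for (j in seq_len(L)) {
    base_col <- (j - 1L) * 4L
    hit <- cbind(seq_len(n), idx[, j])
    prefix_counts[hit] <- prefix_counts[hit] + 1
    out[, base_col + 1L] <- ring[idx[, j]]
    out[, base_col + 2L] <- func[idx[, j]]
    out[, base_col + 3L] <- hbond[idx[, j]]
    out[, base_col + 4L] <- prefix_counts[hit] / j
  }
  pos <- window_positions(L)
  colnames(out) <- sprintf("NCPND:p%+d_%s", rep(pos, each = 4L),
                           rep(c("ring", "func", "hbond", "dens"), times = L))
  out
}
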