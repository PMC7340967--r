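# Fit-free frequency encoders: k-mer composition, windowed composition
# (ENAC) and the gapped k-mer families.

#' k-mer composition (NAC / DNC / TNC)
#'
#' Frequencies of the `L - k + 1` overlapping k-mers of each window over the
#' lexicographic k-mer alphabet; each vector sums to 1. `counts = TRUE`
#' returns raw counts for diagnostics.
#'
#' @param x an [rna_windows] dataset or character vector of sequences.
#' @param k 1, 2 or 3 (NAC, DNC, TNC).
#' @param counts return raw counts instead of frequencies.
#' @return Numeric matrix, one row per window, `4^k` named columns.
#' @export
#' @examples
#' encode_kmer(strrep("A", 41), k = 1)
encode_kmer <- function(x, k = 1L, counts = FALSE) {
  stopifnot(k %in% 1:3)
  seqs <- as_seq_strings(x)
  codes <- kmer_code_matrix(seq_index_matrix(seqs), k)
  nk <- 4L^k
  P <- ncol(codes)
  out <- matrix(0, nrow = length(seqs), ncol = nk)
  for (j in seq_len(P)) {
    hit <- cbind(seq_along(seqs), codes[, j])
    out[hit] <- out[hit] + 1
  }
  if (!counts) out <- out / P
  colnames(out) <- paste0(c("NAC", "DNC", "TNC")[k], ":", kmer_alphabet(k))
  out
}

#' Enhanced nucleic acid composition (ENAC)
#'
#' Slides a fixed-length window (default 5 nt) along the sequence from the
#' 5' to the 3' end with stride 1 and records the four nucleotide
#' frequencies at each placement, giving `(L - win + 1) * 4` features (148
#' at L = 41); every 4-block sums to 1.
#'
#' @param x an [rna_windows] dataset or character vector of sequences.
#' @param win sub-window length.
#' @return Numeric matrix with one 4-block of columns per placement.
#' @export
encode_enac <- function(x, win = 5L) {
  seqs <- as_seq_strings(x)
  idx <- seq_index_matrix(seqs)
  L <- ncol(idx)
  if (win > L) stop("ENAC window (", win, ") wider than sequence (", L, ")")
  starts <- seq_len(L - win + 1L)
  pos <- window_positions(L)
  out <- matrix(0, nrow = nrow(idx), ncol = length(starts) * 4L)
  nm <- character(ncol(out))
  for (s in starts) {
    block <- idx[, s:(s + win - 1L), drop = FALSE]
    for (b in 1:4) {
      col <- (s - 1L) * 4L + b
      out[, col] <- rowSums(block == b) / win
      nm[col] <- sprintf("ENAC:w%+d_%s", pos[s], RNA_BASES[b])
    }
  }
  colnames(out) <- nm
  out
}

#' Gapped k-mer composition (xxKGap families)
#'
#' Frequencies of nucleotide patterns separated by a gap, cumulative over
#' gap sizes `1..kgap`:
#' \describe{
#'   \item{mM}{mono--gap--mono `X _g_ Y`, 16 features per gap size}
#'   \item{mD}{mono--gap--di `X _g_ YZ`, 64 per gap size}
#'   \item{dM}{di--gap--mono `XY _g_ Z`, 64 per gap size}
#' }
#' so e.g. mM with `kgap = 2` yields 4 x 2 x 4 = 32 features. Each g-block
#' is normalized by its own number of valid placements and sums to 1.
#'
#' @param x an [rna_windows] dataset or character vector of sequences.
#' @param family `"mM"`, `"mD"` or `"dM"`.
#' @param kgap maximum gap size (1--3).
#' @return Numeric matrix; feature names follow
#'   `"<family><kgap>Gap:<left>_<g>_<right>"`.
#' @export
encode_xxkgap <- function(x, family = c("mM", "mD", "dM"), kgap = 1L) {
  family <- match.arg(family)
  stopifnot(kgap %in% 1:3)
  seqs <- as_seq_strings(x)
  idx <- seq_index_matrix(seqs)
  L <- ncol(idx)
  n <- nrow(idx)
  left_k <- if (family == "dM") 2L else 1L
  right_k <- if (family == "mD") 2L else 1L
  span <- function(g) left_k + g + right_k
  if (span(kgap) > L)
    stop("pattern span ", span(kgap), " exceeds window length ", L)
  left_codes <- kmer_code_matrix(idx, left_k)
  right_codes <- kmer_code_matrix(idx, right_k)
  nl <- 4L^left_k
  nr <- 4L^right_k
  prefix <- sprintf("%s%dGap", family, kgap)
  blocks <- lapply(seq_len(kgap), function(g) {
    placements <- L - span(g) + 1L
    block <- matrix(0, nrow = n, ncol = nl * nr)
    for (i in seq_len(placements)) {
      code <- (left_codes[, i] - 1L) * nr + right_codes[, i + left_k + g]
      hit <- cbind(seq_len(n), code)
      block[hit] <- block[hit] + 1
    }
    colnames(block) <- paste0(prefix, ":",
                              rep(kmer_alphabet(left_k), each = nr), "_", g,
                              "_", rep(kmer_alphabet(right_k), times = nl))
    block / placements
  })
  do.call(cbind, blocks)
}
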