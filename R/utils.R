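# Shared low-level helpers: alphabet, k-mer indexing, character matrices.

RNA_BASES <- c("A", "C", "G", "U")

#' Lexicographic k-mer alphabet
#'
#' All 4^k k-mers over (A, C, G, U) in lexicographic order. This ordering is
#' frozen: propensity-matrix rows, k-mer composition vectors and PseEIIP
#' components all use it, and fitted matrices written to disk keep it.
#'
#' @param k k-mer order (1, 2 or 3).
#' @return Character vector of length `4^k`.
#' @export
#' @examples
#' kmer_alphabet(1)
#' head(kmer_alphabet(2))
kmer_alphabet <- function(k) {
  stopifnot(k >= 1, k <= 8)
  g <- do.call(expand.grid,
               c(rep(list(RNA_BASES), k), stringsAsFactors = FALSE))
  # expand.grid varies the first column fastest; lexicographic order needs
  # the last character fastest, so paste columns in reverse.
  do.call(paste0, rev(unclass(g)))
}

# character vector of sequences -> n x L character matrix
seq_char_matrix <- function(seqs) {
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("all sequences must share one length; found lengths ",
         paste(L, collapse = ", "))
  matrix(unlist(strsplit(seqs, NULL), use.names = FALSE),
         nrow = length(seqs), ncol = L, byrow = TRUE)
}

# n x L integer matrix of base indices (A=1, C=2, G=3, U=4)
seq_index_matrix <- function(seqs) {
  cm <- seq_char_matrix(seqs)
  idx <- match(cm, RNA_BASES)
  if (anyNA(idx))
    stop("sequences contain characters outside {A,C,G,U}")
  dim(idx) <- dim(cm)
  idx
}

# n x (L-k+1) integer matrix of k-mer codes (1 .. 4^k, lexicographic)
kmer_code_matrix <- function(idx, k) {
  L <- ncol(idx)
  P <- L - k + 1L
  if (P < 1L) stop("sequences shorter than k")
  code <- idx[, seq_len(P), drop = FALSE] - 1L
  if (k >= 2L) {
    for (o in seq_len(k - 1L)) {
      code <- code * 4L + (idx[, o + seq_len(P), drop = FALSE] - 1L)
    }
  }
  code + 1L
}

#' Window position labels
#'
#' Positions are reported as -xi..+xi with 0 at the candidate cytosine, so a
#' 41-nt window spans -20..+20.
#'
#' @param width window length (odd).
#' @return Integer vector of length `width`.
#' @export
window_positions <- function(width) {
  if (width %% 2L != 1L) stop("window width must be odd")
  xi <- (width - 1L) %/% 2L
  seq.int(-xi, xi)
}

# sequences (character) or rna_windows -> character vector of sequences
as_seq_strings <- function(x) {
  if (inherits(x, "rna_windows")) return(x$seq)
  if (is.character(x)) return(x)
  stop("expected an 'rna_windows' dataset or a character vector of sequences")
}
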