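# Position-specific propensity matrices (mono-, di-, tri-nucleotide) and the
# encodings derived from them.

#' Fit a position-specific propensity matrix
#'
#' Computes, for every k-mer i and window position j, its frequency among
#' positive windows (`pos`) and among negative windows (`neg`), and the
#' class difference `diff = pos - neg`. Frequencies are raw counts divided
#' by the class size -- no smoothing -- so each column of `pos` and `neg`
#' sums to 1 and each column of `diff` sums to 0. Rows follow the frozen
#' lexicographic k-mer order of [kmer_alphabet()].
#'
#' @param train an [rna_windows] dataset containing at least one positive
#'   and one negative window.
#' @param k k-mer order: 1 (mononucleotide), 2 (dinucleotide) or
#'   3 (trinucleotide).
#' @return An object of class `propensity_matrix` with elements `k`,
#'   `kmers`, `pos`, `neg`, `diff` (each matrix `4^k x (L-k+1)`), `n_pos`,
#'   `n_neg` and `width`.
#' @export
#' @examples
#' d <- generate_windows(generator_model(delta = 0.1), 50, 50, seed = 1)
#' pm <- fit_propensity(d, k = 1)
#' round(pm$diff[, 1:5], 2)
fit_propensity <- function(train, k = 1L) {
  stopifnot(inherits(train, "rna_windows"), k %in% 1:3)
  pos <- train$seq[train$label == "positive"]
  neg <- train$seq[train$label == "negative"]
  if (length(pos) == 0L || length(neg) == 0L)
    stop("propensity matrix undefined: training data must contain both ",
         "positive and negative windows")
  L <- attr(train, "width")
  P <- L - k + 1L
  nk <- 4L^k
  count_freq <- function(seqs) {
    codes <- kmer_code_matrix(seq_index_matrix(seqs), k)
    f <- vapply(seq_len(P), function(j) tabulate(codes[, j], nbins = nk),
                integer(nk))
    f / length(seqs)
  }
  Zp <- count_freq(pos)
  Zn <- count_freq(neg)
  dimn <- list(kmer_alphabet(k),
               sprintf("p%+d", window_positions(L)[seq_len(P)]))
  dimnames(Zp) <- dimnames(Zn) <- dimn
  out <- list(k = as.integer(k), kmers = dimn[[1L]],
              pos = Zp, neg = Zn, diff = Zp - Zn,
              n_pos = length(pos), n_neg = length(neg),
              width = as.integer(L))
  class(out) <- "propensity_matrix"
  out
}

#' Encode windows with a fitted propensity matrix
#'
#' Component j of the encoding is the `diff` entry for the k-mer observed at
#' start position j, giving a vector of length `L - k + 1` per window
#' (41/40/39 for k = 1/2/3 at the default width).
#'
#' @param x an [rna_windows] dataset or character vector of sequences.
#' @param pm a [fit_propensity()] object; window length must match.
#' @return Numeric matrix, one row per window, with position-labeled columns.
#' @export
encode_psp <- function(x, pm) {
  stopifnot(inherits(pm, "propensity_matrix"))
  seqs <- as_seq_strings(x)
  L <- unique(nchar(seqs))
  if (length(L) != 1L || L != pm$width)
    stop("window length ", paste(L, collapse = "/"),
         " does not match propensity matrix width ", pm$width)
  codes <- kmer_code_matrix(seq_index_matrix(seqs), pm$k)
  P <- ncol(codes)
  out <- matrix(0, nrow = length(seqs), ncol = P)
  for (j in seq_len(P)) out[, j] <- pm$diff[cbind(codes[, j], j)]
  prefix <- c("PSNP", "PSDP", "PSTP")[pm$k]
  colnames(out) <- paste0(prefix, ":", colnames(pm$diff))
  out
}

#' Fit the full propensity-matrix set
#'
#' Convenience wrapper fitting the mono-, di- and tri-nucleotide matrices
#' (PSNP, PSDP, PSTP) in one call; this is the `fitted` argument expected by
#' [fuse()] for propensity-based encoders.
#'
#' @inheritParams fit_propensity
#' @return Named list with elements `psnp`, `psdp`, `pstp`.
#' @export
fit_psp_set <- function(train) {
  list(psnp = fit_propensity(train, 1L),
       psdp = fit_propensity(train, 2L),
       pstp = fit_propensity(train, 3L))
}

#' @export
print.propensity_matrix <- function(x, ...) {
  cat(sprintf(
    "Position-specific propensity matrix (k = %d): %d k-mers x %d positions\n",
    x$k, nrow(x$diff), ncol(x$diff)))
  cat(sprintf("  fitted on %d positive / %d negative windows of length %d\n",
              x$n_pos, x$n_neg, x$width))
  cat(sprintf("  |diff| range: %.4f .. %.4f\n",
              min(abs(x$diff)), max(abs(x$diff))))
  invisible(x)
}

#' Heat map of a propensity matrix
#'
#' Plots the class-difference matrix `diff` (positive minus negative
#' frequency) over k-mers and window positions with base graphics.
#'
#' @param x a `propensity_matrix`.
#' @param ... passed to [graphics::image()].
#' @export
plot.propensity_matrix <- function(x, ...) {
  z <- t(x$diff)
  pos <- window_positions(x$width)[seq_len(ncol(x$diff))]
  graphics::image(x = pos, y = seq_len(nrow(x$diff)), z = z,
                  xlab = "window position (0 = candidate C)",
                  ylab = "k-mer (lexicographic index)",
                  main = sprintf("Propensity difference, k = %d", x$k), ...)
  invisible(x)
}

#' Save / load fitted propensity matrices as TSV
#'
#' Portable plain-text artifact: stacked blocks for the positive, negative
#' and difference matrices, one k-mer per row and one column per position.
#'
#' @param pm a `propensity_matrix`.
#' @param path TSV file.
#' @return `write_propensity` returns `path` invisibly; `read_propensity`
#'   returns the reconstructed `propensity_matrix`.
#' @export
write_propensity <- function(pm, path) {
  stopifnot(inherits(pm, "propensity_matrix"))
  block <- function(set, m)
    data.frame(set = set, kmer = rownames(m), m,
               check.names = FALSE, stringsAsFactors = FALSE)
  tab <- rbind(block("pos", pm$pos), block("neg", pm$neg),
               block("diff", pm$diff))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# propensity_matrix k=%d width=%d n_pos=%d n_neg=%d",
                     pm$k, pm$width, pm$n_pos, pm$n_neg), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_propensity
#' @export
read_propensity <- function(path) {
  header <- readLines(path, n = 1L)
  meta <- as.integer(regmatches(header,
                                gregexpr("[0-9]+", header))[[1L]])
  if (length(meta) != 4L) stop("not a propensity-matrix TSV: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                           check.names = FALSE, stringsAsFactors = FALSE)
  get <- function(set) {
    b <- tab[tab$set == set, , drop = FALSE]
    m <- as.matrix(b[, -(1:2), drop = FALSE])
    rownames(m) <- b$kmer
    m
  }
  out <- list(k = meta[1L], kmers = kmer_alphabet(meta[1L]),
              pos = get("pos"), neg = get("neg"), diff = get("diff"),
              n_pos = meta[3L], n_neg = meta[4L], width = meta[2L])
  class(out) <- "propensity_matrix"
  out
}
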