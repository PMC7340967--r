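# Independent brute-force oracles and fixture builders used across tests.
# These deliberately use naive nested loops over explicit strings, never the
# package's vectorized index arithmetic.

BASES <- c("A", "C", "G", "U")

# strip everything but the numbers from a feature matrix
bare <- function(m) {
  m <- unclass(m)
  attributes(m) <- list(dim = dim(m))
  m
}

rand_windows <- function(n, L = 41L, seed = 1L, center_c = TRUE,
                         label = "unlabeled") {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    s <- sample(BASES, L, replace = TRUE)
    if (center_c) s[(L + 1L) %/% 2L] <- "C"
    paste(s, collapse = "")
  }, character(1))
  rna_windows(seqs, label = label, width = L, strict_center = center_c)
}

rand_labeled <- function(n_pos, n_neg, L = 41L, seed = 1L) {
  d <- rand_windows(n_pos + n_neg, L = L, seed = seed)
  d$label <- rep(c("positive", "negative"), c(n_pos, n_neg))
  d
}

# sliding-window dictionary count of k-mers
oracle_kmer_freq <- function(seq, k) {
  ab <- kmer_alphabet(k)
  ch <- strsplit(seq, "")[[1L]]
  counts <- stats::setNames(numeric(length(ab)), ab)
  for (i in seq_len(length(ch) - k + 1L)) {
    km <- paste(ch[i:(i + k - 1L)], collapse = "")
    counts[km] <- counts[km] + 1
  }
  counts / (length(ch) - k + 1L)
}

# per-position k-mer frequency difference, counted with nested loops
oracle_psp_fit <- function(pos_seqs, neg_seqs, k) {
  ab <- kmer_alphabet(k)
  L <- nchar(pos_seqs[1L])
  P <- L - k + 1L
  count <- function(seqs) {
    m <- matrix(0, nrow = length(ab), ncol = P, dimnames = list(ab, NULL))
    for (s in seqs) {
      ch <- strsplit(s, "")[[1L]]
      for (j in seq_len(P)) {
        km <- paste(ch[j:(j + k - 1L)], collapse = "")
        m[km, j] <- m[km, j] + 1
      }
    }
    m / length(seqs)
  }
  count(pos_seqs) - count(neg_seqs)
}

oracle_psp_encode <- function(seq, Z, k) {
  ch <- strsplit(seq, "")[[1L]]
  P <- length(ch) - k + 1L
  vapply(seq_len(P), function(j)
    Z[paste(ch[j:(j + k - 1L)], collapse = ""), j], numeric(1))
}

oracle_enac <- function(seq, win = 5L) {
  ch <- strsplit(seq, "")[[1L]]
  L <- length(ch)
  out <- numeric(0)
  for (s in seq_len(L - win + 1L)) {
    block <- ch[s:(s + win - 1L)]
    out <- c(out, vapply(BASES, function(b) sum(block == b) / win,
                         numeric(1)))
  }
  unname(out)
}

# cumulative gapped-pattern frequencies by explicit enumeration
oracle_xxkgap <- function(seq, family, kgap) {
  ch <- strsplit(seq, "")[[1L]]
  L <- length(ch)
  left_k <- if (family == "dM") 2L else 1L
  right_k <- if (family == "mD") 2L else 1L
  out <- numeric(0)
  for (g in seq_len(kgap)) {
    lefts <- kmer_alphabet(left_k)
    rights <- kmer_alphabet(right_k)
    block <- stats::setNames(
      numeric(length(lefts) * length(rights)),
      paste0(rep(lefts, each = length(rights)), "_", g,
             "_", rep(rights, times = length(lefts))))
    placements <- 0L
    for (i in seq_len(L)) {
      jr <- i + left_k + g
      if (jr + right_k - 1L > L) break
      placements <- placements + 1L
      key <- paste0(paste(ch[i:(i + left_k - 1L)], collapse = ""), "_", g,
                    "_", paste(ch[jr:(jr + right_k - 1L)], collapse = ""))
      block[key] <- block[key] + 1
    }
    out <- c(out, block / placements)
  }
  out
}

# type-1 pseudo-dinucleotide composition by explicit double loop
oracle_pc_psednc <- function(seq, lambda, w, P) {
  ch <- strsplit(seq, "")[[1L]]
  L <- length(ch)
  din <- vapply(seq_len(L - 1L), function(i)
    paste0(ch[i], ch[i + 1L]), character(1))
  f <- stats::setNames(numeric(16), kmer_alphabet(2L))
  for (d in din) f[d] <- f[d] + 1
  f <- f / length(din)
  theta_pair <- function(a, b) mean((P[, a] - P[, b])^2)
  theta <- vapply(seq_len(lambda), function(g) {
    acc <- 0
    for (i in seq_len(length(din) - g)) acc <- acc +
        theta_pair(din[i], din[i + g])
    acc / (length(din) - g)
  }, numeric(1))
  denom <- 1 + w * sum(theta)
  c(f / denom, w * theta / denom)
}

oracle_ncp_nd <- function(seq) {
  ch <- strsplit(seq, "")[[1L]]
  out <- numeric(0)
  for (i in seq_along(ch)) {
    b <- ch[i]
    out <- c(out,
             as.numeric(b %in% c("A", "G")),
             as.numeric(b %in% c("A", "C")),
             as.numeric(b %in% c("A", "U")),
             sum(ch[seq_len(i)] == b) / i)
  }
  out
}

# contingency-table metrics, written directly from TP/TN/FP/FN
oracle_metrics <- function(truth, predicted) {
  tp <- sum(truth == "positive" & predicted == "positive")
  fn <- sum(truth == "positive" & predicted == "negative")
  tn <- sum(truth == "negative" & predicted == "negative")
  fp <- sum(truth == "negative" & predicted == "positive")
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(Sn = tp / (tp + fn), Sp = tn / (tn + fp),
       Acc = (tp + tn) / length(truth),
       MCC = if (den == 0) 0 else (tp * tn - fp * fn) / den)
}

# the published algebraic MCC rewriting in terms of misclassification counts
chou_mcc <- function(n_pos, n_neg, miscl_pos, miscl_neg) {
  (1 - (miscl_pos / n_pos + miscl_neg / n_neg)) /
    sqrt((1 + (miscl_neg - miscl_pos) / n_pos) *
         (1 + (miscl_pos - miscl_neg) / n_neg))
}

# normalized Mann-Whitney U with half credit for ties
oracle_auc <- function(scores, truth) {
  sp <- scores[truth == "positive"]
  sn <- scores[truth == "negative"]
  u <- 0
  for (a in sp) for (b in sn)
    u <- u + (a > b) + 0.5 * (a == b)
  u / (length(sp) * length(sn))
}
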