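# toy 2-property table over the 16 dinucleotides, standardized like the
# bundled one (population variance)
toy_table <- function() {
  din <- kmer_alphabet(2)
  m <- rbind(seq(-1, 2, length.out = 16),
             c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8, 9, 7, 9, 3))
  colnames(m) <- din
  rownames(m) <- c("toy1", "toy2")
  m <- (m - rowMeans(m)) / sqrt(rowMeans((m - rowMeans(m))^2))
  attr(m, "standardized") <- TRUE
  m
}

test_that("EIIP encoding is a per-position value lookup", {
  g41 <- strrep("G", 41)
  enc <- encode_eiip(g41)
  expect_equal(ncol(enc), 41L)
  expect_equal(unname(enc[1, ]), rep(0.0806, 41))
  d <- rand_windows(10, seed = 4)
  enc2 <- encode_eiip(d)
  vals <- c(A = 0.1260, C = 0.1340, G = 0.0806, U = 0.1335)
  for (i in c(1, 10))
    expect_equal(unname(enc2[i, ]),
                 unname(vals[strsplit(d$seq[i], "")[[1]]]))
})

test_that("PseEIIP weights trinucleotide frequencies by summed EIIP values", {
  enc <- encode_pseeiip(strrep("A", 41))
  expect_equal(ncol(enc), 64L)
  expect_equal(unname(enc[1, "PseEIIP:AAA"]), 3 * 0.1260)
  expect_equal(sum(enc[1, ] != 0), 1L)
  # cross-module consistency: elementwise product of TNC with EIIP sums
  d <- rand_windows(25, seed = 16)
  tnc <- encode_kmer(d, 3)
  tri <- kmer_alphabet(3)
  vals <- c(A = 0.1260, C = 0.1340, G = 0.0806, U = 0.1335)
  esum <- vals[substr(tri, 1, 1)] + vals[substr(tri, 2, 2)] +
    vals[substr(tri, 3, 3)]
  expect_equal(unname(encode_pseeiip(d)),
               unname(sweep(tnc, 2, esum, `*`)), tolerance = 1e-12)
})

test_that("pseudo-dinucleotide composition matches the double-loop oracle", {
  d <- rand_windows(10, seed = 23)
  tab <- toy_table()
  enc <- encode_pc_psednc(d, lambda = 2, w = 0.5, table = tab)
  expect_equal(ncol(enc), 18L)
  for (i in c(1, 5, 10))
    expect_equal(unname(enc[i, ]),
                 unname(oracle_pc_psednc(d$seq[i], 2, 0.5, tab)),
                 tolerance = 1e-12)
})

test_that("pseudo-dinucleotide vectors are normalized for any lambda and w", {
  d <- rand_windows(8, seed = 77)
  for (lam in c(1, 3, 10)) for (w in c(0.1, 0.2, 1)) {
    enc <- encode_pc_psednc(d, lambda = lam, w = w)
    expect_equal(ncol(enc), 16L + lam)
    expect_equal(unname(rowSums(enc)), rep(1, nrow(enc)), tolerance = 1e-12)
  }
  expect_error(encode_pc_psednc(d, lambda = 0), "lambda")
  expect_error(encode_pc_psednc(d, lambda = 40), "lambda")
  expect_error(encode_pc_psednc(d, lambda = 3, w = 0), "w must")
})

test_that("identical dinucleotides throughout reduce to plain DNC", {
  # poly-A has only AA dinucleotides, so every correlation tier is zero
  polyA <- strrep("A", 41)
  enc <- encode_pc_psednc(polyA, lambda = 3, w = 0.2, table = toy_table())
  expect_equal(unname(enc[1, 17:19]), c(0, 0, 0))
  expect_equal(unname(enc[1, 1:16]),
               unname(encode_kmer(polyA, 2)[1, ]), tolerance = 1e-12)
})

test_that("increasing w shifts mass into the correlation tail", {
  s <- rand_windows(1, seed = 3)$seq
  tab <- toy_table()
  tails <- vapply(c(0.1, 0.3, 0.6, 1), function(w)
    sum(encode_pc_psednc(s, lambda = 3, w = w, table = tab)[1, 17:19]),
    numeric(1))
  expect_true(all(diff(tails) > 0))
})

test_that("the bundled property table standardizes to mean 0, variance 1", {
  tab <- dinuc_property_table()
  expect_equal(dim(tab), c(22L, 16L))
  expect_true(isTRUE(attr(tab, "standardized")))
  expect_equal(unname(rowMeans(tab)), rep(0, 22), tolerance = 1e-9)
  expect_equal(unname(rowMeans(unclass(tab)^2)), rep(1, 22),
               tolerance = 1e-9)
  raw <- dinuc_property_table(standardize = FALSE)
  expect_false(isTRUE(all.equal(unname(rowMeans(raw)), rep(0, 22))))
})

test_that("one-hot encoding is position-major with exactly L ones", {
  d <- rand_windows(10, seed = 31)
  enc <- encode_be(d)
  expect_equal(ncol(enc), 164L)
  expect_equal(unname(rowSums(enc)), rep(41, 10))
  expect_true(all(enc %in% c(0, 1)))
  acgu <- paste0("ACGU", strrep("A", 16), "C", strrep("A", 20))
  first16 <- encode_be(acgu)[1, 1:16]
  expect_equal(unname(matrix(first16, nrow = 4)), diag(4))
})

test_that("chemical-property + density encoding follows the indicator and prefix rules", {
  d <- rand_windows(6, seed = 12)
  enc <- encode_ncp_nd(d)
  expect_equal(ncol(enc), 164L)
  for (i in c(1, 6))
    expect_equal(unname(enc[i, ]), oracle_ncp_nd(d$seq[i]),
                 tolerance = 1e-12)
  # A maps to (1,1,1); density of the "ACCA" prefix is 1, 1/2, 2/3, 1/2
  s <- paste0("ACCA", strrep("G", 16), "C", strrep("G", 20))
  e <- encode_ncp_nd(s)[1, ]
  expect_equal(unname(e[1:3]), c(1, 1, 1))
  expect_equal(unname(e[c(4, 8, 12, 16)]), c(1, 1 / 2, 2 / 3, 1 / 2))
  # all-U windows: triplet (0,0,1), density always 1
  u <- encode_ncp_nd(gsub("C", "U", strrep("U", 41)))  # no center check needed
  dens <- u[1, seq(4, 164, by = 4)]
  expect_equal(unname(dens), rep(1, 41))
  expect_equal(unname(u[1, 1:3]), c(0, 0, 1))
  # densities generally lie in (0, 1] and start at 1
  alldens <- enc[, seq(4, 164, by = 4)]
  expect_true(all(alldens > 0 & alldens <= 1))
  expect_equal(unname(enc[, 4]), rep(1, 6))
})
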