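make_disjoint <- function() {
  # positives all one sequence, negatives all another, alphabet-disjoint
  # per position
  pos <- paste(rep(c("A", "C", "G", "U"), length.out = 41), collapse = "")
  neg <- paste(rep(c("U", "G", "C", "A"), length.out = 41), collapse = "")
  rna_windows(rep(c(pos, neg), each = 3),
              label = rep(c("positive", "negative"), each = 3),
              strict_center = FALSE)
}

test_that("disjoint deterministic classes give +1/-1 difference columns", {
  d <- make_disjoint()
  pm <- fit_propensity(d, k = 1)
  expect_equal(dim(pm$diff), c(4L, 41L))
  expect_true(all(apply(pm$diff, 2, function(col)
    sum(col == 1) == 1 && sum(col == -1) == 1 && sum(col == 0) == 2)))
  # encoding a training positive yields all +1
  v <- encode_psp(d[1, ], pm)
  expect_equal(unname(v[1, ]), rep(1, 41))
})

test_that("identical classes give a zero matrix and zero encodings", {
  base <- rand_windows(5, seed = 11)$seq
  d <- rna_windows(rep(base, 2),
                   label = rep(c("positive", "negative"), each = 5),
                   strict_center = FALSE)
  pm <- fit_propensity(d, k = 2)
  expect_equal(max(abs(pm$diff)), 0)
  expect_equal(max(abs(encode_psp(rand_windows(3, seed = 2), pm))), 0)
})

test_that("fitted matrices match the brute-force counting oracle", {
  d <- rand_labeled(10, 10, seed = 77)
  for (k in 1:3) {
    pm <- fit_propensity(d, k = k)
    Z <- oracle_psp_fit(d$seq[d$label == "positive"],
                        d$seq[d$label == "negative"], k)
    expect_equal(unname(pm$diff), unname(Z), tolerance = 1e-12)
    expect_equal(dim(pm$diff), c(4L^k, 41L - k + 1L))
    # class frequency columns are distributions; difference columns sum to 0
    expect_equal(unname(colSums(pm$pos)), rep(1, ncol(pm$pos)))
    expect_equal(unname(colSums(pm$neg)), rep(1, ncol(pm$neg)))
    expect_equal(max(abs(colSums(pm$diff))), 0, tolerance = 1e-12)
    expect_true(all(pm$diff >= -1 & pm$diff <= 1))
  }
})

test_that("encoding matches a per-position lookup oracle", {
  train <- rand_labeled(8, 8, seed = 5)
  probe <- rand_windows(6, seed = 99)
  for (k in 1:3) {
    pm <- fit_propensity(train, k = k)
    enc <- encode_psp(probe, pm)
    for (i in 1:3)
      expect_equal(unname(enc[i, ]),
                   oracle_psp_encode(probe$seq[i], pm$diff, k))
  }
})

test_that("swapping classes negates the matrix and every encoding", {
  d <- rand_labeled(12, 9, seed = 8)
  swapped <- d
  swapped$label <- ifelse(d$label == "positive", "negative", "positive")
  probe <- rand_windows(4, seed = 1)
  for (k in c(1L, 3L)) {
    a <- fit_propensity(d, k)
    b <- fit_propensity(swapped, k)
    expect_equal(unname(a$diff), -unname(b$diff), tolerance = 1e-12)
    expect_equal(unname(encode_psp(probe, a)),
                 -unname(encode_psp(probe, b)), tolerance = 1e-12)
  }
})

test_that("fitting is invariant to window order within classes", {
  d <- rand_labeled(15, 15, seed = 21)
  set.seed(4)
  shuffled <- d[sample(nrow(d)), ]
  expect_equal(fit_propensity(d, 2)$diff, fit_propensity(shuffled, 2)$diff)
})

test_that("degenerate training data and length mismatches error", {
  d <- rand_labeled(5, 5, seed = 1)
  only_pos <- d[d$label == "positive", ]
  expect_error(fit_propensity(only_pos, 1), "both")
  pm <- fit_propensity(d, 1)
  expect_error(encode_psp(rand_windows(2, L = 39, seed = 2), pm),
               "does not match")
})

test_that("propensity matrices round-trip through TSV", {
  pm <- fit_propensity(rand_labeled(7, 9, seed = 31), k = 2)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_propensity(pm, tsv)
  pm2 <- read_propensity(tsv)
  expect_equal(pm2$diff, pm$diff, tolerance = 1e-12)
  expect_equal(pm2$pos, pm$pos, tolerance = 1e-12)
  expect_identical(pm2$k, pm$k)
  expect_identical(pm2$n_pos, pm$n_pos)
  # re-encoding with the reloaded matrix is identical
  probe <- rand_windows(3, seed = 6)
  expect_equal(encode_psp(probe, pm2), encode_psp(probe, pm),
               tolerance = 1e-12)
})
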