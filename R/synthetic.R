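# Synthetic window generator: balanced positive/negative sets with planted
# class-dependent position-specific nucleotide enrichment.

#' Default position-specific enrichment map
#'
#' Emulates the empirically observed class contrast around m5C sites: C and
#' U enriched at the upstream positions of positive windows, with a weaker
#' A/G enrichment downstream. One row per non-central window position:
#' which nucleotides are enriched in the positive class there, and a weight
#' multiplying the generator's delta.
#'
#' @param width window length (odd; the center is never enriched -- it is
#'   always C).
#' @param upstream_bases nucleotides enriched upstream (positions < 0).
#' @param downstream_bases nucleotides enriched downstream (positions > 0).
#' @param downstream_weight delta multiplier for downstream positions.
#' @return data.frame with columns `position` (-xi..+xi without 0),
#'   `bases` (comma-separated) and `weight`.
#' @export
enrichment_map <- function(width = 41L, upstream_bases = c("C", "U"),
                           downstream_bases = c("A", "G"),
                           downstream_weight = 0.5) {
  pos <- setdiff(window_positions(width), 0L)
  data.frame(
    position = pos,
    bases = ifelse(pos < 0L, paste(upstream_bases, collapse = ","),
                   paste(downstream_bases, collapse = ",")),
    weight = ifelse(pos < 0L, 1, downstream_weight),
    stringsAsFactors = FALSE)
}

#' Synthetic window generator model
#'
#' Defines per-position nucleotide emission probabilities for the positive
#' and negative class. At every enriched position the designated
#' nucleotides get `+delta * weight / 2` in the positive class and
#' `-delta * weight / 2` in the negative class, with the complementary
#' nucleotides compensated so each distribution still sums to 1; the
#' planted positive-minus-negative frequency difference therefore equals
#' `delta * weight` exactly, which is what a fitted propensity matrix
#' recovers in expectation. The central position emits C with probability 1
#' in both classes, so generated windows satisfy the strict-center
#' convention. `neighbor_rho > 0` adds first-order neighbor correlation:
#' each non-central position copies its left neighbor with that probability
#' instead of drawing independently (useful for exercising dinucleotide
#' encoders on correlated sequence).
#'
#' @param width window length (odd), default 41.
#' @param delta planted class frequency difference, e.g. 0.05 for a 5-point
#'   enrichment; must keep all probabilities in [0, 1].
#' @param base_freq background nucleotide probabilities (named, sums to 1).
#' @param map an [enrichment_map()]-style data.frame.
#' @param neighbor_rho first-order copy probability in [0, 1).
#' @param seed default seed used by [generate_windows()].
#' @return An object of class `m5c_generator` with the per-class emission
#'   profiles (`profiles$positive`, `profiles$negative`; 4 x width each).
#' @export
#' @examples
#' g <- generator_model(delta = 0.05)
#' round(g$profiles$positive[, 1:3], 3)
generator_model <- function(width = 41L, delta = 0.05,
                            base_freq = c(A = 0.25, C = 0.25,
                                          G = 0.25, U = 0.25),
                            map = enrichment_map(width),
                            neighbor_rho = 0, seed = 1L) {
  stopifnot(width %% 2L == 1L, delta >= 0,
            all(RNA_BASES %in% names(base_freq)),
            neighbor_rho >= 0, neighbor_rho < 1)
  base_freq <- base_freq[RNA_BASES]
  if (abs(sum(base_freq) - 1) > 1e-12)
    stop("base_freq must sum to 1")
  xi <- (width - 1L) %/% 2L
  profile <- matrix(base_freq, nrow = 4L, ncol = width,
                    dimnames = list(RNA_BASES,
                                    sprintf("p%+d", window_positions(width))))
  pos_profile <- neg_profile <- profile
  for (r in seq_len(nrow(map))) {
    j <- map$position[r] + xi + 1L
    if (map$position[r] == 0L) stop("the central position cannot be enriched")
    enr <- match(strsplit(map$bases[r], ",", fixed = TRUE)[[1L]], RNA_BASES)
    if (anyNA(enr)) stop("unknown base in enrichment map row ", r)
    comp <- setdiff(1:4, enr)
    shift <- delta * map$weight[r] / 2
    pos_profile[enr, j] <- pos_profile[enr, j] + shift
    pos_profile[comp, j] <- pos_profile[comp, j] -
      shift * length(enr) / length(comp)
    neg_profile[enr, j] <- neg_profile[enr, j] - shift
    neg_profile[comp, j] <- neg_profile[comp, j] +
      shift * length(enr) / length(comp)
  }
  pos_profile[, xi + 1L] <- neg_profile[, xi + 1L] <- c(0, 1, 0, 0)
  if (any(pos_profile < 0) || any(neg_profile < 0) ||
      any(pos_profile > 1) || any(neg_profile > 1))
    stop("delta = ", delta, " drives a position probability outside [0, 1]; ",
         "reduce delta or flatten the enrichment map")
  out <- list(width = as.integer(width), delta = delta,
              base_freq = base_freq, map = map,
              neighbor_rho = neighbor_rho, seed = as.integer(seed),
              profiles = list(positive = pos_profile,
                              negative = neg_profile))
  class(out) <- "m5c_generator"
  out
}

#' @export
print.m5c_generator <- function(x, ...) {
  cat(sprintf(paste0("Synthetic m5C window generator: width %d, ",
                     "delta %.3f, neighbor_rho %.2f, seed %d\n"),
              x$width, x$delta, x$neighbor_rho, x$seed))
  up <- x$map$bases[x$map$position < 0][1L]
  down <- x$map$bases[x$map$position > 0][1L]
  cat("  enriched in positives: ", up, " upstream, ", down,
      " downstream\n", sep = "")
  invisible(x)
}

#' Generate labeled synthetic windows
#'
#' Draws windows position by position from the generator's class profiles
#' (independently per position, or with first-order neighbor copying when
#' the model's `neighbor_rho > 0`). Output is reproducible for a fixed
#' seed: positives are drawn first, then negatives.
#'
#' @param model a [generator_model()].
#' @param n_pos,n_neg windows per class (either may be 0, not both).
#' @param seed RNG seed; defaults to the model's.
#' @return An [rna_windows] dataset with ids `pos_*` / `neg_*`.
#' @export
generate_windows <- function(model, n_pos, n_neg, seed = model$seed) {
  stopifnot(inherits(model, "m5c_generator"), n_pos >= 0, n_neg >= 0)
  if (n_pos + n_neg == 0L) stop("empty dataset: n_pos + n_neg must be > 0")
  set.seed(seed)
  draw_class <- function(profile, n) {
    if (n == 0L) return(character(0))
    L <- model$width
    idx <- matrix(0L, nrow = n, ncol = L)
    for (j in seq_len(L)) {
      drawn <- sample.int(4L, n, replace = TRUE, prob = profile[, j])
      if (model$neighbor_rho > 0 && j > 1L && j != (L + 1L) %/% 2L) {
        copy <- stats::runif(n) < model$neighbor_rho
        drawn[copy] <- idx[copy, j - 1L]
      }
      idx[, j] <- drawn
    }
    do.call(paste0, lapply(seq_len(L), function(j) RNA_BASES[idx[, j]]))
  }
  pos <- draw_class(model$profiles$positive, n_pos)
  neg <- draw_class(model$profiles$negative, n_neg)
  rna_windows(c(pos, neg),
              id = c(sprintf("pos_%05d", seq_len(n_pos)),
                     sprintf("neg_%05d", seq_len(n_neg))),
              label = rep(c("positive", "negative"), c(n_pos, n_neg)),
              width = model$width, strict_center = TRUE)
}

#' Write the generating model as a JSON sidecar
#'
#' Records the full generator (profiles included) next to emitted FASTA
#' files so parameter-recovery analyses can compare fitted propensities
#' with the planted truth.
#'
#' @param model a [generator_model()].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_generator_json <- function(model, path) {
  stopifnot(inherits(model, "m5c_generator"))
  jsonlite::write_json(
    list(width = model$width, delta = model$delta,
         base_freq = as.list(model$base_freq), map = model$map,
         neighbor_rho = model$neighbor_rho, seed = model$seed,
         profiles = lapply(model$profiles, function(m)
           as.data.frame(t(m)))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
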