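# Encoder registry, feature specs, named presets and feature fusion.

# Canonical encoder table. `fn` encodes a dataset, `needs` names the fitted
# propensity matrix an encoder requires (NULL for fit-free encoders).
encoder_registry <- function() {
  list(
    psnp = list(needs = "psnp",
                fn = function(x, p, fitted) encode_psp(x, fitted$psnp)),
    psdp = list(needs = "psdp",
                fn = function(x, p, fitted) encode_psp(x, fitted$psdp)),
    pstp = list(needs = "pstp",
                fn = function(x, p, fitted) encode_psp(x, fitted$pstp)),
    nac = list(fn = function(x, p, fitted) encode_kmer(x, 1L)),
    dnc = list(fn = function(x, p, fitted) encode_kmer(x, 2L)),
    tnc = list(fn = function(x, p, fitted) encode_kmer(x, 3L)),
    enac = list(fn = function(x, p, fitted)
      encode_enac(x, win = p$win %||% 5L)),
    xxkgap = list(fn = function(x, p, fitted)
      encode_xxkgap(x, family = p$family, kgap = p$kgap)),
    eiip = list(fn = function(x, p, fitted) encode_eiip(x)),
    pseeiip = list(fn = function(x, p, fitted) encode_pseeiip(x)),
    pc_psednc = list(fn = function(x, p, fitted)
      encode_pc_psednc(x, lambda = p$lambda %||% 3L, w = p$w %||% 0.2,
                       table = p$table)),
    be = list(fn = function(x, p, fitted) encode_be(x)),
    ncp_nd = list(fn = function(x, p, fitted) encode_ncp_nd(x))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Parse one encoder shorthand such as "pstp", "kmer", "mM2Gap" or
# "pc_psednc:lambda=3,w=0.2" into a list of list(id, params) entries.
parse_encoder <- function(s) {
  s <- trimws(s)
  parts <- strsplit(s, ":", fixed = TRUE)[[1L]]
  id <- parts[1L]
  params <- list()
  if (length(parts) > 1L) {
    for (kv in strsplit(parts[2L], ",", fixed = TRUE)[[1L]]) {
      kv2 <- strsplit(kv, "=", fixed = TRUE)[[1L]]
      if (length(kv2) != 2L) stop("cannot parse encoder parameter '", kv, "'")
      params[[trimws(kv2[1L])]] <- as.numeric(kv2[2L])
    }
  }
  gap <- regmatches(id, regexec("^(mM|mD|dM)([123])Gap$", id))[[1L]]
  if (length(gap))
    return(list(list(id = "xxkgap",
                     params = list(family = gap[2L],
                                   kgap = as.integer(gap[3L])))))
  idl <- tolower(id)
  if (idl == "psp")
    return(lapply(c("psnp", "psdp", "pstp"),
                  function(e) list(id = e, params = list())))
  if (idl == "kmer") {
    if (!is.null(params$k))
      return(list(list(id = c("nac", "dnc", "tnc")[params$k],
                       params = list())))
    return(lapply(c("nac", "dnc", "tnc"),
                  function(e) list(id = e, params = list())))
  }
  if (idl == "psednc") idl <- "pc_psednc"
  if (!idl %in% names(encoder_registry()))
    stop("unknown encoder '", id, "'; known: ",
         paste(names(encoder_registry()), collapse = ", "),
         " (plus shorthands psp, kmer, mM1Gap..dM3Gap)")
  if (idl == "pc_psednc" && !is.null(params$lambda))
    params$lambda <- as.integer(params$lambda)
  list(list(id = idl, params = params))
}

#' Build a feature specification
#'
#' A feature spec is an ordered list of encoders (with parameters) whose
#' outputs are concatenated by [fuse()]. Encoders are given as shorthand
#' strings, e.g. `"pstp"`, `"kmer"` (expands to NAC+DNC+TNC), `"psp"`
#' (PSNP+PSDP+PSTP), `"mM2Gap"`, `"enac:win=5"` or
#' `"pc_psednc:lambda=3,w=0.2"`. When `expected_dim` is set, [fuse()]
#' validates the fused width against it.
#'
#' @param encoders character vector of encoder shorthands.
#' @param expected_dim optional integer; fused dimension must equal it.
#' @param name optional display name.
#' @return An object of class `feature_spec`.
#' @export
#' @examples
#' feature_spec(c("psp", "kmer"), expected_dim = 204)
feature_spec <- function(encoders, expected_dim = NULL, name = NULL) {
  entries <- do.call(c, lapply(encoders, parse_encoder))
  key <- vapply(entries, function(e)
    paste(e$id, paste(names(e$params), unlist(e$params),
                      sep = "=", collapse = ","), sep = ":"),
    character(1))
  if (anyDuplicated(key))
    stop("duplicate encoder in spec: ", key[duplicated(key)][1L])
  out <- list(entries = entries,
              expected_dim = if (is.null(expected_dim)) NULL
                             else as.integer(expected_dim),
              name = name %||% paste(encoders, collapse = "+"))
  class(out) <- "feature_spec"
  out
}

#' @export
print.feature_spec <- function(x, ...) {
  cat("Feature spec '", x$name, "': ", length(x$entries),
      " encoder(s)", sep = "")
  if (!is.null(x$expected_dim)) cat(", expected dim ", x$expected_dim, sep = "")
  cat("\n  ", paste(vapply(x$entries, function(e) e$id, character(1)),
                    collapse = " + "), "\n", sep = "")
  invisible(x)
}

# Preset table: encoder lists and their verified fused dimensionalities at
# the default 41-nt window. Two published combinations whose printed feature
# counts (476 and 1,571) cannot be reconciled with the per-encoder
# dimensionalities are deliberately not shipped as presets.
preset_table <- function() {
  list(
    "PSP" = list(enc = "psp", dim = 120L),
    "Kmer" = list(enc = "kmer", dim = 84L),
    "PSP+Kmer" = list(enc = c("psp", "kmer"), dim = 204L),
    "PSP+Kmer+ENAC" = list(enc = c("psp", "kmer", "enac"), dim = 352L),
    "PSP+Kmer+ENAC+mM2Gap" = list(enc = c("psp", "kmer", "enac", "mM2Gap"),
                                  dim = 384L),
    "PseEIIP+PseDNC" = list(enc = c("pseeiip", "pc_psednc:lambda=3,w=0.2"),
                            dim = 83L),
    "BEST" = list(enc = c("psp", "kmer", "pseeiip",
                          "pc_psednc:lambda=3,w=0.2"), dim = 287L),
    "BEST+mM2Gap" = list(enc = c("psp", "kmer", "pseeiip",
                                 "pc_psednc:lambda=3,w=0.2", "mM2Gap"),
                         dim = 319L),
    "BEST+ENAC" = list(enc = c("psp", "kmer", "pseeiip",
                               "pc_psednc:lambda=3,w=0.2", "enac"),
                       dim = 435L)
  )
}

#' Named feature-combination presets
#'
#' Returns the feature spec for a documented encoder combination, with its
#' verified fused dimensionality attached (`expected_dim`), e.g. `"PSP"`
#' (120 features), `"Kmer"` (84), `"PSP+Kmer"` (204), `"BEST"` (287 =
#' PSP + Kmer + PseEIIP + PC-PseDNC, the headline combination). Lookup is
#' case-insensitive.
#'
#' @param name preset name; [preset_names()] lists the valid ones.
#' @return A [feature_spec].
#' @export
#' @examples
#' preset("BEST")
preset <- function(name) {
  tab <- preset_table()
  hit <- match(tolower(name), tolower(names(tab)))
  if (is.na(hit))
    stop("unknown preset '", name, "'; valid presets: ",
         paste(names(tab), collapse = ", "))
  p <- tab[[hit]]
  feature_spec(p$enc, expected_dim = p$dim, name = names(tab)[hit])
}

#' @rdname preset
#' @export
preset_names <- function() names(preset_table())

# features argument normalization shared by the model functions
as_feature_spec <- function(features) {
  if (inherits(features, "feature_spec")) return(features)
  if (is.character(features) && length(features) == 1L &&
      tolower(features) %in% tolower(preset_names()))
    return(preset(features))
  feature_spec(features)
}

# encode one spec entry, given the fitted propensity set
encode_entry <- function(x, entry, fitted) {
  reg <- encoder_registry()[[entry$id]]
  if (!is.null(reg$needs)) {
    pm <- fitted[[reg$needs]]
    if (is.null(pm))
      stop("encoder '", entry$id, "' needs a fitted propensity matrix; ",
           "pass `fitted = fit_psp_set(train)`")
  }
  reg$fn(x, entry$params, fitted)
}

#' Fuse encoders into a feature matrix
#'
#' Encodes every window with each encoder of the spec and concatenates the
#' blocks in spec order. Propensity-based encoders (PSNP/PSDP/PSTP) require
#' fitted matrices (`fitted`), so that within cross-validation they can be
#' refit on each training fold. Column names are prefixed by encoder id and
#' globally unique.
#'
#' @param x an [rna_windows] dataset (may have zero rows).
#' @param spec a [feature_spec], preset name, or character vector of
#'   encoder shorthands.
#' @param fitted optional list from [fit_psp_set()].
#' @return A numeric matrix of class `feature_matrix` with attributes
#'   `labels`, `ids` and `spec`; rows follow `x`.
#' @export
#' @examples
#' d <- generate_windows(generator_model(delta = 0.1), 20, 20, seed = 1)
#' fm <- fuse(d, "BEST", fitted = fit_psp_set(d))
#' dim(fm)
fuse <- function(x, spec, fitted = NULL) {
  stopifnot(inherits(x, "rna_windows"))
  spec <- as_feature_spec(spec)
  enc_input <- x
  empty <- nrow(x) == 0L
  if (empty) {
    # encode one dummy window to obtain column names, then drop the row
    w <- attr(x, "width") %||% 41L
    xi <- (w - 1L) %/% 2L
    dummy <- paste0(strrep("A", xi), "C", strrep("A", xi))
    enc_input <- dummy
  }
  blocks <- lapply(spec$entries, function(e) encode_entry(enc_input, e, fitted))
  out <- do.call(cbind, blocks)
  if (empty) out <- out[0L, , drop = FALSE]
  if (anyDuplicated(colnames(out)))
    stop("internal error: duplicated feature names after fusion")
  if (!is.null(spec$expected_dim) && ncol(out) != spec$expected_dim)
    stop("fused dimension ", ncol(out), " does not match expected_dim ",
         spec$expected_dim, " for spec '", spec$name, "'")
  rownames(out) <- if (empty) NULL else x$id
  attr(out, "labels") <- if (empty) character(0) else x$label
  attr(out, "spec") <- spec
  class(out) <- c("feature_matrix", class(out))
  out
}

#' Write / read a feature matrix as TSV
#'
#' Plain-text exchange format: header row of column names, then one row per
#' window with `id` and `label` in the first two columns.
#'
#' @param fm a [fuse()] feature matrix.
#' @param path TSV file.
#' @return `write_features` returns `path` invisibly; `read_features`
#'   returns a `feature_matrix` (without the originating spec).
#' @export
write_features <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  tab <- data.frame(id = rownames(fm) %||% sprintf("win_%05d", seq_len(nrow(fm))),
                    label = attr(fm, "labels"),
                    as.data.frame(unclass(fm)), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(m) <- tab$id
  attr(m, "labels") <- tab$label
  class(m) <- c("feature_matrix", class(m))
  m
}

#' @export
`[.rna_windows` <- function(x, i, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("id", "seq", "label") %in% names(out))) {
    attr(out, "width") <- attr(x, "width")
    class(out) <- c("rna_windows", "data.frame")
  }
  out
}
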