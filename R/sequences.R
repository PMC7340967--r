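# Fixed-length RNA windows: construction, validation, FASTA I/O.

#' Labeled fixed-length RNA windows
#'
#' Constructs the dataset object used throughout the package: one row per
#' window, with an identifier, a sequence over \{A,C,G,U\} and a class label.
#' All windows must share one odd length (default 41 nt, i.e. half-width
#' xi = 20) and, when `strict_center = TRUE`, carry a C at the central
#' position -- the candidate methylation site.
#'
#' @param seq character vector of window sequences (T is normalized to U).
#' @param id character vector of identifiers; autogenerated when `NULL`.
#' @param label class labels: `"positive"`, `"negative"` or `"unlabeled"`;
#'   recycled if length 1.
#' @param width required window length; taken from the sequences when `NULL`.
#' @param strict_center require a central C.
#' @return An object of class `rna_windows`: a data.frame with columns
#'   `id`, `seq`, `label` and a `width` attribute.
#' @export
#' @examples
#' w <- rna_windows(strrep("ACGU", 10) |> paste0("A"), label = "unlabeled",
#'                  strict_center = FALSE)
#' class_counts(w)
rna_windows <- function(seq, id = NULL, label = "unlabeled",
                        width = NULL, strict_center = TRUE) {
  seq <- toupper(as.character(seq))
  seq <- gsub("T", "U", seq, fixed = TRUE)
  if (length(seq) == 0L) stop("empty dataset: no sequences given")
  if (is.null(id)) id <- sprintf("win_%05d", seq_along(seq))
  id <- as.character(id)
  if (length(id) != length(seq)) stop("id and seq lengths differ")
  label <- rep_len(as.character(label), length(seq))
  bad_label <- setdiff(unique(label), c("positive", "negative", "unlabeled"))
  if (length(bad_label))
    stop("invalid label(s): ", paste(bad_label, collapse = ", "))
  if (is.null(width)) {
    width <- unique(nchar(seq))
    if (length(width) != 1L)
      stop("sequences have mixed lengths: ", paste(width, collapse = ", "))
  }
  problems <- check_window_seqs(seq, width, strict_center)
  if (any(nzchar(problems))) {
    i <- which(nzchar(problems))[1L]
    stop("invalid window '", id[i], "': ", problems[i])
  }
  out <- data.frame(id = id, seq = seq, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "width") <- as.integer(width)
  class(out) <- c("rna_windows", "data.frame")
  out
}

# per-sequence validation; returns "" for valid, else a message
check_window_seqs <- function(seq, width, strict_center) {
  if (width %% 2L != 1L) stop("window width must be odd (2*xi + 1)")
  center <- (width + 1L) %/% 2L
  vapply(seq, function(s) {
    if (nchar(s) != width)
      return(sprintf("length %d, expected %d", nchar(s), width))
    if (grepl("[^ACGU]", s))
      return("characters outside {A,C,G,U} (degenerate IUPAC codes are rejected)")
    if (strict_center && substr(s, center, center) != "C")
      return(sprintf("central position (offset 0) is %s, expected C",
                     substr(s, center, center)))
    ""
  }, character(1), USE.NAMES = FALSE)
}

#' Read RNA windows from a FASTA file
#'
#' Reads one window per FASTA record, normalizes T to U and validates
#' length, alphabet and (optionally) the central cytosine. In strict mode
#' (`on_invalid = "error"`) the first failing record aborts the read with a
#' message naming it; in lenient mode failing records are skipped with a
#' warning. Record order is preserved.
#'
#' @param path FASTA file.
#' @param label class label attached to every record.
#' @param width expected window length (default 41).
#' @param strict_center require the central position to be C.
#' @param on_invalid `"error"` to reject invalid records, `"skip"` to drop
#'   them with a warning.
#' @return An [rna_windows] dataset.
#' @export
read_windows <- function(path, label = c("unlabeled", "positive", "negative"),
                         width = 41L, strict_center = TRUE,
                         on_invalid = c("error", "skip")) {
  label <- match.arg(label)
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("empty dataset: no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  problems <- check_window_seqs(seqs, width, strict_center)
  bad <- nzchar(problems)
  if (any(bad)) {
    if (on_invalid == "error") {
      i <- which(bad)[1L]
      stop("invalid record '", ids[i], "' in ", path, ": ", problems[i])
    }
    warning(sum(bad), " record(s) skipped in ", path, ": ",
            paste(sprintf("%s (%s)", ids[bad], problems[bad]),
                  collapse = "; "))
    ids <- ids[!bad]; seqs <- seqs[!bad]
    if (length(seqs) == 0L) stop("empty dataset: no valid records in ", path)
  }
  out <- data.frame(id = ids, seq = seqs, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "width") <- as.integer(width)
  class(out) <- c("rna_windows", "data.frame")
  out
}

#' Write RNA windows to FASTA
#'
#' Round-trip safe: `read_windows(write_windows(x))` reproduces ids and
#' sequences exactly. Duplicate ids are written as-is with a warning.
#'
#' @param x an [rna_windows] dataset.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_windows <- function(x, path) {
  stopifnot(inherits(x, "rna_windows"))
  if (nrow(x) == 0L) stop("refusing to write an empty dataset")
  if (anyDuplicated(x$id))
    warning("duplicate ids written as-is: ",
            paste(unique(x$id[duplicated(x$id)]), collapse = ", "))
  set <- Biostrings::BStringSet(x$seq)
  names(set) <- x$id
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Combine window datasets
#'
#' @param ... `rna_windows` objects sharing one width.
#' @return A single [rna_windows] dataset.
#' @export
bind_windows <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, logical(1), "rna_windows")))
  widths <- unique(vapply(parts, attr, integer(1), "width"))
  if (length(widths) != 1L)
    stop("datasets have different window widths: ",
         paste(widths, collapse = ", "))
  out <- do.call(rbind.data.frame, lapply(parts, as.data.frame))
  rownames(out) <- NULL
  attr(out, "width") <- widths
  class(out) <- c("rna_windows", "data.frame")
  out
}

#' Class counts of a window dataset
#'
#' @param x an [rna_windows] dataset.
#' @return Named integer vector with counts of positive, negative and
#'   unlabeled windows.
#' @export
class_counts <- function(x) {
  stopifnot(inherits(x, "rna_windows"))
  c(positive = sum(x$label == "positive"),
    negative = sum(x$label == "negative"),
    unlabeled = sum(x$label == "unlabeled"))
}

#' @export
print.rna_windows <- function(x, ...) {
  cc <- class_counts(x)
  cat(sprintf("RNA windows: %d sequence(s) of length %d (positions %+d..%+d)\n",
              nrow(x), attr(x, "width"),
              min(window_positions(attr(x, "width"))),
              max(window_positions(attr(x, "width")))))
  cat(sprintf("  positive: %d  negative: %d  unlabeled: %d\n",
              cc["positive"], cc["negative"], cc["unlabeled"]))
  if (nrow(x) > 0L) {
    show <- utils::head(x, 3L)
    for (i in seq_len(nrow(show)))
      cat(sprintf("  %s [%s] %s...\n", show$id[i], show$label[i],
                  substr(show$seq[i], 1L, 24L)))
    if (nrow(x) > 3L) cat("  ...\n")
  }
  invisible(x)
}

#' Write a provenance manifest
#'
#' Plain TSV with one row per window: id, label and source tag, for
#' provenance logging alongside FASTA exports.
#'
#' @param x an [rna_windows] dataset.
#' @param path output TSV.
#' @param source source tag recorded for every row.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(x, path, source = NA_character_) {
  stopifnot(inherits(x, "rna_windows"))
  utils::write.table(
    data.frame(id = x$id, label = x$label, source = source),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
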