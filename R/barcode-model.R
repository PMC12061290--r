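#' Combinatorial split-pool read structure
#'
#' Describes the barcode architecture at the 5' end of the barcode-bearing
#' read of a combinatorial-indexing (split-pool) library. The default layout
#' is three 6-base bead-round segments followed by one 10-base Tn5-plate
#' segment, a 28-base prefix in total; the genomic insert follows the prefix.
#' Segment order and lengths are configurable because the plate segment's
#' position within the prefix is a library-design choice.
#'
#' @param lengths Integer vector of segment lengths in bases (all positive).
#' @param names Character vector of segment names, same length as `lengths`.
#' @param sources Character vector describing the physical origin of each
#'   segment (e.g. `"bead-round-1"`, `"tn5-plate"`).
#' @param barcode_read Which mate carries the prefix, `1L` or `2L`.
#'
#' @return An object of class `read_structure`: a list with `segments`
#'   (data.frame of name, length, source, offset), `total_prefix_length`
#'   and `barcode_read`. Segments are contiguous from position 0 of the
#'   barcode read.
#' @export
read_structure <- function(lengths = c(6L, 6L, 6L, 10L),
                           names = c("bc1", "bc2", "bc3", "tn5"),
                           sources = c("bead-round-1", "bead-round-2",
                                       "bead-round-3", "tn5-plate"),
                           barcode_read = 1L) {
  lengths <- as.integer(lengths)
  if (length(lengths) < 1L || any(lengths <= 0L))
    stop("segment lengths must be positive integers")
  if (length(names) != length(lengths) || anyDuplicated(names))
    stop("segment names must be unique and match the number of lengths")
  if (length(sources) != length(lengths))
    stop("one source per segment is required")
  if (!barcode_read %in% c(1L, 2L))
    stop("barcode_read must be 1 or 2")
  offsets <- c(0L, cumsum(lengths)[-length(lengths)])
  structure(
    list(
      segments = data.frame(name = names, length = lengths,
                            source = sources, offset = offsets,
                            stringsAsFactors = FALSE),
      total_prefix_length = sum(lengths),
      barcode_read = as.integer(barcode_read)
    ),
    class = "read_structure"
  )
}

#' @exportS3Method base::print
print.read_structure <- function(x, ...) {
  cat(sprintf("Read structure: %d segments, %d-base prefix on read %d\n",
              nrow(x$segments), x$total_prefix_length, x$barcode_read))
  for (i in seq_len(nrow(x$segments)))
    cat(sprintf("  %-6s %2d bp  [%s]\n", x$segments$name[i],
                x$segments$length[i], x$segments$source[i]))
  invisible(x)
}

# Integer-encode equal-length DNA strings as an L x n matrix of raw byte
# values; the workhorse behind all Hamming computations.
.encode_seqs <- function(seqs) {
  if (length(seqs) == 0L) return(matrix(integer(0), nrow = 0L))
  L <- nchar(seqs[1L])
  m <- matrix(as.integer(charToRaw(paste(seqs, collapse = ""))), nrow = L)
  m
}

#' Minimum pairwise Hamming distance of a segment set
#'
#' Exact minimum Hamming distance over all unordered pairs of a set of
#' equal-length sequences. A whitelist segment set with minimum distance
#' >= 3 guarantees that one-mismatch correction is unambiguous.
#'
#' @param seqs Character vector of equal-length sequences.
#' @return Integer minimum distance, or `Inf` when fewer than two sequences
#'   are supplied (the degenerate set imposes no constraint).
#' @export
min_pairwise_hamming <- function(seqs) {
  n <- length(seqs)
  if (n < 2L) return(Inf)
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences must all have the same length")
  m <- .encode_seqs(seqs)
  best <- nchar(seqs[1L])
  for (i in seq_len(n - 1L)) {
    d <- colSums(m[, (i + 1L):n, drop = FALSE] != m[, i])
    di <- min(d)
    if (di < best) best <- di
    if (best == 0L) break
  }
  as.integer(best)
}

# Hamming distances from one query sequence to every whitelist entry,
# using a pre-encoded whitelist matrix.
.hamming_to_set <- function(query, enc) {
  q <- as.integer(charToRaw(query))
  colSums(enc != q)
}

.check_segment_seqs <- function(seqs, expected_len, label) {
  if (length(seqs) == 0L)
    stop(sprintf("whitelist %s is empty", label))
  bad_len <- which(nchar(seqs) != expected_len)
  if (length(bad_len))
    stop(sprintf("whitelist %s line %d: sequence length %d, expected %d",
                 label, bad_len[1L], nchar(seqs[bad_len[1L]]), expected_len))
  bad_chr <- grep("[^ACGT]", seqs)
  if (length(bad_chr))
    stop(sprintf("whitelist %s line %d: non-ACGT character in '%s'",
                 label, bad_chr[1L], seqs[bad_chr[1L]]))
  if (anyDuplicated(seqs))
    stop(sprintf("whitelist %s contains duplicate sequences", label))
  invisible(TRUE)
}

#' Build a whitelist from per-segment sequence files
#'
#' Reads one plain-text file (optionally gzip-compressed) of legal sequences
#' per barcode segment, validates lengths and alphabet, and computes each
#' segment's minimum pairwise Hamming distance. When any segment's minimum
#' distance falls below 3, one-mismatch correction is no longer guaranteed
#' unambiguous and a warning is raised; the ambiguity policy itself is the
#' demultiplexer's concern.
#'
#' @param segment_files Character vector of file paths, one per segment, in
#'   segment order.
#' @param structure A [read_structure()].
#' @return A `barcode_whitelist`: list with `sequences` (list of character
#'   vectors per segment), `min_hamming` (integer vector) and `structure`.
#' @export
build_whitelist <- function(segment_files, structure = read_structure()) {
  if (length(segment_files) != nrow(structure$segments))
    stop("need exactly one whitelist file per segment")
  seqs <- vector("list", length(segment_files))
  for (i in seq_along(segment_files)) {
    x <- readLines(segment_files[i])
    x <- x[nzchar(x)]
    .check_segment_seqs(x, structure$segments$length[i], segment_files[i])
    seqs[[i]] <- x
  }
  whitelist(seqs, structure)
}

#' Build a whitelist from in-memory segment sets
#'
#' @param sequences List of character vectors, one per segment.
#' @param structure A [read_structure()].
#' @return A `barcode_whitelist` (see [build_whitelist()]).
#' @export
whitelist <- function(sequences, structure = read_structure()) {
  if (length(sequences) != nrow(structure$segments))
    stop("need one sequence set per segment")
  for (i in seq_along(sequences))
    .check_segment_seqs(sequences[[i]], structure$segments$length[i],
                        sprintf("segment %d", i))
  names(sequences) <- structure$segments$name
  mh <- vapply(sequences, function(s) {
    d <- min_pairwise_hamming(s)
    if (is.infinite(d)) NA_integer_ else as.integer(d)
  }, integer(1))
  low <- which(!is.na(mh) & mh < 3L)
  if (length(low))
    warning(sprintf(
      "segment(s) %s have minimum pairwise Hamming distance < 3; ",
      paste(names(sequences)[low], collapse = ", ")),
      "one-mismatch correction may be ambiguous", call. = FALSE)
  structure(
    list(sequences = sequences, min_hamming = mh, structure = structure),
    class = "barcode_whitelist"
  )
}

#' @exportS3Method base::print
print.barcode_whitelist <- function(x, ...) {
  cat(sprintf("Barcode whitelist: %d segments\n", length(x$sequences)))
  for (i in seq_along(x$sequences))
    cat(sprintf("  %-6s %5d sequences, min pairwise Hamming %s\n",
                names(x$sequences)[i], length(x$sequences[[i]]),
                ifelse(is.na(x$min_hamming[i]), "-", x$min_hamming[i])))
  invisible(x)
}

#' Canonical cell-barcode identifier
#'
#' Joins corrected segment sequences in read order with a fixed separator.
#' Identical corrected segments always yield the identical identifier.
#'
#' @param segments Character vector (one barcode) or a list/data.frame of
#'   per-segment character vectors (many barcodes, vectorized).
#' @param sep Separator between segments; `"+"` by default.
#' @return Character vector of canonical identifiers.
#' @export
cell_barcode_id <- function(segments, sep = "+") {
  if (is.list(segments)) do.call(paste, c(segments, sep = sep))
  else paste(segments, collapse = sep)
}

#' Write whitelist segment files
#'
#' One sequence per line, one file per segment, under `dir` as
#' `<segment-name>.txt`.
#'
#' @param wl A `barcode_whitelist`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_whitelist <- function(wl, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(names(wl$sequences), ".txt"))
  for (i in seq_along(paths)) writeLines(wl$sequences[[i]], paths[i])
  invisible(paths)
}
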