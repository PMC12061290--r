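#' @importFrom Biostrings readDNAStringSet DNAStringSet BStringSet
#'   writeXStringSet
NULL

#' Parse the barcode prefix of a read
#'
#' Slices the raw segment sequences and their qualities from the prefix of a
#' barcode-bearing read and returns the remainder (the genomic insert after
#' trimming).
#'
#' @param seq Read sequence (character scalar).
#' @param qual Phred quality string (same length as `seq`), or `NULL`.
#' @param structure A [read_structure()].
#' @return A list with `segments`, `segment_quals`, `remainder`,
#'   `remainder_qual`; or `NULL` when the read is shorter than the prefix
#'   (the caller counts it as a "too-short" rejection).
#' @export
parse_read <- function(seq, qual = NULL, structure = read_structure()) {
  L <- structure$total_prefix_length
  if (nchar(seq) < L) return(NULL)
  off <- structure$segments$offset
  len <- structure$segments$length
  segs <- substring(seq, off + 1L, off + len)
  names(segs) <- structure$segments$name
  out <- list(segments = segs,
              segment_quals = NULL,
              remainder = substring(seq, L + 1L),
              remainder_qual = NULL)
  if (!is.null(qual)) {
    if (nchar(qual) != nchar(seq)) stop("quality string length mismatch")
    out$segment_quals <- substring(qual, off + 1L, off + len)
    names(out$segment_quals) <- structure$segments$name
    out$remainder_qual <- substring(qual, L + 1L)
  }
  out
}

# Phred scores (offset 33) for a vector of equal-length quality strings,
# as an L x n integer matrix.
.phred_matrix <- function(qual_strings, L) {
  matrix(as.integer(charToRaw(paste(qual_strings, collapse = ""))) - 33L,
         nrow = L)
}

#' Barcode quality gate
#'
#' A read passes when the quality statistic over its barcode-prefix bases is
#' at least `min_q`. The strict reading of a "barcode quality below 10"
#' removal rule takes the statistic to be the minimum base quality; a
#' mean-quality mode is provided as the laxer alternative.
#'
#' @param qual Quality string(s) covering at least the barcode prefix.
#' @param structure A [read_structure()].
#' @param min_q Phred threshold (default 10); the gate is `>= min_q`.
#' @param stat `"min"` (default) or `"mean"`.
#' @return Logical vector, one entry per read.
#' @export
passes_quality <- function(qual, structure = read_structure(),
                           min_q = 10, stat = c("min", "mean")) {
  stat <- match.arg(stat)
  if (any(is.na(qual)) || any(!nzchar(qual)))
    stop("missing barcode qualities: malformed FASTQ")
  L <- structure$total_prefix_length
  if (any(nchar(qual) < L))
    stop("quality string shorter than the barcode prefix")
  m <- .phred_matrix(substr(qual, 1L, L), L)
  s <- if (stat == "min") do.call(pmin, lapply(seq_len(L), function(i) m[i, ]))
       else colMeans(m)
  s >= min_q
}

# Vectorized per-segment whitelist correction. Returns a list with
# `value` (corrected sequence or NA), `status` ("exact", "corrected",
# "uncorrectable", "ambiguous").
.correct_segment <- function(obs, wl_seqs) {
  status <- rep("exact", length(obs))
  value <- obs
  hit <- obs %in% wl_seqs
  if (!all(hit)) {
    enc <- .encode_seqs(wl_seqs)
    fails <- unique(obs[!hit])
    corr <- character(length(fails)); st <- character(length(fails))
    for (i in seq_along(fails)) {
      d <- .hamming_to_set(fails[i], enc)
      near <- which(d <= 1L)
      if (length(near) == 1L) { corr[i] <- wl_seqs[near]; st[i] <- "corrected" }
      else if (length(near) == 0L) { corr[i] <- NA_character_; st[i] <- "uncorrectable" }
      else { corr[i] <- NA_character_; st[i] <- "ambiguous" }
    }
    idx <- match(obs[!hit], fails)
    value[!hit] <- corr[idx]
    status[!hit] <- st[idx]
  }
  list(value = value, status = status)
}

#' Whitelist-correct one barcode observation
#'
#' Each segment is corrected independently: an exact whitelist match is kept;
#' otherwise a unique whitelist entry at Hamming distance 1 replaces it;
#' otherwise the read is rejected ("uncorrectable" when nothing is within
#' distance 1, "ambiguous" when several entries are). All segments must
#' resolve for assignment; ambiguous hits are never tie-broken.
#'
#' @param segments Character vector of observed segment sequences.
#' @param wl A `barcode_whitelist`.
#' @param sep Separator for the canonical identifier.
#' @return A list with `barcode` (canonical id or `NA`), `status`
#'   (`"assigned"`, `"uncorrectable"` or `"ambiguous"`) and `corrected`
#'   (logical per segment).
#' @export
correct_barcode <- function(segments, wl, sep = "+") {
  stopifnot(length(segments) == length(wl$sequences))
  vals <- character(length(segments))
  stats <- character(length(segments))
  for (i in seq_along(segments)) {
    r <- .correct_segment(segments[i], wl$sequences[[i]])
    vals[i] <- r$value; stats[i] <- r$status
  }
  if (anyNA(vals)) {
    status <- if ("uncorrectable" %in% stats) "uncorrectable" else "ambiguous"
    return(list(barcode = NA_character_, status = status,
                corrected = stats == "corrected"))
  }
  list(barcode = cell_barcode_id(vals, sep = sep), status = "assigned",
       corrected = stats == "corrected")
}

.read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  list(name = names(x),
       seq = as.character(x),
       qual = as.character(S4Vectors::mcols(x)$qualities))
}

.write_fastq <- function(name, seq, qual, path) {
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- name
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

.first_word <- function(x) sub("[ /].*$", "", x)

#' Demultiplex a paired FASTQ run
#'
#' Extracts the barcode prefix from the barcode-bearing mate, applies the
#' quality gate, corrects each segment against the whitelist (one mismatch
#' per segment), trims the prefix, and emits assigned pairs with the
#' canonical cell barcode embedded in the read name
#' (`<barcode><sep><original name>`). Rejected reads are counted by category;
#' the categories partition the input.
#'
#' @param r1,r2 Paths to the two mate FASTQ files (optionally gzipped).
#' @param wl A `barcode_whitelist`.
#' @param structure A [read_structure()]; `structure$barcode_read` names the
#'   mate that carries the prefix.
#' @param min_q Phred threshold for the barcode quality gate (default 10).
#' @param qual_stat `"min"` or `"mean"`; see [passes_quality()].
#' @param out_r1,out_r2 Output FASTQ paths; when `NULL`, reads are returned
#'   in memory only.
#' @param name_sep Separator between barcode and original read name.
#' @return A list of class `demux_result`: `stats` (a `DemuxStats`-style
#'   list), `assignments` (data.frame of read name and barcode for assigned
#'   reads), and when no output path is given, `reads` (name/seq/qual
#'   vectors for both trimmed mates).
#' @export
demux_fastq <- function(r1, r2, wl, structure = read_structure(),
                        min_q = 10, qual_stat = c("min", "mean"),
                        out_r1 = NULL, out_r2 = NULL, name_sep = ":") {
  qual_stat <- match.arg(qual_stat)
  f1 <- .read_fastq(r1); f2 <- .read_fastq(r2)
  if (length(f1$name) != length(f2$name))
    stop("mate files differ in read count")
  n1 <- .first_word(f1$name); n2 <- .first_word(f2$name)
  bad <- which(n1 != n2)
  if (length(bad))
    stop(sprintf("desynchronized mates at record %d: '%s' vs '%s'",
                 bad[1L], n1[bad[1L]], n2[bad[1L]]))
  bc <- if (structure$barcode_read == 1L) f1 else f2
  n <- length(bc$seq)
  L <- structure$total_prefix_length

  status <- rep("assigned", n)
  too_short <- nchar(bc$seq) < L
  status[too_short] <- "too-short"
  ok <- !too_short

  qpass <- rep(FALSE, n)
  if (any(ok))
    qpass[ok] <- passes_quality(bc$qual[ok], structure, min_q, qual_stat)
  status[ok & !qpass] <- "quality"
  ok <- ok & qpass

  segs <- structure$segments
  seg_vals <- matrix(NA_character_, nrow = n, ncol = nrow(segs))
  seg_status <- matrix("", nrow = n, ncol = nrow(segs))
  for (j in seq_len(nrow(segs))) {
    obs <- substr(bc$seq[ok], segs$offset[j] + 1L,
                  segs$offset[j] + segs$length[j])
    r <- .correct_segment(obs, wl$sequences[[j]])
    seg_vals[ok, j] <- r$value
    seg_status[ok, j] <- r$status
  }
  unresolved <- ok & rowSums(is.na(seg_vals)) > 0L
  has_uncorr <- unresolved & rowSums(seg_status == "uncorrectable") > 0L
  status[has_uncorr] <- "uncorrectable"
  status[unresolved & !has_uncorr] <- "ambiguous"
  assigned <- ok & !unresolved

  barcodes <- rep(NA_character_, n)
  if (any(assigned))
    barcodes[assigned] <- do.call(
      paste, c(lapply(seq_len(ncol(seg_vals)),
                      function(j) seg_vals[assigned, j]), sep = "+"))

  per_segment_corrections <- colSums(seg_status == "corrected" &
                                       assigned)
  names(per_segment_corrections) <- segs$name
  stats <- list(
    total = n,
    rejected_too_short = sum(status == "too-short"),
    rejected_quality = sum(status == "quality"),
    rejected_uncorrectable = sum(status == "uncorrectable"),
    rejected_ambiguous = sum(status == "ambiguous"),
    assigned = sum(assigned),
    per_segment_corrections = as.list(per_segment_corrections)
  )

  idx <- which(assigned)
  orig <- .first_word(bc$name[idx])
  new_names <- paste0(barcodes[idx], name_sep, orig)
  if (structure$barcode_read == 1L) {
    o1_seq <- substring(f1$seq[idx], L + 1L)
    o1_qual <- substring(f1$qual[idx], L + 1L)
    o2_seq <- f2$seq[idx]; o2_qual <- f2$qual[idx]
  } else {
    o1_seq <- f1$seq[idx]; o1_qual <- f1$qual[idx]
    o2_seq <- substring(f2$seq[idx], L + 1L)
    o2_qual <- substring(f2$qual[idx], L + 1L)
  }

  res <- list(
    stats = stats,
    assignments = data.frame(name = orig, barcode = barcodes[idx],
                             stringsAsFactors = FALSE)
  )
  if (!is.null(out_r1)) {
    .write_fastq(new_names, o1_seq, o1_qual, out_r1)
    .write_fastq(new_names, o2_seq, o2_qual, out_r2)
    res$files <- c(r1 = out_r1, r2 = out_r2)
  } else {
    res$reads <- list(name = new_names,
                      r1 = list(seq = o1_seq, qual = o1_qual),
                      r2 = list(seq = o2_seq, qual = o2_qual))
  }
  class(res) <- "demux_result"
  res
}

#' @exportS3Method base::print
print.demux_result <- function(x, ...) {
  s <- x$stats
  cat(sprintf("Demultiplexed %d read pairs: %d assigned (%.2f%%)\n",
              s$total, s$assigned, 100 * s$assigned / max(s$total, 1L)))
  cat(sprintf("  rejected: %d too-short, %d quality, %d uncorrectable, %d ambiguous\n",
              s$rejected_too_short, s$rejected_quality,
              s$rejected_uncorrectable, s$rejected_ambiguous))
  invisible(x)
}

#' Write demultiplexing statistics
#'
#' @param stats The `stats` element of a [demux_fastq()] result.
#' @param tsv,json Output paths; either may be `NULL`.
#' @return Invisibly, `stats`.
#' @export
write_demux_stats <- function(stats, tsv = NULL, json = NULL) {
  flat <- stats[c("total", "rejected_too_short", "rejected_quality",
                  "rejected_uncorrectable", "rejected_ambiguous",
                  "assigned")]
  if (!is.null(tsv)) {
    df <- data.frame(metric = names(flat), value = unlist(flat))
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json))
    jsonlite::write_json(stats, json, auto_unbox = TRUE, pretty = TRUE)
  invisible(stats)
}
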