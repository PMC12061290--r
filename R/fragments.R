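#' @importFrom Rsamtools asBam scanBam ScanBamParam scanBamFlag
#'   scanBamHeader
NULL

# Read properly-paired primary alignments carrying a cell-barcode tag from a
# SAM or BAM file and pair mates by query name. Coordinates become 0-based
# half-open template intervals [leftmost, rightmost + 1). Returns the raw
# pair table plus skip counters and the header's chromosome lengths.
.read_pairs <- function(path, barcode_tag = "CB", min_mapq = 2,
                        name_sep = ":") {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth", "mapq"),
    tag = barcode_tag,
    flag = Rsamtools::scanBamFlag(isPaired = TRUE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE))
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  bc <- x$tag[[barcode_tag]]
  if (is.null(bc)) bc <- rep(NA_character_, length(x$qname))
  # fall back to barcode-prefixed query names where the tag is absent
  no_tag <- is.na(bc)
  prefixed <- no_tag & grepl(name_sep, x$qname, fixed = TRUE)
  bc[prefixed] <- sub(paste0(name_sep, ".*$"), "", x$qname[prefixed])

  n_records <- length(x$qname)
  proper <- bitwAnd(x$flag, 2L) > 0L
  skipped_improper_rec <- sum(!proper)
  mq_ok <- x$mapq >= min_mapq
  skipped_mapq_rec <- sum(proper & !mq_ok)
  keep <- proper & mq_ok
  no_bc <- keep & is.na(bc)
  skipped_no_barcode_rec <- sum(no_bc)
  keep <- keep & !is.na(bc)

  qn <- x$qname[keep]
  tab <- table(qn)
  full <- names(tab)[tab == 2L]
  keep2 <- keep
  keep2[keep] <- qn %in% full
  broken <- sum(keep) - sum(keep2)

  qname <- x$qname[keep2]
  ord <- order(qname, x$pos[keep2])
  qname <- qname[ord]
  chrom <- as.character(x$rname[keep2])[ord]
  pos <- x$pos[keep2][ord]
  width <- x$qwidth[keep2][ord]
  bc2 <- bc[keep2][ord]
  i1 <- seq(1L, length(qname), by = 2L)
  i2 <- i1 + 1L
  same_chrom <- chrom[i1] == chrom[i2] & bc2[i1] == bc2[i2]
  skipped_cross <- sum(!same_chrom)
  i1 <- i1[same_chrom]; i2 <- i2[same_chrom]

  pairs <- data.frame(
    qname = qname[i1],
    chrom = chrom[i1],
    start = pos[i1] - 1L,                       # 0-based inclusive
    end = pos[i2] + width[i2] - 1L,             # 0-based exclusive
    barcode = bc2[i1],
    stringsAsFactors = FALSE)

  list(pairs = pairs,
       chrom_lengths = hdr,
       counters = c(records = n_records,
                    skipped_improper = skipped_improper_rec,
                    skipped_mapq = skipped_mapq_rec,
                    skipped_no_barcode = skipped_no_barcode_rec,
                    skipped_unpaired = broken + sum(!same_chrom) * 2L))
}

#' Tn5 insertion-site shift
#'
#' Tn5 tagmentation duplicates 9 bp at each insertion, so the two template
#' ends overestimate the accessible interval: the plus-strand insertion is
#' shifted by +4 and the minus-strand insertion by -5. For a raw template
#' interval `[start, end)` (0-based half-open) the corrected interval is
#' `[start + 4, end - 5)`; pairs whose corrected interval is empty are
#' dropped and counted.
#'
#' @param start,end Integer vectors of raw 0-based half-open template
#'   coordinates.
#' @param plus_shift,minus_shift Shift sizes (defaults +4 and -5).
#' @return A list with `start`, `end` (corrected coordinates) and `keep`
#'   (logical; `FALSE` where the corrected interval is empty).
#' @export
shift_insertions <- function(start, end, plus_shift = 4L, minus_shift = -5L) {
  s <- start + plus_shift
  e <- end + minus_shift
  list(start = s, end = e, keep = s < e)
}

#' Build a per-cell fragment table from tagged paired alignments
#'
#' Converts properly paired, barcode-tagged alignments into Tn5-shifted
#' fragments: the raw template interval `[leftmost, rightmost + 1)` is
#' corrected by +4/-5, fragments on excluded chromosomes (chrY and chrM by
#' default, case-insensitive) are removed, exact duplicates (same
#' chromosome, start, end and barcode) are collapsed to one row carrying a
#' duplicate count, and the table is sorted by (chromosome, start, end,
#' barcode).
#'
#' @param path SAM or BAM file with a cell-barcode tag (or barcode-prefixed
#'   query names).
#' @param excluded_chroms Chromosome names to drop (case-insensitive).
#' @param min_mapq Minimum mapping quality, applied per record before
#'   pairing (default 2).
#' @param barcode_tag SAM tag carrying the cell barcode (default `"CB"`).
#' @param genome Optional named vector of chromosome lengths; defaults to
#'   the file header. Unknown chromosomes or out-of-range coordinates are
#'   an error.
#' @return A data.frame of class `fragment_table` with columns `chrom`,
#'   `start`, `end`, `barcode`, `count`, and attributes `counters` (skip
#'   and drop counts) and `chrom_lengths`.
#' @export
build_fragments <- function(path, excluded_chroms = c("chrY", "chrM"),
                            min_mapq = 2, barcode_tag = "CB",
                            genome = NULL) {
  rp <- .read_pairs(path, barcode_tag = barcode_tag, min_mapq = min_mapq)
  pr <- rp$pairs
  if (is.null(genome)) genome <- rp$chrom_lengths
  unknown <- setdiff(unique(pr$chrom), names(genome))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  out_of_range <- pr$end > genome[pr$chrom]
  if (any(out_of_range))
    stop(sprintf("%d fragment(s) extend beyond the declared chromosome length",
                 sum(out_of_range)))

  sh <- shift_insertions(pr$start, pr$end)
  dropped_empty <- sum(!sh$keep)
  pr$start <- sh$start; pr$end <- sh$end
  pr <- pr[sh$keep, , drop = FALSE]

  excl <- tolower(pr$chrom) %in% tolower(excluded_chroms)
  dropped_excluded <- sum(excl)
  pr <- pr[!excl, , drop = FALSE]

  key <- paste(pr$chrom, pr$start, pr$end, pr$barcode, sep = "\r")
  cnt <- table(key)
  first <- !duplicated(key)
  fr <- pr[first, c("chrom", "start", "end", "barcode"), drop = FALSE]
  fr$count <- as.integer(cnt[key[first]])
  ord <- order(fr$chrom, fr$start, fr$end, fr$barcode, method = "radix")
  fr <- fr[ord, , drop = FALSE]
  rownames(fr) <- NULL

  attr(fr, "counters") <- c(rp$counters,
                            pairs = nrow(rp$pairs),
                            dropped_empty_after_shift = dropped_empty,
                            dropped_excluded_chrom = dropped_excluded)
  attr(fr, "chrom_lengths") <- genome
  class(fr) <- c("fragment_table", "data.frame")
  fr
}

#' Write / read a fragments file
#'
#' Five-column BED-like TSV (chrom, start, end, barcode, count),
#' coordinate-sorted, no header; `.gz` paths are compressed.
#'
#' @param fragments A `fragment_table` (or compatible data.frame).
#' @param path Output (input) path.
#' @return `write_fragments` returns `path` invisibly; `read_fragments`
#'   returns a `fragment_table`.
#' @export
write_fragments <- function(fragments, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(as.data.frame(fragments)[, c("chrom", "start", "end",
                                                  "barcode", "count")],
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments
#' @export
read_fragments <- function(path) {
  fr <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end",
                                        "barcode", "count"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "integer"))
  class(fr) <- c("fragment_table", "data.frame")
  fr
}

#' Read / write TSS annotation as BED6
#'
#' Tab-separated, no header: chrom, start (0-based site), end, name,
#' score, strand.
#'
#' @param tss BED6-layout data.frame.
#' @param path File path.
#' @return `write_tss_bed` returns `path` invisibly; `read_tss_bed`
#'   returns the data.frame.
#' @export
write_tss_bed <- function(tss, path) {
  utils::write.table(tss[, c("chrom", "start", "end", "name", "score",
                             "strand")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_tss_bed
#' @export
read_tss_bed <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end", "name",
                                  "score", "strand"),
                    colClasses = c("character", "integer", "integer",
                                   "character", "integer", "character"))
}

#' Per-cell TSS enrichment score
#'
#' Aggregates Tn5 insertion sites (both fragment ends: the start, and
#' `end - 1`) over strand-oriented windows around transcription start
#' sites. Each cell's score is the mean per-base insertion count in the
#' central `window` bases divided by the mean count over the outermost
#' `bg_width` bases of each flank, with the background floored at
#' `bg_floor` to avoid division by zero. Cells with zero fragments score 0
#' and are flagged.
#'
#' @param fragments A `fragment_table`.
#' @param tss data.frame in BED6 layout (`chrom`, `start`, `end`, `name`,
#'   `score`, `strand`); the site is the 0-based `start`.
#' @param flank Half-width of the aggregation window in bases (default 2000).
#' @param window Width of the central window (odd, default 101).
#' @param bg_width Width of the background region at each flank end
#'   (default 100).
#' @param bg_floor Floor on the background mean (default 0.1).
#' @param barcodes Cells to score; defaults to the barcodes present in
#'   `fragments`. Cells listed here with no fragments score 0 and are
#'   flagged.
#' @return data.frame with columns `barcode`, `n_fragments` (unique
#'   fragments), `tss_score`, `zero_fragments` flag.
#' @export
tss_enrichment <- function(fragments, tss, flank = 2000L, window = 101L,
                           bg_width = 100L, bg_floor = 0.1,
                           barcodes = NULL) {
  if (nrow(tss) < 1L) stop("at least one TSS site is required")
  barcodes <- sort(union(unique(fragments$barcode), barcodes))
  half <- (window - 1L) %/% 2L

  # insertion sites: both ends of every fragment, replicated by count
  reps <- rep(seq_len(nrow(fragments)), fragments$count)
  site_chrom <- rep(fragments$chrom[reps], 2L)
  site_pos <- c(fragments$start[reps], fragments$end[reps] - 1L)
  site_bc <- rep(fragments$barcode[reps], 2L)

  rel_list <- vector("list", nrow(tss))
  bc_list <- vector("list", nrow(tss))
  for (i in seq_len(nrow(tss))) {
    on_chrom <- site_chrom == tss$chrom[i]
    d <- site_pos[on_chrom] - tss$start[i]
    inwin <- abs(d) <= flank
    strand_sign <- if (identical(tss$strand[i], "-")) -1L else 1L
    rel_list[[i]] <- d[inwin] * strand_sign
    bc_list[[i]] <- site_bc[on_chrom][inwin]
  }
  rel <- unlist(rel_list)
  bc <- unlist(bc_list)

  center <- abs(rel) <= half
  bg <- abs(rel) > (flank - bg_width)
  cnt_center <- table(factor(bc[center], levels = barcodes))
  cnt_bg <- table(factor(bc[bg], levels = barcodes))
  mean_center <- as.numeric(cnt_center) / window
  mean_bg <- as.numeric(cnt_bg) / (2L * bg_width)
  score <- mean_center / pmax(mean_bg, bg_floor)

  nfrag <- tapply(rep(1L, nrow(fragments)), factor(fragments$barcode,
                                                   levels = barcodes), sum)
  nfrag[is.na(nfrag)] <- 0L
  zero <- as.integer(nfrag) == 0L
  score[zero] <- 0
  data.frame(barcode = barcodes,
             n_fragments = as.integer(nfrag),
             tss_score = score,
             zero_fragments = zero,
             stringsAsFactors = FALSE)
}

#' Select cells passing scATAC quality control
#'
#' Keeps cells with TSS enrichment score strictly greater than `tss_min`
#' and unique fragment count strictly greater than `frag_min` (both
#' conditions required).
#'
#' @param qc data.frame from [tss_enrichment()].
#' @param tss_min TSS score threshold (default 10, strict `>`).
#' @param frag_min Unique-fragment threshold (default 1500, strict `>`).
#' @return Character vector of passing barcodes.
#' @export
filter_cells <- function(qc, tss_min = 10, frag_min = 1500) {
  qc$barcode[qc$tss_score > tss_min & qc$n_fragments > frag_min]
}
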