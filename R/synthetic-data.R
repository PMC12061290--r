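#' Configuration for the synthetic-data generator
#'
#' One seeded configuration object drives all three generators
#' ([simulate_reads()], [simulate_alignments()],
#' [simulate_timecourse()]); the seed fully determines every output.
#' Defaults emulate the assay and study design at desk scale: a
#' 3x6bp + 1x10bp split-pool barcode layout, a small genome with annotated
#' TSSs, and a branching multi-timepoint expression course with planted
#' lineage, entropy and gene-module structure.
#'
#' @param seed Integer master seed.
#' @param n_reads Read pairs to simulate.
#' @param n_cells Distinct cell barcodes behind the reads.
#' @param whitelist_sizes Sequences per barcode segment.
#' @param error_rate Per-base substitution error rate.
#' @param read_length Length of each mate.
#' @param low_quality_frac Fraction of reads given a quality-gate-failing
#'   barcode base (Phred 2).
#' @param genome Named integer vector of chromosome lengths.
#' @param n_tss TSS sites to annotate.
#' @param n_good_cells,n_bg_cells Cells with TSS-concentrated vs uniform
#'   insertions.
#' @param frags_per_good,frags_per_bg Fragments per cell in each class.
#' @param dup_rate Probability that a fragment is emitted a second time
#'   (PCR duplicate).
#' @param mito_frac Fraction of fragments placed on chrM.
#' @param timepoints Timepoint labels, in chronological order.
#' @param cells_per_timepoint Cells per timepoint.
#' @param n_genes Generic (non-module) genes.
#' @param branch_at Index of the first timepoint at which the two lineage
#'   branches are separate (2 = branches separate at the second timepoint).
#' @param drift Log-scale drift magnitude per timepoint step along each
#'   branch (0 makes all timepoints exchangeable).
#' @param dispersion Negative-binomial dispersion (1/size).
#' @param n_branch_genes Genes carrying each branch's program.
#' @param n_drivers Planted driver genes per branch (a subset of the
#'   branch genes).
#' @param n_highdeg Planted high-connectome-degree (hub) genes.
#' @param metastable_frac Fraction of branch-point-timepoint cells planted
#'   as the metastable, hub-gene-expressing population.
#' @param n_rp,n_cc,n_mito Ribosomal-protein, cell-cycle and mitochondrial
#'   genes included in the gene universe.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       # reads
                       n_reads = 10000L, n_cells = 200L,
                       whitelist_sizes = c(24L, 24L, 24L, 96L),
                       error_rate = 0.001, read_length = 100L,
                       low_quality_frac = 0,
                       # alignments
                       genome = c(chr1 = 1000000L, chr2 = 1000000L,
                                  chrY = 200000L, chrM = 16299L),
                       n_tss = 30L,
                       n_good_cells = 20L, n_bg_cells = 20L,
                       frags_per_good = 2500L, frags_per_bg = 600L,
                       dup_rate = 0.1, mito_frac = 0.02,
                       # time course
                       timepoints = c("D0", "D2", "D4", "D6"),
                       cells_per_timepoint = 500L,
                       n_genes = 250L, branch_at = 2L, drift = 0.8,
                       dispersion = 0.1, n_branch_genes = 40L,
                       n_drivers = 10L, n_highdeg = 25L,
                       metastable_frac = 0.3,
                       n_rp = 20L, n_cc = 15L, n_mito = 5L) {
  cfg <- as.list(environment())
  stopifnot(cfg$error_rate >= 0, cfg$error_rate <= 1,
            cfg$dup_rate >= 0, cfg$dup_rate <= 1,
            cfg$branch_at >= 2L, cfg$branch_at <= length(cfg$timepoints))
  if (2L * cfg$n_branch_genes + cfg$n_highdeg > cfg$n_genes)
    stop("n_genes is too small for the planted branch and hub modules")
  if (cfg$n_drivers > cfg$n_branch_genes)
    stop("n_drivers cannot exceed n_branch_genes")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a whitelist with a minimum-distance guarantee
#'
#' Greedy rejection sampling: random sequences are kept only when at
#' Hamming distance >= `min_dist` from every kept sequence. Errors out
#' when the requested size cannot be reached.
#'
#' @param sizes Sequences per segment.
#' @param structure A [read_structure()].
#' @param min_dist Minimum pairwise Hamming distance per segment.
#' @param seed Integer seed.
#' @param max_attempts Sampling attempts per segment before giving up.
#' @return A `barcode_whitelist`.
#' @export
simulate_whitelist <- function(sizes = c(24L, 24L, 24L, 96L),
                               structure = read_structure(),
                               min_dist = 3L, seed = 1L,
                               max_attempts = 50000L) {
  stopifnot(length(sizes) == nrow(structure$segments), all(sizes >= 2L))
  .with_seed(seed, {
    seqs <- vector("list", length(sizes))
    for (s in seq_along(sizes)) {
      L <- structure$segments$length[s]
      kept <- character(0)
      enc <- NULL
      attempts <- 0L
      while (length(kept) < sizes[s]) {
        attempts <- attempts + 1L
        if (attempts > max_attempts)
          stop(sprintf(
            "cannot reach %d length-%d sequences at Hamming distance >= %d",
            sizes[s], L, min_dist))
        cand <- .random_dna(1L, L)
        if (length(kept) == 0L || min(.hamming_to_set(cand, enc)) >= min_dist) {
          kept <- c(kept, cand)
          enc <- .encode_seqs(kept)
        }
      }
      seqs[[s]] <- kept
    }
    whitelist(seqs, structure)
  })
}

# inject substitution errors at `rate` per base; returns the mutated
# sequences and the per-base error mask (L x n logical matrix)
.inject_errors <- function(seqs, rate) {
  if (length(seqs) == 0L || rate <= 0)
    return(list(seqs = seqs,
                errors = matrix(FALSE, nchar(seqs[1] %||% ""), length(seqs))))
  L <- nchar(seqs[1L])
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), nrow = L)
  err <- matrix(stats::runif(length(m)) < rate, nrow = L)
  if (any(err)) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    idx <- which(err)
    pick <- sample.int(3L, length(idx), replace = TRUE)
    m[idx] <- mapply(function(b, p) alt[[b]][p], m[idx], pick,
                     USE.NAMES = FALSE)
  }
  list(seqs = .collapse_cols(m), errors = err)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a barcoded paired-end FASTQ run
#'
#' Draws a whitelist (pairwise Hamming distance >= 3 within each segment),
#' samples cell barcodes from the whitelist product set, emits read pairs
#' whose barcode-bearing mate carries the barcode prefix followed by a
#' random genomic insert, injects per-base substitution errors, and
#' writes Phred qualities consistent with the error status (error bases are
#' assigned lower quality). A ground-truth table records the true barcode
#' of every read.
#'
#' @param config A [sim_config()].
#' @param out_dir When given, FASTQ files are written here
#'   (`reads_R1.fastq.gz`, `reads_R2.fastq.gz`).
#' @param structure A [read_structure()].
#' @return List with `whitelist`, `structure`, `truth` (data.frame of read
#'   `name` and true `barcode`), `reads` (in-memory name/seq/qual lists)
#'   and, when written, `files`.
#' @export
simulate_reads <- function(config = sim_config(), out_dir = NULL,
                           structure = read_structure()) {
  wl <- simulate_whitelist(config$whitelist_sizes, structure,
                           seed = config$seed)
  .with_seed(config$seed + 1L, {
    n <- config$n_reads
    segs <- lapply(wl$sequences, sample, size = config$n_cells,
                   replace = TRUE)
    cell_bc <- do.call(paste, c(segs, sep = "+"))
    cell_prefix <- do.call(paste0, segs)
    who <- sample.int(config$n_cells, n, replace = TRUE)

    L <- config$read_length
    P <- structure$total_prefix_length
    insert <- .random_dna(n, L - P)
    r1 <- paste0(cell_prefix[who], insert)
    r2 <- .random_dna(n, L)

    e1 <- .inject_errors(r1, config$error_rate)
    e2 <- .inject_errors(r2, config$error_rate)
    # qualities consistent with error status: error bases carry Phred 14,
    # everything else Phred 37
    qchar <- function(q) rawToChar(as.raw(33L + q))
    patch <- function(qual, errors, ch) {
      idx <- which(errors, arr.ind = TRUE)
      for (r in seq_len(nrow(idx)))
        substr(qual[idx[r, 2L]], idx[r, 1L], idx[r, 1L]) <- ch
      qual
    }
    qual1 <- patch(rep(strrep(qchar(37L), L), n), e1$errors, qchar(14L))
    qual2 <- patch(rep(strrep(qchar(37L), L), n), e2$errors, qchar(14L))
    if (config$low_quality_frac > 0) {
      lowq <- which(stats::runif(n) < config$low_quality_frac)
      pos <- sample.int(P, length(lowq), replace = TRUE)
      for (r in seq_along(lowq))
        substr(qual1[lowq[r]], pos[r], pos[r]) <- qchar(2L)
    }
    names <- sprintf("read%07d", seq_len(n))

    out <- list(
      whitelist = wl, structure = structure,
      truth = data.frame(name = names, barcode = cell_bc[who],
                         stringsAsFactors = FALSE),
      reads = list(name = names,
                   r1 = list(seq = e1$seqs, qual = qual1),
                   r2 = list(seq = e2$seqs, qual = qual2)))
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      f1 <- file.path(out_dir, "reads_R1.fastq.gz")
      f2 <- file.path(out_dir, "reads_R2.fastq.gz")
      .write_fastq(names, e1$seqs, qual1, f1)
      .write_fastq(names, e2$seqs, qual2, f2)
      utils::write.table(out$truth, file.path(out_dir, "truth_reads.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out$files <- c(r1 = f1, r2 = f2)
    }
    out
  })
}

#' Simulate tagged paired alignments with known insertion sites
#'
#' Emits coordinate-sorted SAM records for two cell classes: "good" cells
#' whose Tn5 insertion sites concentrate around annotated TSSs, and
#' "background" cells with uniform insertions. Raw template intervals are
#' reported pre-shift (start - 4, end + 5 around the true insertion
#' sites), so the +4/-5 correction recovers the planted fragments exactly.
#' Planted PCR duplicates re-emit a fragment under a new query name. A
#' fraction of fragments is placed on chrM to exercise the exclusion
#' filter.
#'
#' @param config A [sim_config()].
#' @param out_sam When given, the SAM text is written to this path.
#' @return List with `sam` (character vector of header + records), `tss`
#'   (BED6 data.frame), `truth` (list: per-cell class and unique-fragment
#'   counts, per-fragment corrected coordinates), and `genome`.
#' @export
simulate_alignments <- function(config = sim_config(), out_sam = NULL) {
  .with_seed(config$seed + 2L, {
    genome <- config$genome
    main_chroms <- setdiff(names(genome), c("chrY", "chrM"))
    tss <- data.frame(
      chrom = sample(main_chroms, config$n_tss, replace = TRUE),
      start = 0L, end = 0L,
      name = sprintf("tss%03d", seq_len(config$n_tss)),
      score = 0L,
      strand = sample(c("+", "-"), config$n_tss, replace = TRUE),
      stringsAsFactors = FALSE)
    tss$start <- as.integer(stats::runif(config$n_tss) *
                              (genome[tss$chrom] - 20000L) + 10000L)
    tss$end <- tss$start + 1L

    cells <- c(sprintf("good_%03d", seq_len(config$n_good_cells)),
               sprintf("bg_%03d", seq_len(config$n_bg_cells)))
    classes <- rep(c("good", "background"),
                   c(config$n_good_cells, config$n_bg_cells))
    nf <- ifelse(classes == "good", config$frags_per_good,
                 config$frags_per_bg)

    frag <- list()
    for (i in seq_along(cells)) {
      n <- nf[i]
      on_m <- stats::runif(n) < config$mito_frac
      len <- as.integer(stats::runif(n, 120, 250))
      if (classes[i] == "good") {
        ti <- sample.int(nrow(tss), n, replace = TRUE)
        s1 <- as.integer(tss$start[ti] + round(stats::rnorm(n, 0, 15)))
        chrom <- tss$chrom[ti]
      } else {
        chrom <- sample(main_chroms, n, replace = TRUE)
        s1 <- as.integer(stats::runif(n) * (genome[chrom] - 20000L) + 10000L)
      }
      chrom[on_m] <- "chrM"
      s1[on_m] <- as.integer(stats::runif(sum(on_m), 1000, 14000))
      frag[[i]] <- data.frame(chrom = chrom, s1 = s1, s2 = s1 + len,
                              barcode = cells[i], stringsAsFactors = FALSE)
    }
    fr <- do.call(rbind, frag)
    # planted duplicates
    dup <- fr[stats::runif(nrow(fr)) < config$dup_rate, , drop = FALSE]
    all_fr <- rbind(fr, dup)

    # truth: corrected fragment = [s1, s2 + 1), unique per cell off chrY/chrM
    keep <- !(tolower(all_fr$chrom) %in% c("chry", "chrm"))
    ukey <- unique(paste(fr$chrom, fr$s1, fr$s2, fr$barcode)[keep[seq_len(nrow(fr))]])
    truth_counts <- table(sub("^.* ", "", ukey))
    truth <- list(
      cell_class = stats::setNames(classes, cells),
      unique_fragments = stats::setNames(
        as.integer(truth_counts[cells]), cells),
      fragments = data.frame(chrom = fr$chrom, start = fr$s1,
                             end = fr$s2 + 1L, barcode = fr$barcode,
                             stringsAsFactors = FALSE))

    # SAM emission: raw template = [s1 - 4, s2 + 6) (0-based half-open),
    # i.e. POS1 = s1 - 3 (1-based) and the mate's last base at s2 + 6
    read_len <- 50L
    pos1 <- all_fr$s1 - 3L
    pos2 <- all_fr$s2 + 7L - read_len
    tlen <- pos2 + read_len - pos1
    qname <- sprintf("pair%07d", seq_len(nrow(all_fr)))
    seqs <- strrep("A", read_len)
    quals <- strrep("I", read_len)
    rec1 <- sprintf("%s\t99\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s\tCB:Z:%s",
                    qname, all_fr$chrom, pos1, read_len, pos2, tlen,
                    seqs, quals, all_fr$barcode)
    rec2 <- sprintf("%s\t147\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s\tCB:Z:%s",
                    qname, all_fr$chrom, pos2, read_len, pos1, -tlen,
                    seqs, quals, all_fr$barcode)
    recs <- c(rec1, rec2)
    ord <- order(rep(all_fr$chrom, 2L), c(pos1, pos2), method = "radix")
    header <- c("@HD\tVN:1.6\tSO:coordinate",
                sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                        as.integer(genome)))
    sam <- c(header, recs[ord])
    out <- list(sam = sam, tss = tss, truth = truth, genome = genome)
    if (!is.null(out_sam)) {
      writeLines(sam, out_sam)
      out$file <- out_sam
    }
    out
  })
}

#' Simulate a branching multi-timepoint expression course
#'
#' Negative-binomial counts around branch-specific mean programs drifting
#' along a two-branch lineage tree. Planted, and recorded in the truth
#' table: branch-specific programs with designated driver genes, a
#' metastable population at the branch point preferentially expressing
#' high-connectome-degree hub genes, cell-cycle and ribosomal-protein
#' modules pulsing at the configured stages, and a toy connectome and
#' homology table matched to the gene universe.
#'
#' @param config A [sim_config()].
#' @param out_dir When given, writes `matrix.mtx`/`genes.tsv`/
#'   `barcodes.tsv`, `metadata.tsv`, `edges.tsv`, `homology.tsv`.
#' @return List with `counts` (cells x genes sparse matrix), `metadata`
#'   (data.frame: barcode, timepoint, branch, cluster, metastable),
#'   `connectome_edges` (two-column data.frame), `homology` (two-column
#'   data.frame) and `truth` (planted gene lists).
#' @export
simulate_timecourse <- function(config = sim_config(), out_dir = NULL) {
  .with_seed(config$seed + 3L, {
    tps <- config$timepoints
    npt <- config$cells_per_timepoint
    n_rps <- config$n_rp %/% 2L
    rp_genes <- c(sprintf("Rps%02d", seq_len(n_rps)),
                  sprintf("Rpl%02d", seq_len(config$n_rp - n_rps)))
    cc_genes <- sprintf("Ccgene%02d", seq_len(config$n_cc))
    mito_genes <- sprintf("mt-Gene%d", seq_len(config$n_mito))
    generic <- sprintf("Gene%04d", seq_len(config$n_genes))
    genes <- c(generic, rp_genes, cc_genes, mito_genes)
    G <- length(genes)

    # planted gene roles, all drawn from the generic pool
    pool <- sample(generic)
    branch_a_genes <- pool[seq_len(config$n_branch_genes)]
    branch_b_genes <- pool[config$n_branch_genes +
                             seq_len(config$n_branch_genes)]
    highdeg_genes <- pool[2L * config$n_branch_genes +
                            seq_len(config$n_highdeg)]
    drivers_a <- branch_a_genes[seq_len(config$n_drivers)]
    drivers_b <- branch_b_genes[seq_len(config$n_drivers)]

    # toy connectome: hubs connect widely, other genes sparsely
    edges <- list()
    non_mito <- setdiff(genes, mito_genes)
    for (h in highdeg_genes) {
      tgt <- sample(setdiff(non_mito, h), 40L)
      edges[[h]] <- data.frame(a = h, b = tgt, stringsAsFactors = FALSE)
    }
    others <- setdiff(non_mito, highdeg_genes)
    tgt <- vapply(others, function(g) sample(setdiff(others, g), 1L), "")
    edges[["bg"]] <- data.frame(a = others, b = tgt,
                                stringsAsFactors = FALSE)
    connectome_edges <- do.call(rbind, c(edges, make.row.names = FALSE))

    # one-to-one homology table into a nominal human namespace
    homology <- data.frame(source_gene = genes,
                           human_gene = paste0("H_", genes),
                           stringsAsFactors = FALSE)

    # baseline log-mean program and branch directions
    mu0 <- stats::rnorm(G, log(3), 0.8)
    names(mu0) <- genes
    mu0[mito_genes] <- log(2)
    dA <- dB <- stats::setNames(numeric(G), genes)
    dA[branch_a_genes] <- stats::runif(config$n_branch_genes, 0.5, 1) *
      config$drift
    dB[branch_b_genes] <- stats::runif(config$n_branch_genes, 0.5, 1) *
      config$drift

    meta <- list(); rows <- list()
    for (k in seq_along(tps)) {
      barcodes <- sprintf("%s_cell%04d", tps[k], seq_len(npt))
      steps <- max(0L, k - config$branch_at + 1L)
      if (steps == 0L) {
        branch <- rep("root", npt)
      } else {
        branch <- rep(c("A", "B"), length.out = npt)
      }
      metastable <- rep(FALSE, npt)
      if (k == config$branch_at)
        metastable[stats::runif(npt) < config$metastable_frac] <- TRUE

      logmu <- matrix(rep(mu0, each = npt), nrow = npt,
                      dimnames = list(barcodes, genes))
      if (steps > 0L) {
        logmu[branch == "A", ] <- sweep(logmu[branch == "A", , drop = FALSE],
                                        2L, dA * steps, "+")
        logmu[branch == "B", ] <- sweep(logmu[branch == "B", , drop = FALSE],
                                        2L, dB * steps, "+")
      }
      if (any(metastable))
        logmu[metastable, highdeg_genes] <-
          logmu[metastable, highdeg_genes] + 1.2
      # module pulses: cell cycle at the branch point, RP one step later
      if (k == config$branch_at)
        logmu[, cc_genes] <- logmu[, cc_genes] + 1.0
      if (k == min(config$branch_at + 1L, length(tps)))
        logmu[, rp_genes] <- logmu[, rp_genes] + 1.0
      # per-cell library-size variation
      logmu <- logmu + stats::rnorm(npt, 0, 0.2)

      counts <- matrix(stats::rnbinom(npt * G, size = 1 / config$dispersion,
                                      mu = exp(logmu)),
                       nrow = npt, dimnames = list(barcodes, genes))
      rows[[k]] <- counts
      meta[[k]] <- data.frame(barcode = barcodes, timepoint = tps[k],
                              branch = branch,
                              cluster = paste(tps[k], branch, sep = "."),
                              metastable = metastable,
                              stringsAsFactors = FALSE)
    }
    counts <- methods::as(do.call(rbind, rows), "CsparseMatrix")
    metadata <- do.call(rbind, c(meta, make.row.names = FALSE))

    out <- list(counts = counts, metadata = metadata,
                connectome_edges = connectome_edges, homology = homology,
                truth = list(branch_a_genes = branch_a_genes,
                             branch_b_genes = branch_b_genes,
                             drivers_a = drivers_a, drivers_b = drivers_b,
                             highdeg_genes = highdeg_genes,
                             rp_genes = rp_genes, cc_genes = cc_genes,
                             mito_genes = mito_genes))
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_matrix(counts, out_dir)
      utils::write.table(metadata, file.path(out_dir, "metadata.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(connectome_edges, file.path(out_dir, "edges.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      utils::write.table(homology, file.path(out_dir, "homology.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      out$dir <- out_dir
    }
    out
  })
}
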