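test_that("error-free reads carry whitelist-product prefixes", {
  cfg <- sim_config(seed = 41L, n_reads = 500L, n_cells = 30L,
                    error_rate = 0)
  sim <- simulate_reads(cfg)
  st <- sim$structure
  for (i in seq_along(sim$reads$r1$seq)) {
    segs <- substring(sim$reads$r1$seq[i], st$segments$offset + 1L,
                      st$segments$offset + st$segments$length)
    for (j in seq_along(segs))
      expect_true(segs[j] %in% sim$whitelist$sequences[[j]])
  }
  # truth covers every emitted read
  expect_setequal(sim$truth$name, sim$reads$name)
})

test_that("read simulation is byte-identical under the same config and seed", {
  cfg <- sim_config(seed = 42L, n_reads = 300L, error_rate = 0.01,
                    low_quality_frac = 0.05)
  a <- simulate_reads(cfg)
  b <- simulate_reads(cfg)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
  expect_identical(a$whitelist$sequences, b$whitelist$sequences)
})

test_that("the barcode-error fraction matches the closed-form binomial rate", {
  cfg <- sim_config(seed = 43L, n_reads = 50000L, n_cells = 100L,
                    error_rate = 0.001)
  sim <- simulate_reads(cfg)
  true_prefix <- gsub("+", "", sim$truth$barcode, fixed = TRUE)
  obs_prefix <- substr(sim$reads$r1$seq, 1L, 28L)
  frac <- mean(obs_prefix != true_prefix)
  p <- 1 - (1 - cfg$error_rate)^28
  # binomial tolerance: 4 standard errors at n = 50000
  expect_lt(abs(frac - p), 4 * sqrt(p * (1 - p) / cfg$n_reads))
})

test_that("quality strings reflect the planted error status", {
  cfg <- sim_config(seed = 44L, n_reads = 2000L, error_rate = 0.01)
  sim <- simulate_reads(cfg)
  i <- which(substr(sim$reads$r1$seq, 1, 28) !=
               gsub("+", "", sim$truth$barcode, fixed = TRUE))[1L]
  expect_false(is.na(i))
  q <- utf8ToInt(substr(sim$reads$r1$qual[i], 1, 28)) - 33L
  expect_true(any(q == 14L))   # error bases carry the lower quality
  expect_true(all(q %in% c(14L, 37L)))
})

test_that("alignments with no duplicates give unique fragments equal to pairs", {
  cfg <- sim_config(seed = 45L, n_good_cells = 3L, n_bg_cells = 2L,
                    frags_per_good = 150L, frags_per_bg = 60L,
                    dup_rate = 0, mito_frac = 0)
  sim <- simulate_alignments(cfg)
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(sim$sam, sam)
  fr <- build_fragments(sam)
  # no planted duplicates: pairs in = fragments out, and the only
  # multiplicities are chance coordinate collisions recorded in the truth
  expect_equal(sum(fr$count), 3L * 150L + 2L * 60L)
  expect_equal(nrow(fr), sum(sim$truth$unique_fragments))
  # the corrected fragments equal the simulator's planted intervals
  truth <- sim$truth$fragments
  key_t <- sort(unique(paste(truth$chrom, truth$start, truth$end,
                             truth$barcode)))
  key_o <- sort(paste(fr$chrom, fr$start, fr$end, fr$barcode))
  expect_equal(key_o, key_t)
})

test_that("planted duplicate pairs collapse with their count preserved", {
  cfg <- sim_config(seed = 46L, n_good_cells = 4L, n_bg_cells = 0L,
                    frags_per_good = 400L, dup_rate = 0.3, mito_frac = 0)
  sim <- simulate_alignments(cfg)
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(sim$sam, sam)
  fr <- build_fragments(sam)
  expect_gt(sum(fr$count > 1L), 0L)
  counts <- tapply(rep(1L, nrow(fr)), fr$barcode, sum)
  expect_equal(as.integer(counts[names(sim$truth$unique_fragments)]),
               unname(sim$truth$unique_fragments))
})

test_that("the time course is deterministic and its truth covers all cells", {
  cfg <- sim_config(seed = 47L, cells_per_timepoint = 40L, n_genes = 60L,
                    n_branch_genes = 15L, n_drivers = 5L, n_highdeg = 10L)
  a <- simulate_timecourse(cfg)
  b <- simulate_timecourse(cfg)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$metadata, b$metadata)
  expect_setequal(a$metadata$barcode, rownames(a$counts))
  expect_equal(nrow(a$metadata), 4L * 40L)
  # every planted gene list lives in the gene universe
  expect_true(all(unlist(a$truth[c("drivers_a", "drivers_b",
                                   "highdeg_genes", "rp_genes",
                                   "cc_genes")]) %in% colnames(a$counts)))
  # cells before the branch point are unbranched
  expect_true(all(a$metadata$branch[a$metadata$timepoint == "D0"] == "root"))
  expect_true(all(a$metadata$branch[a$metadata$timepoint == "D6"] %in%
                    c("A", "B")))
})

test_that("zero drift removes the branch signal from the couplings", {
  cfg <- sim_config(seed = 48L, cells_per_timepoint = 120L, n_genes = 80L,
                    n_branch_genes = 20L, n_drivers = 5L, n_highdeg = 15L,
                    drift = 0, metastable_frac = 0)
  tc <- simulate_timecourse(cfg)
  ch <- fit_transport_chain(normalize_ln_cpm100(tc$counts),
                            tc$metadata$timepoint, n_pcs = 10)
  md <- tc$metadata
  last <- ch$timepoints[length(ch$timepoints)]
  termA <- md$barcode[md$timepoint == last & md$branch == "A"]
  termB <- md$barcode[md$timepoint == last & md$branch == "B"]
  d_ab <- ancestor_divergence(pull_back(ch, termA)[[ch$timepoints[2L]]],
                              pull_back(ch, termB)[[ch$timepoints[2L]]])
  # with exchangeable timepoints the "branches" share their ancestry
  expect_lt(d_ab, 0.5)
})

test_that("emitted files round-trip through the toolkit readers", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 49L, cells_per_timepoint = 30L, n_genes = 40L,
                    n_branch_genes = 10L, n_drivers = 3L, n_highdeg = 8L)
  tc <- simulate_timecourse(cfg, out_dir = dir)
  m <- read_matrix(file.path(dir, "matrix.mtx"),
                   file.path(dir, "genes.tsv"),
                   file.path(dir, "barcodes.tsv"))
  expect_equal(as.matrix(m), as.matrix(tc$counts))
  md <- utils::read.table(file.path(dir, "metadata.tsv"), sep = "\t",
                          header = TRUE)
  expect_equal(md$barcode, tc$metadata$barcode)
  conn <- read_connectome(file.path(dir, "edges.tsv"))
  expect_gt(length(conn), 0L)
  W <- build_homology_weights(file.path(dir, "homology.tsv"))
  expect_equal(unname(range(Matrix::colSums(W))), c(1, 1))
})
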