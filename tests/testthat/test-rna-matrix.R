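toy_counts <- function(m) {
  m <- as.matrix(m)
  rownames(m) <- sprintf("cell%d", seq_len(nrow(m)))
  methods::as(m, "CsparseMatrix")
}

test_that("cell QC removes low-count and high-mito cells at the quoted boundaries", {
  m <- toy_counts(rbind(c(499, 0), c(500, 0), c(400, 100), c(375, 125)))
  colnames(m) <- c("Gene1", "mt-Nd1")
  f <- qc_filter_cells(m)
  # 499 transcripts -> removed; 500 kept; mito 20% kept; 25% removed
  expect_setequal(rownames(f), c("cell2", "cell3"))
  # all-pass matrix comes back unchanged
  ok <- toy_counts(matrix(600, 3, 2, dimnames = list(NULL, c("g1", "mt-x"))))
  ok_f <- qc_filter_cells(toy_counts(cbind(g1 = c(600, 700), `mt-Nd1` = 0)))
  expect_equal(dim(ok_f), c(2L, 2L))
  # no mito genes: warning, mito filter skipped
  m2 <- toy_counts(cbind(g1 = c(600, 400), g2 = c(0, 300)))
  expect_warning(f2 <- qc_filter_cells(m2), "mitochondrial")
  expect_equal(rownames(f2), c("cell1", "cell2"))
})

test_that("QC filters commute and never add cells", {
  .with_test_seed(5, {
    m <- toy_counts(matrix(rpois(600, 30), 20, 30))
    colnames(m) <- c(sprintf("g%d", 1:27), sprintf("mt-g%d", 1:3))
    both <- qc_filter_cells(m)
    t_then_m <- qc_filter_cells(qc_filter_cells(m, max_mito_frac = 1),
                                min_transcripts = 0)
    m_then_t <- qc_filter_cells(qc_filter_cells(m, min_transcripts = 0),
                                max_mito_frac = 1)
    expect_equal(rownames(t_then_m), rownames(both))
    expect_equal(rownames(m_then_t), rownames(both))
    expect_lte(nrow(both), nrow(m))
  })
})

test_that("ln(CPM/100 + 1) has its closed forms and scale invariance", {
  m <- toy_counts(rbind(c(7, 0), c(3, 9)))
  colnames(m) <- c("g1", "g2")
  norm <- normalize_ln_cpm100(m)
  expect_equal(norm["cell1", "g2"], 0)                     # zero count
  expect_equal(norm["cell1", "g1"], log(10001))            # single-gene cell
  # multiplying a cell's counts by a positive integer changes nothing
  m2 <- m; m2[2, ] <- m2[2, ] * 7
  expect_equal(as.matrix(normalize_ln_cpm100(m2)), as.matrix(norm))
  # order within a cell is preserved
  expect_true(norm["cell2", "g2"] > norm["cell2", "g1"])
  # zero-total cells are an error pointing at QC
  expect_error(normalize_ln_cpm100(toy_counts(rbind(c(1, 1), c(0, 0)))),
               "qc_filter_cells")
})

test_that("highly variable gene selection recovers planted variable genes", {
  .with_test_seed(8, {
    # flat genes span a realistic mean range; the planted genes sit inside
    # that range but carry strong multiplicative per-cell rate variation,
    # so only their dispersion distinguishes them from their bin-mates
    n_cells <- 200L; n_flat <- 2000L; n_var <- 20L
    mu_flat <- exp(runif(n_flat, log(2), log(80)))
    flat <- matrix(rpois(n_cells * n_flat, rep(mu_flat, each = n_cells)),
                   n_cells)
    lam <- exp(rnorm(n_cells, 0, 1.5)); lam <- lam / mean(lam)
    mu_var <- exp(runif(n_var, log(10), log(60)))
    varg <- matrix(rpois(n_cells * n_var, outer(lam, mu_var)), n_cells)
    m <- toy_counts(cbind(flat, varg))
    colnames(m) <- c(sprintf("flat%04d", seq_len(n_flat)),
                     sprintf("var%02d", seq_len(n_var)))
    norm <- normalize_ln_cpm100(m)
    hv <- select_hvg(norm, n = n_var)
    expect_setequal(hv, sprintf("var%02d", seq_len(n_var)))
    # determinism and subset property
    expect_identical(hv, select_hvg(norm, n = n_var))
    expect_true(all(hv %in% colnames(m)))
    # stability under a permutation of the cells
    perm <- sample(nrow(norm))
    expect_identical(select_hvg(norm[perm, ], n = n_var), hv)
    # asking for more genes than qualify returns all with a warning
    expect_warning(all_g <- select_hvg(norm, n = 10000), "qualify")
    expect_lte(length(all_g), ncol(m))
  })
})

test_that("gene-set scores are null-centered and detect planted overexpression", {
  .with_test_seed(13, {
    n <- 200L
    base <- matrix(rpois(n * 100L, 15), n)
    colnames(base) <- sprintf("g%03d", 1:100)
    set <- sprintf("g%03d", 1:10)
    # null: set genes behave like everyone else
    null_scores <- score_gene_set(normalize_ln_cpm100(toy_counts(base)),
                                  set, seed = 4L)
    expect_lt(abs(mean(null_scores)), 0.05)
    # planted: 2x overexpression of the set in the first half of cells
    m <- base
    m[1:(n / 2), set] <- m[1:(n / 2), set] * 2L
    sc <- score_gene_set(normalize_ln_cpm100(toy_counts(m)), set, seed = 4L)
    pv <- stats::wilcox.test(sc[1:(n / 2)], sc[(n / 2 + 1):n],
                             alternative = "greater")$p.value
    expect_lt(pv, 0.01)
    # same seed, same input -> identical scores
    sc2 <- score_gene_set(normalize_ln_cpm100(toy_counts(m)), set, seed = 4L)
    expect_identical(sc, sc2)
    expect_error(score_gene_set(normalize_ln_cpm100(toy_counts(m)),
                                c("absent1", "absent2")), "absent1")
  })
})

test_that("the ribosomal-protein score uses the packaged Rps/Rpl set", {
  tc <- timecourse_fixture()
  rp <- score_rp(tc$norm, seed = 2L)
  md <- tc$metadata
  # the RP module pulses one step after the branch point in the fixture
  by_tp <- tapply(rp[md$barcode], md$timepoint, median)
  expect_equal(names(which.max(by_tp)), "D4")
})

test_that("gene-pair co-expression scores multiply profiles and rank symmetrically", {
  pa <- c(g1 = 2, g2 = 1, g3 = 0)
  pb <- c(g2 = 4, g1 = 3, g4 = 9)
  s <- pair_coexpression_score(pa, pb)
  expect_equal(s, c(g1 = 6, g2 = 4))
  expect_equal(names(s), c("g1", "g2"))
  expect_equal(pair_coexpression_score(pb, pa), s)
  expect_equal(unname(pair_coexpression_score(c(g1 = 0, g2 = 1),
                                              c(g1 = 5, g2 = 0))),
               c(0, 0))
  expect_error(pair_coexpression_score(c(a = 1), c(b = 1)), "share no genes")
})

test_that("matrices round-trip through the MTX triplet layout", {
  tc <- timecourse_fixture()
  sub <- tc$counts[1:40, 1:60]
  dir <- withr::local_tempdir()
  write_matrix(sub, dir)
  back <- read_matrix(file.path(dir, "matrix.mtx"),
                      file.path(dir, "genes.tsv"),
                      file.path(dir, "barcodes.tsv"))
  expect_equal(as.matrix(back), as.matrix(sub))
})
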