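# Shared fixtures, built once per test run and memoized: the branching
# time-course with its fitted transport chain is the expensive piece and
# several suites (transport, entropy, acceptance) read from it.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# two-branch time course (500 cells x 4 timepoints) + normalized matrix
timecourse_fixture <- function() {
  fixture("timecourse", function() {
    tc <- simulate_timecourse(sim_config(seed = 101L))
    tc$norm <- normalize_ln_cpm100(tc$counts)
    tc
  })
}

# fitted transport chain over the time-course fixture
chain_fixture <- function() {
  fixture("chain", function() {
    tc <- timecourse_fixture()
    fit_transport_chain(tc$norm, tc$metadata$timepoint)
  })
}

# three well-separated simulated cell types; two replicate datasets
three_type_dataset <- function(seed, n_per_type = 30L, n_genes = 90L) {
  stopifnot(n_genes %% 3L == 0L)
  b <- n_genes %/% 3L
  .with_test_seed(seed, {
    types <- c("t1", "t2", "t3")
    m <- do.call(rbind, lapply(seq_along(types), function(k) {
      mu <- rep(2, n_genes)
      mu[((k - 1L) * b + 1L):(k * b)] <- 20
      matrix(stats::rpois(n_per_type * n_genes, rep(mu, each = n_per_type)),
             nrow = n_per_type)
    }))
    rownames(m) <- sprintf("s%d_cell%03d", seed, seq_len(nrow(m)))
    colnames(m) <- sprintf("g%03d", seq_len(n_genes))
    list(counts = methods::as(m, "CsparseMatrix"),
         labels = rep(types, each = n_per_type))
  })
}

# run expr under a seed without disturbing the session RNG
.with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}

# brute-force O(n^2) pairwise Hamming oracle, independent of the
# byte-matrix implementation under test
oracle_min_hamming <- function(seqs) {
  n <- length(seqs)
  best <- Inf
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- strsplit(seqs[i], "")[[1L]]
    b <- strsplit(seqs[j], "")[[1L]]
    best <- min(best, sum(a != b))
  }
  best
}

# exhaustive per-segment scan: whitelist entries within Hamming distance 1
oracle_entries_within_1 <- function(seg, wl_seqs) {
  d <- vapply(wl_seqs, function(w)
    sum(strsplit(seg, "")[[1L]] != strsplit(w, "")[[1L]]), 0)
  wl_seqs[d <= 1]
}

# exact LP oracle for balanced OT with uniform n-point marginals: the
# optimum is attained at a permutation (Birkhoff), so enumerate them all
lp_oracle_cost <- function(C) {
  n <- nrow(C)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  best <- Inf; best_perm <- NULL
  for (p in perms(seq_len(n))) {
    cost <- sum(C[cbind(seq_len(n), p)]) / n
    if (cost < best) { best <- cost; best_perm <- p }
  }
  list(cost = best, perm = best_perm)
}

# raw 28-base barcode prefixes from a FASTQ, in the order of names_wanted
.read_raw_prefixes <- function(path, names_wanted) {
  lines <- readLines(path)
  nm <- sub("[ /].*$", "", sub("^@", "", lines[c(TRUE, FALSE, FALSE, FALSE)]))
  seqs <- lines[c(FALSE, TRUE, FALSE, FALSE)]
  substr(seqs[match(names_wanted, nm)], 1L, 28L)
}

# write a minimal coordinate-sorted SAM file from a raw pair table
# (0-based half-open template intervals), for hand-built fragment tests
write_test_sam <- function(pairs, genome, path, read_len = 20L) {
  pos1 <- pairs$start + 1L
  pos2 <- pairs$end - read_len + 1L
  tlen <- pairs$end - pairs$start
  qn <- sprintf("q%04d", seq_len(nrow(pairs)))
  s <- strrep("A", read_len); q <- strrep("I", read_len)
  rec1 <- sprintf("%s\t99\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s\tCB:Z:%s",
                  qn, pairs$chrom, pos1, read_len, pos2, tlen, s, q,
                  pairs$barcode)
  rec2 <- sprintf("%s\t147\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s\tCB:Z:%s",
                  qn, pairs$chrom, pos2, read_len, pos1, -tlen, s, q,
                  pairs$barcode)
  recs <- c(rec1, rec2)
  ord <- order(rep(pairs$chrom, 2L), c(pos1, pos2), method = "radix")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                       as.integer(genome)),
               recs[ord]), path)
  path
}
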