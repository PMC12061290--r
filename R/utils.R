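# Seed the RNG for a deterministic block and restore the caller's RNG
# state afterwards, so seeded operations never perturb the session stream.
.seeded_rng <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  list(restore = function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
}

# run expr under a local seed, restoring RNG state on exit
.with_seed <- function(seed, expr) {
  rs <- .seeded_rng(seed)
  on.exit(rs$restore())
  expr
}

# row-wise log-sum-exp of (M + v) for a matrix M (n x m) and a length-m
# vector v, numerically stabilized; used by the log-domain Sinkhorn.
.logsumexp_rows <- function(M, v) {
  A <- sweep(M, 2L, v, "+")
  mx <- apply(A, 1L, max)
  mx + log(rowSums(exp(A - mx)))
}

# collapse an L x n character matrix into n strings, column-wise
.collapse_cols <- function(m) {
  do.call(paste0, lapply(seq_len(nrow(m)), function(i) m[i, ]))
}

.random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  chars <- sample(c("A", "C", "G", "T"), n * len, replace = TRUE)
  .collapse_cols(matrix(chars, nrow = len))
}
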