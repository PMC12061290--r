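#' @importFrom Matrix readMM writeMM rowSums colSums colMeans t Diagonal
#' @importFrom methods as is
NULL

# cells x genes sparse matrix with dimnames, coerced from anything readMM
# returns or a dense matrix.
.as_count_matrix <- function(m) {
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("count matrix must carry cell (row) and gene (column) names")
  m
}

#' Read / write a cells-by-genes matrix in MTX triplet layout
#'
#' MatrixMarket file plus one-per-line row (cell barcode) and column (gene)
#' TSV files. A dense TSV with header and row names is also accepted for
#' small matrices.
#'
#' @param mtx Path to the `.mtx` file, or a dense TSV when
#'   `genes`/`barcodes` are omitted.
#' @param genes,barcodes Paths to the gene and barcode lists.
#' @return A sparse `dgCMatrix`, cells in rows, genes in columns.
#' @export
read_matrix <- function(mtx, genes = NULL, barcodes = NULL) {
  if (is.null(genes)) {
    df <- utils::read.table(mtx, sep = "\t", header = TRUE, row.names = 1L,
                            check.names = FALSE)
    m <- methods::as(as.matrix(df), "CsparseMatrix")
    return(.as_count_matrix(m))
  }
  m <- Matrix::readMM(mtx)
  rownames(m) <- readLines(barcodes)
  colnames(m) <- readLines(genes)
  .as_count_matrix(m)
}

#' @param m Cells-by-genes matrix.
#' @param dir Output directory; writes `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv`.
#' @rdname read_matrix
#' @export
write_matrix <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(m, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(m), file.path(dir, "genes.tsv"))
  writeLines(rownames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Filter cells on transcript count and mitochondrial fraction
#'
#' Removes cells detecting fewer than `min_transcripts` transcripts, and
#' cells in which more than `max_mito_frac` of transcripts derive from
#' mitochondria-encoded genes (identified by a name prefix). When no
#' mitochondrial genes are found the mitochondrial filter is skipped with a
#' warning.
#'
#' @param counts Cells-by-genes count matrix.
#' @param min_transcripts Minimum total transcripts to keep a cell
#'   (default 500; a cell with exactly 500 is kept).
#' @param max_mito_frac Maximum mitochondrial fraction (default 0.20; a
#'   cell at exactly 0.20 is kept).
#' @param mito_prefix Gene-name prefix identifying mitochondria-encoded
#'   genes (default `"mt-"`, case-insensitive).
#' @return The filtered matrix, same gene set, subset of cells.
#' @export
qc_filter_cells <- function(counts, min_transcripts = 500,
                            max_mito_frac = 0.20, mito_prefix = "mt-") {
  totals <- Matrix::rowSums(counts)
  keep <- totals >= min_transcripts
  mito <- grepl(paste0("^", mito_prefix), colnames(counts),
                ignore.case = TRUE)
  if (!any(mito)) {
    warning("no mitochondrial genes matched prefix '", mito_prefix,
            "'; mitochondrial filter skipped", call. = FALSE)
  } else {
    frac <- Matrix::rowSums(counts[, mito, drop = FALSE]) / pmax(totals, 1)
    keep <- keep & frac <= max_mito_frac
  }
  counts[keep, , drop = FALSE]
}

#' ln(CPM/100 + 1) normalization
#'
#' Per-cell library-size normalization to counts-per-million divided by
#' 100, followed by the natural log of (value + 1):
#' `ln(count / cell_total * 1e4 + 1)`. Scale-invariant within each cell.
#'
#' @param counts Cells-by-genes count matrix; every cell must have a
#'   positive total.
#' @return Sparse matrix of normalized values, same shape and dimnames.
#' @export
normalize_ln_cpm100 <- function(counts) {
  totals <- Matrix::rowSums(counts)
  if (any(totals <= 0))
    stop("cells with zero total counts present; run qc_filter_cells first")
  scaled <- Matrix::Diagonal(x = 1e4 / totals) %*% counts
  out <- methods::as(scaled, "CsparseMatrix")
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(counts)
  out
}

# per-gene mean and variance of a sparse cells x genes matrix
.gene_moments <- function(m) {
  n <- nrow(m)
  mu <- Matrix::colMeans(m)
  ex2 <- Matrix::colSums(m^2) / n
  v <- (ex2 - mu^2) * n / max(n - 1L, 1L)
  list(mean = mu, var = pmax(v, 0))
}

#' Select highly variable genes by mean-binned dispersion
#'
#' Genes are binned by mean expression (20 equal-occupancy bins); the
#' dispersion (variance / mean) is z-scored within each bin and the top
#' `n` genes by z-scored dispersion are returned. Ties break
#' deterministically by gene identifier.
#'
#' @param normalized Cells-by-genes normalized matrix.
#' @param n Number of genes to select (default 2000).
#' @param n_bins Number of mean-expression bins (default 20).
#' @return Character vector of gene names, ordered by decreasing z-scored
#'   dispersion.
#' @export
select_hvg <- function(normalized, n = 2000, n_bins = 20) {
  mom <- .gene_moments(normalized)
  ok <- mom$mean > 0 & mom$var > 0
  genes <- colnames(normalized)[ok]
  mu <- mom$mean[ok]
  disp <- mom$var[ok] / mu
  if (length(genes) == 0L) stop("no genes with positive mean and variance")
  nb <- max(1L, min(n_bins, length(genes)))
  br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = nb + 1L)))
  bins <- cut(mu, breaks = br, include.lowest = TRUE)
  z <- stats::ave(disp, bins, FUN = function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  ord <- order(-z, genes, method = "radix")
  if (length(genes) < n) {
    warning(sprintf("only %d genes qualify (requested %d); returning all",
                    length(genes), n), call. = FALSE)
    return(genes[ord])
  }
  genes[ord][seq_len(n)]
}

#' Control-binned gene-set score
#'
#' Per-cell score for a gene set (cell-cycle, ribosomal-protein, or any
#' custom set): the mean normalized expression of the set genes minus the
#' mean over control genes drawn, per set gene, from the same
#' mean-expression bin. Seeded and deterministic.
#'
#' @param normalized Cells-by-genes normalized matrix.
#' @param gene_set Character vector of gene names; at least one must be
#'   present in the matrix.
#' @param n_bins Number of mean-expression bins (default 25).
#' @param n_ctrl Control genes drawn per set gene (default 50).
#' @param seed Integer seed for the control draw.
#' @return Named numeric vector of per-cell scores.
#' @export
score_gene_set <- function(normalized, gene_set, n_bins = 25, n_ctrl = 50,
                           seed = 1L) {
  present <- intersect(gene_set, colnames(normalized))
  if (length(present) == 0L)
    stop("none of the gene-set genes are present: ",
         paste(utils::head(gene_set, 5L), collapse = ", "))
  mu <- Matrix::colMeans(normalized)
  nb <- max(1L, min(n_bins, length(mu)))
  br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = nb + 1L)))
  bins <- cut(mu, breaks = br, include.lowest = TRUE)
  names(bins) <- colnames(normalized)

  ctrl <- local({
    rs <- .seeded_rng(seed)
    on.exit(rs$restore())
    unlist(lapply(present, function(g) {
      pool <- names(bins)[bins == bins[g]]
      sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
    }))
  })
  set_mean <- Matrix::rowSums(normalized[, present, drop = FALSE]) /
    length(present)
  ctrl_mean <- Matrix::rowSums(normalized[, ctrl, drop = FALSE]) /
    length(ctrl)
  stats::setNames(as.numeric(set_mean - ctrl_mean), rownames(normalized))
}

#' Ribosomal-protein score
#'
#' [score_gene_set()] with the set of ribosomal-protein genes, identified
#' by the conventional Rps/Rpl name prefixes (case-insensitive).
#'
#' @inheritParams score_gene_set
#' @return Named numeric vector of per-cell scores.
#' @export
score_rp <- function(normalized, n_bins = 25, n_ctrl = 50, seed = 1L) {
  rp <- grep("^Rp[sl]", colnames(normalized), ignore.case = TRUE,
             value = TRUE)
  if (length(rp) == 0L) stop("no ribosomal-protein (Rps*/Rpl*) genes found")
  score_gene_set(normalized, rp, n_bins = n_bins, n_ctrl = n_ctrl,
                 seed = seed)
}

#' Gene-pair co-expression score between two cell-type profiles
#'
#' For each shared gene, the product of the two cell types' mean normalized
#' expression values; genes highly expressed in both profiles rank first.
#' Symmetric in its arguments.
#'
#' @param prof_a,prof_b Named numeric vectors of mean normalized expression
#'   per gene (one cell type each).
#' @return Named numeric vector of per-gene scores over the shared genes,
#'   sorted in decreasing order (ties by gene name).
#' @export
pair_coexpression_score <- function(prof_a, prof_b) {
  shared <- intersect(names(prof_a), names(prof_b))
  if (length(shared) == 0L)
    stop("the two profiles share no genes")
  s <- prof_a[shared] * prof_b[shared]
  s[order(-s, shared, method = "radix")]
}
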