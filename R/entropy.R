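#' Build a connectome degree vector from an undirected PPI edge list
#'
#' Reads a two-column edge list (TSV or data.frame), drops self-loops and
#' duplicate edges (in either orientation), and returns the degree of every
#' incident gene. Isolated genes do not appear.
#'
#' @param edges Path to a two-column TSV (no header: geneA, geneB) or a
#'   data.frame with two columns.
#' @return Named integer vector of degrees.
#' @export
read_connectome <- function(edges) {
  if (is.character(edges))
    edges <- utils::read.table(edges, sep = "\t", header = FALSE,
                               col.names = c("a", "b"),
                               colClasses = "character")
  a <- as.character(edges[[1L]]); b <- as.character(edges[[2L]])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  dup <- duplicated(key)
  a <- a[!dup]; b <- b[!dup]
  deg <- table(c(a, b))
  stats::setNames(as.integer(deg), names(deg))
}

#' Cross-species homology weight matrix
#'
#' Converts a homology pair table (source-species gene, human gene) —
#' covering one-to-one, one-to-many, many-to-one and many-to-many
#' relations — into a binary incidence matrix normalized per human gene:
#' each human gene's incoming weights sum to 1, so a human-gene expression
#' value is the (equal-weight) average of its source homologs.
#'
#' @param pairs Path to a two-column TSV (source_gene, human_gene) or a
#'   data.frame with those columns.
#' @return Sparse matrix `W`, source genes in rows, human genes in columns;
#'   every column with at least one homolog sums to 1.
#' @export
build_homology_weights <- function(pairs) {
  if (is.character(pairs))
    pairs <- utils::read.table(pairs, sep = "\t", header = FALSE,
                               col.names = c("source_gene", "human_gene"),
                               colClasses = "character")
  src <- as.character(pairs[[1L]]); hum <- as.character(pairs[[2L]])
  if (length(src) == 0L) stop("homology table is empty")
  if (any(!nzchar(src)) || any(!nzchar(hum)))
    stop("homology table contains blank identifiers")
  key <- paste(src, hum, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate homology pairs collapsed", call. = FALSE)
    keep <- !duplicated(key)
    src <- src[keep]; hum <- hum[keep]
  }
  su <- sort(unique(src)); hu <- sort(unique(hum))
  W <- Matrix::sparseMatrix(i = match(src, su), j = match(hum, hu),
                            x = 1, dims = c(length(su), length(hu)),
                            dimnames = list(su, hu))
  cs <- Matrix::colSums(W)
  out <- W %*% Matrix::Diagonal(x = 1 / cs)
  dimnames(out) <- dimnames(W)
  methods::as(out, "CsparseMatrix")
}

#' Identity homology map
#'
#' For same-species analyses: maps every gene to itself with weight 1.
#'
#' @param genes Character vector of gene names.
#' @return Sparse identity matrix with `genes` as both dimnames.
#' @export
identity_homology <- function(genes) {
  Matrix::sparseMatrix(i = seq_along(genes), j = seq_along(genes), x = 1,
                       dims = c(length(genes), length(genes)),
                       dimnames = list(genes, genes))
}

#' Project expression into human gene space through homology weights
#'
#' Per cell, the human-gene value is the weighted sum of its source-species
#' homolog values. Matrix genes absent from the weight matrix are dropped
#' and counted.
#'
#' @param normalized Cells-by-genes normalized matrix (source species).
#' @param W Homology weight matrix from [build_homology_weights()].
#' @return Cells-by-human-genes matrix with attribute `dropped_genes`
#'   (number of matrix genes absent from `W`).
#' @export
project_expression <- function(normalized, W) {
  shared <- intersect(colnames(normalized), rownames(W))
  if (length(shared) == 0L)
    stop("no overlap between matrix genes and homology source genes")
  dropped <- ncol(normalized) - length(shared)
  Ws <- W[shared, , drop = FALSE]
  keep_h <- Matrix::colSums(Ws) > 0
  out <- normalized[, shared, drop = FALSE] %*% Ws[, keep_h, drop = FALSE]
  out <- methods::as(out, "CsparseMatrix")
  attr(out, "dropped_genes") <- dropped
  out
}

#' CCAT: correlation-based network-entropy potency surrogate
#'
#' CCAT approximates single-cell network (signaling) entropy by the Pearson
#' correlation between a cell's transcriptome and the connectome's degree
#' vector over the genes shared by both: cells whose expression
#' concentrates on highly connected hub genes score high, a signature of
#' potent or metastable states. Invariant to per-cell positive affine
#' transforms of expression.
#'
#' @param expression Cells-by-genes (normalized, optionally
#'   homology-projected) matrix.
#' @param connectome Named degree vector from [read_connectome()].
#' @param log_degree Correlate against `log(degree)` instead of raw degree
#'   (default `FALSE`).
#' @return data.frame with `barcode`, `ccat` (in [-1, 1], `NA` for cells
#'   with zero expression variance over the shared genes) and `flagged`.
#' @export
ccat <- function(expression, connectome, log_degree = FALSE) {
  shared <- intersect(colnames(expression), names(connectome))
  if (length(shared) < 10L)
    stop("fewer than 10 genes shared between matrix and connectome")
  X <- as.matrix(expression[, shared, drop = FALSE])
  k <- as.numeric(connectome[shared])
  if (log_degree) k <- log(k)
  sds <- apply(X, 1L, stats::sd)
  r <- rep(NA_real_, nrow(X))
  ok <- sds > 0
  if (any(ok)) r[ok] <- as.numeric(stats::cor(t(X[ok, , drop = FALSE]), k))
  data.frame(barcode = rownames(expression), ccat = r, flagged = !ok,
             stringsAsFactors = FALSE)
}
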