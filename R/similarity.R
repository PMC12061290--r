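#' Aggregate cells into pseudo-cells
#'
#' Within each cluster, cells are shuffled (seeded), partitioned into
#' disjoint groups of exactly `size` distinct cells, and counts are summed
#' per group; remainder cells short of a full group are dropped and
#' counted. Clusters with fewer than `size` cells are skipped with a
#' warning. No cell is used twice.
#'
#' @param counts Cells-by-genes count matrix.
#' @param cluster_labels Named (by barcode) or positional character vector
#'   of cluster labels, one per cell.
#' @param size Cells per pseudo-cell (default 100).
#' @param seed Integer seed for the shuffle.
#' @param pool_remainder When `TRUE`, the last group of a cluster absorbs
#'   the remainder instead of dropping it (default `FALSE`).
#' @return Pseudo-cells-by-genes matrix with attribute `provenance`
#'   (data.frame: pseudo-cell id, source cluster, member count) and
#'   `dropped_cells` (total remainder cells dropped).
#' @export
make_pseudocells <- function(counts, cluster_labels, size = 100, seed = 1L,
                             pool_remainder = FALSE) {
  stopifnot(length(cluster_labels) == nrow(counts))
  clusters <- sort(unique(cluster_labels))
  groups <- list(); prov <- list(); dropped <- 0L
  rs <- .seeded_rng(seed)
  on.exit(rs$restore())
  for (cl in clusters) {
    idx <- which(cluster_labels == cl)
    if (length(idx) < size) {
      warning(sprintf("cluster '%s' has %d < %d cells; skipped",
                      cl, length(idx), size), call. = FALSE)
      next
    }
    idx <- sample(idx)
    ng <- length(idx) %/% size
    rem <- length(idx) - ng * size
    for (g in seq_len(ng)) {
      members <- idx[((g - 1L) * size + 1L):(g * size)]
      if (pool_remainder && g == ng && rem > 0L)
        members <- c(members, idx[(ng * size + 1L):length(idx)])
      id <- sprintf("%s.pc%d", cl, g)
      groups[[id]] <- Matrix::colSums(counts[members, , drop = FALSE])
      prov[[id]] <- data.frame(pseudocell = id, cluster = cl,
                               n_cells = length(members),
                               stringsAsFactors = FALSE)
    }
    if (!pool_remainder) dropped <- dropped + rem
  }
  if (length(groups) == 0L)
    stop("no cluster has enough cells for a single pseudo-cell")
  m <- methods::as(do.call(rbind, groups), "CsparseMatrix")
  colnames(m) <- colnames(counts)
  attr(m, "provenance") <- do.call(rbind, c(prov, make.row.names = FALSE))
  attr(m, "dropped_cells") <- dropped
  m
}

# Mann-Whitney AUROC of scores for positives vs the rest, average ranks
# for ties; identical scores for everyone give 0.5.
.auroc <- function(scores, positive) {
  n1 <- sum(positive); n2 <- sum(!positive)
  if (n1 == 0L || n2 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Neighbor-voting AUROC between the cell types of two datasets
#'
#' Over a shared highly-variable-gene set, builds the cross-dataset
#' Spearman correlation network, rank-standardizes each target sample's
#' correlations to [0, 1], and lets each cell type of dataset A "vote" for
#' the samples of dataset B (a sample's vote is its mean standardized
#' correlation to the A samples of that type). The (typeA, typeB) entry is
#' the Mann-Whitney AUROC that B samples of typeB receive higher votes than
#' the other B samples. Rank-based throughout, hence invariant to monotone
#' transforms of expression.
#'
#' @param a,b Samples-by-genes matrices (cells or pseudo-cells).
#' @param labels_a,labels_b Cell-type labels, one per row of `a` / `b`.
#' @param hvg Optional character vector of genes to use; when `NULL`,
#'   selected with [select_hvg()] on the row-concatenated datasets.
#' @param n_hvg Number of genes to select when `hvg` is `NULL`.
#' @return Matrix of AUROC values, types of `a` in rows, types of `b` in
#'   columns; types with fewer than 2 samples are excluded with a warning.
#' @export
neighbor_voting_auroc <- function(a, labels_a, b, labels_b, hvg = NULL,
                                  n_hvg = 2000) {
  stopifnot(length(labels_a) == nrow(a), length(labels_b) == nrow(b))
  shared <- intersect(colnames(a), colnames(b))
  if (is.null(hvg)) {
    comb <- rbind(methods::as(a[, shared, drop = FALSE], "CsparseMatrix"),
                  methods::as(b[, shared, drop = FALSE], "CsparseMatrix"))
    hvg <- suppressWarnings(select_hvg(comb, n = min(n_hvg, length(shared))))
  }
  hvg <- intersect(hvg, shared)
  if (length(hvg) < 10L) stop("fewer than 10 shared genes to compare on")

  drop_small <- function(labels, who) {
    tab <- table(labels)
    small <- names(tab)[tab < 2L]
    if (length(small))
      warning(sprintf("dataset %s type(s) %s have < 2 samples; excluded",
                      who, paste(small, collapse = ", ")), call. = FALSE)
    !(labels %in% small)
  }
  ka <- drop_small(labels_a, "A"); kb <- drop_small(labels_b, "B")
  a <- a[ka, , drop = FALSE]; labels_a <- labels_a[ka]
  b <- b[kb, , drop = FALSE]; labels_b <- labels_b[kb]
  if (length(unique(labels_a)) < 2L || length(unique(labels_b)) < 2L)
    stop("each dataset needs at least 2 cell types with >= 2 samples")

  # genes x samples, Spearman across the gene axis
  cors <- stats::cor(t(as.matrix(a[, hvg, drop = FALSE])),
                     t(as.matrix(b[, hvg, drop = FALSE])),
                     method = "spearman")          # nA x nB
  std <- apply(cors, 2L, rank) / nrow(cors)        # per-B-sample, in (0, 1]

  types_a <- sort(unique(labels_a))
  types_b <- sort(unique(labels_b))
  out <- matrix(NA_real_, length(types_a), length(types_b),
                dimnames = list(types_a, types_b))
  for (ta in types_a) {
    votes <- colMeans(std[labels_a == ta, , drop = FALSE])
    for (tb in types_b)
      out[ta, tb] <- .auroc(votes, labels_b == tb)
  }
  out
}

#' Match cell types across datasets by the strong-consistency rule
#'
#' All cell-type pairs whose AUROC strictly exceeds the threshold (0.9 by
#' default), sorted by decreasing AUROC.
#'
#' @param auroc AUROC matrix from [neighbor_voting_auroc()].
#' @param threshold Consistency threshold (default 0.9, strict `>`).
#' @return data.frame with columns `type_a`, `type_b`, `auroc`.
#' @export
match_cell_types <- function(auroc, threshold = 0.9) {
  hit <- which(auroc > threshold, arr.ind = TRUE)
  out <- data.frame(type_a = rownames(auroc)[hit[, 1L]],
                    type_b = colnames(auroc)[hit[, 2L]],
                    auroc = auroc[hit],
                    stringsAsFactors = FALSE)
  out[order(-out$auroc, out$type_a, out$type_b), , drop = FALSE]
}
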