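#' Parameters for unbalanced entropic optimal transport
#'
#' Defaults follow the near-balanced setting used for time-course fate
#' mapping: a weak KL penalty on the source (growth-weighted) marginal
#' (`lambda1 = 1`), a strong KL penalty on the target marginal
#' (`lambda2 = 50`, so column sums track the uniform target within about
#' 1%), entropic regularization `epsilon = 0.05`, and a single growth
#' iteration (no re-estimation loop).
#'
#' @param lambda1 Source-marginal KL penalty (> 0).
#' @param lambda2 Target-marginal KL penalty (> 0).
#' @param epsilon Entropic regularization (> 0).
#' @param growth_iters Growth re-estimation iterations (>= 1; 1 means the
#'   supplied growth estimates are used as-is).
#' @param max_iters Maximum Sinkhorn scaling iterations.
#' @param tol Convergence tolerance on the change of the log-domain duals.
#' @return A list of class `ot_params`.
#' @export
ot_params <- function(lambda1 = 1, lambda2 = 50, epsilon = 0.05,
                      growth_iters = 1L, max_iters = 5000L, tol = 1e-8) {
  stopifnot(lambda1 > 0, lambda2 > 0, epsilon > 0, growth_iters >= 1L)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, epsilon = epsilon,
                 growth_iters = as.integer(growth_iters),
                 max_iters = as.integer(max_iters), tol = tol),
            class = "ot_params")
}

#' Unbalanced entropic transport map between two timepoints
#'
#' Minimizes `<C, pi> + lambda1*KL(row-marginal || p) +
#' lambda2*KL(col-marginal || q) - epsilon*H(pi)` by log-domain stabilized
#' scaling iterations with the unbalanced exponent `lambda/(lambda +
#' epsilon)`. The cost `C` is the squared Euclidean distance between cell
#' embeddings, normalized by its median; `p` is the growth-weighted source
#' distribution and `q` the uniform target distribution.
#'
#' @param x0,x1 Embedding matrices (cells x dimensions) for the earlier and
#'   later timepoint; must share dimensionality. Row names identify cells.
#' @param growth Positive per-source-cell growth estimates (default 1 for
#'   every cell).
#' @param params An [ot_params()].
#' @return Coupling matrix (source cells x target cells, entries >= 0)
#'   with attributes `converged`, `iters` and `params`.
#' @export
transport_map <- function(x0, x1, growth = NULL, params = ot_params()) {
  x0 <- as.matrix(x0); x1 <- as.matrix(x1)
  if (ncol(x0) != ncol(x1)) stop("embeddings must share dimensionality")
  n <- nrow(x0); m <- nrow(x1)
  if (is.null(growth)) growth <- rep(1, n)
  if (length(growth) != n || any(growth <= 0))
    stop("growth must be positive, one value per source cell")

  C <- outer(rowSums(x0^2), rowSums(x1^2), "+") - 2 * tcrossprod(x0, x1)
  C[C < 0] <- 0
  med <- stats::median(C)
  if (med > 0) C <- C / med

  p <- growth / sum(growth)
  q <- rep(1 / m, m)
  eps <- params$epsilon
  a1 <- params$lambda1 / (params$lambda1 + eps)
  a2 <- params$lambda2 / (params$lambda2 + eps)
  G <- -C / eps
  lu <- rep(0, n); lv <- rep(0, m)
  converged <- FALSE; it <- 0L
  for (it in seq_len(params$max_iters)) {
    lu_new <- a1 * (log(p) - .logsumexp_rows(G, lv))
    lv_new <- a2 * (log(q) - .logsumexp_rows(t(G), lu_new))
    delta <- max(max(abs(lu_new - lu)), max(abs(lv_new - lv)))
    lu <- lu_new; lv <- lv_new
    if (delta < params$tol) { converged <- TRUE; break }
  }
  pi <- exp(sweep(sweep(G, 1L, lu, "+"), 2L, lv, "+"))
  dimnames(pi) <- list(rownames(x0), rownames(x1))
  attr(pi, "converged") <- converged
  attr(pi, "iters") <- it
  attr(pi, "params") <- params
  pi
}

#' PCA embedding for the transport cost
#'
#' Top principal components of the normalized expression matrix over
#' highly variable genes — the space in which squared-Euclidean transport
#' costs are computed. All cells are embedded together so that adjacent
#' timepoints share the space.
#'
#' @param normalized Cells-by-genes normalized matrix.
#' @param n_pcs Number of components (default 30).
#' @param hvg Optional gene subset; selected with [select_hvg()] when
#'   `NULL`.
#' @param n_hvg Number of genes to select when `hvg` is `NULL`.
#' @return Cells-by-components score matrix.
#' @export
pca_embedding <- function(normalized, n_pcs = 30, hvg = NULL,
                          n_hvg = 2000) {
  if (is.null(hvg))
    hvg <- suppressWarnings(select_hvg(normalized,
                                       n = min(n_hvg, ncol(normalized))))
  X <- as.matrix(normalized[, hvg, drop = FALSE])
  k <- min(n_pcs, ncol(X) - 1L, nrow(X) - 1L)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
  scores <- pc$x
  rownames(scores) <- rownames(normalized)
  scores
}

#' Fit a chain of transport maps across a time course
#'
#' Embeds all cells in a common PCA space and computes one unbalanced
#' entropic coupling per adjacent timepoint pair.
#'
#' @param normalized Cells-by-genes normalized matrix.
#' @param timepoints Per-cell timepoint labels (coerced to factor in the
#'   supplied level order, or chronological order of `levels`).
#' @param params An [ot_params()].
#' @param growth Optional named per-cell growth vector.
#' @param n_pcs,hvg,n_hvg Passed to [pca_embedding()].
#' @return A `transport_chain`: list with `timepoints`, `cells` (list of
#'   barcodes per timepoint) and `couplings` (list of coupling matrices,
#'   one per adjacent pair).
#' @export
fit_transport_chain <- function(normalized, timepoints,
                                params = ot_params(), growth = NULL,
                                n_pcs = 30, hvg = NULL, n_hvg = 2000) {
  stopifnot(length(timepoints) == nrow(normalized))
  tp <- if (is.factor(timepoints)) timepoints else
    factor(timepoints, levels = unique(timepoints))
  levs <- levels(droplevels(tp))
  if (length(levs) < 2L) stop("need at least two timepoints")
  emb <- pca_embedding(normalized, n_pcs = n_pcs, hvg = hvg, n_hvg = n_hvg)
  cells <- split(rownames(normalized), tp)[levs]
  couplings <- vector("list", length(levs) - 1L)
  for (k in seq_len(length(levs) - 1L)) {
    c0 <- cells[[k]]; c1 <- cells[[k + 1L]]
    g <- if (is.null(growth)) NULL else growth[c0]
    couplings[[k]] <- transport_map(emb[c0, , drop = FALSE],
                                    emb[c1, , drop = FALSE],
                                    growth = g, params = params)
  }
  names(couplings) <- paste(levs[-length(levs)], levs[-1L], sep = " -> ")
  structure(list(timepoints = levs, cells = cells, couplings = couplings,
                 params = params),
            class = "transport_chain")
}

#' @exportS3Method base::print
print.transport_chain <- function(x, ...) {
  cat(sprintf("Transport chain over %d timepoints: %s\n",
              length(x$timepoints), paste(x$timepoints, collapse = ", ")))
  for (k in seq_along(x$couplings)) {
    cpl <- x$couplings[[k]]
    cat(sprintf("  %-20s %4d x %-4d cells, mass %.4f, %s\n",
                names(x$couplings)[k], nrow(cpl), ncol(cpl), sum(cpl),
                if (isTRUE(attr(cpl, "converged"))) "converged"
                else "NOT converged"))
  }
  invisible(x)
}

.rownorm <- function(m) m / pmax(rowSums(m), .Machine$double.xmin)

.tp_index <- function(chain, t) {
  i <- match(as.character(t), chain$timepoints)
  if (is.na(i)) stop("timepoint '", t, "' is not in the chain")
  i
}

#' Compose adjacent couplings into a long-range coupling
#'
#' Sequential Markov composition of the row-normalized adjacent couplings
#' between two timepoints, rescaled to total mass 1. Pull-back through the
#' composed map equals sequential pull-back through the factors.
#'
#' @param chain A `transport_chain`.
#' @param t_a,t_b Timepoint labels with `t_a` earlier than `t_b`.
#' @return Coupling matrix (cells at `t_a` x cells at `t_b`), total mass 1.
#' @export
compose_chain <- function(chain, t_a, t_b) {
  ia <- .tp_index(chain, t_a); ib <- .tp_index(chain, t_b)
  if (ia >= ib) stop("t_a must be earlier than t_b")
  M <- .rownorm(chain$couplings[[ia]])
  k <- ia + 1L
  while (k < ib) {
    M <- M %*% .rownorm(chain$couplings[[k]])
    k <- k + 1L
  }
  M / sum(M)
}

#' Pull a target cell set back to its ancestor distributions
#'
#' The indicator over the target cells is normalized to a probability
#' vector and propagated backward through the row-normalized couplings;
#' at each earlier timepoint the result is renormalized to an ancestor
#' probability distribution over that timepoint's cells.
#'
#' @param chain A `transport_chain`.
#' @param target_cells Barcodes of the target cell set.
#' @param at Timepoint label the target cells live at (defaults to the
#'   last timepoint).
#' @return Named list (one entry per earlier timepoint, latest first) of
#'   named probability vectors summing to 1.
#' @export
pull_back <- function(chain, target_cells, at = NULL) {
  if (is.null(at)) at <- chain$timepoints[length(chain$timepoints)]
  ik <- .tp_index(chain, at)
  if (ik < 2L) stop("no earlier timepoint to pull back to")
  here <- chain$cells[[ik]]
  missing <- setdiff(target_cells, here)
  if (length(missing))
    stop("target cells absent from timepoint ", at, ": ",
         paste(utils::head(missing, 5L), collapse = ", "))
  if (length(target_cells) == 0L) stop("target set is empty")
  p <- stats::setNames(as.numeric(here %in% target_cells), here)
  p <- p / sum(p)
  out <- list()
  for (j in seq(ik - 1L, 1L)) {
    M <- .rownorm(chain$couplings[[j]])
    a <- as.numeric(M %*% p)
    a <- a / sum(a)
    names(a) <- chain$cells[[j]]
    out[[chain$timepoints[j]]] <- a
    p <- a
  }
  out
}

#' Push a source cell set forward to descendant distributions
#'
#' The transpose operation of [pull_back()]: propagates a normalized
#' indicator forward through the column-action of the row-normalized
#' couplings.
#'
#' @param chain A `transport_chain`.
#' @param source_cells Barcodes of the source cell set.
#' @param at Timepoint the source cells live at (defaults to the first).
#' @return Named list (one entry per later timepoint, earliest first) of
#'   named probability vectors summing to 1.
#' @export
pull_forward <- function(chain, source_cells, at = NULL) {
  if (is.null(at)) at <- chain$timepoints[1L]
  ik <- .tp_index(chain, at)
  nt <- length(chain$timepoints)
  if (ik >= nt) stop("no later timepoint to push forward to")
  here <- chain$cells[[ik]]
  missing <- setdiff(source_cells, here)
  if (length(missing))
    stop("source cells absent from timepoint ", at, ": ",
         paste(utils::head(missing, 5L), collapse = ", "))
  p <- stats::setNames(as.numeric(here %in% source_cells), here)
  p <- p / sum(p)
  out <- list()
  for (j in seq(ik, nt - 1L)) {
    M <- .rownorm(chain$couplings[[j]])
    d <- as.numeric(Matrix::crossprod(M, p))
    d <- d / sum(d)
    names(d) <- chain$cells[[j + 1L]]
    out[[chain$timepoints[j + 1L]]] <- d
    p <- d
  }
  out
}

#' Per-cell fate probabilities toward terminal cell sets
#'
#' Composes the chain forward from a timepoint to the final timepoint and,
#' for each cell, sums its (row-stochastic) descendant distribution over
#' each terminal set — giving, per cell, the probability of ending in each
#' fate.
#'
#' @param chain A `transport_chain`.
#' @param terminal_sets Named list of barcode vectors at the final
#'   timepoint.
#' @param from Timepoint whose cells are scored (defaults to the first).
#' @return Matrix of fate probabilities, cells in rows, fates in columns;
#'   rows sum to at most 1.
#' @export
fate_probabilities <- function(chain, terminal_sets, from = NULL) {
  if (is.null(from)) from <- chain$timepoints[1L]
  last <- chain$timepoints[length(chain$timepoints)]
  M <- compose_chain(chain, from, last)
  M <- .rownorm(M)
  final <- chain$cells[[length(chain$timepoints)]]
  out <- sapply(terminal_sets, function(s)
    rowSums(M[, final %in% s, drop = FALSE]))
  rownames(out) <- chain$cells[[.tp_index(chain, from)]]
  out
}

#' Trajectory membership by probability threshold
#'
#' Cells whose ancestor probability strictly exceeds the threshold are
#' part of the trajectory; the default threshold is 0.00025 on the
#' normalized ancestor distribution.
#'
#' @param dist Named probability vector (an ancestor distribution).
#' @param threshold Membership threshold (default 2.5e-4, strict `>`).
#' @return Character vector of member cell barcodes.
#' @export
membership <- function(dist, threshold = 0.00025) {
  names(dist)[dist > threshold]
}

#' Ancestor divergence between two trajectories
#'
#' Half the total variation distance — `0.5 * sum(|p - q|)` — between two
#' ancestor distributions over the same cells. 0 when the distributions
#' coincide, 1 when their supports are disjoint.
#'
#' @param p,q Named probability vectors over the same cell index.
#' @return Numeric in [0, 1].
#' @export
ancestor_divergence <- function(p, q) {
  if (length(p) != length(q))
    stop("distributions are over different cell sets")
  if (!is.null(names(p)) && !is.null(names(q))) {
    if (!setequal(names(p), names(q)))
      stop("distributions are over different cell sets")
    q <- q[names(p)]
  }
  0.5 * sum(abs(p - q))
}

#' Distribution-weighted gene expression trends
#'
#' The trend of a gene along a trajectory is its average expression under
#' the ancestor (or descendant) probability distribution at each
#' timepoint.
#'
#' @param normalized Cells-by-genes normalized matrix.
#' @param distributions Named list of named probability vectors (e.g. from
#'   [pull_back()]).
#' @param genes Genes to report (default: all).
#' @return Matrix of trends, timepoints in rows (list order), genes in
#'   columns.
#' @export
gene_trend <- function(normalized, distributions, genes = colnames(normalized)) {
  out <- matrix(NA_real_, length(distributions), length(genes),
                dimnames = list(names(distributions), genes))
  for (i in seq_along(distributions)) {
    d <- distributions[[i]]
    out[i, ] <- as.numeric(
      Matrix::crossprod(normalized[names(d), genes, drop = FALSE], d))
  }
  out
}

#' Rank putative driver genes by correlation with fate probability
#'
#' Per-gene Pearson correlation between expression and a per-cell fate
#' probability vector, ranked in decreasing order; genes with zero
#' expression variance are undefined (`NA`) and rank last.
#'
#' @param normalized Cells-by-genes normalized matrix (>= 20 cells).
#' @param fate Named per-cell fate probabilities in [0, 1].
#' @return data.frame with `gene`, `correlation`, `rank`, ordered by rank.
#' @export
driver_correlation <- function(normalized, fate) {
  if (nrow(normalized) < 20L) stop("need at least 20 cells")
  if (any(fate < 0 | fate > 1)) stop("fate probabilities must be in [0, 1]")
  if (!is.null(names(fate))) fate <- fate[rownames(normalized)]
  if (stats::sd(fate) == 0) stop("fate probability vector is constant")
  X <- as.matrix(normalized)
  sds <- apply(X, 2L, stats::sd)
  r <- rep(NA_real_, ncol(X))
  r[sds > 0] <- as.numeric(stats::cor(X[, sds > 0, drop = FALSE], fate))
  ord <- order(-r, colnames(X), method = "radix", na.last = TRUE)
  data.frame(gene = colnames(X)[ord], correlation = r[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}
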