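test_that("transport parameters validate and carry the fate-mapping defaults", {
  p <- ot_params()
  expect_equal(p$lambda1, 1)
  expect_equal(p$lambda2, 50)
  expect_equal(p$epsilon, 0.05)
  expect_equal(p$growth_iters, 1L)
  expect_error(ot_params(lambda1 = 0), "lambda1")
  expect_error(ot_params(epsilon = -1), "epsilon")
})

test_that("the entropic limit approaches the outer product of the marginals", {
  .with_test_seed(61, {
    x0 <- matrix(rnorm(5 * 2), 5); x1 <- matrix(rnorm(7 * 2), 7)
    cpl <- transport_map(x0, x1,
                         params = ot_params(lambda1 = 1e5, lambda2 = 1e5,
                                            epsilon = 1e3))
    outer_pq <- outer(rep(1 / 5, 5), rep(1 / 7, 7))
    expect_lt(max(abs(cpl - outer_pq)), 1e-3)
  })
})

test_that("near-balanced transport between identical clouds matches the LP oracle", {
  .with_test_seed(62, {
    x <- matrix(rnorm(5 * 3, sd = 3), 5)
    cpl <- transport_map(x, x, params = ot_params(lambda1 = 100,
                                                  lambda2 = 100,
                                                  epsilon = 0.01))
    C <- outer(rowSums(x^2), rowSums(x^2), "+") - 2 * tcrossprod(x)
    C[C < 0] <- 0
    C <- C / stats::median(C)
    oracle <- lp_oracle_cost(C)
    # the LP optimum of identical clouds is the identity pairing
    expect_equal(oracle$perm, 1:5)
    expect_gte(sum(diag(cpl)) / sum(cpl), 0.9)
    # and the entropic cost is within a whisker of the LP cost
    ot_cost <- sum(C * cpl / sum(cpl))
    expect_lt(abs(ot_cost - oracle$cost), 0.05 * max(oracle$cost, 0.01))
  })
})

test_that("lambda2 = 50 keeps column sums within 1% of the uniform target", {
  .with_test_seed(63, {
    x0 <- matrix(rnorm(40 * 5), 40); x1 <- matrix(rnorm(30 * 5), 30)
    cpl <- transport_map(x0, x1)
    expect_true(isTRUE(attr(cpl, "converged")))
    rel <- abs(colSums(cpl) - 1 / 30) / (1 / 30)
    expect_lt(mean(rel), 0.01)
    expect_lt(max(rel), 0.05)
    # total mass within 1% of 1
    expect_lt(abs(sum(cpl) - 1), 0.01)
    # growth reweights the source marginal
    g <- c(rep(4, 20), rep(1, 20))
    cplg <- transport_map(x0, x1, growth = g)
    expect_gt(sum(rowSums(cplg)[1:20]), sum(rowSums(cplg)[21:40]))
  })
})

test_that("hitting the iteration cap reports non-convergence", {
  .with_test_seed(64, {
    x0 <- matrix(rnorm(10 * 2), 10); x1 <- matrix(rnorm(10 * 2), 10)
    cpl <- transport_map(x0, x1, params = ot_params(max_iters = 1L))
    expect_false(attr(cpl, "converged"))
  })
})

# a small hand-built chain with known couplings
toy_chain <- function(mats) {
  cells <- list()
  tps <- paste0("t", seq_len(length(mats) + 1L))
  cells[[1L]] <- sprintf("t1_c%d", seq_len(nrow(mats[[1L]])))
  for (k in seq_along(mats)) {
    cells[[k + 1L]] <- sprintf("t%d_c%d", k + 1L, seq_len(ncol(mats[[k]])))
    dimnames(mats[[k]]) <- list(cells[[k]], cells[[k + 1L]])
  }
  names(cells) <- tps
  structure(list(timepoints = tps, cells = cells, couplings = mats,
                 params = ot_params()), class = "transport_chain")
}

test_that("composition is Markov and consistent with sequential pull-back", {
  .with_test_seed(65, {
    mats <- lapply(1:3, function(k) matrix(stats::runif(16, 0.01, 1), 4))
    ch <- toy_chain(mats)
    # adjacent composition returns the stored coupling, normalized the
    # same way pull-back consumes it (row-stochastic, then total mass 1)
    adj <- compose_chain(ch, "t1", "t2")
    rn <- mats[[1L]] / rowSums(mats[[1L]])
    expect_equal(adj, rn / sum(rn), ignore_attr = TRUE, tolerance = 1e-12)
    # identity couplings compose to the identity
    idc <- toy_chain(replicate(2, diag(4), simplify = FALSE))
    expect_equal(unname(as.matrix(compose_chain(idc, "t1", "t3"))),
                 diag(4) / 4)
    # composed pull-back equals sequential pull-back to 1e-10
    tgt <- ch$cells[["t4"]][1:2]
    seqd <- pull_back(ch, tgt, at = "t4")
    M <- compose_chain(ch, "t1", "t4")
    p <- as.numeric(ch$cells[["t4"]] %in% tgt); p <- p / sum(p)
    direct <- as.numeric(M %*% p); direct <- direct / sum(direct)
    expect_lt(max(abs(direct - unname(seqd[["t1"]]))), 1e-10)
    expect_error(compose_chain(ch, "t3", "t1"), "earlier")
  })
})

test_that("pull-back of everything through identity couplings is uniform", {
  idc <- toy_chain(replicate(2, diag(5), simplify = FALSE))
  anc <- pull_back(idc, idc$cells[["t3"]], at = "t3")
  expect_equal(unname(anc[["t1"]]), rep(0.2, 5))
  expect_equal(unname(anc[["t2"]]), rep(0.2, 5))
  for (a in anc) expect_equal(sum(a), 1)
  expect_error(pull_back(idc, c("nope"), at = "t3"), "absent.*nope")
})

test_that("membership thresholds the normalized distribution strictly", {
  u4000 <- stats::setNames(rep(1 / 4000, 4000), sprintf("c%04d", 1:4000))
  expect_length(membership(u4000), 0L)          # p = 0.00025 exactly
  u1000 <- stats::setNames(rep(1 / 1000, 1000), sprintf("c%04d", 1:1000))
  expect_length(membership(u1000), 1000L)
  point <- stats::setNames(c(1, rep(0, 9)), sprintf("c%d", 1:10))
  expect_equal(membership(point), "c1")
})

test_that("ancestor divergence is half the total variation distance", {
  expect_equal(ancestor_divergence(c(a = 0.5, b = 0.5), c(a = 0.5, b = 0.5)),
               0)
  expect_equal(ancestor_divergence(c(a = 1, b = 0), c(a = 0, b = 1)), 1)
  expect_equal(ancestor_divergence(c(a = 1, b = 0), c(a = 0.5, b = 0.5)),
               0.5)
  # name alignment: order must not matter
  expect_equal(ancestor_divergence(c(a = 0.3, b = 0.7), c(b = 0.7, a = 0.3)),
               0)
  expect_error(ancestor_divergence(c(a = 1), c(b = 1)), "different")
})

test_that("ancestor divergence behaves as a bounded metric on random triples", {
  .with_test_seed(66, {
    for (i in 1:25) {
      rdist <- function() { x <- stats::runif(20); x / sum(x) }
      p <- rdist(); q <- rdist(); r <- rdist()
      dpq <- ancestor_divergence(p, q)
      expect_gte(dpq, 0); expect_lte(dpq, 1)
      expect_equal(dpq, ancestor_divergence(q, p))
      expect_lte(dpq,
                 ancestor_divergence(p, r) + ancestor_divergence(r, q) + 1e-12)
    }
  })
})

test_that("gene trends are distribution-weighted means", {
  m <- methods::as(rbind(c1 = c(g1 = 1, g2 = 10),
                         c2 = c(g1 = 3, g2 = 20),
                         c3 = c(g1 = 5, g2 = 60)), "CsparseMatrix")
  point <- list(t1 = c(c1 = 0, c2 = 1, c3 = 0))
  expect_equal(unname(gene_trend(m, point)[1L, ]), c(3, 20))
  unif <- list(t1 = c(c1 = 1, c2 = 1, c3 = 1) / 3)
  expect_equal(unname(gene_trend(m, unif)[1L, ]), c(3, 30))
})

test_that("driver correlation ranks fate-tracking genes first", {
  .with_test_seed(67, {
    n <- 500L
    fate <- stats::runif(n)
    n_drivers <- 10L; n_noise <- 90L
    drivers <- sapply(seq_len(n_drivers), function(i)
      fate + stats::rnorm(n, 0, 0.3))
    noise <- matrix(stats::rnorm(n * n_noise), n)
    X <- cbind(drivers, noise)
    colnames(X) <- c(sprintf("drv%02d", seq_len(n_drivers)),
                     sprintf("noise%02d", seq_len(n_noise)))
    rownames(X) <- sprintf("c%03d", seq_len(n))
    X <- X - min(X)
    m <- methods::as(X, "CsparseMatrix")
    names(fate) <- rownames(X)

    dr <- driver_correlation(m, fate)
    expect_equal(dr$gene[1L], dr$gene[which.max(dr$correlation)])
    top_decile <- dr$gene[seq_len(ceiling(nrow(dr) / 10))]
    expect_true(all(sprintf("drv%02d", seq_len(n_drivers)) %in% top_decile))
    # a gene equal to the fate vector correlates perfectly and ranks first
    m2 <- cbind(m, perfect = fate)
    expect_equal(driver_correlation(m2, fate)$gene[1L], "perfect")
    # permuted fate decorrelates everything
    perm_fate <- stats::setNames(sample(fate), names(fate))
    drp <- driver_correlation(m, perm_fate)
    expect_lt(mean(abs(drp$correlation), na.rm = TRUE), 0.1)
    # degenerate inputs
    m3 <- cbind(m, const = rep(1, n))
    drc <- driver_correlation(m3, fate)
    expect_true(is.na(drc$correlation[drc$gene == "const"]))
    expect_equal(drc$gene[nrow(drc)], "const")
    expect_error(driver_correlation(m, stats::setNames(rep(0.5, n),
                                                       names(fate))),
                 "constant")
    expect_error(driver_correlation(m[1:10, ], fate[1:10]), "20 cells")
  })
})

test_that("the fitted chain recovers the planted branch ancestry", {
  tc <- timecourse_fixture()
  ch <- chain_fixture()
  md <- tc$metadata
  last <- ch$timepoints[length(ch$timepoints)]
  termA <- md$barcode[md$timepoint == last & md$branch == "A"]
  termB <- md$barcode[md$timepoint == last & md$branch == "B"]
  ancA <- pull_back(ch, termA)
  ancB <- pull_back(ch, termB)
  at_split <- ch$timepoints[2L]
  branch_of <- function(d) md$branch[match(names(d), md$barcode)]
  massA <- sum(ancA[[at_split]][branch_of(ancA[[at_split]]) == "A"])
  expect_gte(massA, 0.9)
  # branch-vs-branch divergence exceeds within-branch divergence
  d_ab <- ancestor_divergence(ancA[[at_split]], ancB[[at_split]])
  halves <- split(termA, rep(1:2, length.out = length(termA)))
  d_within <- ancestor_divergence(pull_back(ch, halves[[1L]])[[at_split]],
                                  pull_back(ch, halves[[2L]])[[at_split]])
  expect_gt(d_ab, d_within)
  # membership at the default threshold contains the high-mass ancestors
  mem <- membership(ancA[[at_split]])
  expect_gt(length(mem), 0L)
  expect_true(all(ancA[[at_split]][mem] > 0.00025))
})

test_that("planted rising genes trend upward along their trajectory", {
  tc <- timecourse_fixture()
  ch <- chain_fixture()
  md <- tc$metadata
  last <- ch$timepoints[length(ch$timepoints)]
  termA <- md$barcode[md$timepoint == last & md$branch == "A"]
  anc <- pull_back(ch, termA)
  dists <- c(rev(anc),
             list(stats::setNames(rep(1 / length(termA), length(termA)),
                                  termA)))
  names(dists)[length(dists)] <- last
  tr <- gene_trend(tc$norm, dists, genes = tc$truth$drivers_a)
  rho <- apply(tr, 2L, function(y)
    stats::cor(seq_along(y), y, method = "spearman"))
  expect_true(all(rho > 0.9))
})
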