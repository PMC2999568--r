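## RELL-based edge supports and topology tests, plus clade queries.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Expected-likelihood-weight (LR-ELW) edge supports
#'
#' For each internal edge, the current tree and the two
#' nearest-neighbour-interchange rearrangements across that edge are
#' evaluated (neighbours get a local branch-length re-optimization around
#' the edge). Site log-likelihoods are then bootstrap-resampled (RELL: sites
#' drawn with replacement, per-site log-likelihoods re-summed, no
#' re-optimization) and likelihood weights
#' `w_j = exp(lnL_j - max) / sum` accumulated over replicates. The edge
#' support is 100 times the mean weight of the maximum-likelihood topology
#' of the triplet.
#'
#' @param fit an `"hmg_ml"` fit, or a `phylo` tree (then `aln` and `model`
#'   are required).
#' @param aln,model alignment and [rate_model()] when `fit` is a tree.
#' @param n_replicates RELL replicates (default 1000; a warning is issued
#'   below 100).
#' @param seed RNG seed (results are reproducible for a fixed seed).
#' @param edges internal edge rows to evaluate (default: all).
#' @return an object of class `"edge_support"`: data frame `support` with
#'   one row per evaluated internal edge (parent and child node, the three
#'   mean weights in percent summing to 100, `support`, and whether the
#'   current topology was the ML one), plus `n_replicates` and `seed`.
#' @export
elw_edge_support <- function(fit, aln = NULL, model = NULL,
                             n_replicates = 1000, seed = 1, edges = NULL) {
  if (inherits(fit, "hmg_ml")) {
    tree <- fit$tree; aln <- fit$alignment; model <- fit$model
  } else tree <- fit
  if (n_replicates < 100)
    warning("fewer than 100 RELL replicates: supports will be unstable",
            call. = FALSE)
  prep0 <- prepare_pruning(tree, aln, model)
  phy <- prep0$phy
  base <- run_pruning(prep0, phy$edge.length, model)
  nsites <- length(base$sitelik)
  if (is.null(edges)) edges <- internal_edges(phy)

  idx <- with_seed(seed, matrix(sample.int(nsites, nsites * n_replicates,
                                           replace = TRUE),
                                nrow = n_replicates))
  rows <- lapply(edges, function(r) {
    nb <- nni_neighbors(phy, r)
    site_mat <- matrix(0, nsites, 3)
    site_mat[, 1] <- base$sitelik
    full <- c(base$loglik, 0, 0)
    for (j in 2:3) {
      cand <- nb[[j - 1]]
      prep <- prepare_pruning(cand, aln, model)
      res <- optimize_edges(prep, prep$phy$edge.length, model,
                            rows = edges_touching(prep$phy, nb$nodes["u"],
                                                  nb$nodes["v"]),
                            rounds = 2)
      sl <- run_pruning(prep, res$blen, model)
      site_mat[, j] <- sl$sitelik
      full[j] <- sl$loglik
    }
    ml_top <- which.max(full)
    wsum <- numeric(3)
    for (b in seq_len(n_replicates)) {
      tot <- colSums(site_mat[idx[b, ], , drop = FALSE])
      w <- exp(tot - max(tot))
      wsum <- wsum + w / sum(w)
    }
    wmean <- 100 * wsum / n_replicates
    data.frame(parent = phy$edge[r, 1], child = phy$edge[r, 2],
               w_current = wmean[1], w_nni1 = wmean[2], w_nni2 = wmean[3],
               support = wmean[ml_top], current_is_ml = ml_top == 1L)
  })
  structure(list(support = do.call(rbind, rows), tree = phy,
                 n_replicates = n_replicates, seed = seed),
            class = "edge_support")
}

#' @export
print.edge_support <- function(x, ...) {
  cat("LR-ELW edge supports (", x$n_replicates, " RELL replicates, seed ",
      x$seed, ")\n", sep = "")
  print(x$support, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Kishino-Hasegawa and Shimodaira-Hasegawa topology tests
#'
#' Branch lengths are optimized per topology, per-site log-likelihoods are
#' RELL-resampled, and each topology is compared with the maximum-likelihood
#' one: KH as a two-sided test on the centred resampled log-likelihood
#' difference, SH with the standard simultaneous max-centred comparison. The
#' best topology receives p = 1 under both by construction.
#'
#' @param topologies list of `phylo` trees over the same tips (>= 2).
#' @param aln alignment.
#' @param model a [rate_model()].
#' @param n_replicates RELL replicates (default 10000).
#' @param seed RNG seed.
#' @param optimize optimize branch lengths per topology first? (default TRUE)
#' @return data frame: `topology`, `loglik`, `delta` (lnL deficit to the
#'   best), `kh_p`, `sh_p`.
#' @export
kh_sh_test <- function(topologies, aln, model, n_replicates = 10000,
                       seed = 1, optimize = TRUE) {
  nt <- length(topologies)
  if (nt < 2L) stop("need at least 2 topologies", call. = FALSE)
  sitemats <- lapply(topologies, function(tr) {
    if (optimize) tr <- optimize_branch_lengths(tr, aln, model, max_rounds = 5)
    tree_loglik(tr, aln, model)$sitelik
  })
  S <- do.call(cbind, sitemats)
  full <- colSums(S)
  best <- which.max(full)
  nsites <- nrow(S)
  idx <- with_seed(seed, matrix(sample.int(nsites, nsites * n_replicates,
                                           replace = TRUE),
                                nrow = n_replicates))
  tots <- matrix(0, n_replicates, nt)
  for (b in seq_len(n_replicates))
    tots[b, ] <- colSums(S[idx[b, ], , drop = FALSE])

  kh <- sh <- numeric(nt)
  centred <- sweep(tots, 2, colMeans(tots))
  maxc <- apply(centred, 1, max)
  for (j in seq_len(nt)) {
    d_obs <- full[best] - full[j]
    dd <- tots[, best] - tots[, j]
    kh[j] <- mean(abs(dd - mean(dd)) >= d_obs)
    sh[j] <- mean(maxc - centred[, j] >= d_obs)
  }
  data.frame(topology = seq_len(nt), loglik = full,
             delta = full[best] - full, kh_p = kh, sh_p = sh)
}

#' Is a taxon set monophyletic?
#'
#' For an unrooted tree, a taxon set is monophyletic when some edge induces
#' the bipartition separating exactly those taxa from the rest. Singleton
#' sets and the full leaf set are trivially monophyletic.
#'
#' @param tree `phylo`.
#' @param taxa character vector of tip labels.
#' @return logical.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' is_monophyletic(tr, c("A", "B"))  # TRUE
#' is_monophyletic(tr, c("A", "C"))  # FALSE
#' @export
is_monophyletic <- function(tree, taxa) {
  tips <- tree$tip.label
  if (!all(taxa %in% tips))
    stop("taxa not all present in the tree", call. = FALSE)
  taxa <- unique(taxa)
  if (length(taxa) <= 1L || length(taxa) == length(tips)) return(TRUE)
  phy <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tips)
  nnode <- ntip + phy$Nnode
  desc <- matrix(FALSE, nnode, ntip)
  desc[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (e in seq_len(nrow(phy$edge)))
    desc[phy$edge[e, 1], ] <- desc[phy$edge[e, 1], ] | desc[phy$edge[e, 2], ]
  target <- tips %in% taxa
  for (e in seq_len(nrow(phy$edge))) {
    clade <- desc[phy$edge[e, 2], ]
    if (all(clade == target) || all(clade == !target)) return(TRUE)
  }
  FALSE
}

#' The internal edge separating a taxon set, if any
#'
#' Returns the edge row of the (postorder) tree inducing the bipartition
#' `taxa | rest`, or `NA` when the set is not monophyletic. Useful to pull
#' the LR-ELW support of a clade of interest.
#'
#' @inheritParams is_monophyletic
#' @return list with `edge` (row index in the postorder tree, or `NA`) and
#'   `tree` (the postorder tree the index refers to).
#' @export
clade_edge <- function(tree, taxa) {
  phy <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  desc <- matrix(FALSE, nnode, ntip)
  desc[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (e in seq_len(nrow(phy$edge)))
    desc[phy$edge[e, 1], ] <- desc[phy$edge[e, 1], ] | desc[phy$edge[e, 2], ]
  target <- phy$tip.label %in% taxa
  hit <- NA_integer_
  for (e in seq_len(nrow(phy$edge))) {
    clade <- desc[phy$edge[e, 2], ]
    if (all(clade == target) || all(clade == !target)) { hit <- e; break }
  }
  list(edge = hit, tree = phy)
}
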