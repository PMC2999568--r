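## NNI moves, tree search, and the user-facing maximum-likelihood fit.

# Internal edges of an unrooted binary phylo stored with the basal
# trifurcation at ntip+1: edge rows whose child is an internal node.
internal_edges <- function(phy) {
  ntip <- length(phy$tip.label)
  which(phy$edge[, 2] > ntip)
}

#' Nearest-neighbour-interchange rearrangements across an internal edge
#'
#' Returns the two NNI topologies obtained by exchanging subtrees across
#' the given internal edge (the edge's local rearrangement neighbourhood,
#' the set the LR-ELW support integrates over). Branch lengths travel with
#' their subtrees; the central edge keeps its length.
#'
#' @param phy unrooted binary `phylo` in postorder (e.g. a [clade_edge()]
#'   tree or an optimized fit tree).
#' @param edge_row row index of an internal edge in `phy$edge`.
#' @return list: the two neighbour trees, plus `nodes` naming the edge's
#'   endpoints `u` and `v`.
#' @export
nni_neighbors <- function(phy, edge_row) {
  ntip <- length(phy$tip.label)
  u <- phy$edge[edge_row, 1]; v <- phy$edge[edge_row, 2]
  if (v <= ntip) stop("not an internal edge", call. = FALSE)
  cv <- which(phy$edge[, 1] == v)
  ou <- which(phy$edge[, 1] == u & phy$edge[, 2] != v)
  w_row <- ou[1]
  make <- function(c_row) {
    t2 <- phy
    t2$edge[w_row, 1] <- v
    t2$edge[c_row, 1] <- u
    attr(t2, "order") <- NULL  # edge matrix was edited; force a real reorder
    ape::reorder.phylo(t2, "postorder")
  }
  list(make(cv[1]), make(cv[2]), nodes = c(u = u, v = v))
}

# Edge rows incident to either endpoint of the rearranged edge (the central
# edge plus its four neighbours) -- the ones worth re-optimizing locally.
edges_touching <- function(phy, u, v) {
  which(phy$edge[, 1] == u | phy$edge[, 1] == v |
        phy$edge[, 2] == u | phy$edge[, 2] == v)
}

# Optimize the given edge rows only (used for NNI candidates and ELW
# neighbour topologies). Joint updates are guarded so the reported
# log-likelihood is always exact for the returned lengths.
optimize_edges <- function(prep, blen, model, rows, rounds = 2,
                           min_bl = 1e-8, max_bl = 50) {
  rows <- rows[!is.na(rows)]
  cur <- run_pruning(prep, blen, model)$loglik
  for (i in seq_len(rounds)) {
    pr <- propose_edges(prep, blen, model, rows, min_bl, max_bl)
    best1 <- max(pr$loglik)
    if (best1 <= cur + 1e-9) break
    cand <- blen; cand[rows] <- pr$t
    ll <- run_pruning(prep, cand, model)$loglik
    if (ll >= best1) { blen <- cand; cur <- ll }
    else {
      j <- which.max(pr$loglik)
      blen[rows[j]] <- pr$t[j]
      cur <- pr$loglik[j]
    }
  }
  list(blen = blen, loglik = cur)
}

#' Hill-climbing tree search over nearest-neighbour interchanges
#'
#' Starting from a tree with branch lengths, repeatedly evaluates all NNI
#' rearrangements (each candidate gets a quick local branch-length
#' re-optimization around the rearranged edge), accepts the best improving
#' neighbour, fully re-optimizes branch lengths, and stops when no
#' rearrangement improves the log-likelihood by more than `tol`. Ties are
#' broken by the first-encountered candidate in deterministic edge order.
#'
#' @param start `phylo` starting tree (unrooted binary) with branch lengths.
#' @param aln alignment.
#' @param model a [rate_model()].
#' @param tol minimum log-likelihood improvement to accept a move.
#' @param max_moves cap on accepted rearrangements.
#' @return the resulting tree; attributes `loglik` and `visited_loglik`
#'   (log-likelihoods of every accepted state, non-decreasing).
#' @export
nni_search <- function(start, aln, model, tol = 1e-3, max_moves = 100) {
  tree <- optimize_branch_lengths(start, aln, model, max_rounds = 5)
  cur <- attr(tree, "loglik")
  visited <- cur
  for (move in seq_len(max_moves)) {
    prep0 <- prepare_pruning(tree, aln, model)
    best_gain <- 0; best_tree <- NULL
    for (r in internal_edges(prep0$phy)) {
      nb <- nni_neighbors(prep0$phy, r)
      for (cand in nb[1:2]) {
        prep <- prepare_pruning(cand, aln, model)
        central <- which((prep$phy$edge[, 1] == nb$nodes[["u"]] &
                          prep$phy$edge[, 2] == nb$nodes[["v"]]) |
                         (prep$phy$edge[, 1] == nb$nodes[["v"]] &
                          prep$phy$edge[, 2] == nb$nodes[["u"]]))
        pr <- propose_edges(prep, prep$phy$edge.length, model, central)
        gain <- pr$loglik[1] - cur
        if (gain > best_gain + tol) {
          best_gain <- gain
          best_tree <- prep$phy
          best_tree$edge.length[central] <- pr$t[1]
        }
      }
    }
    if (is.null(best_tree)) break
    tree <- optimize_branch_lengths(best_tree, aln, model, max_rounds = 3)
    cur <- attr(tree, "loglik")
    visited <- c(visited, cur)
  }
  attr(tree, "loglik") <- cur
  attr(tree, "visited_loglik") <- visited
  tree
}

optimize_shape <- function(tree, aln, model, bounds = c(0.02, 100)) {
  prep <- prepare_pruning(tree, aln, model)
  f <- function(la) {
    m2 <- rate_model(model$model, alpha = exp(la), k = model$k,
                     p_inv = model$p_inv)
    -run_pruning(prep, prep$phy$edge.length, m2)$loglik
  }
  opt <- optimize(f, log(bounds), tol = 1e-4)
  rate_model(model$model, alpha = exp(opt$minimum), k = model$k,
             p_inv = model$p_inv)
}

optimize_pinv <- function(tree, aln, model, upper = 0.9) {
  prep <- prepare_pruning(tree, aln, model)
  f <- function(p) {
    m2 <- rate_model(model$model, alpha = model$alpha, k = model$k, p_inv = p)
    -run_pruning(prep, prep$phy$edge.length, m2)$loglik
  }
  opt <- optimize(f, c(0, upper), tol = 1e-5)
  rate_model(model$model, alpha = model$alpha, k = model$k,
             p_inv = opt$minimum)
}

#' Fit a maximum-likelihood phylogeny
#'
#' The package's central fitting routine: pairwise ML distances, a
#' neighbor-joining starting tree, branch-length optimization, optional
#' estimation of the gamma shape (and invariant proportion), and NNI
#' hill-climbing, all under the LG model family.
#'
#' @param aln a `"domain_alignment"` (>= 4 rows for tree search).
#' @param model a [rate_model()]; default `LG+G` with alpha 1 and 4
#'   categories.
#' @param search `"nni"` (default) or `"none"` (keep the NJ topology).
#' @param optimize_model re-estimate alpha (and p_inv for `LG+I+G`) on the
#'   starting tree before the topology search?
#' @param start optional starting tree (`phylo`); NJ on ML distances when
#'   `NULL`.
#' @return an object of class `"hmg_ml"`: `tree` (optimized `phylo`),
#'   `model`, `loglik`, `sitelik`, `alignment`, `call`.
#' @examples
#' \donttest{
#' cfg <- simulation_config(seed = 1, n_per_class = c(ALPHA1_A = 2,
#'   ALPHA1_B = 2, MATA_HMG = 4, SOX = 4, HMGB = 4))
#' sim <- make_hmg_family_dataset(cfg)
#' fit <- ml_phylogeny(sim$core_alignment, search = "none")
#' fit
#' }
#' @export
ml_phylogeny <- function(aln, model = rate_model("LG+G", alpha = 1),
                         search = c("nni", "none"), optimize_model = FALSE,
                         start = NULL) {
  search <- match.arg(search)
  cl <- match.call()
  if (is.null(start)) {
    d <- ml_distances(aln, model)
    start <- neighbor_joining(d)
  }
  if (optimize_model) {
    t0 <- optimize_branch_lengths(start, aln, model, max_rounds = 3)
    if (model$model != "LG") model <- optimize_shape(t0, aln, model)
    if (model$model == "LG+I+G") model <- optimize_pinv(t0, aln, model)
    start <- t0
  }
  tree <- if (search == "nni") nni_search(start, aln, model)
          else optimize_branch_lengths(start, aln, model)
  sl <- tree_loglik(tree, aln, model)
  structure(list(tree = tree, model = model, loglik = sl$loglik,
                 sitelik = sl$sitelik, alignment = aln, call = cl),
            class = "hmg_ml")
}

#' @export
print.hmg_ml <- function(x, ...) {
  cat("Maximum-likelihood phylogeny (", x$model$model, ")\n", sep = "")
  cat("  ", length(x$tree$tip.label), " tips, log-likelihood ",
      format(x$loglik), "\n", sep = "")
  invisible(x)
}

#' @export
logLik.hmg_ml <- function(object, ...) {
  p <- length(object$tree$edge.length) +
    (!is.null(object$model$alpha)) + (object$model$p_inv > 0)
  structure(object$loglik, df = p, class = "logLik")
}

#' @export
summary.hmg_ml <- function(object, ...) {
  cat("Maximum-likelihood phylogeny\n")
  print(object$model)
  cat("  tips:", length(object$tree$tip.label),
      " sites:", length(object$sitelik), "\n")
  cat("  log-likelihood:", format(object$loglik), "\n")
  cat("  total tree length:", format(sum(object$tree$edge.length)), "\n")
  if (!is.null(attr(object$tree, "visited_loglik")))
    cat("  NNI moves accepted:",
        length(attr(object$tree, "visited_loglik")) - 1L, "\n")
  invisible(object)
}

#' @export
plot.hmg_ml <- function(x, ...) {
  ape::plot.phylo(x$tree, ...)
  invisible(x)
}

#' Rank substitution models by AIC
#'
#' Maximizes the log-likelihood of each candidate (branch lengths plus
#' gamma shape and/or invariant proportion, by coordinate ascent on a fixed
#' topology) and ranks by `AIC = 2p - 2 lnL`.
#'
#' @param aln alignment.
#' @param tree fixed topology (`phylo`); NJ on ML distances when `NULL`.
#' @param candidates subset of `c("LG", "LG+G", "LG+I+G")`.
#' @param k gamma categories.
#' @param cycles coordinate-ascent cycles (default 2).
#' @return data frame with columns `model`, `loglik`, `n_par`, `aic`,
#'   `alpha`, `p_inv`, `note`, sorted by AIC.
#' @export
select_model <- function(aln, tree = NULL,
                         candidates = c("LG", "LG+G", "LG+I+G"), k = 4,
                         cycles = 2) {
  if (is.null(tree)) {
    d <- ml_distances(aln, rate_model("LG"))
    tree <- neighbor_joining(d)
  }
  # warm-start each candidate from the next-simpler fit so the nested-model
  # property (more parameters never lower the maximized lnL) is preserved
  # even under a finite number of coordinate-ascent cycles
  warm <- list(tree = tree, alpha = 1)
  rows <- lapply(candidates, function(cand) {
    out <- tryCatch({
      m <- rate_model(cand, alpha = warm$alpha, k = k, p_inv = 0)
      tr <- warm$tree
      tr <- optimize_branch_lengths(tr, aln, m, max_rounds = 5)
      ll <- attr(tr, "loglik")
      for (cy in seq_len(cycles)) {
        if (cand != "LG") {
          m2 <- optimize_shape(tr, aln, m)
          ll2 <- tree_loglik(tr, aln, m2)$loglik
          if (ll2 > ll) { m <- m2; ll <- ll2 }
        }
        if (cand == "LG+I+G") {
          m2 <- optimize_pinv(tr, aln, m)
          ll2 <- tree_loglik(tr, aln, m2)$loglik
          if (ll2 > ll) { m <- m2; ll <- ll2 }
        }
        tr <- optimize_branch_lengths(tr, aln, m, max_rounds = 5)
        ll <- max(ll, attr(tr, "loglik"))
      }
      warm <<- list(tree = tr, alpha = if (is.null(m$alpha)) 1 else m$alpha)
      p <- length(tr$edge.length) + (cand != "LG") + (cand == "LG+I+G")
      data.frame(model = cand, loglik = ll, n_par = p, aic = 2 * p - 2 * ll,
                 alpha = if (is.null(m$alpha)) NA_real_ else m$alpha,
                 p_inv = m$p_inv, note = "", stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(model = cand, loglik = NA_real_, n_par = NA_integer_,
                 aic = NA_real_, alpha = NA_real_, p_inv = NA_real_,
                 note = conditionMessage(e), stringsAsFactors = FALSE))
    out
  })
  res <- do.call(rbind, rows)
  res[order(res$aic), , drop = FALSE]
}
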