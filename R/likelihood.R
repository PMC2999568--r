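## Internal plumbing shared by the likelihood, support and ancestral stages.

# Encode an alignment as an ntip x nsites integer matrix of 0-based state
# codes in the given tip order; gaps and X become -1 (missing).
encode_states <- function(aln, tip_order) {
  idx <- match(tip_order, aln$id)
  if (anyNA(idx)) stop("tree tips not found in alignment: ",
                       paste(head(tip_order[is.na(idx)], 3), collapse = ", "),
                       call. = FALSE)
  m <- do.call(rbind, strsplit(aln$seq[idx], "", fixed = TRUE))
  s <- matrix(match(m, AA), nrow = nrow(m))
  s[is.na(s)] <- 0L
  s - 1L
}

# Run-time state passed to cpp_pruning for a (tree, alignment, model) triple.
prepare_pruning <- function(tree, aln, model) {
  phy <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(phy$tip.label)
  if (is.null(phy$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  list(phy = phy, ntip = ntip,
       nnode = ntip + phy$Nnode,
       root = ntip + 1L,
       states = encode_states(aln, phy$tip.label))
}

run_pruning <- function(prep, blen, model, return_root = FALSE) {
  cpp_pruning(prep$phy$edge, blen, prep$ntip, prep$nnode, prep$root,
              prep$states, model$U, model$Uinv, model$eval, model$pi,
              model$rates, model$weights, model$p_inv, return_root)
}

#' Phylogenetic log-likelihood by Felsenstein pruning
#'
#' Site log-likelihoods of an alignment on a tree under a [rate_model()],
#' mixing over discrete-gamma rate categories (and an invariant-site spike
#' when the model carries one). Gaps and `X` are treated as missing data.
#'
#' @param tree a `phylo` tree with branch lengths whose tips match the
#'   alignment ids (rooted or unrooted; the model is reversible, so the
#'   likelihood does not depend on the root placement).
#' @param aln a `"domain_alignment"`.
#' @param model a [rate_model()].
#' @return an object of class `"site_lik"`: `sitelik` (per-site log
#'   likelihood), `loglik` (their sum), `n_sites`.
#' @export
tree_loglik <- function(tree, aln, model) {
  prep <- prepare_pruning(tree, aln, model)
  r <- run_pruning(prep, prep$phy$edge.length, model)
  structure(list(sitelik = r$sitelik, loglik = r$loglik,
                 n_sites = length(r$sitelik)),
            class = "site_lik")
}

#' @export
print.site_lik <- function(x, ...) {
  cat("log-likelihood:", format(x$loglik), "over", x$n_sites, "sites\n")
  invisible(x)
}

#' Pairwise maximum-likelihood distances
#'
#' For every sequence pair, the branch length maximizing the two-sequence
#' likelihood under the model (one-dimensional optimization of the pair
#' count table likelihood). Pairs with no overlapping residues, or whose
#' estimate hits the cap, are set to `cap` and flagged.
#'
#' @param aln alignment (>= 3 rows).
#' @param model a [rate_model()].
#' @param cap maximum reported distance (default 10).
#' @return symmetric distance matrix with a `"saturated"` attribute naming
#'   flagged pairs.
#' @export
ml_distances <- function(aln, model, cap = 10) {
  nseq <- length(aln$id)
  if (nseq < 3L) stop("need at least 3 sequences", call. = FALSE)
  st <- encode_states(aln, aln$id)
  ncat <- length(model$rates)
  pmix <- function(t) {
    P <- matrix(0, 20, 20)
    for (c in seq_len(ncat))
      P <- P + model$weights[c] *
        cpp_pmat(model$U, model$Uinv, model$eval, t * model$rates[c])
    if (model$p_inv > 0) P <- (1 - model$p_inv) * P + model$p_inv * diag(20)
    P
  }
  d <- matrix(0, nseq, nseq, dimnames = list(aln$id, aln$id))
  saturated <- character(0)
  for (i in seq_len(nseq - 1)) for (j in (i + 1):nseq) {
    a <- st[i, ]; b <- st[j, ]
    ok <- a >= 0L & b >= 0L
    if (!any(ok)) {
      d[i, j] <- d[j, i] <- cap
      saturated <- c(saturated, paste(aln$id[i], aln$id[j], sep = ":"))
      next
    }
    tab <- table(factor(a[ok], levels = 0:19), factor(b[ok], levels = 0:19))
    nz <- which(tab > 0, arr.ind = TRUE)
    cnt <- tab[nz]
    f <- function(t) {
      J <- model$pi * pmix(t)   # joint probability of a residue pair
      -sum(cnt * log(J[nz]))
    }
    opt <- optimize(f, c(1e-8, cap), tol = 1e-6)
    est <- opt$minimum
    if (est > cap * 0.99) {
      est <- cap
      saturated <- c(saturated, paste(aln$id[i], aln$id[j], sep = ":"))
    }
    d[i, j] <- d[j, i] <- est
  }
  attr(d, "saturated") <- saturated
  d
}

#' Neighbor-joining starting tree
#'
#' Standard NJ agglomeration (via ape) with negative branch lengths floored
#' at zero; additive distances are recovered exactly.
#'
#' @param d symmetric distance matrix (>= 3 taxa).
#' @return unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric",
                                      call. = FALSE)
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Optimize branch lengths by iterated one-dimensional search
#'
#' Cycles over branches, maximizing the log-likelihood in each branch length
#' by Brent search within `[min_bl, max_bl]`, until a full round improves
#' the log-likelihood by less than `tol` or `max_rounds` is reached. The
#' log-likelihood never decreases across rounds.
#'
#' @param tree `phylo` with branch lengths.
#' @param aln alignment.
#' @param model a [rate_model()].
#' @param tol convergence tolerance on the log-likelihood (default 1e-4).
#' @param max_rounds maximum rounds (default 10).
#' @param min_bl,max_bl branch-length bounds (defaults 1e-8 and 50).
#' @return the tree with optimized `edge.length`; attributes `loglik` and
#'   `converged`.
#' @export
optimize_branch_lengths <- function(tree, aln, model, tol = 1e-4,
                                    max_rounds = 25, min_bl = 1e-8,
                                    max_bl = 50) {
  prep <- prepare_pruning(tree, aln, model)
  blen <- pmin(pmax(prep$phy$edge.length, min_bl), max_bl)
  cur <- run_pruning(prep, blen, model)$loglik
  converged <- FALSE
  for (round in seq_len(max_rounds)) {
    pr <- propose_edges(prep, blen, model, seq_along(blen), min_bl, max_bl)
    gain1 <- max(pr$loglik) - cur  # best exact single-edge update
    if (gain1 < tol) { converged <- TRUE; break }
    cand <- pr$t
    ll_all <- run_pruning(prep, cand, model)$loglik
    if (ll_all >= max(pr$loglik)) {      # joint update helped even more
      blen <- cand; cur <- ll_all
    } else {                              # fall back to the best single edge
      half <- (blen + cand) / 2
      ll_half <- run_pruning(prep, half, model)$loglik
      if (ll_half >= max(pr$loglik)) {
        blen <- half; cur <- ll_half
      } else {
        e <- which.max(pr$loglik)
        blen[e] <- pr$t[e]
        cur <- pr$loglik[e]
      }
    }
  }
  out <- prep$phy
  out$edge.length <- blen
  attr(out, "loglik") <- cur
  attr(out, "converged") <- converged
  out
}

# Exact single-edge branch-length proposals (others held fixed) from the
# two-pass flank machinery; `rows` are 1-based edge rows.
propose_edges <- function(prep, blen, model, rows, min_bl = 1e-8,
                          max_bl = 50, iters = 35) {
  cpp_edge_proposals(prep$phy$edge, blen, prep$ntip, prep$nnode, prep$root,
                     prep$states, model$U, model$Uinv, model$eval, model$pi,
                     model$rates, model$weights, model$p_inv,
                     as.integer(rows) - 1L, min_bl, max_bl, iters)
}
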