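test_that("pruning equals brute-force enumeration on toy instances", {
  m1 <- toy_model(ns = 3, rates = 1)
  m2 <- toy_model(ns = 3, rates = c(0.4, 1.6), weights = c(0.5, 0.5))
  set.seed(17)
  for (ntax in 3:5) {
    for (topo in 1:3) {
      phy <- ape::rtree(ntax, rooted = FALSE)
      phy$tip.label <- paste0("t", seq_len(ntax))
      states <- matrix(sample(1:3, ntax * 4, replace = TRUE), ntax)
      states[1, 2] <- NA  # a missing entry
      for (m in list(m1, m2)) {
        got <- toy_pruning(phy, states, m)$loglik
        want <- brute_loglik(phy, states, m)
        expect_equal(got, want, tolerance = 1e-10)
      }
    }
  }
})

test_that("two-leaf closed form and all-missing columns", {
  m <- toy_model(ns = 3)
  phy <- ape::read.tree(text = "(a:0.4,b:0.6);")
  states <- matrix(c(1L, 3L), 2, 1)
  got <- toy_pruning(phy, states, m)$loglik
  # closed form: reversibility pools the two branches
  P <- toy_pmat(m, 1.0)
  expect_equal(got, log(m$pi[1] * P[1, 3]), tolerance = 1e-12)

  miss <- matrix(NA_integer_, 2, 1)
  expect_equal(toy_pruning(phy, miss, m)$loglik, 0)

  lg <- rate_model("LG+G", alpha = 0.8)
  aln <- new_alignment(c("a", "b", "c"), c("MK-", "MR-", "-W-"))
  sl <- tree_loglik(ape::read.tree(text = "(a:0.1,b:0.1,c:0.2);"), aln, lg)
  expect_equal(sl$sitelik[3], 0)              # all-missing column
  expect_equal(sum(sl$sitelik), sl$loglik)    # totals consistent
})

test_that("likelihood agrees with an independent implementation on LG+G", {
  ds <- small_dataset()
  aln <- remove_gappy_columns(ds$core_alignment)
  m <- rate_model("LG+G", alpha = 0.8)
  tr <- ape::unroot(ds$tree)
  mine <- tree_loglik(tr, aln, m)$loglik
  pd <- phangorn::phyDat(setNames(strsplit(gsub("-", "?", aln$seq), ""),
                                  aln$id), type = "AA")
  ref <- phangorn::pml(tr, pd, model = "LG", k = 4, shape = 0.8)$logLik
  expect_equal(mine, ref, tolerance = 1e-6)
})

test_that("log-likelihood is invariant to re-rooting", {
  ds <- small_dataset()
  aln <- remove_gappy_columns(ds$core_alignment)
  m <- rate_model("LG+G", alpha = 0.8)
  tr <- ape::unroot(ds$tree)
  base <- tree_loglik(tr, aln, m)$loglik
  ntip <- length(tr$tip.label)
  for (node in (ntip + 2):(ntip + 6)) {
    re <- ape::root(tr, node = node, resolve.root = FALSE)
    expect_equal(tree_loglik(re, aln, m)$loglik, base, tolerance = 1e-8)
  }
})

test_that("ML distances: zeros, symmetry, and consistency at known divergence", {
  m <- rate_model("LG")
  dup <- new_alignment(c("a", "b", "c"),
                       c(strrep("MKWR", 10), strrep("MKWR", 10),
                         strrep("ADEN", 10)))
  d <- ml_distances(dup, m)
  expect_lt(d["a", "b"], 1e-4)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))

  tree <- ape::read.tree(text = "(a:0.15,b:0.15,c:1.0);")
  ev <- evolve_on_tree(tree, sample_root(5000, seed = 31), m, seed = 32)
  aln <- new_alignment(names(ev$tips), ev$tips)
  d2 <- ml_distances(aln, m)
  expect_lt(abs(d2["a", "b"] - 0.3), 0.05)

  # no overlapping residues: capped and flagged
  g <- new_alignment(c("a", "b", "c"), c("MK--", "--WR", "MKWR"))
  d3 <- ml_distances(g, m, cap = 10)
  expect_equal(d3["a", "b"], 10)
  expect_true("a:b" %in% attr(d3, "saturated"))
})

test_that("neighbor joining recovers additive distances exactly", {
  true <- ape::read.tree(text =
    "((a:0.2,b:0.4):0.15,(c:0.3,d:0.1):0.25);")
  D <- ape::cophenetic.phylo(true)
  nj <- neighbor_joining(D[letters[1:4], letters[1:4]])
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(true), nj)), 0)
  expect_equal(ape::cophenetic.phylo(nj)[letters[1:4], letters[1:4]],
               D[letters[1:4], letters[1:4]], tolerance = 1e-10)

  # 3 taxa: closed-form star branch lengths
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  star <- neighbor_joining(D3)
  bl <- setNames(star$edge.length[match(1:3, star$edge[, 2])],
                 star$tip.label)
  expect_equal(unname(bl[c("x", "y", "z")]), c(1, 2, 3))

  # permutation invariance
  perm <- c("d", "b", "a", "c")
  nj2 <- neighbor_joining(D[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(nj, nj2)), 0)
  bad <- matrix(c(0, 1, 2, 1, 0, 3, 1, 3, 0), 3)
  expect_error(neighbor_joining(bad), "symmetric")
})

test_that("branch-length optimization is monotone, idempotent, and recovers truth", {
  tree <- ape::read.tree(text = paste0(
    "((a:0.25,b:0.35):0.2,(c:0.15,d:0.4):0.1,(e:0.3,f:0.2):0.25);"))
  m <- rate_model("LG+G", alpha = 1)
  ev <- evolve_on_tree(tree, sample_root(2000, seed = 41), m, seed = 42)
  aln <- new_alignment(names(ev$tips), ev$tips)

  start <- tree
  start$edge.length <- rep(0.1, length(tree$edge.length))
  opt <- optimize_branch_lengths(start, aln, m)
  expect_true(attr(opt, "converged"))

  # recovered branch lengths within 20% relative error on >= 80% of
  # branches; match branches between trees by the tip set below each edge
  split_of <- function(phy) {
    phy <- ape::reorder.phylo(phy, "postorder")
    ntip <- length(phy$tip.label)
    desc <- matrix(FALSE, ntip + phy$Nnode, ntip)
    desc[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
    for (e in seq_len(nrow(phy$edge)))
      desc[phy$edge[e, 1], ] <- desc[phy$edge[e, 1], ] | desc[phy$edge[e, 2], ]
    keys <- apply(desc[phy$edge[, 2], , drop = FALSE], 1, function(z) {
      s <- sort(phy$tip.label[z])
      c1 <- paste(s, collapse = ",")
      s2 <- sort(setdiff(phy$tip.label, s))
      min(c1, paste(s2, collapse = ","))
    })
    setNames(phy$edge.length, keys)
  }
  truth <- split_of(tree); est <- split_of(opt)
  relerr <- abs(est[names(truth)] - truth) / truth
  expect_gte(mean(relerr <= 0.2), 0.8)

  # idempotence: optimizing an optimum moves lnL by < tolerance
  again <- optimize_branch_lengths(opt, aln, m)
  expect_lt(abs(attr(again, "loglik") - attr(opt, "loglik")), 1e-3)
})

test_that("NNI search honours its hill-climbing contract", {
  # strongly informative data: 400 sites on a well-separated 8-taxon tree
  true <- ape::read.tree(text = paste0(
    "((a:0.1,b:0.1):0.4,((c:0.1,d:0.1):0.4,(e:0.1,f:0.1):0.4):0.2,",
    "(g:0.1,h:0.1):0.4);"))
  m <- rate_model("LG+G", alpha = 0.8)
  ev <- evolve_on_tree(true, sample_root(400, seed = 141), m, seed = 142)
  aln <- new_alignment(names(ev$tips), ev$tips)

  # starting at the true topology: it is a local optimum and stays put
  out <- nni_search(true, aln, m)
  expect_equal(as.numeric(ape::dist.topo(out, ape::unroot(true))), 0)

  visited <- attr(out, "visited_loglik")
  expect_true(all(diff(visited) >= 0))
  expect_equal(attr(out, "loglik"), max(visited))

  # an NJ start converges to the same topology here
  nj <- neighbor_joining(ml_distances(aln, m))
  out2 <- nni_search(nj, aln, m)
  expect_equal(as.numeric(ape::dist.topo(out2, ape::unroot(true))), 0)
  expect_true(all(diff(attr(out2, "visited_loglik")) >= 0))
  expect_equal(attr(out2, "loglik"), attr(out, "loglik"), tolerance = 1e-4)
})

test_that("monophyly queries resolve bipartitions on unrooted trees", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_false(is_monophyletic(tr, c("A", "C")))
  expect_true(is_monophyletic(tr, "A"))
  expect_true(is_monophyletic(tr, c("A", "B", "C", "D")))
  expect_true(is_monophyletic(tr, c("C", "D")))
  expect_error(is_monophyletic(tr, c("A", "Z")), "present")
})

test_that("the fitted model object reports coherent summaries", {
  ds <- small_dataset()
  aln <- remove_gappy_columns(ds$core_alignment)
  fit <- ml_phylogeny(aln, model = rate_model("LG+G", alpha = 0.8),
                      search = "none")
  expect_s3_class(fit, "hmg_ml")
  expect_equal(unclass(logLik(fit))[1], fit$loglik)
  expect_equal(sum(tree_loglik(fit$tree, aln, fit$model)$sitelik),
               fit$loglik, tolerance = 1e-9)
  expect_output(print(fit), "log-likelihood")
})
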