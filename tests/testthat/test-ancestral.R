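test_that("marginal posteriors equal brute-force Bayes on a toy instance", {
  m <- toy_model(ns = 3, rates = c(0.5, 1.5), weights = c(0.5, 0.5))
  phy <- ape::read.tree(text = "(a:0.3,b:0.5,c:0.2);")
  states <- matrix(c(1L, 2L, 1L), 3, 1)
  r <- toy_pruning(phy, states, m, return_root = TRUE)
  post_mine <- numeric(3)
  for (c in 1:2)
    post_mine <- post_mine + m$weights[c] * m$pi * r$root_partials[, 1, c]
  post_mine <- post_mine / sum(post_mine)

  # brute force: P(root = x | tips) over both categories
  post_ref <- numeric(3)
  for (c in 1:2) {
    Pa <- toy_pmat(m, 0.3 * m$rates[c]); Pb <- toy_pmat(m, 0.5 * m$rates[c])
    Pc <- toy_pmat(m, 0.2 * m$rates[c])
    for (x in 1:3)
      post_ref[x] <- post_ref[x] +
        m$weights[c] * m$pi[x] * Pa[x, 1] * Pb[x, 2] * Pc[x, 1]
  }
  post_ref <- post_ref / sum(post_ref)
  expect_equal(post_mine, post_ref, tolerance = 1e-10)
})

test_that("posteriors are proper and certain when data are certain", {
  ds <- small_dataset()
  aln <- remove_gappy_columns(ds$core_alignment)
  m <- rate_model("LG+G", alpha = 0.8)
  anc <- marginal_posteriors(ds$tree, aln, m, node = "root")
  expect_true(all(abs(rowSums(anc$posterior) - 1) < 1e-9))
  expect_equal(nchar(anc$map), ncol_alignment(aln))

  # zero branch lengths and identical leaves: mass 1 on the shared residue
  tiny <- ape::read.tree(text = "(a:0,b:0,c:0);")
  aln2 <- new_alignment(c("a", "b", "c"), rep("MKW", 3))
  anc2 <- marginal_posteriors(tiny, aln2, m, node = "root")
  expect_equal(anc2$map, "MKW")
  expect_true(all(anc2$map_prob > 1 - 1e-9))
})

test_that("recovery degrades with tree height; reconstruction is order-invariant", {
  m <- rate_model("LG+G", alpha = 1)
  acc_at_height <- function(h) {
    mean(vapply(1:3, function(r) {
      tr <- with(list(), {set.seed(80 + r); ape::rcoal(16)})
      tr$edge.length <- tr$edge.length /
        max(ape::node.depth.edgelength(tr)) * h
      root <- sample_root(60, seed = 90 + r)
      ev <- evolve_on_tree(tr, root, m, seed = 95 + r)
      aln <- new_alignment(names(ev$tips), ev$tips)
      anc <- marginal_posteriors(tr, aln, m, node = "root")
      mean(strsplit(anc$map, "")[[1]] == strsplit(root, "")[[1]])
    }, 0))
  }
  shallow <- acc_at_height(0.1)
  deep <- acc_at_height(1.5)
  expect_gt(shallow, deep)
  expect_gt(shallow, 0.9)

  # order invariance
  set.seed(71)
  tr <- ape::rcoal(8)
  ev <- evolve_on_tree(tr, sample_root(30, seed = 72), m, seed = 73)
  aln <- new_alignment(names(ev$tips), ev$tips)
  perm <- sample(length(aln$id))
  aln2 <- new_alignment(aln$id[perm], aln$seq[perm])
  a1 <- marginal_posteriors(tr, aln, m, node = "root")
  a2 <- marginal_posteriors(tr, aln2, m, node = "root")
  expect_identical(a1$map, a2$map)
  expect_equal(a1$posterior, a2$posterior, tolerance = 1e-12)
})

test_that("family ancestors denoise and compare as expected", {
  m <- rate_model("LG+G", alpha = 1)
  # two families radiating from the same root sequence
  root <- sample_root(40, seed = 101)
  mkfam <- function(seed, prefix) {
    tr <- with(list(), {set.seed(seed); ape::rcoal(8)})
    tr$edge.length <- tr$edge.length /
      max(ape::node.depth.edgelength(tr)) * 0.6
    ev <- evolve_on_tree(tr, root, m, seed = seed + 1)
    new_alignment(paste0(prefix, names(ev$tips)), unname(ev$tips))
  }
  f1 <- mkfam(110, "x"); f2 <- mkfam(120, "y")
  res <- reconstruct_family_ancestors(f1, f2, model = m)
  expect_s3_class(res$comparison, "comparison_result")

  # ancestor-vs-ancestor identity exceeds mean cross-family leaf identity
  anc_ident <- res$comparison$identity_pct
  leaf_ident <- mean(vapply(1:8, function(i)
    mean(strsplit(f1$seq[i], "")[[1]] == strsplit(f2$seq[i], "")[[1]]) * 100,
    0))
  expect_gt(anc_ident, leaf_ident)

  # identical families give identical ancestors
  res2 <- reconstruct_family_ancestors(f1, f1, model = m)
  expect_equal(res2$comparison$identity_pct, 100)
  expect_identical(res2$ancestor1$map, res2$ancestor2$map)
})
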