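test_that("rate matrix satisfies reversibility and normalization", {
  m <- rate_model("LG")
  expect_lt(max(abs(rowSums(m$Q))), 1e-12)
  expect_lt(max(abs(m$pi * m$Q - t(m$pi * m$Q))), 1e-12)   # detailed balance
  expect_equal(-sum(m$pi * diag(m$Q)), 1, tolerance = 1e-12)
  expect_equal(sum(m$pi), 1, tolerance = 1e-12)

  expect_error(rate_model("LG", exchangeabilities = matrix(runif(400), 20)),
               "symmetric")
})

test_that("uniform exchangeabilities give the 20-state symmetric model", {
  S <- matrix(1, 20, 20); diag(S) <- 0
  m <- rate_model("LG", exchangeabilities = S, frequencies = rep(1 / 20, 20))
  off <- m$Q[row(m$Q) != col(m$Q)]
  expect_equal(unique(round(off, 12)), round(1 / 19, 12))
  expect_equal(unique(round(diag(m$Q), 12)), -1)
})

test_that("transition probabilities: identity at t = 0, stochastic, Chapman-Kolmogorov", {
  m <- rate_model("LG+G", alpha = 0.7)
  expect_equal(unname(transition_probabilities(m, 0)), diag(20),
               tolerance = 1e-12)
  for (t in c(0.01, 0.1, 1, 10))
    expect_lt(max(abs(rowSums(transition_probabilities(m, t)) - 1)), 1e-10)
  P1 <- transition_probabilities(m, 0.3) %*% transition_probabilities(m, 0.7)
  expect_equal(P1, unname(transition_probabilities(m, 1.0)) |>
                 `dimnames<-`(dimnames(P1)), tolerance = 1e-8)
  expect_error(transition_probabilities(m, -1), "nonnegative")

  # spectral decomposition agrees with a series-based matrix exponential
  ex <- as.matrix(Matrix::expm(m$Q * 0.37))
  expect_lt(max(abs(transition_probabilities(m, 0.37) - ex)), 1e-10)
})

test_that("discrete gamma categories match quadrature and limits", {
  expect_identical(discretize_gamma(0.5, 1), 1)
  expect_true(all(abs(discretize_gamma(1e7, 4) - 1) < 1e-3))
  for (alpha in c(0.2, 0.5, 1, 2)) {
    k <- 4
    r <- discretize_gamma(alpha, k)
    expect_equal(mean(r), 1, tolerance = 1e-9)
    bounds <- qgamma(seq(0, 1, length.out = k + 1), alpha, alpha)
    quad <- vapply(seq_len(k), function(i)
      k * integrate(function(x) x * dgamma(x, alpha, alpha),
                    bounds[i], bounds[i + 1], rel.tol = 1e-12)$value, 0)
    expect_equal(r, quad, tolerance = 1e-8)
  }
  expect_error(discretize_gamma(-1, 4), "alpha")
  expect_error(discretize_gamma(1, 0), "k")
})

test_that("model nesting is exact: k = 1 gamma equals plain LG, p_inv = 0 equals LG+G", {
  ds <- small_dataset()
  aln <- remove_gappy_columns(ds$core_alignment)
  tr <- ape::unroot(ds$tree)
  lg <- tree_loglik(tr, aln, rate_model("LG"))$loglik
  g1 <- tree_loglik(tr, aln, rate_model("LG+G", alpha = 1.3, k = 1))$loglik
  expect_equal(g1, lg)
  gg <- tree_loglik(tr, aln, rate_model("LG+G", alpha = 0.8))$loglik
  ig <- tree_loglik(tr, aln, rate_model("LG+I+G", alpha = 0.8,
                                        p_inv = 0))$loglik
  expect_equal(ig, gg)
})

test_that("AIC model selection identifies rate heterogeneity", {
  n_rep <- 10
  tree <- ape::read.tree(text = paste0(
    "((a:0.3,b:0.3):0.15,(c:0.3,d:0.3):0.15,(e:0.3,(f:0.2,g:0.2):0.2):0.1);"))
  win_plain <- 0L; win_gamma <- 0L
  for (r in seq_len(n_rep)) {
    root <- sample_root(150, seed = 100 + r)
    ev_p <- evolve_on_tree(tree, root, rate_model("LG"), seed = 200 + r)
    aln_p <- new_alignment(names(ev_p$tips), ev_p$tips)
    res_p <- select_model(aln_p, tree = tree, cycles = 1)
    if (res_p$model[1] == "LG") win_plain <- win_plain + 1L

    ev_g <- evolve_on_tree(tree, root,
                           rate_model("LG+G", alpha = 0.5), seed = 300 + r)
    aln_g <- new_alignment(names(ev_g$tips), ev_g$tips)
    res_g <- select_model(aln_g, tree = tree, cycles = 1)
    if (res_g$model[1] %in% c("LG+G", "LG+I+G")) win_gamma <- win_gamma + 1L

    # nesting: adding parameters never decreases the maximized lnL
    ll <- res_g$loglik[match(c("LG", "LG+G", "LG+I+G"), res_g$model)]
    expect_lte(ll[1], ll[2] + 1e-3)
    expect_lte(ll[2], ll[3] + 1e-3)
  }
  expect_gte(win_plain, 8L)
  expect_gte(win_gamma, 8L)
})
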