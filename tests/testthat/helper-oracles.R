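## Independent oracles and tiny fixture builders shared across tests.

# A small reversible toy model on an arbitrary number of states, with the
# same interface pieces (U, Uinv, eval, pi, rates, weights) the pruning
# engine consumes. Exchangeabilities are fixed arbitrary positives.
toy_model <- function(ns = 3, rates = 1, weights = rep(1 / length(rates),
                                                       length(rates)),
                      pinv = 0, seed = 42) {
  set.seed(seed)
  S <- matrix(0, ns, ns)
  S[lower.tri(S)] <- runif(ns * (ns - 1) / 2, 0.2, 2)
  S <- S + t(S)
  pi <- runif(ns, 0.5, 1.5); pi <- pi / sum(pi)
  Q <- S * rep(pi, each = ns)
  diag(Q) <- -rowSums(Q)
  Q <- Q / (-sum(pi * diag(Q)))
  sp <- sqrt(pi)
  B <- Q * (sp %o% (1 / sp)); B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  list(Q = Q, pi = pi, U = eig$vectors / sp,
       Uinv = t(eig$vectors) * rep(sp, each = ns), eval = eig$values,
       rates = rates, weights = weights, p_inv = pinv, ns = ns)
}

toy_pmat <- function(m, t) m$U %*% diag(exp(m$eval * t), m$ns) %*% m$Uinv

# Brute-force tree likelihood: explicit summation over all internal-node
# state assignments. states: ntip x nsites, 1-based, NA = missing.
brute_loglik <- function(phy, states, m) {
  phy <- ape::reorder.phylo(phy, "postorder")
  ntip <- nrow(states); nnode <- ntip + phy$Nnode
  root <- ntip + 1L
  internal <- (ntip + 1L):nnode
  grid <- as.matrix(expand.grid(rep(list(seq_len(m$ns)), length(internal))))
  P <- lapply(seq_len(nrow(phy$edge)), function(e) list())
  total <- 0
  for (s in seq_len(ncol(states))) {
    Ls <- 0
    for (c in seq_along(m$rates)) {
      Pe <- lapply(phy$edge.length, function(t) toy_pmat(m, t * m$rates[c]))
      Lc <- 0
      for (g in seq_len(nrow(grid))) {
        asg <- integer(nnode)
        asg[seq_len(ntip)] <- states[, s]
        asg[internal] <- grid[g, ]
        p <- m$pi[asg[root]]
        for (e in seq_len(nrow(phy$edge))) {
          a <- asg[phy$edge[e, 1]]; b <- asg[phy$edge[e, 2]]
          if (is.na(b)) next  # missing tip: sum over states = 1
          p <- p * Pe[[e]][a, b]
        }
        Lc <- Lc + p
      }
      Ls <- Ls + m$weights[c] * Lc
    }
    # missing tips leave duplicate internal sums; handled because NA tips
    # contribute factor 1 regardless of internal states
    total <- total + log(Ls)
  }
  total
}

# Run the package's pruning engine directly on a toy model.
toy_pruning <- function(phy, states, m, return_root = FALSE) {
  phy <- ape::reorder.phylo(phy, "postorder")
  st <- states; st[is.na(st)] <- 0L
  st <- st - 1L; st[is.na(states)] <- -1L
  hmgtrace:::cpp_pruning(phy$edge, phy$edge.length, nrow(states),
                         nrow(states) + phy$Nnode, nrow(states) + 1L,
                         st, m$U, m$Uinv, m$eval, m$pi, m$rates, m$weights,
                         m$p_inv, return_root)
}

# Exhaustive affine-gap pairwise alignment score by recursive enumeration
# of alignment paths (independent of the package's DP). Gap of length L
# costs go + L * ge.
brute_align_score <- function(a, b, S, go, ge) {
  n <- nchar(a); m <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m)
      best <- max(best, S[av[i], bv[j]] + rec(i + 1, j + 1, 0L))
    if (i <= n)
      best <- max(best, -(if (last == 1L) ge else go + ge) +
                    rec(i + 1, j, 1L))
    if (j <= m)
      best <- max(best, -(if (last == 2L) ge else go + ge) +
                    rec(i, j + 1, 2L))
    best
  }
  rec(1L, 1L, 0L)
}

# Tiny default dataset for pipeline-level tests.
small_dataset <- function(seed = 11,
                          n = c(ALPHA1_A = 3, ALPHA1_B = 3, MATA_HMG = 6,
                                SOX = 6, HMGB = 6)) {
  make_hmg_family_dataset(simulation_config(seed = seed, n_per_class = n))
}
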