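test_that("generation is deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 31, n_per_class = c(
    ALPHA1_A = 2, ALPHA1_B = 2, MATA_HMG = 4, SOX = 4, HMGB = 4))
  d1 <- make_hmg_family_dataset(cfg)
  d2 <- make_hmg_family_dataset(cfg)
  expect_identical(d1$proteins$seq, d2$proteins$seq)
  expect_identical(d1$core_alignment$seq, d2$core_alignment$seq)
  expect_identical(ape::write.tree(d1$tree), ape::write.tree(d2$tree))
  expect_identical(d1$motif, d2$motif)

  d3 <- make_hmg_family_dataset(simulation_config(seed = 32, n_per_class =
    cfg$n_per_class))
  expect_false(identical(d1$proteins$seq, d3$proteins$seq))

  expect_error(simulation_config(), "seed")
})

test_that("root sampling matches its frequencies", {
  expect_identical(sample_root(25, seed = 4), sample_root(25, seed = 4))
  expect_equal(sample_root(0), "")
  s <- sample_root(1e5, freqs = rep(1 / 20, 20), seed = 5)
  counts <- table(factor(strsplit(s, "")[[1]], levels = hmgtrace:::AA))
  p <- 1 / 20
  sd3 <- 3 * sqrt(1e5 * p * (1 - p))
  expect_true(all(abs(counts - 1e5 * p) < sd3 + 1e-9))
})

test_that("evolution along branches follows the model", {
  m <- rate_model("LG")
  frozen <- ape::read.tree(text = "(a:0,b:0);")
  root <- sample_root(100, seed = 8)
  ev <- evolve_on_tree(frozen, root, m, seed = 9)
  expect_equal(unname(ev$tips[["a"]]), root)
  expect_equal(unname(ev$tips[["b"]]), root)
  # ancestors at branch length 0 equal their children
  expect_equal(unname(ev$internal[[1]]), root)

  # substitution fraction on one branch matches 1 - sum(pi * P_ii)
  t <- 0.4
  ev2 <- evolve_on_tree(ape::read.tree(text = sprintf("(a:%g,b:0);", t)),
                        sample_root(1e4, seed = 10), m, seed = 11)
  obs <- mean(strsplit(ev2$tips[["a"]], "")[[1]] !=
                strsplit(ev2$tips[["b"]], "")[[1]])
  p_sub <- 1 - sum(m$pi * diag(transition_probabilities(m, t)))
  expect_lt(abs(obs - p_sub), 3 * sqrt(p_sub * (1 - p_sub) / 1e4))

  expect_identical(evolve_on_tree(frozen, root, m, seed = 12)$tips,
                   evolve_on_tree(frozen, root, m, seed = 12)$tips)
})

test_that("class truncations shorten the designated cores", {
  seqs <- domain_sequences(c("a1", "b1", "m1"),
                           rep(strrep("K", 40), 3),
                           class = c("ALPHA1_A", "ALPHA1_B", "MATA_HMG"))
  out <- apply_class_truncation(seqs)
  expect_equal(nchar(out$seq), c(38L, 36L, 40L))
  expect_identical(apply_class_truncation(seqs, spec = integer(0)), seqs)
})

test_that("full proteins carry recoverable motifs only where planted", {
  cfg <- simulation_config(seed = 37, n_per_class = c(
    ALPHA1_A = 3, ALPHA1_B = 3, MATA_HMG = 5, SOX = 5, HMGB = 5))
  ds <- make_hmg_family_dataset(cfg)

  a1_ids <- ds$proteins$id[ds$proteins$class %in% c("ALPHA1_A", "ALPHA1_B")]
  expect_setequal(ds$motif$id, a1_ids)
  # every planted instance sits inside the 60-residue downstream window
  dend <- ds$domain_end[ds$motif$id]
  expect_true(all(ds$motif$start > dend))
  expect_true(all(ds$motif$start + nchar(ds$motif$instance) - 1 <=
                    dend + cfg$motif_window))
  # recall 1.0 by scanning
  for (i in seq_len(nrow(ds$motif))) {
    prot <- ds$proteins$seq[ds$proteins$id == ds$motif$id[i]]
    expect_true(ds$motif$start[i] %in%
                  scan_pattern(prot, cfg$motif_pattern)$start)
  }

  shortcfg <- simulation_config(seed = 38, c_flank = 5)
  cores <- domain_sequences("z", strrep("K", 40), class = "ALPHA1_A")
  expect_error(build_full_proteins(cores, shortcfg), "motif|flank")
})

test_that("the generated truth encodes the nested-clade structure", {
  ds <- small_dataset(seed = 39)
  tr <- ds$tree
  cls <- setNames(ds$core_sequences$class, ds$core_sequences$id)
  a1 <- names(cls)[cls %in% c("ALPHA1_A", "ALPHA1_B")]
  mata <- names(cls)[cls == "MATA_HMG"]
  expect_true(is_monophyletic(tr, a1))
  expect_true(is_monophyletic(tr, c(a1, mata)))
  expect_false(is_monophyletic(tr, mata))   # paraphyletic by construction
  expect_equal(unname(table(cls)[c("ALPHA1_A", "ALPHA1_B", "MATA_HMG",
                                   "SOX", "HMGB")]),
               unname(ds$config$n_per_class[c("ALPHA1_A", "ALPHA1_B",
                                              "MATA_HMG", "SOX", "HMGB")]),
               ignore_attr = TRUE)

  # truncated classes are shorter exactly as configured
  lens <- nchar(ds$core_sequences$seq)
  has_insert <- grepl("-", ds$core_alignment$seq[
    match(ds$core_sequences$id, ds$core_alignment$id)]) == FALSE
  a1a <- ds$core_sequences$class == "ALPHA1_A"
  a1b <- ds$core_sequences$class == "ALPHA1_B"
  expect_true(all(lens[a1a] == ds$config$core_length - 2))
  expect_true(all(lens[a1b] == ds$config$core_length - 4))

  # dataset files round-trip
  dir <- tempfile()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "true_tree.nwk")))
  back <- read_alignment_fasta(file.path(dir, "core_alignment.fasta"))
  expect_equal(back$seq, ds$core_alignment$seq)
  gt <- jsonlite::fromJSON(file.path(dir, "ground_truth.json"))
  expect_equal(gt$seed, ds$config$seed)
})
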