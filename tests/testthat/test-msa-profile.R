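test_that("guide tree: cherries, duplicate ids, hand-computed k-mer joins", {
  two <- domain_sequences(c("a", "b"), c("MKKR", "MKTR"))
  g <- build_guide_tree(two, k = 2)
  expect_setequal(g$tip.label, c("a", "b"))
  expect_equal(ape::Ntip(g), 2L)

  expect_error(build_guide_tree(
    data.frame(id = c("a", "a"), seq = c("MK", "MR"),
               class = "UNKNOWN", taxon = "a")), "duplicate")

  # identical pair joins before anything else
  four <- domain_sequences(c("s1", "s2", "s3", "s4"),
                           c("MKKRAA", "MKKRAA", "WWPPHH", "MKKRHH"))
  g4 <- build_guide_tree(four, k = 2)
  # s1/s2 distance 0 -> sisters
  pair <- ape::getMRCA(g4, c("s1", "s2"))
  expect_equal(length(ape::extract.clade(g4, pair)$tip.label), 2L)

  # hand-computed k = 2 distances: s1 kmers {MK,KK,KR,RA,AA},
  # s4 kmers {MK,KK,KR,RH,HH}; shared 3, min size 5 -> d = 0.4;
  # s3 shares none with s1 -> d = 1
  km <- function(s) unique(substring(s, 1:(nchar(s) - 1), 2:nchar(s)))
  d14 <- 1 - length(intersect(km("MKKRAA"), km("MKKRHH"))) / 5
  expect_equal(d14, 0.4)
  # UPGMA therefore joins {s1,s2} first, then s4, then s3
  expect_true(is_monophyletic(g4, c("s1", "s2", "s4")))
})

test_that("progressive alignment round-trips sequences and places deletions", {
  same <- domain_sequences(paste0("s", 1:4), rep("MKKRWAT", 4))
  a <- progressive_align(same)
  expect_equal(unique(a$seq), "MKKRWAT")  # zero gap characters

  one <- domain_sequences("x", "MKVR")
  expect_equal(progressive_align(one)$seq, "MKVR")

  # single internal deletion: gap column at the deleted position
  trio <- domain_sequences(c("p", "q", "r"),
                           c("MKKRWA", "MKRWA", "MKKRWA"))
  al <- progressive_align(trio)
  expect_equal(ncol_alignment(al), 6L)
  expect_equal(gsub("-", "", al$seq[2]), "MKRWA")
  gappos <- which(strsplit(al$seq[al$id == "q"], "")[[1]] == "-")
  expect_length(gappos, 1L)
  expect_true(gappos %in% 2:3)  # either K of the KK pair

  # round trip on random input
  set.seed(8)
  seqs <- domain_sequences(paste0("t", 1:6), vapply(1:6, function(i)
    paste(sample(c("A", "R", "N", "D", "K", "W", "F"),
                 sample(8:14, 1), replace = TRUE), collapse = ""), ""))
  al2 <- progressive_align(seqs)
  expect_equal(gsub("-", "", al2$seq), seqs$seq)
  expect_error(progressive_align(seqs, guide = ape::rtree(4)), "guide")
})

test_that("extract_core honours anchor-row coordinates", {
  aln <- new_alignment(c("anchor", "other"), c("MKKRPT", "MARRPT"))
  full <- extract_core(aln, "anchor", 1, 6)
  expect_equal(full$seq, aln$seq)
  mid <- extract_core(aln, "anchor", 2, 4)
  expect_equal(mid$seq[1], "KKR")
  expect_error(extract_core(aln, "anchor", 2, 9), "window")

  # internal gap column inside the window is retained
  g <- new_alignment(c("anchor", "other"), c("MK-KRT", "MKWKRT"))
  win <- extract_core(g, "anchor", 2, 4)
  expect_equal(ncol_alignment(win), 4L)  # window length 3 + 1 gap column
  expect_equal(win$seq[1], "K-KR")
})

test_that("coverage filter keeps exactly-at-threshold rows and is idempotent", {
  mk <- function(ngap) paste0(strrep("K", 40 - ngap), strrep("-", ngap))
  aln <- new_alignment(c("full", "r32", "r31"),
                       c(mk(0), mk(8), mk(9)))
  out <- coverage_filter(aln, 0.8)
  expect_setequal(out$alignment$id, c("full", "r32"))  # 32/40 = 0.800 kept
  expect_equal(out$removed_ids, "r31")                 # 31/40 = 0.775 removed

  again <- coverage_filter(out$alignment, 0.8)
  expect_length(again$removed_ids, 0L)

  strict <- coverage_filter(aln, 1.0)
  expect_setequal(strict$removed_ids, c("r32", "r31"))
  expect_error(coverage_filter(new_alignment(character(0), character(0)), 0.8),
               "empty")
})

test_that("gappy-column removal deletes minority-insert columns only", {
  clean <- new_alignment(paste0("s", 1:4), rep("MKKR", 4))
  expect_equal(remove_gappy_columns(clean, 0.1)$seq, clean$seq)

  one <- new_alignment(paste0("s", 1:4), c("MWKR", "M-KR", "M-KR", "M-KR"))
  expect_equal(ncol_alignment(remove_gappy_columns(one, 0.5)), 3L)

  # 5-column insert in 1 of 10 rows
  rows <- c(paste0("MKKR", "WWWWW", "TTCD"),
            rep(paste0("MKKR", "-----", "TTCD"), 9))
  big <- new_alignment(paste0("s", 1:10), rows)
  out <- remove_gappy_columns(big, 0.5)
  expect_equal(ncol_alignment(out), 8L)
  expect_equal(unique(out$seq), "MKKRTTCD")
})

test_that("column frequencies, information content and consensus", {
  aln <- new_alignment(paste0("s", 1:4), c("RRAC", "RKAC", "RRCC", "RKCA"))
  prof <- column_frequencies(aln)
  expect_true(all(abs(colSums(prof$freq) - 1) < 1e-9))
  expect_equal(prof$ic[1], log2(20))            # all R
  expect_equal(prof$ic[2], log2(20) - 1)        # half R half K
  expect_equal(unname(prof$freq["R", 2]), 0.5)

  cons <- consensus(prof)
  expect_equal(nchar(cons$seq), ncol(prof$freq))
  expect_equal(substr(cons$seq, 1, 1), "R")
  expect_equal(substr(cons$seq, 2, 2), "K")   # tie R/K -> alphabetical
  expect_equal(substr(cons$seq, 3, 3), "A")     # tie A/C -> alphabetical
  expect_equal(substr(cons$seq, 4, 4), "C")     # 3/4 majority
  expect_equal(cons$support, c(1, 0.5, 0.5, 0.75))

  # IC decreases as a column is mixed with uniform noise
  mixcol <- function(n_noise) {
    res <- c(rep("R", 12), AAs <- sample(hmgtrace:::AA, n_noise, replace = TRUE))
    column_frequencies(new_alignment(paste0("x", seq_along(res)),
                                     res))$ic[1]
  }
  set.seed(3)
  ics <- vapply(c(0, 4, 12, 30), mixcol, 0)
  expect_true(all(diff(ics) < 0))

  # all-gap column: uniform, IC 0, flagged
  g <- column_frequencies(new_alignment(c("a", "b"), c("K-", "R-")))
  expect_true(g$all_gap[2])
  expect_equal(g$ic[2], 0)
  expect_equal(unname(g$freq[, 2]), rep(1 / 20, 20))

  # single-sequence consensus equals the sequence
  single <- column_frequencies(new_alignment("z", "MKWR"))
  expect_equal(consensus(single)$seq, "MKWR")

  # uniform column over all 20 residues has IC 0
  u <- column_frequencies(new_alignment(paste0("u", 1:20), hmgtrace:::AA))
  expect_equal(u$ic[1], 0)
})

test_that("alignment and profile files round-trip", {
  ds <- small_dataset()
  tmp <- tempfile(fileext = ".fasta")
  write_alignment_fasta(ds$core_alignment, tmp)
  back <- read_alignment_fasta(tmp)
  expect_equal(back$seq, ds$core_alignment$seq)
  expect_equal(back$id, ds$core_alignment$id)

  prof <- column_frequencies(ds$core_alignment)
  tsv <- tempfile(fileext = ".tsv")
  write_profile_tsv(prof, tsv)
  d <- read.table(tsv, header = TRUE, sep = "\t", check.names = FALSE)
  expect_equal(nrow(d), ncol(prof$freq))
  expect_equal(d$ic_bits, unname(prof$ic), tolerance = 1e-12)

  tab <- tempfile(fileext = ".csv")
  write.table(data.frame(id = ds$proteins$id, class = ds$proteins$class,
                         sequence = ds$proteins$seq),
              tab, sep = ",", row.names = FALSE)
  seqs <- read_domain_table(tab)
  expect_equal(seqs$seq, ds$proteins$seq)
  counts <- check_class_counts(seqs)
  expect_equal(unname(counts["total"]), nrow(ds$proteins))
})
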