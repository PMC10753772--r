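test_that("p-distance uses pairwise deletion of gaps and N", {
  a <- aln_of(x = "ACGT", y = "ACGT")
  expect_equal(pairwise_divergence(a, "x", "y"), 0)
  expect_equal(pairwise_divergence(aln_of(x = "ACGT", y = "ACGA"), "x", "y"),
               0.25)
  expect_equal(pairwise_divergence(aln_of(x = "AC-T", y = "ACGT"), "x", "y"),
               0)
  expect_equal(pairwise_divergence(aln_of(x = "ANGT", y = "ACGA"), "x", "y"),
               1 / 3)
  expect_error(pairwise_divergence(aln_of(x = "A---", y = "-CGT"), "x", "y"),
               "no comparable")
})

test_that("pi equals the brute-force pairwise computation", {
  expect_equal(nucleotide_diversity(aln_of(a = "ACGT", b = "ACGT",
                                           c = "ACGT"))$pi, 0)
  # two rows, 2 diffs over 10 gap-free columns
  a2 <- aln_of(a = "ACGTACGTAC", b = "ACGAACGAAC")
  expect_equal(nucleotide_diversity(a2)$pi, 0.2)
  set.seed(11)
  for (i in 1:12) {
    n <- sample(3:8, 1)
    w <- sample(50:300, 1)
    rows <- vapply(seq_len(n), function(k)
      paste(sample(c("A", "C", "G", "T", "N", "-"), w, TRUE,
                   prob = c(.23, .23, .23, .23, .04, .04)), collapse = ""), "")
    names(rows) <- paste0("s", seq_len(n))
    a <- tryCatch(alignment(rows), error = function(e) NULL)
    if (is.null(a)) next
    got <- nucleotide_diversity(a)
    expect_equal(got$pi, brute_pi(a), tolerance = 1e-12)
  }
})

test_that("for two rows pi equals the pairwise divergence on shared columns", {
  a <- aln_of(x = "ACGTA-GTNCGT", y = "ACTTACGT-CGA")
  expect_equal(nucleotide_diversity(a)$pi, pairwise_divergence(a, "x", "y"))
})

test_that("window grid starts at 1 and truncates the last window", {
  rows <- c(a = strrep("ACGTA", 200), b = strrep("ACGTA", 200))
  a <- alignment(rows)
  w <- sliding_pi(a, window = 600, step = 200)
  expect_equal(w$start, c(1L, 201L, 401L, 601L, 801L))
  expect_equal(w$end[5L], 1000L)
  expect_true(all(w$pi == 0))
  # window longer than the alignment: a single truncated window
  short <- aln_of(a = strrep("AC", 50), b = strrep("AC", 50))
  w2 <- sliding_pi(short, window = 600, step = 200)
  expect_equal(nrow(w2), 1L)
  expect_equal(w2$end, 100L)
})

test_that("pi of a concatenation is the net-site-weighted mean of its parts", {
  set.seed(5)
  rows <- vapply(1:4, function(k)
    paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = ""), "")
  names(rows) <- paste0("s", 1:4)
  a <- alignment(rows)
  left <- nucleotide_diversity(a, interval = c(1L, 200L))
  right <- nucleotide_diversity(a, interval = c(201L, 400L))
  whole <- nucleotide_diversity(a, interval = c(1L, 400L))
  expect_equal(whole$pi,
               (left$pi * left$net_sites + right$pi * right$net_sites) /
                 (left$net_sites + right$net_sites),
               tolerance = 1e-12)
})

test_that("distance matrices are symmetric with zero diagonal", {
  sim <- shared_sim(1L)
  m <- distance_matrix(sim$alignment)
  expect_true(all(m == t(m)))
  expect_true(all(diag(m) == 0))
  expect_true(all(m >= 0 & m <= 1))
})

test_that("group summaries behave on degenerate partitions", {
  m <- matrix(0.1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(m) <- 0
  part <- c(a = "g1", b = "g1", c = "g2", d = "g2")
  gs <- group_summary(m, part)
  expect_equal(gs$ratio, 1)
  expect_error(group_summary(m, c(a = "g", b = "g", c = "g", d = "g")),
               "single group")
  expect_error(group_summary(m, c(a = "g1", b = "g2", c = "g2", d = "g2")),
               "at least 2")
})

test_that("raising the between-species rate raises mean between divergence", {
  lo <- 0; hi <- 0
  anc <- make_ancestor(sim_config(seed = 99))
  for (s in 1:20) {
    base <- list(n_ssr_indels = 5L, n_nonssr_indels = 2L, n_inversions = 1L,
                 n_hotspot_substitutions = 0L)
    cfg_lo <- do.call(sim_config, c(list(seed = s, subst_rate_between = 2e-3),
                                    base))
    cfg_hi <- do.call(sim_config, c(list(seed = s, subst_rate_between = 8e-3),
                                    base))
    sub <- c("sp1_1", "sp1_2", "sp2_1", "sp2_2")
    part <- c(sp1_1 = "a", sp1_2 = "a", sp2_1 = "b", sp2_2 = "b")
    m_lo <- distance_matrix(evolve_individuals(anc, cfg_lo)$alignment, sub)
    m_hi <- distance_matrix(evolve_individuals(anc, cfg_hi)$alignment, sub)
    lo <- lo + group_summary(m_lo, part)$mean_between
    hi <- hi + group_summary(m_hi, part)$mean_between
  }
  expect_gt(hi, lo)
})

test_that("hotspot naming maps windows onto annotation labels", {
  # all-invariant alignment: no hotspot
  inv_aln <- aln_of(a = strrep("ACGT", 50), b = strrep("ACGT", 50))
  expect_length(name_hotspots(sliding_pi(inv_aln, window = 50, step = 25),
                              list()), 0L)
  # one variable block inside the spacer between gene3 and gene4
  set.seed(2)
  base <- sample(c("A", "C", "G", "T"), 800, TRUE)
  v <- base
  v[500:540] <- vapply(base[500:540], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  a <- alignment(c(a = paste(base, collapse = ""),
                   b = paste(v, collapse = "")))
  feats <- list(feature_record("gene1", "gene", "+", 1, 100),
                feature_record("gene2", "gene", "+", 150, 250),
                feature_record("gene3", "gene", "+", 300, 420),
                feature_record("gene4", "gene", "+", 600, 700))
  got <- name_hotspots(sliding_pi(a, window = 100, step = 50), feats, k = 1L)
  expect_equal(got, "gene3-gene4")
  # k larger than the number of variable windows: all nonzero windows return
  many <- name_hotspots(sliding_pi(a, window = 100, step = 50), feats,
                        k = 1000L)
  expect_gte(length(many), 1L)
})
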