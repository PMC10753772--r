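test_that("an inverted segment is detected and identity is excluded", {
  a <- aln_of(A = "GGTGATCC", B = "GGATCACC")
  inv <- find_inversions(a, "A", "B")
  expect_equal(nrow(inv), 1L)
  expect_equal(inv$start, 3L)
  expect_equal(inv$end, 6L)
  expect_equal(inv$seq_a, "TGAT")
  expect_equal(inv$seq_b, revcomp(inv$seq_a))
  # identical rows over the same motif: no call
  same <- aln_of(A = "GGTGATCC", B = "GGTGATCG")
  expect_equal(nrow(find_inversions(same, "A", "B")), 0L)
  expect_error(find_inversions(a, "A", "Z"), "no such row")
})

test_that("runs beyond the loop range are flagged, not dropped", {
  loop <- "TGTGTGTGTG"   # 10 bp, every position anti-complementary
  a <- aln_of(A = paste0("CC", loop, "CC"),
              B = paste0("CC", revcomp(loop), "CC"))
  inv <- find_inversions(a, "A", "B", min_len = 2L, max_len = 4L)
  expect_equal(nrow(inv), 1L)
  expect_true(inv$out_of_range)
})

test_that("stems are recovered around published hairpin loops", {
  # psbA-trnH record: 16-bp exact stems around a 4-bp loop
  s1 <- toupper(paste0("tcaataccaaacttct", "tgat", "agaagtttggtattga"))
  st <- find_stems(s1, c(17L, 20L))
  expect_true(st$found)
  expect_equal(st$stem_length, 16L)
  expect_equal(st$n_mismatches, 0L)
  expect_equal(st$upstream_stem, "TCAATACCAAACTTCT")
  expect_equal(st$downstream_stem, "AGAAGTTTGGTATTGA")
  expect_equal(revcomp(st$upstream_stem), st$downstream_stem)
  # ccsA-psaC record: minimal 3-bp stem
  s2 <- toupper(paste0("aat", "atc", "att"))
  st2 <- find_stems(s2, c(4L, 6L))
  expect_true(st2$found)
  expect_equal(st2$stem_length, 3L)
  expect_equal(st2$upstream_stem, "AAT")
  expect_equal(st2$downstream_stem, "ATT")
  # poly-A flanks never pair at zero mismatches: explicit no-stem result
  s3 <- paste0(strrep("A", 10), "CGT", strrep("A", 10))
  st3 <- find_stems(s3, c(11L, 13L))
  expect_false(st3$found)
  expect_equal(st3$stem_length, 0L)
})

test_that("stem search tolerates a gap between stem and loop", {
  stem <- "GGCTCGGCTA"
  s <- paste0(stem, "TT", "TCCCACC", "AG", revcomp(stem))
  st <- find_stems(toupper(s), c(13L, 19L), max_gap_to_loop = 5L)
  expect_true(st$found)
  expect_equal(st$stem_length, 10L)
  expect_equal(st$gap_upstream, 2L)
  expect_equal(st$gap_downstream, 2L)
})

test_that("locations are labeled by gene, spacer and intron context", {
  feats <- list(
    feature_record("psbA", "gene", "+", 10, 100),
    feature_record("trnH", "tRNA", "+", 200, 260),
    feature_record("rps16", "gene", "-", c(300, 400), c(350, 450)),
    feature_record("ycf2", "gene", "+", 500, 600))
  expect_equal(label_location(c(120, 130), feats), "psbA-trnH")
  expect_equal(label_location(c(360, 370), feats), "rps16 intron")
  expect_equal(label_location(c(540, 550), feats), "ycf2")
  expect_equal(label_location(c(20, 30), feats), "psbA")
  expect_equal(label_location(c(120, 130), list()), "unlabeled:120-130")
})

test_that("reverse-complementing both rows mirrors the inversion set", {
  sim <- shared_sim(1L)
  aln <- sim$alignment
  ids <- names(sim$truth$species)
  a <- ids[1L]; b <- ids[5L]
  # a clean two-row alignment (columns gapped in both rows dropped)
  va <- chars(aln$rows[[a]]); vb <- chars(aln$rows[[b]])
  keep <- !(va == "-" & vb == "-")
  rows <- c(paste(va[keep], collapse = ""), paste(vb[keep], collapse = ""))
  names(rows) <- c(a, b)
  pair <- alignment(rows)
  inv <- find_inversions(pair, a, b)
  expect_gt(nrow(inv), 0L)
  flip <- function(r) {
    x <- revcomp(gsub("-", "N", r))
    gsub("N", "-", x)
  }
  mirrored <- alignment(stats::setNames(c(flip(rows[[1]]), flip(rows[[2]])),
                                        c(a, b)))
  inv_rc <- find_inversions(mirrored, a, b)
  expect_equal(nrow(inv_rc), nrow(inv))
  expect_setequal(pair$ncol - inv$end + 1L, inv_rc$start)
  expect_setequal(pair$ncol - inv$start + 1L, inv_rc$end)
})

test_that("planted inversions are recovered with their stems and ranges", {
  sim <- shared_sim(1L)
  aln <- sim$alignment
  ids <- names(sim$truth$species)
  inv <- find_inversions(aln, ids[1L], ids[5L])
  t_inv <- sim$truth$events[sim$truth$events$class == "inversion", ]
  expect_setequal(paste(inv$start, inv$end),
                  paste(t_inv$aligned_start, t_inv$aligned_end))
  # every emitted exact record satisfies the palindrome property, and the
  # loop/stem extremes stay within the configured planting ranges
  hp <- characterize_inversions(inv, aln, ids[1L], sim$genomes[[ids[1L]]])
  expect_true(all(hp$n_mismatches == 0L))
  expect_true(all(revcomp(hp$upstream_stem) == hp$downstream_stem))
  cfg <- sim$truth$config
  expect_true(all(hp$loop_size >= cfg$inversion_loop_range[1L] &
                  hp$loop_size <= cfg$inversion_loop_range[2L]))
  expect_true(all(hp$stem_length >= cfg$stem_length_range[1L] &
                  hp$stem_length <= cfg$stem_length_range[2L]))
})

test_that("hairpin validation reports non-palindromic records unchanged", {
  df <- data.frame(upstream_stem = c("AATT", "AAAA"),
                   downstream_stem = c("AATT", "AAAA"))
  v0 <- validate_hairpins(df, max_mismatch = 0L)
  expect_equal(v0$n_stem_mismatches, c(0L, 4L))
  expect_equal(v0$palindromic, c(TRUE, FALSE))
  expect_identical(v0$upstream_stem, df$upstream_stem)   # never "fixed"
  v4 <- validate_hairpins(df, max_mismatch = 4L)
  expect_equal(v4$palindromic, c(TRUE, TRUE))
})
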