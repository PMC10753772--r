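test_that("substitution calling finds polymorphic columns and skips gaps", {
  expect_equal(call_substitutions(aln_of("ACGT", "ACGA"))$column, 4L)
  expect_equal(nrow(call_substitutions(aln_of("AC-T", "ACGT"))), 0L)
  # N is missing, never polymorphic
  expect_equal(nrow(call_substitutions(aln_of("ACNT", "ACGT"))), 0L)
  expect_equal(call_substitutions(aln_of("ANGT", "ACGA"))$column, 4L)
  expect_error(call_substitutions(aln_of("ACGT", "ACGA"), subset = "r1"),
               "at least 2")
  # excluded columns (e.g. inside called inversions) are not reported
  expect_equal(nrow(call_substitutions(aln_of("ACGT", "ACGA"),
                                       exclude_columns = 4L)), 0L)
})

test_that("indel events are maximal runs of one gap pattern", {
  ev <- call_indels(aln_of("AAA--A", "AAATTA"))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start, 4L)
  expect_equal(ev$end, 5L)
  expect_equal(ev$fragment, "TT")
  expect_equal(ev$length, 2L)
  expect_equal(ev$bearers, "r1")
  # adjacent columns with different bearer patterns are distinct events
  ev2 <- call_indels(aln_of("A--A", "AT-A", "ATCA"))
  expect_equal(nrow(ev2), 2L)
  expect_equal(ev2$bearers, c("r1", "r1,r2"))
})

test_that("SSR classification matches a brute-force motif enumeration", {
  # canonical homopolymer slippage: deleting one A inside a run
  a1 <- aln_of(carrier = "TTCAAAAAAGG", bearer = "TTC-AAAAAGG")
  ev <- call_indels(a1)
  cls <- classify_ssr(ev[1L, ], a1)
  expect_equal(cls$ssr_class, "SSR")
  expect_equal(cls$motif, "A")
  # no repeat context: GATC deletion
  a2 <- aln_of(carrier = "TTGATCAGCGT", bearer = "TT----AGCGT")
  expect_equal(classify_ssr(call_indels(a2)[1L, ], a2)$ssr_class, "non-SSR")
  # dinucleotide: ATAT deletion adjacent to AT
  a3 <- aln_of(carrier = "CGATATATGC", bearer = "CG----ATGC")
  cls3 <- classify_ssr(call_indels(a3)[1L, ], a3)
  expect_equal(cls3$ssr_class, "SSR")
  expect_equal(cls3$motif, "AT")
  # agreement with the independent brute-force oracle on random events
  set.seed(7)
  for (i in 1:40) {
    frag <- paste(sample(c("A", "C", "G", "T"), sample(1:8, 1), TRUE),
                  collapse = "")
    left <- paste(sample(c("A", "C", "G", "T"), 12, TRUE), collapse = "")
    right <- paste(sample(c("A", "C", "G", "T"), 12, TRUE), collapse = "")
    carrier <- paste0(left, frag, right)
    bearer <- paste0(left, strrep("-", nchar(frag)), right)
    a <- aln_of(carrier = carrier, bearer = bearer)
    ev <- call_indels(a)
    got <- classify_ssr(ev[1L, ], a)
    want <- brute_ssr(frag, left, right)
    expect_equal(got$ssr_class == "SSR", want$ssr, info = carrier)
    if (want$ssr) expect_equal(got$motif, want$motif, info = carrier)
  }
})

test_that("the tally is additive over its components", {
  t0 <- tally_mutations(0L, 0L, 0L)
  expect_equal(t0$total, 0L)
  sim <- shared_sim(1L)
  truth <- sim$truth$events
  t1 <- tally_mutations(sum(truth$class == "substitution"),
                        sum(truth$class == "indel"),
                        sum(truth$class == "inversion"))
  expect_equal(t1$total, nrow(truth))
})

test_that("callers recover the planted truth exactly on a synthetic design", {
  sim <- shared_sim(1L)
  rec <- recovery_report(sim)
  expect_equal(rec$substitutions$precision, 1)
  expect_equal(rec$substitutions$recall, 1)
  expect_equal(rec$indels$precision, 1)
  expect_equal(rec$indels$recall, 1)
  expect_equal(rec$ssr_label_agreement, 1)
})

test_that("row order does not change any call counts", {
  sim <- shared_sim(1L)
  aln <- sim$alignment
  set.seed(3)
  perm <- sample(aln$labels)
  aln2 <- alignment(aln$rows[perm])
  expect_equal(nrow(call_substitutions(aln2)),
               nrow(call_substitutions(aln)))
  i1 <- call_indels(aln); i2 <- call_indels(aln2)
  expect_equal(nrow(i2), nrow(i1))
  expect_setequal(paste(i2$start, i2$end, i2$bearers),
                  paste(i1$start, i1$end, i1$bearers))
})

test_that("every aligned column belongs to at most one event category", {
  sim <- shared_sim(1L)
  aln <- sim$alignment
  ids <- names(sim$truth$species)
  inv <- find_inversions(aln, ids[1L], ids[5L])
  inv_cols <- unlist(mapply(seq, inv$start, inv$end, SIMPLIFY = FALSE))
  subs <- call_substitutions(aln, exclude_columns = inv_cols)
  indels <- call_indels(aln)
  ind_cols <- unlist(mapply(seq, indels$start, indels$end, SIMPLIFY = FALSE))
  expect_length(intersect(subs$column, ind_cols), 0L)
  expect_length(intersect(subs$column, inv_cols), 0L)
  expect_length(intersect(ind_cols, inv_cols), 0L)
})
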