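test_that("the inverted repeat is found where planted and lost when deleted", {
  cfg <- sim_config(seed = 21)
  anc <- make_ancestor(cfg)
  reg <- attr(anc, "regions")
  ir <- find_ir(anc)
  expect_equal(ir$ir_status, "quadripartite")
  expect_gte(ir$length, cfg$ir_length)
  # detected intervals sit on the planted IRa/IRb (allow a few bp of chance
  # extension into the flanking spacers)
  expect_lt(abs(ir$intervals["IRa", "start"] -
                  reg$start[reg$region == "IRa"]), 10L)
  expect_lt(abs(ir$intervals["IRb", "end"] -
                  reg$end[reg$region == "IRb"]), 10L)
  red <- apply_structural_edits(anc, list(list(op = "delete_ir_copy")))
  expect_equal(find_ir(red$record)$ir_status, "ir_lacking")
})

test_that("a random sequence has no kilobase inverted repeat", {
  set.seed(8)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  ir <- find_ir(s)
  expect_equal(ir$ir_status, "ir_lacking")
  expect_lt(ir$length, 1000L)
})

test_that("find_ir reports repeats of equal length on both strands", {
  cfg <- sim_config(seed = 22)
  anc <- make_ancestor(cfg)
  a <- find_ir(anc$seq)
  b <- find_ir(revcomp(anc$seq))
  expect_equal(a$length, b$length)
})

test_that("missing segments are maximal runs of absent reference genes", {
  anc <- make_ancestor(sim_config(seed = 23))
  expect_equal(nrow(missing_segments(anc, anc)), 0L)
  one <- apply_structural_edits(anc, list(
    list(op = "delete_segment", genes = c("ndhC", "ndhK", "ndhJ"))))
  segs <- missing_segments(anc, one$record)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$genes, "ndhC,ndhJ,ndhK")
  expect_equal(segs$flank_left, "trnV-UAC")
  expect_equal(segs$flank_right, "trnM-CAU")
  expect_gte(segs$length, one$applied$length)
  # two non-adjacent deleted blocks stay two segments
  two <- apply_structural_edits(anc, list(
    list(op = "delete_segment", genes = c("ndhC", "ndhK", "ndhJ")),
    list(op = "delete_segment", genes = c("ndhG", "ndhI", "ndhA"))))
  segs2 <- missing_segments(anc, two$record)
  expect_equal(nrow(segs2), 2L)
  expect_setequal(segs2$genes, c("ndhC,ndhJ,ndhK", "ndhA,ndhG,ndhI"))
})

test_that("pseudogenes are called from truncation, frameshift and stops", {
  mk <- function(name, cds, extra = "") {
    genome_record(paste0("g_", name),
                  paste0("ACGT", cds, "ACGT", extra), circular = FALSE,
                  features = list(feature_record(name, "gene", "+", 5,
                                                 4 + nchar(cds))))
  }
  codons <- function(n) strrep("GCT", n)
  # truncation at the published psi-ndhB scale: 2181 bp -> 1191 bp
  ref <- mk("ndhB", paste0("ATG", codons(725), "TAA"))
  qry <- mk("ndhB", paste0("ATG", codons(395), "TAA"),
            extra = strrep("A", 990))
  ps <- call_pseudogenes(ref, qry)
  expect_equal(nrow(ps), 1L)
  expect_true(ps$truncation)
  expect_equal(ps$observed_length, 1191L)
  expect_equal(ps$reference_length, 2181L)
  # identical gene: not called
  expect_equal(nrow(call_pseudogenes(ref, ref)), 0L)
  # internal stop at codon 10 of 100
  good <- mk("psbB", paste0("ATG", codons(98), "TAA"))
  broken_cds <- paste0("ATG", codons(8), "TAA", codons(89), "TAA")
  bad <- mk("psbB", broken_cds)
  ps2 <- call_pseudogenes(good, bad)
  expect_equal(nrow(ps2), 1L)
  expect_true(ps2$premature_stop)
  # frameshift: length not a multiple of three
  fs <- mk("rbcL", paste0("ATG", codons(50), "TAA", "GG"))
  ok <- mk("rbcL", paste0("ATG", codons(50), "TAA"))
  ps3 <- call_pseudogenes(ok, fs)
  expect_equal(nrow(ps3), 1L)
  expect_true(ps3$frameshift)
})

test_that("raising min_intact_frac never removes a truncation call", {
  sim <- shared_sim(1L)
  g <- sim$genomes[[1L]]
  loose <- call_pseudogenes(sim$ancestor, g, min_intact_frac = 0.5)
  strict <- call_pseudogenes(sim$ancestor, g, min_intact_frac = 0.9)
  expect_true(all(loose$name[loose$truncation] %in%
                    strict$name[strict$truncation]))
})

test_that("summaries count unique functional genes and exclude pseudogenes", {
  anc <- make_ancestor(sim_config(seed = 24))
  s <- summarize_genome(anc)
  expect_equal(s$n_genes, 107L)
  expect_equal(s$n_protein_coding, 73L)
  expect_equal(s$n_trna, 30L)
  expect_equal(s$n_rrna, 4L)
  expect_equal(gc_content("ACGTACGTAC") * 100, 50.0)
  red <- apply_structural_edits(anc, list(
    list(op = "truncate_gene", gene = "ndhD", keep_frac = 0.28)))
  s2 <- summarize_genome(red$record)
  expect_equal(s2$n_protein_coding, 72L)
  expect_equal(s2$n_genes, 106L)
})

test_that("the structural diff ties IR status, segments and pseudogenes", {
  sim <- shared_sim(1L)
  d <- structure_compare(sim$ancestor, sim$genomes[[1L]])
  expect_s3_class(d, "structural_diff")
  expect_equal(d$ir_status, "ir_lacking")
  expect_equal(nrow(d$missing_segments), 2L)
  expect_setequal(tolower(d$pseudogenes$name),
                  c("ndhb", "ndhd", "ndhe", "ndhf", "ndhh"))
  expect_setequal(d$lost_genes,
                  c("ndhA", "ndhC", "ndhG", "ndhI", "ndhJ", "ndhK"))
})
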