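test_that("revcomp handles published hairpin stems and is an involution", {
  # stem pairs as printed for the psbA-trnH and first ycf2 hairpin records
  expect_equal(revcomp("tcaataccaaacttct"), "AGAAGTTTGGTATTGA")
  expect_equal(revcomp("tttcattc"), "GAATGAAA")
  set.seed(42)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(1:50, 1),
                      replace = TRUE), collapse = "")
    expect_equal(revcomp(revcomp(s)), s)
    expect_equal(nchar(revcomp(s)), nchar(s))
  }
  expect_error(revcomp("ACGR"), "non-nucleotide")
})

test_that("gc_content excludes N and rejects all-N input", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content("ACGTN"), 0.5)
  expect_error(gc_content("NNNN"), "undefined")
})

test_that("genome records validate alphabet and feature bounds", {
  expect_error(genome_record("x", "ACGR"), "ambiguity")
  expect_error(genome_record("x", ""), "empty")
  f_out <- feature_record("g1", "gene", "+", 5, 12)
  expect_error(genome_record("x", "ACGTACGT", features = list(f_out)),
               "outside")
  rec <- genome_record("x", "acgtn")
  expect_equal(rec$seq, "ACGTN")
})

test_that("FASTA + GFF3 round-trips sequence and features", {
  rec <- genome_record(
    "G1", paste(rep("ACGTTGCA", 50), collapse = ""), circular = TRUE,
    features = list(
      feature_record("psbA", "gene", "-", 10, 90),
      feature_record("rps16", "gene", "+", c(120, 200), c(150, 260)),
      feature_record("trnQ-UUG", "tRNA", "+", 300, 371)))
  fa <- tempfile(fileext = ".fasta"); gff <- tempfile(fileext = ".gff3")
  write_genome(rec, fa, "fasta", gff = gff)
  back <- read_genome(fa, "fasta", gff = gff, rotate_trnH = FALSE)
  expect_identical(back$seq, rec$seq)
  expect_equal(length(back$features), 3L)
  nm <- vapply(back$features, `[[`, "", "name")
  for (f in rec$features) {
    g <- back$features[[match(f$name, nm)]]
    expect_identical(unname(g$intervals), unname(f$intervals))
    expect_identical(g$strand, f$strand)
    expect_identical(g$ftype, f$ftype)
  }
})

test_that("a minimal FASTA with an empty GFF3 reads as a bare record", {
  fa <- tempfile(fileext = ".fasta"); gff <- tempfile(fileext = ".gff3")
  writeLines(c(">tiny", "ACGT"), fa)
  writeLines("##gff-version 3", gff)
  rec <- read_genome(fa, "fasta", gff = gff)
  expect_equal(nchar(rec$seq), 4L)
  expect_length(rec$features, 0L)
})

test_that("GenBank round-trips, including an origin-wrapping feature", {
  L <- 200L
  seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  rec <- genome_record(
    "SYN1", seq, circular = TRUE,
    features = list(
      feature_record("ndhB", "gene", "+", 10, 90),
      feature_record("ndhF", "pseudogene", "-", 100, 150),
      feature_record("wrapper", "gene", "+", c(190, 1), c(L, 8))))
  gb <- tempfile(fileext = ".gb")
  write_genome(rec, gb, "genbank")
  back <- read_genome(gb, "genbank", rotate_trnH = FALSE)
  expect_identical(back$seq, rec$seq)
  expect_true(back$circular)
  expect_equal(length(back$features), 3L)
  w <- back$features[[3L]]
  expect_identical(unname(w$intervals),
                   unname(rec$features[[3L]]$intervals))
  expect_identical(back$features[[2L]]$ftype, "pseudogene")
})

test_that("a 1-based GenBank gene location maps onto the same coordinates", {
  gb <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       MINI             120 bp    DNA     linear PLN 01-JAN-2000",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "     gene            1..90",
    "                     /gene=\"psbA\"",
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    paste0("       61 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    "//"), gb)
  rec <- read_genome(gb, "genbank")
  expect_equal(nchar(rec$seq), 120L)
  f <- rec$features[[1L]]
  expect_identical(f$name, "psbA")
  expect_equal(unname(f$intervals[1L, ]), c(1L, 90L))
  expect_identical(f$strand, "+")
})

test_that("written GenBank parses under an independent parser (Biopython)", {
  rec <- genome_record(
    "CONF1", paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                   collapse = ""),
    circular = TRUE,
    features = list(feature_record("rbcL", "gene", "-", 21, 320),
                    feature_record("trnH-GUG", "tRNA", "+", 1, 72)))
  gb <- tempfile(fileext = ".gb")
  write_genome(rec, gb, "genbank")
  out <- system2("python", c("-c", shQuote(paste0(
    "from Bio import SeqIO; r = SeqIO.read('", gb, "', 'genbank'); ",
    "print(len(r.seq), len([f for f in r.features if f.type != 'source']))"
  ))), stdout = TRUE)
  expect_equal(out, "500 2")
})

test_that("circular genomes are rotated so trnH-GUG starts at position 1", {
  L <- 300L
  seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  rec <- genome_record("R1", seq, circular = TRUE,
                       features = list(
                         feature_record("psbA", "gene", "+", 90, 110),
                         feature_record("trnH-GUG", "tRNA", "+", 101, 172)))
  fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
  write_genome(rec, fa, "fasta", gff = gff)
  rot <- read_genome(fa, "fasta", gff = gff, rotate_trnH = TRUE)
  nm <- vapply(rot$features, `[[`, "", "name")
  trnh <- rot$features[[match("trnH-GUG", nm)]]
  expect_equal(trnh$intervals[1L, "start"], c(start = 1L))
  expect_identical(rot$seq, paste0(substr(seq, 101, L), substr(seq, 1, 100)))
  # psbA now wraps the new origin and is split in wrap order
  psba <- rot$features[[match("psbA", nm)]]
  expect_equal(nrow(psba$intervals), 2L)
  expect_identical(feature_seq(rot, psba), substr(seq, 90, 110))
})
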