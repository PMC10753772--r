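# genome_io: plastome records, features, sequence utilities and file formats.
#
# Coordinates are 1-based inclusive throughout the package (the R/Bioconductor
# convention); GFF3 and GenBank use the same convention, so no conversion
# happens at format boundaries.

FEATURE_TYPES <- c("gene", "tRNA", "rRNA", "pseudogene", "intergenic")

#' Create a plastome feature
#'
#' A named, stranded feature over one or more intervals of a genome. Multiple
#' intervals encode introns or wrap around the origin of a circular molecule
#' (in wrap order: the interval ending at the sequence end first, then the one
#' starting at position 1).
#'
#' @param name Gene symbol, e.g. `"ndhB"` or `"trnH-GUG"`.
#' @param ftype One of `"gene"`, `"tRNA"`, `"rRNA"`, `"pseudogene"`,
#'   `"intergenic"`.
#' @param strand `"+"` or `"-"`.
#' @param start,end Integer vectors of equal length: 1-based inclusive
#'   interval bounds, in strand-independent genome order.
#' @return An object of class `plastome_feature`.
#' @export
feature_record <- function(name, ftype, strand = "+", start, end) {
  stopifnot(is_string(name), ftype %in% FEATURE_TYPES, strand %in% c("+", "-"),
            length(start) == length(end), length(start) >= 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (any(end < start)) stop("feature '", name, "': interval end < start")
  structure(list(name = name, ftype = ftype, strand = strand,
                 intervals = cbind(start = start, end = end)),
            class = "plastome_feature")
}

feat_length <- function(f) sum(f$intervals[, "end"] - f$intervals[, "start"] + 1L)
feat_start <- function(f) f$intervals[1L, "start"]

#' Create a genome record
#'
#' @param id Accession-like identifier.
#' @param seq Nucleotide sequence over `{A,C,G,T,N}`; lower case is upcased.
#' @param circular Is the molecule circular?
#' @param features List of [feature_record()] objects.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(id, seq, circular = TRUE, features = list()) {
  stopifnot(is_string(id), is_string(seq), is.logical(circular))
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("empty sequence")
  if (grepl("[^ACGTN]", seq))
    stop("sequence of '", id, "' contains characters outside {A,C,G,T,N} ",
         "(ambiguity codes other than N are rejected)")
  rec <- structure(list(id = id, seq = seq, circular = circular,
                        features = features),
                   class = "genome_record")
  validate_genome(rec)
  rec
}

validate_genome <- function(rec) {
  L <- nchar(rec$seq)
  for (f in rec$features) {
    iv <- f$intervals
    if (any(iv < 1L) || any(iv > L))
      stop("feature '", f$name, "' outside sequence [1,", L, "]")
    if (nrow(iv) > 1L && !rec$circular &&
        any(diff(iv[, "start"]) < 0))
      stop("feature '", f$name, "' wraps the origin of a linear molecule")
  }
  invisible(rec)
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp, %s, %d features\n", x$id,
              nchar(x$seq), if (x$circular) "circular" else "linear",
              length(x$features)))
  invisible(x)
}

genome_length <- function(rec) nchar(rec$seq)

feature_names <- function(rec) vapply(rec$features, `[[`, "", "name")
feature_types <- function(rec) vapply(rec$features, `[[`, "", "ftype")

# Extract the (spliced, strand-corrected) sequence of a feature.
feature_seq <- function(rec, f) {
  parts <- apply(f$intervals, 1L, function(iv)
    substr(rec$seq, iv[["start"]], iv[["end"]]))
  s <- paste0(parts, collapse = "")
  if (f$strand == "-") revcomp(s) else s
}

#' Reverse complement
#'
#' @param s Character vector of nucleotide strings over `{A,C,G,T,N}`
#'   (case-insensitive).
#' @return Uppercase reverse-complemented strings.
#' @export
revcomp <- function(s) {
  stopifnot(is.character(s))
  if (any(grepl("[^ACGTNacgtn]", s)))
    stop("revcomp: non-nucleotide character (alphabet is {A,C,G,T,N})")
  out <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(toupper(s))))
  unname(out)
}

#' GC content
#'
#' Fraction (G+C)/(A+C+G+T); `N` bases are excluded from the denominator.
#'
#' @param x A `genome_record` or a nucleotide string.
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(x) {
  s <- if (inherits(x, "genome_record")) x$seq else toupper(x)
  v <- chars(s)
  acgt <- sum(v %in% c("A", "C", "G", "T"))
  if (acgt == 0L) stop("gc_content undefined: no A/C/G/T bases")
  sum(v %in% c("G", "C")) / acgt
}

#' Rotate a circular genome to a new origin
#'
#' Position `new_origin` becomes position 1; features are remapped, splitting
#' any that come to span the new origin into wrap-order intervals.
#'
#' @param rec A circular `genome_record`.
#' @param new_origin 1-based position of the new first base.
#' @return Rotated `genome_record`.
#' @export
rotate_genome <- function(rec, new_origin) {
  stopifnot(inherits(rec, "genome_record"), rec$circular)
  L <- genome_length(rec)
  new_origin <- as.integer(new_origin)
  stopifnot(new_origin >= 1L, new_origin <= L)
  if (new_origin == 1L) return(rec)
  shift <- function(p) ((p - new_origin) %% L) + 1L
  seq2 <- paste0(substr(rec$seq, new_origin, L),
                 substr(rec$seq, 1L, new_origin - 1L))
  feats <- lapply(rec$features, function(f) {
    iv <- f$intervals
    out_s <- integer(0); out_e <- integer(0)
    for (i in seq_len(nrow(iv))) {
      s <- shift(iv[i, "start"]); e <- shift(iv[i, "end"])
      if (s <= e) { out_s <- c(out_s, s); out_e <- c(out_e, e) }
      else { # interval now spans the new origin: split in wrap order
        out_s <- c(out_s, s, 1L); out_e <- c(out_e, L, e)
      }
    }
    feature_record(f$name, f$ftype, f$strand, out_s, out_e)
  })
  genome_record(rec$id, seq2, circular = TRUE, features = feats)
}

# Conventional plastome linearization: start the sequence at the first base of
# trnH-GUG when that tRNA is annotated. Makes coordinates comparable across
# individuals.
normalize_origin <- function(rec) {
  if (!rec$circular) return(rec)
  idx <- which(feature_names(rec) == "trnH-GUG")
  if (length(idx) == 0L) return(rec)
  rotate_genome(rec, feat_start(rec$features[[idx[1L]]]))
}

## ---- FASTA + GFF3 ----------------------------------------------------------

read_fasta_genome <- function(path, gff = NULL, circular = TRUE) {
  dss <- Biostrings::readDNAStringSet(path)
  if (length(dss) != 1L)
    stop("expected a single-record FASTA, got ", length(dss),
         " records in ", path)
  id <- sub("\\s.*$", "", names(dss)[1L])
  feats <- if (!is.null(gff)) read_gff3_features(gff) else list()
  genome_record(id, as.character(dss[[1L]]), circular = circular,
                features = feats)
}

read_gff3_features <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(body) == 0L) return(list())
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  nm <- if ("Name" %in% names(mc)) as.character(mc$Name) else NA_character_
  id <- if ("ID" %in% names(mc)) as.character(mc$ID) else NA_character_
  key <- ifelse(is.na(id) | id == "", nm, id)
  key[is.na(key) | key == ""] <- paste0("feat", seq_along(gr))[is.na(key) | key == ""]
  feats <- list()
  for (k in unique(key)) {
    sel <- which(key == k)
    typ <- as.character(mc$type[sel[1L]])
    if (!typ %in% FEATURE_TYPES)
      typ <- switch(typ, CDS = "gene", mRNA = "gene", "gene")
    nmk <- nm[sel[1L]]
    if (is.na(nmk) || nmk == "") nmk <- k
    o <- sel[order(GenomicRanges::start(gr)[sel])]
    feats[[length(feats) + 1L]] <- feature_record(
      nmk, typ, as.character(GenomicRanges::strand(gr))[sel[1L]],
      GenomicRanges::start(gr)[o], GenomicRanges::end(gr)[o])
  }
  feats
}

write_gff3_features <- function(rec, path) {
  feats <- rec$features
  if (length(feats) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  n_iv <- vapply(feats, function(f) nrow(f$intervals), 0L)
  gr <- GenomicRanges::GRanges(
    seqnames = rec$id,
    ranges = IRanges::IRanges(
      start = unlist(lapply(feats, function(f) f$intervals[, "start"])),
      end = unlist(lapply(feats, function(f) f$intervals[, "end"]))),
    strand = rep(vapply(feats, `[[`, "", "strand"), n_iv))
  S4Vectors::mcols(gr)$type <- rep(vapply(feats, `[[`, "", "ftype"), n_iv)
  S4Vectors::mcols(gr)$ID <- rep(make.unique(feature_names(rec)), n_iv)
  S4Vectors::mcols(gr)$Name <- rep(feature_names(rec), n_iv)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

## ---- GenBank flat file -----------------------------------------------------
# Minimal reader/writer for the subset this package emits: LOCUS, FEATURES
# with gene/tRNA/rRNA/misc_feature keys and join()/complement() locations,
# ORIGIN. No installed R package parses GenBank flat files from disk.

gb_ftype_to_key <- c(gene = "gene", tRNA = "tRNA", rRNA = "rRNA",
                     pseudogene = "gene", intergenic = "misc_feature")

gb_location <- function(f) {
  parts <- apply(f$intervals, 1L, function(iv)
    if (iv[["start"]] == iv[["end"]]) as.character(iv[["start"]])
    else paste0(iv[["start"]], "..", iv[["end"]]))
  loc <- if (length(parts) > 1L) paste0("join(", paste(parts, collapse = ","), ")")
         else parts[[1L]]
  if (f$strand == "-") paste0("complement(", loc, ")") else loc
}

write_genbank <- function(rec, path) {
  L <- genome_length(rec)
  con <- file(path, "w"); on.exit(close(con))
  topo <- if (rec$circular) "circular" else "linear"
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %s PLN 01-JAN-2000",
                     rec$id, L, topo), con)
  writeLines(sprintf("DEFINITION  %s plastome.", rec$id), con)
  writeLines(sprintf("ACCESSION   %s", rec$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  for (f in rec$features) {
    key <- gb_ftype_to_key[[f$ftype]]
    writeLines(sprintf("     %-15s %s", key, gb_location(f)), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$name), con)
    if (f$ftype == "pseudogene")
      writeLines("                     /pseudo", con)
    if (f$ftype == "intergenic")
      writeLines("                     /note=\"intergenic\"", con)
  }
  writeLines("ORIGIN", con)
  pos <- seq(1L, L, by = 60L)
  for (p in pos) {
    block <- substr(rec$seq, p, min(p + 59L, L))
    tens <- substring(block, seq(1L, nchar(block), 10L),
                      pmin(seq(10L, nchar(block) + 9L, 10L), nchar(block)))
    writeLines(sprintf("%9d %s", p, tolower(paste(tens, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

parse_gb_location <- function(loc) {
  strand <- "+"
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^<?(\\d+)(\\.\\.>?(\\d+))?$", parts))
  if (any(vapply(m, length, 0L) == 0L))
    stop("unparseable GenBank location: ", loc)
  start <- as.integer(vapply(m, `[`, "", 2L))
  endc <- vapply(m, `[`, "", 4L)
  end <- ifelse(endc == "" | is.na(endc), start, suppressWarnings(as.integer(endc)))
  list(strand = strand, start = start, end = as.integer(end))
}

read_genbank <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) stop("not a GenBank flat file (no LOCUS line): ", path)
  toks <- strsplit(trimws(sub("^LOCUS", "", locus[1L])), "\\s+")[[1L]]
  id <- toks[1L]
  circular <- any(toks == "circular")
  i_feat <- grep("^FEATURES", lines)
  i_orig <- grep("^ORIGIN", lines)
  if (length(i_orig) == 0L) stop("GenBank record without ORIGIN: ", path)
  feats <- list()
  if (length(i_feat) > 0L) {
    block <- lines[(i_feat[1L] + 1L):(i_orig[1L] - 1L)]
    cur <- NULL
    flush_cur <- function(cur) {
      if (is.null(cur) || cur$key == "source") return(NULL)
      typ <- switch(cur$key, gene = "gene", tRNA = "tRNA", rRNA = "rRNA",
                    CDS = "gene", misc_feature = "intergenic", "gene")
      if (isTRUE(cur$pseudo)) typ <- "pseudogene"
      loc <- parse_gb_location(cur$loc)
      feature_record(cur$name %||% "unnamed", typ, loc$strand,
                     loc$start, loc$end)
    }
    for (ln in block) {
      if (grepl("^     \\S", ln)) {             # new feature key line
        f <- flush_cur(cur)
        if (!is.null(f)) feats[[length(feats) + 1L]] <- f
        toks <- strsplit(trimws(ln), "\\s+")[[1L]]
        cur <- list(key = toks[1L], loc = paste(toks[-1L], collapse = ""),
                    name = NULL, pseudo = FALSE)
      } else if (grepl("^\\s+/", ln)) {          # qualifier
        q <- trimws(ln)
        if (grepl("^/gene=", q))
          cur$name <- gsub("\"", "", sub("^/gene=", "", q))
        if (q == "/pseudo") cur$pseudo <- TRUE
      } else if (!is.null(cur)) {                # location continuation
        cur$loc <- paste0(cur$loc, trimws(ln))
      }
    }
    f <- flush_cur(cur)
    if (!is.null(f)) feats[[length(feats) + 1L]] <- f
  }
  i_end <- grep("^//", lines)
  i_end <- if (length(i_end)) i_end[i_end > i_orig[1L]][1L] else length(lines) + 1L
  seq_lines <- lines[(i_orig[1L] + 1L):(i_end - 1L)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  genome_record(id, seq, circular = circular, features = feats)
}

## ---- public I/O ------------------------------------------------------------

#' Read a plastome from disk
#'
#' @param path FASTA or GenBank flat-file path.
#' @param format `"fasta"` (optionally with a GFF3 annotation via `gff`) or
#'   `"genbank"`.
#' @param gff Optional GFF3 path holding the annotation for a FASTA genome.
#' @param circular Assumed topology for FASTA input (GenBank records carry
#'   their own topology flag).
#' @param rotate_trnH Normalize the origin of circular genomes by rotating so
#'   that `trnH-GUG` (if annotated) starts at position 1. This conventional
#'   linearization makes coordinates comparable across individuals.
#' @return A [genome_record()].
#' @export
read_genome <- function(path, format = c("fasta", "genbank"), gff = NULL,
                        circular = TRUE, rotate_trnH = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  rec <- switch(format,
    fasta = read_fasta_genome(path, gff = gff, circular = circular),
    genbank = read_genbank(path))
  if (rotate_trnH) rec <- normalize_origin(rec)
  rec
}

#' Write a plastome to disk
#'
#' `read_genome(write_genome(rec))` is the identity on sequence and features.
#'
#' @param rec A [genome_record()].
#' @param path Output path (FASTA or GenBank).
#' @param format `"fasta"` or `"genbank"`.
#' @param gff Optional GFF3 path to write the annotation to (FASTA mode).
#' @return `path`, invisibly.
#' @export
write_genome <- function(rec, path, format = c("fasta", "genbank"),
                         gff = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "genome_record"))
  if (format == "fasta") {
    dss <- Biostrings::DNAStringSet(rec$seq)
    names(dss) <- rec$id
    Biostrings::writeXStringSet(dss, path)
    if (!is.null(gff)) write_gff3_features(rec, gff)
  } else {
    write_genbank(rec, path)
  }
  invisible(path)
}
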