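# structure_compare: compare a reduced plastome against a quadripartite
# reference -- inverted-repeat presence, missing gene segments, pseudogene
# calls, and summary tables.

#' Locate the inverted repeat of a genome
#'
#' Finds the longest pair of disjoint intervals where one equals the reverse
#' complement of the other, by exact k-mer seed matching between the sequence
#' and its reverse complement followed by ungapped extension. The genome is
#' quadripartite when the longest such repeat reaches `min_ir`; assembled
#' plastome IR copies are near-identical, so exact seeds suffice.
#'
#' @param rec A [genome_record()] or nucleotide string.
#' @param min_ir Minimum repeat length in bp to call a true IR (default 1000,
#'   separating IRs from small dispersed repeats).
#' @param seed_k Seed k-mer length (default 21).
#' @param max_seed_hits Seeds occurring more often than this in either strand
#'   are skipped as low-complexity.
#' @return List with `ir_status` (`"quadripartite"` or `"ir_lacking"`),
#'   `intervals` (2x2 matrix, rows = the two repeat copies, columns
#'   start/end; `NULL` when nothing found) and `length` (bp of the longest
#'   inverted repeat, 0 when none).
#' @export
find_ir <- function(rec, min_ir = 1000L, seed_k = 21L, max_seed_hits = 10L) {
  s <- if (inherits(rec, "genome_record")) rec$seq else toupper(rec)
  n <- nchar(s)
  k <- as.integer(seed_k)
  empty <- list(ir_status = "ir_lacking", intervals = NULL, length = 0L)
  if (n < 2L * k) return(empty)
  r <- revcomp(s)
  sv <- chars(s); rv <- chars(r)
  pos <- seq_len(n - k + 1L)
  kms <- substring(s, pos, pos + k - 1L)
  kmr <- substring(r, pos, pos + k - 1L)
  idx_s <- split(pos, kms)
  idx_r <- split(pos, kmr)
  common <- intersect(names(idx_s), names(idx_r))
  hits_s <- idx_s[match(common, names(idx_s))]
  hits_r <- idx_r[match(common, names(idx_r))]
  best_len <- 0L
  best_iv <- NULL
  covered <- new.env(parent = emptyenv())   # per-diagonal covered end in i
  for (h in seq_along(common)) {
    is_ <- hits_s[[h]]
    js_ <- hits_r[[h]]
    if (length(is_) > max_seed_hits || length(js_) > max_seed_hits) next
    for (i in is_) for (j in js_) {
      dkey <- as.character(i - j)
      cov <- covered[[dkey]]
      if (!is.null(cov) && i <= cov) next
      a <- 0L
      while (i - a - 1L >= 1L && j - a - 1L >= 1L &&
             sv[i - a - 1L] == rv[j - a - 1L]) a <- a + 1L
      b <- 0L
      while (i + k + b <= n && j + k + b <= n &&
             sv[i + k + b] == rv[j + k + b]) b <- b + 1L
      i1 <- i - a; i2 <- i + k - 1L + b       # match interval in s
      j1 <- j - a; j2 <- j + k - 1L + b       # match interval in revcomp(s)
      covered[[dkey]] <- i2
      # interval of the second copy back on the forward strand
      m1 <- n - j2 + 1L; m2 <- n - j1 + 1L
      iv <- rbind(c(i1, i2), c(m1, m2))
      iv <- iv[order(iv[, 1L]), , drop = FALSE]
      if (iv[1L, 2L] >= iv[2L, 1L]) next      # overlapping: palindrome, not IR
      len <- i2 - i1 + 1L
      if (len > best_len) { best_len <- len; best_iv <- iv }
    }
  }
  if (is.null(best_iv)) return(empty)
  colnames(best_iv) <- c("start", "end")
  rownames(best_iv) <- c("IRa", "IRb")
  list(ir_status = if (best_len >= min_ir) "quadripartite" else "ir_lacking",
       intervals = best_iv, length = best_len)
}

# Bacterial/plastid genetic code (NCBI table 11), fetched once.
plastid_code <- local({
  code <- NULL
  function() {
    if (is.null(code)) code <<- Biostrings::getGeneticCode("11")
    code
  }
})

ordered_genes <- function(rec) {
  feats <- Filter(function(f) f$ftype != "intergenic", rec$features)
  feats[order(vapply(feats, feat_start, 0L))]
}

#' Missing gene segments of a query genome relative to a reference
#'
#' Builds the reference gene order and reports maximal runs of reference
#' genes absent from the query (by case-insensitive gene name), bounded by
#' shared genes. Each segment carries its reference interval and length, its
#' flanking shared gene names, and the contained gene names.
#'
#' @param ref,query Annotated [genome_record()] objects sharing gene
#'   nomenclature.
#' @return Data frame with `ref_start`, `ref_end`, `length`, `flank_left`,
#'   `flank_right`, `genes` (comma-separated contained genes).
#' @export
missing_segments <- function(ref, query) {
  rg <- ordered_genes(ref)
  qnames <- tolower(vapply(ordered_genes(query), `[[`, "", "name"))
  nm <- vapply(rg, `[[`, "", "name")
  present <- tolower(nm) %in% qnames
  if (sum(present) < 2L)
    stop("fewer than 2 shared genes between reference and query")
  runs <- true_runs(!present)
  if (nrow(runs) == 0L)
    return(data.frame(ref_start = integer(0), ref_end = integer(0),
                      length = integer(0), flank_left = character(0),
                      flank_right = character(0), genes = character(0)))
  ends <- vapply(rg, function(f) max(f$intervals[, "end"]), 0L)
  starts <- vapply(rg, feat_start, 0L)
  out <- lapply(seq_len(nrow(runs)), function(i) {
    a <- runs$start[i]; b <- runs$end[i]
    left <- if (a > 1L) nm[a - 1L] else NA_character_
    right <- if (b < length(nm)) nm[b + 1L] else NA_character_
    ref_s <- if (a > 1L) ends[a - 1L] + 1L else 1L
    ref_e <- if (b < length(nm)) starts[b + 1L] - 1L else genome_length(ref)
    data.frame(ref_start = ref_s, ref_end = ref_e,
               length = ref_e - ref_s + 1L, flank_left = left,
               flank_right = right,
               genes = paste(sort(nm[a:b]), collapse = ","))
  })
  do.call(rbind, out)
}

#' Call pseudogenes in a query genome relative to a reference
#'
#' A shared protein-coding gene is called a pseudogene when its observed
#' length falls below `min_intact_frac` of the reference length (truncation),
#' when its length is not a multiple of 3 (frameshift evidence), or when its
#' translation under the bacterial/plastid genetic code (table 11) contains a
#' premature stop. Evidence flags accumulate; any flag makes the call.
#'
#' @param ref,query Annotated [genome_record()] objects.
#' @param min_intact_frac Truncation threshold (default 0.9).
#' @return Data frame with `name`, `observed_length`, `reference_length`,
#'   `truncation`, `frameshift`, `premature_stop`, `pseudogene`.
#' @export
call_pseudogenes <- function(ref, query, min_intact_frac = 0.9) {
  ref_genes <- Filter(function(f) f$ftype == "gene", ref$features)
  ref_by_name <- split(ref_genes, tolower(vapply(ref_genes, `[[`, "", "name")))
  q_feats <- Filter(function(f) f$ftype %in% c("gene", "pseudogene"),
                    query$features)
  q_by_name <- split(q_feats, tolower(vapply(q_feats, `[[`, "", "name")))
  shared <- intersect(names(ref_by_name), names(q_by_name))
  out <- lapply(sort(shared), function(nm) {
    rf <- ref_by_name[[nm]][[1L]]
    qf <- q_by_name[[nm]][[1L]]
    obs <- feat_length(qf)
    refl <- feat_length(rf)
    trunc <- obs < min_intact_frac * refl
    fshift <- obs %% 3L != 0L
    pstop <- FALSE
    if (!fshift && obs >= 6L) {
      cds <- gsub("N", "A", feature_seq(query, qf), fixed = TRUE)
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(cds), genetic.code = plastid_code()))
      internal <- substr(aa, 1L, nchar(aa) - 1L)
      pstop <- grepl("*", internal, fixed = TRUE)
    }
    data.frame(name = qf$name, observed_length = obs,
               reference_length = refl, truncation = trunc,
               frameshift = fshift, premature_stop = pstop,
               pseudogene = trunc || fshift || pstop)
  })
  res <- do.call(rbind, out)
  res[res$pseudogene, , drop = FALSE]
}

#' Summarize an annotated plastome
#'
#' Genome size, GC content (percent, one decimal) and functional gene counts
#' by category. Pseudogenes are excluded from all counts; genes duplicated in
#' the inverted repeat are counted once (unique names).
#'
#' @param rec An annotated [genome_record()].
#' @return List of class `genome_summary` with `size_bp`, `gc_percent`,
#'   `n_genes`, `n_protein_coding`, `n_trna`, `n_rrna`.
#' @export
summarize_genome <- function(rec) {
  nm <- feature_names(rec)
  ft <- feature_types(rec)
  uniq <- !duplicated(paste(tolower(nm), ft))
  nm <- nm[uniq]; ft <- ft[uniq]
  n_cds <- sum(ft == "gene")
  n_trna <- sum(ft == "tRNA")
  n_rrna <- sum(ft == "rRNA")
  structure(list(id = rec$id, size_bp = genome_length(rec),
                 gc_percent = round(100 * gc_content(rec), 1L),
                 n_genes = n_cds + n_trna + n_rrna,
                 n_protein_coding = n_cds, n_trna = n_trna, n_rrna = n_rrna),
            class = "genome_summary")
}

#' @export
print.genome_summary <- function(x, ...) {
  cat(sprintf(paste0("<genome_summary> %s: %s bp, GC %.1f%%, %d functional",
                     " genes (%d protein-coding, %d tRNA, %d rRNA)\n"),
              x$id, format(x$size_bp, big.mark = ","), x$gc_percent,
              x$n_genes, x$n_protein_coding, x$n_trna, x$n_rrna))
  invisible(x)
}

#' Full structural comparison of a query genome against a reference
#'
#' @param ref,query Annotated [genome_record()] objects.
#' @param min_ir,min_intact_frac See [find_ir()] and [call_pseudogenes()].
#' @return List of class `structural_diff` with `ir_status`, `ir` (the
#'   [find_ir()] result on the query), `missing_segments`, `pseudogenes`,
#'   `lost_genes` (reference gene names absent from the query).
#' @export
structure_compare <- function(ref, query, min_ir = 1000L,
                              min_intact_frac = 0.9) {
  ir <- find_ir(query, min_ir = min_ir)
  segs <- missing_segments(ref, query)
  pseudo <- call_pseudogenes(ref, query, min_intact_frac = min_intact_frac)
  qn <- tolower(feature_names(query))
  lost <- sort(unique(feature_names(ref)[!tolower(feature_names(ref)) %in% qn]))
  structure(list(ir_status = ir$ir_status, ir = ir, missing_segments = segs,
                 pseudogenes = pseudo, lost_genes = lost),
            class = "structural_diff")
}

#' @export
print.structural_diff <- function(x, ...) {
  cat("<structural_diff>", x$ir_status, "\n")
  cat(sprintf("  %d missing segment(s), %d lost gene(s), %d pseudogene(s)\n",
              nrow(x$missing_segments), length(x$lost_genes),
              nrow(x$pseudogenes)))
  for (i in seq_len(nrow(x$missing_segments))) {
    s <- x$missing_segments[i, ]
    cat(sprintf("  segment %d: %s bp flanked by %s and %s, containing %s\n",
                i, format(s$length, big.mark = ","), s$flank_left,
                s$flank_right, s$genes))
  }
  invisible(x)
}
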