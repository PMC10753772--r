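# inversion_hairpin: detect micro-inversions between aligned plastomes and
# characterize the flanking inverted-repeat (hairpin stem) structure.
#
# A micro-inversion shows up between two rows as a maximal run of mismatching
# columns whose segment on one row equals the reverse complement of the other
# row's segment. The inverted segment is the hairpin loop; the flanking
# inverted-repeat pair in the genome is the stem.

#' Find micro-inversions between two alignment rows
#'
#' Scans maximal runs of mismatching, gap-free columns and reports those where
#' the segment of `rowA` equals the reverse complement of the segment of
#' `rowB` (identity is excluded). Runs longer than `max_len` are still
#' reported, flagged out-of-range.
#'
#' @param aln A [alignment()].
#' @param rowA,rowB Row labels.
#' @param min_len,max_len Loop length range in bp (defaults 2 and 46).
#' @return Data frame with `start`, `end` (aligned columns), `length`,
#'   `seq_a`, `seq_b` and `out_of_range`.
#' @export
find_inversions <- function(aln, rowA, rowB, min_len = 2L, max_len = 46L) {
  a <- chars(aln_row(aln, rowA))
  b <- chars(aln_row(aln, rowB))
  mism <- a != b & a != "-" & b != "-" & a != "N" & b != "N"
  runs <- true_runs(mism)
  out <- list()
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i]; e <- runs$end[i]
    if (e - s + 1L < min_len) next
    sa <- str_from(a[s:e]); sb <- str_from(b[s:e])
    if (sa != sb && sa == revcomp(sb))
      out[[length(out) + 1L]] <- data.frame(
        start = s, end = e, length = e - s + 1L, seq_a = sa, seq_b = sb,
        out_of_range = (e - s + 1L) > max_len)
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), seq_a = character(0),
                      seq_b = character(0), out_of_range = logical(0)))
  do.call(rbind, out)
}

#' Find the hairpin stem flanking an inversion locus
#'
#' Searches for the longest pair of windows -- one ending at most
#' `max_gap_to_loop` bp before the interval, one starting at most
#' `max_gap_to_loop` bp after -- such that the upstream window equals the
#' reverse complement of the downstream window up to `max_mismatch`
#' mismatches. Ties are broken by longer stem, then smaller total gap to the
#' loop, then leftmost upstream window. Both stems are reported as read 5'->3'
#' on the forward strand.
#'
#' @param x A [genome_record()] or a plain nucleotide string.
#' @param interval Length-2 integer vector: 1-based inclusive loop interval.
#' @param min_stem,max_stem Stem length range in bp (defaults 3 and 23).
#' @param max_mismatch Maximum tolerated stem mismatches (default 0).
#' @param max_gap_to_loop Maximum distance in bp between stem and loop.
#' @return List with `found`, `upstream_stem`, `downstream_stem`,
#'   `stem_length`, `n_mismatches`, `gap_upstream`, `gap_downstream`. When no
#'   stem of at least `min_stem` bp exists the result has `found = FALSE`
#'   (not an error).
#' @export
find_stems <- function(x, interval, min_stem = 3L, max_stem = 23L,
                       max_mismatch = 0L, max_gap_to_loop = 5L) {
  s <- if (inherits(x, "genome_record")) x$seq else toupper(x)
  L <- nchar(s)
  lo <- as.integer(interval[1L]); hi <- as.integer(interval[2L])
  stopifnot(lo >= 1L, hi >= lo, hi <= L)
  no_stem <- list(found = FALSE, upstream_stem = NA_character_,
                  downstream_stem = NA_character_, stem_length = 0L,
                  n_mismatches = NA_integer_, gap_upstream = NA_integer_,
                  gap_downstream = NA_integer_)
  best <- no_stem
  for (k in seq(max_stem, min_stem)) {
    for (gap_total in 0:(2L * max_gap_to_loop)) {
      for (gu in max(0L, gap_total - max_gap_to_loop):min(gap_total, max_gap_to_loop)) {
        gd <- gap_total - gu
        ue <- lo - 1L - gu
        us <- ue - k + 1L
        ds <- hi + 1L + gd
        de <- ds + k - 1L
        if (us < 1L || de > L) next
        up <- substr(s, us, ue)
        dn <- substr(s, ds, de)
        mm <- sum(chars(up) != chars(revcomp(dn)))
        if (mm <= max_mismatch) {
          return(list(found = TRUE, upstream_stem = up, downstream_stem = dn,
                      stem_length = k, n_mismatches = mm, gap_upstream = gu,
                      gap_downstream = gd))
        }
      }
    }
  }
  best
}

#' Label a genomic interval by its annotation context
#'
#' @param interval Length-2 vector (1-based inclusive); the midpoint is used.
#' @param features List of [feature_record()] objects.
#' @return `"gene"` when the midpoint lies inside a gene, `"gene intron"`
#'   between two intervals of one multi-interval feature, `"geneX-geneY"` for
#'   the spacer between the nearest flanking genes, or
#'   `"unlabeled:<start>-<end>"` when no annotation is available.
#' @export
label_location <- function(interval, features) {
  lo <- as.integer(interval[1L]); hi <- as.integer(interval[length(interval)])
  mid <- (lo + hi) %/% 2L
  feats <- Filter(function(f) f$ftype != "intergenic", features)
  if (length(feats) == 0L) return(sprintf("unlabeled:%d-%d", lo, hi))
  for (f in feats) {
    iv <- f$intervals
    if (any(mid >= iv[, "start"] & mid <= iv[, "end"]))
      return(f$name)
    if (nrow(iv) > 1L) {
      ivo <- iv[order(iv[, "start"]), , drop = FALSE]
      for (i in seq_len(nrow(ivo) - 1L))
        if (mid > ivo[i, "end"] && mid < ivo[i + 1L, "start"])
          return(paste(f$name, "intron"))
    }
  }
  starts <- vapply(feats, feat_start, 0L)
  ends <- vapply(feats, function(f) max(f$intervals[, "end"]), 0L)
  left <- which(ends < mid)
  right <- which(starts > mid)
  left_nm <- if (length(left) > 0L) feats[[left[which.max(ends[left])]]]$name else NA
  right_nm <- if (length(right) > 0L) feats[[right[which.min(starts[right])]]]$name else NA
  if (is.na(left_nm) || is.na(right_nm))
    return(sprintf("unlabeled:%d-%d", lo, hi))
  paste0(left_nm, "-", right_nm)
}

#' Build a hairpin record table for detected inversions
#'
#' Maps each inversion from aligned coordinates onto a reference row's genome,
#' finds the flanking stems, and labels the location -- one record per
#' inversion, mirroring the standard published layout (location, loop motif,
#' size, upstream and downstream stem).
#'
#' @param inversions Result of [find_inversions()].
#' @param aln The [alignment()] used for detection.
#' @param ref_label Reference row label (the row whose genome provides
#'   coordinates, stems and annotation).
#' @param rec [genome_record()] of the reference row (annotated; may be
#'   `NULL`, in which case locations are unlabeled and stems are searched on
#'   the degapped row itself).
#' @param ... Passed to [find_stems()].
#' @return Data frame with `no`, `location`, `loop_motif`, `loop_size`,
#'   `upstream_stem`, `downstream_stem`, `stem_length`, `n_mismatches`.
#' @export
characterize_inversions <- function(inversions, aln, ref_label, rec = NULL,
                                    ...) {
  u <- aligned_to_ungapped(aln, ref_label)
  seq <- if (!is.null(rec)) rec$seq else degap(aln_row(aln, ref_label))
  feats <- if (!is.null(rec)) rec$features else list()
  n <- nrow(inversions)
  out <- data.frame(no = seq_len(n), location = character(n),
                    loop_motif = character(n), loop_size = integer(n),
                    upstream_stem = character(n),
                    downstream_stem = character(n), stem_length = integer(n),
                    n_mismatches = integer(n))
  for (i in seq_len(n)) {
    us <- u[inversions$start[i]]; ue <- u[inversions$end[i]]
    st <- find_stems(seq, c(us, ue), ...)
    out$location[i] <- label_location(c(us, ue), feats)
    out$loop_motif[i] <- substr(seq, us, ue)
    out$loop_size[i] <- ue - us + 1L
    out$upstream_stem[i] <- st$upstream_stem
    out$downstream_stem[i] <- st$downstream_stem
    out$stem_length[i] <- st$stem_length
    out$n_mismatches[i] <- if (st$found) st$n_mismatches else NA_integer_
  }
  out
}

## ---- bundled hairpin records ----------------------------------------------

#' Published hairpin records of the eight Cassytha plastomes
#'
#' The 24 predicted hairpin loop/stem records (location, loop motif, size,
#' upstream and downstream stem) reported for micro-inversions across eight
#' Cassytha plastomes, bundled as a plain-text table.
#'
#' @return Data frame with `no`, `location`, `loop_motif`, `loop_size`,
#'   `upstream_stem`, `downstream_stem`.
#' @export
cassytha_hairpins <- function() {
  path <- system.file("extdata", "cassytha_hairpins.tsv",
                      package = "plastocomp", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$loop_size <- as.integer(df$loop_size)
  df
}

#' Validate hairpin records against the palindrome rule
#'
#' Checks, for every record, that the upstream stem equals the reverse
#' complement of the downstream stem up to `max_mismatch` mismatches. Records
#' failing the rule are reported, not altered.
#'
#' @param records Data frame as returned by [cassytha_hairpins()].
#' @param max_mismatch Allowed stem mismatches (default 0: exact palindromes).
#' @return `records` with `stem_length`, `n_stem_mismatches` and `palindromic`
#'   columns appended.
#' @export
validate_hairpins <- function(records, max_mismatch = 0L) {
  stopifnot(all(c("upstream_stem", "downstream_stem") %in% names(records)))
  up <- toupper(records$upstream_stem)
  dn <- toupper(records$downstream_stem)
  if (any(nchar(up) != nchar(dn)))
    stop("stem pair lengths differ in rows: ",
         paste(which(nchar(up) != nchar(dn)), collapse = ", "))
  mm <- mapply(function(u, d) sum(chars(u) != chars(revcomp(d))), up, dn)
  records$stem_length <- nchar(up)
  records$n_stem_mismatches <- as.integer(mm)
  records$palindromic <- mm <= max_mismatch
  records
}
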