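# msa_variants: call substitutions and indel events from a multiple
# alignment, classify indels as SSR vs non-SSR, and tally the mutation
# spectrum. Indels are counted as events (maximal runs of columns sharing one
# gap pattern), not as gap columns.

subset_matrix <- function(aln, subset) {
  if (is.null(subset)) subset <- aln$labels
  if (!all(subset %in% aln$labels))
    stop("subset contains unknown labels: ",
         paste(setdiff(subset, aln$labels), collapse = ", "))
  if (length(subset) < 2L) stop("subset must contain at least 2 rows")
  aln_char_matrix(aln$rows[subset])
}

#' Call substitutions from an alignment
#'
#' One substitution per polymorphic column among the subset. Columns with a
#' gap in any subset row are excluded (they belong to indel events); `N` is
#' treated as missing and never makes a column polymorphic. Columns inside
#' called micro-inversions should be passed via `exclude_columns` so inversion
#' mismatches are not double-counted as SNPs.
#'
#' @param aln A [alignment()].
#' @param subset Optional character vector of row labels (default: all rows).
#' @param exclude_columns Integer vector of aligned columns to skip.
#' @return Data frame with `column`, `states` (comma-separated `label=base`)
#'   and `pattern` (the base carried by each subset row, in subset order).
#' @export
call_substitutions <- function(aln, subset = NULL, exclude_columns = integer(0)) {
  m <- subset_matrix(aln, subset)
  has_gap <- colSums(m == "-") > 0L
  n_states <- (colSums(m == "A") > 0L) + (colSums(m == "C") > 0L) +
    (colSums(m == "G") > 0L) + (colSums(m == "T") > 0L)
  poly <- !has_gap & n_states >= 2L
  if (length(exclude_columns) > 0L) poly[exclude_columns] <- FALSE
  cols <- which(poly)
  if (length(cols) == 0L)
    return(data.frame(column = integer(0), states = character(0),
                      pattern = character(0)))
  data.frame(
    column = cols,
    states = vapply(cols, function(j)
      paste(rownames(m), m[, j], sep = "=", collapse = ","), ""),
    pattern = vapply(cols, function(j) paste(m[, j], collapse = ""), ""))
}

#' Call indel events from an alignment
#'
#' An indel event is a maximal run of columns whose gap/non-gap row pattern is
#' identical; adjacent columns with different bearer patterns are distinct
#' events. The fragment is read from the first gap-free row over the event
#' columns.
#'
#' @inheritParams call_substitutions
#' @return Data frame with `start`, `end` (aligned columns, inclusive),
#'   `bearers` (comma-separated labels of the rows carrying gaps), `fragment`
#'   and `length`.
#' @export
call_indels <- function(aln, subset = NULL) {
  m <- subset_matrix(aln, subset)
  gap <- m == "-"
  pattern <- do.call(paste0, as.data.frame(t(gap) + 0L))
  pattern[!grepl("1", pattern, fixed = TRUE)] <- ""
  r <- rle(pattern)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != ""
  if (!any(keep))
    return(data.frame(start = integer(0), end = integer(0),
                      bearers = character(0), fragment = character(0),
                      length = integer(0)))
  starts <- starts[keep]; ends <- ends[keep]; pats <- r$values[keep]
  bearers <- vapply(pats, function(p)
    paste(sort(rownames(m)[strsplit(p, "", fixed = TRUE)[[1L]] == "1"]),
          collapse = ","), "", USE.NAMES = FALSE)
  frag <- vapply(seq_along(starts), function(i) {
    carriers <- which(!gap[, starts[i]])
    degap(paste(m[carriers[1L], starts[i]:ends[i]], collapse = ""))
  }, "")
  data.frame(start = starts, end = ends, bearers = bearers,
             fragment = frag, length = nchar(frag))
}

#' Classify an indel event as SSR or non-SSR
#'
#' An event is an SSR (slipped-strand) indel when its fragment is an integer
#' number of copies of some motif of length `1..max_motif` and at least
#' `min_extra_copies` adjacent copies of that motif flank the event site in
#' the ungapped sequence of a gap-free row. The smallest qualifying motif is
#' reported.
#'
#' @param event One row of the [call_indels()] result (a list or 1-row data
#'   frame with `start`, `end`, `bearers`).
#' @param aln The [alignment()] the event was called from.
#' @param subset Subset used for calling (default: all rows).
#' @param max_motif Maximum motif length in bp.
#' @param min_extra_copies Minimum adjacent flanking copies required.
#' @return List with `ssr_class` (`"SSR"` or `"non-SSR"`) and `motif`
#'   (`NA` for non-SSR).
#' @export
classify_ssr <- function(event, aln, subset = NULL, max_motif = 6L,
                         min_extra_copies = 1L) {
  if (is.null(subset)) subset <- aln$labels
  bearers <- strsplit(event$bearers, ",")[[1L]]
  carrier <- setdiff(subset, bearers)[1L]
  if (is.na(carrier)) stop("event has no gap-free row")
  row <- aln$rows[[carrier]]
  u <- aligned_to_ungapped(aln, carrier)
  us <- u[event$start]; ue <- u[event$end]
  ug <- degap(row)
  fragment <- substr(ug, us, ue)
  left <- substr(ug, max(1L, us - 10L * max_motif), us - 1L)
  right <- substr(ug, ue + 1L, min(nchar(ug), ue + 10L * max_motif))
  motif <- ssr_motif_of(fragment, left, right, max_motif, min_extra_copies)
  if (is.null(motif)) list(ssr_class = "non-SSR", motif = NA_character_)
  else list(ssr_class = "SSR", motif = motif)
}

#' Classify all indel events of an alignment
#'
#' @param indels Result of [call_indels()].
#' @inheritParams classify_ssr
#' @return `indels` with `ssr_class` and `motif` columns appended.
#' @export
classify_indels <- function(indels, aln, subset = NULL, max_motif = 6L,
                            min_extra_copies = 1L) {
  if (nrow(indels) == 0L) {
    indels$ssr_class <- character(0)
    indels$motif <- character(0)
    return(indels)
  }
  cls <- lapply(seq_len(nrow(indels)), function(i)
    classify_ssr(indels[i, ], aln, subset, max_motif, min_extra_copies))
  indels$ssr_class <- vapply(cls, `[[`, "", "ssr_class")
  indels$motif <- vapply(cls, `[[`, "", "motif")
  indels
}

#' Tally the mutation spectrum
#'
#' @param substitutions,indels,inversions Event data frames (from
#'   [call_substitutions()], [call_indels()], [find_inversions()]) or bare
#'   counts.
#' @return List of class `mutation_tally` with `n_substitutions`, `n_indels`,
#'   `n_ssr_indels`, `n_nonssr_indels`, `n_inversions` and `total`.
#' @export
tally_mutations <- function(substitutions, indels, inversions) {
  count_of <- function(x) if (is.data.frame(x)) nrow(x) else as.integer(x)
  n_sub <- count_of(substitutions)
  n_ind <- count_of(indels)
  n_inv <- count_of(inversions)
  n_ssr <- if (is.data.frame(indels) && "ssr_class" %in% names(indels))
    sum(indels$ssr_class == "SSR") else NA_integer_
  structure(list(n_substitutions = n_sub, n_indels = n_ind,
                 n_ssr_indels = n_ssr,
                 n_nonssr_indels = if (is.na(n_ssr)) NA_integer_
                                   else n_ind - n_ssr,
                 n_inversions = n_inv,
                 total = n_sub + n_ind + n_inv),
            class = "mutation_tally")
}

#' @export
print.mutation_tally <- function(x, ...) {
  cat(sprintf(
    "<mutation_tally> %d substitutions + %d indels + %d micro-inversions = %d sites\n",
    x$n_substitutions, x$n_indels, x$n_inversions, x$total))
  if (!is.na(x$n_ssr_indels))
    cat(sprintf("  indels: %d SSR, %d non-SSR\n", x$n_ssr_indels,
                x$n_nonssr_indels))
  invisible(x)
}

#' Write called events as a per-event TSV
#'
#' @param substitutions,indels,inversions Event data frames.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_event_tsv <- function(substitutions, indels, inversions, path) {
  blank <- function(n, what) rep(what, n)
  ev <- rbind(
    data.frame(type = blank(nrow(substitutions), "substitution"),
               aligned_start = substitutions$column,
               aligned_end = substitutions$column,
               bearers = "", fragment = "",
               ssr_class = "", motif = ""),
    data.frame(type = blank(nrow(indels), "indel"),
               aligned_start = indels$start, aligned_end = indels$end,
               bearers = indels$bearers, fragment = indels$fragment,
               ssr_class = indels$ssr_class %||% "",
               motif = ifelse(is.na(indels$motif %||% NA), "", indels$motif)),
    data.frame(type = blank(nrow(inversions), "inversion"),
               aligned_start = inversions$start, aligned_end = inversions$end,
               bearers = "", fragment = inversions$seq_a,
               ssr_class = "", motif = ""))
  ev <- ev[order(ev$aligned_start), , drop = FALSE]
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
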