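# Gapped multiple alignments over {A,C,G,T,N,-} with per-row coordinate maps.

#' Create a multiple alignment
#'
#' @param rows Named character vector of equal-length gapped sequences over
#'   `{A,C,G,T,N,-}` (case-insensitive).
#' @return An object of class `plastome_alignment` with elements `labels`,
#'   `rows` (named uppercase strings) and `ncol`.
#' @export
alignment <- function(rows) {
  stopifnot(is.character(rows), length(rows) >= 2L, !is.null(names(rows)),
            !anyDuplicated(names(rows)))
  rows <- toupper(rows)
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("alignment rows differ in length")
  if (w == 0L) stop("empty alignment")
  if (any(grepl("[^ACGTN-]", rows)))
    stop("alignment contains characters outside {A,C,G,T,N,-}")
  m <- aln_char_matrix(rows)
  if (any(colSums(m != "-") == 0L)) stop("alignment has an all-gap column")
  if (any(vapply(rows, function(r) nchar(gsub("-", "", r)) == 0L, TRUE)))
    stop("alignment has an all-gap row")
  structure(list(labels = names(rows), rows = rows, ncol = w),
            class = "plastome_alignment")
}

aln_char_matrix <- function(rows) {
  m <- do.call(rbind, strsplit(unname(rows), "", fixed = TRUE))
  rownames(m) <- names(rows)
  m
}

#' @export
print.plastome_alignment <- function(x, ...) {
  cat(sprintf("<plastome_alignment> %d rows x %d columns\n",
              length(x$labels), x$ncol))
  invisible(x)
}

#' Remove gaps from a sequence
#' @param s Character vector of (possibly gapped) sequences.
#' @return Sequences with `-` removed.
#' @export
degap <- function(s) gsub("-", "", s, fixed = TRUE)

aln_row <- function(aln, label) {
  if (!label %in% aln$labels) stop("no such row: ", label)
  aln$rows[[label]]
}

#' Map aligned columns to ungapped positions
#'
#' @param aln A [alignment()].
#' @param label Row label.
#' @return Integer vector of length `aln$ncol`: for each aligned column the
#'   1-based position in the degapped row, `NA` at gap columns.
#' @export
aligned_to_ungapped <- function(aln, label) {
  v <- chars(aln_row(aln, label))
  idx <- cumsum(v != "-")
  idx[v == "-"] <- NA_integer_
  as.integer(idx)
}

#' Map ungapped positions to aligned columns
#'
#' @inheritParams aligned_to_ungapped
#' @return Integer vector over the degapped row's positions giving the aligned
#'   column of each base.
#' @export
ungapped_to_aligned <- function(aln, label) {
  v <- chars(aln_row(aln, label))
  which(v != "-")
}

#' Read an aligned FASTA file
#' @param path Aligned-FASTA path.
#' @return A [alignment()].
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  rows <- as.character(ss)
  names(rows) <- sub("\\s.*$", "", names(ss))
  alignment(rows)
}

#' Write an alignment as aligned FASTA
#' @param aln A [alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  ss <- Biostrings::BStringSet(aln$rows)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
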