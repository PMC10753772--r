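# diversity_stats: nucleotide diversity in sliding windows and by group,
# pairwise divergence matrices, and hotspot naming.
#
# Divergence is the uncorrected p-distance by default: at the divergence
# scale of conspecific plastomes (1e-5 .. 1e-2) multiple-hit correction is
# numerically negligible. Jukes-Cantor is available as an option.

#' Pairwise divergence between two alignment rows
#'
#' p-distance with pairwise deletion: columns where either row has a gap or
#' `N` are excluded; the distance is (differing columns) / (comparable
#' columns).
#'
#' @param aln A [alignment()].
#' @param labelA,labelB Row labels.
#' @param model `"p"` (uncorrected, default) or `"JC69"`.
#' @return Divergence as a fraction.
#' @export
pairwise_divergence <- function(aln, labelA, labelB, model = c("p", "JC69")) {
  model <- match.arg(model)
  a <- chars(aln_row(aln, labelA))
  b <- chars(aln_row(aln, labelB))
  ok <- a != "-" & b != "-" & a != "N" & b != "N"
  n <- sum(ok)
  if (n == 0L) stop("no comparable columns between ", labelA, " and ", labelB)
  p <- sum(a[ok] != b[ok]) / n
  if (model == "JC69") {
    if (p >= 0.75) stop("p-distance >= 0.75: JC69 undefined")
    p <- -3 / 4 * log(1 - 4 * p / 3)
  }
  p
}

#' Nucleotide diversity of a set of rows
#'
#' pi: the mean over all unordered row pairs of per-site differences, under
#' complete deletion -- only columns free of gaps and `N` across the whole
#' subset (within `interval`) are evaluated.
#'
#' @param aln A [alignment()].
#' @param subset Row labels (default: all; at least 2).
#' @param interval Optional aligned-column interval `c(start, end)`,
#'   1-based inclusive.
#' @param exclude_columns Aligned columns to drop from the computation
#'   (typically columns of called micro-inversions, whose mismatches are
#'   inversion events, not substitutional diversity).
#' @return List with `pi` (fraction, `NA` when no net sites) and `net_sites`.
#' @export
nucleotide_diversity <- function(aln, subset = NULL, interval = NULL,
                                 exclude_columns = integer(0)) {
  m <- subset_matrix(aln, subset)
  cols <- seq_len(ncol(m))
  if (!is.null(interval)) {
    stopifnot(length(interval) == 2L, interval[1L] >= 1L,
              interval[2L] <= ncol(m))
    cols <- interval[1L]:interval[2L]
    m <- m[, cols, drop = FALSE]
  }
  n <- nrow(m)
  cd <- column_diffs(m)
  clean <- cd$clean & !(cols %in% exclude_columns)
  net <- sum(clean)
  if (net == 0L) return(list(pi = NA_real_, net_sites = 0L))
  npairs <- n * (n - 1L) / 2L
  list(pi = sum(cd$diffs[clean]) / (npairs * net), net_sites = net)
}

# Per-column pairwise difference counts via state counts:
# diff pairs = C(n,2) - sum_b C(count_b, 2); `clean` marks columns free of
# gaps and N across all rows.
column_diffs <- function(m) {
  n <- nrow(m)
  npairs <- n * (n - 1) / 2
  same <- 0
  for (b in c("A", "C", "G", "T")) {
    cb <- colSums(m == b)
    same <- same + cb * (cb - 1) / 2
  }
  clean <- colSums(m == "-" | m == "N") == 0L
  list(diffs = npairs - same, clean = clean)
}

#' Sliding-window nucleotide diversity
#'
#' Windows start at column 1 and advance by `step` over aligned coordinates;
#' the last window is truncated at the alignment end. The window/step defaults
#' (600/200 bp) follow common practice for plastome divergence scans.
#'
#' @param aln A [alignment()].
#' @param subset Row labels (default: all).
#' @param window Window length in aligned columns (default 600).
#' @param step Step size in aligned columns (default 200).
#' @param exclude_columns See [nucleotide_diversity()].
#' @return Data frame with `start`, `end`, `net_sites`, `pi`.
#' @export
sliding_pi <- function(aln, subset = NULL, window = 600L, step = 200L,
                       exclude_columns = integer(0)) {
  stopifnot(window >= step, step >= 1L)
  m <- subset_matrix(aln, subset)
  nr <- nrow(m)
  npairs <- nr * (nr - 1) / 2
  cd <- column_diffs(m)
  clean <- cd$clean
  if (length(exclude_columns) > 0L) clean[exclude_columns] <- FALSE
  wdiff <- ifelse(clean, cd$diffs, 0)
  n <- aln$ncol
  starts <- seq(1L, n, by = as.integer(step))
  ends <- pmin(starts + as.integer(window) - 1L, n)
  cum_net <- c(0L, cumsum(clean))
  cum_diff <- c(0, cumsum(wdiff))
  net <- cum_net[ends + 1L] - cum_net[starts]
  diffs <- cum_diff[ends + 1L] - cum_diff[starts]
  data.frame(start = starts, end = ends, net_sites = net,
             pi = ifelse(net > 0L, diffs / (npairs * net), NA_real_))
}

#' Pairwise divergence matrix over alignment rows
#'
#' @param aln A [alignment()].
#' @param subset Row labels (default: all).
#' @param model See [pairwise_divergence()].
#' @return Symmetric labeled matrix with zero diagonal.
#' @export
distance_matrix <- function(aln, subset = NULL, model = c("p", "JC69")) {
  model <- match.arg(model)
  if (is.null(subset)) subset <- aln$labels
  n <- length(subset)
  m <- matrix(0, n, n, dimnames = list(subset, subset))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- pairwise_divergence(aln, subset[i], subset[j], model)
    m[i, j] <- d; m[j, i] <- d
  }
  m
}

#' Read a labeled distance matrix from TSV
#' @param path TSV with a `label` column and one column per label.
#' @return Symmetric labeled matrix.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  labels <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- labels
  storage.mode(m) <- "double"
  if (!identical(rownames(m), colnames(m)))
    stop("matrix row/column labels disagree")
  if (any(abs(m - t(m)) > 1e-12)) stop("matrix is not symmetric")
  m
}

#' Write a labeled distance matrix as TSV
#' @param m Labeled matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(m, path) {
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Published pairwise divergences of the eight Cassytha plastomes
#'
#' The 8x8 pairwise nucleotide divergence matrix of four C. larsenii and four
#' C. filiformis plastomes, bundled as a plain-text table, with the species
#' partition of its accessions.
#'
#' @return List with `matrix` (labeled 8x8) and `partition` (named character
#'   vector label -> species).
#' @export
cassytha_divergence <- function() {
  path <- system.file("extdata", "cassytha_divergence.tsv",
                      package = "plastocomp", mustWork = TRUE)
  m <- read_distance_matrix(path)
  filiformis <- c("OR766688", "OR766689", "OR766690", "OR766691")
  partition <- ifelse(rownames(m) %in% filiformis, "C_filiformis",
                      "C_larsenii")
  names(partition) <- rownames(m)
  list(matrix = m, partition = partition)
}

#' Within/between-group divergence summary
#'
#' @param m Labeled symmetric divergence matrix.
#' @param partition Named character vector mapping each label to its group;
#'   must define at least two groups with at least two labels each.
#' @return List with `mean_within`, `mean_between` and `ratio`
#'   (`mean_between / mean_within`; `NA` when `mean_within` is 0).
#' @export
group_summary <- function(m, partition) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  labels <- rownames(m)
  if (!all(labels %in% names(partition)))
    stop("partition does not cover all matrix labels")
  grp <- partition[labels]
  if (length(unique(grp)) < 2L)
    stop("partition defines a single group")
  if (any(table(grp) < 2L))
    stop("every group needs at least 2 labels")
  within <- c(); between <- c()
  n <- length(labels)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (grp[i] == grp[j]) within <- c(within, m[i, j])
    else between <- c(between, m[i, j])
  }
  mw <- mean(within); mb <- mean(between)
  list(mean_within = mw, mean_between = mb,
       ratio = if (mw == 0) NA_real_ else mb / mw,
       n_within = length(within), n_between = length(between))
}

#' Name the top diversity hotspot regions
#'
#' Ranks windows by pi (ties broken leftmost), merges overlapping top
#' windows, and labels each merged region via [label_location()] at its
#' midpoint, mapped through a reference row's coordinates when an alignment
#' and reference are supplied.
#'
#' @param windows Result of [sliding_pi()].
#' @param features Annotation of the reference genome (list of
#'   [feature_record()]); empty list gives coordinate-only labels.
#' @param k Number of top windows considered (default 5).
#' @param aln,ref_label Optional alignment and reference row used to map
#'   aligned window coordinates onto the reference genome.
#' @param min_net_sites Windows with fewer gap-free sites are not ranked
#'   (default 100): a truncated terminal window of a handful of sites would
#'   otherwise dominate the per-site ranking on noise alone.
#' @return Character vector of location labels (at most `k`; only windows
#'   with pi > 0 are eligible).
#' @export
name_hotspots <- function(windows, features, k = 5L, aln = NULL,
                          ref_label = NULL, min_net_sites = 100L) {
  w <- windows[!is.na(windows$pi) & windows$pi > 0 &
                 windows$net_sites >= min_net_sites, , drop = FALSE]
  if (nrow(w) == 0L) return(character(0))
  w <- w[order(-w$pi, w$start), , drop = FALSE]
  top <- w[seq_len(min(k, nrow(w))), , drop = FALSE]
  top <- top[order(top$start), , drop = FALSE]
  # merge overlapping top windows
  merged <- list()
  cur <- c(top$start[1L], top$end[1L])
  for (i in seq_len(nrow(top))[-1L]) {
    if (top$start[i] <= cur[2L]) cur[2L] <- max(cur[2L], top$end[i])
    else { merged[[length(merged) + 1L]] <- cur; cur <- c(top$start[i], top$end[i]) }
  }
  merged[[length(merged) + 1L]] <- cur
  u <- if (!is.null(aln) && !is.null(ref_label))
    aligned_to_ungapped(aln, ref_label) else NULL
  vapply(merged, function(iv) {
    if (!is.null(u)) {
      pos <- u[iv[1L]:iv[2L]]
      pos <- pos[!is.na(pos)]
      if (length(pos) == 0L) return(sprintf("unlabeled:%d-%d", iv[1L], iv[2L]))
      iv <- range(pos)
    }
    label_location(iv, features)
  }, "")
}
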