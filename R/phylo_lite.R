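# phylo_lite: distance-based tree construction (Saitou-Nei neighbor joining)
# and species-grouping checks. Trees are ape "phylo" objects; Newick I/O goes
# through ape.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration on a labeled symmetric distance matrix.
#' Ties in the Q criterion are broken deterministically by label order (the
#' lexicographically smallest pair of subtree lead labels wins). Negative
#' branch-length estimates are clamped to zero; the number of clamped edges is
#' stored in the tree's `clamped` attribute.
#'
#' @param m Labeled symmetric matrix with zero diagonal, n >= 3.
#' @return An unrooted `phylo` tree (package ape).
#' @export
neighbor_joining <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), !is.null(rownames(m)))
  if (nrow(m) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (any(abs(m - t(m)) > 1e-9)) stop("matrix is not symmetric")
  if (any(diag(m) != 0)) stop("matrix diagonal must be zero")
  labels <- rownames(m)
  D <- unname(m)
  node <- quote_newick(labels)   # newick fragment per active node
  lead <- labels                 # lexicographic lead leaf per active node
  clamped <- 0L
  clamp <- function(x) {
    if (x < 0) { clamped <<- clamped + 1L; 0 } else x
  }
  bl <- function(x) sprintf("%.12g", x)

  while (length(lead) > 3L) {
    n <- length(lead)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 0, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key <- paste(pmin(lead[cand[, 1L]], lead[cand[, 2L]]),
                 pmax(lead[cand[, 1L]], lead[cand[, 2L]]), sep = "\r")
    pick <- cand[order(key)[1L], ]
    i <- pick[[1L]]; j <- pick[[2L]]
    di <- clamp(D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2)))
    dj <- clamp(D[i, j] - D[i, j] / 2 - (r[i] - r[j]) / (2 * (n - 2)))
    new_node <- sprintf("(%s:%s,%s:%s)", node[i], bl(di), node[j], bl(dj))
    new_lead <- min(lead[i], lead[j])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    node <- c(node[keep], new_node)
    lead <- c(lead[keep], new_lead)
  }
  d12 <- D[1L, 2L]; d13 <- D[1L, 3L]; d23 <- D[2L, 3L]
  b1 <- clamp((d12 + d13 - d23) / 2)
  b2 <- clamp((d12 + d23 - d13) / 2)
  b3 <- clamp((d13 + d23 - d12) / 2)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", node[1L], bl(b1), node[2L], bl(b2),
                 node[3L], bl(b3))
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

# Quote labels per the Newick standard when they contain reserved characters.
quote_newick <- function(x) {
  bad <- grepl("[ \t()\\[\\]:;,']", x)
  x[bad] <- paste0("'", gsub("'", "''", x[bad]), "'")
  x
}

# Tip index sets below each node of a phylo tree (rooted view).
node_tipsets <- function(tree) {
  n <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

#' Does one tree edge separate the two groups of a partition?
#'
#' Reciprocal monophyly on an unrooted tree: true iff some edge splits the
#' leaves exactly into the partition's two groups.
#'
#' @param tree An unrooted `phylo` tree.
#' @param partition Named character vector leaf label -> group, exactly two
#'   groups covering all leaves.
#' @return Logical.
#' @export
is_reciprocally_monophyletic <- function(tree, partition) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (!all(tips %in% names(partition)))
    stop("partition does not cover all leaves")
  grp <- partition[tips]
  groups <- unique(grp)
  if (length(groups) != 2L) stop("partition must define exactly two groups")
  g1 <- sort(unname(which(grp == groups[1L])))
  desc <- node_tipsets(tree)
  for (k in seq_len(nrow(tree$edge))) {
    below <- sort(desc[[tree$edge[k, 2L]]])
    if (identical(below, g1) ||
        identical(below, sort(setdiff(seq_along(tips), g1))))
      return(TRUE)
  }
  FALSE
}
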