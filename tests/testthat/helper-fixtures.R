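# Shared fixtures: tiny alignments built in code, plus one cached synthetic
# study design so several test files can score callers against the same
# planted truth without re-simulating.

aln_of <- function(...) {
  rows <- c(...)
  if (is.null(names(rows)) || any(names(rows) == ""))
    names(rows) <- paste0("r", seq_along(rows))
  alignment(rows)
}

.sim_cache <- new.env(parent = emptyenv())

shared_sim <- function(seed = 1L) {
  key <- as.character(seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_plastomes(sim_config(seed = seed))
  .sim_cache[[key]]
}

# Independent brute-force SSR oracle: enumerate motif lengths and flank
# copies directly on the strings.
brute_ssr <- function(fragment, left, right, max_motif = 6L,
                      min_extra = 1L) {
  n <- nchar(fragment)
  for (ml in seq_len(min(max_motif, n))) {
    if (n %% ml != 0L) next
    motif <- substr(fragment, 1L, ml)
    pieces <- substring(fragment, seq(1L, n, ml), seq(ml, n, ml))
    if (!all(pieces == motif)) next
    copies <- 0L
    l <- left
    while (nchar(l) >= ml && substr(l, nchar(l) - ml + 1L, nchar(l)) == motif) {
      copies <- copies + 1L
      l <- substr(l, 1L, nchar(l) - ml)
    }
    r <- right
    while (nchar(r) >= ml && substr(r, 1L, ml) == motif) {
      copies <- copies + 1L
      r <- substr(r, ml + 1L, nchar(r))
    }
    if (copies >= min_extra) return(list(ssr = TRUE, motif = motif))
  }
  list(ssr = FALSE, motif = NA_character_)
}

# Independent brute-force nucleotide diversity: mean over unordered pairs of
# per-pair differences on columns gap/N-free across the whole subset.
brute_pi <- function(aln, subset = NULL, interval = NULL) {
  if (is.null(subset)) subset <- aln$labels
  m <- do.call(rbind, strsplit(unname(aln$rows[subset]), ""))
  if (!is.null(interval)) m <- m[, interval[1L]:interval[2L], drop = FALSE]
  clean <- apply(m, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, clean, drop = FALSE]
  if (ncol(m) == 0L) return(NA_real_)
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    tot <- tot + sum(m[i, ] != m[j, ])
  tot / (n * (n - 1L) / 2L) / ncol(m)
}
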