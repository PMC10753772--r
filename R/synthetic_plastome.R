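# synthetic_plastome: generate a quadripartite ancestor and derived
# individuals carrying planted mutations and structural reductions, with a
# machine-readable truth ledger. The emitted alignment is the truth alignment:
# event coordinates are exact, so variant callers can be scored at
# precision = recall = 1.

## ---- configuration ---------------------------------------------------------

#' Default structural reduction edits
#'
#' One inverted-repeat copy is deleted, two gene blocks (three ndh genes each)
#' are excised, and five ndh genes are truncated to pseudogenes. The kept
#' fractions follow the observed pseudogene/intact length ratios of reduced
#' Lauraceae plastomes (psi-ndhB 0.55, psi-ndhD 0.28, psi-ndhE 0.52,
#' psi-ndhF 0.14, psi-ndhH 0.46).
#'
#' @return List of edit descriptors understood by [apply_structural_edits()].
#' @export
default_structural_edits <- function() {
  list(
    list(op = "delete_ir_copy"),
    list(op = "delete_segment", genes = c("ndhC", "ndhK", "ndhJ")),
    list(op = "delete_segment", genes = c("ndhG", "ndhI", "ndhA")),
    list(op = "truncate_gene", gene = "ndhB", keep_frac = 0.55),
    list(op = "truncate_gene", gene = "ndhD", keep_frac = 0.28),
    list(op = "truncate_gene", gene = "ndhE", keep_frac = 0.52),
    list(op = "truncate_gene", gene = "ndhF", keep_frac = 0.14),
    list(op = "truncate_gene", gene = "ndhH", keep_frac = 0.46)
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic two-species plastome design. Defaults emulate
#' an eight-genome, two-species study: within-species divergence around
#' 5e-4 and between-species divergence around 5.7e-3 (expected pairwise
#' p-distances), micro-inversion loops of 2-46 bp flanked by 3-23 bp
#' inverted-repeat stems, and SSR/non-SSR indel counts scaled from a 114-kb
#' plastome survey (195/54/24 events) to the 30-kb default genome.
#'
#' @param seed Integer seed; the only source of randomness.
#' @param genome_length Ancestor length in bp (default 30000).
#' @param ir_length Length of each inverted-repeat copy in bp.
#' @param n_species,n_individuals_per_species Study design (default 2 x 4).
#' @param subst_rate_within,subst_rate_between Expected pairwise p-distance
#'   within and between species; realized substitution counts are binomial
#'   draws at half these rates per species stem / individual.
#' @param n_ssr_indels,n_nonssr_indels,n_inversions Planted event counts.
#' @param inversion_loop_range,stem_length_range Loop and stem length ranges
#'   in bp.
#' @param n_hotspot_substitutions Extra species-stem substitutions
#'   concentrated in one designated spacer, creating a diversity hotspot.
#' @param hotspot_width Width of the hotspot region in bp.
#' @param structural_edits List of edits (see [default_structural_edits()]).
#' @param min_event_spacing Minimum distance in bp between planted events.
#' @param retry_cap Rejection-sampling retry cap per event.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       genome_length = 30000L,
                       ir_length = 4000L,
                       n_species = 2L,
                       n_individuals_per_species = 4L,
                       subst_rate_within = 5e-4,
                       subst_rate_between = 5.7e-3,
                       n_ssr_indels = 50L,
                       n_nonssr_indels = 14L,
                       n_inversions = 6L,
                       inversion_loop_range = c(2L, 46L),
                       stem_length_range = c(3L, 23L),
                       n_hotspot_substitutions = 40L,
                       hotspot_width = 600L,
                       structural_edits = default_structural_edits(),
                       min_event_spacing = 4L,
                       retry_cap = 1000L) {
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              ir_length = as.integer(ir_length), n_species = as.integer(n_species),
              n_individuals_per_species = as.integer(n_individuals_per_species),
              subst_rate_within = subst_rate_within,
              subst_rate_between = subst_rate_between,
              n_ssr_indels = as.integer(n_ssr_indels),
              n_nonssr_indels = as.integer(n_nonssr_indels),
              n_inversions = as.integer(n_inversions),
              inversion_loop_range = as.integer(inversion_loop_range),
              stem_length_range = as.integer(stem_length_range),
              n_hotspot_substitutions = as.integer(n_hotspot_substitutions),
              hotspot_width = as.integer(hotspot_width),
              structural_edits = structural_edits,
              min_event_spacing = as.integer(min_event_spacing),
              retry_cap = as.integer(retry_cap))
  rates <- c(cfg$subst_rate_within, cfg$subst_rate_between)
  if (any(rates < 0) || any(rates >= 1)) stop("rates must lie in [0, 1)")
  if (2L * cfg$ir_length >= cfg$genome_length)
    stop("infeasible layout: 2 * ir_length must be < genome_length")
  if (diff(cfg$inversion_loop_range) < 0 || diff(cfg$stem_length_range) < 0)
    stop("empty loop/stem range")
  structure(cfg, class = "sim_config")
}

## ---- gene roster -----------------------------------------------------------
# A plastome-like gene complement: 73 protein-coding + 30 tRNA + 4 rRNA = 107
# functional genes, in an order close to canonical angiosperm plastomes. The
# 11 ndh genes are all present in the ancestor.

roster_lsc <- function() {
  nm <- c("trnH-GUG", "psbA", "trnK-UUU", "matK", "rps16", "trnQ-UUG", "psbK",
          "psbI", "trnS-GCU", "trnG-UCC", "trnR-UCU", "atpA", "atpF", "atpH",
          "atpI", "rps2", "rpoC2", "rpoC1", "rpoB", "trnC-GCA", "psbM",
          "trnD-GUC", "trnY-GUA", "trnE-UUC", "trnT-GGU", "psbD", "psbC",
          "trnS-UGA", "rps14", "trnG-GCC", "trnfM-CAU", "psaB", "psaA", "ycf3",
          "trnS-GGA", "rps4", "trnT-UGU", "trnL-UAA", "trnF-GAA", "trnV-UAC",
          "ndhC", "ndhK", "ndhJ", "trnM-CAU", "atpE", "atpB", "rbcL", "accD",
          "ycf4", "cemA", "petA", "psbJ", "psbL", "psbF", "psbE", "petL",
          "petG", "trnW-CCA", "trnP-UGG", "psaJ", "rpl20", "rps12", "clpP",
          "psbB", "psbT", "psbN", "psbH", "petB", "petD", "rpoA", "rps11",
          "rpl36", "rps8", "rpl14", "rpl16", "rps3", "rpl22", "rps19")
  data.frame(name = nm, ftype = ifelse(grepl("^trn", nm), "tRNA", "gene"))
}

roster_ir <- function() {
  nm <- c("rpl2", "rpl23", "trnI-CAU", "ycf2", "trnL-CAA", "ndhB", "rps7",
          "trnV-GAC", "rrn16", "trnI-GAU", "trnA-UGC", "rrn23", "rrn4.5",
          "rrn5", "trnR-ACG", "trnN-GUU")
  data.frame(name = nm,
             ftype = ifelse(grepl("^trn", nm), "tRNA",
                            ifelse(grepl("^rrn", nm), "rRNA", "gene")))
}

roster_ssc <- function() {
  nm <- c("ndhF", "rpl32", "trnL-UAG", "ccsA", "ndhD", "psaC", "ndhE", "ndhG",
          "ndhI", "ndhA", "ndhH", "rps15", "ycf1")
  data.frame(name = nm, ftype = ifelse(grepl("^trn", nm), "tRNA", "gene"))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Random CDS of n_codons codons: ATG start, no internal stop, one stop at the
# end, so an intact gene translates without a premature stop.
random_cds <- function(n_codons) {
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense <- setdiff(all_codons, STOP_CODONS)
  paste0("ATG",
         paste(sample(sense, n_codons - 2L, replace = TRUE), collapse = ""),
         sample(STOP_CODONS, 1L))
}

random_seq <- function(n) str_from(sample(c("A", "C", "G", "T"), n, replace = TRUE))

# Spacer with (usually) one embedded SSR run, the slippage substrate for
# planted SSR indels.
random_spacer <- function(n, ssr_prob = 0.8) {
  s <- chars(random_seq(n))
  if (n >= 16L && runif(1) < ssr_prob) {
    if (runif(1) < 0.6) {                       # mononucleotide run
      run <- rep(sample(c("A", "C", "G", "T"), 1L), sample(6:10, 1L))
    } else {                                    # dinucleotide run
      b <- sample(c("A", "C", "G", "T"), 2L)
      run <- rep(b, sample(4:6, 1L))
    }
    k <- length(run)
    if (k + 2L <= n) {
      at <- sample.int(n - k - 1L, 1L) + 1L
      s[at:(at + k - 1L)] <- run
    }
  }
  str_from(s)
}

# Partition `budget` bp into n spacers of >= min_len each.
spacer_lengths <- function(budget, n, min_len = 20L) {
  if (budget < n * min_len)
    stop("infeasible layout: intergenic budget ", budget,
         " bp cannot hold ", n, " spacers of >= ", min_len, " bp")
  w <- runif(n)
  extra <- floor((budget - n * min_len) * w / sum(w))
  len <- min_len + extra
  len[1L] <- len[1L] + (budget - sum(len))
  as.integer(len)
}

gene_length_bp <- function(name, ftype) {
  if (ftype == "tRNA") return(72L)
  if (ftype == "rRNA")
    return(switch(name, rrn16 = 240L, rrn23 = 320L, rrn4.5 = 60L, rrn5 = 100L,
                  120L))
  n_codons <- if (grepl("^ndh", name)) sample(80:120, 1L) else sample(30:70, 1L)
  3L * n_codons
}

## ---- ancestor --------------------------------------------------------------

#' Generate a quadripartite ancestral plastome
#'
#' Builds a circular genome with LSC / IRa / SSC / IRb layout where the IRb
#' sequence is the exact reverse complement of IRa (features mirrored), a gene
#' complement of 73 protein-coding + 30 tRNA + 4 rRNA genes including all 11
#' ndh genes, and intergenic spacers seeded with SSR runs. The spacer between
#' trnQ-UUG and psbK is kept long enough to host a planted diversity hotspot.
#' trnH-GUG starts at position 1 (the conventional linearization origin).
#'
#' @param cfg A [sim_config()].
#' @return A [genome_record()] with a `regions` attribute giving the
#'   LSC/IRa/SSC/IRb intervals.
#' @export
make_ancestor <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, build_ancestor(cfg))
}

build_region <- function(roster, region_len, origin, long_spacer_after = NULL,
                         long_spacer_len = 0L) {
  lens <- mapply(gene_length_bp, roster$name, roster$ftype)
  genic <- sum(lens)
  n_sp <- nrow(roster)                      # one spacer after each gene
  budget <- region_len - genic
  sp_len <- spacer_lengths(budget - long_spacer_len, n_sp)
  if (!is.null(long_spacer_after)) {
    i <- match(long_spacer_after, roster$name)
    sp_len[i] <- sp_len[i] + long_spacer_len
  }
  pieces <- character(0)
  feats <- list()
  pos <- origin
  for (i in seq_len(n_sp)) {
    gl <- lens[[i]]
    gseq <- switch(roster$ftype[i],
                   gene = random_cds(gl %/% 3L),
                   random_seq(gl))
    strand <- if (roster$ftype[i] == "gene" && runif(1) < 0.4) "-" else "+"
    pieces <- c(pieces, if (strand == "-") revcomp(gseq) else gseq,
                random_spacer(sp_len[i]))
    feats[[i]] <- feature_record(roster$name[i], roster$ftype[i], strand,
                                 pos, pos + gl - 1L)
    pos <- pos + gl + sp_len[i]
  }
  list(seq = paste(pieces, collapse = ""), features = feats, next_pos = pos)
}

build_ancestor <- function(cfg) {
  L <- cfg$genome_length
  ir <- cfg$ir_length
  sc <- L - 2L * ir
  lsc_len <- as.integer(round(sc * 0.75))
  ssc_len <- sc - lsc_len
  long_sp <- max(cfg$hotspot_width + 200L, 800L)

  lsc <- build_region(roster_lsc(), lsc_len, 1L,
                      long_spacer_after = "trnQ-UUG", long_spacer_len = long_sp)
  ira <- build_region(roster_ir(), ir, lsc$next_pos)
  ssc <- build_region(roster_ssc(), ssc_len, ira$next_pos)

  ira_start <- lsc$next_pos
  ira_end <- ira$next_pos - 1L
  irb_start <- ssc$next_pos
  irb_seq <- revcomp(ira$seq)
  # mirror IRa features into IRb
  irb_feats <- lapply(ira$features, function(f) {
    iv <- f$intervals
    s2 <- irb_start + (ira_end - iv[, "end"])
    e2 <- irb_start + (ira_end - iv[, "start"])
    o <- order(s2)
    feature_record(f$name, f$ftype, if (f$strand == "+") "-" else "+",
                   s2[o], e2[o])
  })
  seq <- paste0(lsc$seq, ira$seq, ssc$seq, irb_seq)
  stopifnot(nchar(seq) == L)
  feats <- c(lsc$features, ira$features, ssc$features, irb_feats)
  rec <- genome_record("ancestor", seq, circular = TRUE, features = feats)
  attr(rec, "regions") <- data.frame(
    region = c("LSC", "IRa", "SSC", "IRb"),
    start = c(1L, ira_start, ira$next_pos, irb_start),
    end = c(ira_start - 1L, ira_end, irb_start - 1L, L))
  rec
}

## ---- structural edits ------------------------------------------------------

#' Apply structural reduction edits to a genome
#'
#' Supported edits: `delete_ir_copy` (removes the IRb interval and its
#' features), `delete_segment` (excises a named gene block plus the inner
#' halves of its flanking spacers) and `truncate_gene` (keeps the 5' fraction
#' of a gene and marks it `pseudogene`).
#'
#' @param rec A [genome_record()] (typically from [make_ancestor()]).
#' @param edits List of edit descriptors, see [default_structural_edits()].
#' @return List with `record` (the reduced genome) and `applied` (a ledger
#'   data frame: op, genes, reference interval, deleted length).
#' @export
apply_structural_edits <- function(rec, edits) {
  if (length(edits) == 0L)
    return(list(record = rec, applied = structural_ledger()))
  feats <- rec$features
  cuts <- list()
  ledger <- structural_ledger()
  starts <- vapply(feats, feat_start, 0L)
  ord <- order(starts)

  for (ed in edits) {
    if (ed$op == "delete_ir_copy") {
      reg <- attr(rec, "regions")
      if (is.null(reg)) {
        irres <- find_ir(rec)
        if (irres$ir_status != "quadripartite")
          stop("delete_ir_copy: no inverted repeat found")
        cut <- c(irres$intervals[2L, "start"], irres$intervals[2L, "end"])
      } else {
        cut <- unlist(reg[reg$region == "IRb", c("start", "end")])
      }
      cuts[[length(cuts) + 1L]] <- cut
      ledger <- rbind(ledger, data.frame(
        op = "delete_ir_copy", genes = "", ref_start = cut[1L],
        ref_end = cut[2L], length = cut[2L] - cut[1L] + 1L))
    } else if (ed$op == "delete_segment") {
      idx <- which(feature_names(rec) %in% ed$genes)
      if (length(idx) == 0L) stop("delete_segment: no such genes")
      block_s <- min(vapply(feats[idx], feat_start, 0L))
      block_e <- max(vapply(feats[idx], function(f) max(f$intervals[, "end"]), 0L))
      others_e <- vapply(feats, function(f) max(f$intervals[, "end"]), 0L)
      others_s <- vapply(feats, feat_start, 0L)
      left_end <- max(others_e[others_e < block_s])
      right_start <- min(others_s[others_s > block_e])
      cut_s <- left_end + 1L + (block_s - left_end - 1L) %/% 2L
      cut_e <- right_start - 1L - (right_start - block_e - 1L) %/% 2L
      cuts[[length(cuts) + 1L]] <- c(cut_s, cut_e)
      ledger <- rbind(ledger, data.frame(
        op = "delete_segment", genes = paste(sort(ed$genes), collapse = ","),
        ref_start = cut_s, ref_end = cut_e, length = cut_e - cut_s + 1L))
    } else if (ed$op == "truncate_gene") {
      i <- which(feature_names(rec) == ed$gene)
      if (length(i) == 0L) stop("truncate_gene: no such gene: ", ed$gene)
      i <- i[1L]
      f <- feats[[i]]
      stopifnot(nrow(f$intervals) == 1L)
      len <- feat_length(f)
      keep <- max(30L, as.integer(floor(len * ed$keep_frac)))
      s <- f$intervals[1L, "start"]; e <- f$intervals[1L, "end"]
      if (f$strand == "+") {
        feats[[i]] <- feature_record(f$name, "pseudogene", "+", s, s + keep - 1L)
        cut <- c(s + keep, e)
      } else {
        feats[[i]] <- feature_record(f$name, "pseudogene", "-", e - keep + 1L, e)
        cut <- c(s, e - keep)
      }
      cuts[[length(cuts) + 1L]] <- cut
      ledger <- rbind(ledger, data.frame(
        op = "truncate_gene", genes = ed$gene, ref_start = cut[1L],
        ref_end = cut[2L], length = cut[2L] - cut[1L] + 1L))
    } else stop("unknown structural edit op: ", ed$op)
  }

  cutm <- do.call(rbind, cuts)
  cutm <- cutm[order(cutm[, 1L]), , drop = FALSE]
  if (any(cutm[-1L, 1L] <= cutm[-nrow(cutm), 2L]))
    stop("structural edits overlap")
  L <- genome_length(rec)
  keep_mask <- rep(TRUE, L)
  for (i in seq_len(nrow(cutm))) keep_mask[cutm[i, 1L]:cutm[i, 2L]] <- FALSE
  newpos <- cumsum(keep_mask)

  new_feats <- list()
  for (f in feats) {
    iv <- f$intervals
    inside <- !keep_mask[iv[, "start"]] & !keep_mask[iv[, "end"]]
    if (all(inside)) next
    iv <- iv[!inside, , drop = FALSE]
    if (any(!keep_mask[iv[, "start"]]) || any(!keep_mask[iv[, "end"]]))
      stop("feature '", f$name, "' partially overlaps a structural cut")
    new_feats[[length(new_feats) + 1L]] <-
      feature_record(f$name, f$ftype, f$strand,
                     newpos[iv[, "start"]], newpos[iv[, "end"]])
  }
  new_seq <- str_from(chars(rec$seq)[keep_mask])
  out <- genome_record(rec$id, new_seq, circular = rec$circular,
                       features = new_feats)
  list(record = out, applied = ledger)
}

structural_ledger <- function() {
  data.frame(op = character(0), genes = character(0),
             ref_start = integer(0), ref_end = integer(0),
             length = integer(0))
}

## ---- mutation planting -----------------------------------------------------

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Loop whose every position differs from its reverse-complement counterpart,
# so that an inverted copy mismatches the original at every column.
sample_anticomplementary_loop <- function(len) {
  bases <- c("A", "C", "G", "T")
  v <- character(len)
  for (i in seq_len(ceiling(len / 2))) {
    j <- len - i + 1L
    v[i] <- sample(bases, 1L)
    if (j > i) v[j] <- sample(setdiff(bases, COMP[[v[i]]]), 1L)
  }
  str_from(v)
}

# Fragment/context SSR rule shared by the classifier and the generator's
# placement filter; see classify_ssr() for the definition.
is_ssr_fragment <- function(fragment, left_ctx, right_ctx, max_motif = 6L,
                            min_extra_copies = 1L) {
  !is.null(ssr_motif_of(fragment, left_ctx, right_ctx, max_motif,
                        min_extra_copies))
}

ssr_motif_of <- function(fragment, left_ctx, right_ctx, max_motif = 6L,
                         min_extra_copies = 1L) {
  n <- nchar(fragment)
  if (n == 0L) return(NULL)
  for (ml in seq_len(min(max_motif, n))) {
    if (n %% ml != 0L) next
    motif <- substr(fragment, 1L, ml)
    copies <- strsplit(gsub(sprintf("(.{%d})", ml), "\\1 ", fragment), " ")[[1L]]
    if (!all(copies == motif)) next
    cl <- adjacent_copies(motif, left_ctx, from_right = TRUE)
    cr <- adjacent_copies(motif, right_ctx, from_right = FALSE)
    if (cl + cr >= min_extra_copies) return(motif)
  }
  NULL
}

adjacent_copies <- function(motif, ctx, from_right) {
  ml <- nchar(motif)
  n <- nchar(ctx)
  k <- 0L
  while ((k + 1L) * ml <= n) {
    piece <- if (from_right) substr(ctx, n - (k + 1L) * ml + 1L, n - k * ml)
             else substr(ctx, k * ml + 1L, (k + 1L) * ml)
    if (piece != motif) break
    k <- k + 1L
  }
  k
}

# Find candidate SSR runs (mononucleotide >= 6, dinucleotide >= 4 copies).
scan_ssr_runs <- function(seq) {
  v <- chars(seq)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= 6L & r$values %in% c("A", "C", "G", "T")
  runs <- data.frame(start = starts[keep], end = ends[keep],
                     motif = r$values[keep])
  bases <- c("A", "C", "G", "T")
  for (a in bases) for (b in setdiff(bases, a)) {
    m <- gregexpr(sprintf("(%s%s){4,}", a, b), seq)[[1L]]
    if (m[1L] != -1L)
      runs <- rbind(runs, data.frame(
        start = as.integer(m),
        end = as.integer(m) + attr(m, "match.length") - 1L,
        motif = paste0(a, b)))
  }
  runs[order(runs$start), , drop = FALSE]
}

# Intergenic positions of a genome (margin bp away from any feature).
intergenic_mask <- function(rec, margin = 2L) {
  L <- genome_length(rec)
  open <- rep(TRUE, L)
  for (f in rec$features) {
    iv <- f$intervals
    for (i in seq_len(nrow(iv))) {
      s <- max(1L, iv[i, "start"] - margin)
      e <- min(L, iv[i, "end"] + margin)
      open[s:e] <- FALSE
    }
  }
  open
}

place_interval <- function(open, len, retry_cap) {
  L <- length(open)
  avail <- which(open)
  if (length(avail) == 0L) return(NA_integer_)
  for (i in seq_len(retry_cap)) {
    s <- avail[sample.int(length(avail), 1L)]
    if (s + len - 1L <= L && all(open[s:(s + len - 1L)])) return(s)
  }
  NA_integer_
}

block <- function(open, s, e, spacing) {
  open[max(1L, s - spacing):min(length(open), e + spacing)] <- FALSE
  open
}

## ---- individual evolution --------------------------------------------------

#' Evolve individuals from an ancestor
#'
#' Applies the configured structural edits to the ancestor (the shared reduced
#' backbone of all individuals), then plants species-stem and
#' individual-private substitutions, SSR and non-SSR indels, and micro-
#' inversions with exact flanking stems. All point events are placed in
#' intergenic regions, non-overlapping with a minimum spacing, so the truth
#' ledger is unambiguous.
#'
#' @param ancestor A [genome_record()] from [make_ancestor()].
#' @param cfg The [sim_config()] used to build the ancestor.
#' @return List with `genomes` (named list of [genome_record()]), `alignment`
#'   (the truth [alignment()]), `truth` (events data frame, hotspot interval,
#'   structural ledger) and `reduced` (the shared reduced backbone).
#' @export
evolve_individuals <- function(ancestor, cfg) {
  stopifnot(inherits(ancestor, "genome_record"), inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 1L, evolve_impl(ancestor, cfg))
}

evolve_impl <- function(ancestor, cfg) {
  red <- apply_structural_edits(ancestor, cfg$structural_edits)
  backbone <- red$record
  S <- backbone$seq
  L <- nchar(S)
  n_ind <- cfg$n_species * cfg$n_individuals_per_species
  ids <- as.vector(t(outer(seq_len(cfg$n_species),
                           seq_len(cfg$n_individuals_per_species),
                           function(s, i) sprintf("sp%d_%d", s, i))))
  species_of <- rep(seq_len(cfg$n_species), each = cfg$n_individuals_per_species)
  names(species_of) <- ids
  spacing <- cfg$min_event_spacing
  cap <- cfg$retry_cap
  open <- intergenic_mask(backbone)

  events <- list()
  add_event <- function(e) events[[length(events) + 1L]] <<- e

  ## 1. micro-inversions: overwrite the backbone with stem+loop+revcomp(stem),
  ##    then invert the loop in one species.
  Sv <- chars(S)
  inversions <- list()
  for (k in seq_len(cfg$n_inversions)) {
    stem_len <- sample(cfg$stem_length_range[1L]:cfg$stem_length_range[2L], 1L)
    loop_len <- sample(cfg$inversion_loop_range[1L]:cfg$inversion_loop_range[2L], 1L)
    total <- 2L * stem_len + loop_len
    s <- place_interval(open, total, cap)
    if (is.na(s))
      stop("placement impossible for event class 'inversion' after ",
           cap, " retries")
    stem <- random_seq(stem_len)
    loop <- sample_anticomplementary_loop(loop_len)
    locus <- paste0(stem, loop, revcomp(stem))
    Sv[s:(s + total - 1L)] <- chars(locus)
    sp <- sample.int(cfg$n_species, 1L)
    loop_s <- s + stem_len
    loop_e <- loop_s + loop_len - 1L
    inversions[[k]] <- list(loop_start = loop_s, loop_end = loop_e,
                            loop = loop, stem = stem, stem_len = stem_len,
                            species = sp)
    open <- block(open, s, s + total - 1L, spacing)
  }
  S <- str_from(Sv)

  ## 2. SSR indels: pick slippage runs, delete or insert one motif copy.
  runs <- scan_ssr_runs(S)
  order_pick <- sample.int(nrow(runs))
  deletions <- list(); insertions <- list()
  n_placed <- 0L
  for (i in order_pick) {
    if (n_placed >= cfg$n_ssr_indels) break
    if (!all(open[runs$start[i]:runs$end[i]])) next
    motif <- runs$motif[i]
    ml <- nchar(motif)
    bearer_rows <- sample_bearers(ids, species_of, cfg)
    if (runif(1) < 0.5) {
      deletions[[length(deletions) + 1L]] <- list(
        start = runs$start[i], end = runs$start[i] + ml - 1L,
        rows = bearer_rows, ssr_class = "SSR", motif = motif)
    } else {
      insertions[[length(insertions) + 1L]] <- list(
        after = runs$start[i] - 1L, fragment = motif, rows = bearer_rows,
        ssr_class = "SSR", motif = motif)
    }
    open <- block(open, runs$start[i], runs$end[i], spacing)
    n_placed <- n_placed + 1L
  }
  if (n_placed < cfg$n_ssr_indels)
    stop("placement impossible for event class 'SSR indel': only ",
         n_placed, " of ", cfg$n_ssr_indels, " events placeable")

  ## 3. non-SSR indels: random fragments verified to fail the SSR rule.
  for (k in seq_len(cfg$n_nonssr_indels)) {
    placed <- FALSE
    for (try in seq_len(cap)) {
      len <- sample(2:12, 1L)
      del <- runif(1) < 0.5
      s <- place_interval(open, len + 1L, cap)
      if (is.na(s)) break
      if (del) {
        frag <- substr(S, s, s + len - 1L)
        lctx <- substr(S, max(1L, s - 60L), s - 1L)
        rctx <- substr(S, s + len, min(L, s + len + 59L))
      } else {
        frag <- random_seq(len)
        lctx <- substr(S, max(1L, s - 60L), s - 1L)
        rctx <- substr(S, s, min(L, s + 59L))
      }
      if (is_ssr_fragment(frag, lctx, rctx)) next
      bearer_rows <- sample_bearers(ids, species_of, cfg)
      if (del) {
        deletions[[length(deletions) + 1L]] <- list(
          start = s, end = s + len - 1L, rows = bearer_rows,
          ssr_class = "non-SSR", motif = NA_character_)
      } else {
        insertions[[length(insertions) + 1L]] <- list(
          after = s - 1L, fragment = frag, rows = bearer_rows,
          ssr_class = "non-SSR", motif = NA_character_)
      }
      # block the whole flank a 6-bp motif copy could occupy, so later
      # substitutions cannot create SSR context around a non-SSR event
      open <- block(open, s, s + len - 1L, max(spacing, 6L))
      placed <- TRUE
      break
    }
    if (!placed)
      stop("placement impossible for event class 'non-SSR indel' after ",
           cap, " retries")
  }

  ## 4. substitutions: species stems, hotspot stem block, private.
  subs <- list()
  place_sub <- function(region_open, rows, tag) {
    s <- place_interval(region_open, 1L, cap)
    if (is.na(s))
      stop("placement impossible for event class 'substitution (", tag,
           ")' after ", cap, " retries")
    ref <- substr(S, s, s)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    subs[[length(subs) + 1L]] <<- list(pos = s, ref = ref, alt = alt,
                                       rows = rows, tag = tag)
    open <<- block(open, s, s, spacing)
    s
  }
  # hotspot: a designated region of concentrated between-species divergence
  hotspot <- locate_hotspot(backbone, cfg)
  if (cfg$n_hotspot_substitutions > 0L) {
    hs_rows <- ids[species_of == 1L]
    for (k in seq_len(cfg$n_hotspot_substitutions)) {
      ro <- open
      ro[-(hotspot[1L]:hotspot[2L])] <- FALSE
      place_sub(ro, hs_rows, "hotspot")
    }
  }
  for (sp in seq_len(cfg$n_species)) {
    n_stem <- rbinom(1L, L, cfg$subst_rate_between / 2)
    rows <- ids[species_of == sp]
    for (k in seq_len(n_stem)) place_sub(open, rows, "stem")
  }
  for (id in ids) {
    n_priv <- rbinom(1L, L, cfg$subst_rate_within / 2)
    for (k in seq_len(n_priv)) place_sub(open, id, "private")
  }

  ## 5. assemble the truth alignment.
  ins_ord <- order(vapply(insertions, `[[`, 0L, "after"))
  insertions <- insertions[ins_ord]
  ins_after <- vapply(insertions, `[[`, 0L, "after")
  ins_len <- vapply(insertions, function(x) nchar(x$fragment), 0L)
  cum_len <- c(0L, cumsum(ins_len))
  col_of <- function(p) p + cum_len[findInterval(p - 0.5, ins_after) + 1L]

  base <- chars(S)
  rows_chr <- list()
  for (id in ids) {
    v <- base
    for (e in subs) if (id %in% e$rows) v[e$pos] <- e$alt
    for (iv in inversions) if (species_of[[id]] == iv$species)
      v[iv$loop_start:iv$loop_end] <- chars(revcomp(iv$loop))
    for (d in deletions) if (id %in% d$rows) v[d$start:d$end] <- "-"
    if (length(insertions) > 0L) {
      parts <- character(0)
      prev <- 0L
      for (j in seq_along(insertions)) {
        a <- ins_after[j]
        if (a >= prev + 1L) parts <- c(parts, v[(prev + 1L):a])
        piece <- if (id %in% insertions[[j]]$rows) insertions[[j]]$fragment
                 else strrep("-", ins_len[j])
        parts <- c(parts, piece)
        prev <- a
      }
      if (prev < L) parts <- c(parts, v[(prev + 1L):L])
      rows_chr[[id]] <- paste(parts, collapse = "")
    } else rows_chr[[id]] <- str_from(v)
  }
  aln <- alignment(unlist(rows_chr))

  ## 6. truth ledger in aligned coordinates.
  ev <- list()
  for (e in subs) ev[[length(ev) + 1L]] <- data.frame(
    class = "substitution", aligned_start = col_of(e$pos),
    aligned_end = col_of(e$pos), backbone_start = e$pos, backbone_end = e$pos,
    gap_rows = "", alt_rows = paste(sort(e$rows), collapse = ","),
    fragment = e$alt, ssr_class = NA_character_, motif = NA_character_,
    tag = e$tag)
  for (d in deletions) ev[[length(ev) + 1L]] <- data.frame(
    class = "indel", aligned_start = col_of(d$start),
    aligned_end = col_of(d$start) + (d$end - d$start),
    backbone_start = d$start, backbone_end = d$end,
    gap_rows = paste(sort(d$rows), collapse = ","),
    alt_rows = "", fragment = substr(S, d$start, d$end),
    ssr_class = d$ssr_class, motif = d$motif, tag = "deletion")
  for (j in seq_along(insertions)) {
    i <- insertions[[j]]
    a_start <- i$after + cum_len[j] + 1L
    ev[[length(ev) + 1L]] <- data.frame(
      class = "indel", aligned_start = a_start,
      aligned_end = a_start + ins_len[j] - 1L,
      backbone_start = i$after, backbone_end = i$after,
      gap_rows = paste(sort(setdiff(ids, i$rows)), collapse = ","),
      alt_rows = paste(sort(i$rows), collapse = ","), fragment = i$fragment,
      ssr_class = i$ssr_class, motif = i$motif, tag = "insertion")
  }
  for (iv in inversions) ev[[length(ev) + 1L]] <- data.frame(
    class = "inversion", aligned_start = col_of(iv$loop_start),
    aligned_end = col_of(iv$loop_end),
    backbone_start = iv$loop_start, backbone_end = iv$loop_end,
    gap_rows = "", alt_rows = paste(sort(ids[species_of == iv$species]),
                                    collapse = ","),
    fragment = iv$loop, ssr_class = NA_character_, motif = iv$stem,
    tag = sprintf("stem_len=%d", iv$stem_len))
  events_df <- if (length(ev) == 0L)
    data.frame(class = character(0), aligned_start = integer(0),
               aligned_end = integer(0), backbone_start = integer(0),
               backbone_end = integer(0), gap_rows = character(0),
               alt_rows = character(0), fragment = character(0),
               ssr_class = character(0), motif = character(0),
               tag = character(0))
  else do.call(rbind, ev)
  events_df <- events_df[order(events_df$aligned_start), , drop = FALSE]
  rownames(events_df) <- NULL

  ## 7. per-individual genome records with remapped features.
  genomes <- lapply(ids, function(id) {
    a2u <- aligned_to_ungapped(aln, id)
    feats <- lapply(backbone$features, function(f) {
      iv <- f$intervals
      feature_record(f$name, f$ftype, f$strand,
                     a2u[vapply(iv[, "start"], col_of, 0L)],
                     a2u[vapply(iv[, "end"], col_of, 0L)])
    })
    genome_record(id, degap(aln$rows[[id]]), circular = TRUE,
                  features = feats)
  })
  names(genomes) <- ids

  list(genomes = genomes, alignment = aln,
       truth = list(events = events_df,
                    hotspot = c(aligned_start = col_of(hotspot[1L]),
                                aligned_end = col_of(hotspot[2L])),
                    structural = red$applied,
                    species = species_of,
                    config = cfg),
       reduced = backbone)
}

sample_bearers <- function(ids, species_of, cfg) {
  if (runif(1) < 0.5) {
    sp <- sample.int(cfg$n_species, 1L)
    ids[species_of == sp]
  } else sample(ids, 1L)
}

# The designated hotspot region: the long spacer downstream of trnQ-UUG
# (falls back to the longest intergenic gap).
locate_hotspot <- function(rec, cfg) {
  nm <- feature_names(rec)
  starts <- vapply(rec$features, feat_start, 0L)
  ends <- vapply(rec$features, function(f) max(f$intervals[, "end"]), 0L)
  o <- order(starts)
  gaps <- data.frame(start = ends[o][-length(o)] + 1L,
                     end = starts[o][-1L] - 1L,
                     left = nm[o][-length(o)])
  gaps <- gaps[gaps$end >= gaps$start, , drop = FALSE]
  i <- which(gaps$left == "trnQ-UUG")
  g <- if (length(i) > 0L && gaps$end[i[1L]] - gaps$start[i[1L]] + 1L >=
             cfg$hotspot_width) gaps[i[1L], ]
       else gaps[which.max(gaps$end - gaps$start), ]
  c(g$start, g$end)
}

#' Run the full synthetic study design
#'
#' Convenience wrapper: builds the quadripartite ancestor, applies the
#' structural reductions, and evolves the two-species individual set.
#'
#' @param cfg A [sim_config()].
#' @return List with `ancestor`, plus everything [evolve_individuals()]
#'   returns.
#' @export
simulate_plastomes <- function(cfg) {
  anc <- make_ancestor(cfg)
  out <- evolve_individuals(anc, cfg)
  out$ancestor <- anc
  out
}
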