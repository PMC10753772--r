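# Pipeline orchestration: run the stages end-to-end with one configuration,
# write per-stage TSV/JSON outputs plus a combined summary, and (in synthetic
# mode) score every caller against the planted truth.

#' Pipeline configuration
#'
#' @param mode `"synthetic"` (generate the study design from `sim`) or
#'   `"input"` (load an alignment and optionally genomes/reference from
#'   disk).
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed used in synthetic mode.
#' @param sim Named list of [sim_config()] overrides (synthetic mode).
#' @param alignment Aligned-FASTA path (input mode).
#' @param genomes Named character vector of genome FASTA paths (input mode;
#'   optional).
#' @param reference GenBank path of the quadripartite reference (input mode;
#'   required for the structure stage).
#' @param stages Stages to run, in dependency order, from
#'   `c("inversions", "variants", "diversity", "structure", "tree")`.
#' @param ref_label Reference alignment row for inversion characterization
#'   and hotspot labeling (default: first row).
#' @param partition Named character vector row label -> species; in synthetic
#'   mode inferred from the generator's labels.
#' @param window,step Sliding-window parameters (bp).
#' @param ssr_max_motif,ssr_min_extra_copies SSR classification rule.
#' @param stem_min,stem_max,stem_max_mismatch,stem_max_gap Hairpin stem rule.
#' @param min_ir,min_intact_frac Structure-stage thresholds.
#' @return List of class `pipeline_config` with all parameters resolved.
#' @export
pipeline_config <- function(mode = c("synthetic", "input"),
                            outdir = tempfile("plastocomp_run_"),
                            seed = 1L,
                            sim = list(),
                            alignment = NULL,
                            genomes = NULL,
                            reference = NULL,
                            stages = c("inversions", "variants", "diversity",
                                       "structure", "tree"),
                            ref_label = NULL,
                            partition = NULL,
                            window = 600L, step = 200L,
                            ssr_max_motif = 6L, ssr_min_extra_copies = 1L,
                            stem_min = 3L, stem_max = 23L,
                            stem_max_mismatch = 0L, stem_max_gap = 5L,
                            min_ir = 1000L, min_intact_frac = 0.9) {
  mode <- match.arg(mode)
  stages <- match.arg(stages, several.ok = TRUE)
  cfg <- list(mode = mode, outdir = outdir, seed = as.integer(seed),
              sim = sim, alignment = alignment, genomes = genomes,
              reference = reference, stages = stages, ref_label = ref_label,
              partition = partition, window = as.integer(window),
              step = as.integer(step),
              ssr_max_motif = as.integer(ssr_max_motif),
              ssr_min_extra_copies = as.integer(ssr_min_extra_copies),
              stem_min = as.integer(stem_min), stem_max = as.integer(stem_max),
              stem_max_mismatch = as.integer(stem_max_mismatch),
              stem_max_gap = as.integer(stem_max_gap),
              min_ir = as.integer(min_ir),
              min_intact_frac = min_intact_frac)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  if (cfg$mode == "input") {
    if (is.null(cfg$alignment))
      stop("input mode requires an alignment path")
    for (p in c(cfg$alignment, cfg$genomes, cfg$reference))
      if (!file.exists(p)) stop("no such file: ", p)
    if ("structure" %in% cfg$stages &&
        (is.null(cfg$genomes) || is.null(cfg$reference)))
      stop("the structure stage requires genome and reference inputs")
  }
  stopifnot(cfg$window >= cfg$step, cfg$step >= 1L)
  invisible(cfg)
}

#' Read a YAML pipeline configuration
#' @param path YAML file of [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

log_stage <- function(con, stage, t0, info = list()) {
  elapsed <- round(as.numeric(Sys.time()) - t0, 3)
  message(sprintf("[plastocomp] %s done (%.2fs)", stage, elapsed))
  writeLines(jsonlite::toJSON(c(list(stage = stage, elapsed_s = elapsed),
                                info), auto_unbox = TRUE), con)
}

#' Run the comparative-plastome pipeline
#'
#' Executes the requested stages in dependency order (inversions before
#' variants, so inversion columns are masked out of SNP calling), writes
#' per-stage TSV/JSON files, a combined `summary.json` with the full resolved
#' parameter set, and -- in synthetic mode -- a `recovery.json` scoring every
#' caller against the planted truth. Identical configuration yields identical
#' outputs (the stage log carries the only timing information).
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the per-stage results.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  validate_pipeline_config(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(cfg$outdir, "log.jsonl"), "w")
  on.exit(close(logcon))
  res <- list()
  pars <- unclass(cfg)
  pars$outdir <- NULL          # identical runs stay byte-identical
  summary <- list(parameters = pars)

  ## load or simulate inputs
  t0 <- as.numeric(Sys.time())
  if (cfg$mode == "synthetic") {
    sim <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
    sim_out <- simulate_plastomes(sim)
    aln <- sim_out$alignment
    genomes <- sim_out$genomes
    reference <- sim_out$ancestor
    partition <- vapply(sim_out$truth$species, function(s)
      sprintf("species%d", s), "")
    names(partition) <- names(sim_out$truth$species)
    write_alignment(aln, file.path(cfg$outdir, "alignment.fasta"))
    gdir <- file.path(cfg$outdir, "genomes")
    dir.create(gdir, showWarnings = FALSE)
    for (id in names(genomes))
      write_genome(genomes[[id]], file.path(gdir, paste0(id, ".fasta")),
                   "fasta", gff = file.path(gdir, paste0(id, ".gff3")))
    write_genome(reference, file.path(gdir, "reference.gb"), "genbank")
    jsonlite::write_json(sim_out$truth$events,
                         file.path(cfg$outdir, "truth_events.json"))
    res$sim <- sim_out
  } else {
    aln <- read_alignment(cfg$alignment)
    genomes <- if (!is.null(cfg$genomes)) {
      g <- lapply(cfg$genomes, read_genome, format = "fasta")
      names(g) <- names(cfg$genomes) %||%
        vapply(g, `[[`, "", "id")
      g
    }
    reference <- if (!is.null(cfg$reference))
      read_genome(cfg$reference, format = "genbank")
    partition <- cfg$partition
  }
  ref_label <- cfg$ref_label %||% aln$labels[1L]
  log_stage(logcon, "load", t0, list(rows = length(aln$labels),
                                     columns = aln$ncol))

  ## inversions
  inv <- NULL
  if ("inversions" %in% cfg$stages) {
    t0 <- as.numeric(Sys.time())
    inv <- merged_inversions(aln, ref_label)
    ref_rec <- if (cfg$mode == "synthetic")
      res$sim$genomes[[ref_label]] else genomes[[ref_label]]
    hairpins <- characterize_inversions(
      inv, aln, ref_label, ref_rec, min_stem = cfg$stem_min,
      max_stem = cfg$stem_max, max_mismatch = cfg$stem_max_mismatch,
      max_gap_to_loop = cfg$stem_max_gap)
    utils::write.table(hairpins, file.path(cfg$outdir, "inversions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$inversions <- inv
    res$hairpins <- hairpins
    log_stage(logcon, "inversions", t0, list(n = nrow(inv)))
  }

  ## variants
  if ("variants" %in% cfg$stages) {
    t0 <- as.numeric(Sys.time())
    mask <- inversion_columns(inv)
    subs <- call_substitutions(aln, exclude_columns = mask)
    indels <- classify_indels(call_indels(aln), aln,
                              max_motif = cfg$ssr_max_motif,
                              min_extra_copies = cfg$ssr_min_extra_copies)
    tally <- tally_mutations(subs, indels,
                             if (is.null(inv)) 0L else inv)
    write_event_tsv(subs, indels,
                    inv %||% data.frame(start = integer(0), end = integer(0),
                                        seq_a = character(0)),
                    file.path(cfg$outdir, "events.tsv"))
    res$substitutions <- subs
    res$indels <- indels
    res$tally <- tally
    summary$mutation_tally <- unclass(tally)
    log_stage(logcon, "variants", t0,
              list(substitutions = tally$n_substitutions,
                   indels = tally$n_indels))
  }

  ## diversity
  if ("diversity" %in% cfg$stages) {
    t0 <- as.numeric(Sys.time())
    windows <- sliding_pi(aln, window = cfg$window, step = cfg$step,
                          exclude_columns = inversion_columns(inv))
    utils::write.table(windows, file.path(cfg$outdir, "pi_windows.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dm <- distance_matrix(aln)
    write_distance_matrix(dm, file.path(cfg$outdir, "divergence_matrix.tsv"))
    feats <- if (cfg$mode == "synthetic") res$sim$genomes[[ref_label]]$features
             else if (!is.null(genomes[[ref_label]]))
               genomes[[ref_label]]$features else list()
    hot <- name_hotspots(windows, feats, k = 5L, aln = aln,
                         ref_label = ref_label)
    res$windows <- windows
    res$distance_matrix <- dm
    res$hotspots <- hot
    summary$hotspots <- hot
    if (!is.null(partition)) {
      gs <- group_summary(dm, partition)
      res$group_summary <- gs
      summary$group_summary <- gs
    }
    log_stage(logcon, "diversity", t0, list(windows = nrow(windows)))
  }

  ## structure
  if ("structure" %in% cfg$stages) {
    t0 <- as.numeric(Sys.time())
    if (is.null(genomes) || is.null(reference))
      stop("the structure stage requires genome and reference inputs")
    summaries <- lapply(c(list(reference), unname(genomes)),
                        summarize_genome)
    stab <- do.call(rbind, lapply(summaries, function(s)
      as.data.frame(unclass(s))))
    utils::write.table(stab, file.path(cfg$outdir, "genome_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    diffs <- lapply(genomes, function(g)
      structure_compare(reference, g, min_ir = cfg$min_ir,
                        min_intact_frac = cfg$min_intact_frac))
    jsonlite::write_json(
      lapply(diffs, function(d)
        list(ir_status = d$ir_status,
             missing_segments = d$missing_segments,
             pseudogenes = d$pseudogenes, lost_genes = d$lost_genes)),
      file.path(cfg$outdir, "structure.json"))
    txt <- utils::capture.output(for (d in diffs) print(d))
    writeLines(txt, file.path(cfg$outdir, "structure.txt"))
    res$structure <- diffs
    log_stage(logcon, "structure", t0, list(genomes = length(diffs)))
  }

  ## tree
  if ("tree" %in% cfg$stages) {
    t0 <- as.numeric(Sys.time())
    dm <- res$distance_matrix %||% distance_matrix(aln)
    tree <- neighbor_joining(dm)
    ape::write.tree(tree, file.path(cfg$outdir, "tree.nwk"))
    res$tree <- tree
    if (!is.null(partition)) {
      mono <- is_reciprocally_monophyletic(tree, partition)
      res$monophyletic <- mono
      summary$reciprocal_monophyly <- mono
    }
    log_stage(logcon, "tree", t0, list())
  }

  ## recovery report (synthetic mode)
  if (cfg$mode == "synthetic") {
    rec <- recovery_report(res$sim, window = cfg$window, step = cfg$step,
                           ssr_max_motif = cfg$ssr_max_motif,
                           ssr_min_extra_copies = cfg$ssr_min_extra_copies,
                           min_ir = cfg$min_ir,
                           min_intact_frac = cfg$min_intact_frac)
    res$recovery <- rec
    jsonlite::write_json(rec, file.path(cfg$outdir, "recovery.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  yaml::write_yaml(unclass(cfg), file.path(cfg$outdir, "config.yaml"))
  jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(res)
}

# Detect inversions of every row against the reference row and merge across
# pairs by interval identity.
merged_inversions <- function(aln, ref_label, min_len = 2L, max_len = 46L) {
  others <- setdiff(aln$labels, ref_label)
  all <- do.call(rbind, lapply(others, function(lb)
    find_inversions(aln, ref_label, lb, min_len = min_len, max_len = max_len)))
  if (is.null(all) || nrow(all) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), seq_a = character(0),
                      seq_b = character(0), out_of_range = logical(0)))
  all <- all[!duplicated(all[, c("start", "end")]), , drop = FALSE]
  all <- all[order(all$start), , drop = FALSE]
  rownames(all) <- NULL
  all
}

inversion_columns <- function(inv) {
  if (is.null(inv) || nrow(inv) == 0L) return(integer(0))
  unlist(lapply(seq_len(nrow(inv)), function(i) inv$start[i]:inv$end[i]))
}

#' Score callers against the planted truth of a synthetic run
#'
#' Reruns substitution, indel and inversion calling plus the diversity scan
#' and structural comparison on the truth alignment of a
#' [simulate_plastomes()] result, and compares every call against the planted
#' ledger.
#'
#' @param sim Result of [simulate_plastomes()].
#' @param window,step Sliding-window parameters for the hotspot check.
#' @param ssr_max_motif,ssr_min_extra_copies SSR classification rule.
#' @param min_ir,min_intact_frac Structure thresholds.
#' @return List of precision/recall per event class, SSR label agreement,
#'   hotspot argmax hit, and structural recovery indicators.
#' @export
recovery_report <- function(sim, window = 600L, step = 200L,
                            ssr_max_motif = 6L, ssr_min_extra_copies = 1L,
                            min_ir = 1000L, min_intact_frac = 0.9) {
  aln <- sim$alignment
  truth <- sim$truth$events
  species <- sim$truth$species
  ids <- names(species)
  pr <- function(called, planted) {
    list(precision = if (length(called) == 0L) 1 else
           mean(called %in% planted),
         recall = if (length(planted) == 0L) 1 else
           mean(planted %in% called),
         n_called = length(called), n_planted = length(planted))
  }

  ## inversions: compare one representative per species pair
  refA <- ids[species == 1L][1L]
  refB <- ids[species == 2L][1L]
  inv <- find_inversions(aln, refA, refB)
  t_inv <- truth[truth$class == "inversion", ]
  inv_pr <- pr(paste(inv$start, inv$end), paste(t_inv$aligned_start,
                                                t_inv$aligned_end))

  ## substitutions (inversion columns masked)
  subs <- call_substitutions(aln, exclude_columns = inversion_columns(inv))
  t_sub <- truth[truth$class == "substitution", ]
  sub_pr <- pr(subs$column, t_sub$aligned_start)

  ## indels + SSR labels
  indels <- classify_indels(call_indels(aln), aln,
                            max_motif = ssr_max_motif,
                            min_extra_copies = ssr_min_extra_copies)
  t_ind <- truth[truth$class == "indel", ]
  key <- function(s, e, g) paste(s, e, g, sep = "|")
  ind_pr <- pr(key(indels$start, indels$end, indels$bearers),
               key(t_ind$aligned_start, t_ind$aligned_end, t_ind$gap_rows))
  mk <- match(key(indels$start, indels$end, indels$bearers),
              key(t_ind$aligned_start, t_ind$aligned_end, t_ind$gap_rows))
  matched <- !is.na(mk)
  ssr_agreement <- if (!any(matched)) NA_real_ else
    mean(indels$ssr_class[matched] == t_ind$ssr_class[mk[matched]])

  ## hotspot: argmax-pi window overlaps the planted hotspot (inversion
  ## columns are inversion events, not substitutional diversity)
  windows <- sliding_pi(aln, window = window, step = step,
                        exclude_columns = inversion_columns(inv))
  ranked <- windows[windows$net_sites >= 100L, , drop = FALSE]
  wmax <- ranked[which.max(ranked$pi), ]
  hs <- sim$truth$hotspot
  hotspot_hit <- wmax$start <= hs[["aligned_end"]] &&
    wmax$end >= hs[["aligned_start"]]

  ## structural recovery on one individual vs the quadripartite ancestor
  g1 <- sim$genomes[[1L]]
  anc_ir <- find_ir(sim$ancestor, min_ir = min_ir)
  ind_ir <- find_ir(g1, min_ir = min_ir)
  segs <- missing_segments(sim$ancestor, g1)
  pseudo <- call_pseudogenes(sim$ancestor, g1,
                             min_intact_frac = min_intact_frac)
  st <- sim$truth$structural
  planted_segs <- st$genes[st$op == "delete_segment"]
  planted_trunc <- st$genes[st$op == "truncate_gene"]
  ir_deleted <- any(st$op == "delete_ir_copy")
  list(
    substitutions = sub_pr,
    indels = ind_pr,
    inversions = inv_pr,
    ssr_label_agreement = ssr_agreement,
    hotspot_argmax_hit = hotspot_hit,
    ancestor_quadripartite = anc_ir$ir_status == "quadripartite",
    individual_ir_status_correct =
      ind_ir$ir_status == if (ir_deleted) "ir_lacking" else "quadripartite",
    missing_segments_match = setequal(segs$genes, planted_segs),
    pseudogenes_match = setequal(tolower(pseudo$name),
                                 tolower(planted_trunc)))
}
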