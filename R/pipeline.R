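# ---- pipeline orchestration -------------------------------------------------

#' Pipeline configuration with the study's thresholds as defaults
#'
#' All analysis thresholds in one validated object: Q20 mean-quality filter,
#' >=5 reads per UMI, <=0.1 group mismatch rate, 0.1 junction clustering cut,
#' >=100 unique sequences per admitted sample, bootstrap depth 126 with 200
#' repetitions, >50-member large-clone rule, >=30% CDR3 coverage for a
#' proteome match, and FDR cutoffs 0.1 (DDA) / 0.01 (DIA).
#'
#' @param seed integer master seed.
#' @param sim [sim_config()] for the generator stage.
#' @param qmin,min_reads,max_group_error consensus thresholds.
#' @param clone_threshold junction distance cut.
#' @param min_unique sample admission floor.
#' @param subsample_n,reps bootstrap settings.
#' @param large_clone_min strict clone-size threshold.
#' @param cdr3_match CDR3 coverage threshold.
#' @param proteome_mode acquisition mode for the proteome stage.
#' @return validated config list.
#' @export
pipeline_config <- function(seed = 1L, sim = sim_config(seed = seed),
                            qmin = 20, min_reads = 5, max_group_error = 0.1,
                            clone_threshold = 0.1, min_unique = 100,
                            subsample_n = 126, reps = 200,
                            large_clone_min = 50, cdr3_match = 0.30,
                            proteome_mode = "DIA") {
  stopifnot(qmin >= 0, min_reads >= 1,
            max_group_error >= 0, max_group_error <= 1,
            clone_threshold >= 0, clone_threshold <= 1,
            cdr3_match >= 0, cdr3_match <= 1,
            proteome_mode %in% c("DDA", "DIA"))
  list(seed = as.integer(seed), sim = sim, qmin = qmin, min_reads = min_reads,
       max_group_error = max_group_error, clone_threshold = clone_threshold,
       min_unique = min_unique, subsample_n = subsample_n, reps = reps,
       large_clone_min = large_clone_min, cdr3_match = cdr3_match,
       proteome_mode = proteome_mode)
}

# polynomial rolling hash of the deparsed config (mod 2^31-1, so arithmetic
# stays exact in doubles), for output provenance lines
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = ""))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full pipeline on a simulated longitudinal pair
#'
#' Simulate -> reads -> consensus -> annotate -> clones -> metrics ->
#' proteome, writing TSV outputs (rearrangements, metrics, overlap, proteome
#' report, rejection log) plus a provenance file carrying the seed and
#' config hash. Reruns with an identical config are byte-identical.
#'
#' @param config [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @param subject subject label.
#' @return invisibly, a list with the in-memory stage outputs
#'   (`rearrangements`, `metrics`, `overlap`, `proteome`, `rejections`).
#' @export
run_pipeline <- function(config, out_dir, subject = "S1") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- vh_toy_germline()
  pair <- simulate_longitudinal_pair(config$sim, subject, ref)
  mol <- rbind(pair$bl$molecules, pair$fup6$molecules)
  rd <- generate_reads(mol, config$sim)
  res <- consensus_pipeline(rd$reads, rd$manifest, config$qmin,
                            config$min_reads, config$max_group_error)
  ann <- annotate_rearrangements(res$unique_sequences, ref)
  rear <- assign_clones(ann$rearrangements, config$clone_threshold)
  pooled <- assign_clones(ann$rearrangements, config$clone_threshold,
                          pool_timepoints = TRUE)
  metrics <- repertoire_metrics(rear, config$subsample_n, config$reps,
                                config$seed, config$min_unique)
  ov <- list()
  for (subset in unique(pooled$cell_subset)) {
    bl_ids <- pooled$clone_id[pooled$cell_subset == subset &
                              pooled$timepoint == "BL"]
    f6_ids <- pooled$clone_id[pooled$cell_subset == subset &
                              pooled$timepoint == "FUP6"]
    if (!qc_filter_sample(length(bl_ids), config$min_unique) ||
        !qc_filter_sample(length(f6_ids), config$min_unique)) next
    o <- clonal_overlap(bl_ids, f6_ids, config$subsample_n, config$reps,
                        config$seed, min_unique = config$min_unique)
    o$subject <- subject; o$cell_subset <- subset
    ov[[subset]] <- o
  }
  overlap <- if (length(ov)) do.call(rbind, ov) else NULL
  set.seed(config$seed + 1L)
  peps <- simulate_peptides(mol, mode = config$proteome_mode)
  db <- build_patient_db(rear[rear$timepoint == "BL", ],
                         rear[rear$timepoint == "FUP6", ])
  prot <- match_report(db, peps, config$proteome_mode, config$cdr3_match)

  write_airr(rear, file.path(out_dir, "rearrangements.tsv"))
  write_tsv(metrics, file.path(out_dir, "metrics.tsv"))
  if (!is.null(overlap)) write_tsv(overlap, file.path(out_dir, "overlap.tsv"))
  write_tsv(prot, file.path(out_dir, "proteome_matches.tsv"))
  write_tsv(res$rejections, file.path(out_dir, "consensus_rejections.tsv"))
  writeLines(c(paste0("seed\t", config$seed),
               paste0("config_hash\t", config_hash(config))),
             file.path(out_dir, "provenance.tsv"))
  invisible(list(rearrangements = rear, pooled = pooled, metrics = metrics,
                 overlap = overlap, proteome = prot,
                 rejections = res$rejections, truth = pair))
}
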