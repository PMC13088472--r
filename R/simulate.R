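# ---- synthetic repertoire generator -----------------------------------------
# Emulates the statistical structure of sorted peripheral B-cell subsets:
# naive (N) diverse and essentially unmutated, double-negative (DN), memory (M)
# and plasmablasts (P) progressively more expanded, mutated and class-switched.
# All randomness flows through R's RNG; callers seed via the config.

.subset_index_tags <- c(N = "AACGTG", DN = "CGTACA", M = "GTCAGT", P = "TGACTC")

.bases <- c("A", "C", "G", "T")

random_dna <- function(n) paste0(sample(.bases, n, replace = TRUE), collapse = "")

#' Default per-subset simulation settings
#'
#' One list per sorted B-cell subset. Clone sizes are in unique sequences per
#' clone and follow a truncated zeta (power) law so that repertoires contain
#' both singletons and clones with more than 50 members. SHM rates are
#' per-site substitution probabilities against the germline; naive cells are
#' essentially unmutated and IgD/IgM, antigen-experienced subsets are mutated
#' and class-switched.
#'
#' @return Named list with entries `N`, `DN`, `M`, `P`.
#' @export
subset_defaults <- function() {
  list(
    N  = list(n_clones = 300L, clone_size_law = list(name = "zeta", s = 3.0, max = 3L),
              shm_rate = 0.001,
              isotype_probs = c(IgD = 0.45, IgM = 0.50, IgG = 0.03, IgA = 0.02)),
    DN = list(n_clones = 150L, clone_size_law = list(name = "zeta", s = 2.0, max = 100L),
              shm_rate = 0.03,
              isotype_probs = c(IgD = 0.05, IgM = 0.35, IgG = 0.40, IgA = 0.20)),
    M  = list(n_clones = 120L, clone_size_law = list(name = "zeta", s = 1.8, max = 150L),
              shm_rate = 0.05,
              isotype_probs = c(IgD = 0.02, IgM = 0.18, IgG = 0.50, IgA = 0.30)),
    P  = list(n_clones = 80L,  clone_size_law = list(name = "zeta", s = 1.5, max = 200L),
              shm_rate = 0.06,
              isotype_probs = c(IgD = 0.01, IgM = 0.09, IgG = 0.60, IgA = 0.30))
  )
}

#' Simulation configuration
#'
#' Assembles and validates all generator settings. Probability vectors must
#' sum to one; rates and fractions must lie in `[0, 1]`; the UMI length is 8
#' or 12 nt as used by the sequencing protocol being emulated.
#'
#' @param seed integer seed controlling every downstream draw.
#' @param subsets per-subset settings, see [subset_defaults()].
#' @param vfamily_probs sampling probabilities over V families IGHV1-IGHV5.
#' @param insert_max maximum N/D/N junction insert length in nt (multiple of 3).
#' @param reads_per_molecule_law `list(name = "constant", value = k)` or
#'   `list(name = "poisson", lambda = l)`.
#' @param per_base_read_error substitution error probability per sequenced base.
#' @param umi_length 8 or 12.
#' @param q15_fraction fraction of reads assigned Phred 15 instead of 30,
#'   exercising the quality filter.
#' @param retention_fraction probability that a baseline clone re-seeds the
#'   six-month follow-up repertoire.
#' @param fup6_diversity_scale multiplier on `n_clones` at follow-up.
#' @return A validated `vhrep_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       subsets = subset_defaults(),
                       vfamily_probs = c(IGHV1 = 0.15, IGHV2 = 0.10, IGHV3 = 0.35,
                                         IGHV4 = 0.25, IGHV5 = 0.15),
                       insert_max = 30L,
                       reads_per_molecule_law = list(name = "poisson", lambda = 8),
                       per_base_read_error = 0.001,
                       umi_length = 12L,
                       q15_fraction = 0.05,
                       retention_fraction = 0.02,
                       fup6_diversity_scale = 1.0) {
  stopifnot(abs(sum(vfamily_probs) - 1) < 1e-9,
            per_base_read_error >= 0, per_base_read_error <= 1,
            retention_fraction >= 0, retention_fraction <= 1,
            umi_length %in% c(8L, 12L),
            insert_max %% 3L == 0L)
  for (s in names(subsets)) {
    cfg <- subsets[[s]]
    stopifnot(abs(sum(cfg$isotype_probs) - 1) < 1e-9,
              cfg$shm_rate >= 0, cfg$shm_rate <= 1, cfg$n_clones >= 1)
  }
  structure(list(seed = as.integer(seed), subsets = subsets,
                 vfamily_probs = vfamily_probs, insert_max = as.integer(insert_max),
                 reads_per_molecule_law = reads_per_molecule_law,
                 per_base_read_error = per_base_read_error,
                 umi_length = as.integer(umi_length), q15_fraction = q15_fraction,
                 retention_fraction = retention_fraction,
                 fup6_diversity_scale = fup6_diversity_scale),
            class = "vhrep_sim_config")
}

#' Recombine a naive VH molecule from germline segments
#'
#' Joins a V segment (up to and including its conserved cysteine anchor
#' codon), a random in-frame N/D/N insert, and a J segment (from its
#' conserved tryptophan/phenylalanine anchor codon onward). Inserts that
#' introduce a stop codon are resampled, so every emitted molecule is
#' productive. The junction runs from the V anchor codon through the J anchor
#' codon inclusive.
#'
#' @param ref germline reference data.frame.
#' @param vfamily_probs named sampling probabilities over V families present
#'   in `ref`.
#' @param insert_max maximum insert length (nt, multiple of 3).
#' @return list with `nt_sequence`, `v_name`, `j_name`, `junction_nt`,
#'   `junction_start` (0-based) and `junction_length`.
#' @export
recombine_vdj <- function(ref, vfamily_probs = NULL, insert_max = 30L) {
  vs <- ref[ref$segment_class == "V", , drop = FALSE]
  js <- ref[ref$segment_class == "J", , drop = FALSE]
  if (!nrow(vs) || !nrow(js)) stop("reference lacks V or J segments")
  if (is.null(vfamily_probs)) {
    vi <- sample(nrow(vs), 1L)
  } else {
    fam <- sample(names(vfamily_probs), 1L, prob = vfamily_probs)
    cand <- which(vs$family == fam)
    if (!length(cand)) stop("no V segment of family ", fam, " in reference")
    vi <- cand[sample.int(length(cand), 1L)]
  }
  ji <- sample(nrow(js), 1L)
  v <- vs[vi, ]; j <- js[ji, ]
  v_prefix <- substr(v$nt_sequence, 1L, v$anchor_offset + 3L)
  j_suffix <- substr(j$nt_sequence, j$anchor_offset + 1L, nchar(j$nt_sequence))
  for (try in 1:200) {
    ins_len <- 3L * sample.int(insert_max %/% 3L + 1L, 1L) - 3L
    insert <- if (ins_len > 0) random_dna(ins_len) else ""
    seq <- paste0(v_prefix, insert, j_suffix)
    if (!grepl("\\*", translate_nt(seq))) {
      junction_start <- v$anchor_offset
      junction_length <- 3L + ins_len + 3L
      return(list(nt_sequence = seq, v_name = v$name, j_name = j$name,
                  junction_nt = substr(seq, junction_start + 1L,
                                       junction_start + junction_length),
                  junction_start = junction_start,
                  junction_length = junction_length))
    }
  }
  stop("could not draw a stop-free junction insert in 200 attempts")
}

#' Apply somatic hypermutation to a VH molecule
#'
#' Substitutes each eligible site independently with probability `shm_rate`
#' to a uniformly chosen different base. By default the junction is spared so
#' that all members of a simulated clone keep an identical junction and the
#' true clonal partition is recoverable by clustering; set
#' `mutate_junction = TRUE` for stress tests.
#'
#' @param nt_sequence molecule sequence.
#' @param shm_rate per-site substitution probability in `[0, 1]`.
#' @param junction_start 0-based start of the junction.
#' @param junction_length junction length in nt.
#' @param mutate_junction allow substitutions inside the junction.
#' @return list with `nt_sequence`, `n_mutations` (all eligible sites) and
#'   `n_mutations_v` (sites 5' of the junction, i.e. the germline-alignable
#'   V region that SHM quantification uses).
#' @export
apply_shm <- function(nt_sequence, shm_rate, junction_start, junction_length,
                      mutate_junction = FALSE) {
  stopifnot(shm_rate >= 0, shm_rate <= 1)
  n <- nchar(nt_sequence)
  eligible <- seq_len(n)
  if (!mutate_junction)
    eligible <- setdiff(eligible, (junction_start + 1L):(junction_start + junction_length))
  hit <- eligible[stats::runif(length(eligible)) < shm_rate]
  if (!length(hit))
    return(list(nt_sequence = nt_sequence, n_mutations = 0L, n_mutations_v = 0L))
  v <- strsplit(nt_sequence, "")[[1]]
  v[hit] <- vapply(v[hit], function(b) sample(setdiff(.bases, b), 1L), character(1))
  list(nt_sequence = paste0(v, collapse = ""),
       n_mutations = length(hit),
       n_mutations_v = sum(hit <= junction_start))
}

.draw_clone_sizes <- function(law, n) {
  switch(law$name,
    constant = rep(as.integer(law$value), n),
    zeta = {
      k <- seq_len(law$max)
      p <- k^(-law$s)
      sample(k, n, replace = TRUE, prob = p / sum(p))
    },
    stop("unknown clone_size_law: ", law$name))
}

.draw_reads_per_molecule <- function(law, n) {
  switch(law$name,
    constant = rep(as.integer(law$value), n),
    poisson = stats::rpois(n, law$lambda),
    stop("unknown reads_per_molecule_law: ", law$name))
}

# expand one founder clone into `size` member molecules (independent SHM
# draws). Draws that introduce a stop codon are redrawn: circulating B cells
# are under productive selection, and stop-bearing variants would be removed
# by the productivity filter downstream, distorting clone sizes.
.expand_clone <- function(founder, size, shm_rate, mutate_junction = FALSE) {
  lapply(seq_len(size), function(i) {
    for (try in 1:50) {
      m <- apply_shm(founder$nt_sequence, shm_rate,
                     founder$junction_start, founder$junction_length,
                     mutate_junction = mutate_junction)
      if (!grepl("\\*", translate_nt(m$nt_sequence))) break
    }
    c(founder[c("v_name", "j_name", "junction_nt", "junction_start",
                "junction_length")], m)
  })
}

#' Simulate one repertoire sample (all four subsets)
#'
#' Draws founders by V(D)J recombination, clone sizes from the configured
#' law, and clone members as independent SHM draws from each founder. Members
#' of one clone therefore share V gene, J gene and junction, satisfying the
#' clone-definition preconditions exactly.
#'
#' @param config [sim_config()] object. The caller controls seeding.
#' @param subject subject label.
#' @param timepoint "BL" or "FUP6".
#' @param ref germline reference, default the packaged toy set.
#' @param founders optional named list (per subset) of founder lists to reuse
#'   (longitudinal retention); missing founders are drawn fresh.
#' @param mutate_junction propagate to [apply_shm()].
#' @return list with `molecules` (the SimulatedTruth table: one row per
#'   molecule with subject, timepoint, subset, true_clone_id, sequence,
#'   isotype, V/J truth, junction truth, realized mutation counts) and
#'   `founders` (per-subset founder lists, for longitudinal reuse).
#' @export
simulate_repertoire <- function(config, subject = "S1", timepoint = "BL",
                                ref = vh_toy_germline(), founders = NULL,
                                mutate_junction = FALSE) {
  out <- list(); founder_out <- list()
  mol_counter <- 0L
  for (subset in names(config$subsets)) {
    cfg <- config$subsets[[subset]]
    fs <- founders[[subset]]
    n_new <- cfg$n_clones - length(fs)
    # distinct founders must be distinguishable as clones: redraw any fresh
    # founder whose junction sits within 0.2 normalized Hamming of an
    # existing same-V/J/length founder (twice the clustering cut, so the
    # true partition is identifiable by construction)
    same_lineage <- function(a, b) {
      a$v_name == b$v_name && a$j_name == b$j_name &&
        nchar(a$junction_nt) == nchar(b$junction_nt) &&
        normalized_hamming(a$junction_nt, b$junction_nt) <= 0.2
    }
    for (k in seq_len(max(n_new, 0L))) {
      for (try in 1:200) {
        cand <- recombine_vdj(ref, config$vfamily_probs, config$insert_max)
        if (!any(vapply(fs, same_lineage, TRUE, a = cand))) break
      }
      fs[[length(fs) + 1L]] <- cand
    }
    sizes <- .draw_clone_sizes(cfg$clone_size_law, length(fs))
    # lineage ids: retained founders keep their baseline id, fresh founders
    # get a timepoint-scoped id so labels never collide across timepoints
    for (ci in seq_along(fs)) {
      if (is.null(fs[[ci]]$lineage_id))
        fs[[ci]]$lineage_id <- paste0(subject, "_", timepoint, "_", subset, "_L", ci)
    }
    rows <- vector("list", length(fs))
    for (ci in seq_along(fs)) {
      members <- .expand_clone(fs[[ci]], sizes[ci], cfg$shm_rate, mutate_junction)
      clone_id <- paste0(subject, "_", timepoint, "_", subset, "_C", ci)
      rows[[ci]] <- data.frame(
        molecule_id = paste0("M", mol_counter + seq_along(members)),
        subject = subject, timepoint = timepoint, subset = subset,
        true_clone_id = clone_id,
        true_lineage_id = fs[[ci]]$lineage_id,
        nt_sequence = vapply(members, `[[`, "", "nt_sequence"),
        isotype = sample(names(cfg$isotype_probs), length(members),
                         replace = TRUE, prob = cfg$isotype_probs),
        v_name = fs[[ci]]$v_name, j_name = fs[[ci]]$j_name,
        true_junction_nt = fs[[ci]]$junction_nt,
        junction_start = fs[[ci]]$junction_start,
        junction_length = fs[[ci]]$junction_length,
        n_mutations = vapply(members, `[[`, 0L, "n_mutations"),
        n_mutations_v = vapply(members, `[[`, 0L, "n_mutations_v"),
        stringsAsFactors = FALSE
      )
      mol_counter <- mol_counter + length(members)
    }
    out[[subset]] <- do.call(rbind, rows)
    founder_out[[subset]] <- fs
  }
  list(molecules = do.call(rbind, out), founders = founder_out)
}

#' Simulate a longitudinal baseline / six-month follow-up pair
#'
#' Each baseline clone is retained independently with probability
#' `retention_fraction`: a retained clone keeps its junction lineage (same
#' V/J and junction) but draws fresh SHM and clone size at follow-up. New
#' clones are recombined so the follow-up repertoire holds
#' `fup6_diversity_scale * n_clones` clones per subset.
#'
#' @param config [sim_config()].
#' @param subject subject label.
#' @param ref germline reference.
#' @return list with `bl`, `fup6` (each as [simulate_repertoire()] output)
#'   and `true_retained` (per subset, the number of baseline lineages
#'   re-seeded at follow-up).
#' @export
simulate_longitudinal_pair <- function(config, subject = "S1",
                                       ref = vh_toy_germline()) {
  set.seed(config$seed)
  bl <- simulate_repertoire(config, subject, "BL", ref)
  retained <- list(); n_ret <- integer(0)
  cfg2 <- config
  for (subset in names(config$subsets)) {
    fs <- bl$founders[[subset]]
    keep <- stats::runif(length(fs)) < config$retention_fraction
    retained[[subset]] <- fs[keep]
    n_ret[subset] <- sum(keep)
    cfg2$subsets[[subset]]$n_clones <-
      max(as.integer(round(config$fup6_diversity_scale *
                           config$subsets[[subset]]$n_clones)), sum(keep))
  }
  fup6 <- simulate_repertoire(cfg2, subject, "FUP6", ref, founders = retained)
  list(bl = bl, fup6 = fup6, true_retained = n_ret)
}

#' Generate UMI-tagged sequencing reads for simulated molecules
#'
#' Each molecule receives a unique UMI and a number of reads drawn from the
#' configured law. A read is the 6-nt subset index tag, the UMI, and the
#' molecule sequence with i.i.d. per-base substitution errors. Qualities are
#' constant Phred 30, except a configured fraction of reads at Phred 15 so
#' the quality filter has something to remove.
#'
#' @param molecules SimulatedTruth molecule table.
#' @param config [sim_config()].
#' @return list with `reads` (read_id, index_tag, umi, payload, qualities as
#'   a Phred+33 string) and `manifest` (one row per molecule: index_tag, umi,
#'   subject, timepoint, subset, isotype, umi_length — the library annotation
#'   that travels with the FASTQ).
#' @export
generate_reads <- function(molecules, config) {
  n_mol <- nrow(molecules)
  repeat {  # unique UMI per molecule within each subset tag
    umis <- vapply(seq_len(n_mol), function(i) random_dna(config$umi_length), "")
    if (!anyDuplicated(paste(molecules$subset, umis))) break
  }
  nreads <- .draw_reads_per_molecule(config$reads_per_molecule_law, n_mol)
  idx <- rep(seq_len(n_mol), nreads)
  payload <- molecules$nt_sequence[idx]
  if (config$per_base_read_error > 0 && length(idx)) {
    payload <- vapply(payload, function(s) {
      v <- strsplit(s, "")[[1]]
      hit <- which(stats::runif(length(v)) < config$per_base_read_error)
      if (length(hit))
        v[hit] <- vapply(v[hit], function(b) sample(setdiff(.bases, b), 1L), "")
      paste0(v, collapse = "")
    }, "", USE.NAMES = FALSE)
  }
  qchar <- ifelse(stats::runif(length(idx)) < config$q15_fraction,
                  rawToChar(as.raw(15L + 33L)), rawToChar(as.raw(30L + 33L)))
  quals <- vapply(seq_along(idx), function(i)
    strrep(qchar[i], nchar(payload[i])), "")
  reads <- data.frame(
    read_id = sprintf("R%d", seq_along(idx)),
    index_tag = .subset_index_tags[molecules$subset[idx]],
    umi = umis[idx], payload = payload, qualities = quals,
    stringsAsFactors = FALSE, row.names = NULL
  )
  manifest <- data.frame(
    index_tag = .subset_index_tags[molecules$subset],
    umi = umis, subject = molecules$subject, timepoint = molecules$timepoint,
    subset = molecules$subset, isotype = molecules$isotype,
    umi_length = config$umi_length, stringsAsFactors = FALSE, row.names = NULL
  )
  list(reads = reads, manifest = manifest)
}

#' Simulate mass-spectrometry peptide observations from a repertoire
#'
#' Translates each sampled molecule, digests it in silico with trypsin, and
#' emits a random subset of the resulting peptides with q-values below the
#' mode's FDR cutoff. Decoys are residue-shuffled true peptides with q-values
#' spanning the cutoff, so downstream FDR filtering is exercised.
#'
#' @param molecules SimulatedTruth molecule table (or any table with an
#'   `nt_sequence` column of in-frame VH sequences).
#' @param sampling_fraction fraction of molecules observed.
#' @param decoy_fraction decoys emitted per true peptide.
#' @param mode "DDA" or "DIA" (sets the q-value scale via the mode's cutoff).
#' @param peptide_emit_prob probability that each tryptic peptide of a
#'   sampled molecule is observed.
#' @return data.frame with columns `peptide`, `q_value`, `mode`.
#' @export
simulate_peptides <- function(molecules, sampling_fraction = 0.5,
                              decoy_fraction = 0.2, mode = "DIA",
                              peptide_emit_prob = 0.8) {
  stopifnot(sampling_fraction >= 0, sampling_fraction <= 1,
            decoy_fraction >= 0, decoy_fraction <= 1)
  cutoff <- fdr_cutoff(mode)
  n_take <- as.integer(round(sampling_fraction * nrow(molecules)))
  if (n_take == 0)
    return(data.frame(peptide = character(0), q_value = numeric(0),
                      mode = character(0), stringsAsFactors = FALSE))
  take <- sample(nrow(molecules), n_take)
  peps <- unlist(lapply(molecules$nt_sequence[take], function(nt) {
    aa <- translate_nt(nt)
    digest_tryptic(aa)$peptide
  }), use.names = FALSE)
  peps <- peps[stats::runif(length(peps)) < peptide_emit_prob]
  obs <- data.frame(peptide = peps,
                    q_value = stats::runif(length(peps), 0, cutoff * 0.9),
                    mode = mode, stringsAsFactors = FALSE)
  n_decoy <- as.integer(round(decoy_fraction * length(peps)))
  if (n_decoy > 0) {
    src <- sample(peps, n_decoy, replace = TRUE)
    dec <- vapply(src, function(p)
      paste0(sample(strsplit(p, "")[[1]]), collapse = ""), "", USE.NAMES = FALSE)
    obs <- rbind(obs, data.frame(peptide = dec,
                                 q_value = stats::runif(n_decoy, 0, 2 * cutoff),
                                 mode = mode, stringsAsFactors = FALSE))
  }
  obs
}
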