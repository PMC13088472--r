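# synthetic repertoire generator

test_that("recombined molecules have well-formed, anchored, in-frame junctions", {
  ref <- vh_toy_germline()
  set.seed(11)
  for (i in 1:50) {
    m <- recombine_vdj(ref, insert_max = 30L)
    expect_identical(substr(m$nt_sequence, m$junction_start + 1,
                            m$junction_start + m$junction_length),
                     m$junction_nt)
    expect_equal(m$junction_length %% 3, 0)
    aa <- vhrep:::translate_nt(m$junction_nt)
    expect_match(aa, "^C")                      # conserved Cys anchor
    expect_match(aa, "[WF]$")                   # conserved Trp/Phe anchor
    expect_false(grepl("\\*", vhrep:::translate_nt(m$nt_sequence)))
  }
})

test_that("zero-insert recombination yields the 6-nt anchor-only junction", {
  ref <- vh_toy_germline()[c(1, 11), ]            # one V, one J
  set.seed(1)
  m <- recombine_vdj(ref, insert_max = 0L)
  expect_equal(m$junction_length, 6L)
  expect_match(vhrep:::translate_nt(m$junction_nt), "^C[WF]$")
})

test_that("V-family sampling frequencies match the configured probabilities", {
  ref <- vh_toy_germline()
  probs <- c(IGHV1 = 0.2, IGHV2 = 0.2, IGHV3 = 0.2, IGHV4 = 0.2, IGHV5 = 0.2)
  set.seed(42)
  fams <- vapply(1:1000, function(i)
    vhrep:::v_family_of(recombine_vdj(ref, probs)$v_name), "")
  ci <- qnorm(0.995) * sqrt(0.2 * 0.8 / 1000)     # binomial 99% CI
  for (f in names(probs))
    expect_lt(abs(mean(fams == f) - 0.2), ci + 1e-12)
})

test_that("SHM substitution counts follow the configured rate", {
  ref <- vh_toy_germline()
  set.seed(5)
  m <- recombine_vdj(ref)
  # rate 0: identity; junction untouched at any rate
  r0 <- apply_shm(m$nt_sequence, 0, m$junction_start, m$junction_length)
  expect_identical(r0$nt_sequence, m$nt_sequence)
  expect_equal(r0$n_mutations, 0L)
  r1 <- apply_shm(m$nt_sequence, 1, m$junction_start, m$junction_length)
  eligible <- setdiff(seq_len(nchar(m$nt_sequence)),
                      (m$junction_start + 1):(m$junction_start + m$junction_length))
  v0 <- strsplit(m$nt_sequence, "")[[1]]; v1 <- strsplit(r1$nt_sequence, "")[[1]]
  expect_true(all(v0[eligible] != v1[eligible]))
  expect_identical(substr(r1$nt_sequence, m$junction_start + 1,
                          m$junction_start + m$junction_length), m$junction_nt)
  # realized count ~ Binomial(10000, 0.05) within its 99% CI
  long <- paste0(strrep("ACGGTA", 1667), "TGCTGG")  # 10002 eligible + 6 junction
  rr <- apply_shm(paste0(long, "AAAAAA"), 0.05, nchar(long), 6L)
  n_sites <- nchar(long)
  expect_lt(abs(rr$n_mutations - n_sites * 0.05),
            qnorm(0.995) * sqrt(n_sites * 0.05 * 0.95))
})

test_that("read generation respects coverage, error rate and UMI sharing", {
  cfg <- small_sim_config(seed = 2, n_clones = 3L)
  set.seed(2)
  rep <- simulate_repertoire(cfg)
  rd <- generate_reads(rep$molecules, cfg)
  expect_equal(nrow(rd$reads), 5 * nrow(rep$molecules))
  # error-free reads of one molecule are identical payloads
  one <- rd$reads[rd$reads$umi == rd$reads$umi[1] &
                  rd$reads$index_tag == rd$reads$index_tag[1], ]
  expect_equal(length(unique(one$payload)), 1L)
  expect_equal(nrow(one), 5L)
  # zero reads per molecule -> empty read set
  cfg0 <- small_sim_config(seed = 2, n_clones = 2L, reads = 0)
  rd0 <- generate_reads(rep$molecules[1:3, ], cfg0)
  expect_equal(nrow(rd0$reads), 0L)
  # realized per-base error within binomial 99% CI
  cfg_e <- small_sim_config(seed = 3, n_clones = 10L, error = 0.01, reads = 3)
  set.seed(3)
  rep_e <- simulate_repertoire(cfg_e)
  rd_e <- generate_reads(rep_e$molecules, cfg_e)
  idx <- match(paste0(rd_e$reads$index_tag, rd_e$reads$umi),
               paste0(rd_e$manifest$index_tag, rd_e$manifest$umi))
  true_seq <- rep_e$molecules$nt_sequence[idx]
  mm <- sum(mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                   rd_e$reads$payload, true_seq))
  n_bases <- sum(nchar(rd_e$reads$payload))
  expect_lt(abs(mm - n_bases * 0.01), qnorm(0.995) * sqrt(n_bases * 0.01 * 0.99))
})

test_that("longitudinal retention behaves at its extremes and on average", {
  # retention 0: no shared lineages; retention 1 at scale 1: all shared
  cfg0 <- small_sim_config(seed = 4, n_clones = 10L)
  cfg0$retention_fraction <- 0
  p0 <- simulate_longitudinal_pair(cfg0)
  expect_length(intersect(p0$bl$molecules$true_lineage_id,
                          p0$fup6$molecules$true_lineage_id), 0L)
  cfg1 <- small_sim_config(seed = 4, n_clones = 10L)
  cfg1$retention_fraction <- 1
  p1 <- simulate_longitudinal_pair(cfg1)
  expect_setequal(unique(p1$fup6$molecules$true_lineage_id),
                  unique(p1$bl$molecules$true_lineage_id))
  # retained FUP6 clones keep their ancestor's V/J and junction
  bl_one <- p1$bl$molecules[!duplicated(p1$bl$molecules$true_lineage_id), ]
  f6_one <- p1$fup6$molecules[!duplicated(p1$fup6$molecules$true_lineage_id), ]
  mi <- match(f6_one$true_lineage_id, bl_one$true_lineage_id)
  expect_identical(f6_one$v_name, bl_one$v_name[mi])
  expect_identical(f6_one$true_junction_nt, bl_one$true_junction_nt[mi])
  # mean retained count over replicates ~ Binomial(n_clones_total, r)
  subs <- subset_defaults()[c("N")]
  subs$N$n_clones <- 100L
  tot <- 0
  for (s in 1:50) {
    cfg <- sim_config(seed = s, subsets = subs, retention_fraction = 0.02)
    tot <- tot + simulate_longitudinal_pair(cfg)$true_retained[["N"]]
  }
  n_draws <- 50 * 100
  expect_lt(abs(tot - n_draws * 0.02), qnorm(0.995) * sqrt(n_draws * 0.02 * 0.98))
})

test_that("identical config and seed reproduce byte-identical truth", {
  cfg <- small_sim_config(seed = 9, n_clones = 5L)
  p1 <- simulate_longitudinal_pair(cfg)
  p2 <- simulate_longitudinal_pair(cfg)
  expect_identical(p1$bl$molecules, p2$bl$molecules)
  expect_identical(p1$fup6$molecules, p2$fup6$molecules)
})

test_that("realized clone sizes follow the configured power law", {
  subs <- list(M = subset_defaults()$M)
  subs$M$n_clones <- 600L
  subs$M$clone_size_law <- list(name = "zeta", s = 2, max = 20L)
  cfg <- sim_config(seed = 31, subsets = subs)
  set.seed(31)
  rep <- simulate_repertoire(cfg)
  sizes <- as.integer(table(rep$molecules$true_clone_id))
  k <- 1:20; p <- k^-2 / sum(k^-2)
  obs <- tabulate(sizes, 20)
  # pool the sparse tail so expected counts stay reasonable
  cutk <- 6
  obs2 <- c(obs[1:cutk], sum(obs[(cutk + 1):20]))
  p2 <- c(p[1:cutk], sum(p[(cutk + 1):20]))
  gof <- suppressWarnings(chisq.test(obs2, p = p2))
  expect_gt(gof$p.value, 0.01)
})

test_that("simulated peptides respect fractions and map back to sources", {
  cfg <- small_sim_config(seed = 12, n_clones = 4L)
  set.seed(12)
  rep <- simulate_repertoire(cfg)
  set.seed(12)
  expect_equal(nrow(simulate_peptides(rep$molecules, 0, 0)), 0L)
  set.seed(12)
  obs <- simulate_peptides(rep$molecules, 1, 0, mode = "DIA",
                           peptide_emit_prob = 1)
  expect_true(all(obs$q_value <= 0.01))
  prots <- vhrep:::translate_nt(rep$molecules$nt_sequence)
  hits <- vapply(obs$peptide, function(p) any(grepl(p, prots, fixed = TRUE)),
                 TRUE)
  expect_true(all(hits))
})
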