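# diversity, clone-size, usage, SHM and overlap metrics

test_that("sample admission floor is a sharp boundary at 100", {
  expect_false(qc_filter_sample(99))
  expect_true(qc_filter_sample(100))
  expect_true(qc_filter_sample(126))
})

test_that("Hill numbers match closed forms and are monotone in q", {
  expect_equal(hill_diversity(c(1, 1, 1, 1), 0), 4)
  expect_equal(hill_diversity(c(1, 1, 1, 1), 1), 4)
  expect_equal(hill_diversity(c(2, 1, 1), 1), exp(1.5 * log(2)),
               tolerance = 1e-10)
  expect_error(hill_diversity(numeric(0), 0), "empty")
  set.seed(27)
  for (i in 1:1000) {
    sizes <- sample(1:50, sample(1:30, 1), replace = TRUE)
    h0 <- hill_diversity(sizes, 0)
    h1 <- hill_diversity(sizes, 1)
    h2 <- hill_diversity(sizes, 2)
    expect_lte(h1, h0 + 1e-9)
    expect_lte(h2, h1 + 1e-9)
    expect_gte(h1, 1 - 1e-9)
  }
})

test_that("bootstrap diversity matches the distinct-draw closed form", {
  # 126 singleton clones: E[q0 of a with-replacement draw of 126]
  ids <- paste0("c", 1:126)
  res <- bootstrap_diversity(ids, qs = 0, n = 126, reps = 200, seed = 5)
  expected <- 126 * (1 - (1 - 1 / 126)^126)
  se <- res$sd_hill / sqrt(res$n_reps)
  expect_lt(abs(res$mean_hill - expected), 3 * se)
  # one clone: both orders are exactly 1 with zero spread
  one <- bootstrap_diversity(rep("c1", 150), qs = c(0, 1), seed = 5)
  expect_equal(one$mean_hill, c(1, 1))
  expect_equal(one$sd_hill, c(0, 0))
  # determinism
  r1 <- bootstrap_diversity(ids, seed = 11)
  r2 <- bootstrap_diversity(ids, seed = 11)
  expect_identical(r1, r2)
  expect_error(bootstrap_diversity(paste0("c", 1:99)), "admission floor")
})

test_that("subsampling makes diversity insensitive to sample duplication", {
  set.seed(28)
  ids <- sample(paste0("c", 1:60), 300, replace = TRUE, prob = (1:60)^-1.5)
  base <- bootstrap_diversity(ids, seed = 3)
  doubled <- bootstrap_diversity(c(ids, ids), seed = 3)
  for (i in 1:2) {
    se <- sqrt(base$sd_hill[i]^2 + doubled$sd_hill[i]^2) / sqrt(base$n_reps[i])
    expect_lt(abs(base$mean_hill[i] - doubled$mean_hill[i]), 2 * se)
  }
})

test_that("large-clone percentage uses a strict > threshold", {
  expect_equal(pct_large_clones(c(60, 10, 5)), 100 / 3)
  expect_equal(pct_large_clones(c(50)), 0)
  expect_equal(pct_large_clones(c(51, 60, 70)), 100)
  expect_error(pct_large_clones(integer(0)), "empty")
})

test_that("usage fractions cover the fixed universe and recover simulation probs", {
  u <- usage_fractions(rep("IGHV3", 4))
  expect_equal(unname(u["IGHV3"]), 1)
  expect_equal(sum(u), 1)
  expect_length(u, 7)
  u2 <- usage_fractions(c("IGHV1", "IGHV1", "IGHV2", "IGHV2"))
  expect_equal(unname(u2[c("IGHV1", "IGHV2", "IGHV3")]), c(0.5, 0.5, 0))
  # multinomial recovery at n = 2000
  probs <- c(IGHV1 = 0.15, IGHV2 = 0.10, IGHV3 = 0.35, IGHV4 = 0.25,
             IGHV5 = 0.15)
  set.seed(29)
  draws <- sample(names(probs), 2000, TRUE, probs)
  got <- usage_fractions(draws)
  for (f in names(probs)) {
    ci <- qnorm(0.995) * sqrt(probs[f] * (1 - probs[f]) / 2000)
    expect_lt(abs(got[f] - probs[f]), ci)
  }
})

test_that("SHM summary is the unweighted mean over unique sequences", {
  expect_equal(shm_summary(c(0, 0, 0)), 0)
  expect_equal(shm_summary(c(0.01, 0.03)), 0.02)
  expect_error(shm_summary(numeric(0)), "empty")
})

test_that("clonal overlap hits its bounds and is monotone in retention", {
  # identical one-clone samples -> exactly 1; disjoint -> exactly 0
  one <- rep("cl1", 120)
  expect_equal(clonal_overlap(one, one, seed = 1)$mean_overlap, 1)
  expect_equal(clonal_overlap(rep("a", 120), rep("b", 120), seed = 1)$mean_overlap, 0)
  # monotone in simulator retention_fraction, averaged over 5 seeds
  mean_ov <- function(retention) {
    vals <- vapply(1:5, function(s) {
      subs <- list(M = subset_defaults()$M)
      subs$M$n_clones <- 60L
      subs$M$clone_size_law <- list(name = "zeta", s = 1.2, max = 12L)
      cfg <- sim_config(seed = 100 * s, subsets = subs,
                        retention_fraction = retention)
      pair <- simulate_longitudinal_pair(cfg)
      bl <- pair$bl$molecules; f6 <- pair$fup6$molecules
      bl_u <- bl[!duplicated(bl$nt_sequence), ]
      f6_u <- f6[!duplicated(f6$nt_sequence), ]
      clonal_overlap(bl_u$true_lineage_id, f6_u$true_lineage_id,
                     seed = s, min_unique = 50)$mean_overlap
    }, 0)
    mean(vals)
  }
  ovs <- vapply(c(0, 0.25, 0.5, 1), mean_ov, 0)
  expect_equal(ovs[1], 0)
  expect_true(all(diff(ovs) > 0))
})

test_that("full-sample q0 equals the clone count from the clone table", {
  cfg <- small_sim_config(seed = 30, n_clones = 20L)
  set.seed(30)
  rep <- simulate_repertoire(cfg)
  rd <- generate_reads(rep$molecules, cfg)
  ann <- annotate_rearrangements(consensus_pipeline(rd$reads, rd$manifest)$unique_sequences)
  rear <- assign_clones(ann$rearrangements)
  m <- rear[rear$cell_subset == "M", ]
  expect_equal(hill_diversity(as.integer(table(m$clone_id)), 0),
               nrow(clone_table(m)))
})

test_that("the tidy metric panel is complete, bounded and deterministic", {
  subs <- subset_defaults()[c("N", "M")]
  subs$N$n_clones <- 150L; subs$M$n_clones <- 60L
  cfg <- sim_config(seed = 33, subsets = subs)
  set.seed(33)
  rep <- simulate_repertoire(cfg)
  u <- rep$molecules[!duplicated(paste(rep$molecules$subset,
                                       rep$molecules$nt_sequence)), ]
  rear <- data.frame(sequence_id = paste0("U", seq_len(nrow(u))),
                     sequence = u$nt_sequence, v_call = u$v_name,
                     j_call = u$j_name,
                     v_family = vhrep:::v_family_of(u$v_name),
                     junction = u$true_junction_nt,
                     junction_length = nchar(u$true_junction_nt),
                     junction_aa = vhrep:::translate_nt(u$true_junction_nt),
                     productive = TRUE, c_call = u$isotype,
                     duplicate_count = 1L, subject = u$subject,
                     timepoint = u$timepoint, cell_subset = u$subset,
                     shm_count = u$n_mutations_v,
                     shm_freq = u$n_mutations_v / 288,
                     stringsAsFactors = FALSE)
  rear <- assign_clones(rear)
  m1 <- repertoire_metrics(rear, seed = 2)
  m2 <- repertoire_metrics(rear, seed = 2)
  expect_identical(m1, m2)
  usage <- m1[grepl("^usage_", m1$metric), ]
  expect_true(all(usage$value >= 0 & usage$value <= 1))
  for (k in split(usage, paste(usage$cell_subset, grepl("IGHV", usage$metric))))
    expect_equal(sum(k$value), 1, tolerance = 1e-9)
  expect_true(all(m1$value[m1$metric == "pct_large_clones_gt50"] >= 0 &
                  m1$value[m1$metric == "pct_large_clones_gt50"] <= 100))
})
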