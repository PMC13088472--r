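# patient database, tryptic digest, peptide mapping, CDR3 coverage

mk_rear <- function(seqs, junctions, timepoint = "BL", subset = "M",
                    isotype = "IgG") {
  data.frame(sequence_id = paste0(timepoint, "_", seq_along(seqs)),
             sequence = seqs, junction = junctions,
             junction_aa = vhrep:::translate_nt(junctions),
             productive = TRUE, c_call = isotype, timepoint = timepoint,
             cell_subset = subset, stringsAsFactors = FALSE)
}

test_that("tryptic digest follows the K/R-not-before-P rule", {
  d <- digest_tryptic("AKPRGK", min_length = 1, max_length = Inf)
  expect_equal(d$peptide, c("AKPR", "GK"))
  d2 <- digest_tryptic("MNQWSTV", min_length = 1, max_length = Inf)
  expect_equal(d2$peptide, "MNQWSTV")
  # conservation: fragments concatenate to the input
  set.seed(35)
  for (i in 1:25) {
    aa <- paste0(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                        sample(10:60, 1), TRUE), collapse = "")
    d3 <- digest_tryptic(aa, min_length = 1, max_length = Inf)
    expect_equal(paste0(d3$peptide, collapse = ""), aa)
    # per-position oracle: each boundary is after K/R not followed by P
    v <- strsplit(aa, "")[[1]]
    cuts <- which(v %in% c("K", "R"))
    cuts <- cuts[cuts < length(v) & v[cuts + 1] != "P"]
    expect_equal(d3$end[-nrow(d3)], cuts)
  }
  # missed cleavages extend fragments
  dm <- digest_tryptic("AAAKCCCRDDD", missed_cleavages = 1,
                       min_length = 1, max_length = Inf)
  expect_true(all(c("AAAK", "CCCR", "DDD", "AAAKCCCR", "CCCRDDD") %in% dm$peptide))
})

test_that("patient database combines timepoints and deduplicates proteins", {
  set.seed(36)
  ref <- vh_toy_germline()
  m1 <- recombine_vdj(ref); m2 <- recombine_vdj(ref)
  bl <- mk_rear(c(m1$nt_sequence, m2$nt_sequence),
                c(m1$junction_nt, m2$junction_nt), "BL")
  f6 <- mk_rear(m1$nt_sequence, m1$junction_nt, "FUP6")
  db <- build_patient_db(bl, f6)
  expect_equal(nrow(db), 2L)
  shared <- db[db$vh_aa == vhrep:::translate_nt(m1$nt_sequence), ]
  expect_equal(shared$timepoints, "BL,FUP6")
  # CDR3 span = junction minus anchors, and sits inside the protein
  for (i in seq_len(nrow(db))) {
    expect_equal(substr(db$vh_aa[i], db$cdr3_start[i] + 1, db$cdr3_end[i]),
                 db$cdr3_aa[i])
  }
  # empty follow-up: database is the baseline translations
  expect_equal(nrow(build_patient_db(bl, NULL)), 2L)
})

test_that("FDR filtering applies the mode-specific cutoff", {
  obs <- data.frame(peptide = c("AAAAAA", "CCCCCC", "DDDDDD"),
                    q_value = c(0.05, 0.005, 0.15),
                    mode = "DDA", stringsAsFactors = FALSE)
  expect_equal(filter_peptides(obs, "DDA")$peptide, c("CCCCCC", "AAAAAA"))
  obs$mode <- "DIA"
  expect_equal(filter_peptides(obs, "DIA")$peptide, "CCCCCC")
  expect_error(fdr_cutoff("SRM"), "unknown")
  expect_equal(nrow(filter_peptides(obs[0, ], "DDA")), 0L)
})

test_that("peptide mapping equals a brute-force substring oracle", {
  set.seed(37)
  ref <- vh_toy_germline()
  mols <- lapply(1:20, function(i) recombine_vdj(ref))
  bl <- mk_rear(vapply(mols, `[[`, "", "nt_sequence"),
                vapply(mols, `[[`, "", "junction_nt"))
  db <- build_patient_db(bl, NULL)
  peps <- unique(unlist(lapply(db$vh_aa[1:5], function(aa)
    digest_tryptic(aa)$peptide)))
  obs <- data.frame(peptide = peps, q_value = 0.001, mode = "DIA",
                    stringsAsFactors = FALSE)
  occ <- map_peptides(db, filter_peptides(obs, "DIA"))
  # oracle: every (peptide, entry) substring occurrence is present
  for (p in peps) for (ei in seq_len(nrow(db))) {
    hits <- gregexpr(p, db$vh_aa[ei], fixed = TRUE)[[1]]
    n_hits <- if (hits[1] == -1) 0L else length(hits)
    expect_equal(sum(occ$peptide == p & occ$entry_id == db$entry_id[ei]), n_hits)
  }
  # round trip: peptides digested from an entry map back to it
  for (ei in 1:5) {
    own <- digest_tryptic(db$vh_aa[ei])$peptide
    expect_true(all(own %in% occ$peptide[occ$entry_id == db$entry_id[ei]]))
  }
})

test_that("shared-framework peptides are not unique; CDR3-private ones are", {
  # two entries: identical framework, different CDR3
  fw1 <- "MGGGGGGGGGK"; fw2 <- "SSSSSSSSSSK"
  db <- data.frame(entry_id = c("P1", "P2"),
                   vh_aa = c(paste0(fw1, "CAAAWDDK", fw2),
                             paste0(fw1, "CEEEWDDK", fw2)),
                   cdr3_aa = c("AAAWDD", "EEEWDD"),
                   cdr3_start = 12, cdr3_end = 18,
                   stringsAsFactors = FALSE)
  obs <- data.frame(peptide = c("CAAAWDDK", "CEEEWDDK", fw1),
                    q_value = 0.001, mode = "DIA", stringsAsFactors = FALSE)
  occ <- map_peptides(db, obs)
  expect_true(all(occ$unique[occ$peptide == "CAAAWDDK"]))
  expect_true(all(occ$unique[occ$peptide == "CEEEWDDK"]))
  expect_false(any(occ$unique[occ$peptide == fw1]))  # no CDR3 overlap
})

test_that("CDR3 coverage is an interval union with a sharp 30% match rule", {
  entry <- data.frame(entry_id = "P1", cdr3_start = 10, cdr3_end = 20,
                      stringsAsFactors = FALSE)
  occ <- function(s, e) data.frame(entry_id = "P1", peptide = "x", start = s,
                                   end = e, cdr3_overlap = pmax(0, pmin(e, 20) - pmax(s, 10)),
                                   unique = TRUE, stringsAsFactors = FALSE)
  # one peptide covering 3 of 10 residues: exactly 0.30 -> matched
  sc <- score_cdr3_coverage(entry, occ(7, 13))
  expect_equal(sc$coverage, 0.3)
  expect_true(sc$matched)
  # 0.29-type case: 2 of 10 residues -> unmatched
  sc2 <- score_cdr3_coverage(entry, occ(8, 12))
  expect_false(sc2$matched)
  # union, not sum: {0..3} and {2..5} of a 10-residue CDR3 -> 0.6
  sc3 <- score_cdr3_coverage(entry, rbind(occ(10, 14), occ(12, 16)))
  expect_equal(sc3$coverage, 0.6)
  # no overlapping peptide -> 0, unmatched
  sc0 <- score_cdr3_coverage(entry, occ(0, 5)[0, ])
  expect_equal(sc0$coverage, 0)
  expect_false(sc0$matched)
  # 100 random cases against the interval-union oracle
  set.seed(38)
  for (i in 1:100) {
    k <- sample(0:6, 1)
    s <- sample(0:25, k, replace = TRUE); e <- s + sample(3:12, max(k, 1), replace = TRUE)[seq_len(k)]
    oc <- if (k > 0) do.call(rbind, lapply(seq_len(k), function(j) occ(s[j], e[j])))
          else occ(0, 5)[0, ]
    oc <- oc[oc$cdr3_overlap > 0, , drop = FALSE]
    got <- score_cdr3_coverage(entry, oc)$coverage
    want <- oracle_interval_union(oc$start, oc$end, 10, 20) / 10
    expect_equal(got, want)
  }
})

test_that("coverage is monotone under added peptides and rollups count provenance", {
  set.seed(39)
  ref <- vh_toy_germline()
  mols <- lapply(1:12, function(i) recombine_vdj(ref))
  bl <- mk_rear(vapply(mols, `[[`, "", "nt_sequence"),
                vapply(mols, `[[`, "", "junction_nt"))
  db <- build_patient_db(bl, NULL)
  all_peps <- unique(unlist(lapply(db$vh_aa, function(aa)
    digest_tryptic(aa)$peptide)))
  obs_all <- data.frame(peptide = all_peps, q_value = 0.001, mode = "DIA",
                        stringsAsFactors = FALSE)
  half <- obs_all[seq_len(nrow(obs_all) %/% 2), , drop = FALSE]
  r_half <- match_report(db, half, "DIA")
  r_all <- match_report(db, obs_all, "DIA")
  expect_true(all(r_all$cdr3_coverage >= r_half$cdr3_coverage - 1e-12))
  roll <- rollup_matches(r_all, "timepoint")
  expect_true(all(roll$category %in% c("BL", "FUP6")))
  expect_equal(sum(rollup_matches(r_all, "isotype")$n_matched),
               sum(r_all$matched))
})
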