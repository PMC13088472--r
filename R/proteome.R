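# ---- proteome-transcriptome CDR3 matching -----------------------------------
# Patient-specific protein databases are translated VH transcriptomes with
# baseline and follow-up combined; identified peptides pass a mode-specific
# FDR cutoff (DDA 0.1, DIA 0.01), map by exact substring, and an entry
# matches when uniquely mapping peptides cover >= 30% of its CDR3.

#' Mode-specific peptide FDR cutoff
#'
#' @param mode "DDA" (cutoff 0.1) or "DIA" (cutoff 0.01).
#' @return numeric q-value cutoff.
#' @export
fdr_cutoff <- function(mode) {
  switch(mode, DDA = 0.1, DIA = 0.01,
         stop("unknown acquisition mode: ", mode))
}

#' In silico tryptic digest
#'
#' Cleaves C-terminal to K or R except when the next residue is P. Zero
#' missed cleavages by default; peptides outside the length window are
#' dropped (window disabled with `min_length = 1, max_length = Inf`).
#'
#' @param aa amino-acid string.
#' @param missed_cleavages 0-2 allowed missed cleavage sites, default 0.
#' @param min_length,max_length retained peptide length window, default 6-40.
#' @return data.frame with `peptide`, `start`, `end` (0-based half-open
#'   coordinates within `aa`).
#' @export
digest_tryptic <- function(aa, missed_cleavages = 0, min_length = 6,
                           max_length = 40) {
  stopifnot(nzchar(aa), missed_cleavages %in% 0:2)
  v <- strsplit(aa, "")[[1]]
  n <- length(v)
  cut_after <- which(v %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & v[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, n)            # fragment boundaries, 0-based
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1]
  out <- list()
  for (mc in 0:missed_cleavages) {
    i <- seq_len(length(starts) - mc)
    if (!length(i)) break
    s <- starts[i]; e <- ends[i + mc]
    out[[mc + 1L]] <- data.frame(
      peptide = substring(aa, s + 1L, e), start = s, end = e,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  len <- res$end - res$start
  res <- res[len >= min_length & len <= max_length, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build a patient-specific protein database from VH rearrangements
#'
#' Translates each productive VH nucleotide sequence in the V reading frame,
#' records the CDR3 amino-acid span (junction minus the two anchor
#' residues), and deduplicates identical proteins; baseline and follow-up
#' sequences are combined into one database, with provenance preserved, for
#' more sensitive peptide identification.
#'
#' @param rearrangements_bl,rearrangements_fup6 annotated rearrangement
#'   tables (either may be empty / NULL).
#' @return data.frame: `entry_id`, `vh_aa`, `cdr3_aa`, `cdr3_start`,
#'   `cdr3_end` (0-based half-open within `vh_aa`), `timepoints`
#'   (comma-joined provenance), `source_ids`, `c_call`, `cell_subset`.
#' @export
build_patient_db <- function(rearrangements_bl, rearrangements_fup6 = NULL) {
  df <- rbind(rearrangements_bl, rearrangements_fup6)
  df <- df[df$productive, , drop = FALSE]
  if (!nrow(df)) stop("no productive sequences to build a database from")
  n <- nchar(df$sequence)
  aa <- translate_nt(substr(df$sequence, 1L, n - n %% 3L))
  keep <- !grepl("\\*", aa) & !grepl("X", aa)
  df <- df[keep, , drop = FALSE]; aa <- aa[keep]
  junction_aa <- df$junction_aa
  # CDR3 = junction minus the conserved anchor residues at either end
  cdr3 <- substr(junction_aa, 2L, nchar(junction_aa) - 1L)
  jpos <- vapply(seq_along(aa), function(i)
    as.integer(regexpr(junction_aa[i], aa[i], fixed = TRUE)), 0L)
  ok <- jpos > 0L & nchar(cdr3) > 0L
  df <- df[ok, , drop = FALSE]; aa <- aa[ok]; cdr3 <- cdr3[ok]; jpos <- jpos[ok]
  cdr3_start <- jpos                        # 0-based: junction starts at jpos-1, CDR3 one later
  cdr3_end <- cdr3_start + nchar(cdr3)
  sp <- split(seq_along(aa), aa)
  sp <- sp[order(vapply(sp, min, 0L))]
  rows <- lapply(seq_along(sp), function(i) {
    ix <- sp[[i]]
    data.frame(entry_id = paste0("P", i), vh_aa = aa[ix[1]],
               cdr3_aa = cdr3[ix[1]],
               cdr3_start = cdr3_start[ix[1]], cdr3_end = cdr3_end[ix[1]],
               timepoints = paste(sort(unique(df$timepoint[ix])), collapse = ","),
               source_ids = paste(df$sequence_id[ix], collapse = ","),
               c_call = df$c_call[ix[1]], cell_subset = df$cell_subset[ix[1]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter peptide observations at the mode-specific FDR cutoff
#'
#' @param observations data.frame with `peptide`, `q_value`, `mode`.
#' @param mode "DDA" or "DIA"; observations of other modes are dropped.
#' @return retained observations (unique peptides, best q-value kept).
#' @export
filter_peptides <- function(observations, mode) {
  cutoff <- fdr_cutoff(mode)
  if (is.null(observations$q_value)) stop("observations must carry q_value")
  obs <- observations[observations$mode == mode &
                      observations$q_value <= cutoff, , drop = FALSE]
  if (!nrow(obs)) return(obs)
  obs <- obs[order(obs$q_value), ]
  obs <- obs[!duplicated(obs$peptide), , drop = FALSE]
  rownames(obs) <- NULL
  obs
}

#' Map observed peptides onto a protein database
#'
#' Exact substring matching of every peptide against every entry. A peptide
#' is *unique* when the set of its CDR3-overlapping occurrences touches
#' exactly one CDR3 group (entries sharing an identical CDR3 amino-acid
#' string count as one group — clonally related entries share framework and
#' CDR3, and only CDR3-level discrimination is biologically meaningful).
#' Peptides that never overlap a CDR3 are not CDR3-informative.
#'
#' @param db database from [build_patient_db()].
#' @param observations filtered peptide observations.
#' @param il_equivalent treat I and L as equivalent during matching
#'   (mass-spectrometry cannot distinguish them), default FALSE.
#' @return data.frame of occurrences: `peptide`, `entry_id`, `start`, `end`
#'   (0-based half-open in `vh_aa`), `cdr3_overlap` (residues), `unique`
#'   (CDR3-group uniqueness flag).
#' @export
map_peptides <- function(db, observations, il_equivalent = FALSE) {
  if (!nrow(db)) stop("empty protein database")
  empty <- data.frame(peptide = character(0), entry_id = character(0),
                      start = integer(0), end = integer(0),
                      cdr3_overlap = integer(0), unique = logical(0))
  if (!nrow(observations)) return(empty)
  canon <- function(x) if (il_equivalent) gsub("I", "L", x) else x
  targets <- canon(db$vh_aa)
  occ <- vector("list", nrow(observations))
  for (pi in seq_len(nrow(observations))) {
    pep <- observations$peptide[pi]
    # gregexpr is vectorized over targets: one scan of the whole database
    hits <- gregexpr(canon(pep), targets, fixed = TRUE)
    n_hit <- vapply(hits, function(h) if (h[1] == -1L) 0L else length(h), 0L)
    if (!sum(n_hit)) next
    ei <- rep(which(n_hit > 0L), n_hit[n_hit > 0L])
    st <- unlist(hits[n_hit > 0L], use.names = FALSE) - 1L
    en <- st + nchar(pep)
    occ[[pi]] <- data.frame(
      peptide = pep, entry_id = db$entry_id[ei], start = st, end = en,
      cdr3_overlap = pmax(0L, pmin(en, db$cdr3_end[ei]) -
                               pmax(st, db$cdr3_start[ei])),
      stringsAsFactors = FALSE)
  }
  occ <- do.call(rbind, occ)
  if (is.null(occ) || !nrow(occ)) return(empty)
  # uniqueness at the CDR3-group level, over CDR3-overlapping occurrences
  grp <- db$cdr3_aa[match(occ$entry_id, db$entry_id)]
  n_groups <- vapply(split(grp[occ$cdr3_overlap > 0], occ$peptide[occ$cdr3_overlap > 0]),
                     function(g) length(unique(g)), 0L)
  occ$unique <- occ$cdr3_overlap > 0 &
    n_groups[occ$peptide] == 1L & !is.na(n_groups[occ$peptide])
  rownames(occ) <- NULL
  occ
}

#' CDR3 coverage and match call for one database entry
#'
#' Coverage is the fraction of CDR3 residues lying under the union of the
#' entry's uniquely mapping peptide occurrences; the entry matches when
#' coverage reaches `min_coverage`.
#'
#' @param entry one row of the database.
#' @param occurrences occurrence table from [map_peptides()] (any subset;
#'   only this entry's unique, CDR3-overlapping rows are used).
#' @param min_coverage match threshold, default 0.30.
#' @return list with `coverage` and `matched`.
#' @export
score_cdr3_coverage <- function(entry, occurrences, min_coverage = 0.30) {
  cdr3_len <- entry$cdr3_end - entry$cdr3_start
  if (cdr3_len <= 0L) stop("zero-length CDR3 span")
  occ <- occurrences[occurrences$entry_id == entry$entry_id &
                     occurrences$unique & occurrences$cdr3_overlap > 0, ,
                     drop = FALSE]
  covered <- logical(cdr3_len)
  for (i in seq_len(nrow(occ))) {
    a <- max(occ$start[i], entry$cdr3_start) - entry$cdr3_start + 1L
    b <- min(occ$end[i], entry$cdr3_end) - entry$cdr3_start
    covered[a:b] <- TRUE
  }
  coverage <- mean(covered)
  list(coverage = coverage, matched = coverage >= min_coverage)
}

#' Full proteome match report
#'
#' Filters observations at the mode's FDR cutoff, maps them onto the
#' database, and scores CDR3 coverage per entry.
#'
#' @param db database from [build_patient_db()].
#' @param observations raw peptide observations.
#' @param mode "DDA" or "DIA".
#' @param min_coverage match threshold, default 0.30.
#' @return data.frame: one row per entry with `entry_id`, `cdr3_coverage`,
#'   `matched`, `timepoints`, `c_call`, `cell_subset`.
#' @export
match_report <- function(db, observations, mode, min_coverage = 0.30) {
  obs <- filter_peptides(observations, mode)
  occ <- map_peptides(db, obs)
  res <- lapply(seq_len(nrow(db)), function(i) {
    sc <- score_cdr3_coverage(db[i, ], occ, min_coverage)
    data.frame(entry_id = db$entry_id[i], cdr3_coverage = sc$coverage,
               matched = sc$matched, timepoints = db$timepoints[i],
               c_call = db$c_call[i], cell_subset = db$cell_subset[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Roll up match counts by category
#'
#' Counts matched entries per category. For `by = "timepoint"` an entry with
#' provenance `BL,FUP6` counts in both categories.
#'
#' @param report output of [match_report()].
#' @param by one of "timepoint", "isotype", "subset".
#' @return data.frame with `category` and `n_matched`.
#' @export
rollup_matches <- function(report, by = c("timepoint", "isotype", "subset")) {
  by <- match.arg(by)
  m <- report[report$matched, , drop = FALSE]
  cats <- switch(by,
    timepoint = unlist(strsplit(m$timepoints, ",")),
    isotype = m$c_call,
    subset = m$cell_subset)
  tab <- table(cats)
  data.frame(category = names(tab), n_matched = as.integer(tab),
             stringsAsFactors = FALSE)
}
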