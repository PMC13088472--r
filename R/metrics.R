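# ---- repertoire summary statistics ------------------------------------------
# Hill-number diversity on bootstrap subsamples of fixed depth (n = 126,
# 200 repetitions, admission at >= 100 unique sequences), large-clone
# percentage, SHM and usage summaries, and bootstrap clonal overlap between
# timepoints. The sampling unit is the unique sequence throughout.

#' Sample admission filter
#'
#' A repertoire sample enters diversity and overlap analyses only if it holds
#' at least `min_unique` unique sequences.
#'
#' @param n_unique unique-sequence count of the sample.
#' @param min_unique admission floor, default 100.
#' @return logical: retained?
#' @export
qc_filter_sample <- function(n_unique, min_unique = 100) {
  n_unique >= min_unique
}

#' Hill number of order q for a clone abundance vector
#'
#' `q = 0` is clone richness; `q = 1` is the exponential of Shannon entropy
#' (diversity weighted by clone size); other orders use the general form
#' `(sum p_i^q)^(1/(1-q))`.
#'
#' @param sizes positive clone sizes (unique sequences per clone).
#' @param q diversity order.
#' @return the Hill number, a single numeric value.
#' @export
hill_diversity <- function(sizes, q) {
  if (!length(sizes)) stop("empty abundance vector")
  stopifnot(all(sizes > 0))
  if (q == 0) return(length(sizes))
  p <- sizes / sum(sizes)
  if (q == 1) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

#' Bootstrap Hill diversity at fixed subsampling depth
#'
#' Per repetition, draws `n` unique sequences with replacement, tabulates
#' their clone ids into an abundance vector and computes the requested Hill
#' numbers; reports mean and sd over repetitions. Subsampling puts samples
#' of different sizes on a common footing.
#'
#' @param clone_ids clone id per unique sequence of the sample.
#' @param qs diversity orders, default `c(0, 1)`.
#' @param n subsample depth, default 126.
#' @param reps repetitions, default 200.
#' @param seed RNG seed.
#' @param min_unique admission floor, default 100.
#' @return data.frame with one row per order: `q`, `mean_hill`, `sd_hill`,
#'   `n_subsample`, `n_reps`, `seed`.
#' @export
bootstrap_diversity <- function(clone_ids, qs = c(0, 1), n = 126, reps = 200,
                                seed = 1L, min_unique = 100) {
  if (!qc_filter_sample(length(clone_ids), min_unique))
    stop("sample below the admission floor of ", min_unique,
         " unique sequences; excluded by the qc rule")
  set.seed(seed)
  hills <- matrix(0, nrow = reps, ncol = length(qs))
  for (r in seq_len(reps)) {
    draw <- sample(clone_ids, n, replace = TRUE)
    sizes <- as.integer(table(draw))
    hills[r, ] <- vapply(qs, function(q) hill_diversity(sizes, q), 0)
  }
  data.frame(q = qs, mean_hill = colMeans(hills),
             sd_hill = apply(hills, 2, stats::sd),
             n_subsample = n, n_reps = reps, seed = seed)
}

#' Percentage of large clones
#'
#' Percent of clones holding strictly more than `min_members` unique
#' sequences.
#'
#' @param sizes clone sizes.
#' @param min_members strict threshold, default 50.
#' @return percentage in `[0, 100]`.
#' @export
pct_large_clones <- function(sizes, min_members = 50) {
  if (!length(sizes)) stop("empty clone table")
  100 * sum(sizes > min_members) / length(sizes)
}

#' Usage fractions over a fixed category universe
#'
#' Fraction of unique sequences per V family or isotype. Categories absent
#' from the sample are reported as zero so vectors are comparable across
#' samples.
#'
#' @param values character vector (per unique sequence): `v_family` or
#'   isotype values.
#' @param universe category universe; defaults to IGHV1-IGHV7 when values
#'   look like V families, else IgD/IgM/IgG/IgA.
#' @return named numeric vector of fractions summing to 1 (all zeros for an
#'   empty sample).
#' @export
usage_fractions <- function(values, universe = NULL) {
  if (is.null(universe)) {
    universe <- if (any(grepl("^IGHV", values))) paste0("IGHV", 1:7)
                else c("IgD", "IgM", "IgG", "IgA")
  }
  out <- stats::setNames(numeric(length(universe)), universe)
  if (!length(values)) return(out)
  tab <- table(factor(values, levels = universe))
  out[] <- as.numeric(tab) / length(values)
  out
}

#' Mean somatic hypermutation frequency of a sample
#'
#' Unweighted mean of per-sequence SHM frequencies over unique sequences.
#'
#' @param shm_freqs per-unique-sequence SHM frequencies.
#' @return mean frequency.
#' @export
shm_summary <- function(shm_freqs) {
  if (!length(shm_freqs)) stop("empty sample")
  mean(shm_freqs)
}

#' Bootstrap clonal overlap between two timepoints
#'
#' Requires clone ids assigned on the pooled (subject, subset) stratum so a
#' clone has one identity across timepoints. Per repetition, `n` unique
#' sequences are drawn with replacement independently from each timepoint;
#' the repetition's overlap is the proportion of shared clones between the
#' two draws under the chosen denominator.
#'
#' @param clone_ids_bl,clone_ids_fup6 pooled-stratum clone ids per unique
#'   sequence at baseline / follow-up.
#' @param n subsample depth, default 126.
#' @param reps repetitions, default 200.
#' @param seed RNG seed.
#' @param definition denominator: `"jaccard"` (shared / union, default),
#'   `"bl"` (shared / clones in the baseline draw) or `"mean"` (mean of the
#'   two directional proportions).
#' @param min_unique admission floor applied to both samples, default 100.
#' @return data.frame with `mean_overlap`, `sd_overlap`, `n_reps`,
#'   `definition_tag`.
#' @export
clonal_overlap <- function(clone_ids_bl, clone_ids_fup6, n = 126, reps = 200,
                           seed = 1L, definition = c("jaccard", "bl", "mean"),
                           min_unique = 100) {
  definition <- match.arg(definition)
  if (!qc_filter_sample(length(clone_ids_bl), min_unique) ||
      !qc_filter_sample(length(clone_ids_fup6), min_unique))
    stop("both samples must pass the admission floor of ", min_unique)
  set.seed(seed)
  ov <- numeric(reps)
  for (r in seq_len(reps)) {
    a <- unique(sample(clone_ids_bl, n, replace = TRUE))
    b <- unique(sample(clone_ids_fup6, n, replace = TRUE))
    shared <- length(intersect(a, b))
    ov[r] <- switch(definition,
      jaccard = shared / length(union(a, b)),
      bl = shared / length(a),
      mean = (shared / length(a) + shared / length(b)) / 2)
  }
  data.frame(mean_overlap = mean(ov), sd_overlap = stats::sd(ov),
             n_reps = reps, definition_tag = definition,
             stringsAsFactors = FALSE)
}

#' Compute the full per-sample metric panel
#'
#' Convenience wrapper producing the tidy metrics table: bootstrap Hill
#' diversity at q = 0 and q = 1, large-clone percentage, mean SHM frequency,
#' and V-family / isotype usage, per (subject, timepoint, subset) sample.
#'
#' @param rearrangements clone-assigned rearrangement table.
#' @param n,reps,seed bootstrap settings (defaults 126 / 200).
#' @param min_unique admission floor; samples below it are skipped.
#' @return tidy data.frame: `subject`, `timepoint`, `cell_subset`, `metric`,
#'   `value`, `sd`, `n_unique`.
#' @export
repertoire_metrics <- function(rearrangements, n = 126, reps = 200, seed = 1L,
                               min_unique = 100) {
  key <- paste(rearrangements$subject, rearrangements$timepoint,
               rearrangements$cell_subset, sep = "|")
  out <- list()
  for (k in unique(key)) {
    df <- rearrangements[key == k, ]
    if (!qc_filter_sample(nrow(df), min_unique)) next
    sizes <- as.integer(table(df$clone_id))
    div <- bootstrap_diversity(df$clone_id, c(0, 1), n, reps, seed, min_unique)
    vals <- c(stats::setNames(div$mean_hill, paste0("diversity_q", div$q)),
              pct_large_clones_gt50 = pct_large_clones(sizes),
              mean_shm_freq = shm_summary(df$shm_freq),
              stats::setNames(usage_fractions(df$v_family),
                              paste0("usage_", names(usage_fractions(df$v_family)))),
              stats::setNames(usage_fractions(df$c_call),
                              paste0("usage_", c("IgD", "IgM", "IgG", "IgA"))))
    sds <- c(stats::setNames(div$sd_hill, paste0("diversity_q", div$q)))
    out[[k]] <- data.frame(
      subject = df$subject[1], timepoint = df$timepoint[1],
      cell_subset = df$cell_subset[1], metric = names(vals),
      value = as.numeric(vals),
      sd = as.numeric(sds[names(vals)]),
      n_unique = nrow(df), stringsAsFactors = FALSE, row.names = NULL
    )
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
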