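# ---- UMI consensus building -------------------------------------------------
# pRESTO-style collapse of UMI-tagged amplicon reads into validated unique
# sequences: mean-quality filter at Q20, per-UMI weighted majority consensus,
# admission at >=5 reads and group mismatch rate <=0.1, then duplicate
# collapse (identical sequences under different UMIs = copies).

phred_from_string <- function(q) as.integer(charToRaw(q)) - 33L

#' Filter reads by mean base quality
#'
#' Retains reads whose mean Phred score is at least `q_threshold` (mean-read
#' semantics, as in pRESTO's FilterSeq quality step). Input order is
#' preserved.
#'
#' @param reads data.frame with `payload` and `qualities` (Phred+33 string).
#' @param q_threshold minimum mean Phred, default 20.
#' @return The retained subset of `reads`.
#' @export
filter_quality <- function(reads, q_threshold = 20) {
  if (is.null(reads$qualities) || any(is.na(reads$qualities)))
    stop("reads must carry per-base qualities")
  mq <- vapply(reads$qualities, function(q) mean(phred_from_string(q)), 0,
               USE.NAMES = FALSE)
  reads[mq >= q_threshold, , drop = FALSE]
}

#' Group reads by (index tag, UMI)
#'
#' @param reads read data.frame.
#' @return Named list of read data.frames; names are `"<index_tag>:<umi>"`.
#'   Every read lands in exactly one group.
#' @export
group_by_umi <- function(reads) {
  if (!nrow(reads)) return(list())
  split(reads, paste0(reads$index_tag, ":", reads$umi))
}

#' Build a consensus sequence for one UMI read group
#'
#' Per-position majority vote weighted by summed Phred quality; positions
#' with a tied vote become `N`. The group error is the mean per-read mismatch
#' fraction against the consensus (N positions excluded). A record is emitted
#' only if the group holds at least `min_reads` reads and the group error is
#' at most `max_error`; otherwise a typed rejection is returned with reason
#' `too_few_reads`, `error_exceeded` or `length_conflict` (reads of unequal
#' length are not aligned).
#'
#' @param group read data.frame, all rows sharing one (index_tag, umi).
#' @param max_error maximum mean mismatch rate per read group, default 0.1.
#' @param min_reads minimum reads per UMI, default 5.
#' @return list with `status` ("ok" or "rejected"); on success `umi`,
#'   `index_tag`, `consensus_nt`, `read_support`, `mean_error`; on rejection
#'   `reason`.
#' @export
build_consensus <- function(group, max_error = 0.1, min_reads = 5) {
  if (!nrow(group)) stop("empty read group")
  rej <- function(reason) list(status = "rejected", reason = reason,
                               umi = group$umi[1], index_tag = group$index_tag[1],
                               read_support = nrow(group))
  if (length(unique(nchar(group$payload))) != 1L) return(rej("length_conflict"))
  if (nrow(group) < min_reads) return(rej("too_few_reads"))
  mat <- do.call(rbind, strsplit(group$payload, ""))
  qmat <- do.call(rbind, lapply(group$qualities, phred_from_string))
  # per-position summed Phred per base, as a 5 x L weight matrix
  alph <- c("A", "C", "G", "T", "N")
  w <- vapply(alph, function(b) colSums(qmat * (mat == b)), numeric(ncol(mat)))
  w <- matrix(w, ncol = length(alph),
              dimnames = list(NULL, alph))  # L x 5 even for L == 1
  wmax <- apply(w, 1, max)
  n_top <- rowSums(w == wmax)
  cons <- alph[max.col(w, ties.method = "first")]
  cons[n_top > 1L] <- "N"
  keep <- cons != "N"
  err <- if (any(keep)) {
    mean(colMeans(t(mat[, keep, drop = FALSE]) != cons[keep]))
  } else 0
  if (err > max_error) return(rej("error_exceeded"))
  list(status = "ok", umi = group$umi[1], index_tag = group$index_tag[1],
       consensus_nt = paste0(cons, collapse = ""),
       read_support = nrow(group), mean_error = err)
}

#' Collapse identical consensus sequences into unique sequences with copy counts
#'
#' Sequence copies are identical sequences carried by different UMIs within
#' one (subject, timepoint, subset) stratum; they merge into one unique
#' sequence whose `duplicate_count` is the number of merged consensus
#' records. Conflicting isotype annotations resolve to the most frequent
#' (ties lexicographic).
#'
#' @param records data.frame of consensus records annotated with `subject`,
#'   `timepoint`, `subset`, `isotype`, `consensus_nt`.
#' @return data.frame of unique sequences: `sequence_id`, `sequence`,
#'   `duplicate_count`, `subject`, `timepoint`, `subset`, `isotype`.
#' @export
collapse_duplicates <- function(records) {
  if (!nrow(records))
    return(data.frame(sequence_id = character(0), sequence = character(0),
                      duplicate_count = integer(0), subject = character(0),
                      timepoint = character(0), subset = character(0),
                      isotype = character(0), stringsAsFactors = FALSE))
  key <- paste(records$subject, records$timepoint, records$subset,
               records$consensus_nt, sep = "\r")
  grp <- split(seq_len(nrow(records)), key)
  grp <- grp[order(vapply(grp, min, 0L))]  # deterministic, input-ordered
  rows <- lapply(seq_along(grp), function(i) {
    ix <- grp[[i]]
    iso <- sort(table(records$isotype[ix]), decreasing = TRUE)
    iso <- names(iso)[iso == max(iso)][1]
    data.frame(sequence_id = paste0("U", i),
               sequence = records$consensus_nt[ix[1]],
               duplicate_count = length(ix),
               subject = records$subject[ix[1]],
               timepoint = records$timepoint[ix[1]],
               subset = records$subset[ix[1]],
               isotype = iso, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full consensus stage on a read set
#'
#' Quality filter, UMI grouping, per-group consensus, manifest join and
#' duplicate collapse in one call.
#'
#' @param reads read data.frame (see [generate_reads()]).
#' @param manifest library annotation keyed by (index_tag, umi): subject,
#'   timepoint, subset, isotype.
#' @param q_threshold mean-quality admission threshold, default 20.
#' @param min_reads minimum reads per UMI, default 5.
#' @param max_error maximum group mismatch rate, default 0.1.
#' @return list with `unique_sequences` (see [collapse_duplicates()]),
#'   `consensus` (accepted records) and `rejections` (umi, index_tag, reason,
#'   read_support).
#' @export
consensus_pipeline <- function(reads, manifest, q_threshold = 20,
                               min_reads = 5, max_error = 0.1) {
  reads <- filter_quality(reads, q_threshold)
  groups <- group_by_umi(reads)
  res <- lapply(groups, build_consensus, max_error = max_error,
                min_reads = min_reads)
  ok <- res[vapply(res, `[[`, "", "status") == "ok"]
  rejected <- res[vapply(res, `[[`, "", "status") == "rejected"]
  rejections <- if (length(rejected)) {
    data.frame(umi = vapply(rejected, `[[`, "", "umi"),
               index_tag = vapply(rejected, `[[`, "", "index_tag"),
               reason = vapply(rejected, `[[`, "", "reason"),
               read_support = vapply(rejected, `[[`, 0L, "read_support"),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(umi = character(0), index_tag = character(0),
               reason = character(0), read_support = integer(0))
  }
  if (!length(ok)) {
    return(list(unique_sequences = collapse_duplicates(
                  data.frame(subject = character(0), timepoint = character(0),
                             subset = character(0), isotype = character(0),
                             consensus_nt = character(0))),
                consensus = NULL, rejections = rejections))
  }
  cons <- data.frame(umi = vapply(ok, `[[`, "", "umi"),
                     index_tag = vapply(ok, `[[`, "", "index_tag"),
                     consensus_nt = vapply(ok, `[[`, "", "consensus_nt"),
                     read_support = vapply(ok, `[[`, 0L, "read_support"),
                     mean_error = vapply(ok, `[[`, 0, "mean_error"),
                     stringsAsFactors = FALSE, row.names = NULL)
  mi <- match(paste0(cons$index_tag, ":", cons$umi),
              paste0(manifest$index_tag, ":", manifest$umi))
  if (anyNA(mi)) stop("consensus group without manifest entry")
  cons$subject <- manifest$subject[mi]
  cons$timepoint <- manifest$timepoint[mi]
  cons$subset <- manifest$subset[mi]
  cons$isotype <- manifest$isotype[mi]
  list(unique_sequences = collapse_duplicates(cons),
       consensus = cons, rejections = rejections)
}
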