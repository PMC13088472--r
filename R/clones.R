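# ---- clone definition -------------------------------------------------------
# Three criteria: identical junction length, same IGHV and IGHJ gene
# (allele-stripped), and single-linkage clustering of the nucleotide junction
# at length-normalized Hamming distance <= 0.1. Single linkage at a fixed cut
# equals connected components of the threshold graph, realized by union-find.

#' Clone partition key for a rearrangement
#'
#' Gene-level V and J names (allele suffix stripped) plus junction length in
#' nt; only sequences sharing this key can be clonally related.
#'
#' @param v_call,j_call germline calls (may carry `*NN` allele suffixes).
#' @param junction_length junction length in nt.
#' @return character key `"<v_gene>|<j_gene>|<length>"`.
#' @export
partition_key <- function(v_call, j_call, junction_length) {
  paste(strip_allele(v_call), strip_allele(j_call), junction_length, sep = "|")
}

#' Length-normalized Hamming distance between equal-length junctions
#'
#' @param a,b nucleotide strings of equal length.
#' @return mismatches / length, in `[0, 1]`.
#' @export
normalized_hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("normalized_hamming requires equal lengths")
  .hamming_chars(a, b) / nchar(a)
}

# union-find with path compression
.uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Single-linkage clone assignment within one partition
#'
#' Connected components of the graph joining any two members whose junction
#' distance is at most `threshold`. Chaining is intentional: A-B and B-C
#' within threshold places A and C in one clone even if their direct distance
#' exceeds it (single linkage).
#'
#' @param junctions character vector of equal-length junction sequences.
#' @param threshold normalized Hamming cut, default 0.1.
#' @return integer component label per input element (1-based, arbitrary
#'   but deterministic labels).
#' @export
single_linkage_clones <- function(junctions, threshold = 0.1) {
  n <- length(junctions)
  if (!n) return(integer(0))
  if (length(unique(nchar(junctions))) != 1L)
    stop("all junctions in a partition must share one length")
  parent <- seq_len(n)
  # distances via a character matrix: columns are sequences
  mat <- matrix(unlist(strsplit(junctions, "")), ncol = n)
  len <- nrow(mat)
  for (i in seq_len(n - 1L)) {
    d <- colSums(mat[, (i + 1L):n, drop = FALSE] != mat[, i]) / len
    for (k in which(d <= threshold)) {
      ri <- .uf_find(parent, i); rj <- .uf_find(parent, i + k)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), function(i) .uf_find(parent, i), 0L)
  match(roots, unique(roots))
}

#' Assign clones across a rearrangement table
#'
#' Applies the partition key and single-linkage clustering per partition and
#' writes a `clone_id` back onto each productive rearrangement. Clone ids
#' are deterministic: clones are numbered by decreasing size, ties by the
#' lexicographically smallest member `sequence_id`.
#'
#' @param rearrangements annotated AIRR-style data.frame.
#' @param threshold junction distance cut, default 0.1.
#' @param pool_timepoints cluster `BL` and `FUP6` jointly within (subject,
#'   subset) so clone identity is comparable across timepoints (required for
#'   overlap analyses). Default `FALSE`: strata are (subject, timepoint,
#'   subset).
#' @param productive_only drop non-productive sequences first (default TRUE).
#' @return the input table, productive rows only, with a `clone_id` column.
#' @export
assign_clones <- function(rearrangements, threshold = 0.1,
                          pool_timepoints = FALSE, productive_only = TRUE) {
  df <- rearrangements
  if (productive_only) df <- df[df$productive, , drop = FALSE]
  if (!nrow(df)) { df$clone_id <- character(0); return(df) }
  stratum <- if (pool_timepoints) paste(df$subject, df$cell_subset, sep = "|")
             else paste(df$subject, df$timepoint, df$cell_subset, sep = "|")
  pk <- partition_key(df$v_call, df$j_call, df$junction_length)
  full_key <- paste(stratum, pk, sep = "|")
  df$clone_id <- NA_character_
  for (key in unique(full_key)) {
    ix <- which(full_key == key)
    comp <- single_linkage_clones(df$junction[ix], threshold)
    # deterministic clone labels: size desc, then smallest member sequence_id
    size <- table(comp)
    first_id <- vapply(split(df$sequence_id[ix], comp), min, "")
    ord <- order(-as.integer(size[names(first_id)]), first_id)
    relabel <- match(as.character(comp), names(first_id)[ord])
    df$clone_id[ix] <- paste0(stratum[ix], "|", pk[ix], "|CL", relabel)
  }
  df
}

#' Summarize a clone assignment into a clone table
#'
#' @param rearrangements clone-assigned table from [assign_clones()].
#' @return data.frame with one row per clone: `clone_id`, `size` (unique
#'   sequences), `v_gene`, `j_gene`, `junction_length`, `subject`,
#'   `cell_subset`.
#' @export
clone_table <- function(rearrangements) {
  sp <- split(seq_len(nrow(rearrangements)), rearrangements$clone_id)
  rows <- lapply(sp, function(ix) {
    r <- rearrangements[ix[1], ]
    data.frame(clone_id = r$clone_id, size = length(ix),
               v_gene = strip_allele(r$v_call), j_gene = strip_allele(r$j_call),
               junction_length = r$junction_length,
               subject = r$subject, cell_subset = r$cell_subset,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(-out$size, out$clone_id), ]
}
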