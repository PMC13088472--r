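#' Packaged toy germline reference
#'
#' Returns the built-in germline segment set used by the simulator and the
#' annotator: ten V segments spanning families IGHV1-IGHV5 (two genes per
#' family, 291 nt each, conserved cysteine anchor codon at offset 288) and
#' four J segments (48 nt, conserved tryptophan/phenylalanine anchor codon at
#' offset 6). The set is synthetic and fixed; it stands in for a full IMGT
#' reference so the pipeline is self-contained.
#'
#' @return A `data.frame` with columns `name`, `segment_class` ("V" or "J"),
#'   `family`, `nt_sequence` and `anchor_offset` (0-based nt index of the
#'   anchor codon).
#' @export
vh_toy_germline <- function() {
  ref <- data.frame(
    name = c(.toy_v_names, .toy_j_names),
    segment_class = rep(c("V", "J"), c(length(.toy_v_names), length(.toy_j_names))),
    family = c(substr(.toy_v_names, 1, 5), rep("IGHJ", length(.toy_j_names))),
    nt_sequence = c(.toy_v_seqs, .toy_j_seqs),
    anchor_offset = rep(c(288L, 6L), c(length(.toy_v_names), length(.toy_j_names))),
    stringsAsFactors = FALSE
  )
  validate_germline(ref)
  ref
}

#' Validate a germline reference table
#'
#' Checks the structural invariants a reference must satisfy before it can
#' drive recombination or annotation: DNA alphabet, in-frame anchor offsets,
#' and presence of at least one V and one J segment.
#'
#' @param ref data.frame as returned by [vh_toy_germline()] or [read_germline()].
#' @return The reference, invisibly; errors on violation.
#' @export
validate_germline <- function(ref) {
  req <- c("name", "segment_class", "family", "nt_sequence", "anchor_offset")
  miss <- setdiff(req, names(ref))
  if (length(miss)) stop("germline reference missing column(s): ", paste(miss, collapse = ", "))
  if (!all(ref$segment_class %in% c("V", "D", "J")))
    stop("segment_class must be one of V, D, J")
  if (!any(ref$segment_class == "V") || !any(ref$segment_class == "J"))
    stop("reference must contain at least one V and one J segment")
  if (any(!nzchar(ref$nt_sequence)) || any(grepl("[^ACGT]", ref$nt_sequence)))
    stop("nt_sequence must be nonempty over alphabet {A,C,G,T}")
  if (any(ref$anchor_offset %% 3L != 0L))
    stop("anchor_offset must fall on a codon boundary")
  if (any(ref$anchor_offset + 3L > nchar(ref$nt_sequence)))
    stop("anchor codon must lie within the segment")
  invisible(ref)
}

#' Read a germline reference from FASTA
#'
#' Headers carry the segment metadata as `key=value` tags, e.g.
#' `>IGHV3-23*01 class=V family=IGHV3 anchor=288`.
#'
#' @param path FASTA file.
#' @return Germline reference data.frame (see [vh_toy_germline()]).
#' @export
read_germline <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  hdr <- names(seqs)
  tag <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    sub(paste0(key, "="), "", m)
  }
  ref <- data.frame(
    name = sub(" .*", "", hdr),
    segment_class = tag("class"),
    family = tag("family"),
    nt_sequence = unname(as.character(seqs)),
    anchor_offset = as.integer(tag("anchor")),
    stringsAsFactors = FALSE, row.names = NULL
  )
  validate_germline(ref)
  ref
}

#' Write a germline reference to FASTA
#'
#' @param ref germline reference data.frame.
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
write_germline <- function(ref, path) {
  validate_germline(ref)
  x <- Biostrings::DNAStringSet(ref$nt_sequence)
  names(x) <- sprintf("%s class=%s family=%s anchor=%d",
                      ref$name, ref$segment_class, ref$family, ref$anchor_offset)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# gene-level name: strip the "*NN" allele suffix
strip_allele <- function(x) sub("\\*.*$", "", x)

# IGHV family from a segment or gene name ("IGHV3-23*01" -> "IGHV3")
v_family_of <- function(x) sub("^(IGHV[0-9]+).*$", "\\1", x)

# standard genetic code, indexed by codon
.codon_table <- local({
  b <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(as.vector(t(outer(b, b, paste0))), b, paste0)))
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(unlist(aas), codons)
})

# standard-code translation of in-frame nucleotide strings; plain lookup
# kept in base R because it sits in the simulator's innermost loop
translate_nt <- function(nt) {
  if (!length(nt)) return(character(0))
  vapply(nt, function(s) {
    n <- nchar(s)
    cod <- substring(s, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
    aa <- .codon_table[cod]
    aa[is.na(aa)] <- "X"
    paste0(aa, collapse = "")
  }, "", USE.NAMES = FALSE)
}
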