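# ---- germline assignment, junction extraction, SHM --------------------------
# Self-contained replacement for IgBLAST-style annotation: best ungapped
# identity against the packaged germline set (the generator produces no
# indels), IMGT-convention junction (conserved Cys ... conserved Trp/Phe,
# anchors included), SHM counted over the germline-alignable V region.

.hamming_chars <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

#' Assign germline V and J segments to a VH sequence
#'
#' The V call is the segment maximizing ungapped identity of its region up to
#' and including the anchor codon against the sequence prefix; the J call
#' maximizes identity of its anchor-codon-onward suffix against the sequence
#' end. Ties break by identity, then lexicographically smallest segment
#' name. Anchors are projected through the alignment.
#'
#' @param nt_sequence VH nucleotide sequence.
#' @param ref germline reference data.frame.
#' @param min_v_identity V identity below which annotation fails, default 0.6.
#' @return list with `v_call`, `j_call`, `v_identity`, `j_identity`,
#'   `v_anchor_start`, `j_anchor_start` (0-based starts of the two anchor
#'   codons within the sequence) and `v_aligned_length` (nt of germline-
#'   alignable V region 5' of the junction); or `NULL` on annotation failure.
#' @export
assign_germline <- function(nt_sequence, ref, min_v_identity = 0.6) {
  vs <- ref[ref$segment_class == "V", , drop = FALSE]
  js <- ref[ref$segment_class == "J", , drop = FALSE]
  n <- nchar(nt_sequence)

  best <- function(segs, score_fun) {
    sc <- vapply(seq_len(nrow(segs)), score_fun, 0)
    ord <- order(-sc, segs$name)
    list(i = ord[1], identity = sc[ord[1]])
  }
  v_best <- best(vs, function(i) {
    tmpl <- substr(vs$nt_sequence[i], 1L, vs$anchor_offset[i] + 3L)
    len <- min(nchar(tmpl), n)
    1 - .hamming_chars(substr(tmpl, 1L, len), substr(nt_sequence, 1L, len)) / len
  })
  if (v_best$identity < min_v_identity) return(NULL)
  v <- vs[v_best$i, ]

  j_best <- best(js, function(i) {
    tmpl <- substr(js$nt_sequence[i], js$anchor_offset[i] + 1L,
                   nchar(js$nt_sequence[i]))
    len <- min(nchar(tmpl), n)
    1 - .hamming_chars(substr(tmpl, nchar(tmpl) - len + 1L, nchar(tmpl)),
                       substr(nt_sequence, n - len + 1L, n)) / len
  })
  j <- js[j_best$i, ]
  j_suffix_len <- nchar(j$nt_sequence) - j$anchor_offset

  list(v_call = v$name, j_call = j$name,
       v_identity = v_best$identity, j_identity = j_best$identity,
       v_anchor_start = v$anchor_offset,
       j_anchor_start = n - j_suffix_len,
       v_aligned_length = min(v$anchor_offset, n))
}

#' Extract the junction from an annotated sequence
#'
#' The junction spans the codons from the conserved V anchor (Cys) through
#' the conserved J anchor (Trp/Phe) inclusive — the CDR3 plus its two
#' flanking anchor residues.
#'
#' @param nt_sequence VH nucleotide sequence.
#' @param anchors list from [assign_germline()].
#' @return list with `junction_nt` and `junction_aa`, or `NULL` if the span
#'   is not a codon multiple (malformed junction).
#' @export
extract_junction <- function(nt_sequence, anchors) {
  start <- anchors$v_anchor_start
  end <- anchors$j_anchor_start + 3L
  if (end <= start || end > nchar(nt_sequence)) return(NULL)
  if ((end - start) %% 3L != 0L) return(NULL)
  junction_nt <- substr(nt_sequence, start + 1L, end)
  list(junction_nt = junction_nt, junction_aa = translate_nt(junction_nt))
}

#' Somatic hypermutation count and frequency
#'
#' Mismatches between the sequence and its assigned germline V segment over
#' the aligned V region 5' of the junction (the junction itself has no
#' germline and is excluded).
#'
#' @param nt_sequence VH nucleotide sequence.
#' @param anchors list from [assign_germline()].
#' @param ref germline reference.
#' @return list with `shm_count` and `shm_freq` (= count / aligned length).
#' @export
shm_metrics <- function(nt_sequence, anchors, ref) {
  v <- ref[ref$name == anchors$v_call, ]
  len <- anchors$v_aligned_length
  shm_count <- .hamming_chars(substr(v$nt_sequence, 1L, len),
                              substr(nt_sequence, 1L, len))
  list(shm_count = shm_count, shm_freq = shm_count / len)
}

#' Is a sequence productive?
#'
#' TRUE iff the junction is in frame (codon-multiple span starting on the V
#' reading frame) and the translated VH region contains no stop codon.
#'
#' @param nt_sequence VH nucleotide sequence.
#' @param anchors list from [assign_germline()].
#' @return logical flag.
#' @export
check_productive <- function(nt_sequence, anchors) {
  span <- anchors$j_anchor_start + 3L - anchors$v_anchor_start
  if (span <= 0L || span %% 3L != 0L) return(FALSE)
  if (anchors$v_anchor_start %% 3L != 0L) return(FALSE)
  n <- nchar(nt_sequence)
  aa <- translate_nt(substr(nt_sequence, 1L, n - n %% 3L))
  !grepl("\\*", aa)
}

#' Annotate a table of unique sequences
#'
#' Runs germline assignment, junction extraction, SHM quantification and the
#' productivity check over every unique sequence, producing an AIRR-style
#' rearrangement table. Sequences failing annotation (V identity below the
#' floor, malformed junction) are excluded and logged.
#'
#' @param unique_sequences data.frame from the consensus stage (columns
#'   `sequence_id`, `sequence`, `duplicate_count`, `subject`, `timepoint`,
#'   `subset`, `isotype`).
#' @param ref germline reference, default the packaged toy set.
#' @param min_v_identity V identity floor for annotation, default 0.6.
#' @return list with `rearrangements` (AIRR-style data.frame: sequence_id,
#'   sequence, v_call, j_call, v_family, junction, junction_aa, junction_length,
#'   productive, c_call, duplicate_count, subject, timepoint, cell_subset,
#'   shm_count, shm_freq) and `failures` (sequence_id, reason).
#' @export
annotate_rearrangements <- function(unique_sequences, ref = vh_toy_germline(),
                                    min_v_identity = 0.6) {
  rows <- vector("list", nrow(unique_sequences))
  fails <- list()
  for (i in seq_len(nrow(unique_sequences))) {
    u <- unique_sequences[i, ]
    anc <- assign_germline(u$sequence, ref, min_v_identity)
    if (is.null(anc)) {
      fails[[length(fails) + 1L]] <- data.frame(sequence_id = u$sequence_id,
                                                reason = "low_v_identity")
      next
    }
    jx <- extract_junction(u$sequence, anc)
    if (is.null(jx)) {
      fails[[length(fails) + 1L]] <- data.frame(sequence_id = u$sequence_id,
                                                reason = "malformed_junction")
      next
    }
    shm <- shm_metrics(u$sequence, anc, ref)
    rows[[i]] <- data.frame(
      sequence_id = u$sequence_id, sequence = u$sequence,
      v_call = anc$v_call, j_call = anc$j_call,
      v_family = v_family_of(anc$v_call),
      junction = jx$junction_nt, junction_aa = jx$junction_aa,
      junction_length = nchar(jx$junction_nt),
      productive = check_productive(u$sequence, anc),
      c_call = u$isotype, duplicate_count = u$duplicate_count,
      subject = u$subject, timepoint = u$timepoint, cell_subset = u$subset,
      shm_count = shm$shm_count, shm_freq = shm$shm_freq,
      stringsAsFactors = FALSE
    )
  }
  list(rearrangements = do.call(rbind, rows),
       failures = if (length(fails)) do.call(rbind, fails)
                  else data.frame(sequence_id = character(0), reason = character(0)))
}
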