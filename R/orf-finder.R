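# Six-frame ORF extraction and completeness classification.
#
# A deduced protein is classified from three booleans read off the frame
# translation: is there an in-frame stop upstream of the ORF, does the ORF
# begin with a start methionine, and is the ORF flanked downstream by a
# stop codon.  The truth table:
#
#   upstream stop + Met + downstream stop  -> full_length
#   Met + downstream stop, no upstream stop-> putative_full_length
#   no Met, downstream stop                -> c_terminal_partial
#   Met, no downstream stop                -> n_terminal_partial
#   neither                                -> internal_fragment
#
# "putative_full_length" records proteins whose start methionine is present
# but cannot be anchored by an upstream in-frame stop (typically because the
# transcript begins at or just before the start codon); a putative
# full-length protein is promoted to full_length when its methionine aligns
# with the initial methionine of the protein query that retrieved it (see
# pick_protein_for_hit).

COMPLETENESS_LEVELS <- c("full_length", "putative_full_length",
                         "c_terminal_partial", "n_terminal_partial",
                         "internal_fragment")

#' Completeness class from flanking context
#'
#' @param has_upstream_stop,has_start_met,has_downstream_stop Logicals.
#' @return One of `"full_length"`, `"putative_full_length"`,
#'   `"c_terminal_partial"`, `"n_terminal_partial"`, `"internal_fragment"`.
#' @export
classify_completeness <- function(has_upstream_stop, has_start_met,
                                  has_downstream_stop) {
  ifelse(has_start_met & has_downstream_stop,
         ifelse(has_upstream_stop, "full_length", "putative_full_length"),
         ifelse(has_downstream_stop, "c_terminal_partial",
                ifelse(has_start_met, "n_terminal_partial",
                       "internal_fragment")))
}

# Map an ORF interval in frame-translation space (1-based aa positions) to
# transcript nucleotide coordinates (1-based inclusive, plus strand).
.orf_nt_coords <- function(frame, aa_start, aa_end, length_bp) {
  off <- abs(frame) - 1
  s <- off + 3 * (aa_start - 1) + 1
  e <- off + 3 * aa_end
  if (frame > 0) c(s, e) else c(length_bp - e + 1, length_bp - s + 1)
}

#' Extract candidate ORFs from a transcript
#'
#' Every maximal stop-free stretch of length at least `min_orf_len` in each
#' of the six frame translations is reported in up to two resolved forms:
#' the full stretch, and (when the stretch does not already begin with a
#' methionine but contains one) the form initiated at the first methionine.
#' Flanking booleans and the completeness class are set for each form.
#'
#' @param transcript A single-row transcript-record data.frame (or a list
#'   with `id`, `seq`, `length_bp`).
#' @param min_orf_len Minimum ORF length in amino acids (default 40).
#' @return A data.frame of deduced proteins with columns `id`,
#'   `transcript_id`, `frame`, `aa_seq`, `aa_start`, `aa_end`, `nt_start`,
#'   `nt_end`, `has_upstream_stop`, `has_start_met`, `has_downstream_stop`,
#'   `completeness`.  Zero rows when no stretch reaches `min_orf_len`.
#' @export
extract_orfs <- function(transcript, min_orf_len = 40) {
  stopifnot(min_orf_len >= 1)
  id <- transcript$id[1]
  seq <- transcript$seq[1]
  length_bp <- nchar(seq)
  frames <- six_frame_translation(seq)
  out <- vector("list", 0)
  for (k in seq_len(nrow(frames))) {
    frame <- frames$frame[k]
    aa <- frames$aa[k]
    chars <- strsplit(aa, "")[[1]]
    n <- length(chars)
    stops <- which(chars == "*")
    bounds <- c(0, stops, n + 1)
    for (j in seq_len(length(bounds) - 1)) {
      s <- bounds[j] + 1
      e <- bounds[j + 1] - 1
      if (e - s + 1 < min_orf_len) next
      upstream <- bounds[j] > 0           # stretch preceded by in-frame stop
      downstream <- bounds[j + 1] <= n    # stretch followed by stop codon
      stretch <- chars[s:e]
      starts <- s                          # the full stretch, always
      first_met <- which(stretch == "M")[1]
      if (!is.na(first_met) && first_met > 1 &&
          (e - (s + first_met - 1) + 1) >= min_orf_len)
        starts <- c(starts, s + first_met - 1)
      for (st in starts) {
        nt <- .orf_nt_coords(frame, st, e, length_bp)
        out[[length(out) + 1]] <- data.frame(
          transcript_id = id, frame = frame,
          aa_seq = paste(chars[st:e], collapse = ""),
          aa_start = st, aa_end = e, nt_start = nt[1], nt_end = nt[2],
          # the upstream-stop flag asks for a stop somewhere 5' of the
          # start methionine, so a Met-initiated form inherits the flag of
          # its enclosing stretch
          has_upstream_stop = upstream,
          has_start_met = chars[st] == "M",
          has_downstream_stop = downstream,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(id = character(), transcript_id = character(),
                      frame = integer(), aa_seq = character(),
                      aa_start = integer(), aa_end = integer(),
                      nt_start = integer(), nt_end = integer(),
                      has_upstream_stop = logical(),
                      has_start_met = logical(),
                      has_downstream_stop = logical(),
                      completeness = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res$completeness <- classify_completeness(res$has_upstream_stop,
                                            res$has_start_met,
                                            res$has_downstream_stop)
  frame_tag <- ifelse(res$frame > 0, paste0("+", res$frame), res$frame)
  res$id <- paste0(res$transcript_id, "|", frame_tag, "|", res$aa_start)
  res[, c("id", "transcript_id", "frame", "aa_seq", "aa_start", "aa_end",
          "nt_start", "nt_end", "has_upstream_stop", "has_start_met",
          "has_downstream_stop", "completeness")]
}

# Frame precedence for tie-breaking: +1,+2,+3,-1,-2,-3.
.frame_rank <- function(frame) match(frame, c(1, 2, 3, -1, -2, -3))

#' Pick the deduced protein supported by a protein query
#'
#' Among the candidate ORFs of a transcript, returns the one with the
#' highest local-alignment score against the query (ties broken towards the
#' longer ORF, then the lower frame in the order +1,+2,+3,-1,-2,-3).  When
#' the chosen ORF's methionine aligns with the query's initial methionine, a
#' putative full-length classification is promoted to full_length.
#'
#' @param orfs Data.frame from [extract_orfs()] (non-empty).
#' @param query_seq Amino-acid string of the protein query.
#' @param scoring Alignment scoring parameters, see [alignment_scoring()].
#' @return A single-row deduced-protein data.frame with an extra column
#'   `query_score`.
#' @export
pick_protein_for_hit <- function(orfs, query_seq,
                                 scoring = alignment_scoring()) {
  stopifnot(nrow(orfs) > 0)
  scores <- local_alignment_scores(query_seq, orfs$aa_seq, scoring)
  ord <- order(-scores, -nchar(orfs$aa_seq), .frame_rank(orfs$frame))
  best <- orfs[ord[1], , drop = FALSE]
  best$query_score <- scores[ord[1]]
  if (best$completeness == "putative_full_length" &&
      substr(query_seq, 1, 1) == "M" &&
      substr(best$aa_seq, 1, 1) == "M") {
    aln <- align_pair(best$aa_seq, query_seq, mode = "local",
                      scoring = scoring)
    if (aln$start_a == 1L && aln$start_b == 1L)
      best$completeness <- "full_length"
  }
  rownames(best) <- NULL
  best
}
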