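# Translated homology search of an assembly with protein queries, and
# reciprocal best-hit annotation against a labeled reference panel.
#
# Each query is aligned (Smith-Waterman) against all six frame translations
# of every contig; the best frame per contig is the hit.  Significance is
# estimated with the Karlin-Altschul formula E = K * m * n * exp(-lambda*S)
# using the ungapped BLOSUM62 parameters (lambda = 0.3176, K = 0.134) and
# database size n = total translated residues across the six frames.  These
# E-values order hits sensibly at desk scale; only their relative ordering
# is treated as meaningful.

KA_LAMBDA <- 0.3176
KA_K <- 0.134

.ka_evalue <- function(score, m, n) KA_K * m * n * exp(-KA_LAMBDA * score)
.ka_bitscore <- function(score) (KA_LAMBDA * score - log(KA_K)) / log(2)

# Six-frame translations of every contig, one row per (transcript, frame).
.frame_table <- function(assembly) {
  tabs <- lapply(seq_len(nrow(assembly)), function(i) {
    ft <- six_frame_translation(assembly$seq[i])
    ft$transcript_id <- assembly$id[i]
    ft
  })
  do.call(rbind, tabs)
}

#' Mine an assembly for transcripts matching protein queries
#'
#' @param queries Protein-record data.frame (the query set).
#' @param assembly Transcript-record data.frame.
#' @param evalue_cutoff Retain hits with E-value at or below this cutoff
#'   (default 1e-5; must be positive).
#' @param scoring See [alignment_scoring()].
#' @param rank Order hits by `"evalue"` (ascending, then bitscore
#'   descending) or `"score"` (raw Smith-Waterman score, descending).
#' @return A data.frame of search hits with columns `query_id`,
#'   `transcript_id`, `frame`, `score`, `bitscore`, `evalue`.
#' @export
mine_assembly <- function(queries, assembly, evalue_cutoff = 1e-5,
                          scoring = alignment_scoring(),
                          rank = c("evalue", "score")) {
  rank <- match.arg(rank)
  if (evalue_cutoff <= 0) stop("evalue_cutoff must be positive")
  stopifnot(nrow(queries) > 0, nrow(assembly) > 0)
  frames <- .frame_table(assembly)
  n_db <- sum(nchar(frames$aa))
  hits <- lapply(seq_len(nrow(queries)), function(qi) {
    qseq <- queries$seq[qi]
    sc <- local_alignment_scores(qseq, frames$aa, scoring)
    # best frame per transcript
    best <- tapply(seq_along(sc), frames$transcript_id,
                   function(ix) ix[which.max(sc[ix])])
    best <- unlist(best, use.names = FALSE)
    data.frame(query_id = queries$id[qi],
               transcript_id = frames$transcript_id[best],
               frame = frames$frame[best],
               score = sc[best],
               bitscore = .ka_bitscore(sc[best]),
               evalue = .ka_evalue(sc[best], nchar(qseq), n_db),
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  hits <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  ord <- if (rank == "evalue") order(hits$evalue, -hits$bitscore)
         else order(-hits$score)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Collapse hits to a non-redundant transcript list
#'
#' Different queries commonly retrieve the same transcript; this keeps one
#' entry per transcript with its best supporting hit (lowest E-value, then
#' highest bitscore), ordered by that E-value.
#'
#' @param hits Data.frame from [mine_assembly()].
#' @return A data.frame with the same columns, one row per transcript.
#' @export
collapse_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  ord <- order(hits$evalue, -hits$bitscore)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits$transcript_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Full local alignment for a retained hit
#'
#' @param hit Single-row data.frame from [mine_assembly()].
#' @param queries,assembly The inputs given to [mine_assembly()].
#' @param scoring See [alignment_scoring()].
#' @return An `"alignment_result"` of the query against the hit's frame
#'   translation (stops rendered as `X` for display).
#' @export
hit_alignment <- function(hit, queries, assembly,
                          scoring = alignment_scoring()) {
  qseq <- queries$seq[match(hit$query_id, queries$id)]
  tseq <- assembly$seq[match(hit$transcript_id, assembly$id)]
  aa <- chartr("*", "X", translate_frame(tseq, hit$frame))
  align_pair(qseq, aa, mode = "local", scoring = scoring)
}

# Score floor for reciprocal annotation.  Empirical null scores of shuffled
# family proteins against the panel stay below ~75 (BLOSUM62, gap 11/1,
# ~200-260 aa proteins); 100 sits well above the null's 99th percentile
# while true family members score several hundred.
DEFAULT_ANNOTATION_SCORE_FLOOR <- 100

#' Annotate a deduced protein by reciprocal best hit
#'
#' The deduced protein is aligned (locally) against every member of a
#' labeled reference panel; the class/subclass of the best-scoring member
#' is assigned (ties broken towards higher percent identity, then
#' lexicographic hit id).  Identity/similarity against the top hit are
#' computed from a global alignment, with the region-of-overlap rule
#' applied unless the protein is full length.
#'
#' @param protein Single-row deduced-protein data.frame (needs `id`,
#'   `aa_seq`, `completeness`), or a list with those elements.
#' @param panel Protein-record data.frame with `label` tags of the form
#'   `class|subclass`.
#' @param score_floor Hits scoring below this are not trusted: the protein
#'   is reported with class `"unassigned"`.
#' @param scoring See [alignment_scoring()].
#' @return A single-row annotation data.frame with columns `protein_id`,
#'   `assigned_class`, `assigned_subclass`, `top_hit_id`, `top_hit_label`,
#'   `score`, `identity_pct`, `similarity_pct`, `completeness`.
#' @export
annotate_reciprocal <- function(protein, panel,
                                score_floor = DEFAULT_ANNOTATION_SCORE_FLOOR,
                                scoring = alignment_scoring()) {
  if (any(is.na(panel$label)))
    stop("all panel members must carry a class|subclass label")
  sc <- local_alignment_scores(protein$aa_seq, panel$seq, scoring)
  top <- which(sc == max(sc))
  if (length(top) > 1) {
    ids <- vapply(top, function(i) {
      pairwise_identity(protein$aa_seq, panel$seq[i], partial_mode = TRUE,
                        scoring = scoring)$pct_identity
    }, numeric(1))
    top <- top[order(-ids, panel$id[top])]
  }
  top <- top[1]
  unassigned <- sc[top] < score_floor
  partial <- !(protein$completeness %in% c("full_length",
                                           "putative_full_length"))
  rep_ <- if (!unassigned) {
    pairwise_identity(protein$aa_seq, panel$seq[top],
                      partial_mode = partial, scoring = scoring)
  } else list(pct_identity = NA_real_, pct_similarity = NA_real_)
  lab <- strsplit(panel$label[top], "|", fixed = TRUE)[[1]]
  data.frame(
    protein_id = protein$id,
    assigned_class = if (unassigned) "unassigned" else lab[1],
    assigned_subclass = if (unassigned) NA_character_ else lab[2],
    top_hit_id = panel$id[top],
    top_hit_label = panel$label[top],
    score = sc[top],
    identity_pct = rep_$pct_identity,
    similarity_pct = rep_$pct_similarity,
    completeness = protein$completeness,
    stringsAsFactors = FALSE)
}
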