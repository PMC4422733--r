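# End-to-end orchestration: mine -> deduce -> annotate -> vet -> compare
# -> report.  These functions are the programmatic surface driven by the
# scripts under analysis/ and by the acceptance script.

#' Write a data.frame as TSV
#'
#' @param x Data.frame.
#' @param path Output path (directories are created).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign report names to annotated proteins
#'
#' Names follow the convention `<prefix>-<Subclass>-<RomanNumeral>`,
#' numbering within each subclass in descending annotation-score order.
#'
#' @param annotations Data.frame with `assigned_subclass` and `score`.
#' @param prefix Name prefix (default `"Synth"`).
#' @return The input with a `name` column added.
#' @export
assign_protein_names <- function(annotations, prefix = "Synth") {
  annotations$name <- NA_character_
  for (sc in unique(annotations$assigned_subclass)) {
    ix <- which(annotations$assigned_subclass == sc)
    ord <- ix[order(-annotations$score[ix])]
    annotations$name[ord] <- paste0(prefix, "-", sc, "-",
                                    as.character(utils::as.roman(
                                      seq_along(ord))))
  }
  annotations
}

#' Validate a pipeline configuration
#'
#' @param evalue_cutoff Positive E-value cutoff.
#' @param min_orf_len Minimum ORF length in aa (>= 1).
#' @param t_same,t_distinct Correspondence thresholds with
#'   `0 < t_distinct < t_same <= 100`.
#' @param score_floor Annotation score floor (>= 0).
#' @param prefix Protein-name prefix.
#' @param scoring See [alignment_scoring()].
#' @return A validated config list.
#' @export
pipeline_config <- function(evalue_cutoff = 1e-5, min_orf_len = 40,
                            t_same = 90, t_distinct = 50,
                            score_floor = DEFAULT_ANNOTATION_SCORE_FLOOR,
                            prefix = "Synth",
                            scoring = alignment_scoring()) {
  if (evalue_cutoff <= 0) stop("config error: evalue_cutoff must be > 0")
  if (min_orf_len < 1) stop("config error: min_orf_len must be >= 1")
  if (!(t_distinct > 0 && t_distinct < t_same && t_same <= 100))
    stop("config error: need 0 < t_distinct < t_same <= 100")
  if (score_floor < 0) stop("config error: score_floor must be >= 0")
  list(evalue_cutoff = evalue_cutoff, min_orf_len = min_orf_len,
       t_same = t_same, t_distinct = t_distinct, score_floor = score_floor,
       prefix = prefix, scoring = scoring)
}

#' Mine, deduce and annotate one assembly
#'
#' Runs the single-assembly workflow: translated homology search with the
#' reference panel as queries, collapse to unique transcripts, ORF
#' extraction and query-guided protein deduction, reciprocal best-hit
#' annotation (unassigned proteins are discarded as non-family), optional
#' domain vetting, and report-name assignment.
#'
#' @param assembly Transcript-record data.frame.
#' @param panel Labeled protein-record data.frame (queries and reciprocal
#'   reference).
#' @param profiles Domain profile set from [load_domain_profiles()], or
#'   `NULL` to skip domain scanning.
#' @param config See [pipeline_config()].
#' @return A list with `hits` (all retained search hits), `proteins`
#'   (annotated deduced proteins incl. `aa_seq`), `transcripts` (mined
#'   transcript report), `annotations` (annotation report), `counts`
#'   (genes per class/subclass), `domains` (domain calls, if profiles
#'   given).
#' @export
run_single <- function(assembly, panel, profiles = NULL,
                       config = pipeline_config()) {
  empty <- list(hits = data.frame(), proteins = data.frame(),
                transcripts = data.frame(), annotations = data.frame(),
                counts = data.frame(), domains = data.frame())
  if (is.null(assembly) || nrow(assembly) == 0) {
    warning("empty assembly: nothing to mine")
    return(empty)
  }
  hits <- mine_assembly(panel, assembly, evalue_cutoff = config$evalue_cutoff,
                        scoring = config$scoring)
  uniq <- collapse_hits(hits)
  if (nrow(uniq) == 0) {
    warning("no hits at the configured E-value cutoff")
    return(empty)
  }
  prot_rows <- list(); dom_rows <- list()
  for (k in seq_len(nrow(uniq))) {
    tx <- assembly[assembly$id == uniq$transcript_id[k], , drop = FALSE]
    orfs <- extract_orfs(tx, min_orf_len = config$min_orf_len)
    if (nrow(orfs) == 0) next
    qseq <- panel$seq[match(uniq$query_id[k], panel$id)]
    prot <- pick_protein_for_hit(orfs, qseq, scoring = config$scoring)
    ann <- annotate_reciprocal(prot, panel, score_floor = config$score_floor,
                               scoring = config$scoring)
    if (ann$assigned_class == "unassigned") next
    row <- cbind(ann,
                 data.frame(transcript_id = prot$transcript_id,
                            frame = prot$frame, aa_seq = prot$aa_seq,
                            aa_len = nchar(prot$aa_seq),
                            nt_start = prot$nt_start, nt_end = prot$nt_end,
                            evalue = uniq$evalue[k],
                            bitscore = uniq$bitscore[k],
                            stringsAsFactors = FALSE))
    if (!is.null(profiles)) {
      dc <- scan_domains(prot, profiles)
      row$domains <- paste(dc$domain_name[dc$present], collapse = ",")
      row$domains_expected_ok <- vet_domain_complement(
        dc, ann$assigned_class, ann$completeness)
      dom_rows[[length(dom_rows) + 1]] <- dc
    }
    prot_rows[[length(prot_rows) + 1]] <- row
  }
  if (length(prot_rows) == 0) {
    warning("no annotatable family proteins found")
    return(empty)
  }
  proteins <- do.call(rbind, prot_rows)
  proteins <- assign_protein_names(proteins, prefix = config$prefix)
  proteins$class <- proteins$assigned_class
  proteins$subclass <- proteins$assigned_subclass
  transcripts <- data.frame(
    class = proteins$class, subclass = proteins$subclass,
    transcript_id = proteins$transcript_id,
    length_bp = assembly$length_bp[match(proteins$transcript_id,
                                         assembly$id)],
    stringsAsFactors = FALSE)
  transcripts <- transcripts[order(transcripts$class, transcripts$subclass), ]
  ann_cols <- c("name", "transcript_id", "aa_len", "completeness",
                "top_hit_id", "identity_pct", "similarity_pct", "evalue")
  if ("domains" %in% names(proteins)) ann_cols <- append(ann_cols, "domains",
                                                         after = 4)
  annotations <- proteins[order(proteins$class, proteins$subclass,
                                proteins$name), ann_cols]
  counts <- stats::aggregate(list(n_genes = proteins$name),
                             by = list(class = proteins$class,
                                       subclass = proteins$subclass),
                             FUN = length)
  rownames(transcripts) <- rownames(annotations) <- NULL
  list(hits = hits, proteins = proteins, transcripts = transcripts,
       annotations = annotations, counts = counts,
       domains = if (length(dom_rows)) do.call(rbind, dom_rows)
                 else data.frame())
}

#' Compare two annotated assemblies and merge their catalogs
#'
#' Runs cross-assembly correspondence on the outputs of [run_single()]:
#' bidirectional best-hit pairing within subclass, additional-gene
#' detection with targeted re-search, and catalog merging.
#'
#' @param res_a,res_b Results of [run_single()] for the two assemblies.
#' @param assembly_a,assembly_b The corresponding transcript records
#'   (used by the targeted re-search; may be `NULL`).
#' @param config See [pipeline_config()].
#' @return A list with `pairs` (correspondence report), `additional`
#'   (additional-gene report), `catalog` (merged gene catalog), `counts`
#'   (merged genes per class/subclass), `total_genes`.
#' @export
run_compare <- function(res_a, res_b, assembly_a = NULL, assembly_b = NULL,
                        config = pipeline_config()) {
  set_for <- function(res) {
    if (nrow(res$proteins) == 0) {
      return(data.frame(protein_id = character(), aa_seq = character(),
                        subclass = character(), class = character(),
                        completeness = character(),
                        stringsAsFactors = FALSE))
    }
    data.frame(protein_id = res$proteins$name,
               aa_seq = res$proteins$aa_seq,
               subclass = res$proteins$subclass,
               class = res$proteins$class,
               completeness = res$proteins$completeness,
               stringsAsFactors = FALSE)
  }
  set_a <- set_for(res_a); set_b <- set_for(res_b)
  pairs <- match_assemblies(set_a, set_b, t_same = config$t_same,
                            t_distinct = config$t_distinct,
                            scoring = config$scoring)
  det <- detect_additional_genes(pairs, set_a, set_b, assembly_a, assembly_b,
                                 t_same = config$t_same,
                                 t_distinct = config$t_distinct,
                                 evalue_cutoff = config$evalue_cutoff,
                                 min_orf_len = config$min_orf_len,
                                 scoring = config$scoring)
  catalog <- merge_catalogs(det$pairs, set_a, set_b)
  counts <- catalog_counts(catalog)
  list(pairs = det$pairs, additional = det$additional, catalog = catalog,
       counts = counts, total_genes = nrow(catalog))
}
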