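# Cross-assembly correspondence: matching deduced proteins between two
# populations and classifying each pair by its overlap identity.
#
# Two proteins from different assemblies that align at >= t_same percent
# identity in their region of overlap are read as the same gene; a pair
# below t_distinct (the upper edge of the typical within-subclass paralog
# band) likely represents distinct genes; pairs in between are divergent
# orthologs - more alike than paralogs, but short of one-to-one
# correspondence.  Defaults t_same = 90 and t_distinct = 50 encode the
# field-standard thresholds (>= 90% one-to-one; 30-50% among paralogs).

.is_full <- function(completeness)
  completeness %in% c("full_length", "putative_full_length")

.verdict <- function(identity, t_same, t_distinct) {
  ifelse(identity >= t_same, "same_gene",
         ifelse(identity < t_distinct, "distinct_gene",
                "divergent_ortholog"))
}

#' Match deduced proteins between two assemblies
#'
#' Pairs proteins by bidirectional best hit within each assigned subclass,
#' using the overlap identity (region-of-overlap rule applied whenever
#' either partner is partial) as the pairing score.  Unpaired proteins are
#' reported with verdict `"unmatched"`.
#'
#' @param set_a,set_b Data.frames of annotated deduced proteins with
#'   columns `protein_id`, `aa_seq`, `subclass`, `completeness` (and
#'   optionally `class`).
#' @param t_same,t_distinct Verdict thresholds (percent identity;
#'   defaults 90 and 50).
#' @param scoring See [alignment_scoring()].
#' @return A data.frame of correspondence pairs: `protein_a_id`,
#'   `protein_b_id`, `subclass`, `overlap_identity_pct`,
#'   `completeness_a`, `completeness_b`, `verdict`, `note`.
#' @export
match_assemblies <- function(set_a, set_b, t_same = 90, t_distinct = 50,
                             scoring = alignment_scoring()) {
  subclasses <- union(set_a$subclass, set_b$subclass)
  pairs <- list()
  for (sc in subclasses) {
    a <- set_a[set_a$subclass == sc, , drop = FALSE]
    b <- set_b[set_b$subclass == sc, , drop = FALSE]
    if (nrow(a) > 0 && nrow(b) > 0) {
      idm <- matrix(NA_real_, nrow(a), nrow(b))
      for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
        partial <- !(.is_full(a$completeness[i]) &&
                       .is_full(b$completeness[j]))
        idm[i, j] <- pairwise_identity(a$aa_seq[i], b$aa_seq[j],
                                       partial_mode = partial,
                                       scoring = scoring)$pct_identity
      }
      best_for_a <- apply(idm, 1, which.max)
      best_for_b <- apply(idm, 2, which.max)
      paired_a <- logical(nrow(a)); paired_b <- logical(nrow(b))
      for (i in seq_len(nrow(a))) {
        j <- best_for_a[i]
        if (best_for_b[j] == i) {
          paired_a[i] <- TRUE; paired_b[j] <- TRUE
          pairs[[length(pairs) + 1]] <- data.frame(
            protein_a_id = a$protein_id[i], protein_b_id = b$protein_id[j],
            subclass = sc, overlap_identity_pct = idm[i, j],
            completeness_a = a$completeness[i],
            completeness_b = b$completeness[j],
            verdict = .verdict(idm[i, j], t_same, t_distinct),
            note = "", stringsAsFactors = FALSE)
        }
      }
      a_un <- which(!paired_a); b_un <- which(!paired_b)
    } else {
      a_un <- seq_len(nrow(a)); b_un <- seq_len(nrow(b))
    }
    for (i in a_un)
      pairs[[length(pairs) + 1]] <- data.frame(
        protein_a_id = a$protein_id[i], protein_b_id = NA_character_,
        subclass = sc, overlap_identity_pct = NA_real_,
        completeness_a = a$completeness[i], completeness_b = NA_character_,
        verdict = "unmatched", note = "", stringsAsFactors = FALSE)
    for (j in b_un)
      pairs[[length(pairs) + 1]] <- data.frame(
        protein_a_id = NA_character_, protein_b_id = b$protein_id[j],
        subclass = sc, overlap_identity_pct = NA_real_,
        completeness_a = NA_character_, completeness_b = b$completeness[j],
        verdict = "unmatched", note = "", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pairs)
  rownames(out) <- NULL
  out
}

#' Detect population-private ("additional") genes
#'
#' An unmatched protein whose identity to every same-assembly member of
#' its subclass stays below `t_distinct` is a candidate additional gene.
#' Each candidate triggers a targeted re-search of the other assembly with
#' the candidate as query; when that search recovers a (possibly partial)
#' protein at `t_same` or better in the region of overlap, the candidate
#' is upgraded to a same-gene pair with the note `"present in both"` -
#' the gene was in both assemblies but missed by the original mining.
#'
#' @param pairs Data.frame from [match_assemblies()].
#' @param set_a,set_b Annotated protein sets given to [match_assemblies()].
#' @param assembly_a,assembly_b Transcript records of the two assemblies
#'   (for the targeted re-search); may be `NULL` to skip re-searching.
#' @param t_same,t_distinct Thresholds as in [match_assemblies()].
#' @param evalue_cutoff Cutoff for the targeted re-search.
#' @param min_orf_len Minimum ORF length for re-search translation.
#' @param scoring See [alignment_scoring()].
#' @return A list with `pairs` (updated) and `additional` (data.frame:
#'   `protein_id`, `assembly`, `subclass`, `status` of
#'   `"additional_gene"` or `"present_in_both"`).
#' @export
detect_additional_genes <- function(pairs, set_a, set_b,
                                    assembly_a = NULL, assembly_b = NULL,
                                    t_same = 90, t_distinct = 50,
                                    evalue_cutoff = 1e-5, min_orf_len = 40,
                                    scoring = alignment_scoring()) {
  additional <- list()
  for (side in c("a", "b")) {
    own_set <- if (side == "a") set_a else set_b
    other_assembly <- if (side == "a") assembly_b else assembly_a
    id_col <- paste0("protein_", side, "_id")
    un <- which(pairs$verdict == "unmatched" & !is.na(pairs[[id_col]]))
    for (k in un) {
      pid <- pairs[[id_col]][k]
      me <- own_set[own_set$protein_id == pid, , drop = FALSE]
      sibs <- own_set[own_set$subclass == me$subclass &
                        own_set$protein_id != pid, , drop = FALSE]
      if (nrow(sibs) > 0) {
        ids <- vapply(sibs$aa_seq, function(s)
          pairwise_identity(me$aa_seq, s, partial_mode = TRUE,
                            scoring = scoring)$pct_identity, numeric(1))
        if (any(ids >= t_distinct)) next
      }
      status <- "additional_gene"
      if (!is.null(other_assembly)) {
        q <- protein_records(pid, me$aa_seq)
        hits <- mine_assembly(q, other_assembly,
                              evalue_cutoff = evalue_cutoff,
                              scoring = scoring)
        if (nrow(hits) > 0) {
          top <- hits[1, ]
          tx <- other_assembly[other_assembly$id == top$transcript_id, ,
                               drop = FALSE]
          orfs <- extract_orfs(tx, min_orf_len = min_orf_len)
          if (nrow(orfs) > 0) {
            best <- pick_protein_for_hit(orfs, me$aa_seq, scoring = scoring)
            ovl <- pairwise_identity(me$aa_seq, best$aa_seq,
                                     partial_mode = TRUE,
                                     scoring = scoring)$pct_identity
            if (ovl >= t_same) {
              status <- "present_in_both"
              pairs$verdict[k] <- "same_gene"
              pairs$note[k] <- "present in both"
              pairs$overlap_identity_pct[k] <- ovl
              other_id_col <- if (side == "a") "protein_b_id"
                              else "protein_a_id"
              other_comp_col <- if (side == "a") "completeness_b"
                                else "completeness_a"
              pairs[[other_id_col]][k] <- best$id
              pairs[[other_comp_col]][k] <- best$completeness
            }
          }
        }
      }
      additional[[length(additional) + 1]] <- data.frame(
        protein_id = pid, assembly = side, subclass = me$subclass,
        status = status, stringsAsFactors = FALSE)
    }
  }
  additional <- if (length(additional)) do.call(rbind, additional)
    else data.frame(protein_id = character(), assembly = character(),
                    subclass = character(), status = character(),
                    stringsAsFactors = FALSE)
  list(pairs = pairs, additional = additional)
}

#' Merge two assemblies' annotations into a gene catalog
#'
#' One catalog entry per inferred gene: a matched pair at or above
#' `t_distinct` (same gene or divergent ortholog) contributes one gene; a
#' pair below `t_distinct` contributes two (the populations carry distinct
#' genes); every unmatched protein contributes one.  Completeness is
#' upgraded to the best evidence across assemblies (a full-length partner
#' beats a partial one).
#'
#' @param pairs Data.frame from [match_assemblies()] (after
#'   [detect_additional_genes()] upgrades, if run).
#' @param set_a,set_b Annotated protein sets (used for class lookups).
#' @return A data.frame with one row per gene: `gene`, `class`,
#'   `subclass`, `protein_a_id`, `protein_b_id`, `type_a`, `type_b`
#'   (`"F"`/`"P"`), `overlap_identity_pct`, `completeness_merged`,
#'   `origin` (`"paired"`, `"distinct_pair_a"`, `"distinct_pair_b"`,
#'   `"only_a"`, `"only_b"`).
#' @export
merge_catalogs <- function(pairs, set_a, set_b) {
  class_of <- function(set, pid) {
    if ("class" %in% names(set)) set$class[match(pid, set$protein_id)]
    else NA_character_
  }
  fp <- function(completeness)
    ifelse(is.na(completeness), NA_character_,
           ifelse(.is_full(completeness), "F", "P"))
  rows <- list()
  add_row <- function(...) rows[[length(rows) + 1]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  for (k in seq_len(nrow(pairs))) {
    p <- pairs[k, ]
    cls <- if (!is.na(p$protein_a_id)) class_of(set_a, p$protein_a_id)
           else class_of(set_b, p$protein_b_id)
    if (p$verdict %in% c("same_gene", "divergent_ortholog")) {
      merged <- if (.is_full(p$completeness_a) || .is_full(p$completeness_b))
        "full_length" else "partial"
      add_row(gene = p$protein_a_id, class = cls, subclass = p$subclass,
              protein_a_id = p$protein_a_id, protein_b_id = p$protein_b_id,
              type_a = fp(p$completeness_a), type_b = fp(p$completeness_b),
              overlap_identity_pct = p$overlap_identity_pct,
              completeness_merged = merged, origin = "paired")
    } else if (p$verdict == "distinct_gene") {
      add_row(gene = p$protein_a_id, class = cls, subclass = p$subclass,
              protein_a_id = p$protein_a_id, protein_b_id = NA_character_,
              type_a = fp(p$completeness_a), type_b = NA_character_,
              overlap_identity_pct = p$overlap_identity_pct,
              completeness_merged = if (.is_full(p$completeness_a))
                "full_length" else "partial",
              origin = "distinct_pair_a")
      add_row(gene = p$protein_b_id, class = class_of(set_b, p$protein_b_id),
              subclass = p$subclass,
              protein_a_id = NA_character_, protein_b_id = p$protein_b_id,
              type_a = NA_character_, type_b = fp(p$completeness_b),
              overlap_identity_pct = p$overlap_identity_pct,
              completeness_merged = if (.is_full(p$completeness_b))
                "full_length" else "partial",
              origin = "distinct_pair_b")
    } else {  # unmatched
      only <- if (!is.na(p$protein_a_id)) "a" else "b"
      pid <- if (only == "a") p$protein_a_id else p$protein_b_id
      comp <- if (only == "a") p$completeness_a else p$completeness_b
      add_row(gene = pid, class = cls, subclass = p$subclass,
              protein_a_id = if (only == "a") pid else NA_character_,
              protein_b_id = if (only == "b") pid else NA_character_,
              type_a = if (only == "a") fp(comp) else NA_character_,
              type_b = if (only == "b") fp(comp) else NA_character_,
              overlap_identity_pct = NA_real_,
              completeness_merged = if (.is_full(comp)) "full_length"
                                    else "partial",
              origin = paste0("only_", only))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-class/subclass gene counts of a merged catalog
#'
#' @param catalog Data.frame from [merge_catalogs()].
#' @return A data.frame with columns `class`, `subclass`, `n_genes`.
#' @export
catalog_counts <- function(catalog) {
  agg <- stats::aggregate(list(n_genes = catalog$gene),
                          by = list(class = catalog$class,
                                    subclass = catalog$subclass),
                          FUN = length)
  agg[order(agg$class, agg$subclass), ]
}
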