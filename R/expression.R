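# RPKM expression quantification from read-count tables and per-stage
# replicate summaries on the log2 scale.
#
# RPKM (reads per kilobase of transcript per million mapped reads) is a
# within-library relative measure: the reads mapped to a transcript are
# divided by the library's total mapped reads (in millions) and by the
# transcript length (in kilobases).  The library total counts reads mapped
# to the whole reference transcriptome, not only to the transcripts of
# interest, so the per-transcript RPKMs of a catalog satisfy
#   sum_i rpkm_i * length_kb_i = 1e6 * (catalog-mapped / total-mapped).

#' Construct a count table
#'
#' @param counts Integer matrix, transcripts x libraries (rownames are
#'   transcript ids).
#' @param stage Stage label per library (length = ncol(counts)).
#' @param replicate Replicate index per library.
#' @param total_mapped Total reads mapped to the whole reference per
#'   library; must be at least the column sum of `counts`.
#' @param length_bp Named numeric vector of transcript lengths (bp).
#' @return A `count_table` object.
#' @export
count_table <- function(counts, stage, replicate, total_mapped, length_bp) {
  counts <- as.matrix(counts)
  stopifnot(length(stage) == ncol(counts),
            length(replicate) == ncol(counts),
            length(total_mapped) == ncol(counts),
            all(rownames(counts) %in% names(length_bp)),
            all(counts >= 0), all(total_mapped >= 0))
  if (any(colSums(counts) > total_mapped))
    stop("total_mapped must be at least the per-library catalog count sum")
  structure(list(counts = counts, stage = as.character(stage),
                 replicate = as.integer(replicate),
                 total_mapped = as.numeric(total_mapped),
                 length_bp = length_bp[rownames(counts)]),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d transcripts x %d libraries (%d stages)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$stage))))
  invisible(x)
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = counts / ((length_bp / 1000) * (total_mapped / 1e6))`.
#'
#' @param counts Read counts (vectorised).
#' @param total_mapped Total mapped reads in the library (> 0).
#' @param length_bp Transcript length in bp (> 0).
#' @return Numeric RPKM values.
#' @export
rpkm <- function(counts, total_mapped, length_bp) {
  if (any(total_mapped <= 0)) stop("total_mapped must be positive")
  if (any(length_bp <= 0)) stop("length_bp must be positive")
  counts / ((length_bp / 1000) * (total_mapped / 1e6))
}

#' RPKM matrix for a count table
#'
#' @param ct A [count_table()].
#' @return Numeric matrix, transcripts x libraries.
#' @export
rpkm_matrix <- function(ct) {
  stopifnot(inherits(ct, "count_table"))
  sweep(ct$counts / (ct$length_bp / 1000), 2, ct$total_mapped / 1e6, "/")
}

#' Per-stage expression summaries on the log2 scale
#'
#' Computes `log2(rpkm + pseudocount)` per library and summarises each
#' transcript x stage cell by the mean and standard deviation over
#' replicates (SD is 0 for a single replicate).
#'
#' @param ct A [count_table()].
#' @param pseudocount Non-negative value added before the log (default 1,
#'   so that zero counts map to 0 on the log2 scale).
#' @return A data.frame with columns `transcript_id`, `stage`,
#'   `mean_log2_rpkm`, `sd_log2_rpkm`, `mean_rpkm`, `n_replicates`.
#'   Stages keep their input order.
#' @export
summarize_stages <- function(ct, pseudocount = 1) {
  stopifnot(inherits(ct, "count_table"))
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  rp <- rpkm_matrix(ct)
  lg <- log2(rp + pseudocount)
  stages <- unique(ct$stage)
  out <- lapply(stages, function(st) {
    cols <- which(ct$stage == st)
    data.frame(
      transcript_id = rownames(rp), stage = st,
      mean_log2_rpkm = rowMeans(lg[, cols, drop = FALSE]),
      sd_log2_rpkm = if (length(cols) > 1)
        apply(lg[, cols, drop = FALSE], 1, stats::sd) else 0,
      mean_rpkm = rowMeans(rp[, cols, drop = FALSE]),
      n_replicates = length(cols),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
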