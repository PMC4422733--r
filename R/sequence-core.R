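# Core sequence records, FASTA I/O, translation and reverse complement.
#
# Collections of sequence records are plain data.frames so that they can be
# filtered, joined and written as TSV without ceremony.  Transcript records
# carry an assembly-of-origin tag; protein records may carry a
# "class|subclass" label (used for reference-panel members).

.valid_dna <- function(seq) grepl("^[ACGTN]*$", seq)
.valid_protein <- function(seq) grepl("^[ACDEFGHIKLMNPQRSTVWYX*]*$", seq)

#' Construct transcript records
#'
#' @param id Character vector of accession-like identifiers (unique).
#' @param seq Nucleotide sequences over `A,C,G,T,N` (upper-cased; `U` is
#'   mapped to `T`).
#' @param assembly Assembly-of-origin label, e.g. `"gulf_of_maine"`.
#' @param description Optional free-text remainder of the FASTA header.
#' @return A data.frame with columns `id`, `seq`, `assembly`, `length_bp`,
#'   `description`.
#' @export
transcript_records <- function(id, seq, assembly = "assembly",
                               description = "") {
  seq <- chartr("u", "t", toupper(as.character(seq)))
  seq <- chartr("U", "T", seq)
  bad <- !.valid_dna(seq)
  if (any(bad))
    stop("non-nucleotide characters in sequence(s): ",
         paste(id[bad], collapse = ", "))
  dup <- duplicated(id)
  if (any(dup))
    stop("duplicate transcript id(s): ", paste(unique(id[dup]), collapse = ", "))
  data.frame(id = as.character(id), seq = seq,
             assembly = rep_len(assembly, length(id)),
             length_bp = nchar(seq),
             description = rep_len(description, length(id)),
             stringsAsFactors = FALSE)
}

#' Construct protein records
#'
#' @param id Character vector of identifiers (unique).
#' @param seq Amino-acid sequences over the 20 standard residues plus `X`;
#'   `*` is allowed only as a terminal stop marker in raw translations.
#' @param label Optional `class|subclass` tag for reference-panel members
#'   (`NA` otherwise).
#' @param description Optional header remainder.
#' @return A data.frame with columns `id`, `seq`, `label`, `length_aa`,
#'   `description`.
#' @export
protein_records <- function(id, seq, label = NA_character_,
                            description = "") {
  seq <- toupper(as.character(seq))
  bad <- !.valid_protein(seq)
  if (any(bad))
    stop("non-amino-acid characters in sequence(s): ",
         paste(id[bad], collapse = ", "))
  internal_stop <- grepl("\\*.", seq)
  if (any(internal_stop))
    stop("internal stop codon(s) in protein(s): ",
         paste(id[internal_stop], collapse = ", "))
  if (any(nchar(seq) == 0)) stop("empty protein sequence")
  dup <- duplicated(id)
  if (any(dup))
    stop("duplicate protein id(s): ", paste(unique(id[dup]), collapse = ", "))
  data.frame(id = as.character(id), seq = seq,
             label = rep_len(label, length(id)),
             length_aa = nchar(gsub("\\*", "", seq)),
             description = rep_len(description, length(id)),
             stringsAsFactors = FALSE)
}

#' Read a FASTA file into sequence records
#'
#' Headers are parsed as `id = first whitespace-delimited token`; the
#' remainder is retained as the description.  For protein FASTA, a
#' description token of the form `class|subclass` is interpreted as a
#' reference-panel label.  Sequences are upper-cased; for nucleotide input
#' `U` is mapped to `T`.
#'
#' @param path Path to a FASTA file.
#' @param type `"dna"` or `"protein"`, or `"auto"` to guess from the
#'   residue composition.
#' @param assembly Assembly label attached to transcript records.
#' @return A transcript- or protein-record data.frame, in file order.
#' @export
read_fasta <- function(path, type = c("auto", "dna", "protein"),
                       assembly = "assembly") {
  type <- match.arg(type)
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty FASTA file: ", path)
  headers <- names(ss)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  seq <- toupper(as.character(ss))
  names(seq) <- NULL
  dup <- duplicated(id)
  if (any(dup))
    stop("duplicate FASTA id(s): ", paste(unique(id[dup]), collapse = ", "))
  if (type == "auto") {
    dna_like <- mean(.valid_dna(chartr("U", "T", seq))) == 1
    type <- if (dna_like) "dna" else "protein"
  }
  if (type == "dna") {
    transcript_records(id, seq, assembly = assembly,
                       description = description)
  } else {
    label <- ifelse(grepl("^\\S+\\|\\S+", description),
                    sub("^(\\S+).*$", "\\1", description), NA_character_)
    protein_records(id, seq, label = label, description = description)
  }
}

#' Write sequence records to a FASTA file
#'
#' @param records A transcript- or protein-record data.frame.
#' @param path Output path.
#' @param width Line-wrap width (0 for unwrapped).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  header <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", header[i]), con)
    s <- records$seq[i]
    if (width > 0 && nchar(s) > width) {
      starts <- seq(1, nchar(s), by = width)
      s <- substring(s, starts, pmin(starts + width - 1, nchar(s)))
    }
    writeLines(s, con)
  }
  invisible(path)
}

#' Reverse complement of a nucleotide sequence
#'
#' @param seq Nucleotide string(s) over `A,C,G,T,N`.
#' @return Reverse-complemented string(s).
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Codon -> amino acid lookup (standard code, table 1); any codon touching
# an N translates to X via the NA fallback.
.CODON_MAP <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

#' Translate a nucleotide sequence in a given reading frame
#'
#' Uses the standard genetic code (translation table 1).  Frames `+1..+3`
#' read the given strand with an offset of 0..2; frames `-1..-3` translate
#' the reverse complement.  Trailing 1-2 nt that do not fill a codon are
#' dropped.  Codons containing `N` translate to `X`; stop codons are
#' rendered as `*`.
#'
#' @param seq A single nucleotide string.
#' @param frame Integer in `{+1,+2,+3,-1,-2,-3}`.
#' @return The amino-acid translation as a single string.
#' @export
translate_frame <- function(seq, frame) {
  stopifnot(length(seq) == 1, frame %in% c(1, 2, 3, -1, -2, -3))
  s <- if (frame < 0) revcomp(seq) else seq
  off <- abs(frame) - 1
  n <- nchar(s)
  if (n - off < 3) stop("sequence shorter than one codon in frame ", frame)
  n_codons <- (n - off) %/% 3
  starts <- off + 1 + 3 * (seq_len(n_codons) - 1)
  codons <- substring(s, starts, starts + 2)
  aa <- unname(.CODON_MAP[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Six-frame translation of a transcript
#'
#' @param seq A single nucleotide string.
#' @return A data.frame with columns `frame` and `aa` (one row per frame
#'   with at least one full codon).
#' @export
six_frame_translation <- function(seq) {
  frames <- c(1, 2, 3, -1, -2, -3)
  keep <- vapply(frames, function(f) nchar(seq) - (abs(f) - 1) >= 3, logical(1))
  frames <- frames[keep]
  aa <- vapply(frames, function(f) translate_frame(seq, f), character(1))
  data.frame(frame = frames, aa = aa, stringsAsFactors = FALSE)
}
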