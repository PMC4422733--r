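# Domain-presence vetting by position-specific scoring matrices (PSSMs)
# built from shipped seed alignments, and wildcard motif scanning with
# per-position substitution calls.
#
# The PSSM score of a window is the sum of per-column log-odds
# (log2 of Laplace-smoothed column frequency over a uniform background).
# A domain is called present when the best full window in the protein
# reaches the domain's threshold; thresholds are calibrated so that the
# false-positive rate on shuffled proteins is at most 1%.  Because scoring
# is position-specific, a protein retaining only part of a domain (a
# truncated terminus) scores near the null and the domain is reported
# absent, matching the vetting semantics for partial proteins.

#' Build a position-specific scoring matrix from a seed alignment
#'
#' @param seqs Character vector of equal-length aligned amino-acid
#'   sequences (gaps `-` and `X` are ignored in the counts).
#' @param pseudocount Laplace pseudocount added per residue (default 1).
#' @return A 20 x width matrix of log2 odds against a uniform background.
#' @export
build_pssm <- function(seqs, pseudocount = 1) {
  stopifnot(length(seqs) > 0, length(unique(nchar(seqs))) == 1)
  width <- nchar(seqs[1])
  chars <- do.call(rbind, strsplit(seqs, ""))
  pssm <- matrix(0, nrow = 20, ncol = width,
                 dimnames = list(AA_STANDARD, NULL))
  for (j in seq_len(width)) {
    col <- chars[, j]
    col <- col[col %in% AA_STANDARD]
    cnt <- table(factor(col, levels = AA_STANDARD))
    freq <- (as.numeric(cnt) + pseudocount) /
      (length(col) + 20 * pseudocount)
    pssm[, j] <- log2(freq / 0.05)
  }
  pssm
}

# Best-scoring full window of a PSSM in a protein; X residues contribute 0.
.best_pssm_window <- function(aa_chars, pssm) {
  w <- ncol(pssm)
  L <- length(aa_chars)
  if (L < w) return(list(score = -Inf, start = NA_integer_))
  idx <- match(aa_chars, AA_STANDARD)
  scores <- vapply(seq_len(L - w + 1), function(s) {
    ii <- idx[s:(s + w - 1)]
    ok <- !is.na(ii)
    sum(pssm[cbind(ii[ok], which(ok))])
  }, numeric(1))
  best <- which.max(scores)
  list(score = scores[best], start = best)
}

#' Load a domain profile set
#'
#' A profile set is a directory of aligned FASTA seed files plus a
#' `thresholds.yml` mapping each domain name to its seed file and
#' presence threshold.  The package ships a synthetic profile set for the
#' four GST-family domains (GSTN, GSTC, THX, MAPEG) used by the synthetic
#' scenario; users may point to their own directory.
#'
#' @param dir Profile directory (default: the shipped profile set).
#' @return A named list of profiles, each with elements `name`, `pssm`,
#'   `width`, `threshold`, `seed_seqs`.
#' @export
load_domain_profiles <- function(dir = system.file("extdata", "profiles",
                                                   package = "gstmine")) {
  cfg_path <- file.path(dir, "thresholds.yml")
  if (!file.exists(cfg_path)) stop("no thresholds.yml in ", dir)
  cfg <- yaml::read_yaml(cfg_path)
  profiles <- lapply(names(cfg$domains), function(nm) {
    entry <- cfg$domains[[nm]]
    seed <- read_fasta(file.path(dir, entry$seed), type = "protein")
    pssm <- build_pssm(seed$seq)
    list(name = nm, pssm = pssm, width = ncol(pssm),
         threshold = as.numeric(entry$threshold), seed_seqs = seed$seq)
  })
  names(profiles) <- names(cfg$domains)
  profiles
}

#' Calibrate a domain-presence threshold from an empirical null
#'
#' Scores `n` random proteins (drawn from the seed alignment's residue
#' composition) and returns the requested quantile of the best-window
#' score null distribution.  Thresholds at the 99th percentile bound the
#' false-positive rate on unrelated proteins at about 1%.
#'
#' @param profile A profile from [load_domain_profiles()] (needs `pssm`
#'   and `seed_seqs`).
#' @param n Number of null proteins (default 1000).
#' @param length_aa Null protein length (default 250).
#' @param quantile Null quantile used as the threshold (default 0.99).
#' @param seed RNG seed.
#' @return Numeric threshold.
#' @export
calibrate_domain_threshold <- function(profile, n = 1000, length_aa = 250,
                                       quantile = 0.99, seed = 1) {
  set.seed(seed)
  pool <- unlist(strsplit(profile$seed_seqs, ""))
  pool <- pool[pool %in% AA_STANDARD]
  null_scores <- vapply(seq_len(n), function(i) {
    .best_pssm_window(sample(pool, length_aa, replace = TRUE),
                      profile$pssm)$score
  }, numeric(1))
  as.numeric(stats::quantile(null_scores, quantile))
}

#' Scan a protein for domain presence
#'
#' @param protein Single-row deduced-protein data.frame (needs `id` and
#'   `aa_seq`), or a list with those elements.
#' @param profiles Profile set from [load_domain_profiles()].
#' @return A data.frame with one row per domain: `protein_id`,
#'   `domain_name`, `start`, `end` (1-based inclusive positions of the
#'   best window), `score`, `present`.
#' @export
scan_domains <- function(protein, profiles) {
  if (length(profiles) == 0) stop("empty domain profile set")
  aa <- strsplit(protein$aa_seq, "")[[1]]
  rows <- lapply(profiles, function(pr) {
    best <- .best_pssm_window(aa, pr$pssm)
    data.frame(protein_id = protein$id, domain_name = pr$name,
               start = best$start,
               end = if (is.na(best$start)) NA_integer_
                     else best$start + pr$width - 1L,
               score = best$score,
               present = is.finite(best$score) & best$score >= pr$threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expected domain complement for a class/subclass
#'
#' Cytosolic GSTs carry both the N-terminal (GSTN) and C-terminal (GSTC)
#' domains; the mitochondrial Kappa class carries a thioredoxin-like
#' domain (THX); microsomal GSTs carry the MAPEG domain.
#'
#' @param class One of `"cytosolic"`, `"mitochondrial"`, `"microsomal"`.
#' @return Character vector of required domain names.
#' @export
expected_domains <- function(class) {
  switch(class,
         cytosolic = c("GSTN", "GSTC"),
         mitochondrial = "THX",
         microsomal = "MAPEG",
         stop("unknown class: ", class))
}

#' Check a protein's domain calls against its expected complement
#'
#' Full-length (and putative full-length) proteins must show every
#' expected domain; partial proteins may lack the domain(s) at the
#' truncated terminus and pass with at least one expected domain present.
#'
#' @param domain_calls Data.frame from [scan_domains()].
#' @param class Assigned class (see [expected_domains()]).
#' @param completeness Completeness class of the protein.
#' @return Logical: does the protein pass the vetting check?
#' @export
vet_domain_complement <- function(domain_calls, class, completeness) {
  req <- expected_domains(class)
  present <- domain_calls$domain_name[domain_calls$present]
  if (completeness %in% c("full_length", "putative_full_length"))
    all(req %in% present)
  else
    any(req %in% present)
}

#' Scan a protein for a wildcard motif
#'
#' The pattern mixes fixed residues with `x` wildcards (case-insensitive),
#' e.g. the 16-residue MAPEG motif `VERVRRxHLNDxENIx`.  Every window with
#' at most `max_mismatches` mismatches at non-wildcard positions is
#' reported, together with the full substitution list; wildcard positions
#' never produce substitutions.  Each substitution is classified as
#' conservative or not via the Clustal strong/weak groups.
#'
#' @param aa_seq Amino-acid string to scan.
#' @param pattern Wildcard pattern.
#' @param max_mismatches Maximum mismatches at non-wildcard positions
#'   (default 0).
#' @return A list with `matches` (data.frame: `start`, `n_mismatches`) and
#'   `substitutions` (data.frame: `start`, `motif_position`, `expected`,
#'   `observed`, `conservative`).
#' @export
scan_motif <- function(aa_seq, pattern, max_mismatches = 0) {
  stopifnot(nzchar(pattern))
  pat <- strsplit(toupper(pattern), "")[[1]]
  wildcard <- pat == "X"  # x/X is the wildcard; scanning is case-insensitive
  aa <- strsplit(toupper(aa_seq), "")[[1]]
  w <- length(pat)
  matches <- list(); subs <- list()
  if (length(aa) >= w) {
    fixed <- which(!wildcard)
    for (s in seq_len(length(aa) - w + 1)) {
      win <- aa[s:(s + w - 1)]
      mm <- fixed[win[fixed] != pat[fixed]]
      if (length(mm) <= max_mismatches) {
        matches[[length(matches) + 1]] <-
          data.frame(start = s, n_mismatches = length(mm))
        if (length(mm) > 0) {
          subs[[length(subs) + 1]] <- data.frame(
            start = s, motif_position = mm, expected = pat[mm],
            observed = win[mm],
            conservative = is_conservative_substitution(pat[mm], win[mm]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(matches = if (length(matches)) do.call(rbind, matches)
                 else data.frame(start = integer(), n_mismatches = integer()),
       substitutions = if (length(subs)) do.call(rbind, subs)
                       else data.frame(start = integer(),
                                       motif_position = integer(),
                                       expected = character(),
                                       observed = character(),
                                       conservative = logical()))
}
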