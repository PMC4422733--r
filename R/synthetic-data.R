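# Ground-truthed synthetic data: gene families with controlled divergence
# planted in transcriptome contigs for two populations, plus stage-
# structured read counts.
#
# Divergence is simulated by accept/reject point substitution: residues at
# mutable positions are replaced (preferring, 70% of the time, a residue
# from the same Clustal strong group, so that percent similarity exceeds
# percent identity as in real protein families) until the measured identity
# reaches the target.  Domain anchor columns, the start methionine and a
# short N-terminal leader are held invariant within a subclass lineage, so
# planted proteins keep a detectable domain architecture and an alignable
# start at any divergence.  Paralogs form a star around a subclass
# ancestor; the realized within-subclass identity of a gene is its maximum
# pairwise identity to the other members of its subclass.

.NT <- c("A", "C", "G", "T")

.codons_by_aa <- NULL
.codon_table <- function() {
  if (is.null(.codons_by_aa)) {
    gc <- Biostrings::GENETIC_CODE
    utils::assignInMyNamespace(".codons_by_aa", split(names(gc), gc))
  }
  .codons_by_aa
}

.pct_id <- function(a, b) 100 * mean(a == b)

.rand_nt <- function(n) paste(sample(.NT, n, replace = TRUE), collapse = "")

# One point substitution at a random mutable position.
.mutate_once <- function(chars, mutable) {
  pos <- if (length(mutable) == 1) mutable else sample(mutable, 1)
  cur <- chars[pos]
  partners <- unique(unlist(lapply(.STRONG_SETS, function(s)
    if (cur %in% s) s else NULL)))
  partners <- setdiff(partners, cur)
  chars[pos] <- if (length(partners) > 0 && stats::runif(1) < 0.7) {
    if (length(partners) == 1) partners else sample(partners, 1)
  } else {
    sample(setdiff(AA_STANDARD, cur), 1)
  }
  chars
}

# Mutate until the maximum identity against the reference set drops to the
# target (percent).  Errors when the target is infeasible for the anchor
# structure.
.mutate_to_identity <- function(chars, mutable, refs, target) {
  max_id <- function(x) max(vapply(refs, function(r) .pct_id(x, r),
                                   numeric(1)))
  limit <- 60L * length(chars)
  it <- 0L
  while (max_id(chars) > target) {
    chars <- .mutate_once(chars, mutable)
    it <- it + 1L
    if (it > limit)
      stop("infeasible identity target ", target,
           "% for the anchored architecture")
  }
  chars
}

#' Back-translate a protein with uniform codon choice
#'
#' @param aa_seq Amino-acid string (no stops).
#' @return A nucleotide string of length `3 * nchar(aa_seq)`.
#' @export
back_translate <- function(aa_seq) {
  tab <- .codon_table()
  chars <- strsplit(aa_seq, "")[[1]]
  codons <- vapply(chars, function(a) {
    opts <- tab[[a]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1), USE.NAMES = FALSE)
  paste(codons, collapse = "")
}

# Class architecture: base protein built from domain consensus segments
# plus random leader/linker/tail, with the anchored position set and the
# domain spans in protein coordinates.
.class_architecture <- function(class) {
  rand_aa <- function(n) sample(AA_STANDARD, n, replace = TRUE)
  if (class == "cytosolic") {
    leader <- rand_aa(4); linker <- rand_aa(8); tail <- rand_aa(6)
    segs <- list(M = "M", leader = leader,
                 GSTN = strsplit(DOMAIN_CONSENSUS$GSTN, "")[[1]],
                 linker = linker,
                 GSTC = strsplit(DOMAIN_CONSENSUS$GSTC, "")[[1]],
                 tail = tail)
    doms <- c("GSTN", "GSTC")
  } else if (class == "mitochondrial") {
    leader <- rand_aa(4); linker <- rand_aa(6); ext <- rand_aa(100)
    segs <- list(M = "M", leader = leader,
                 THX = strsplit(DOMAIN_CONSENSUS$THX, "")[[1]],
                 linker = linker, ext = ext)
    doms <- "THX"
  } else if (class == "microsomal") {
    leader <- rand_aa(3); tail <- rand_aa(5)
    segs <- list(M = "M", leader = leader,
                 MAPEG = strsplit(DOMAIN_CONSENSUS$MAPEG, "")[[1]],
                 tail = tail)
    doms <- "MAPEG"
  } else stop("unknown class: ", class)
  chars <- unlist(segs, use.names = FALSE)
  offset <- 0L
  anchors <- integer(0)
  spans <- list()
  for (nm in names(segs)) {
    len <- length(segs[[nm]])
    if (nm %in% doms) {
      anchors <- c(anchors, offset + domain_anchor_columns(nm))
      spans[[nm]] <- c(offset + 1L, offset + len)
    }
    offset <- offset + len
  }
  # start methionine and leader are anchored so that every family member
  # keeps an alignable, query-matching N-terminus
  anchors <- sort(union(seq_len(1L + length(segs$leader)), anchors))
  list(chars = chars, anchors = anchors, domains = spans)
}

#' Specify a planted gene family (one subclass)
#'
#' @param subclass Subclass name (e.g. `"Delta"`, `"Kappa"`, `"mGST-1"`).
#' @param class `"cytosolic"`, `"mitochondrial"` or `"microsomal"`.
#' @param n_genes Number of paralogs planted in both populations.
#' @param within_identity_range Target range (percent) for the realized
#'   within-subclass identity of each paralog (default 30-60, the typical
#'   divergence among same-subclass GST paralogs).
#' @param cross_population_identity Per-gene target identity between the
#'   two population variants (scalar or length-`n_genes` vector); `NULL`
#'   samples each target uniformly from 88-100.
#' @param fraction_partial Probability that a planted transcript is
#'   truncated to a partial (default 0.15).
#' @param private_genes_a,private_genes_b Number of additional
#'   population-private genes (default 0).
#' @param private_identity_range Within-subclass identity targets for
#'   private genes (default 30-45, so that they read as additional genes
#'   rather than divergent orthologs).
#' @return A `family_spec` list.
#' @export
family_spec <- function(subclass, class, n_genes,
                        within_identity_range = c(30, 60),
                        cross_population_identity = NULL,
                        fraction_partial = 0.15,
                        private_genes_a = 0, private_genes_b = 0,
                        private_identity_range = c(30, 45)) {
  stopifnot(n_genes >= 1,
            within_identity_range[1] > 0,
            within_identity_range[1] <= within_identity_range[2],
            within_identity_range[2] <= 100)
  structure(list(subclass = subclass, class = class, n_genes = n_genes,
                 within_identity_range = within_identity_range,
                 cross_population_identity = cross_population_identity,
                 fraction_partial = fraction_partial,
                 private_genes_a = private_genes_a,
                 private_genes_b = private_genes_b,
                 private_identity_range = private_identity_range),
            class = "family_spec")
}

#' Default two-population study design
#'
#' Mirrors the gene-family structure recovered from the Gulf of Maine
#' assembly (Delta 11, Theta 1, Mu 5, Omega 3, Sigma 10, Zeta 2, Kappa 1,
#' mGST-1 2, mGST-3 4 = 39 genes) plus one private Delta and one private
#' Omega gene in the second population, so the merged catalog holds 41
#' genes.
#'
#' @return A list of [family_spec()] objects.
#' @export
default_family_specs <- function() {
  list(
    family_spec("Delta", "cytosolic", 11, private_genes_b = 1),
    family_spec("Theta", "cytosolic", 1),
    family_spec("Mu", "cytosolic", 5),
    family_spec("Omega", "cytosolic", 3, private_genes_b = 1),
    family_spec("Sigma", "cytosolic", 10),
    family_spec("Zeta", "cytosolic", 2),
    family_spec("Kappa", "mitochondrial", 1),
    # microsomal paralogs are less diverged than cytosolic ones (a
    # same-top-hit mGST-3 pair aligns at 77% identity), and the short
    # single-domain architecture leaves less room for divergence
    family_spec("mGST-1", "microsomal", 2,
                within_identity_range = c(50, 77)),
    family_spec("mGST-3", "microsomal", 4,
                within_identity_range = c(50, 77)))
}

#' Generate planted gene families for two populations
#'
#' For each family spec, a subclass ancestor is derived from the class
#' architecture, one labeled reference-panel member is branched off at
#' about 72% identity, and paralogs are diverged until their realized
#' within-subclass identity (maximum pairwise identity to the other
#' members) falls at the per-gene target.  Population-B variants are
#' diverged from the population-A protein to the per-gene cross-population
#' target.  mGST-1 lineages carry the glutamine replacement at MAPEG motif
#' position 9; all other lineages keep the stereotypical leucine.
#'
#' @param specs List of [family_spec()] objects.
#' @param seed RNG seed (all randomness is derived from it).
#' @return A list with `truth` (one row per gene: sequences for both
#'   populations, realized identities, presence) and `panel` (labeled
#'   protein records for reciprocal annotation).
#' @export
generate_families <- function(specs, seed) {
  set.seed(seed)
  truth <- list(); panel <- list()
  for (spec in specs) {
    arch <- .class_architecture(spec$class)
    mutable <- setdiff(seq_along(arch$chars), arch$anchors)
    ancestor <- .mutate_to_identity(arch$chars, mutable,
                                    list(arch$chars), 40)
    if (spec$subclass == "mGST-1") {
      pos9 <- arch$domains$MAPEG[1] + MAPEG_MOTIF_START + 8L - 1L
      ancestor[pos9] <- "Q"
    }
    # lineage signature: a small set of positions that diverged in the
    # ancestor and stay fixed throughout the subclass (subclass-specific
    # conserved residues), keeping every paralog recognizably closer to
    # its own lineage than to any other subclass
    signature <- sample(mutable, round(0.065 * length(arch$chars)))
    mutable <- setdiff(mutable, signature)
    pan <- .mutate_to_identity(ancestor, mutable, list(ancestor), 80)
    panel[[length(panel) + 1]] <- data.frame(
      id = paste0("PANEL_", spec$subclass),
      seq = paste(pan, collapse = ""),
      label = paste0(spec$class, "|", spec$subclass),
      stringsAsFactors = FALSE)
    members_a <- list()
    add_gene <- function(present_in, within_range, k) {
      t_within <- stats::runif(1, within_range[1], within_range[2])
      # initial star radius from the ancestor, scaled so that sibling
      # identities start above the within-subclass target and are then
      # trimmed down onto it (a target of 100 leaves the ancestor intact)
      radius <- min(100, (100 + t_within) / 2 + 10)
      g <- .mutate_to_identity(ancestor, mutable, list(ancestor), radius)
      realized_within <- NA_real_
      if (length(members_a) > 0) {
        g <- .mutate_to_identity(g, mutable, members_a, t_within)
        realized_within <- max(vapply(members_a, function(r) .pct_id(g, r),
                                      numeric(1)))
      }
      if (present_in == "both") {
        ct <- spec$cross_population_identity
        target_cross <- if (is.null(ct)) stats::runif(1, 88, 100)
                        else ct[min(k, length(ct))]
        gb <- .mutate_to_identity(g, mutable, list(g), target_cross)
        realized_cross <- .pct_id(g, gb)
      } else {
        target_cross <- NA_real_; realized_cross <- NA_real_
        gb <- g
      }
      list(g = g, gb = gb, realized_within = realized_within,
           target_cross = target_cross, realized_cross = realized_cross)
    }
    n_main <- spec$n_genes
    for (k in seq_len(n_main)) {
      res <- add_gene("both", spec$within_identity_range, k)
      members_a[[length(members_a) + 1]] <- res$g
      truth[[length(truth) + 1]] <- data.frame(
        gene_id = sprintf("%s-%02d", spec$subclass, k),
        class = spec$class, subclass = spec$subclass, present_in = "both",
        aa_a = paste(res$g, collapse = ""),
        aa_b = paste(res$gb, collapse = ""),
        realized_within_identity = res$realized_within,
        target_cross_identity = res$target_cross,
        realized_cross_identity = res$realized_cross,
        fraction_partial = spec$fraction_partial,
        stringsAsFactors = FALSE)
    }
    for (side in c("a", "b")) {
      n_priv <- if (side == "a") spec$private_genes_a else spec$private_genes_b
      for (k in seq_len(n_priv)) {
        res <- add_gene(side, spec$private_identity_range, k)
        truth[[length(truth) + 1]] <- data.frame(
          gene_id = sprintf("%s-P%s%d", spec$subclass, toupper(side), k),
          class = spec$class, subclass = spec$subclass, present_in = side,
          aa_a = if (side == "a") paste(res$g, collapse = "") else NA,
          aa_b = if (side == "b") paste(res$g, collapse = "") else NA,
          realized_within_identity = res$realized_within,
          target_cross_identity = NA_real_,
          realized_cross_identity = NA_real_,
          fraction_partial = spec$fraction_partial,
          stringsAsFactors = FALSE)
      }
    }
  }
  truth <- do.call(rbind, truth)
  panel <- do.call(rbind, panel)
  list(truth = truth,
       panel = protein_records(panel$id, panel$seq, label = panel$label))
}

# Number of codons removed by a truncation (10-30% of the ORF).  Cuts are
# codon-aligned so that the 0-2 nt of random frame padding added at the
# contig ends can never complete a codon at a truncated terminus.
.truncate_codons <- function(aa_len) {
  lo <- max(2L, ceiling(0.10 * aa_len))
  hi <- max(lo, floor(0.30 * aa_len))
  sample(lo:hi, 1)
}

#' Embed planted proteins in transcriptome contigs for one population
#'
#' Proteins are back-translated with uniform codon choice and wrapped in
#' random UTRs.  Full-length plants get an in-frame stop immediately
#' upstream of the start codon; a fraction of the full-length plants keep
#' no 5' UTR at all so that their deduced proteins read as putative full
#' length (start methionine, no upstream stop).  A `fraction_partial`
#' subset is truncated into C-terminal partials (start context removed) or
#' N-terminal partials (stop context removed).  Each transcript is placed
#' on a random strand with a random frame shift.  Decoy contigs are random
#' nucleotide sequence and back-translations of shuffled planted proteins.
#'
#' @param truth Truth table from [generate_families()].
#' @param population `"a"` or `"b"`.
#' @param seed RNG seed.
#' @param utr_range UTR length range in nt (default 30-90).
#' @param n_decoys Number of decoy contigs (default 100).
#' @param putative_fraction Fraction of non-partial plants embedded
#'   without a 5' UTR (default 0.25).
#' @param assembly Assembly label for the transcript records.
#' @return A list with `assembly` (transcript records, plants shuffled
#'   among decoys) and `plants` (per-transcript truth: expected deduced
#'   protein, ORF-level completeness and expected pipeline completeness).
#' @export
embed_in_contigs <- function(truth, population, seed,
                             utr_range = c(30, 90), n_decoys = 100,
                             putative_fraction = 0.25,
                             assembly = paste0("pop_", population)) {
  set.seed(seed)
  aa_col <- paste0("aa_", population)
  rows <- which(truth$present_in %in% c("both", population))
  recs <- list(); plants <- list()
  for (i in rows) {
    aa <- truth[[aa_col]][i]
    aa_len <- nchar(aa)
    orf_nt <- back_translate(aa)
    stop_codon <- sample(c("TAA", "TAG", "TGA"), 1)
    is_partial <- stats::runif(1) < truth$fraction_partial[i]
    kind <- if (!is_partial) {
      if (stats::runif(1) < putative_fraction) "putative" else "full"
    } else sample(c("cterm", "nterm"), 1)
    u5 <- sample(utr_range[1]:utr_range[2], 1)
    u3 <- sample(utr_range[1]:utr_range[2], 1)
    if (kind == "full") {
      utr5 <- paste0(.rand_nt(u5), "TAA")
      tx <- paste0(utr5, orf_nt, stop_codon, .rand_nt(u3))
      expected_aa <- aa
      orf_class <- "full_length"; expected_class <- "full_length"
    } else if (kind == "putative") {
      tx <- paste0(orf_nt, stop_codon, .rand_nt(u3))
      expected_aa <- aa
      orf_class <- "putative_full_length"; expected_class <- "full_length"
    } else if (kind == "cterm") {
      repeat {
        ca <- .truncate_codons(aa_len)
        first <- ca + 1L
        if (substr(aa, first, first) != "M") break
      }
      tx <- paste0(substr(orf_nt, 3L * ca + 1, nchar(orf_nt)), stop_codon,
                   .rand_nt(u3))
      expected_aa <- substr(aa, first, aa_len)
      orf_class <- "c_terminal_partial"; expected_class <- "c_terminal_partial"
    } else {  # nterm
      na_ <- .truncate_codons(aa_len)
      utr5 <- paste0(.rand_nt(u5), "TAA")
      tx <- paste0(utr5, substr(orf_nt, 1, nchar(orf_nt) - 3L * na_))
      expected_aa <- substr(aa, 1, aa_len - na_)
      orf_class <- "n_terminal_partial"; expected_class <- "n_terminal_partial"
    }
    # random strand and frame shift
    tx <- paste0(.rand_nt(sample(0:2, 1)), tx, .rand_nt(sample(0:2, 1)))
    if (stats::runif(1) < 0.5) tx <- revcomp(tx)
    tid <- sprintf("TX%s_%s", toupper(population), truth$gene_id[i])
    recs[[length(recs) + 1]] <- data.frame(id = tid, seq = tx,
                                           stringsAsFactors = FALSE)
    plants[[length(plants) + 1]] <- data.frame(
      transcript_id = tid, gene_id = truth$gene_id[i],
      class = truth$class[i], subclass = truth$subclass[i],
      expected_aa = expected_aa, orf_completeness = orf_class,
      expected_completeness = expected_class,
      stringsAsFactors = FALSE)
  }
  planted <- do.call(rbind, recs)
  n_shuffle <- floor(n_decoys * 0.4)
  n_random <- n_decoys - n_shuffle
  decoys <- character(0)
  if (n_random > 0)
    decoys <- vapply(seq_len(n_random), function(j)
      .rand_nt(sample(300:1200, 1)), character(1))
  if (n_shuffle > 0) {
    src <- truth[[aa_col]][rows]
    decoys <- c(decoys, vapply(seq_len(n_shuffle), function(j) {
      aa <- sample(strsplit(src[sample(length(src), 1)], "")[[1]])
      paste0(.rand_nt(sample(20:80, 1)),
             back_translate(paste(aa, collapse = "")),
             .rand_nt(sample(20:80, 1)))
    }, character(1)))
  }
  decoy_df <- if (n_decoys > 0) {
    data.frame(id = sprintf("DECOY_%s_%03d", toupper(population),
                            seq_len(n_decoys)),
               seq = decoys, stringsAsFactors = FALSE)
  } else NULL
  all_df <- rbind(planted, decoy_df)
  all_df <- all_df[sample(nrow(all_df)), , drop = FALSE]
  list(assembly = transcript_records(all_df$id, all_df$seq,
                                     assembly = assembly),
       plants = do.call(rbind, plants))
}

#' Generate a complete two-population synthetic scenario
#'
#' Convenience wrapper: [generate_families()] followed by
#' [embed_in_contigs()] for both populations (decoys split evenly).
#'
#' @param specs List of [family_spec()]s (default: [default_family_specs()]).
#' @param seed RNG seed.
#' @param n_decoys Decoy contigs per population (default 100).
#' @param ... Passed on to [embed_in_contigs()].
#' @return A list with `truth`, `panel`, `assembly_a`, `assembly_b`,
#'   `plants_a`, `plants_b`.
#' @export
generate_scenario <- function(specs = default_family_specs(), seed = 1,
                              n_decoys = 100, ...) {
  fam <- generate_families(specs, seed = seed)
  emb_a <- embed_in_contigs(fam$truth, "a", seed = seed + 1000L,
                            n_decoys = n_decoys, ...)
  emb_b <- embed_in_contigs(fam$truth, "b", seed = seed + 2000L,
                            n_decoys = n_decoys, ...)
  list(truth = fam$truth, panel = fam$panel,
       assembly_a = emb_a$assembly, plants_a = emb_a$plants,
       assembly_b = emb_b$assembly, plants_b = emb_b$plants)
}

# Developmental stage labels, in life-cycle order.
STAGES <- c("embryo", "NI-II", "NV-VI", "CI-II", "CV", "adult_female")

#' Simulate stage-structured read counts for planted genes
#'
#' Planted expression is a per-gene base level (log-uniform) times a
#' class-specific stage profile: cytosolic genes are low in embryos and
#' high in late copepodites and adult females; mitochondrial and
#' microsomal genes are flat after a lower embryo level.  Library counts
#' are multinomial over the planted transcripts plus a background mass
#' (the rest of the transcriptome), with sampling weight proportional to
#' level x transcript length; replicate noise is log-normal on the level.
#'
#' @param plants Per-transcript truth table from [embed_in_contigs()].
#' @param lengths Named vector of transcript lengths (bp), names matching
#'   `plants$transcript_id`.
#' @param seed RNG seed.
#' @param stages Stage labels (default the six developmental stages).
#' @param replicates Replicates per stage (default 3).
#' @param depth Total mapped reads per library (default 2e6).
#' @param background_weight Sampling weight of the non-family
#'   transcriptome relative to the summed family weight (default 19, i.e.
#'   the family receives about 5% of reads).
#' @param sigma Log-normal replicate noise on the level (default 0.25).
#' @param levels Optional planted level matrix (transcripts x stages)
#'   overriding the default class profiles.
#' @return A list with `counts` (a [count_table()]) and `levels` (planted
#'   per-gene stage levels, transcripts x stages).
#' @export
simulate_counts <- function(plants, lengths, seed, stages = STAGES,
                            replicates = 3, depth = 2e6,
                            background_weight = 19, sigma = 0.25,
                            levels = NULL) {
  stopifnot(depth > 0)
  set.seed(seed)
  tx <- plants$transcript_id
  n <- length(tx)
  len <- as.numeric(lengths[tx])
  if (is.null(levels)) {
    profile <- function(class) {
      if (class == "cytosolic") c(0.15, 0.5, 0.7, 1, 3, 3.5)
      else c(0.4, 1, 1, 1, 1, 1)
    }
    base <- 2^stats::runif(n, 0, 6)
    levels <- t(vapply(seq_len(n), function(i)
      base[i] * profile(plants$class[i]), numeric(length(stages))))
    dimnames(levels) <- list(tx, stages)
  } else {
    stopifnot(nrow(levels) == n, ncol(levels) == length(stages))
    dimnames(levels) <- list(tx, stages)
  }
  libs <- expand.grid(replicate = seq_len(replicates), stage = stages,
                      stringsAsFactors = FALSE)[, c("stage", "replicate")]
  counts <- matrix(0L, nrow = n, ncol = nrow(libs),
                   dimnames = list(tx, paste0(libs$stage, "_",
                                              libs$replicate)))
  # the background (non-family) transcriptome has a fixed absolute
  # sampling weight, so stage-wide changes in family expression show up
  # as changes in family RPKM instead of being renormalized away
  w_bg <- background_weight * sum(rowMeans(levels) * len)
  for (j in seq_len(nrow(libs))) {
    lev <- levels[, libs$stage[j]] *
      stats::rlnorm(n, meanlog = 0, sdlog = sigma)
    w <- lev * len
    p <- c(w, w_bg) / (sum(w) + w_bg)
    draw <- stats::rmultinom(1, size = depth, prob = p)[, 1]
    counts[, j] <- draw[seq_len(n)]
  }
  ct <- count_table(counts, stage = libs$stage, replicate = libs$replicate,
                    total_mapped = rep(depth, nrow(libs)),
                    length_bp = stats::setNames(len, tx))
  list(counts = ct, levels = levels)
}
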