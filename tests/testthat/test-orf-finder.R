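# Helpers to build transcripts with known ORF structure.
codon_join <- function(aa) {
  # deterministic back-translation (first codon of each residue)
  tab <- local({
    gc <- Biostrings::GENETIC_CODE
    split(names(gc), gc)
  })
  paste(vapply(strsplit(aa, "")[[1]], function(a) tab[[a]][1],
               character(1)), collapse = "")
}

test_that("completeness follows the flanking-context truth table", {
  expect_equal(classify_completeness(TRUE, TRUE, TRUE), "full_length")
  expect_equal(classify_completeness(FALSE, TRUE, TRUE),
               "putative_full_length")
  expect_equal(classify_completeness(TRUE, FALSE, TRUE),
               "c_terminal_partial")
  expect_equal(classify_completeness(FALSE, FALSE, TRUE),
               "c_terminal_partial")
  expect_equal(classify_completeness(TRUE, TRUE, FALSE),
               "n_terminal_partial")
  expect_equal(classify_completeness(FALSE, FALSE, FALSE),
               "internal_fragment")
})

test_that("a stop-flanked Met-initiated ORF is called full length", {
  set.seed(5)
  body <- rand_protein(60)
  body <- gsub("M", "L", body)  # keep the planted Met unique at the start
  tx <- transcript_records(
    "t1", paste0("CCCCC", "TAA", codon_join(paste0("M", body)), "TGA",
                 "GGGGG"))
  orfs <- extract_orfs(tx, min_orf_len = 40)
  full <- orfs[orfs$completeness == "full_length", ]
  expect_equal(nrow(full), 1)
  expect_equal(nchar(full$aa_seq), 61)
  expect_equal(substr(full$aa_seq, 1, 1), "M")
  expect_equal(full$frame, 3)  # 5 nt lead-in puts the ORF in frame +3
})

test_that("missing start or stop context yields the partial classes", {
  set.seed(6)
  body <- gsub("M", "K", rand_protein(50))
  # no ATG before the stop: C-terminal partial
  tx1 <- transcript_records("t1", paste0(codon_join(body), "TAA", "CCC"))
  o1 <- extract_orfs(tx1, min_orf_len = 40)
  expect_true(any(o1$completeness == "c_terminal_partial"))
  expect_false(any(o1$completeness %in%
                     c("full_length", "putative_full_length")))
  # Met ORF running off the 3' end: N-terminal partial
  tx2 <- transcript_records(
    "t2", paste0("CC", "TAA", codon_join(paste0("M", body))))
  o2 <- extract_orfs(tx2, min_orf_len = 40)
  np <- o2[o2$completeness == "n_terminal_partial", ]
  expect_equal(nrow(np), 1)
  expect_true(np$has_upstream_stop)
  # no Met, no stop: internal fragment
  tx3 <- transcript_records("t3", codon_join(body))
  o3 <- extract_orfs(tx3, min_orf_len = 40)
  expect_true(any(o3$completeness == "internal_fragment"))
  # transcript starting at its ATG: putative full length
  tx4 <- transcript_records(
    "t4", paste0(codon_join(paste0("M", body)), "TAA", "GG"))
  o4 <- extract_orfs(tx4, min_orf_len = 40)
  expect_true(any(o4$completeness == "putative_full_length"))
})

test_that("a stretch with an internal Met is reported in both forms", {
  set.seed(7)
  lead <- gsub("M", "T", rand_protein(45))
  body <- gsub("M", "L", rand_protein(60))
  tx <- transcript_records(
    "t1", paste0(codon_join(paste0(lead, "M", body)), "TAA"))
  orfs <- extract_orfs(tx, min_orf_len = 40)
  plus1 <- orfs[orfs$frame == 1, ]
  expect_equal(nrow(plus1), 2)
  expect_setequal(plus1$completeness,
                  c("c_terminal_partial", "putative_full_length"))
  expect_equal(sort(nchar(plus1$aa_seq)), c(61, 106))
})

test_that("reported coordinates re-translate to the reported protein", {
  sc <- generate_scenario(specs = list(
    family_spec("Delta", "cytosolic", 3),
    family_spec("mGST-3", "microsomal", 2,
                within_identity_range = c(50, 77))),
    seed = 21, n_decoys = 0)
  for (k in seq_len(nrow(sc$assembly_a))) {
    tx <- sc$assembly_a[k, ]
    orfs <- extract_orfs(tx, min_orf_len = 40)
    for (i in seq_len(nrow(orfs))) {
      o <- orfs[i, ]
      nt <- substr(tx$seq, o$nt_start, o$nt_end)
      if (o$frame < 0) nt <- revcomp(nt)
      expect_identical(translate_frame(nt, 1), o$aa_seq)
    }
  }
})

test_that("ORF classification matches the planted truth on synthetic data", {
  sc <- generate_scenario(seed = 31, n_decoys = 0)
  for (pop in c("a", "b")) {
    plants <- sc[[paste0("plants_", pop)]]
    assembly <- sc[[paste0("assembly_", pop)]]
    for (k in seq_len(nrow(plants))) {
      tx <- assembly[assembly$id == plants$transcript_id[k], ]
      orfs <- extract_orfs(tx, min_orf_len = 40)
      hit <- orfs[orfs$aa_seq == plants$expected_aa[k], ]
      expect_equal(nrow(hit), 1)
      expect_equal(hit$completeness, plants$orf_completeness[k])
    }
  }
})

test_that("the query picks the best-scoring ORF with deterministic ties", {
  set.seed(9)
  query <- rand_protein(50)
  other <- rand_protein(50)
  orfs <- data.frame(
    id = c("o1", "o2"), transcript_id = "t", frame = c(1, 2),
    aa_seq = c(other, query), aa_start = 1,
    aa_end = 50, nt_start = 1, nt_end = 150,
    has_upstream_stop = TRUE, has_start_met = FALSE,
    has_downstream_stop = TRUE, completeness = "c_terminal_partial",
    stringsAsFactors = FALSE)
  best <- pick_protein_for_hit(orfs, query)
  expect_equal(best$aa_seq, query)
  # independent check that the verbatim ORF really scores higher
  expect_gt(oracle_align_score(query, query, "local"),
            oracle_align_score(query, other, "local"))
  # equal scores: the longer ORF wins
  sub <- substr(query, 11, 50)
  orfs2 <- orfs
  orfs2$aa_seq <- c(query, sub)
  best2 <- pick_protein_for_hit(orfs2, sub)
  expect_equal(best2$aa_seq, query)
})

test_that("putative full length is promoted when the Met matches the query", {
  set.seed(10)
  body <- gsub("M", "V", rand_protein(59))
  aa <- paste0("M", body)
  orfs <- data.frame(
    id = "o1", transcript_id = "t", frame = 1, aa_seq = aa,
    aa_start = 1, aa_end = 60, nt_start = 1, nt_end = 180,
    has_upstream_stop = FALSE, has_start_met = TRUE,
    has_downstream_stop = TRUE, completeness = "putative_full_length",
    stringsAsFactors = FALSE)
  promoted <- pick_protein_for_hit(orfs, aa)
  expect_equal(promoted$completeness, "full_length")
  # a query whose own start lies elsewhere does not promote
  not_promoted <- pick_protein_for_hit(orfs, substr(aa, 20, 60))
  expect_equal(not_promoted$completeness, "putative_full_length")
})
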