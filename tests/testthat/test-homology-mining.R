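# Small planted-search fixtures: one query back-translated into a contig
# among random decoys.
make_planted_db <- function(query, n_decoys = 10, seed = 1) {
  set.seed(seed)
  nt <- c("A", "C", "G", "T")
  rand_nt <- function(n) paste(sample(nt, n, TRUE), collapse = "")
  planted <- paste0(rand_nt(30), back_translate(query), "TAA", rand_nt(30))
  decoys <- vapply(seq_len(n_decoys), function(i)
    rand_nt(sample(250:500, 1)), character(1))
  transcript_records(c("PLANT", paste0("D", seq_len(n_decoys))),
                     c(planted, decoys))
}

test_that("a verbatim planted query is recovered as the top hit", {
  set.seed(20)
  query <- protein_records("q1", rand_protein(80))
  db <- make_planted_db(query$seq, n_decoys = 10, seed = 21)
  hits <- mine_assembly(query, db, evalue_cutoff = 1e-5)
  expect_equal(hits$transcript_id[1], "PLANT")
  aln <- hit_alignment(hits[1, ], query, db)
  rep <- identity_report(aln, partial_mode = TRUE)
  expect_equal(rep$pct_identity, 100)
})

test_that("only the planted contig passes the cutoff among decoys", {
  set.seed(22)
  query <- protein_records("q1", rand_protein(70))
  db <- make_planted_db(query$seq, n_decoys = 25, seed = 23)
  hits <- mine_assembly(query, db, evalue_cutoff = 1e-5)
  expect_equal(hits$transcript_id, "PLANT")
  # brute-force confirmation on a down-scaled database: the planted
  # contig's best six-frame DP score dominates every decoy's
  small <- db[1:6, ]
  best_scores <- vapply(seq_len(nrow(small)), function(k) {
    max(vapply(six_frame_translation(small$seq[k])$aa, function(aa)
      oracle_align_score(query$seq, chartr("*", "X", aa), "local"),
      numeric(1)))
  }, numeric(1))
  expect_equal(which.max(best_scores), 1L)
  expect_gt(best_scores[1], 2 * max(best_scores[-1]))
})

test_that("hits are deterministic and invariant under contig order", {
  set.seed(24)
  query <- protein_records("q1", rand_protein(60))
  db <- make_planted_db(query$seq, n_decoys = 8, seed = 25)
  h1 <- mine_assembly(query, db)
  perm <- db[rev(seq_len(nrow(db))), ]
  h2 <- mine_assembly(query, perm)
  expect_equal(h1$transcript_id[1], h2$transcript_id[1])
  expect_equal(h1$score, h2$score)
})

test_that("related queries retrieve the same transcript, collapsed once", {
  sc <- generate_scenario(specs = list(family_spec("Delta", "cytosolic", 1)),
                          seed = 26, n_decoys = 5)
  # three increasingly diverged copies of the panel query
  set.seed(27)
  qs <- sc$panel
  q2 <- strsplit(qs$seq, "")[[1]]
  q2[sample(length(q2), 30)] <- sample(AA20, 30, TRUE)
  q3 <- strsplit(qs$seq, "")[[1]]
  q3[sample(length(q3), 60)] <- sample(AA20, 60, TRUE)
  queries <- protein_records(c("qa", "qb", "qc"),
                             c(qs$seq, paste(q2, collapse = ""),
                               paste(q3, collapse = "")))
  hits <- mine_assembly(queries, sc$assembly_a)
  planted_id <- sc$plants_a$transcript_id[1]
  expect_setequal(hits$transcript_id, planted_id)
  expect_equal(nrow(hits), 3)
  collapsed <- collapse_hits(hits)
  expect_equal(nrow(collapsed), 1)
  expect_equal(collapsed$evalue, min(hits$evalue))
})

test_that("the E-value cutoff must be positive", {
  q <- protein_records("q", "MKVLLLAV")
  db <- transcript_records("t", "ATGAAAGTA")
  expect_error(mine_assembly(q, db, evalue_cutoff = 0), "positive")
})

test_that("reciprocal annotation assigns the best panel subclass", {
  sc <- generate_families(list(
    family_spec("Delta", "cytosolic", 2),
    family_spec("Zeta", "cytosolic", 2)), seed = 28)
  panel <- sc$panel
  prot <- list(id = "p", aa_seq = panel$seq[panel$id == "PANEL_Delta"],
               completeness = "full_length")
  ann <- annotate_reciprocal(prot, panel)
  expect_equal(ann$assigned_subclass, "Delta")
  expect_equal(ann$identity_pct, 100)
  # a planted Delta gene is annotated Delta even when mined by the Zeta
  # query (annotation follows the reciprocal best hit, not the miner)
  delta_gene <- list(id = "g", aa_seq = sc$truth$aa_a[1],
                     completeness = "full_length")
  ann2 <- annotate_reciprocal(delta_gene, panel)
  expect_equal(ann2$assigned_subclass, "Delta")
})

test_that("shuffled proteins fall below the annotation score floor", {
  sc <- generate_families(list(family_spec("Delta", "cytosolic", 1)),
                          seed = 29)
  set.seed(30)
  for (i in 1:20) {
    shuf <- paste(sample(strsplit(sc$truth$aa_a[1], "")[[1]]),
                  collapse = "")
    ann <- annotate_reciprocal(list(id = "s", aa_seq = shuf,
                                    completeness = "full_length"),
                               sc$panel)
    expect_equal(ann$assigned_class, "unassigned")
  }
})
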