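profiles <- load_domain_profiles()

test_that("the shipped profile set loads with all four domains", {
  expect_setequal(names(profiles), c("GSTN", "GSTC", "THX", "MAPEG"))
  for (p in profiles) {
    expect_equal(nrow(p$pssm), 20)
    expect_equal(ncol(p$pssm), p$width)
    expect_true(is.finite(p$threshold))
  }
})

test_that("consensus-built cytosolic proteins show both expected domains", {
  ns <- asNamespace("gstmine")
  aa <- paste0("MSSSS", ns$DOMAIN_CONSENSUS$GSTN, "GGGGGGGG",
               ns$DOMAIN_CONSENSUS$GSTC, "KKKKKK")
  calls <- scan_domains(list(id = "p", aa_seq = aa), profiles)
  expect_true(all(calls$present[calls$domain_name %in% c("GSTN", "GSTC")]))
  # reported spans point at the embedded segments
  expect_equal(calls$start[calls$domain_name == "GSTN"], 6)
  expect_equal(calls$start[calls$domain_name == "GSTC"], 94)
  expect_true(vet_domain_complement(calls, "cytosolic", "full_length"))
})

test_that("a protein retaining only the C-terminal domain loses GSTN", {
  set.seed(40)
  ns <- asNamespace("gstmine")
  aa <- paste0(rand_protein(10), ns$DOMAIN_CONSENSUS$GSTC, rand_protein(6))
  calls <- scan_domains(list(id = "p", aa_seq = aa), profiles)
  expect_true(calls$present[calls$domain_name == "GSTC"])
  expect_false(calls$present[calls$domain_name == "GSTN"])
  expect_true(vet_domain_complement(calls, "cytosolic",
                                    "c_terminal_partial"))
  expect_false(vet_domain_complement(calls, "cytosolic", "full_length"))
})

test_that("planted family members keep their expected domains", {
  sc <- generate_scenario(seed = 41, n_decoys = 0)
  for (k in seq_len(nrow(sc$plants_a))) {
    p <- sc$plants_a[k, ]
    if (p$expected_completeness != "full_length") next
    calls <- scan_domains(list(id = p$gene_id, aa_seq = p$expected_aa),
                          profiles)
    expect_true(vet_domain_complement(calls, p$class, "full_length"),
                info = p$gene_id)
  }
})

test_that("domain false-positive rate on shuffled proteins is at most 1%", {
  set.seed(42)
  sc <- generate_families(list(family_spec("Delta", "cytosolic", 2)),
                          seed = 43)
  src <- strsplit(sc$truth$aa_a[1], "")[[1]]
  fp <- matrix(FALSE, 200, length(profiles))
  for (i in 1:200) {
    shuf <- paste(sample(src), collapse = "")
    calls <- scan_domains(list(id = "s", aa_seq = shuf), profiles)
    fp[i, ] <- calls$present
  }
  expect_lte(max(colMeans(fp)), 0.01)
})

test_that("motif scanning finds exact windows and none in random protein", {
  hit <- scan_motif(paste0("GGGG", "VERVRRAHLNDAENIA", "GGGG"),
                    "VERVRRxHLNDxENIx")
  expect_equal(hit$matches$start, 5)
  expect_equal(hit$matches$n_mismatches, 0)
  expect_equal(nrow(hit$substitutions), 0)
  set.seed(44)
  aa <- rand_protein(200)
  none <- scan_motif(aa, "VERVRRxHLNDxENIx", max_mismatches = 1)
  expect_equal(nrow(none$matches),
               length(oracle_motif_scan(aa, "VERVRRxHLNDxENIx", 1)))
  expect_equal(nrow(none$matches), 0)
})

test_that("a glutamine at motif position 9 is a non-conservative call", {
  seq9 <- paste0("AAAA", "VERVRRAHQNDAENIA", "WWWW")  # L9 -> Q
  res <- scan_motif(seq9, "VERVRRxHLNDxENIx", max_mismatches = 1)
  expect_equal(res$matches$start, 5)
  expect_equal(res$matches$n_mismatches, 1)
  sub <- res$substitutions
  expect_equal(sub$motif_position, 9)
  expect_equal(sub$expected, "L")
  expect_equal(sub$observed, "Q")
  expect_false(sub$conservative)
  # F -> Y at a fixed position would be conservative by the same groups
  expect_true(is_conservative_substitution("F", "Y"))
})

test_that("motif scan equals the exhaustive window oracle", {
  set.seed(45)
  pat <- "VERVRRxHLNDxENIx"
  for (i in 1:30) {
    aa <- rand_protein(sample(30:500, 1))
    # sprinkle in near-motif windows
    if (i %% 3 == 0) {
      ins <- sample(nchar(aa) - 16, 1)
      win <- strsplit("VERVRRAHLNDAENIA", "")[[1]]
      win[sample(16, sample(0:2, 1))] <- sample(AA20, 2, TRUE)[1]
      aa <- paste0(substr(aa, 1, ins - 1), paste(win, collapse = ""),
                   substr(aa, ins + 16, nchar(aa)))
    }
    for (mm in 0:2) {
      got <- scan_motif(aa, pat, max_mismatches = mm)
      expect_equal(got$matches$start, oracle_motif_scan(aa, pat, mm))
    }
  }
})

test_that("planted microsomal lineages carry the position-9 substitution", {
  sc <- generate_families(list(
    family_spec("mGST-1", "microsomal", 2,
                within_identity_range = c(50, 77)),
    family_spec("mGST-3", "microsomal", 2,
                within_identity_range = c(50, 77))), seed = 46)
  pat <- "VERVRRxHLNDxENIx"
  for (k in seq_len(nrow(sc$truth))) {
    res <- scan_motif(sc$truth$aa_a[k], pat, max_mismatches = 1)
    expect_equal(nrow(res$matches), 1)
    if (sc$truth$subclass[k] == "mGST-1") {
      expect_equal(res$substitutions$motif_position, 9)
      expect_equal(res$substitutions$observed, "Q")
      expect_false(res$substitutions$conservative)
    } else {
      expect_equal(nrow(res$substitutions), 0)
    }
  }
})

test_that("calibrated thresholds sit at the null's upper tail", {
  th <- calibrate_domain_threshold(profiles$GSTN, n = 100, seed = 47)
  expect_true(is.finite(th))
  expect_lt(abs(th - profiles$GSTN$threshold), 0.5 * profiles$GSTN$threshold)
})

test_that("an empty profile set is rejected", {
  expect_error(scan_domains(list(id = "p", aa_seq = "MKV"), list()),
               "empty")
})
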