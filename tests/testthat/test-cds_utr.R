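test_that("poly(A) stripping follows the 90%-A maximal-suffix rule", {
  r <- strip_polya(paste0("ACGT", strrep("A", 20)))
  expect_identical(r$body, "ACGT")
  expect_equal(r$polya_len, 20L)
  expect_equal(r$polya_start, 5L)

  # 19 A + 1 internal G: the whole 20-nt suffix qualifies (95% A)
  pre <- "CCGTCCGTGC"
  suf <- paste0(strrep("A", 9), "G", strrep("A", 10))
  r2 <- strip_polya(paste0(pre, suf))
  expect_identical(r2$body, pre)
  expect_equal(r2$polya_len, 20L)

  r3 <- strip_polya("ACGTACGTACGTACGTACGT")
  expect_equal(r3$polya_len, 0L)
  expect_identical(r3$body, "ACGTACGTACGTACGTACGT")
  # suffix shorter than 10 nt never qualifies
  expect_equal(strip_polya(paste0("CCGT", strrep("A", 9)))$polya_len, 0L)
})

test_that("ORF enumeration matches the exhaustive triplet-walk oracle", {
  expect_equal(find_orfs("ATGAAATAG")$protein, "MK")

  set.seed(81)
  for (rep in 1:3) {
    s <- rand_dna(2000)
    got <- find_orfs(s, all_nested = TRUE)
    got <- got[got$has_start & got$has_stop, c("start", "end")]
    want <- orf_oracle(s)
    expect_setequal(paste(got$start, got$end), paste(want$start, want$end))
  }
  expect_equal(nrow(find_orfs("CCCCCCCCCCCC")), 0L)
})

test_that("ORFs come out sorted by protein length, longest first", {
  set.seed(82)
  s <- rand_dna(1500)
  orfs <- find_orfs(s)
  expect_true(all(diff(orfs$aa_len) <= 0))
})

test_that("homology-ranked CDS selection prefers hits over length", {
  set.seed(83)
  known <- "MDSKTLVAAGREYWQHPLNEMTRFVDKCSAQILHGGW"
  known_nt <- paste(
    vapply(strsplit(known, "")[[1]], function(aa) {
      names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == aa][1]
    }, ""), collapse = "")
  # long hit-less ORF in front, short known ORF behind it
  long_orf <- paste0("ATG", paste(sample(setdiff(names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE != "*"], "ATG"), 80, replace = TRUE),
    collapse = ""), "TAA")
  cdna <- paste0("CCTCCT", long_orf, "CCTAAG", "ATG", known_nt, "TGA", "CCGCCG")
  orfs <- find_orfs(cdna)
  pdb <- reference_db(c(P1 = known), "protein")
  ann <- select_cds("q", cdna, orfs, pdb)
  expect_identical(ann$selection_basis, "homology")
  expect_identical(substr(ann$protein, 2, nchar(known) + 1),
                   substr(known, 2, nchar(known)))
  # without the database the longer ORF wins
  ann2 <- select_cds("q", cdna, orfs, NULL)
  expect_identical(ann2$selection_basis, "longest_orf")
  expect_gt(nchar(ann2$protein), nchar(known))
})

test_that("proteins shorter than 10 aa never qualify", {
  ann <- select_cds("q", "ATGAAAAAAAAAAAAAAAAAAAAATAG",
                    find_orfs("ATGAAAAAAAAAAAAAAAAAAAAATAG"), NULL)
  expect_identical(ann$completeness, "none")  # 7-aa ORF only
})

test_that("completeness classification covers full/partial/none", {
  expect_identical(classify_completeness(TRUE, TRUE), "full_length")
  expect_identical(classify_completeness(TRUE, FALSE), "partial")
  expect_identical(classify_completeness(FALSE, TRUE), "partial")
  expect_identical(classify_completeness(FALSE, FALSE), "none")
  # an ORF running off the 3' end is partial
  s <- paste0("CCT", "ATG", strrep("GCT", 30))
  ann <- select_cds("q", s, find_orfs(s), NULL)
  expect_identical(ann$completeness, "partial")
})

test_that("UTR extraction partitions the cDNA exactly", {
  fx <- fx_small()
  cds <- annotate_cds(fx$tx$seqs, fx$dbs$protein_db)
  expect_gt(length(cds$utrs), 0)
  for (id in names(cds$utrs)) {
    u <- cds$utrs[[id]]
    ann <- cds$annotations[[id]]
    cds_len <- ann$cds_end - ann$cds_start + 1L
    expect_equal(u$utr5_len + cds_len + u$utr3_len + u$polya_len,
                 nchar(fx$tx$seqs[[id]]))
  }
  # truth join: planted UTR and tail lengths recovered exactly
  truth <- fx$sim$truth$genes
  for (i in seq_len(nrow(truth))) {
    id <- paste0(truth$gene_id[i], ".t1")
    u <- cds$utrs[[id]]
    expect_equal(u$utr5_len, truth$utr5_len[i])
    expect_equal(u$utr3_len, truth$utr3_len[i])
    expect_equal(u$polya_len, truth$polya_len[i])
  }
  # CDS starting at position 1 leaves an empty 5' UTR
  s <- paste0("ATG", strrep("GCT", 20), "TGA")
  ann <- select_cds("q", s, find_orfs(s), NULL)
  u <- extract_utrs(s, ann, strip_polya(s))
  expect_equal(u$utr5_len, 0L)
  expect_error(extract_utrs("ACGT", list(completeness = "partial")),
               "full-length")
})

test_that("composition counts match a direct tally and exclude N/X", {
  expect_equal(composition("AAAA")$pct_A, 100)
  set.seed(84)
  seqs <- vapply(1:5, function(i) rand_dna(200), "")
  comp <- composition(seqs)
  tally <- table(factor(unlist(strsplit(seqs, "")),
                        levels = c("A", "T", "G", "C")))
  expect_equal(comp$n_A, unname(tally[["A"]]))
  expect_equal(comp$pct_A + comp$pct_T + comp$pct_G + comp$pct_C, 100)
  withN <- composition("AANNXT")
  expect_equal(withN$n_N, 2L)
  expect_equal(withN$pct_A, 200 / 3)   # N/X excluded from the denominator
})

test_that("stop-codon usage sums to 100 and respects the planted codon", {
  anns <- list(
    list(cdna_id = "a", cds_end = 9L, completeness = "full_length"),
    list(cdna_id = "b", cds_end = 9L, completeness = "full_length"))
  seqs <- c(a = "ATGAAATGA", b = "ATGAAATGA")
  u <- stop_codon_usage(anns, seqs)
  expect_equal(u$pct[u$stop_codon == "TGA"], 100)
  expect_equal(sum(u$pct), 100)
})

test_that("length summaries use the even-n median convention", {
  expect_equal(unname(length_summary(c(1, 2, 3))), c(2, 2))
  expect_equal(unname(length_summary(c(1, 2, 3, 4))), c(2.5, 2.5))
  expect_error(length_summary(numeric(0)), "empty")
})
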