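test_that("degenerate and deterministic generator contracts hold", {
  cfg <- sim_config(seed = 3, n_genes = 0L)
  empty <- simulate_genome(cfg)
  expect_length(empty$genome, 0L)
  expect_equal(nrow(empty$truth$genes), 0L)

  cfg2 <- sim_config(seed = 5, n_genes = 6)
  a <- simulate_genome(cfg2)
  b <- simulate_genome(cfg2)
  expect_identical(a, b)
  ta <- simulate_transcripts(a, cfg2$isoform_rates, seed = 6)
  tb <- simulate_transcripts(b, cfg2$isoform_rates, seed = 6)
  expect_identical(ta, tb)
  la <- simulate_clone_library(ta, cfg2, a, seed = 7)
  lb <- simulate_clone_library(tb, cfg2, b, seed = 7)
  expect_identical(la, lb)

  expect_error(sim_config(seed = 1, chimera_rate = 1.5), "configuration")
  expect_error(sim_config(seed = 1, intron_sdlog = -1), "configuration")
  expect_error(simulate_variant_genome(a$genome, 0.5), "configuration")
})

test_that("every emitted intron starts GT and ends AG (dinucleotide scan)", {
  sim <- fx_study()$sim
  truth <- sim$truth
  strands <- setNames(truth$genes$strand, truth$genes$gene_id)
  scafs <- setNames(truth$genes$scaffold_id, truth$genes$gene_id)
  n_bad <- 0L
  for (i in seq_len(nrow(truth$introns))) {
    r <- truth$introns[i, ]
    s <- substr(sim$genome[[scafs[[r$gene_id]]]], r$g_start, r$g_end)
    if (strands[[r$gene_id]] == "-") s <- revcomp(s)
    if (substr(s, 1, 2) != "GT" ||
        substr(s, nchar(s) - 1, nchar(s)) != "AG") n_bad <- n_bad + 1L
  }
  expect_gt(nrow(truth$introns), 500)
  expect_equal(n_bad, 0L)
})

test_that("variant genome applies recorded substitutions and nothing else", {
  set.seed(71)
  genome <- c(chr1 = rand_dna(200000), chr2 = rand_dna(150000))
  # zero rate: identity
  v0 <- simulate_variant_genome(genome, 0, seed = 1)
  expect_identical(v0$genome, genome)
  expect_equal(nrow(v0$snp_positions), 0L)

  v <- simulate_variant_genome(genome, 0.002, seed = 2)
  snp <- v$snp_positions
  for (sc in names(genome)) {
    ref <- strsplit(genome[[sc]], "")[[1]]
    alt <- strsplit(v$genome[[sc]], "")[[1]]
    pos <- snp$pos[snp$scaffold_id == sc]
    expect_true(all(ref[pos] != alt[pos]))
    expect_true(all(ref[-pos] == alt[-pos]))
    expect_identical(snp$ref[snp$scaffold_id == sc], ref[pos])
    expect_identical(snp$alt[snp$scaffold_id == sc], alt[pos])
  }
})

test_that("realized substitution count falls inside the binomial 3-sigma band", {
  set.seed(72)
  genome <- c(chr = rand_dna(2e6))
  rate <- 0.00061
  v <- simulate_variant_genome(genome, rate, seed = 3)
  expected <- 2e6 * rate
  sigma <- sqrt(2e6 * rate * (1 - rate))
  expect_lt(abs(nrow(v$snp_positions) - expected), 3 * sigma)
})

test_that("isoform construction obeys the planted event geometry", {
  fx <- fx_small()
  # all rates zero: references only
  expect_true(all(fx$tx$isoforms$event == "reference"))
  expect_equal(length(fx$tx$seqs), nrow(fx$sim$truth$genes))

  tx <- simulate_transcripts(fx$sim,
                             c(retained_intron = 0.5, alt_donor = 0.2,
                               alt_acceptor = 0.2, exon_skip = 0.1),
                             seed = 77)
  iso <- tx$isoforms
  truth <- fx$sim$truth
  for (i in which(iso$event == "retained_intron")) {
    gid <- iso$gene_id[i]
    ref <- tx$seqs[[paste0(gid, ".t1")]]
    alt <- tx$seqs[[iso$transcript_id[i]]]
    ilen <- truth$introns$length[truth$introns$gene_id == gid &
                                 truth$introns$intron_index == iso$intron_index[i]]
    expect_equal(nchar(alt), nchar(ref) + ilen)
  }
  for (i in which(iso$event %in% c("alt_donor", "alt_acceptor"))) {
    gid <- iso$gene_id[i]
    expect_equal(nchar(tx$seqs[[iso$transcript_id[i]]]),
                 nchar(tx$seqs[[paste0(gid, ".t1")]]) + iso$delta[i])
  }
  for (i in which(iso$event == "exon_skip")) {
    gid <- iso$gene_id[i]
    ex <- truth$exons[truth$exons$gene_id == gid &
                      truth$exons$exon_index == iso$exon_index[i], ]
    expect_equal(nchar(tx$seqs[[iso$transcript_id[i]]]),
                 nchar(tx$seqs[[paste0(gid, ".t1")]]) -
                   (ex$tx_end - ex$tx_start + 1L))
  }
})

test_that("clone library conserves truth classes and plants chimera junctions", {
  lib <- fx_cluster()$lib
  # conservation: one truth row per emitted clone, in both views
  expect_setequal(lib$classes$clone_id, names(lib$inserts))
  expect_setequal(lib$classes$clone_id, names(lib$reads$seq))
  expect_true(all(lengths(lib$reads$qual[lib$classes$clone_id]) ==
                  nchar(lib$reads$seq[lib$classes$clone_id])))

  # chimera_rate 0 / redundancy_mean 1: clone count equals transcript count
  fx <- fx_small()
  cfg1 <- sim_config(seed = 41, n_genes = 12, chimera_rate = 0,
                     ncrna_rate = 0, pathogen_rate = 0, redundancy_mean = 1)
  lib1 <- simulate_clone_library(fx$tx, cfg1, fx$sim, seed = 42)
  expect_equal(length(lib1$inserts), length(fx$tx$seqs))
  expect_true(all(lib1$classes$class == "normal"))

  # chimeras carry the recorded enzyme site at the recorded junction
  cfg2 <- sim_config(seed = 43, n_genes = 12, chimera_rate = 0.5,
                     ncrna_rate = 0, pathogen_rate = 0, redundancy_mean = 1)
  lib2 <- simulate_clone_library(fx$tx, cfg2, fx$sim, seed = 44)
  chim <- lib2$classes[lib2$classes$class == "chimera", ]
  expect_gt(nrow(chim), 0)
  for (i in seq_len(nrow(chim))) {
    s <- lib2$inserts[[chim$clone_id[i]]]
    expect_identical(substr(s, chim$junction_start[i],
                            chim$junction_start[i] + 5L),
                     chim$junction_site[i])
  }
})

test_that("redundant clones group by source transcript (truth join)", {
  lib <- fx_cluster()$lib
  cl <- lib$classes
  expect_true(all(cl$trunc5[cl$class == "normal"] == 0L))
  expect_true(all(cl$trunc5[cl$class == "redundant"] > 0L))
  # every redundant clone is a suffix of its source transcript's insert
  tx <- fx_cluster()$tx
  for (i in which(cl$class == "redundant")) {
    full <- tx$seqs[[cl$transcript_id[i]]]
    expect_identical(lib$inserts[[cl$clone_id[i]]],
                     substr(full, cl$trunc5[i] + 1L, nchar(full)))
  }
})
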