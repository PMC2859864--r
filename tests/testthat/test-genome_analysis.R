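test_that("mapped gene models recover planted exon structures exactly", {
  fx <- fx_small()
  bodies <- fx$sim$truth$tx_seq
  mp <- map_transcripts(bodies, fx$sim$genome, margin = 2000L)
  expect_equal(nrow(mp$unmapped), 0L)
  tm <- truth_gene_models(fx$sim)
  for (gid in names(mp$models)) {
    m <- mp$models[[gid]]
    te <- tm[[gid]]$exons
    expect_identical(m$scaffold_id, tm[[gid]]$scaffold_id)
    expect_identical(m$strand, tm[[gid]]$strand)
    expect_equal(sort(m$exons$g_start), sort(te$g_start))
    expect_equal(sort(m$exons$g_end), sort(te$g_end))
    expect_identical(m$exons$type, te$type)
    expect_equal(m$identity, 1)
  }
})

test_that("unmapped cDNAs report the failing criterion", {
  fx <- fx_small()
  g <- fx$sim$truth$genes
  body <- fx$sim$truth$tx_seq[[g$gene_id[1]]]
  # heavily diverged copy: identity below 90%
  set.seed(91)
  v <- strsplit(body, "")[[1]]
  pos <- sample(seq_along(v), round(0.15 * length(v)))
  for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  r1 <- map_to_genome(paste(v, collapse = ""), fx$sim$genome, margin = 2000L)
  expect_s3_class(r1, "unmapped")
  expect_true(r1$reason %in% c("low_identity", "no_hit"))

  # foreign 3' extension: coverage below 90%
  ext <- paste0(body, rand_dna(round(0.25 * nchar(body))))
  r2 <- map_to_genome(ext, fx$sim$genome, margin = 2000L)
  expect_s3_class(r2, "unmapped")
  expect_identical(r2$reason, "low_coverage")

  r3 <- map_to_genome(rand_dna(500), fx$sim$genome)
  expect_identical(r3$reason, "no_hit")
})

test_that("exon typing follows transcript order", {
  one <- gene_model("a", "s", "+", data.frame(g_start = 1L, g_end = 50L))
  expect_identical(classify_exons(one)$exons$type, "single")
  three <- gene_model("b", "s", "+",
                      data.frame(g_start = c(1L, 100L, 200L),
                                 g_end = c(50L, 150L, 260L)))
  expect_identical(classify_exons(three)$exons$type,
                   c("initial", "internal", "terminal"))
})

test_that("exon/intron statistics satisfy the structural identities", {
  m <- gene_model("g", "s", "+",
                  exons = data.frame(g_start = c(1L, 401L),
                                     g_end = c(100L, 600L),
                                     type = c("initial", "terminal")),
                  introns = data.frame(g_start = 101L, g_end = 400L,
                                       donor = "GT", acceptor = "AG",
                                       canonical = TRUE))
  st <- exon_intron_stats(list(m))
  expect_equal(st$gene_lengths, 600)
  expect_equal(sum(st$exon_lengths) + sum(st$intron_lengths), 600)

  fx <- fx_small()
  models <- map_transcripts(fx$sim$truth$tx_seq, fx$sim$genome,
                            margin = 2000L)$models
  st2 <- exon_intron_stats(models)
  # gene length = sum of exon and intron lengths, for every model
  for (m in models) {
    glen <- max(m$exons$g_end) - min(m$exons$g_start) + 1L
    expect_equal(glen, sum(m$exons$g_end - m$exons$g_start + 1L) +
                   sum(m$introns$g_end - m$introns$g_start + 1L))
  }
  # typing totals: one initial and one terminal per multi-exon model
  types <- unlist(lapply(models, function(m) m$exons$type))
  multi <- sum(vapply(models, function(m) nrow(m$exons) > 1, TRUE))
  expect_equal(sum(types == "initial"), multi)
  expect_equal(sum(types == "terminal"), multi)
  expect_equal(sum(types == "single"), length(models) - multi)
  # per-type medians equal a direct truth computation
  tm <- truth_gene_models(fx$sim)
  tl <- do.call(rbind, lapply(tm, function(m) {
    data.frame(type = m$exons$type,
               len = m$exons$g_end - m$exons$g_start + 1L)
  }))
  for (ty in unique(tl$type)) {
    expect_equal(st2$exon_by_type$median[st2$exon_by_type$type == ty],
                 median(tl$len[tl$type == ty]))
  }
})

test_that("start/stop codon placement onto exon types matches truth", {
  fx <- fx_small()
  cds <- annotate_cds(fx$tx$seqs, fx$dbs$protein_db)
  bodies <- cds$bodies
  names(bodies) <- sub("\\.t1$", "", names(bodies))
  anns <- cds$annotations
  names(anns) <- sub("\\.t1$", "", names(anns))
  models <- map_transcripts(bodies, fx$sim$genome, margin = 2000L)$models
  occ <- utr_intron_occurrence(models, anns)
  # truth: which exon holds the start / stop codon
  truth <- fx$sim$truth
  start_int <- logical(0); stop_int <- logical(0)
  for (i in seq_len(nrow(truth$genes))) {
    g <- truth$genes[i, ]
    ex <- truth$exons[truth$exons$gene_id == g$gene_id, ]
    p_start <- g$utr5_len + 1L
    p_stop <- g$utr5_len + g$cds_len - 2L
    t_start <- ex$type[ex$tx_start <= p_start & ex$tx_end >= p_start]
    t_stop <- ex$type[ex$tx_start <= p_stop & ex$tx_end >= p_stop]
    start_int <- c(start_int, t_start == "internal")
    stop_int <- c(stop_int, t_stop == "internal")
  }
  expect_equal(occ$freq_start_internal, mean(start_int))
  expect_equal(occ$freq_stop_internal, mean(stop_int))
  # single-exon-only input yields zero frequencies by definition
  single <- models[vapply(models, function(m) nrow(m$exons) == 1, TRUE)]
  if (length(single)) {
    occ1 <- utr_intron_occurrence(single, anns)
    expect_equal(occ1$freq_start_internal, 0)
    expect_equal(occ1$freq_stop_internal, 0)
  }
})

test_that("splice-event classification matches hand-built structures", {
  ex <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(g_start = m[, 1], g_end = m[, 2])
  }
  intr <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(g_start = m[, 1], g_end = m[, 2], donor = "GT",
               acceptor = "AG", canonical = TRUE)
  }
  ref <- gene_model("ref", "s", "+",
                    exons = ex(1, 100, 201, 300, 401, 500),
                    introns = intr(101, 200, 301, 400))
  # identical models: no events
  expect_equal(nrow(classify_splice_events(ref, ref)), 0L)
  # retained intron 1
  ri <- gene_model("ri", "s", "+", exons = ex(1, 300, 401, 500),
                   introns = intr(301, 400))
  e1 <- classify_splice_events(ref, ri)
  expect_identical(e1$type, "retained_intron")
  expect_equal(c(e1$g_start, e1$g_end), c(101, 200))
  # shifted intron start on the plus strand moves the donor site
  ad <- gene_model("ad", "s", "+", exons = ex(1, 120, 201, 300, 401, 500),
                   introns = intr(121, 200, 301, 400))
  expect_identical(classify_splice_events(ref, ad)$type, "alt_donor")
  # shifted intron end moves the acceptor site
  expect_identical(classify_splice_events(ref,
    gene_model("aa", "s", "+", exons = ex(1, 100, 221, 300, 401, 500),
               introns = intr(101, 220, 301, 400)))$type, "alt_acceptor")
  # exon skip: middle exon absent, introns merged
  sk <- gene_model("sk", "s", "+", exons = ex(1, 100, 401, 500),
                   introns = intr(101, 400))
  esk <- classify_splice_events(sk, ref)
  expect_identical(esk$type, "exon_skip")
  # different scaffolds: empty
  other <- gene_model("o", "s2", "+", exons = ex(1, 100))
  expect_equal(nrow(classify_splice_events(ref, other)), 0L)
})

test_that("alt donor/acceptor orientation respects the strand", {
  ex <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(g_start = m[, 1], g_end = m[, 2])
  }
  intr <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(g_start = m[, 1], g_end = m[, 2], donor = "GT",
               acceptor = "AG", canonical = TRUE)
  }
  # on the minus strand the intron's g_end is the donor side
  refm <- gene_model("refm", "s", "-", exons = ex(401, 500, 201, 300, 1, 100),
                     introns = intr(101, 200, 301, 400))
  alt <- gene_model("altm", "s", "-", exons = ex(401, 500, 221, 300, 1, 100),
                    introns = intr(101, 200, 301, 420))
  # intron 301..400 vs 301..420: same g_start (acceptor on minus), donor moved
  expect_identical(classify_splice_events(refm, alt)$type, "alt_donor")
})

test_that("planted simulator events are classified exactly", {
  fx <- fx_small()
  tx <- simulate_transcripts(fx$sim,
                             c(retained_intron = 0.3, alt_donor = 0.2,
                               alt_acceptor = 0.2, exon_skip = 0.2),
                             seed = 93)
  iso <- tx$isoforms[tx$isoforms$event != "reference", , drop = FALSE]
  expect_gt(nrow(iso), 2)
  for (i in seq_len(nrow(iso))) {
    gid <- iso$gene_id[i]
    a <- map_to_genome(strip_polya(tx$seqs[[iso$transcript_id[i]]])$body,
                       fx$sim$genome, iso$transcript_id[i], margin = 2000L)
    b <- map_to_genome(strip_polya(tx$seqs[[paste0(gid, ".t1")]])$body,
                       fx$sim$genome, paste0(gid, ".t1"), margin = 2000L)
    ev <- classify_splice_events(a, b)
    expect_identical(ev$type, iso$event[i])
  }
})

test_that("SNP estimation counts only exon mismatches above the identity floor", {
  fx <- fx_small()
  # transcripts against their own genome: zero rate
  models <- map_transcripts(fx$sim$truth$tx_seq, fx$sim$genome,
                            margin = 2000L)$models
  est0 <- estimate_snp_rate(models)
  expect_equal(est0$rate_pct, 0)
  expect_gt(est0$aligned_exon_bases, 10000)

  # a pair below the 99.5% identity floor contributes nothing
  fake <- models[[1]]
  fake$identity <- 0.994
  est1 <- estimate_snp_rate(c(models, list(low = fake)))
  expect_equal(est1$pairs_used, length(models))
  expect_equal(est1$aligned_exon_bases, est0$aligned_exon_bases)
  expect_error(estimate_snp_rate(list(fake)), "undefined|no aligned")
})
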