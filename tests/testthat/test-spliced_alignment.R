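test_that("an exact genomic substring aligns as a single perfect exon", {
  set.seed(31)
  g <- rand_dna(400)
  est <- substr(g, 101, 250)
  a <- spliced_align(est, g)
  expect_equal(nrow(a$exons), 1L)
  expect_equal(nrow(a$introns), 0L)
  expect_equal(a$identity, 1)
  expect_equal(a$est_coverage, 1)
  expect_equal(a$exons$g_start, 101L)
  expect_equal(a$exons$g_end, 250L)
})

test_that("a planted GT..AG intron is recovered at the exact boundaries", {
  set.seed(32)
  for (rep in 1:5) {
    e1 <- rand_dna(60); e2 <- rand_dna(60)
    interior <- rand_dna(120)
    g <- paste0(e1, "GT", interior, "AG", e2)
    a <- spliced_align(paste0(e1, e2), g, spliced_params(min_intron = 60))
    expect_equal(nrow(a$exons), 2L)
    expect_equal(a$introns$g_start, 61L)
    expect_equal(a$introns$g_end, 60L + 124L)
    expect_identical(a$introns$donor, "GT")
    expect_identical(a$introns$acceptor, "AG")
    expect_true(a$introns$canonical)
    expect_equal(a$score, 120 - 40)
  }
})

test_that("a retained intron aligns as one exon spanning the intron", {
  set.seed(33)
  e1 <- rand_dna(80); e2 <- rand_dna(80)
  g <- paste0(e1, "GT", rand_dna(150), "AG", e2)
  a <- spliced_align(g, g)   # est retains the intron
  expect_equal(nrow(a$exons), 1L)
  expect_equal(nrow(a$introns), 0L)
})

test_that("an indel below min_intron is absorbed as a gap, not an intron", {
  set.seed(34)
  g <- rand_dna(300)
  est <- paste0(substr(g, 1, 150), substr(g, 156, 300))  # 5-nt deletion
  a <- spliced_align(est, g, spliced_params(min_intron = 60))
  expect_equal(nrow(a$introns), 0L)
  expect_equal(nrow(a$exons), 1L)
})

test_that("with the intron state disabled the spliced score equals local alignment", {
  set.seed(35)
  for (rep in 1:5) {
    a <- rand_dna(150)
    b <- paste0(rand_dna(30), substr(a, 21, 120), rand_dna(40))
    sp <- spliced_align(a, b, spliced_params(min_intron = 20,
                                             intron_penalty = 1e9))
    h <- local_align(a, b)
    expect_equal(sp$score, h$score)
  }
})

test_that("minus-strand spliced alignments report forward coordinates and sense dinucleotides", {
  set.seed(36)
  e1 <- rand_dna(70); e2 <- rand_dna(70)
  gene <- paste0(e1, "GT", rand_dna(100), "AG", e2)
  g <- revcomp(gene)   # gene sits on the minus strand of g
  a <- spliced_align(paste0(e1, e2), g, spliced_params(min_intron = 60))
  expect_identical(a$strand, "-")
  expect_identical(a$introns$donor, "GT")
  expect_identical(a$introns$acceptor, "AG")
  # gene-sense intron [71, 174] maps to forward coordinates [n-174+1, n-71+1]
  n <- nchar(g)
  expect_equal(a$introns$g_start, n - 174 + 1)
  expect_equal(a$introns$g_end, n - 71 + 1)
  # exons stay in transcript order: first exon has the higher coordinates
  expect_gt(a$exons$g_start[1], a$exons$g_end[2])
})

test_that("bidirectional intron detection is asymmetric for a retained-intron pair", {
  set.seed(37)
  e1 <- rand_dna(100); e2 <- rand_dna(100)
  spliced <- paste0(e1, e2)
  retained <- paste0(e1, "GT", rand_dna(200), "AG", e2)
  r <- detect_intron_pairwise(spliced, retained)
  expect_equal(nrow(r$introns_in_a), 0L)    # spliced isoform carries none
  expect_equal(nrow(r$introns_in_b), 1L)    # retained isoform carries one
  same <- detect_intron_pairwise(spliced, spliced)
  expect_equal(nrow(same$introns_in_a) + nrow(same$introns_in_b), 0L)
})

test_that("spliced DP score equals the naive enumeration oracle on small instances", {
  set.seed(38)
  p <- spliced_params(min_intron = 20)
  for (case in 1:40) {
    m <- sample(8:30, 1); n <- sample(25:60, 1)
    g <- rand_dna(n)
    est <- if (case %% 3 == 0) rand_dna(m) else {
      # exon/intron-like: two pieces of the genome joined
      cut1 <- sample(5:(n %/% 2), 1); cut2 <- sample((cut1 + 21):min(n, cut1 + 40), 1)
      paste0(substr(g, 1, cut1), substr(g, cut2, n))
    }
    got <- flcdna:::spliced_align_dp(est, g, scoring_scheme()$matrix,
                                     5, 2, 40, 20, 20L)$score
    expect_equal(got, spliced_score_oracle(est, g), label = paste("case", case))
  }
})
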