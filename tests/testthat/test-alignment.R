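test_that("Karlin-Altschul lambda matches an independent bisection root", {
  # match +1 / mismatch -1, uniform background:
  # lambda solves 0.25 e^l + 0.75 e^-l = 1
  f <- function(l) 0.25 * exp(l) + 0.75 * exp(-l) - 1
  lo <- 1e-6; hi <- 4
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  ka <- ka_calibrate(scoring_scheme(match = 1, mismatch = -1))
  expect_equal(ka$lambda, (lo + hi) / 2, tolerance = 1e-9)

  # same for the default +1/-3 scheme
  f3 <- function(l) 0.25 * exp(l) + 0.75 * exp(-3 * l) - 1
  lo <- 1e-6; hi <- 4
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (f3(mid) > 0) hi <- mid else lo <- mid
  }
  ka3 <- ka_calibrate(scoring_scheme())
  expect_equal(ka3$lambda, (lo + hi) / 2, tolerance = 1e-9)
})

test_that("scaling all scores by 2 halves lambda; K stays positive and sane", {
  ka1 <- ka_calibrate(scoring_scheme(match = 1, mismatch = -3))
  ka2 <- ka_calibrate(scoring_scheme(match = 2, mismatch = -6))
  expect_equal(ka2$lambda, ka1$lambda / 2, tolerance = 1e-9)
  expect_gt(ka1$K, 0.05)
  expect_lt(ka1$K, 1)
})

test_that("a scheme with non-negative expected score is rejected", {
  expect_error(ka_calibrate(scoring_scheme(match = 1, mismatch = 1)),
               "negative")
})

test_that("self-alignment gives identity 1 and full length", {
  h <- local_align("ACGTACGT", "ACGTACGT")
  expect_equal(h$score, 8)
  expect_equal(h$identity, 1)
  expect_equal(h$align_len, 8L)
  expect_equal(c(h$q_start, h$q_end, h$s_start, h$s_end), c(1, 8, 1, 8))
  expect_error(local_align("", "ACGT"), "empty")
})

test_that("local alignment score equals the plain-R DP oracle and Biostrings", {
  set.seed(42)
  mat <- scoring_scheme()$matrix[1:4, 1:4]
  for (case in 1:6) {
    a <- rand_dna(300)
    # half the cases share a planted common segment so scores are non-trivial
    b <- if (case %% 2) rand_dna(300) else
      paste0(rand_dna(80), substr(a, 101, 220), rand_dna(100))
    h <- local_align(a, b, both_strands = FALSE)
    expect_equal(h$score, sw_score_oracle(a, b))
    pa <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 5, gapExtension = 2)
    expect_equal(h$score, Biostrings::score(pa))
  }
})

test_that("reverse-complemented subject gives the same score on the minus strand", {
  set.seed(7)
  a <- rand_dna(200)
  b <- paste0(rand_dna(40), substr(a, 51, 160), rand_dna(40))
  h1 <- local_align(a, b)
  h2 <- local_align(a, revcomp(b))
  expect_equal(h2$score, h1$score)
  expect_identical(h2$strand, "-")
  expect_identical(h1$strand, "+")
  # minus-strand subject interval maps back to the forward strand
  L <- nchar(b)
  expect_equal(h2$s_start, L - h1$s_end + 1)
  expect_equal(h2$s_end, L - h1$s_start + 1)
})

test_that("search ranks an identical record first and honors the threshold", {
  set.seed(9)
  seqs <- setNames(vapply(1:5, function(i) rand_dna(300), ""),
                   paste0("r", 1:5))
  db <- reference_db(seqs, "transcript")
  hits <- search_db(seqs[["r3"]], db, max_evalue = 1e-5)
  expect_identical(hits$subject_id[1], "r3")
  expect_equal(nrow(search_db(seqs[["r3"]], db, max_evalue = 0)), 0L)
})

test_that("a planted 97%-identity homolog among decoys is the top hit", {
  set.seed(13)
  target <- rand_dna(600)
  hom <- strsplit(target, "")[[1]]
  pos <- sample(600, 18)
  for (p in pos) hom[p] <- setdiff(c("A", "C", "G", "T"), hom[p])[1]
  db_seqs <- c(setNames(vapply(1:50, function(i) rand_dna(600), ""),
                        paste0("decoy", 1:50)),
               homolog = paste(hom, collapse = ""))
  db <- reference_db(db_seqs, "transcript")
  hits <- search_db(target, db, max_evalue = 1e-10)
  expect_identical(hits$subject_id[1], "homolog")
  expect_gte(hits$identity[1], 0.97)
})

test_that("E-values decrease strictly as scores increase (fixed m, n)", {
  ka <- ka_calibrate(scoring_scheme())
  ev <- function(s) ka$K * 500 * 500 * exp(-ka$lambda * s)
  scores <- seq(20, 200, by = 20)
  expect_true(all(diff(ev(scores)) < 0))
  # and through the aligner: longer exact match => smaller E-value
  set.seed(15)
  a <- rand_dna(500)
  h_long <- local_align(substr(a, 1, 200), a)
  h_short <- local_align(substr(a, 1, 60), a)
  expect_lt(h_long$evalue, h_short$evalue)
})
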