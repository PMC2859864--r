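mutate_seq <- function(s, n_sub, seed) {
  set.seed(seed)
  v <- strsplit(s, "")[[1]]
  pos <- sample(seq(5, length(v) - 5), n_sub)
  for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  paste(v, collapse = "")
}

test_that("redundancy collapse links at 97% identity but not at 96%", {
  set.seed(61)
  base <- rand_dna(1000)
  seqs <- c(s01 = base,
            s02 = mutate_seq(base, 30, 62),   # 97.0% identity
            s03 = mutate_seq(base, 40, 63),   # 96.0% identity
            s04 = rand_dna(1000))
  r <- remove_redundant(seqs)
  expect_true("s03" %in% r$kept)              # below the identity cut
  expect_true("s04" %in% r$kept)
  expect_false(all(c("s01", "s02") %in% r$kept))  # 97% pair collapsed
})

test_that("byte-identical sequences collapse to the longest / smallest id", {
  set.seed(64)
  a <- rand_dna(900)
  r <- remove_redundant(c(y = a, x = a, z = substr(a, 101, 900)))
  expect_identical(r$kept, "x")   # z is a 5'-truncation, same component
})

test_that("redundancy components close transitively", {
  set.seed(65)
  a <- rand_dna(1200)
  b <- mutate_seq(a, 24, 66)      # 98% to a
  c2 <- mutate_seq(b, 24, 67)     # 98% to b, ~96% to a
  r <- remove_redundant(c(a = a, b = b, c = c2))
  expect_equal(length(r$kept), 1L)
  expect_equal(length(unique(r$groups$group_id)), 1L)
})

test_that("redundancy collapse is idempotent and keeps its ledger identity", {
  lib <- fx_cluster()$lib
  r1 <- remove_redundant(lib$inserts)
  r2 <- remove_redundant(lib$inserts[r1$kept])
  expect_identical(sort(r2$kept), sort(r1$kept))
  expect_equal(nrow(r1$groups), length(lib$inserts))
})

test_that("an intron-scale internal gap blocks a redundancy link", {
  set.seed(68)
  e1 <- rand_dna(700); e2 <- rand_dna(700)
  spliced <- paste0(e1, e2)
  retained <- paste0(e1, rand_dna(300), e2)
  r <- remove_redundant(c(sp = spliced, re = retained))
  expect_setequal(r$kept, c("sp", "re"))
})

test_that("ncRNA flagging hits planted contaminants and nothing else", {
  set.seed(69)
  pool <- setNames(vapply(1:5, function(i) rand_dna(600), ""),
                   paste0("nc", 1:5))
  db <- reference_db(pool, "ncrna")
  expect_true(as.logical(flag_ncrna(pool[["nc3"]], db)))
  expect_false(as.logical(flag_ncrna(rand_dna(600), db)))
  expect_warning(got <- flag_ncrna(rand_dna(100),
                                   reference_db(character(0) |>
                                                  setNames(character(0)),
                                                "ncrna")),
                 "empty")
  expect_false(as.logical(got))
})

test_that("pathogen flagging respects the host-rescue rule", {
  set.seed(70)
  pathogen <- rand_dna(800)
  pdb <- reference_db(c(p1 = pathogen), "pathogen")
  host_without <- reference_db(c(h1 = rand_dna(800)), "transcript")
  host_with <- reference_db(c(h1 = rand_dna(800), h2 = pathogen),
                            "transcript")
  expect_true(flag_pathogen(pathogen, pdb, host_without))
  expect_false(flag_pathogen(pathogen, pdb, host_with))   # rescued
  expect_false(flag_pathogen(rand_dna(800), pdb, host_without))
})

test_that("chimera detection fires the scaffold rule, then the enzyme rule", {
  set.seed(73)
  txA <- rand_dna(700); txB <- rand_dna(700)
  chim <- paste0(substr(txA, 1, 400), "GGATCC",
                 substr(txB, 301, 700))
  uni <- reference_db(c(ugA = txA, ugB = txB), "transcript",
                      desc = c(ugA = "protein kinase 7",
                               ugB = "cellulose synthase 2"))
  two_scaf <- reference_db(c(s1 = paste0(rand_dna(500), txA, rand_dna(500)),
                             s2 = paste0(rand_dna(500), txB, rand_dna(500))),
                           "genome")
  r <- flag_chimera(chim, uni, two_scaf)
  expect_true(r$chimera)
  expect_identical(r$rule_fired, "scaffold")

  one_scaf <- reference_db(
    c(s1 = paste0(rand_dna(300), txA, rand_dna(2000), txB, rand_dna(300))),
    "genome")
  r2 <- flag_chimera(chim, uni, one_scaf)
  expect_true(r2$chimera)
  expect_identical(r2$rule_fired, "enzyme_site")

  r3 <- flag_chimera(txA, uni, two_scaf)
  expect_false(r3$chimera)
  expect_identical(r3$rule_fired, "none")
})

test_that("identical functional descriptions never form a chimera candidate", {
  set.seed(74)
  txA <- rand_dna(700); txB <- rand_dna(700)
  chim <- paste0(substr(txA, 1, 400), "CTCGAG", substr(txB, 301, 700))
  uni_same <- reference_db(c(ugA = txA, ugB = txB), "transcript",
                           desc = c(ugA = "putative kinase",
                                    ugB = "kinase protein"))
  scafs <- reference_db(c(s1 = paste0(rand_dna(200), txA, rand_dna(200)),
                          s2 = paste0(rand_dna(200), txB, rand_dna(200))),
                        "genome")
  # token sets are nested after normalization -> not "different"
  r <- flag_chimera(chim, uni_same, scafs)
  expect_false(r$chimera)
})

test_that("retained-intron flagging is asymmetric and needs a homolog", {
  set.seed(75)
  e1 <- rand_dna(400); e2 <- rand_dna(400)
  spliced <- paste0(e1, e2)
  retained <- paste0(e1, "GT", rand_dna(250), "AG", e2)
  comp <- reference_db(c(sp = spliced, re = retained, bg = rand_dna(800)),
                       "transcript")
  expect_true(as.logical(flag_retained_intron(retained, "re", comp)))
  expect_false(as.logical(flag_retained_intron(spliced, "sp", comp)))
  expect_false(as.logical(flag_retained_intron(rand_dna(700), "q", comp)))
})

test_that("the cascade ledger conserves counts and empty input yields zeros", {
  r0 <- run_curation(character(0) |> setNames(character(0)), dbs = list())
  expect_equal(nrow(r0$ledger), 0L)
  expect_length(r0$kept, 0L)

  st <- fx_study()
  led <- st$curation$ledger
  expect_true(all(led$n_in == led$removed + led$kept))
  expect_equal(led$n_in[-1], led$kept[-nrow(led)])
  expect_equal(led$n_in[1], length(st$lib$inserts))
  acc <- pipeline_accounting(st$ledger)
  expect_true(acc$valid)
})
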