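# Seeded generator of a toy genome, gene models, transcript isoforms and
# clone libraries with cloning artifacts, together with machine-readable
# truth tables for every downstream stage. The generator is first-class,
# tested code: its defaults define the study conditions used throughout the
# test-suite, and several rejection-sampling guards make the planted truth
# unambiguous (see the methods vignette for the rationale of each guard).

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.ALL_CODONS <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                     paste0), c("T", "C", "A", "G"), paste0))
.SENSE_CODONS <- setdiff(.ALL_CODONS, .STOP_CODONS)

# a fixed synthetic cloning-vector fragment (deterministic constant)
.DEFAULT_VECTOR <- paste0("GTTTTCCCAGTCACGACGTTGTAAAACGACGGCCAGTGAATTC",
                          "GAGCTCGGTACCCGGGGATCCTCTAG")

#' Simulation configuration
#'
#' Length families are log-normal (parameterised by target median and
#' dispersion) with hard bounds, reproducing the heavy right tails seen in
#' real cDNA collections. Defaults emulate a tomato-like full-length cDNA
#' study: mean 4.9 exons per gene, median exon/intron lengths about 154 and
#' 264 nt, mean 5'-UTR/CDS/3'-UTR lengths about 175/938/257 nt, an
#' AT-rich (59.7%) base composition, stop-codon usage 40.6/35.6/23.8
#' (TGA/TAA/TAG), and a variant-genome substitution rate of 0.061%.
#'
#' @param seed integer seed; together with the configuration it fully
#'   determines every output byte
#' @param n_genes number of genes to simulate
#' @param exon_count_mean mean exons per gene (count is 1 + Poisson)
#' @param exon_len_meanlog,exon_len_sdlog log-normal weights used to cut a
#'   transcript into exons
#' @param min_exon minimum internal exon length (nt)
#' @param min_terminal_exon minimum first/terminal exon length (nt); kept
#'   above the intron penalty so a local spliced alignment always gains by
#'   including a terminal exon
#' @param intron_meanlog,intron_sdlog,intron_min,intron_max intron length
#'   family (nt)
#' @param utr5_meanlog,utr5_sdlog,utr5_min,utr5_max 5'-UTR length family
#' @param utr3_meanlog,utr3_sdlog,utr3_min,utr3_max 3'-UTR length family
#' @param cds_codons_meanlog,cds_codons_sdlog,cds_codons_min,cds_codons_max
#'   CDS length family in codons (excluding the stop codon)
#' @param base_freq background base frequencies (named A/C/G/T, sums to 1)
#' @param stop_freq stop-codon usage probabilities (named TGA/TAA/TAG)
#' @param isoform_rates per-gene probabilities of one splice event, named
#'   retained_intron/alt_donor/alt_acceptor/exon_skip
#' @param chimera_rate,ncrna_rate,pathogen_rate artifact rates (fraction of
#'   base transcripts)
#' @param redundancy_mean mean clones per transcript (count is 1 + Poisson)
#' @param trunc5_frac_range 5'-truncation of redundant clones, as a uniform
#'   fraction of insert length
#' @param polya_range poly(A) tail length range (nt)
#' @param snp_rate substitution rate of the variant ("second cultivar")
#'   genome
#' @param vector_seq cloning-vector sequence used for read flanks
#' @param q_mean,q_sd,q_clip,q_decay_start,q_decay_slope per-position Phred
#'   model: N(q_mean, q_sd) clipped to q_clip, with linear decay of
#'   q_decay_slope per base after position q_decay_start
#' @param read_max_len maximum 5'-read length (nt)
#' @param genes_per_scaffold,spacer_len scaffold layout
#' @return a list of class `sim_config`
#' @export
sim_config <- function(seed = 1L, n_genes = 200L,
                       exon_count_mean = 4.9,
                       exon_len_meanlog = log(154), exon_len_sdlog = 0.8,
                       min_exon = 30L, min_terminal_exon = 60L,
                       intron_meanlog = log(264), intron_sdlog = 0.55,
                       intron_min = 70L, intron_max = 10000L,
                       utr5_meanlog = log(106), utr5_sdlog = 1.0,
                       utr5_min = 20L, utr5_max = 2500L,
                       utr3_meanlog = log(220), utr3_sdlog = 0.56,
                       utr3_min = 30L, utr3_max = 2500L,
                       cds_codons_meanlog = log(292), cds_codons_sdlog = 0.36,
                       cds_codons_min = 50L, cds_codons_max = 3000L,
                       base_freq = c(A = 0.293, C = 0.186, G = 0.217, T = 0.304),
                       stop_freq = c(TGA = 0.406, TAA = 0.356, TAG = 0.238),
                       isoform_rates = c(retained_intron = 0.055,
                                         alt_donor = 0.016,
                                         alt_acceptor = 0.020,
                                         exon_skip = 0.005),
                       chimera_rate = 0.02, ncrna_rate = 0.01,
                       pathogen_rate = 0.01,
                       redundancy_mean = 2, trunc5_frac_range = c(0.03, 0.15),
                       polya_range = c(15L, 40L),
                       snp_rate = 0.00061,
                       vector_seq = .DEFAULT_VECTOR,
                       q_mean = 38, q_sd = 4, q_clip = c(2, 60),
                       q_decay_start = 500L, q_decay_slope = 0.04,
                       read_max_len = 800L,
                       genes_per_scaffold = 20L, spacer_len = 2000L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  .validate_config(cfg)
  cfg
}

.validate_config <- function(cfg) {
  rates <- c(cfg$isoform_rates, chimera = cfg$chimera_rate,
             ncrna = cfg$ncrna_rate, pathogen = cfg$pathogen_rate)
  if (any(rates < 0 | rates > 1))
    .stopf("configuration error: all rates must lie in [0, 1]")
  if (sum(cfg$isoform_rates) > 1)
    .stopf("configuration error: isoform rates sum to more than 1")
  if (cfg$n_genes < 0) .stopf("configuration error: n_genes must be >= 0")
  sds <- c(cfg$exon_len_sdlog, cfg$intron_sdlog, cfg$utr5_sdlog,
           cfg$utr3_sdlog, cfg$cds_codons_sdlog)
  if (any(!is.finite(sds)) || any(sds <= 0))
    .stopf("configuration error: length dispersions must be positive")
  if (any(cfg$base_freq < 0) || abs(sum(cfg$base_freq) - 1) > 1e-6)
    .stopf("configuration error: base_freq must be frequencies summing to 1")
  if (cfg$snp_rate < 0 || cfg$snp_rate >= 0.1)
    .stopf("configuration error: snp_rate must lie in [0, 0.1)")
  if (cfg$intron_min < 60L)
    .stopf("configuration error: intron_min below the intron-detection floor")
  invisible(TRUE)
}

# bounded log-normal draws (resample out-of-bounds values)
.rlnorm_b <- function(n, meanlog, sdlog, lo, hi) {
  x <- rlnorm(n, meanlog, sdlog)
  for (it in 1:100) {
    bad <- x < lo | x > hi
    if (!any(bad)) break
    x[bad] <- rlnorm(sum(bad), meanlog, sdlog)
  }
  pmin(pmax(x, lo), hi)
}

.codon_weights <- function(base_freq) {
  w <- vapply(.SENSE_CODONS, function(cod) {
    prod(base_freq[strsplit(cod, "")[[1]]])
  }, numeric(1))
  w / sum(w)
}

# maximal poly(A) suffix rule (>= 10 nt, >= 90% A, starting with an A); the
# generator uses it to reject 3'-UTRs whose tail boundary would be ambiguous
.polya_scan <- function(s) {
  n <- nchar(s)
  if (n == 0L) return(0L)
  ch <- rev(strsplit(s, "")[[1]]) == "A"
  frac <- cumsum(ch) / seq_len(n)
  ok <- which(frac >= 0.9 & seq_len(n) >= 10L & ch)
  if (!length(ok)) 0L else max(ok)
}

# no in-frame ATG upstream of the true start without an intervening in-frame
# stop (would create a nested ORF indistinguishable from the true CDS)
.utr5_ok <- function(u5) {
  n <- nchar(u5)
  starts <- seq(n %% 3 + 1L, n - 2L, by = 3L)
  if (n < 3L || length(starts) == 0L) return(TRUE)
  cods <- substring(u5, starts, starts + 2L)
  atg <- which(cods == "ATG")
  if (!length(atg)) return(TRUE)
  stops <- which(cods %in% .STOP_CODONS)
  all(vapply(atg, function(a) any(stops > a), logical(1)))
}

# TRUE when no slid canonical splice placement scores equal to the junction
# [a, b] (intron interval, 1-based on the transcription-sense gene sequence)
.junction_ok <- function(S, a, b, smax = 20L) {
  n <- nchar(S)
  sub <- function(i, j) substr(S, i, j)
  for (s in seq_len(smax)) {
    if (b + s <= n && a + s + 1L <= b &&
        sub(a, a + s - 1L) == sub(b + 1L, b + s) &&
        sub(a + s, a + s + 1L) == "GT" &&
        sub(b + s - 1L, b + s) == "AG") return(FALSE)
    if (a - s >= 1L && b - s - 1L >= a &&
        sub(a - s, a - 1L) == sub(b - s + 1L, b) &&
        sub(a - s, a - s + 1L) == "GT" &&
        sub(b - s - 1L, b - s) == "AG") return(FALSE)
  }
  TRUE
}

.translate_cds <- function(cds) {
  cods <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
  aa <- Biostrings::GENETIC_CODE[cods]
  paste(aa[aa != "*"], collapse = "")
}

# one gene: transcript pieces, exon cuts, introns with planted alternative
# splice sites, all on the transcription-sense strand
.sim_gene <- function(cfg, gene_id) {
  bf <- cfg$base_freq
  ncod <- as.integer(round(.rlnorm_b(1, cfg$cds_codons_meanlog,
                                     cfg$cds_codons_sdlog,
                                     cfg$cds_codons_min, cfg$cds_codons_max)))
  stopc <- sample(names(cfg$stop_freq), 1, prob = cfg$stop_freq)
  cds <- paste0("ATG",
                paste(sample(.SENSE_CODONS, ncod - 1L, replace = TRUE,
                             prob = .codon_weights(bf)), collapse = ""),
                stopc)
  u5len <- as.integer(round(.rlnorm_b(1, cfg$utr5_meanlog, cfg$utr5_sdlog,
                                      cfg$utr5_min, cfg$utr5_max)))
  repeat {
    u5 <- .rand_seq(u5len, bf)
    if (.utr5_ok(u5)) break
  }
  u3len <- as.integer(round(.rlnorm_b(1, cfg$utr3_meanlog, cfg$utr3_sdlog,
                                      cfg$utr3_min, cfg$utr3_max)))
  polya_len <- sample(seq(cfg$polya_range[1], cfg$polya_range[2]), 1)
  repeat {
    u3 <- .rand_seq(u3len, bf)
    if (.polya_scan(paste0(u3, strrep("A", polya_len))) == polya_len) break
  }
  tx <- paste0(u5, cds, u3)
  L <- nchar(tx)

  k <- 1L + rpois(1, max(0, cfg$exon_count_mean - 1))
  k <- max(1L, min(k, (L - 2L * cfg$min_terminal_exon) %/% cfg$min_exon + 2L,
                   L %/% cfg$min_exon))
  exlen <- .alloc_lengths(L, k, cfg$exon_len_meanlog, cfg$exon_len_sdlog,
                          cfg$min_exon, cfg$min_terminal_exon)
  ex_end <- cumsum(exlen)
  ex_start <- c(1L, head(ex_end, -1L) + 1L)

  ilen <- if (k > 1L)
    as.integer(round(.rlnorm_b(k - 1L, cfg$intron_meanlog, cfg$intron_sdlog,
                               cfg$intron_min, cfg$intron_max))) else integer(0)

  for (attempt in 1:60) {
    introns <- lapply(ilen, function(iL) {
      interior <- .rand_seq(iL - 4L, bf)
      I <- paste0("GT", interior, "AG")
      # alt-site shifts are capped at 35 nt: a longer shifted block plus a
      # chance GT in the flanking exon can be rewritten by the aligner as a
      # canonical intron plus a short gap at lower cost than the plain gap,
      # i.e. it becomes indistinguishable from a retained intron fragment
      dmax <- min(35L, iL - 60L)
      alt_d <- if (dmax >= 9L) sample(9:dmax, 1) else NA_integer_
      alt_a <- if (dmax >= 9L) sample(9:dmax, 1) else NA_integer_
      if (!is.na(alt_d))
        substr(I, alt_d + 1L, alt_d + 2L) <- "GT"
      if (!is.na(alt_a))
        substr(I, iL - alt_a - 1L, iL - alt_a) <- "AG"
      list(seq = I, alt_donor_delta = alt_d, alt_acceptor_delta = alt_a)
    })
    # assemble the sense gene sequence and sense intron coordinates
    parts <- character(0)
    ist <- integer(0); ien <- integer(0)
    pos <- 0L
    for (e in seq_len(k)) {
      parts <- c(parts, substr(tx, ex_start[e], ex_end[e]))
      pos <- pos + exlen[e]
      if (e < k) {
        ist <- c(ist, pos + 1L)
        ien <- c(ien, pos + ilen[e])
        parts <- c(parts, introns[[e]]$seq)
        pos <- pos + ilen[e]
      }
    }
    gene_seq <- paste(parts, collapse = "")
    ok <- TRUE
    for (e in seq_along(ist)) {
      a <- ist[e]; b <- ien[e]
      if (!.junction_ok(gene_seq, a, b)) { ok <- FALSE; break }
      ad <- introns[[e]]$alt_donor_delta
      if (!is.na(ad) && !.junction_ok(gene_seq, a + ad, b)) { ok <- FALSE; break }
      aa <- introns[[e]]$alt_acceptor_delta
      if (!is.na(aa) && !.junction_ok(gene_seq, a, b - aa)) { ok <- FALSE; break }
    }
    if (ok && k > 2L) {
      for (e in 2:(k - 1L)) {   # merged junction left by skipping exon e
        if (!.junction_ok(gene_seq, ist[e - 1L], ien[e])) { ok <- FALSE; break }
      }
    }
    if (ok) break
  }
  if (!ok) .stopf("could not build an unambiguous gene after 60 attempts (%s)", gene_id)

  list(gene_id = gene_id, gene_seq = gene_seq, tx_seq = tx,
       utr5_len = u5len, cds_len = nchar(cds), utr3_len = u3len,
       polya_len = polya_len, stop_codon = stopc,
       protein = .translate_cds(cds),
       exon_tx_start = ex_start, exon_tx_end = ex_end,
       intron_sense_start = ist, intron_sense_end = ien,
       intron_seq = vapply(introns, `[[`, character(1), "seq"),
       alt_donor_delta = vapply(introns, `[[`, integer(1), "alt_donor_delta"),
       alt_acceptor_delta = vapply(introns, `[[`, integer(1), "alt_acceptor_delta"))
}

.alloc_lengths <- function(L, k, meanlog, sdlog, minlen, min_terminal = minlen) {
  if (k == 1L) return(L)
  mins <- c(min_terminal, rep(minlen, k - 2L), min_terminal)
  w <- rlnorm(k, meanlog, sdlog)
  len <- pmax(mins, as.integer(round(w / sum(w) * L)))
  d <- L - sum(len)
  while (d != 0L) {
    for (j in order(len, decreasing = TRUE)) {
      if (d == 0L) break
      step <- if (d > 0L) 1L else -1L
      if (len[j] + step >= mins[j]) { len[j] <- len[j] + step; d <- d - step }
    }
  }
  len
}

#' Simulate a toy genome with known gene models
#'
#' Genes are placed on scaffolds (`genes_per_scaffold` per scaffold,
#' separated by random intergenic spacers), each on a random strand. Every
#' multi-exon gene's introns begin GT and end AG; every CDS begins ATG and
#' ends with a stop codon. Alternative donor/acceptor sites are planted
#' inside introns so that splice-variant truth is exact, and intron
#' junctions are rejection-sampled so that no slid splice placement scores
#' equal to the planted one.
#'
#' @param config a [sim_config()]
#' @return list with `genome` (named character vector of scaffolds) and
#'   `truth` (tables `genes`, `exons`, `introns`, plus per-gene sequences:
#'   `tx_seq`, `protein`, `intron_seq`)
#' @export
simulate_genome <- function(config) {
  .validate_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  empty <- list(
    genes = data.frame(gene_id = character(), scaffold_id = character(),
                       strand = character(), g_start = integer(),
                       g_end = integer(), n_exons = integer(),
                       utr5_len = integer(), cds_len = integer(),
                       utr3_len = integer(), polya_len = integer(),
                       tx_len = integer(), stop_codon = character(),
                       stringsAsFactors = FALSE),
    exons = data.frame(gene_id = character(), exon_index = integer(),
                       tx_start = integer(), tx_end = integer(),
                       g_start = integer(), g_end = integer(),
                       type = character(), stringsAsFactors = FALSE),
    introns = data.frame(gene_id = character(), intron_index = integer(),
                         g_start = integer(), g_end = integer(),
                         length = integer(), alt_donor_delta = integer(),
                         alt_acceptor_delta = integer(),
                         stringsAsFactors = FALSE),
    tx_seq = setNames(character(0), character(0)),
    protein = setNames(character(0), character(0)),
    intron_seq = list())
  if (n == 0L)
    return(list(genome = setNames(character(0), character(0)), truth = empty))

  genes <- lapply(seq_len(n), function(i) .sim_gene(config, sprintf("g%04d", i)))
  strands <- ifelse(runif(n) < 0.5, "+", "-")

  gsc <- config$genes_per_scaffold
  n_sc <- ceiling(n / gsc)
  genome <- character(n_sc)
  names(genome) <- sprintf("scaf%03d", seq_len(n_sc))
  grows <- list(); erows <- list(); irows <- list()
  gi <- 0L
  for (s in seq_len(n_sc)) {
    idx <- seq((s - 1L) * gsc + 1L, min(s * gsc, n))
    parts <- character(0)
    pos <- 0L
    for (i in idx) {
      gi <- gi + 1L
      g <- genes[[i]]
      spacer <- .rand_seq(config$spacer_len, config$base_freq)
      parts <- c(parts, spacer)
      pos <- pos + config$spacer_len
      glen <- nchar(g$gene_seq)
      o1 <- pos + 1L
      strand <- strands[i]
      placed <- if (strand == "+") g$gene_seq else revcomp(g$gene_seq)
      parts <- c(parts, placed)
      pos <- pos + glen
      # sense position p -> genomic coordinate
      g_of <- if (strand == "+") function(p) o1 + p - 1L else function(p) o1 + glen - p
      k <- length(g$exon_tx_start)
      ex_sense <- .exon_sense_intervals(g)
      ex_g1 <- vapply(seq_len(k), function(e) g_of(ex_sense$start[e]), integer(1))
      ex_g2 <- vapply(seq_len(k), function(e) g_of(ex_sense$end[e]), integer(1))
      types <- if (k == 1L) "single" else
        c("initial", rep("internal", max(0L, k - 2L)), "terminal")
      erows[[gi]] <- data.frame(
        gene_id = g$gene_id, exon_index = seq_len(k),
        tx_start = g$exon_tx_start, tx_end = g$exon_tx_end,
        g_start = pmin(ex_g1, ex_g2), g_end = pmax(ex_g1, ex_g2),
        type = types, stringsAsFactors = FALSE)
      if (k > 1L) {
        in_g1 <- vapply(g$intron_sense_start, g_of, integer(1))
        in_g2 <- vapply(g$intron_sense_end, g_of, integer(1))
        irows[[gi]] <- data.frame(
          gene_id = g$gene_id, intron_index = seq_len(k - 1L),
          g_start = pmin(in_g1, in_g2), g_end = pmax(in_g1, in_g2),
          length = g$intron_sense_end - g$intron_sense_start + 1L,
          alt_donor_delta = g$alt_donor_delta,
          alt_acceptor_delta = g$alt_acceptor_delta,
          stringsAsFactors = FALSE)
      }
      grows[[gi]] <- data.frame(
        gene_id = g$gene_id, scaffold_id = names(genome)[s], strand = strand,
        g_start = o1, g_end = o1 + glen - 1L, n_exons = k,
        utr5_len = g$utr5_len, cds_len = g$cds_len, utr3_len = g$utr3_len,
        polya_len = g$polya_len, tx_len = nchar(g$tx_seq),
        stop_codon = g$stop_codon, stringsAsFactors = FALSE)
    }
    parts <- c(parts, .rand_seq(config$spacer_len, config$base_freq))
    genome[s] <- paste(parts, collapse = "")
  }
  truth <- list(
    genes = do.call(rbind, grows),
    exons = do.call(rbind, erows),
    introns = if (length(irows)) do.call(rbind, Filter(Negate(is.null), irows))
              else empty$introns,
    tx_seq = setNames(vapply(genes, `[[`, character(1), "tx_seq"),
                      vapply(genes, `[[`, character(1), "gene_id")),
    protein = setNames(vapply(genes, `[[`, character(1), "protein"),
                       vapply(genes, `[[`, character(1), "gene_id")),
    intron_seq = setNames(lapply(genes, `[[`, "intron_seq"),
                          vapply(genes, `[[`, character(1), "gene_id")),
    polya_len = setNames(vapply(genes, `[[`, integer(1), "polya_len"),
                         vapply(genes, `[[`, character(1), "gene_id")))
  list(genome = genome, truth = truth)
}

# sense-strand exon intervals on the gene sequence (exon tx cuts + introns)
.exon_sense_intervals <- function(g) {
  k <- length(g$exon_tx_start)
  ilen <- if (k > 1L) g$intron_sense_end - g$intron_sense_start + 1L else integer(0)
  shift <- c(0L, cumsum(ilen))
  list(start = g$exon_tx_start + shift, end = g$exon_tx_end + shift)
}

#' Derive a variant ("second cultivar") genome by random substitutions
#'
#' Substitutions only, no indels; each base is substituted independently
#' with probability `snp_rate`, to a uniformly chosen different base.
#'
#' @param genome named character vector of scaffolds
#' @param snp_rate per-base substitution probability in `[0, 0.1)`
#' @param seed integer seed
#' @return list with `genome` (variant scaffolds) and `snp_positions`
#'   (data.frame scaffold/pos/ref/alt)
#' @export
simulate_variant_genome <- function(genome, snp_rate, seed = 1L) {
  if (snp_rate < 0 || snp_rate >= 0.1)
    .stopf("configuration error: snp_rate must lie in [0, 0.1)")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  rows <- list()
  out <- genome
  for (sc in names(genome)) {
    L <- nchar(genome[[sc]])
    nsub <- rbinom(1, L, snp_rate)
    if (nsub == 0L) next
    pos <- sort(sample.int(L, nsub))
    s <- strsplit(genome[[sc]], "")[[1]]
    ref <- s[pos]
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    s[pos] <- alt
    out[[sc]] <- paste(s, collapse = "")
    rows[[sc]] <- data.frame(scaffold_id = sc, pos = pos, ref = ref,
                             alt = alt, stringsAsFactors = FALSE)
  }
  snp <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scaffold_id = character(), pos = integer(),
               ref = character(), alt = character(), stringsAsFactors = FALSE)
  rownames(snp) <- NULL
  list(genome = out, snp_positions = snp)
}

#' Simulate transcript isoforms with planted splice events
#'
#' Every gene contributes its reference isoform (the exon concatenation);
#' genes drawn for an event additionally contribute one event isoform:
#' a retained intron, an alternative donor/acceptor using the planted
#' alternative GT/AG site, or a skipped internal exon. A poly(A) tail is
#' appended to every transcript. Events infeasible for a gene's structure
#' (any event on a single-exon gene, exon skip without an internal exon)
#' are skipped and logged.
#'
#' @param sim result of [simulate_genome()]
#' @param isoform_rates named per-gene event probabilities (see
#'   [sim_config()]); the remainder is the no-event probability
#' @param seed integer seed
#' @return list with `seqs` (named transcripts, tails appended), `isoforms`
#'   (truth table: transcript_id, gene_id, event, intron/exon index, delta)
#'   and `skipped` (log of infeasible events)
#' @export
simulate_transcripts <- function(sim, isoform_rates = NULL, seed = 1L) {
  truth <- sim$truth
  if (nrow(truth$genes) == 0L) .stopf("no genes to transcribe")
  rates <- isoform_rates %||% c(retained_intron = 0.055, alt_donor = 0.016,
                                alt_acceptor = 0.020, exon_skip = 0.005)
  if (any(rates < 0) || sum(rates) > 1)
    .stopf("configuration error: invalid isoform rates")
  set.seed(seed)
  events <- c(names(rates), "none")
  probs <- c(rates, none = 1 - sum(rates))
  seqs <- character(0); iso <- list(); skipped <- list()
  for (i in seq_len(nrow(truth$genes))) {
    gid <- truth$genes$gene_id[i]
    tx <- truth$tx_seq[[gid]]
    tail <- strrep("A", truth$polya_len[[gid]])
    ref_id <- paste0(gid, ".t1")
    seqs[ref_id] <- paste0(tx, tail)
    iso[[ref_id]] <- data.frame(transcript_id = ref_id, gene_id = gid,
                                event = "reference", intron_index = NA_integer_,
                                exon_index = NA_integer_, delta = NA_integer_,
                                stringsAsFactors = FALSE)
    ev <- sample(events, 1, prob = probs)
    if (ev == "none") next
    ex <- truth$exons[truth$exons$gene_id == gid, , drop = FALSE]
    k <- nrow(ex)
    if (k < 2L || (ev == "exon_skip" && k < 3L)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(gene_id = gid, event = ev, reason = "structure infeasible",
                   stringsAsFactors = FALSE)
      next
    }
    itr <- truth$introns[truth$introns$gene_id == gid, , drop = FALSE]
    iseqs <- truth$intron_seq[[gid]]
    piece <- function(e) substr(tx, ex$tx_start[e], ex$tx_end[e])
    iso_id <- paste0(gid, ".t2")
    intron_index <- NA_integer_; exon_index <- NA_integer_; delta <- NA_integer_
    if (ev == "retained_intron") {
      # only introns far enough from both transcript ends are retained:
      # a near-end retained intron lets the redundancy rule link the
      # isoform pair by clipping one end (no intron-scale gap involved),
      # which would contradict the planted classes
      L <- nchar(tx); tail_len <- truth$polya_len[[gid]]
      lim <- 0.78 * (L + tail_len) - 30
      pre <- ex$tx_end[seq_len(k - 1L)]
      elig <- which(pre < lim & (L - pre + tail_len) < lim)
      if (!length(elig)) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(gene_id = gid, event = ev, reason = "no central intron",
                     stringsAsFactors = FALSE)
        next
      }
      intron_index <- if (length(elig) == 1L) elig else sample(elig, 1)
      body <- paste0(paste(vapply(seq_len(intron_index), piece, character(1)),
                           collapse = ""),
                     iseqs[[intron_index]],
                     paste(vapply(seq(intron_index + 1L, k), piece, character(1)),
                           collapse = ""))
    } else if (ev %in% c("alt_donor", "alt_acceptor")) {
      col <- if (ev == "alt_donor") "alt_donor_delta" else "alt_acceptor_delta"
      elig <- which(!is.na(itr[[col]]))
      if (!length(elig)) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(gene_id = gid, event = ev, reason = "no planted site",
                     stringsAsFactors = FALSE)
        next
      }
      intron_index <- sample(elig, 1)
      delta <- itr[[col]][intron_index]
      I <- iseqs[[intron_index]]
      iL <- nchar(I)
      chunks <- vapply(seq_len(k), piece, character(1))
      if (ev == "alt_donor") {
        chunks[intron_index] <- paste0(chunks[intron_index], substr(I, 1L, delta))
      } else {
        chunks[intron_index + 1L] <- paste0(substr(I, iL - delta + 1L, iL),
                                            chunks[intron_index + 1L])
      }
      body <- paste(chunks, collapse = "")
    } else { # exon_skip
      exon_index <- sample(2:(k - 1L), 1)
      body <- paste(vapply(setdiff(seq_len(k), exon_index), piece, character(1)),
                    collapse = "")
    }
    seqs[iso_id] <- paste0(body, tail)
    iso[[iso_id]] <- data.frame(transcript_id = iso_id, gene_id = gid,
                                event = ev, intron_index = intron_index,
                                exon_index = exon_index, delta = delta,
                                stringsAsFactors = FALSE)
  }
  list(seqs = seqs,
       isoforms = do.call(rbind, iso),
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(gene_id = character(), event = character(),
                    reason = character(), stringsAsFactors = FALSE))
}

#' Simulate a clone library with cloning artifacts
#'
#' Produces two synchronized views of the same library: full clone inserts
#' (finished, error-free sequences, as after full-length sequencing) and
#' single-pass 5'-end reads (vector flank prepended, per-position Phred
#' qualities with a degraded 3' tail). Artifact classes: redundant
#' 5'-truncated copies, chimeras joining two transcripts from different
#' scaffolds at a BamHI/XhoI site, and contaminant inserts drawn from
#' separate ncRNA and pathogen pools. Genes carrying an alternative
#' donor/acceptor or exon-skip event are represented by the event isoform
#' only; retained-intron genes contribute both isoforms (so the spliced
#' sibling needed for detection is present).
#'
#' @param tx result of [simulate_transcripts()]
#' @param config the [sim_config()]
#' @param sim result of [simulate_genome()] (for scaffold assignments)
#' @param seed integer seed
#' @return list with `inserts` (named character vector), `reads`
#'   (list `seq`, `qual`, `library`), `classes` (truth table per clone),
#'   `ncrna_db`, `pathogen_db`, `vector_db`
#' @export
simulate_clone_library <- function(tx, config, sim, seed = 1L) {
  if (!length(tx$seqs)) .stopf("no transcripts to clone")
  set.seed(seed)
  iso <- tx$isoforms
  keep <- logical(nrow(iso))
  for (i in seq_len(nrow(iso))) {
    ev_gene <- iso$event[iso$gene_id == iso$gene_id[i] & iso$event != "reference"]
    keep[i] <- if (iso$event[i] == "reference")
      !length(ev_gene) || ev_gene[1] %in% c("retained_intron") else TRUE
  }
  base <- iso[keep, , drop = FALSE]

  clone_rows <- list(); inserts <- character(0)
  cid <- 0L
  next_id <- function() { cid <<- cid + 1L; sprintf("cl%05d", cid) }
  libs <- c("LEFL1", "FC", "LEFL2", "LEFL3")

  for (i in seq_len(nrow(base))) {
    tid <- base$transcript_id[i]
    s <- tx$seqs[[tid]]
    ncl <- 1L + rpois(1, max(0, config$redundancy_mean - 1))
    # a truncated copy of a retained-intron isoform must keep the retained
    # intron: truncated past it, the copy is a pure suffix of the spliced
    # reference and would (correctly, but against the planted classes)
    # collapse the reference as redundant
    trunc_cap <- nchar(s)
    if (base$event[i] == "retained_intron") {
      gid <- base$gene_id[i]
      ex <- sim$truth$exons[sim$truth$exons$gene_id == gid, , drop = FALSE]
      intron_at <- ex$tx_end[ex$exon_index == base$intron_index[i]] + 1L
      trunc_cap <- intron_at - 10L
    }
    for (j in seq_len(ncl)) {
      id <- next_id()
      trunc <- 0L
      if (j > 1L) {
        fr <- runif(1, config$trunc5_frac_range[1], config$trunc5_frac_range[2])
        trunc <- max(10L, as.integer(round(fr * nchar(s))))
        if (trunc >= trunc_cap) trunc <- 0L   # emit untruncated instead
      }
      inserts[id] <- substr(s, trunc + 1L, nchar(s))
      clone_rows[[id]] <- data.frame(
        clone_id = id, class = if (j == 1L) "normal" else "redundant",
        transcript_id = tid, gene_id = base$gene_id[i],
        event = base$event[i], trunc5 = trunc,
        junction_start = NA_integer_, junction_site = NA_character_,
        source_a = NA_character_, source_b = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  n_base <- nrow(base)

  # chimeras: 5' part of one reference transcript + enzyme site + 3' part of
  # another, sources preferentially on different scaffolds
  refs <- iso$transcript_id[iso$event == "reference"]
  gmap <- setNames(sim$truth$genes$scaffold_id, sim$truth$genes$gene_id)
  long_enough <- refs[nchar(tx$seqs[refs]) >= 700]
  n_chim <- rbinom(1, n_base, config$chimera_rate)
  for (z in seq_len(min(n_chim, length(long_enough) %/% 2))) {
    a <- sample(long_enough, 1)
    ga <- iso$gene_id[iso$transcript_id == a]
    other <- long_enough[long_enough != a &
                         gmap[iso$gene_id[match(long_enough, iso$transcript_id)]] != gmap[[ga]]]
    if (!length(other)) other <- long_enough[long_enough != a]
    b <- sample(other, 1)
    gb <- iso$gene_id[iso$transcript_id == b]
    sa <- tx$seqs[[a]]; sb <- tx$seqs[[b]]
    frag_a <- substr(sa, 1L, max(300L, as.integer(nchar(sa) * 0.55)))
    frag_b <- substr(sb, max(1L, nchar(sb) - max(300L, as.integer(nchar(sb) * 0.55)) + 1L),
                     nchar(sb))
    site <- sample(c("GGATCC", "CTCGAG"), 1)
    id <- next_id()
    inserts[id] <- paste0(frag_a, site, frag_b)
    clone_rows[[id]] <- data.frame(
      clone_id = id, class = "chimera", transcript_id = NA_character_,
      gene_id = NA_character_, event = NA_character_, trunc5 = 0L,
      junction_start = nchar(frag_a) + 1L, junction_site = site,
      source_a = a, source_b = b, stringsAsFactors = FALSE)
  }

  # contaminant pools (one clone per pool record at most)
  ncr_pool <- setNames(.rand_seq(round(runif(12, 400, 800))),
                       sprintf("ncRNA%02d", 1:12))
  pat_pool <- setNames(.rand_seq(round(runif(10, 500, 1500))),
                       sprintf("path%02d", 1:10))
  n_ncr <- min(rbinom(1, n_base, config$ncrna_rate), length(ncr_pool))
  if (n_ncr > 0) for (nm in sample(names(ncr_pool), n_ncr)) {
    id <- next_id()
    inserts[id] <- ncr_pool[[nm]]
    clone_rows[[id]] <- data.frame(
      clone_id = id, class = "ncRNA", transcript_id = NA_character_,
      gene_id = NA_character_, event = NA_character_, trunc5 = 0L,
      junction_start = NA_integer_, junction_site = NA_character_,
      source_a = nm, source_b = NA_character_, stringsAsFactors = FALSE)
  }
  n_pat <- min(rbinom(1, n_base, config$pathogen_rate), length(pat_pool))
  if (n_pat > 0) for (nm in sample(names(pat_pool), n_pat)) {
    id <- next_id()
    inserts[id] <- paste0(pat_pool[[nm]], strrep("A", 20L))
    clone_rows[[id]] <- data.frame(
      clone_id = id, class = "pathogen", transcript_id = NA_character_,
      gene_id = NA_character_, event = NA_character_, trunc5 = 0L,
      junction_start = NA_integer_, junction_site = NA_character_,
      source_a = nm, source_b = NA_character_, stringsAsFactors = FALSE)
  }

  classes <- do.call(rbind, clone_rows)
  rownames(classes) <- NULL
  classes$library <- sample(libs, nrow(classes), replace = TRUE)

  # 5'-end read view
  flank <- substr(config$vector_seq, nchar(config$vector_seq) - 29L,
                  nchar(config$vector_seq))
  rseq <- character(0); rqual <- list()
  for (i in seq_len(nrow(classes))) {
    id <- classes$clone_id[i]
    full <- paste0(flank, inserts[[id]])
    rl <- min(nchar(full), config$read_max_len)
    rd <- substr(full, 1L, rl)
    q <- rnorm(rl, config$q_mean, config$q_sd) -
      config$q_decay_slope * pmax(0, seq_len(rl) - config$q_decay_start)
    q <- as.integer(round(pmin(pmax(q, config$q_clip[1]), config$q_clip[2])))
    rseq[id] <- rd
    rqual[[id]] <- q
  }

  list(inserts = inserts,
       reads = list(seq = rseq, qual = rqual,
                    library = setNames(classes$library, classes$clone_id)),
       classes = classes,
       ncrna_db = reference_db(ncr_pool, "ncrna", name = "sim_ncrna"),
       pathogen_db = reference_db(pat_pool, "pathogen", name = "sim_pathogen"),
       vector_db = reference_db(setNames(config$vector_seq, "vector1"),
                                "vector", name = "sim_vector"))
}

#' Reference databases derived from simulation truth
#'
#' Builds the host-side databases the curation cascade needs: a unigene-like
#' transcript database (one reference transcript per gene, with distinct
#' functional descriptions), the scaffold genome database and the truth
#' protein database.
#'
#' @param sim result of [simulate_genome()]
#' @return list with `unigene_db`, `genome_db`, `protein_db`
#' @export
sim_reference_dbs <- function(sim) {
  truth <- sim$truth
  ids <- truth$genes$gene_id
  unigene <- setNames(truth$tx_seq[ids], paste0("UG_", ids))
  desc <- setNames(sprintf("hypothetical protein gene %s", ids),
                   paste0("UG_", ids))
  list(
    unigene_db = reference_db(unigene, "transcript", name = "sim_unigene",
                              desc = desc),
    genome_db = reference_db(sim$genome, "genome", name = "sim_genome"),
    protein_db = reference_db(setNames(truth$protein[ids], paste0("P_", ids)),
                              "protein", name = "sim_protein"))
}

#' Expected terminal disposition of each simulated clone
#'
#' Joins the clone truth classes with the isoform truth to give, per clone,
#' the stage of the curation cascade expected to remove it (or
#' `nrFLcDNA_candidate` if it should survive).
#'
#' @param lib result of [simulate_clone_library()]
#' @return data.frame clone_id / expected disposition
#' @export
truth_disposition <- function(lib) {
  cl <- lib$classes
  disp <- ifelse(cl$class == "redundant", "redundant",
          ifelse(cl$class == "ncRNA", "ncRNA",
          ifelse(cl$class == "pathogen", "pathogen",
          ifelse(cl$class == "chimera", "chimera",
          ifelse(!is.na(cl$event) & cl$event == "retained_intron",
                 "retained_intron", "nrFLcDNA_candidate")))))
  data.frame(clone_id = cl$clone_id, expected = disp, stringsAsFactors = FALSE)
}

#' Truth gene models as `gene_model` objects
#'
#' @param sim result of [simulate_genome()]
#' @return named list of [gene_model()] objects (one per gene)
#' @export
truth_gene_models <- function(sim) {
  truth <- sim$truth
  out <- list()
  for (i in seq_len(nrow(truth$genes))) {
    gid <- truth$genes$gene_id[i]
    ex <- truth$exons[truth$exons$gene_id == gid, , drop = FALSE]
    itr <- truth$introns[truth$introns$gene_id == gid, , drop = FALSE]
    strand <- truth$genes$strand[i]
    if (strand == "-") ex <- ex[order(-ex$g_start), , drop = FALSE]
    out[[gid]] <- gene_model(
      cdna_id = gid, scaffold_id = truth$genes$scaffold_id[i],
      strand = strand,
      exons = data.frame(est_start = ex$tx_start, est_end = ex$tx_end,
                         g_start = ex$g_start, g_end = ex$g_end,
                         type = ex$type, stringsAsFactors = FALSE),
      introns = if (nrow(itr))
        data.frame(g_start = itr$g_start, g_end = itr$g_end,
                   donor = "GT", acceptor = "AG", canonical = TRUE,
                   stringsAsFactors = FALSE) else NULL)
  }
  out
}
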