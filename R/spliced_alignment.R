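# est2genome-style spliced alignment: a transcript ("est") aligned to a
# genomic sequence with an intron state, producing exon/intron block
# structure. The dynamic program lives in src/spliced_align.cpp; this file
# handles strand, parameter defaults and the bidirectional intron scan used
# for retained-intron screening.

#' Parameters for spliced alignment
#'
#' @param min_intron minimum genomic jump treated as an intron (nt, >= 20)
#' @param intron_penalty flat score penalty per intron with GT..AG termini
#' @param noncanon_extra additional penalty for non-GT..AG introns
#' @param scheme nucleotide [scoring_scheme()] for exon columns
#' @return list of class `spliced_params`
#' @export
spliced_params <- function(min_intron = 60L, intron_penalty = 40,
                           noncanon_extra = 20, scheme = scoring_scheme()) {
  if (min_intron < 20L) .stopf("min_intron must be >= 20")
  structure(list(min_intron = as.integer(min_intron),
                 intron_penalty = intron_penalty,
                 noncanon_extra = noncanon_extra, scheme = scheme),
            class = "spliced_params")
}

.spliced_one <- function(est, genome, p) {
  spliced_align_dp(est, genome, p$scheme$matrix, p$scheme$gap_open,
                   p$scheme$gap_ext, p$intron_penalty, p$noncanon_extra,
                   p$min_intron)
}

#' Spliced alignment of a transcript against a genomic region
#'
#' Both orientations of the genomic sequence are tried and the better
#' scoring one kept; coordinates are reported on the forward strand of the
#' genomic input, exons in transcript order, and splice dinucleotides in
#' transcription sense. Identity is computed over aligned exon columns
#' (gap columns excluded); est coverage is the fraction of the transcript
#' covered by exon blocks.
#'
#' @param est transcript sequence (character string, poly(A) stripped for
#'   genome mapping)
#' @param genome genomic sequence (character string)
#' @param params a [spliced_params()]
#' @param est_id,genome_id ids carried into the result
#' @param strands `"both"` (default) or a single orientation (`"+"`/`"-"`)
#'   when the strand is already known, e.g. from a seed scan
#' @return object of class `spliced_alignment`: fields `est_id`,
#'   `genome_id`, `strand`, `score`, `exons` (est/genome intervals),
#'   `introns` (genome intervals, donor/acceptor, canonical flag),
#'   `identity`, `est_coverage`, `n_match`, `n_mismatch`,
#'   `mismatch_gpos` (genomic positions of mismatching exon columns)
#' @export
spliced_align <- function(est, genome, params = spliced_params(),
                          est_id = "est", genome_id = "genome",
                          strands = c("both", "+", "-")) {
  strands <- match.arg(strands)
  if (!nzchar(est) || !nzchar(genome)) .stopf("empty sequence")
  fw <- if (strands != "-") .spliced_one(est, genome, params) else NULL
  rv <- if (strands != "+") .spliced_one(est, revcomp(genome), params) else NULL
  strand <- if (is.null(fw) || (!is.null(rv) && rv$score > fw$score)) "-" else "+"
  r <- if (strand == "-") rv else fw
  n <- nchar(genome)

  exons <- as.data.frame(r$exons)
  introns <- data.frame(g_start = r$intron_start, g_end = r$intron_end,
                        donor = as.character(r$donor),
                        acceptor = as.character(r$acceptor),
                        canonical = r$canonical, stringsAsFactors = FALSE)
  mismatch_gpos <- r$mismatch_gpos
  if (strand == "-" && nrow(exons)) {
    gs <- n - exons$g_end + 1L; ge <- n - exons$g_start + 1L
    exons$g_start <- gs; exons$g_end <- ge
    if (nrow(introns)) {
      is <- n - introns$g_end + 1L; ie <- n - introns$g_start + 1L
      introns$g_start <- is; introns$g_end <- ie
      introns <- introns[order(introns$g_start), , drop = FALSE]
    }
    mismatch_gpos <- sort(n - mismatch_gpos + 1L)
  }
  aligned_cols <- r$nmatch + r$nmismatch
  structure(list(
    est_id = est_id, genome_id = genome_id, strand = strand,
    score = r$score, exons = exons, introns = introns,
    n_match = r$nmatch, n_mismatch = r$nmismatch,
    identity = if (aligned_cols > 0) r$nmatch / aligned_cols else 0,
    est_coverage = if (nrow(exons))
      sum(exons$est_end - exons$est_start + 1L) / nchar(est) else 0,
    est_len = nchar(est), genome_len = n,
    mismatch_gpos = mismatch_gpos),
    class = "spliced_alignment")
}

#' @export
print.spliced_alignment <- function(x, ...) {
  cat(sprintf(
    "<spliced_alignment> %s vs %s (%s): score %.0f, %d exon(s), %d intron(s), identity %.3f, coverage %.3f\n",
    x$est_id, x$genome_id, x$strand, x$score, nrow(x$exons),
    nrow(x$introns), x$identity, x$est_coverage))
  invisible(x)
}

#' Bidirectional intron detection between two transcripts
#'
#' Runs [spliced_align()] both ways: a retained intron in sequence X shows
#' up as a genomic jump of at least `min_intron` when X plays the "genome"
#' role and the other sequence the "est" role.
#'
#' @param seq_a,seq_b sequences (character strings)
#' @param params a [spliced_params()]
#' @return list with data.frames `introns_in_a` and `introns_in_b`
#'   (genome-role coordinates within the respective sequence)
#' @export
detect_intron_pairwise <- function(seq_a, seq_b, params = spliced_params()) {
  in_a <- spliced_align(seq_b, seq_a, params)$introns
  in_b <- spliced_align(seq_a, seq_b, params)$introns
  list(introns_in_a = in_a, introns_in_b = in_b)
}

#' Emit the exon structure of spliced alignments as GFF3 plus intron table
#'
#' @param alignments list of `spliced_alignment` objects
#' @param gff3_path,intron_path output paths
#' @return invisibly, the intron table
#' @export
write_spliced_gff3 <- function(alignments, gff3_path, intron_path) {
  models <- lapply(alignments, function(a) {
    gene_model(cdna_id = a$est_id, scaffold_id = a$genome_id,
               strand = a$strand, exons = a$exons, introns = a$introns,
               identity = a$identity, est_coverage = a$est_coverage)
  })
  write_gff3(models, gff3_path)
  itab <- do.call(rbind, lapply(alignments, function(a) {
    if (!nrow(a$introns)) return(NULL)
    cbind(est_id = a$est_id, genome_id = a$genome_id, a$introns)
  }))
  if (is.null(itab))
    itab <- data.frame(est_id = character(), genome_id = character(),
                       g_start = integer(), g_end = integer(),
                       donor = character(), acceptor = character(),
                       canonical = logical())
  write_table(itab, intron_path)
  invisible(itab)
}
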