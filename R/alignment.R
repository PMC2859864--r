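# Local alignment with Karlin-Altschul E-value calibration: the pipeline's
# BLASTN/BLASTP stand-in. Smith-Waterman with affine gaps is executed by
# Biostrings::pairwiseAlignment; calibration, strand handling, E-values and
# ranked database search are implemented here. E-values are internally
# consistent but are not expected to bit-match NCBI BLAST; every threshold
# taken from them is a configuration knob.

#' Scoring scheme for local alignment
#'
#' Defaults follow classic BLASTN-like nucleotide scoring (+1/-3, gap open
#' 5, gap extend 2); protein schemes use BLOSUM62 with gap open 11 /
#' extend 1. A gap of length k costs `gap_open + k * gap_ext`.
#'
#' @param match match reward (nucleotide only)
#' @param mismatch mismatch penalty, negative (nucleotide only)
#' @param gap_open,gap_ext non-negative gap costs
#' @param alphabet `"dna"` or `"protein"`
#' @param submat substitution matrix for protein schemes (default BLOSUM62)
#' @return object of class `scoring_scheme`
#' @export
scoring_scheme <- function(match = 1, mismatch = -3, gap_open = 5,
                           gap_ext = 2, alphabet = c("dna", "protein"),
                           submat = NULL) {
  alphabet <- match.arg(alphabet)
  if (gap_open < 0 || gap_ext < 0) .stopf("gap costs must be non-negative")
  if (alphabet == "dna") {
    if (match <= 0) .stopf("match reward must be positive")
    letters <- .ALPHABETS$dna
    mat <- matrix(mismatch, length(letters), length(letters),
                  dimnames = list(letters, letters))
    diag(mat) <- match
    # ambiguity characters never reward a 'match'
    mat[c("N", "X"), ] <- mismatch
    mat[, c("N", "X")] <- mismatch
    core <- c("A", "C", "G", "T")
  } else {
    if (is.null(submat)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      submat <- e$BLOSUM62
    }
    core <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    mat <- submat
    storage.mode(mat) <- "double"
  }
  structure(list(alphabet = alphabet, matrix = mat, core = core,
                 gap_open = gap_open, gap_ext = gap_ext),
            class = "scoring_scheme")
}

#' Karlin-Altschul calibration of a scoring scheme
#'
#' Solves sum(p_i p_j exp(lambda s_ij)) = 1 for lambda, and approximates K
#' by the classical ungapped series over partial-sum distributions,
#' truncated at `kmax` terms (the truncated terms decay geometrically; the
#' default leaves a relative error well below 1e-6 for the schemes used
#' here).
#'
#' @param scheme a [scoring_scheme()]
#' @param background named vector of background letter frequencies over the
#'   scheme's core alphabet (default uniform)
#' @param kmax series truncation
#' @return list with elements `lambda`, `K`, `H` (relative entropy)
#' @export
ka_calibrate <- function(scheme, background = NULL, kmax = 60L) {
  core <- scheme$core
  if (is.null(background))
    background <- setNames(rep(1 / length(core), length(core)), core)
  background <- background[core] / sum(background[core])
  S <- scheme$matrix[core, core]
  P <- outer(background, background)
  es <- sum(P * S)
  if (es >= 0)
    .stopf("expected score per aligned pair is non-negative (%.4f); E-value theory requires a negative drift", es)
  if (max(S) <= 0) .stopf("scheme admits no positive score")

  f <- function(l) sum(P * exp(l * S)) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  lambda <- uniroot(f, c(1e-8, hi), tol = 1e-12)$root

  # collapse to the per-pair score distribution on its integer lattice
  vals <- sort(unique(as.vector(S)))
  prob <- vapply(vals, function(v) sum(P[S == v]), numeric(1))
  d <- Reduce(.gcd, abs(c(diff(vals), vals[vals != 0])))
  lat <- as.integer(round(vals / d))

  # distributions of partial sums S_k on the lattice, by convolution
  sum_term <- 0
  cur <- setNames(prob, lat)
  step <- setNames(prob, lat)
  for (k in seq_len(kmax)) {
    sup <- as.integer(names(cur))
    pos <- sum(cur[sup >= 0])
    negE <- sum(cur[sup < 0] * exp(lambda * d * sup[sup < 0]))
    sum_term <- sum_term + (pos + negE) / k
    if (k < kmax) cur <- .convolve_lattice(cur, step)
  }
  Cstar <- exp(-2 * sum_term)
  mu_tilt <- sum(prob * (lat * d) * exp(lambda * (lat * d)))
  # lattice correction for integer-valued scores with span d
  K <- Cstar * (lambda * d) / ((1 - exp(-lambda * d)) * lambda * mu_tilt)
  H <- lambda * mu_tilt  # relative entropy per aligned pair
  list(lambda = lambda, K = K, H = H)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

.convolve_lattice <- function(p, q) {
  sp <- as.integer(names(p)); sq <- as.integer(names(q))
  out <- new.env(hash = TRUE)
  res <- tapply(as.vector(outer(p, q)),
                as.vector(outer(sp, sq, "+")), sum)
  setNames(as.numeric(res), names(res))
}

.ka_cache <- new.env(parent = emptyenv())

.ka_for <- function(scheme) {
  key <- paste(scheme$alphabet, paste(range(scheme$matrix), collapse = ","),
               scheme$gap_open, scheme$gap_ext, sep = "|")
  if (is.null(.ka_cache[[key]])) .ka_cache[[key]] <- ka_calibrate(scheme)
  .ka_cache[[key]]
}

.hit_row <- function(query_id = NA_character_, subject_id = NA_character_,
                     strand = "+", q_start = NA_integer_, q_end = NA_integer_,
                     s_start = NA_integer_, s_end = NA_integer_, score = NA_real_,
                     bit_score = NA_real_, evalue = NA_real_, identity = NA_real_,
                     align_len = NA_integer_, n_match = NA_integer_,
                     n_mismatch = NA_integer_, gaps = NA_integer_,
                     max_gap = NA_integer_, subject_description = "") {
  data.frame(query_id = query_id, subject_id = subject_id, strand = strand,
             q_start = q_start, q_end = q_end, s_start = s_start,
             s_end = s_end, score = score, bit_score = bit_score,
             evalue = evalue, identity = identity, align_len = align_len,
             n_match = n_match, n_mismatch = n_mismatch, gaps = gaps,
             max_gap = max_gap, subject_description = subject_description,
             stringsAsFactors = FALSE)
}

# Smith-Waterman details via the compiled aligner (the spliced DP with the
# intron transition disabled reduces exactly to affine-gap local alignment)
.sw_details <- function(query, subject, scheme) {
  r <- spliced_align_dp(query, subject, scheme$matrix, scheme$gap_open,
                        scheme$gap_ext, 0, 0, nchar(subject) + 1L)
  ex <- r$exons
  if (nrow(ex) == 0L)
    return(list(score = 0, q_start = NA_integer_, q_end = NA_integer_,
                s_start = NA_integer_, s_end = NA_integer_, n_match = 0L,
                n_mismatch = 0L, gaps = 0L, max_gap = 0L, align_len = 0L))
  gaps <- r$est_gap_cols + r$genome_gap_cols
  list(score = r$score, q_start = ex[1, 1], q_end = ex[nrow(ex), 2],
       s_start = ex[1, 3], s_end = ex[nrow(ex), 4],
       n_match = r$nmatch, n_mismatch = r$nmismatch,
       gaps = gaps, max_gap = r$max_gap,
       align_len = r$nmatch + r$nmismatch + gaps)
}

#' Best local alignment between two sequences
#'
#' Smith-Waterman with affine gaps. For nucleotide schemes both strands of
#' the subject are tried and the better one kept; subject coordinates are
#' always reported on the forward strand. Identity is the fraction of
#' aligned non-gap columns that match; `evalue = K m n exp(-lambda score)`
#' with raw sequence lengths m, n.
#'
#' @param query,subject sequences (plain character strings)
#' @param scheme a [scoring_scheme()]
#' @param query_id,subject_id ids used in the returned hit row
#' @param both_strands try the reverse complement of the subject as well
#' @return one-row data.frame (an alignment hit)
#' @export
local_align <- function(query, subject, scheme = scoring_scheme(),
                        query_id = "query", subject_id = "subject",
                        both_strands = (scheme$alphabet == "dna")) {
  if (!nzchar(query) || !nzchar(subject)) .stopf("empty sequence")
  fw <- .sw_details(query, subject, scheme)
  res <- fw; strand <- "+"
  if (both_strands) {
    rv <- .sw_details(query, revcomp(subject), scheme)
    if (rv$score > fw$score) {
      res <- rv; strand <- "-"
      L <- nchar(subject)
      s2 <- L - res$s_start + 1L
      res$s_start <- L - res$s_end + 1L
      res$s_end <- s2
    }
  }
  ka <- .ka_for(scheme)
  mn <- as.numeric(nchar(query)) * as.numeric(nchar(subject))
  evalue <- ka$K * mn * exp(-ka$lambda * res$score)
  bit <- (ka$lambda * res$score - log(ka$K)) / log(2)
  ident <- if (res$n_match + res$n_mismatch > 0)
    res$n_match / (res$n_match + res$n_mismatch) else 0
  .hit_row(query_id, subject_id, strand, res$q_start, res$q_end, res$s_start,
           res$s_end, res$score, bit, evalue, ident, res$align_len,
           res$n_match, res$n_mismatch, res$gaps, res$max_gap)
}

#' Search a query against a reference database
#'
#' Aligns the query against each database record (optionally restricted to
#' records passing a shared-word prescreen) and returns hits with
#' `evalue <= max_evalue`, ordered by (evalue, subject id).
#'
#' @param query sequence (character string)
#' @param db a [reference_db()]
#' @param scheme a [scoring_scheme()]
#' @param max_evalue E-value threshold
#' @param query_id id for the hit rows
#' @param prescreen if `TRUE`, only align records sharing at least
#'   `min_shared` informative k-words with the query
#' @param k,min_shared,max_occ prescreen word length, minimum shared words
#'   and word occupancy cap
#' @return data.frame of hits (possibly empty)
#' @export
search_db <- function(query, db, scheme = scoring_scheme(),
                      max_evalue = 1e-10, query_id = "query",
                      prescreen = TRUE,
                      k = if (scheme$alphabet == "dna") 12L else 5L,
                      min_shared = 3L, max_occ = 200L) {
  stopifnot(inherits(db, "reference_db"))
  if (length(db$seqs) == 0L) .stopf("empty reference database '%s'", db$name)
  subjects <- names(db$seqs)
  if (prescreen) {
    alpha <- paste(scheme$core, collapse = "")
    qs <- if (scheme$alphabet == "dna") c(query, revcomp(query)) else query
    cand <- kmer_shared_pairs(qs, unname(db$seqs), k, alpha, max_occ, FALSE)
    keep <- unique(cand$subject[cand$shared >= min_shared])
    subjects <- subjects[sort(keep)]
  }
  hits <- lapply(subjects, function(sid) {
    h <- local_align(query, db$seqs[[sid]], scheme, query_id, sid)
    h$subject_description <- unname(db$desc[[sid]] %||% "")
    h
  })
  hits <- if (length(hits)) do.call(rbind, hits) else .hit_row()[0, ]
  hits <- hits[!is.na(hits$evalue) & hits$evalue <= max_evalue, , drop = FALSE]
  hits[order(hits$evalue, hits$subject_id), , drop = FALSE]
}

#' Write alignment hits as BLAST outfmt-6 style TSV
#'
#' Columns: query, subject, %identity, alignment length, mismatches, gaps,
#' query start/end, subject start/end, evalue, bitscore (1-based inclusive).
#'
#' @param hits a data.frame of alignment hits
#' @param path output path
#' @return `path`, invisibly
#' @export
write_hits <- function(hits, path) {
  out <- data.frame(query = hits$query_id, subject = hits$subject_id,
                    pident = round(100 * hits$identity, 2),
                    length = hits$align_len, mismatch = hits$n_mismatch,
                    gaps = hits$gaps, qstart = hits$q_start,
                    qend = hits$q_end, sstart = hits$s_start,
                    send = hits$s_end, evalue = hits$evalue,
                    bitscore = round(hits$bit_score, 1))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
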