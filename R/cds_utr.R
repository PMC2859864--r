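# ORF enumeration, homology-guided CDS selection, completeness
# classification, UTR extraction, poly(A) stripping, and composition /
# stop-codon statistics. External gene-finders are deliberately not used:
# the cascade enumerates ORFs exhaustively and applies homology-ranked
# selection, which subsumes the longest-amino-acid-sequence rule.
# Conventions: the stop codon is included inside the CDS interval; the
# protein excludes it (so a 938 bp mean CDS corresponds to 313 aa).

#' Strip a poly(A) tail
#'
#' The tail is the maximal suffix of length >= `min_len` that begins with
#' an A and contains at least `min_frac_a` adenines; empty when no suffix
#' qualifies. (Requiring the suffix to begin with an A pins the tail
#' boundary: without it the 90% rule always absorbs the last non-A of the
#' 3'-UTR.)
#'
#' @param seq cDNA sequence (character string)
#' @param min_len minimum tail length
#' @param min_frac_a minimum fraction of A in the tail
#' @return list with `body`, `polya_start`, `polya_len`
#' @export
strip_polya <- function(seq, min_len = 10L, min_frac_a = 0.9) {
  n <- nchar(seq)
  if (n == 0L) return(list(body = "", polya_start = 0L, polya_len = 0L))
  ch <- rev(strsplit(seq, "")[[1]]) == "A"
  frac <- cumsum(ch) / seq_len(n)
  ok <- which(frac >= min_frac_a & seq_len(n) >= min_len & ch)
  len <- if (length(ok)) max(ok) else 0L
  list(body = substr(seq, 1L, n - len),
       polya_start = if (len > 0L) n - len + 1L else 0L,
       polya_len = len)
}

#' Enumerate candidate ORFs in sense orientation
#'
#' For each of the three sense frames, the sequence is segmented at stop
#' codons; each segment contributes its first-ATG..stop ORF and every
#' nested downstream ATG ORF, plus the open-ended candidates needed for
#' partial CDSs: an ATG..sequence-end ORF with no stop, and a
#' segment-start..stop candidate lacking an ATG (5'-truncated CDS).
#' Candidates are sorted by protein length, longest first.
#'
#' @param seq cDNA sequence, poly(A) stripped
#' @param all_nested when TRUE (default) every ATG of a stop-delimited
#'   segment opens a candidate; nested ATGs code for suffixes of the same
#'   protein, so FALSE keeps only the first ATG per segment
#' @return data.frame with columns `start`, `end` (1-based inclusive,
#'   stop codon included when present), `frame` (0-2), `has_start`,
#'   `has_stop`, `protein` (stop excluded), `aa_len`
#' @export
find_orfs <- function(seq, all_nested = TRUE) {
  n <- nchar(seq)
  rows <- list()
  for (f in 0:2) {
    starts <- seq(f + 1L, n - 2L, by = 3L)
    if (f + 1L > n - 2L) next
    cods <- substring(seq, starts, starts + 2L)
    is_stop <- cods %in% .STOP_CODONS
    seg_id <- cumsum(c(TRUE, utils::head(is_stop, -1L)))
    for (sg in split(seq_along(cods), seg_id)) {
      stop_i <- sg[is_stop[sg]]
      body <- sg[!is_stop[sg]]
      atg <- body[cods[body] == "ATG"]
      if (!all_nested && length(atg)) atg <- atg[1]
      has_stop <- length(stop_i) > 0L
      for (a in atg) {
        cfrom <- a
        cto <- if (has_stop) stop_i[1] else body[length(body)]
        rows[[length(rows) + 1L]] <- data.frame(
          start = starts[cfrom], end = starts[cto] + 2L, frame = f,
          has_start = TRUE, has_stop = has_stop, stringsAsFactors = FALSE)
      }
      # 5'-truncated candidate: segment reaching the sequence start with a
      # stop but no usable ATG before it
      if (has_stop && sg[1] == 1L && !length(atg) && length(body)) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = starts[sg[1]], end = starts[stop_i[1]] + 2L, frame = f,
          has_start = FALSE, has_stop = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(), frame = integer(),
                      has_start = logical(), has_stop = logical(),
                      protein = character(), aa_len = integer(),
                      stringsAsFactors = FALSE))
  orfs <- do.call(rbind, rows)
  orfs$protein <- vapply(seq_len(nrow(orfs)), function(i) {
    .translate_cds(substr(seq, orfs$start[i], orfs$end[i]))
  }, character(1))
  orfs$aa_len <- nchar(orfs$protein)
  orfs <- orfs[orfs$aa_len > 0L, , drop = FALSE]
  orfs[order(-orfs$aa_len, orfs$start), , drop = FALSE]
}

#' Select the representative CDS of a cDNA
#'
#' The longest `max_candidates` ORFs with proteins of at least `min_aa`
#' residues are searched against the protein database (threshold
#' `max_evalue`). Among candidates with hits, the full-length candidate
#' with the smallest E-value is selected; if the best-E candidate is not
#' full length, selection falls through the E-ranked order to the first
#' full-length one (keeping the best-E candidate when none is full
#' length). When all E-values tie, or nothing hits, the longest qualifying
#' ORF is selected.
#'
#' @param cdna_id id carried into the annotation
#' @param body poly(A)-stripped cDNA sequence
#' @param orfs result of [find_orfs()] on `body`
#' @param protein_db protein [reference_db()] (may be NULL or empty)
#' @param min_aa minimum protein length (aa)
#' @param max_candidates number of longest ORFs searched
#' @param max_evalue protein-hit threshold
#' @param scheme protein [scoring_scheme()]
#' @return list of class `cds_annotation`: `cdna_id`, `cds_start`,
#'   `cds_end`, `frame`, `protein`, `has_start`, `has_stop`,
#'   `completeness` (`full_length`/`partial`/`none`), `selection_basis`
#'   (`homology`/`longest_orf`/`none`), `best_evalue`
#' @export
select_cds <- function(cdna_id, body, orfs, protein_db = NULL,
                       min_aa = 10L, max_candidates = 20L,
                       max_evalue = 1e-10,
                       scheme = scoring_scheme(alphabet = "protein",
                                               gap_open = 11, gap_ext = 1)) {
  none <- list(cdna_id = cdna_id, cds_start = NA_integer_,
               cds_end = NA_integer_, frame = NA_integer_, protein = "",
               has_start = FALSE, has_stop = FALSE, completeness = "none",
               selection_basis = "none", best_evalue = NA_real_)
  class(none) <- "cds_annotation"
  cand <- orfs[orfs$aa_len >= min_aa, , drop = FALSE]
  if (!nrow(cand)) return(none)
  cand <- utils::head(cand, max_candidates)

  ev <- rep(NA_real_, nrow(cand))
  if (!is.null(protein_db) && length(protein_db$seqs)) {
    # one shared-word prescreen over all candidates, then align only the
    # candidate x record pairs that share words
    alpha <- paste(scheme$core, collapse = "")
    pairs <- kmer_shared_pairs(cand$protein, unname(protein_db$seqs),
                               5L, alpha, 500L, FALSE)
    pairs <- pairs[pairs$shared >= 3L, , drop = FALSE]
    for (z in seq_len(nrow(pairs))) {
      i <- pairs$query[z]
      h <- local_align(cand$protein[i],
                       protein_db$seqs[[pairs$subject[z]]], scheme,
                       both_strands = FALSE)
      if (!is.na(h$evalue) && h$evalue <= max_evalue &&
          (is.na(ev[i]) || h$evalue < ev[i])) ev[i] <- h$evalue
    }
  }
  hit <- which(!is.na(ev))
  if (length(hit) && length(unique(ev[hit])) > 1L) {
    ord <- hit[order(ev[hit], -cand$aa_len[hit], cand$start[hit])]
    full <- ord[cand$has_start[ord] & cand$has_stop[ord]]
    pick <- if (length(full)) full[1] else ord[1]
    basis <- "homology"
  } else if (length(hit)) {  # all hit E-values tie: take the longest
    ord <- hit[order(-cand$aa_len[hit], cand$start[hit])]
    pick <- ord[1]
    basis <- "homology"
  } else {
    pick <- 1L  # cand is sorted longest-first
    basis <- "longest_orf"
  }
  ann <- list(cdna_id = cdna_id, cds_start = cand$start[pick],
              cds_end = cand$end[pick], frame = cand$frame[pick],
              protein = cand$protein[pick], has_start = cand$has_start[pick],
              has_stop = cand$has_stop[pick],
              completeness = classify_completeness(cand$has_start[pick],
                                                   cand$has_stop[pick]),
              selection_basis = basis, best_evalue = ev[pick])
  class(ann) <- "cds_annotation"
  ann
}

#' Classify CDS completeness
#'
#' `full_length` iff both start and stop codon are present; `partial` when
#' a CDS exists lacking one; `none` otherwise.
#'
#' @param has_start,has_stop logicals (or a `cds_annotation` as first
#'   argument)
#' @return character scalar
#' @export
classify_completeness <- function(has_start, has_stop = NULL) {
  if (inherits(has_start, "cds_annotation")) {
    ann <- has_start
    if (is.na(ann$cds_start)) return("none")
    has_stop <- ann$has_stop; has_start <- ann$has_start
  }
  if (has_start && has_stop) "full_length"
  else if (has_start || has_stop) "partial"
  else "none"
}

#' Extract UTRs and the poly(A) interval of a full-length cDNA
#'
#' The 5'-UTR is the sequence upstream of the start codon; the 3'-UTR the
#' sequence downstream of the stop codon up to the poly(A) tail. The four
#' intervals partition the cDNA exactly.
#'
#' @param cdna full cDNA sequence (tail included)
#' @param ann a `cds_annotation` from [select_cds()] (computed on the
#'   poly(A)-stripped body)
#' @param polya list from [strip_polya()] for the same cDNA
#' @return list of class `utr_annotation`: `utr5_start/end`, `utr3_start/end`,
#'   `polya_start/end`, `utr5_len`, `utr3_len`, `polya_len`
#' @export
extract_utrs <- function(cdna, ann, polya = strip_polya(cdna)) {
  if (!identical(ann$completeness, "full_length"))
    .stopf("extract_utrs requires a full-length CDS annotation (got '%s')",
           ann$completeness)
  n <- nchar(cdna)
  body_end <- if (polya$polya_len > 0L) polya$polya_start - 1L else n
  if (ann$cds_end > body_end)
    .stopf("CDS interval exceeds the poly(A)-stripped body")
  u5l <- ann$cds_start - 1L
  u3l <- body_end - ann$cds_end
  out <- list(utr5_start = if (u5l > 0L) 1L else 0L,
              utr5_end = u5l,
              utr3_start = if (u3l > 0L) ann$cds_end + 1L else 0L,
              utr3_end = if (u3l > 0L) body_end else -1L,
              polya_start = polya$polya_start,
              polya_end = if (polya$polya_len > 0L) n else -1L,
              utr5_len = u5l, utr3_len = u3l, polya_len = polya$polya_len)
  class(out) <- "utr_annotation"
  out
}

#' Base composition of sequence regions
#'
#' Counts A, T, G, C (and N, X separately); the four base frequencies are
#' percentages of the A+T+G+C total, so N and X never enter the four-way
#' denominator.
#'
#' @param seqs character vector of region sequences
#' @return one-row data.frame with counts `n_A`..`n_X`, percentages
#'   `pct_A`..`pct_C` and `pct_AT`; zero-row data.frame for empty input
#' @export
composition <- function(seqs) {
  if (!length(seqs))
    return(data.frame(n_A = integer(), n_T = integer(), n_G = integer(),
                      n_C = integer(), n_N = integer(), n_X = integer(),
                      pct_A = numeric(), pct_T = numeric(), pct_G = numeric(),
                      pct_C = numeric(), pct_AT = numeric()))
  x <- Biostrings::BStringSet(seqs)
  cnt <- colSums(Biostrings::letterFrequency(x, letters = c("A", "T", "G", "C", "N", "X")))
  tot <- sum(cnt[c("A", "T", "G", "C")])
  pct <- if (tot > 0) 100 * cnt[c("A", "T", "G", "C")] / tot else rep(NA_real_, 4)
  data.frame(n_A = cnt[["A"]], n_T = cnt[["T"]], n_G = cnt[["G"]],
             n_C = cnt[["C"]], n_N = cnt[["N"]], n_X = cnt[["X"]],
             pct_A = pct[["A"]], pct_T = pct[["T"]], pct_G = pct[["G"]],
             pct_C = pct[["C"]], pct_AT = pct[["A"]] + pct[["T"]])
}

#' Stop codon usage over full-length CDS annotations
#'
#' @param anns list of `cds_annotation` objects
#' @param seqs named character vector of the (poly(A)-stripped) bodies the
#'   annotations refer to
#' @return data.frame stop_codon / count / pct (percentages of full-length
#'   annotations; sums to 100 before rounding)
#' @export
stop_codon_usage <- function(anns, seqs) {
  full <- Filter(function(a) identical(a$completeness, "full_length"), anns)
  codons <- vapply(full, function(a)
    substr(seqs[[a$cdna_id]], a$cds_end - 2L, a$cds_end), character(1))
  cnt <- table(factor(codons, levels = c("TGA", "TAA", "TAG")))
  data.frame(stop_codon = names(cnt), count = as.integer(cnt),
             pct = if (sum(cnt) > 0) 100 * as.integer(cnt) / sum(cnt)
                   else rep(NA_real_, 3),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mean and median of a length distribution
#'
#' The median uses the standard even-n average of the two central values.
#'
#' @param values numeric vector (non-empty)
#' @return named numeric vector c(mean, median)
#' @export
length_summary <- function(values) {
  if (!length(values)) .stopf("empty length vector")
  c(mean = mean(values), median = median(values))
}

#' Annotate CDS and UTRs for a set of cDNAs
#'
#' Convenience driver: strips poly(A), enumerates ORFs, selects the CDS
#' against `protein_db`, classifies completeness, and extracts UTRs for
#' full-length annotations.
#'
#' @param seqs named character vector of cDNAs (tails included)
#' @param protein_db protein [reference_db()] or NULL
#' @param ... passed to [select_cds()]
#' @return list with `annotations` (named list of `cds_annotation`),
#'   `utrs` (named list of `utr_annotation`, full-length only),
#'   `bodies` (poly(A)-stripped sequences), `table` (flat per-cDNA
#'   data.frame)
#' @export
annotate_cds <- function(seqs, protein_db = NULL, ...) {
  anns <- list(); utrs <- list(); bodies <- character(0)
  rows <- list()
  for (id in names(seqs)) {
    pa <- strip_polya(seqs[[id]])
    bodies[id] <- pa$body
    orfs <- find_orfs(pa$body)
    ann <- select_cds(id, pa$body, orfs, protein_db, ...)
    anns[[id]] <- ann
    u5 <- NA_integer_; u3 <- NA_integer_
    if (identical(ann$completeness, "full_length")) {
      u <- extract_utrs(seqs[[id]], ann, pa)
      utrs[[id]] <- u
      u5 <- u$utr5_len; u3 <- u$utr3_len
    }
    rows[[id]] <- data.frame(
      cdna_id = id, cds_start = ann$cds_start, cds_end = ann$cds_end,
      frame = ann$frame, completeness = ann$completeness,
      selection_basis = ann$selection_basis, aa_len = nchar(ann$protein),
      utr5_len = u5, utr3_len = u3, polya_len = pa$polya_len,
      insert_len = nchar(seqs[[id]]),
      stop_codon = if (isTRUE(ann$has_stop))
        substr(pa$body, ann$cds_end - 2L, ann$cds_end) else NA_character_,
      stringsAsFactors = FALSE)
  }
  list(annotations = anns, utrs = utrs, bodies = bodies,
       table = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
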