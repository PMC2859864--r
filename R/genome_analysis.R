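# Transcript-to-genome mapping, full-length mapping criteria, exon typing,
# exon/intron/gene statistics, translation-site-to-exon mapping,
# alternative-splicing event classification, and exon-restricted SNP rate
# estimation.

#' Gene model container
#'
#' @param cdna_id,scaffold_id,strand identifiers and orientation
#' @param exons data.frame with `g_start`, `g_end` (and, for mapped models,
#'   `est_start`, `est_end`, `type`), rows in transcript order
#' @param introns data.frame with `g_start`, `g_end`, `donor`, `acceptor`,
#'   `canonical` (or NULL for single-exon models)
#' @param identity,est_coverage,score alignment statistics (optional)
#' @param cds optional data.frame of CDS genome intervals
#' @param start_codon_exon,stop_codon_exon exon indices (transcript order)
#'   of the translation start/stop, or NA
#' @return object of class `gene_model`
#' @export
gene_model <- function(cdna_id, scaffold_id, strand, exons, introns = NULL,
                       identity = NA_real_, est_coverage = NA_real_,
                       score = NA_real_, cds = NULL,
                       start_codon_exon = NA_integer_,
                       stop_codon_exon = NA_integer_) {
  if (!nrow(exons)) .stopf("a gene model needs at least one exon")
  if (is.null(introns))
    introns <- data.frame(g_start = integer(), g_end = integer(),
                          donor = character(), acceptor = character(),
                          canonical = logical(), stringsAsFactors = FALSE)
  structure(list(cdna_id = cdna_id, scaffold_id = scaffold_id,
                 strand = strand, exons = exons, introns = introns,
                 identity = identity, est_coverage = est_coverage,
                 score = score, cds = cds,
                 start_codon_exon = start_codon_exon,
                 stop_codon_exon = stop_codon_exon),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s on %s (%s): %d exon(s), span %d-%d\n",
              x$cdna_id, x$scaffold_id, x$strand, nrow(x$exons),
              min(x$exons$g_start), max(x$exons$g_end)))
  invisible(x)
}

#' Assign exon types to a gene model
#'
#' Orientation is defined by transcript sense (exon rows are in transcript
#' order): one `initial` and one `terminal` exon for multi-exon models,
#' `internal` in between, `single` for one-exon models.
#'
#' @param model a [gene_model()]
#' @return the model with an exon `type` column
#' @export
classify_exons <- function(model) {
  k <- nrow(model$exons)
  model$exons$type <- if (k == 1L) "single" else
    c("initial", rep("internal", max(0L, k - 2L)), "terminal")
  model
}

#' Map a cDNA onto genome scaffolds
#'
#' The best-matching scaffold and approximate locus are found by a
#' shared-word scan (both orientations); the spliced aligner then runs on
#' the locus extended by `margin` nt each side. The cDNA is full-length
#' mapped iff exon-column identity >= `min_identity`, est coverage >=
#' `min_coverage`, and the alignment starts within the first and ends
#' within the last `end_slack` nt of the (poly(A)-stripped) cDNA.
#'
#' @param body poly(A)-stripped cDNA (character string)
#' @param genome named character vector of scaffolds
#' @param cdna_id id carried into the model
#' @param params [spliced_params()]
#' @param margin locus extension (nt) each side before spliced alignment
#' @param min_identity,min_coverage,end_slack full-length mapping rule
#' @param k,min_shared,max_occ locate-scan parameters
#' @return a typed [gene_model()] (class also `mapped_model`) on success;
#'   otherwise a list of class `unmapped` with `reason` in
#'   `no_hit`/`low_identity`/`low_coverage` and the alignment (if any)
#' @export
map_to_genome <- function(body, genome, cdna_id = "cdna",
                          params = spliced_params(), margin = 12000L,
                          min_identity = 0.90, min_coverage = 0.90,
                          end_slack = 20L, k = 14L, min_shared = 10L,
                          max_occ = 20L) {
  loc <- kmer_locate(c(body, revcomp(body)), unname(genome), as.integer(k),
                     "ACGT", as.integer(max_occ), as.integer(min_shared))
  .map_one(body, genome, cdna_id, loc, params, margin, min_identity,
           min_coverage, end_slack)
}

# core of map_to_genome once the locate rows for this cDNA are known
# (locate query 1 = forward, 2 = reverse complement)
.map_one <- function(body, genome, cdna_id, loc, params, margin,
                     min_identity, min_coverage, end_slack) {
  if (!nrow(loc))
    return(structure(list(cdna_id = cdna_id, reason = "no_hit",
                          alignment = NULL), class = "unmapped"))
  best <- loc[which.max(loc$shared), ]
  sc <- names(genome)[best$subject]
  L <- nchar(genome[[sc]])
  lo <- max(1L, best$span_start - margin)
  hi <- min(L, best$span_end + margin)
  region <- substr(genome[[sc]], lo, hi)
  hint <- if (best$query == 1L) "+" else "-"   # which orientation seeded
  aln <- spliced_align(body, region, params, est_id = cdna_id,
                       genome_id = sc, strands = hint)
  # shift to scaffold coordinates
  aln$exons$g_start <- aln$exons$g_start + lo - 1L
  aln$exons$g_end <- aln$exons$g_end + lo - 1L
  if (nrow(aln$introns)) {
    aln$introns$g_start <- aln$introns$g_start + lo - 1L
    aln$introns$g_end <- aln$introns$g_end + lo - 1L
  }
  if (nrow(aln$exons) == 0L)
    return(structure(list(cdna_id = cdna_id, reason = "no_hit",
                          alignment = aln), class = "unmapped"))
  if (aln$identity < min_identity)
    return(structure(list(cdna_id = cdna_id, reason = "low_identity",
                          alignment = aln), class = "unmapped"))
  m <- nchar(body)
  est_lo <- min(aln$exons$est_start); est_hi <- max(aln$exons$est_end)
  if (aln$est_coverage < min_coverage ||
      est_lo > end_slack || est_hi < m - end_slack + 1L)
    return(structure(list(cdna_id = cdna_id, reason = "low_coverage",
                          alignment = aln), class = "unmapped"))
  model <- gene_model(cdna_id = cdna_id, scaffold_id = sc,
                      strand = aln$strand, exons = aln$exons,
                      introns = aln$introns, identity = aln$identity,
                      est_coverage = aln$est_coverage, score = aln$score)
  model <- classify_exons(model)
  model$n_match <- aln$n_match
  model$n_mismatch <- aln$n_mismatch
  model$mismatch_gpos <- aln$mismatch_gpos
  class(model) <- c("mapped_model", "gene_model")
  model
}

#' Map a set of cDNAs onto scaffolds
#'
#' Same criteria as [map_to_genome()], with the scaffold word index built
#' once for the whole batch.
#'
#' @param bodies named character vector of poly(A)-stripped cDNAs
#' @param genome named character vector of scaffolds
#' @inheritParams map_to_genome
#' @return list with `models` (named list of mapped models) and `unmapped`
#'   (data.frame id/reason)
#' @export
map_transcripts <- function(bodies, genome, params = spliced_params(),
                            margin = 12000L, min_identity = 0.90,
                            min_coverage = 0.90, end_slack = 20L,
                            k = 14L, min_shared = 10L, max_occ = 20L) {
  n <- length(bodies)
  # one scaffold word index for the whole batch
  loc <- kmer_locate(c(unname(bodies), revcomp(unname(bodies))),
                     unname(genome), as.integer(k), "ACGT",
                     as.integer(max_occ), as.integer(min_shared))
  models <- list(); un <- list()
  for (i in seq_len(n)) {
    id <- names(bodies)[i]
    rows <- loc[loc$query %in% c(i, i + n), , drop = FALSE]
    rows$query <- ifelse(rows$query == i, 1L, 2L)
    r <- .map_one(bodies[[i]], genome, id, rows, params, margin,
                  min_identity, min_coverage, end_slack)
    if (inherits(r, "unmapped"))
      un[[id]] <- data.frame(cdna_id = id, reason = r$reason,
                             stringsAsFactors = FALSE)
    else models[[id]] <- r
  }
  list(models = models,
       unmapped = if (length(un)) do.call(rbind, c(un, list(make.row.names = FALSE)))
       else data.frame(cdna_id = character(), reason = character(),
                       stringsAsFactors = FALSE))
}

#' Exon/intron/gene statistics over mapped models
#'
#' @param models list of [gene_model()] objects
#' @return list with `summary` (metric/mean/median), `exon_by_type`
#'   (per-type count/mean/median), `exon_lengths`, `intron_lengths`,
#'   `gene_lengths`, `exons_per_gene`
#' @export
exon_intron_stats <- function(models) {
  if (!length(models)) .stopf("no models")
  exlen <- list(); extype <- list(); inlen <- list()
  glen <- numeric(0); nex <- integer(0)
  for (m in models) {
    el <- m$exons$g_end - m$exons$g_start + 1L
    exlen[[m$cdna_id]] <- el
    extype[[m$cdna_id]] <- m$exons$type %||% rep(NA_character_, length(el))
    if (nrow(m$introns))
      inlen[[m$cdna_id]] <- m$introns$g_end - m$introns$g_start + 1L
    glen <- c(glen, max(m$exons$g_end) - min(m$exons$g_start) + 1L)
    nex <- c(nex, nrow(m$exons))
  }
  exon_lengths <- unlist(exlen, use.names = FALSE)
  exon_types <- unlist(extype, use.names = FALSE)
  intron_lengths <- unlist(inlen, use.names = FALSE) %||% numeric(0)
  summ <- rbind(
    data.frame(metric = "exons_per_gene", mean = mean(nex), median = median(nex)),
    data.frame(metric = "exon_length", mean = mean(exon_lengths),
               median = median(exon_lengths)),
    if (length(intron_lengths))
      data.frame(metric = "intron_length", mean = mean(intron_lengths),
                 median = median(intron_lengths)),
    data.frame(metric = "gene_length", mean = mean(glen), median = median(glen)))
  bytype <- do.call(rbind, lapply(split(exon_lengths, exon_types), function(v)
    data.frame(count = length(v), mean = mean(v), median = median(v))))
  bytype <- cbind(type = rownames(bytype), bytype)
  rownames(bytype) <- NULL
  list(summary = summ, exon_by_type = bytype, exon_lengths = exon_lengths,
       intron_lengths = intron_lengths, gene_lengths = glen,
       exons_per_gene = nex)
}

# exon index (transcript order) containing a transcript position
.exon_of_position <- function(model, pos) {
  hit <- which(model$exons$est_start <= pos & model$exons$est_end >= pos)
  if (length(hit)) hit[1] else NA_integer_
}

#' Frequency of translation start/stop codons in internal exons
#'
#' For each mapped full-length model the CDS annotation places the first
#' methionine and the stop codon on an exon; the reported frequencies are
#' the fractions of models whose start (resp. stop) codon lies in an exon
#' typed `internal`.
#'
#' @param models named list of mapped [gene_model()]s (with est coordinates)
#' @param anns named list of `cds_annotation`s on the same
#'   (poly(A)-stripped) cDNAs
#' @return list with `freq_start_internal`, `freq_stop_internal`
#'   (fractions), `n_models`, and the per-model exon indices
#' @export
utr_intron_occurrence <- function(models, anns) {
  ids <- intersect(names(models),
                   names(Filter(function(a) identical(a$completeness, "full_length"),
                                anns)))
  if (!length(ids)) .stopf("no mapped full-length models")
  start_int <- logical(0); stop_int <- logical(0)
  idx <- list()
  for (id in ids) {
    m <- models[[id]]; a <- anns[[id]]
    ei_start <- .exon_of_position(m, a$cds_start)
    ei_stop <- .exon_of_position(m, a$cds_end - 2L)
    idx[[id]] <- c(start_exon = ei_start, stop_exon = ei_stop)
    start_int <- c(start_int, !is.na(ei_start) && m$exons$type[ei_start] == "internal")
    stop_int <- c(stop_int, !is.na(ei_stop) && m$exons$type[ei_stop] == "internal")
  }
  list(freq_start_internal = mean(start_int),
       freq_stop_internal = mean(stop_int),
       n_models = length(ids), exon_indices = idx)
}

#' Classify alternative-splicing events between two gene models
#'
#' For each structural difference between two models mapped to the same
#' locus: `retained_intron` when one model's exon fully spans the other's
#' intron; `alt_acceptor` / `alt_donor` when an intron pair shares its
#' donor but not its acceptor (or vice versa; donor/acceptor read in
#' transcription sense); `exon_skip` when an internal exon of one model has
#' no overlapping exon in the other while the flanking intron boundaries
#' merge; anything left is `other`. One transcript pair can yield several
#' events.
#'
#' @param model_a,model_b mapped [gene_model()]s
#' @return data.frame with columns `type`, `g_start`, `g_end`,
#'   `in_model` (which model carries the differing structure); empty for
#'   non-overlapping or identical models
#' @export
classify_splice_events <- function(model_a, model_b) {
  empty <- data.frame(type = character(), g_start = integer(),
                      g_end = integer(), in_model = character(),
                      stringsAsFactors = FALSE)
  if (model_a$scaffold_id != model_b$scaffold_id ||
      model_a$strand != model_b$strand) return(empty)
  span <- function(m) c(min(m$exons$g_start), max(m$exons$g_end))
  sa <- span(model_a); sb <- span(model_b)
  if (sa[2] < sb[1] || sb[2] < sa[1]) return(empty)
  strand <- model_a$strand

  ikey <- function(d) paste(d$g_start, d$g_end)
  ia <- model_a$introns; ib <- model_b$introns
  shared <- intersect(ikey(ia), ikey(ib))
  ua <- ia[!(ikey(ia) %in% shared), , drop = FALSE]
  ub <- ib[!(ikey(ib) %in% shared), , drop = FALSE]
  da <- rep(FALSE, nrow(ua)); db <- rep(FALSE, nrow(ub))
  ev <- list()
  add <- function(type, s, e, who)
    ev[[length(ev) + 1L]] <<- data.frame(type = type, g_start = s, g_end = e,
                                         in_model = who,
                                         stringsAsFactors = FALSE)

  # retained intron: an unmatched intron fully inside an exon of the other
  spans_exon <- function(exons, s, e)
    any(exons$g_start < s & exons$g_end > e)
  for (i in seq_len(nrow(ua)))
    if (spans_exon(model_b$exons, ua$g_start[i], ua$g_end[i])) {
      add("retained_intron", ua$g_start[i], ua$g_end[i], model_b$cdna_id)
      da[i] <- TRUE
    }
  for (j in seq_len(nrow(ub)))
    if (spans_exon(model_a$exons, ub$g_start[j], ub$g_end[j])) {
      add("retained_intron", ub$g_start[j], ub$g_end[j], model_a$cdna_id)
      db[j] <- TRUE
    }

  # exon skip (checked before the alt-site scan: a merged intron shares its
  # donor with one flanking intron and would otherwise look like an
  # alternative acceptor): an intron of one model exactly merges two
  # introns of the other across a skipped internal exon
  skip_scan <- function(u, handled_u, other_introns, other_exons, who) {
    for (j in seq_len(nrow(u))) {
      if (handled_u[j]) next
      oi <- other_introns
      left <- which(oi$g_start == u$g_start[j])
      right <- which(oi$g_end == u$g_end[j])
      if (length(left) && length(right) && left[1] != right[1]) {
        skipped <- other_exons$g_start > u$g_start[j] &
          other_exons$g_end < u$g_end[j]
        if (any(skipped)) {
          add("exon_skip", u$g_start[j], u$g_end[j], who)
          handled_u[j] <- TRUE
        }
      }
    }
    handled_u
  }
  db <- skip_scan(ub, db, ia, model_a$exons, model_b$cdna_id)
  da <- skip_scan(ua, da, ib, model_b$exons, model_a$cdna_id)
  # the two flanking introns of a detected skip are explained as well
  for (e in ev) if (e$type == "exon_skip") {
    da[ua$g_start == e$g_start | ua$g_end == e$g_end] <- TRUE
    db[ub$g_start == e$g_start | ub$g_end == e$g_end] <- TRUE
  }

  # alternative donor / acceptor on overlapping intron pairs
  don <- function(d) if (strand == "+") d$g_start else d$g_end
  acc <- function(d) if (strand == "+") d$g_end else d$g_start
  for (i in seq_len(nrow(ua))) {
    if (da[i]) next
    for (j in seq_len(nrow(ub))) {
      if (db[j]) next
      if (ua$g_start[i] > ub$g_end[j] || ub$g_start[j] > ua$g_end[i]) next
      dd <- don(ua)[i] == don(ub)[j]; aa <- acc(ua)[i] == acc(ub)[j]
      if (dd && !aa) {
        add("alt_acceptor", min(ua$g_start[i], ub$g_start[j]),
            max(ua$g_end[i], ub$g_end[j]), model_a$cdna_id)
        da[i] <- TRUE; db[j] <- TRUE
      } else if (aa && !dd) {
        add("alt_donor", min(ua$g_start[i], ub$g_start[j]),
            max(ua$g_end[i], ub$g_end[j]), model_a$cdna_id)
        da[i] <- TRUE; db[j] <- TRUE
      }
      if (da[i]) break
    }
  }

  for (i in which(!da)) add("other", ua$g_start[i], ua$g_end[i], model_a$cdna_id)
  for (j in which(!db)) add("other", ub$g_start[j], ub$g_end[j], model_b$cdna_id)
  if (!length(ev)) return(empty)
  out <- do.call(rbind, ev)
  cbind(pair_a = model_a$cdna_id, pair_b = model_b$cdna_id, out,
        stringsAsFactors = FALSE)
}

#' Estimate the exon-restricted nucleotide mismatch (SNP) rate
#'
#' Over mapped models (cDNA vs a variant genome), only pairs with
#' exon-column identity >= `identity_floor` contribute. The numerator is
#' the number of substitution columns inside exon blocks, the denominator
#' the number of aligned non-gap exon columns; indel columns enter
#' neither.
#'
#' @param models list of mapped [gene_model()]s (from [map_to_genome()]
#'   against the variant genome)
#' @param identity_floor minimum pair identity (default 0.995)
#' @return list of class `snp_estimate`: `pairs_used`, `mismatches`,
#'   `aligned_exon_bases`, `rate_pct` (percentage), `one_in_nt`
#' @export
estimate_snp_rate <- function(models, identity_floor = 0.995) {
  used <- 0L; mm <- 0L; cols <- 0L
  for (m in models) {
    if (is.na(m$identity) || m$identity < identity_floor) next
    used <- used + 1L
    mm <- mm + m$n_mismatch
    cols <- cols + m$n_match + m$n_mismatch
  }
  if (cols == 0L) .stopf("no aligned exon bases; SNP rate undefined")
  rate <- mm / cols
  structure(list(pairs_used = used, mismatches = mm,
                 aligned_exon_bases = cols, rate_pct = 100 * rate,
                 one_in_nt = if (rate > 0) 1 / rate else Inf),
            class = "snp_estimate")
}

#' @export
print.snp_estimate <- function(x, ...) {
  cat(sprintf(
    "<snp_estimate> %d pairs, %d mismatches / %d exon bases = %.4f%% (one in %.0f nt)\n",
    x$pairs_used, x$mismatches, x$aligned_exon_bases, x$rate_pct,
    x$one_in_nt))
  invisible(x)
}
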