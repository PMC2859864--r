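# Summary tables, Fisher's exact frequency comparisons, and the pipeline
# accounting ledger. Every report number is recomputable from the
# persisted per-sequence annotation tables; nothing is cached.

#' Validate a pipeline accounting ledger
#'
#' Checks, exactly, that every stage satisfies `in = removed + kept` and
#' that each stage's kept count equals the next stage's input count.
#'
#' @param ledger data.frame with columns `stage`, `n_in`, `removed`,
#'   `kept`, rows in pipeline order
#' @return list with `valid` (logical) and `violations` (data.frame
#'   stage/identity, empty when valid)
#' @export
pipeline_accounting <- function(ledger) {
  viol <- list()
  for (i in seq_len(nrow(ledger))) {
    if (ledger$n_in[i] != ledger$removed[i] + ledger$kept[i])
      viol[[length(viol) + 1L]] <- data.frame(
        stage = ledger$stage[i], identity = "in != removed + kept",
        stringsAsFactors = FALSE)
    if (i > 1L && ledger$n_in[i] != ledger$kept[i - 1L])
      viol[[length(viol) + 1L]] <- data.frame(
        stage = ledger$stage[i], identity = "in != previous kept",
        stringsAsFactors = FALSE)
  }
  list(valid = !length(viol),
       violations = if (length(viol))
         do.call(rbind, c(viol, list(make.row.names = FALSE)))
       else data.frame(stage = character(), identity = character(),
                       stringsAsFactors = FALSE))
}

#' Fisher's exact frequency comparison per category
#'
#' For each category, a two-sided Fisher exact test on the 2x2 table
#' (in-category / not-in-category x set / reference). No multiplicity
#' correction by default, matching the classical procedure; set
#' `adjust = "BH"` for Benjamini-Hochberg.
#'
#' @param counts data.frame with columns `category`, `count_set`,
#'   `count_ref`
#' @param total_set,total_ref totals of the two collections
#' @param alpha significance level
#' @param adjust `"none"` (default) or `"BH"`
#' @return data.frame category / count_set / count_ref / p_value /
#'   significant
#' @export
fisher_category_test <- function(counts, total_set, total_ref,
                                 alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (total_set <= 0 || total_ref <= 0) .stopf("zero totals")
  if (any(counts$count_set > total_set) || any(counts$count_ref > total_ref))
    .stopf("category counts exceed totals")
  p <- vapply(seq_len(nrow(counts)), function(i) {
    tab <- matrix(c(counts$count_set[i], total_set - counts$count_set[i],
                    counts$count_ref[i], total_ref - counts$count_ref[i]),
                  nrow = 2)
    fisher.test(tab, alternative = "two.sided")$p.value
  }, numeric(1))
  padj <- if (adjust == "BH") p.adjust(p, "BH") else p
  data.frame(category = counts$category, count_set = counts$count_set,
             count_ref = counts$count_ref, p_value = p,
             significant = padj < alpha, stringsAsFactors = FALSE)
}

.hist_table <- function(values, breaks = 30L) {
  if (!length(values)) return(data.frame(bin_start = numeric(),
                                         bin_end = numeric(),
                                         count = integer()))
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  data.frame(bin_start = utils::head(h$breaks, -1L),
             bin_end = h$breaks[-1L], count = h$counts)
}

#' Assemble the report bundle
#'
#' Builds the length-summary, composition, stop-codon, exon/intron,
#' splice-event and SNP tables from stage outputs, writes them as TSV plus
#' one JSON summary, and returns everything invisibly. Missing stages
#' leave explicit gaps.
#'
#' @param outdir output directory (created if needed)
#' @param cds result of [annotate_cds()] (or NULL)
#' @param ledger curation ledger (or NULL)
#' @param stats result of [exon_intron_stats()] (or NULL)
#' @param events data.frame of splice events (or NULL)
#' @param snp a `snp_estimate` (or NULL)
#' @param seqs named character vector of the annotated cDNAs (required with
#'   `cds` for composition tables)
#' @return list of report tables, invisibly
#' @export
build_report <- function(outdir, cds = NULL, ledger = NULL, stats = NULL,
                         events = NULL, snp = NULL, seqs = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rep <- list()
  if (!is.null(cds)) {
    tab <- cds$table
    full <- tab[tab$completeness == "full_length", , drop = FALSE]
    lens <- rbind(
      data.frame(region = "insert", t(length_summary(tab$insert_len))),
      data.frame(region = "cds",
                 t(length_summary(full$cds_end - full$cds_start + 1L))),
      data.frame(region = "utr5", t(length_summary(full$utr5_len))),
      data.frame(region = "utr3", t(length_summary(full$utr3_len))))
    rep$length_summary <- lens
    if (!is.null(seqs)) {
      reg <- function(sel) vapply(seq_len(nrow(full)), function(i) {
        s <- cds$bodies[[full$cdna_id[i]]]
        switch(sel,
               full = s,
               utr5 = substr(s, 1L, full$cds_start[i] - 1L),
               cdsr = substr(s, full$cds_start[i], full$cds_end[i]),
               utr3 = substr(s, full$cds_end[i] + 1L, nchar(s)))
      }, character(1))
      comp <- rbind(cbind(region = "full_length", composition(reg("full"))),
                    cbind(region = "utr5", composition(reg("utr5"))),
                    cbind(region = "cds", composition(reg("cdsr"))),
                    cbind(region = "utr3", composition(reg("utr3"))))
      rep$composition <- comp
    }
    rep$stop_codon_usage <- stop_codon_usage(cds$annotations, cds$bodies)
    rep$insert_length_hist <- .hist_table(tab$insert_len)
    rep$cds_length_hist <- .hist_table(full$cds_end - full$cds_start + 1L)
  }
  if (!is.null(ledger)) rep$ledger <- ledger
  if (!is.null(stats)) {
    rep$exon_intron_summary <- stats$summary
    rep$exon_by_type <- stats$exon_by_type
    rep$exon_length_hist <- .hist_table(stats$exon_lengths)
    rep$intron_length_hist <- .hist_table(stats$intron_lengths)
  }
  if (!is.null(events) && nrow(events)) {
    tab <- table(events$type)
    rep$splice_events <- data.frame(type = names(tab),
                                    count = as.integer(tab),
                                    pct = 100 * as.integer(tab) / sum(tab),
                                    stringsAsFactors = FALSE)
    rep$splice_event_table <- events
  }
  if (!is.null(snp))
    rep$snp <- data.frame(pairs_used = snp$pairs_used,
                          mismatches = snp$mismatches,
                          aligned_exon_bases = snp$aligned_exon_bases,
                          rate_pct = snp$rate_pct, one_in_nt = snp$one_in_nt)

  for (nm in names(rep)) write_table(rep[[nm]], file.path(outdir, paste0(nm, ".tsv")))
  summary <- list()
  if (!is.null(rep$length_summary)) summary$length_summary <- rep$length_summary
  if (!is.null(rep$stop_codon_usage)) summary$stop_codon_usage <- rep$stop_codon_usage
  if (!is.null(rep$exon_intron_summary)) summary$exon_intron <- rep$exon_intron_summary
  if (!is.null(rep$splice_events)) summary$splice_events <- rep$splice_events
  if (!is.null(rep$snp)) summary$snp <- rep$snp
  if (!is.null(rep$ledger)) summary$ledger <- rep$ledger
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(rep)
}
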