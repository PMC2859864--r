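# The curation cascade that turns finished cDNA (HTC) sequences into
# non-redundant full-length cDNA candidates: redundancy collapse, ncRNA
# filter, pathogen filter with host rescue, chimera detection, and
# retained-intron flagging. Filters run in that fixed order; a sequence
# removed by an earlier filter is never tested by later ones, so stage
# counts are order-dependent. An audit ledger records, per stage, the exact
# conservation identity in = kept + removed.

#' Collapse redundant sequences
#'
#' Two sequences are linked when their best local alignment satisfies all
#' of: `evalue < max_evalue`, identity >= `min_identity`, aligned length at
#' least `min_coverage` of BOTH sequence lengths, and no single alignment
#' gap of `max_link_gap` nt or more (intron-scale gaps indicate a
#' structural difference, not redundancy). Linked components are collapsed
#' to their longest member (ties to the smallest id).
#'
#' @param seqs named character vector of sequences
#' @param max_evalue,min_identity,min_coverage,max_link_gap link rule
#' @param scheme nucleotide [scoring_scheme()]
#' @param k,min_shared,max_occ shared-word prescreen parameters
#' @param recheck assert that no kept pair still meets the link rule
#' @return list with `kept` (ids), `groups` (data.frame group_id,
#'   member_id, kept) and `links` (the linked pairs)
#' @export
remove_redundant <- function(seqs, max_evalue = 1e-180, min_identity = 0.97,
                             min_coverage = 0.80, max_link_gap = 30L,
                             scheme = scoring_scheme(), k = 14L,
                             min_shared = 40L, max_occ = 100L,
                             recheck = TRUE) {
  if (!length(seqs)) .stopf("no sequences")
  ids <- sort(names(seqs))
  seqs <- seqs[ids]
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  linked <- function(h, la, lb) {
    !is.na(h$evalue) && h$evalue < max_evalue &&
      h$identity >= min_identity &&
      (h$q_end - h$q_start + 1L) >= min_coverage * la &&
      (h$s_end - h$s_start + 1L) >= min_coverage * lb &&
      h$max_gap < max_link_gap
  }
  links <- list()
  if (n > 1L) {
    cand <- kmer_shared_pairs(unname(seqs), unname(seqs), k, "ACGT",
                              max_occ, TRUE)
    cand <- cand[cand$shared >= min_shared, , drop = FALSE]
    for (z in seq_len(nrow(cand))) {
      i <- cand$query[z]; j <- cand$subject[z]
      h <- local_align(seqs[[i]], seqs[[j]], scheme, ids[i], ids[j])
      if (linked(h, nchar(seqs[[i]]), nchar(seqs[[j]]))) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        links[[length(links) + 1L]] <- h
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  kept <- character(0)
  groups <- list()
  for (r in unique(roots)) {
    members <- ids[roots == r]
    lens <- nchar(seqs[members])
    keep <- members[order(-lens, members)][1]
    kept <- c(kept, keep)
    groups[[length(groups) + 1L]] <-
      data.frame(group_id = paste0("rg_", ids[r]), member_id = members,
                 kept = members == keep, stringsAsFactors = FALSE)
  }
  kept <- sort(kept)
  if (recheck && length(kept) > 1L) {
    ks <- seqs[kept]
    cand <- kmer_shared_pairs(unname(ks), unname(ks), k, "ACGT", max_occ, TRUE)
    cand <- cand[cand$shared >= min_shared, , drop = FALSE]
    for (z in seq_len(nrow(cand))) {
      i <- cand$query[z]; j <- cand$subject[z]
      h <- local_align(ks[[i]], ks[[j]], scheme)
      if (linked(h, nchar(ks[[i]]), nchar(ks[[j]])))
        .stopf("redundancy re-check failed: kept pair %s / %s still links",
               kept[i], kept[j])
    }
  }
  list(kept = kept,
       groups = do.call(rbind, c(groups, list(make.row.names = FALSE))),
       links = if (length(links)) do.call(rbind, links) else NULL)
}

#' Flag a sequence as non-coding-RNA derived
#'
#' TRUE iff the best hit against the ncRNA database has
#' `evalue <= max_evalue`.
#'
#' @param seq sequence (character string)
#' @param ncrna_db a [reference_db()]; an empty database flags nothing
#' @param max_evalue threshold
#' @param scheme nucleotide [scoring_scheme()]
#' @return logical, with attribute `hit` (best hit row or NULL)
#' @export
flag_ncrna <- function(seq, ncrna_db, max_evalue = 1e-180,
                       scheme = scoring_scheme()) {
  if (is.null(ncrna_db) || !length(ncrna_db$seqs)) {
    warning("empty ncRNA database; nothing flagged")
    return(FALSE)
  }
  hits <- search_db(seq, ncrna_db, scheme, max_evalue = max_evalue)
  structure(nrow(hits) > 0,
            hit = if (nrow(hits)) hits[1, , drop = FALSE] else NULL)
}

#' Flag a sequence as pathogen-derived, with host rescue
#'
#' TRUE iff the best pathogen hit has `evalue < max_evalue` AND no
#' host-database hit matches at least as well (a host hit with an E-value
#' less than or equal to the pathogen's rescues the sequence as
#' host-derived; the tie case covers a transcript present verbatim in both
#' databases).
#'
#' @param seq sequence (character string)
#' @param pathogen_db,host_db [reference_db()] objects
#' @param max_evalue pathogen E-value threshold
#' @param scheme nucleotide [scoring_scheme()]
#' @return logical
#' @export
flag_pathogen <- function(seq, pathogen_db, host_db, max_evalue = 1e-30,
                          scheme = scoring_scheme()) {
  ph <- search_db(seq, pathogen_db, scheme, max_evalue = Inf)
  ph <- ph[ph$evalue < max_evalue, , drop = FALSE]
  if (!nrow(ph)) return(FALSE)
  hh <- search_db(seq, host_db, scheme, max_evalue = Inf)
  if (nrow(hh) && min(hh$evalue) <= min(ph$evalue)) return(FALSE)
  TRUE
}

# normalized token set of a functional description: casefold, strip
# punctuation and generic tokens; two descriptions "differ" iff neither
# token set is a subset of the other
.desc_tokens <- function(x) {
  x <- tolower(gsub("[[:punct:]]", " ", x))
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  setdiff(toks, c("putative", "predicted", "like", "family", "protein", ""))
}

.descs_differ <- function(a, b) {
  ta <- .desc_tokens(a); tb <- .desc_tokens(b)
  if (!length(ta) || !length(tb)) return(FALSE)
  !(all(ta %in% tb) || all(tb %in% ta))
}

# genome hits restricted to shared-word located regions (aligning a cDNA
# against whole scaffolds is never needed: a chimera check only has to know
# which scaffolds the query regions match)
.genome_region_hits <- function(seq, genome_db, scheme, max_evalue,
                                k = 14L, min_shared = 10L, margin = 300L) {
  gseqs <- genome_db$seqs
  loc <- kmer_locate(c(seq, revcomp(seq)), unname(gseqs), as.integer(k),
                     "ACGT", 50L, as.integer(min_shared))
  if (!nrow(loc)) return(.hit_row()[0, ])
  hits <- list()
  for (sj in unique(loc$subject)) {
    rows <- loc[loc$subject == sj, , drop = FALSE]
    sc <- names(gseqs)[sj]
    L <- nchar(gseqs[[sc]])
    lo <- max(1L, min(rows$span_start) - margin)
    hi <- min(L, max(rows$span_end) + margin)
    h <- local_align(seq, substr(gseqs[[sc]], lo, hi), scheme,
                     query_id = "query", subject_id = sc)
    h$s_start <- h$s_start + lo - 1L
    h$s_end <- h$s_end + lo - 1L
    # E-value against the full scaffold length
    ka <- .ka_for(scheme)
    h$evalue <- ka$K * as.numeric(nchar(seq)) * as.numeric(L) *
      exp(-ka$lambda * h$score)
    if (!is.na(h$evalue) && h$evalue <= max_evalue)
      hits[[length(hits) + 1L]] <- h
  }
  if (!length(hits)) return(.hit_row()[0, ])
  hits <- do.call(rbind, hits)
  hits[order(hits$evalue, hits$subject_id), , drop = FALSE]
}

# batched prescreen: candidate subject indices per query (both query
# orientations), one shared-word pass for a whole stage. Every similarity
# the cascade acts on implies at least ~100 nt of near-identity (hundreds
# of shared words), so the default floor is comfortably conservative while
# screening out chance low-complexity word sharing in AT-rich sequence.
.batch_cand <- function(queries, db_seqs, k = 12L, min_shared = 15L,
                        max_occ = 200L) {
  nq <- length(queries)
  out <- rep(list(integer(0)), nq)
  if (!nq || !length(db_seqs)) return(out)
  qs <- c(unname(queries), revcomp(unname(queries)))
  pr <- kmer_shared_pairs(qs, unname(db_seqs), as.integer(k), "ACGT",
                          as.integer(max_occ), FALSE)
  pr <- pr[pr$shared >= min_shared, , drop = FALSE]
  qi <- ifelse(pr$query > nq, pr$query - nq, pr$query)
  sp <- split(pr$subject, qi)
  for (nm in names(sp)) out[[as.integer(nm)]] <- sort(unique(sp[[nm]]))
  out
}

# align a query against chosen db records, keep hits below the threshold,
# ordered by (evalue, subject id)
.aligned_hits <- function(query, query_id, db, subjects, scheme, max_evalue) {
  hits <- lapply(subjects, function(sid) {
    h <- local_align(query, db$seqs[[sid]], scheme, query_id, sid)
    h$subject_description <- unname(db$desc[[sid]] %||% "")
    h
  })
  hits <- if (length(hits)) do.call(rbind, hits) else .hit_row()[0, ]
  hits <- hits[!is.na(hits$evalue) & hits$evalue <= max_evalue, , drop = FALSE]
  hits[order(hits$evalue, hits$subject_id), , drop = FALSE]
}

# query-interval overlap as a fraction of the shorter interval
.overlap_frac <- function(s1, e1, s2, e2) {
  ov <- max(0L, min(e1, e2) - max(s1, s2) + 1L)
  ov / min(e1 - s1 + 1L, e2 - s2 + 1L)
}

#' Detect a chimeric clone
#'
#' A sequence is a chimera candidate when it hits two or more transcript
#' (unigene) records with different functional descriptions on essentially
#' disjoint query regions (overlap < `max_overlap_frac` of the shorter
#' region). A candidate is confirmed when its two regions match two
#' distinct genome scaffolds, or when a BamHI/XhoI site (GGATCC/CTCGAG)
#' lies strictly between the two matched regions.
#'
#' @param seq sequence (character string)
#' @param unigene_db transcript [reference_db()] with description lines
#' @param genome_db scaffold [reference_db()]
#' @param max_evalue unigene/scaffold hit threshold
#' @param enzyme_sites restriction-site sequences
#' @param max_overlap_frac disjointness tolerance
#' @param site_slack how far (nt) a site may overlap a matched-region end
#'   and still count as lying between the regions
#' @param scheme nucleotide [scoring_scheme()]
#' @return list with `chimera` (logical) and `rule_fired`
#'   (`"scaffold"`, `"enzyme_site"` or `"none"`)
#' @export
flag_chimera <- function(seq, unigene_db, genome_db, max_evalue = 1e-50,
                         enzyme_sites = c("GGATCC", "CTCGAG"),
                         max_overlap_frac = 0.20, site_slack = 10L,
                         scheme = scoring_scheme()) {
  if (all(!nzchar(unigene_db$desc))) {
    warning("unigene database has no descriptions; chimera candidates cannot form")
    return(list(chimera = FALSE, rule_fired = "none"))
  }
  hits <- search_db(seq, unigene_db, scheme, max_evalue = max_evalue)
  .chimera_decide(seq, hits, genome_db, max_evalue, enzyme_sites,
                  max_overlap_frac, site_slack, scheme)
}

# decision core of flag_chimera, given the unigene hit table
.chimera_decide <- function(seq, hits, genome_db, max_evalue, enzyme_sites,
                            max_overlap_frac, site_slack, scheme) {
  if (nrow(hits) < 2L) return(list(chimera = FALSE, rule_fired = "none"))
  # find a disjoint pair with differing descriptions
  pair <- NULL
  for (i in seq_len(nrow(hits) - 1L)) {
    for (j in seq(i + 1L, nrow(hits))) {
      if (.descs_differ(hits$subject_description[i], hits$subject_description[j]) &&
          .overlap_frac(hits$q_start[i], hits$q_end[i],
                        hits$q_start[j], hits$q_end[j]) < max_overlap_frac) {
        pair <- c(i, j); break
      }
    }
    if (!is.null(pair)) break
  }
  if (is.null(pair)) return(list(chimera = FALSE, rule_fired = "none"))
  gh <- .genome_region_hits(seq, genome_db, scheme, max_evalue)
  if (nrow(gh) >= 2L) {
    for (i in seq_len(nrow(gh) - 1L)) {
      for (j in seq(i + 1L, nrow(gh))) {
        if (gh$subject_id[i] != gh$subject_id[j] &&
            .overlap_frac(gh$q_start[i], gh$q_end[i],
                          gh$q_start[j], gh$q_end[j]) < max_overlap_frac)
          return(list(chimera = TRUE, rule_fired = "scaffold"))
      }
    }
  }
  # the site must sit between the two matched regions; a few nt of slack
  # absorbs local-alignment ends that extend into the site by chance
  left_end <- min(hits$q_end[pair]); right_start <- max(hits$q_start[pair])
  for (site in enzyme_sites) {
    m <- gregexpr(site, seq, fixed = TRUE)[[1]]
    if (m[1] == -1L) next
    if (any(m > left_end - site_slack &
            (m + nchar(site) - 1L) < right_start + site_slack))
      return(list(chimera = TRUE, rule_fired = "enzyme_site"))
  }
  list(chimera = FALSE, rule_fired = "none")
}

#' Flag a retained intron by bidirectional spliced alignment
#'
#' The sequence's multi-sequence group is formed from companion-database
#' hits with `evalue < max_evalue`; the sequence is flagged iff, against
#' any group member, the pairwise intron scan reports an intron inside the
#' target (target in the "genome" role).
#'
#' @param seq sequence, poly(A) stripped (character string)
#' @param seq_id id of the sequence (excluded from its own group)
#' @param companion_db [reference_db()] of poly(A)-stripped companions
#'   (the sequence set itself plus unigene/TC-like transcripts)
#' @param max_evalue grouping threshold
#' @param params [spliced_params()] for the intron scan
#' @param scheme nucleotide [scoring_scheme()] for grouping
#' @param max_members cap on group members scanned (best hits first)
#' @return logical with attribute `introns` (data.frame, possibly empty)
#' @export
flag_retained_intron <- function(seq, seq_id, companion_db,
                                 max_evalue = 1e-50,
                                 params = spliced_params(),
                                 scheme = scoring_scheme(),
                                 max_members = 10L) {
  hits <- search_db(seq, companion_db, scheme, max_evalue = max_evalue)
  hits <- hits[hits$subject_id != seq_id, , drop = FALSE]
  members <- utils::head(hits$subject_id, max_members)
  .retained_decide(seq, seq_id, companion_db$seqs[members], params)
}

# decision core of flag_retained_intron, given the group member sequences
.retained_decide <- function(seq, seq_id, member_seqs, params) {
  for (m in names(member_seqs)) {
    aln <- spliced_align(member_seqs[[m]], seq, params,
                         est_id = m, genome_id = seq_id)
    itr <- aln$introns
    itr <- itr[(itr$g_end - itr$g_start + 1L) >= params$min_intron, , drop = FALSE]
    if (nrow(itr)) return(structure(TRUE, introns = itr, witness = m))
  }
  structure(FALSE, introns = NULL)
}

#' Run the full curation cascade
#'
#' Applies, in order: redundancy collapse, ncRNA filter, pathogen filter
#' with host rescue, chimera detection, retained-intron flagging. Emits a
#' per-stage audit ledger (`in = kept + removed`, exact) and a per-sequence
#' disposition table.
#'
#' @param htcs named character vector of finished cDNA sequences
#' @param dbs list with `ncrna_db`, `pathogen_db`, `unigene_db`,
#'   `genome_db` (any may be NULL to skip its stage test)
#' @param thresholds named list overriding the default E-value thresholds
#'   (`redundant = 1e-180`, `ncrna = 1e-180`, `pathogen = 1e-30`,
#'   `chimera = 1e-50`, `retained = 1e-50`)
#' @param params [spliced_params()] for intron detection
#' @param scheme nucleotide [scoring_scheme()]
#' @param verbose print stage counts
#' @return list with `kept` (surviving ids), `ledger` (stage table),
#'   `disposition` (data.frame id/disposition), `evidence` (per-stage
#'   detail tables)
#' @export
run_curation <- function(htcs, dbs, thresholds = list(),
                         params = spliced_params(),
                         scheme = scoring_scheme(), verbose = FALSE) {
  if (!length(htcs)) {
    ledger <- data.frame(stage = character(), n_in = integer(),
                         removed = integer(), kept = integer(),
                         stringsAsFactors = FALSE)
    return(list(kept = character(0), ledger = ledger,
                disposition = data.frame(id = character(),
                                         disposition = character(),
                                         stringsAsFactors = FALSE),
                evidence = list()))
  }
  th <- utils::modifyList(list(redundant = 1e-180, ncrna = 1e-180,
                               pathogen = 1e-30, chimera = 1e-50,
                               retained = 1e-50), thresholds)
  disposition <- setNames(rep(NA_character_, length(htcs)), names(htcs))
  ledger <- list()
  evidence <- list()
  note <- function(stage, n_in, kept_ids) {
    removed <- n_in - length(kept_ids)
    ledger[[stage]] <<- data.frame(stage = stage, n_in = n_in,
                                   removed = removed,
                                   kept = length(kept_ids),
                                   stringsAsFactors = FALSE)
    if (verbose) message(sprintf("%-16s in=%d removed=%d kept=%d",
                                 stage, n_in, removed, length(kept_ids)))
  }

  # 1. redundancy
  red <- remove_redundant(htcs, max_evalue = th$redundant, scheme = scheme)
  cur <- red$kept
  disposition[setdiff(names(htcs), cur)] <- "redundant"
  note("redundancy", length(htcs), cur)
  evidence$redundancy <- red$groups

  # 2. ncRNA (batched prescreen: flagged iff any hit at or below threshold)
  if (!is.null(dbs$ncrna_db) && length(dbs$ncrna_db$seqs)) {
    cand <- .batch_cand(htcs[cur], dbs$ncrna_db$seqs)
    fl <- vapply(seq_along(cur), function(qi) {
      for (sj in cand[[qi]]) {
        h <- local_align(htcs[[cur[qi]]], dbs$ncrna_db$seqs[[sj]], scheme)
        if (!is.na(h$evalue) && h$evalue <= th$ncrna) return(TRUE)
      }
      FALSE
    }, logical(1))
    disposition[cur[fl]] <- "ncRNA"
    n_in <- length(cur); cur <- cur[!fl]
    note("ncRNA", n_in, cur)
  } else note("ncRNA", length(cur), cur)

  # 3. pathogen (host db = unigenes; host hit at least as good rescues)
  if (!is.null(dbs$pathogen_db) && length(dbs$pathogen_db$seqs)) {
    candp <- .batch_cand(htcs[cur], dbs$pathogen_db$seqs)
    candh <- if (!is.null(dbs$unigene_db))
      .batch_cand(htcs[cur], dbs$unigene_db$seqs) else
      rep(list(integer(0)), length(cur))
    best_e <- function(query, db, subjects) {
      e <- Inf
      for (sj in subjects) {
        h <- local_align(query, db$seqs[[sj]], scheme)
        if (!is.na(h$evalue) && h$evalue < e) e <- h$evalue
      }
      e
    }
    fl <- vapply(seq_along(cur), function(qi) {
      pe <- best_e(htcs[[cur[qi]]], dbs$pathogen_db, candp[[qi]])
      if (!(pe < th$pathogen)) return(FALSE)
      he <- best_e(htcs[[cur[qi]]], dbs$unigene_db, candh[[qi]])
      he > pe
    }, logical(1))
    disposition[cur[fl]] <- "pathogen"
    n_in <- length(cur); cur <- cur[!fl]
    note("pathogen", n_in, cur)
  } else note("pathogen", length(cur), cur)

  # 4. chimera
  if (!is.null(dbs$unigene_db) && !is.null(dbs$genome_db)) {
    cand <- .batch_cand(htcs[cur], dbs$unigene_db$seqs)
    rules <- character(0)
    fl <- vapply(seq_along(cur), function(qi) {
      id <- cur[qi]
      hits <- .aligned_hits(htcs[[id]], id, dbs$unigene_db,
                            names(dbs$unigene_db$seqs)[cand[[qi]]],
                            scheme, th$chimera)
      r <- .chimera_decide(htcs[[id]], hits, dbs$genome_db, th$chimera,
                           c("GGATCC", "CTCGAG"), 0.20, 10L, scheme)
      rules[id] <<- r$rule_fired
      r$chimera
    }, logical(1))
    disposition[cur[fl]] <- "chimera"
    evidence$chimera <- data.frame(id = names(rules), rule = unname(rules),
                                   stringsAsFactors = FALSE)
    n_in <- length(cur); cur <- cur[!fl]
    note("chimera", n_in, cur)
  } else note("chimera", length(cur), cur)

  # 5. retained intron: companion db = surviving set (poly(A) stripped)
  #    plus unigene-like transcripts
  stripped <- vapply(htcs[cur], function(s) strip_polya(s)$body, character(1))
  comp_seqs <- stripped
  if (!is.null(dbs$unigene_db)) {
    uni <- vapply(dbs$unigene_db$seqs, function(s) strip_polya(s)$body,
                  character(1))
    comp_seqs <- c(comp_seqs, uni)
  }
  comp_db <- reference_db(comp_seqs, "transcript", name = "companions")
  cand <- .batch_cand(stripped, comp_db$seqs)
  ret <- list()
  fl <- vapply(seq_along(cur), function(qi) {
    id <- cur[qi]
    hits <- .aligned_hits(stripped[[id]], id, comp_db,
                          setdiff(names(comp_db$seqs)[cand[[qi]]], id),
                          scheme, th$retained)
    members <- utils::head(hits$subject_id, 10L)
    r <- .retained_decide(stripped[[id]], id, comp_db$seqs[members], params)
    if (isTRUE(as.logical(r)))
      ret[[id]] <<- cbind(id = id, attr(r, "introns"),
                          witness = attr(r, "witness"))
    as.logical(r)
  }, logical(1))
  disposition[cur[fl]] <- "retained_intron"
  evidence$retained_intron <- if (length(ret))
    do.call(rbind, c(ret, list(make.row.names = FALSE))) else NULL
  n_in <- length(cur); cur <- cur[!fl]
  note("retained_intron", n_in, cur)

  disposition[cur] <- "nrFLcDNA_candidate"
  list(kept = cur,
       ledger = do.call(rbind, c(ledger, list(make.row.names = FALSE))),
       disposition = data.frame(id = names(disposition),
                                disposition = unname(disposition),
                                stringsAsFactors = FALSE),
       evidence = evidence)
}
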