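# Read trimming and filtering, EST clustering, and 5'-most representative
# selection. The original workflow delegated these steps to cross_match,
# phred and phrap; here vector masking uses the local aligner, quality
# trimming a sliding-window rule, and clustering greedy single linkage over
# pairwise overlaps (phrap's overlap-quality model is out of scope; only
# cluster membership is consumed downstream).

#' Trim vector sequence and low-quality ends from a read
#'
#' Vector matches (identity >= `min_identity`, aligned length >=
#' `min_length` against any record of `vector_db`) are masked and clipped
#' from the read ends; the remainder is cut to the longest contiguous
#' window whose `window`-nt sliding mean Phred quality is at least
#' `min_quality`. Reads without qualities skip quality trimming.
#'
#' @param seq read sequence (character string)
#' @param qual integer Phred vector of the same length, or `NULL`
#' @param vector_db a [reference_db()] of vector sequences
#' @param min_quality sliding-mean quality threshold
#' @param window sliding window width (nt)
#' @param min_identity,min_length vector-match acceptance rule
#' @param scheme nucleotide [scoring_scheme()]
#' @return list with `seq`, `qual` (possibly empty) and `trim_start`,
#'   `trim_end` (kept interval on the input read; 0/−1 when empty)
#' @export
trim_read <- function(seq, qual = NULL, vector_db = NULL,
                      min_quality = 30, window = 20L,
                      min_identity = 0.9, min_length = 15L,
                      scheme = scoring_scheme()) {
  if (!nzchar(seq)) .stopf("empty read")
  n <- nchar(seq)
  if (!is.null(qual) && length(qual) != n)
    .stopf("quality length does not match read length")
  mask <- rep(FALSE, n)
  if (!is.null(vector_db) && length(vector_db$seqs)) {
    for (v in names(vector_db$seqs)) {
      h <- local_align(seq, vector_db$seqs[[v]], scheme,
                       query_id = "read", subject_id = v)
      if (!is.na(h$identity) && h$identity >= min_identity &&
          (h$q_end - h$q_start + 1L) >= min_length)
        mask[h$q_start:h$q_end] <- TRUE
    }
  }
  # clip contiguous masked runs from the ends
  lo <- 1L; hi <- n
  while (lo <= hi && mask[lo]) lo <- lo + 1L
  while (hi >= lo && mask[hi]) hi <- hi - 1L
  if (lo > hi) return(list(seq = "", qual = integer(0), trim_start = 0L,
                           trim_end = -1L))
  if (!is.null(qual)) {
    q <- qual[lo:hi]
    m <- length(q)
    if (m < window) {
      if (mean(q) < min_quality)
        return(list(seq = "", qual = integer(0), trim_start = 0L, trim_end = -1L))
      win <- c(lo, hi)
    } else {
      sm <- as.numeric(stats::filter(q, rep(1 / window, window), sides = 1))
      good <- which(!is.na(sm) & sm >= min_quality)  # window end positions
      if (!length(good))
        return(list(seq = "", qual = integer(0), trim_start = 0L, trim_end = -1L))
      # longest run of consecutive qualifying windows, kept from the first
      # window's start to the last window's end
      grp <- cumsum(c(1L, diff(good) != 1L))
      spans <- vapply(split(good, grp),
                      function(g) c(g[1] - window + 1L, g[length(g)]),
                      integer(2))
      b <- which.max(spans[2, ] - spans[1, ])
      s1 <- spans[1, b]; s2 <- spans[2, b]
      # the kept segment must not end in below-threshold bases (a window
      # mean >= threshold can drag in a few low-quality boundary bases)
      while (s2 >= s1 && q[s2] < min_quality) s2 <- s2 - 1L
      while (s1 <= s2 && q[s1] < min_quality) s1 <- s1 + 1L
      if (s1 > s2)
        return(list(seq = "", qual = integer(0), trim_start = 0L, trim_end = -1L))
      win <- c(lo + s1 - 1L, lo + s2 - 1L)
    }
    lo2 <- unname(win[1]); hi2 <- unname(win[2])
  } else {
    lo2 <- lo; hi2 <- hi
  }
  list(seq = substr(seq, lo2, hi2),
       qual = if (is.null(qual)) integer(0) else qual[lo2:hi2],
       trim_start = lo2, trim_end = hi2)
}

#' Keep/discard rule for a trimmed read
#'
#' Discards reads shorter than `min_len` nt and reads whose longest
#' single-nucleotide run exceeds `max_homopolymer_frac` of their length
#' (strictly greater).
#'
#' @param seq trimmed read sequence
#' @param min_len minimum length (nt)
#' @param max_homopolymer_frac homopolymer-run fraction threshold
#' @return list with `keep` (logical) and `reason`
#'   (`""`, `"length"` or `"homopolymer"`)
#' @export
filter_read <- function(seq, min_len = 50L, max_homopolymer_frac = 0.10) {
  n <- nchar(seq)
  if (n < min_len) return(list(keep = FALSE, reason = "length"))
  r <- rle(strsplit(seq, "")[[1]])
  if (max(r$lengths) > max_homopolymer_frac * n)
    return(list(keep = FALSE, reason = "homopolymer"))
  list(keep = TRUE, reason = "")
}

#' Cluster reads by greedy single linkage over pairwise overlaps
#'
#' Two reads are linked when they share a local alignment of at least
#' `min_overlap` columns at identity >= `min_identity`; clusters are the
#' connected components. Candidate pairs come from a shared-word prescreen.
#' Cluster ids are deterministic (named after the lexicographically
#' smallest member), and the result is invariant to input order.
#'
#' @param reads named character vector of trimmed, filtered reads
#' @param min_overlap minimum alignment length (columns)
#' @param min_identity minimum identity over aligned non-gap columns
#' @param scheme nucleotide [scoring_scheme()]
#' @param k,min_shared,max_occ prescreen parameters
#' @return data.frame cluster_id / member_id
#' @export
cluster_ests <- function(reads, min_overlap = 100L, min_identity = 0.95,
                         scheme = scoring_scheme(), k = 12L,
                         min_shared = 5L, max_occ = 100L) {
  ids <- sort(names(reads))
  reads <- reads[ids]
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  if (n > 1L) {
    cand <- kmer_shared_pairs(unname(reads), unname(reads), k,
                              "ACGT", max_occ, TRUE)
    cand <- cand[cand$shared >= min_shared, , drop = FALSE]
    for (z in seq_len(nrow(cand))) {
      i <- cand$query[z]; j <- cand$subject[z]
      if (find(i) == find(j)) next
      h <- local_align(reads[[i]], reads[[j]], scheme)
      if (!is.na(h$align_len) && h$align_len >= min_overlap &&
          h$identity >= min_identity) union_(i, j)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  data.frame(cluster_id = paste0("cluster_", ids[roots]),
             member_id = ids, stringsAsFactors = FALSE, row.names = NULL)
}

#' Select the 5'-most representative of a cluster
#'
#' Members are anchored to the lexicographically smallest member by their
#' best local alignment; each member's 5' end is projected onto the anchor
#' coordinate system and the member with the smallest (5'-most) offset
#' wins. Ties go to the longest insert, then the smallest id. Members that
#' cannot be anchored (alignment score below `min_anchor_score`) stay in
#' the cluster but never become representative.
#'
#' @param member_ids character vector of member ids
#' @param reads named character vector holding the member sequences
#' @param scheme nucleotide [scoring_scheme()]
#' @param min_anchor_score minimum anchoring alignment score
#' @return list with `representative`, `offsets` (named signed offsets of
#'   each anchored member's 5' end relative to the representative's) and
#'   `unanchored` (ids)
#' @export
select_representative <- function(member_ids, reads,
                                  scheme = scoring_scheme(),
                                  min_anchor_score = 30) {
  member_ids <- sort(member_ids)
  if (!length(member_ids)) .stopf("empty cluster")
  anchor <- member_ids[1]
  off <- setNames(rep(NA_real_, length(member_ids)), member_ids)
  off[anchor] <- 0
  for (m in setdiff(member_ids, anchor)) {
    h <- local_align(reads[[m]], reads[[anchor]], scheme)
    if (!is.na(h$score) && h$score >= min_anchor_score && h$strand == "+") {
      # member position q_start sits at anchor position s_start
      off[m] <- (h$s_start - 1) - (h$q_start - 1)
    }
  }
  anchored <- names(off)[!is.na(off)]
  lens <- nchar(unlist(reads[anchored]))
  ord <- order(off[anchored], -lens, anchored)
  rep_id <- anchored[ord[1]]
  list(representative = rep_id,
       offsets = setNames(off[anchored] - off[[rep_id]], anchored),
       unanchored = setdiff(member_ids, anchored))
}

#' Run trim + filter + cluster + representative selection over a read set
#'
#' @param reads list with `seq` (named character) and `qual` (named list),
#'   as produced by [simulate_clone_library()]
#' @param vector_db a [reference_db()] of vector sequences
#' @param ... passed to [trim_read()], [filter_read()], [cluster_ests()]
#' @return list with `trimmed` (named character), `discarded`
#'   (data.frame id/reason), `clusters` (data.frame cluster_id, member_id,
#'   offset, is_representative)
#' @export
preprocess_reads <- function(reads, vector_db, ...) {
  trimmed <- character(0)
  disc <- list()
  for (id in names(reads$seq)) {
    t <- trim_read(reads$seq[[id]], reads$qual[[id]], vector_db)
    if (!nzchar(t$seq)) {
      disc[[id]] <- data.frame(id = id, reason = "empty_after_trim",
                               stringsAsFactors = FALSE)
      next
    }
    f <- filter_read(t$seq)
    if (!f$keep) {
      disc[[id]] <- data.frame(id = id, reason = f$reason,
                               stringsAsFactors = FALSE)
      next
    }
    trimmed[id] <- t$seq
  }
  cl <- cluster_ests(trimmed)
  rows <- list()
  for (cid in unique(cl$cluster_id)) {
    members <- cl$member_id[cl$cluster_id == cid]
    sel <- select_representative(members, trimmed)
    rows[[cid]] <- data.frame(
      cluster_id = cid, member_id = members,
      offset = unname(sel$offsets[members]),
      is_representative = members == sel$representative,
      stringsAsFactors = FALSE)
  }
  list(trimmed = trimmed,
       discarded = if (length(disc)) do.call(rbind, disc) else
         data.frame(id = character(), reason = character(),
                    stringsAsFactors = FALSE),
       clusters = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
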