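# Readers/writers for the formats the pipeline touches: FASTA, phrap-style
# .qual files, GFF3 gene models and plain TSV tables. Coordinates are
# 1-based inclusive everywhere, inside and outside the package.

.ALPHABETS <- list(
  dna     = c("A", "C", "G", "T", "N", "X"),
  protein = c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "*", "X"),
  any     = NULL
)

#' Read a FASTA file
#'
#' Sequences are uppercased; characters outside the requested alphabet are
#' rejected. Record order and description lines are preserved.
#'
#' @param path path to a FASTA file
#' @param alphabet one of `"dna"`, `"protein"` or `"any"` (no validation)
#' @return a data.frame with columns `id` (first word of the header),
#'   `desc` (remainder of the header, possibly `""`) and `seq`
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein", "any")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) .stopf("FASTA file not found: %s", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) .stopf("no FASTA records in %s", path)
  hdr <- names(x)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  seq <- toupper(as.character(x))
  if (any(id == "")) .stopf("malformed FASTA header (record %d) in %s",
                            which(id == "")[1], path)
  if (any(nchar(seq) == 0L))
    .stopf("empty sequence for record '%s' in %s", id[nchar(seq) == 0L][1], path)
  if (anyDuplicated(id))
    .stopf("duplicate FASTA id '%s' in %s", id[duplicated(id)][1], path)
  ab <- .ALPHABETS[[alphabet]]
  if (!is.null(ab)) {
    bad <- !grepl(sprintf("^[%s]+$", paste(gsub("\\*", "\\\\*", ab), collapse = "")), seq)
    if (any(bad))
      .stopf("illegal %s character in record '%s' of %s",
             alphabet, id[bad][1], path)
  }
  data.frame(id = unname(id), desc = unname(desc), seq = unname(seq),
             stringsAsFactors = FALSE)
}

#' Write sequences as FASTA
#'
#' @param x a data.frame as returned by [read_fasta()], or a named character
#'   vector of sequences
#' @param path output path
#' @param width line-wrap width
#' @return `path`, invisibly
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) {
    x <- data.frame(id = names(x), desc = "", seq = unname(x),
                    stringsAsFactors = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    hdr <- if (nzchar(x$desc[i])) paste(x$id[i], x$desc[i]) else x$id[i]
    writeLines(paste0(">", hdr), con)
    s <- x$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Build a reference sequence database
#'
#' A light container pairing sequences with their description lines and a
#' declared kind, as used by the curation filters.
#'
#' @param seqs named character vector of sequences, or a [read_fasta()] frame
#' @param kind one of transcript, ncrna, pathogen, protein, genome, vector
#' @param name database label used in reports
#' @param desc optional named character vector of descriptions
#' @return an object of class `reference_db`
#' @export
reference_db <- function(seqs, kind = c("transcript", "ncrna", "pathogen",
                                        "protein", "genome", "vector"),
                         name = "db", desc = NULL) {
  kind <- match.arg(kind)
  if (is.data.frame(seqs)) {
    desc <- setNames(seqs$desc, seqs$id)
    seqs <- setNames(seqs$seq, seqs$id)
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    .stopf("reference_db sequences must be named")
  if (is.null(desc)) desc <- setNames(rep("", length(seqs)), names(seqs))
  structure(list(name = name, kind = kind, seqs = seqs,
                 desc = desc[names(seqs)]),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("<reference_db '%s'> kind=%s, %d records, %d nt/aa total\n",
              x$name, x$kind, length(x$seqs), sum(nchar(x$seqs))))
  invisible(x)
}

#' Read a phrap-style quality file
#'
#' One record per read, headers as in FASTA, bodies of whitespace-separated
#' Phred integers.
#'
#' @param path path to the .qual file
#' @param fasta optional [read_fasta()] frame; when given, quality lengths
#'   are validated against sequence lengths
#' @return named list of integer vectors
#' @export
read_qual <- function(path, fasta = NULL) {
  if (!file.exists(path)) .stopf(".qual file not found: %s", path)
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) .stopf("no records in %s", path)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  ends <- c(hdr[-1] - 1L, length(lines))
  out <- vector("list", length(hdr))
  for (i in seq_along(hdr)) {
    body <- paste(lines[seq(hdr[i] + 1L, ends[i])], collapse = " ")
    q <- suppressWarnings(as.integer(strsplit(trimws(body), "\\s+")[[1]]))
    if (anyNA(q)) .stopf("non-integer quality value in record '%s'", ids[i])
    out[[i]] <- q
  }
  names(out) <- ids
  if (!is.null(fasta)) {
    common <- intersect(names(out), fasta$id)
    lens <- setNames(nchar(fasta$seq), fasta$id)
    bad <- common[vapply(common, function(id) length(out[[id]]) != lens[[id]], logical(1))]
    if (length(bad))
      .stopf("quality count mismatch vs FASTA for record '%s'", bad[1])
  }
  out
}

#' Write a phrap-style quality file
#'
#' @param quals named list of integer vectors
#' @param path output path
#' @param per_line Phred values per line
#' @return `path`, invisibly
#' @export
write_qual <- function(quals, path, per_line = 25L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(quals)) {
    writeLines(paste0(">", id), con)
    q <- quals[[id]]
    idx <- split(q, ceiling(seq_along(q) / per_line))
    writeLines(vapply(idx, paste, character(1), collapse = " "), con)
  }
  invisible(path)
}

# ---- GFF3 ---------------------------------------------------------------

#' Write gene models as GFF3
#'
#' Emits gene/mRNA/exon (and, when present, CDS) features with ID/Parent
#' attributes, 1-based inclusive coordinates.
#'
#' @param models a list of `gene_model` objects (see [gene_model()])
#' @param path output path
#' @param source value for the GFF3 source column
#' @return `path`, invisibly
#' @export
write_gff3 <- function(models, path, source = "flcdna") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  line <- function(seqid, type, start, end, strand, attrs) {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
            seqid, source, type, start, end, strand, attrs)
  }
  for (m in models) {
    stopifnot(inherits(m, "gene_model"))
    gid <- paste0("gene:", m$cdna_id)
    tid <- paste0("mRNA:", m$cdna_id)
    span <- c(min(m$exons$g_start), max(m$exons$g_end))
    writeLines(line(m$scaffold_id, "gene", span[1], span[2], m$strand,
                    sprintf("ID=%s", gid)), con)
    writeLines(line(m$scaffold_id, "mRNA", span[1], span[2], m$strand,
                    sprintf("ID=%s;Parent=%s", tid, gid)), con)
    ex <- m$exons
    for (i in seq_len(nrow(ex))) {
      attrs <- sprintf("ID=%s.exon%d;Parent=%s;exon_type=%s",
                       tid, i, tid, ex$type[i] %||% "NA")
      writeLines(line(m$scaffold_id, "exon", ex$g_start[i], ex$g_end[i],
                      m$strand, attrs), con)
    }
    if (!is.null(m$cds) && nrow(m$cds)) {
      for (i in seq_len(nrow(m$cds))) {
        writeLines(line(m$scaffold_id, "CDS", m$cds$g_start[i],
                        m$cds$g_end[i], m$strand,
                        sprintf("ID=%s.cds%d;Parent=%s", tid, i, tid)), con)
      }
    }
  }
  invisible(path)
}

#' Read a GFF3 file written by [write_gff3()]
#'
#' @param path path to the GFF3 file
#' @return list of `gene_model` objects (coordinates, strand, exon types and
#'   CDS intervals; alignment statistics are not round-tripped)
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) .stopf("GFF3 file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) return(list())
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 9L)
  if (length(bad)) .stopf("malformed GFF3 line %d", bad[1])
  tab <- as.data.frame(do.call(rbind, f), stringsAsFactors = FALSE)
  names(tab) <- c("seqid", "source", "type", "start", "end", "score",
                  "strand", "phase", "attrs")
  tab$start <- as.integer(tab$start); tab$end <- as.integer(tab$end)
  attr_val <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(sprintf("(?:^|;)%s=[^;]*", key), attrs))
    ifelse(lengths(regmatches(attrs, gregexpr(sprintf("(?:^|;)%s=", key), attrs))) > 0,
           sub(sprintf("^(?:;)?%s=", key), "", sub("^;", "", m)), NA_character_)
  }
  mrnas <- tab[tab$type == "mRNA", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(mrnas))) {
    tid <- attr_val(mrnas$attrs[i], "ID")
    cid <- sub("^mRNA:", "", tid)
    kids <- tab[grepl(sprintf("Parent=%s(;|$)", tid), tab$attrs), , drop = FALSE]
    ex <- kids[kids$type == "exon", , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    cds <- kids[kids$type == "CDS", , drop = FALSE]
    cds <- cds[order(cds$start), , drop = FALSE]
    out[[cid]] <- gene_model(
      cdna_id = cid, scaffold_id = mrnas$seqid[i], strand = mrnas$strand[i],
      exons = data.frame(g_start = ex$start, g_end = ex$end,
                         type = attr_val(ex$attrs, "exon_type"),
                         stringsAsFactors = FALSE),
      introns = NULL,
      cds = if (nrow(cds)) data.frame(g_start = cds$start, g_end = cds$end)
            else NULL)
  }
  out
}

#' Write a TSV table
#'
#' @param rows a data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_table <- function(rows, path) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table written by [write_table()]
#' @param path input path
#' @return data.frame
#' @export
read_table <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
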