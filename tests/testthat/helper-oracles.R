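# Independent plain-R oracles used to verify the compiled dynamic programs.
# They share no machinery with the package implementation: affine gaps are
# handled through the textbook closed form (a gap ending at j opened after
# the best M[k] + ge*k, found with cummax), and the intron transition by
# prefix maxima over donor columns computed directly from the recurrence
# definition.

rand_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# affine-gap Smith-Waterman score; gap of length k costs go + k * ge
sw_score_oracle <- function(a, b, match = 1, mismatch = -3, go = 5, ge = 2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  NEG <- -1e9
  Mp <- rep(NEG, n + 1); Ixp <- rep(NEG, n + 1); Iyp <- rep(NEG, n + 1)
  best <- 0
  for (i in seq_len(m)) {
    s <- ifelse(av[i] == bv, match, mismatch)
    Mc <- c(NEG, pmax(0, Mp[1:n], Ixp[1:n], Iyp[1:n]) + s)
    Iyc <- c(NEG, pmax(Mp[-1] - go - ge, Iyp[-1] - ge))
    Ixc <- rep(NEG, n + 1)
    if (n >= 2) {
      v <- cummax(Mc[2:(n + 1)] + ge * (1:n))
      Ixc[3:(n + 1)] <- v[1:(n - 1)] - go - ge * (2:n)
    }
    best <- max(best, Mc)
    Mp <- Mc; Ixp <- Ixc; Iyp <- Iyc
  }
  best
}

# spliced-alignment score; intron = genomic jump of length >= min_intron
# between aligned columns, charged ip (GT..AG) or ip + nc otherwise
spliced_score_oracle <- function(est, genome, match = 1, mismatch = -3,
                                 go = 5, ge = 2, ip = 40, nc = 20,
                                 min_intron = 20) {
  ev <- strsplit(est, "")[[1]]; gv <- strsplit(genome, "")[[1]]
  m <- length(ev); n <- length(gv)
  NEG <- -1e9
  # donor column jp admits a canonical intron when positions jp+1, jp+2
  # read GT; an intron ending before column j needs AG at j-2, j-1
  don <- c(gv[-1], "x") == "G" & c(gv[-(1:2)], "x", "x") == "T"   # jp = 1..n
  acc <- c(FALSE, FALSE, gv[1:(n - 2)] == "A" & gv[2:(n - 1)] == "G")
  jp_max <- pmax(0L, seq_len(n) - min_intron - 1L)

  Mp <- rep(NEG, n + 1); Ixp <- rep(NEG, n + 1); Iyp <- rep(NEG, n + 1)
  best <- 0
  for (i in seq_len(m)) {
    s <- ifelse(ev[i] == gv, match, mismatch)
    cumAll <- c(NEG, cummax(Mp[2:(n + 1)]))
    cumGT <- c(NEG, cummax(ifelse(don, Mp[2:(n + 1)], NEG)))
    candN <- cumAll[jp_max + 1L] - ip - nc
    candC <- ifelse(acc, cumGT[jp_max + 1L] - ip, NEG)
    Mc <- c(NEG, pmax(0, Mp[1:n], Ixp[1:n], Iyp[1:n], candC, candN) + s)
    Iyc <- c(NEG, pmax(Mp[-1] - go - ge, Iyp[-1] - ge))
    Ixc <- rep(NEG, n + 1)
    if (n >= 2) {
      v <- cummax(Mc[2:(n + 1)] + ge * (1:n))
      Ixc[3:(n + 1)] <- v[1:(n - 1)] - go - ge * (2:n)
    }
    best <- max(best, Mc)
    Mp <- Mc; Ixp <- Ixc; Iyp <- Iyc
  }
  best
}

# exhaustive ATG..stop ORF enumeration (sense frames only)
orf_oracle <- function(seq) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (p in seq_len(n - 2)) {
    if (paste(v[p:(p + 2)], collapse = "") != "ATG") next
    q <- p
    while (q + 2 <= n) {
      cod <- paste(v[q:(q + 2)], collapse = "")
      if (cod %in% stops) {
        out[[length(out) + 1]] <- c(start = p, end = q + 2)
        break
      }
      q <- q + 3
    }
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer()))
  m <- unique(do.call(rbind, out))
  data.frame(start = m[, "start"], end = m[, "end"])
}

# two-sided Fisher p-value by hypergeometric enumeration
fisher_oracle <- function(a, b, c, d) {
  # table rbind(c(a, b), c(c, d)); margins fixed
  m <- a + c; n2 <- b + d; k <- a + b
  x <- max(0, k - n2):min(k, m)
  probs <- dhyper(x, m, n2, k)
  p0 <- dhyper(a, m, n2, k)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}
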