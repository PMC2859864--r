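#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// est2genome-style spliced alignment of an est (cDNA) against one
// orientation of a genomic sequence.
//
// Three affine-gap states (M diagonal, Ix gap-in-est, Iy gap-in-genome)
// plus an intron transition: a genomic jump of length >= min_intron
// between two aligned exon columns, charged a flat intron_penalty
// (plus noncanon_extra unless the jump starts GT and ends AG).
// Local semantics: an alignment may start and end anywhere; the intron
// jump is only available between aligned (M) columns, so introns exactly
// fill the genomic gaps between consecutive exon blocks.
//
// The O(m*n) fill uses per-row running maxima over donor columns so the
// intron transition costs O(1) per cell; ties between equal-scoring donor
// placements resolve to the leftmost donor (running maxima updated with
// strict improvement as the donor column advances). The core is templated
// on the score type: integer scoring schemes (the default) run on int
// arithmetic, anything else on double.

template <typename T>
static List spliced_core(const std::string &est, const std::string &genome,
                         const std::vector<T> &S, int nc,
                         const std::vector<int> &ecode,
                         const std::vector<int> &gcode,
                         T gap_open, T gap_ext,
                         T intron_penalty, T noncanon_extra,
                         int min_intron) {
  const int m = (int) est.size();
  const int n = (int) genome.size();
  const T NEG = std::numeric_limits<T>::lowest() / 4;

  const size_t W = (size_t)(n + 1);
  const bool use_introns = min_intron <= n;   // else plain local alignment
  std::vector<uint8_t> ptr((size_t)(m + 1) * W, 0);
  std::vector<int> donor(use_introns ? (size_t)(m + 1) * W : 1, 0);

  std::vector<T> prevM(W, NEG), curM(W, NEG);
  std::vector<T> prevIx(W, NEG), curIx(W, NEG);
  std::vector<T> prevIy(W, NEG), curIy(W, NEG);

  T best = 0; int bi = 0, bj = 0;

  for (int i = 1; i <= m; ++i) {
    curM[0] = NEG; curIx[0] = NEG; curIy[0] = NEG;
    T runGT = NEG, runAny = NEG;
    int posGT = 0, posAny = 0;
    const T *srow = &S[(size_t) ecode[i - 1] * nc];
    const T *pM = prevM.data(); const T *pIx = prevIx.data();
    const T *pIy = prevIy.data();
    T *cM = curM.data(); T *cIx = curIx.data(); T *cIy = curIy.data();
    uint8_t *prow = &ptr[(size_t)i * W];
    int *drow = use_introns ? &donor[(size_t)i * W] : donor.data();
    for (int j = 1; j <= n; ++j) {
      // admit donor column jd once the minimum intron length is reachable
      if (use_introns) {
        const int jd = j - min_intron - 1;
        if (jd >= 1) {
          const T v = pM[jd];
          if (v > runAny) { runAny = v; posAny = jd; }
          if (jd + 1 < n && genome[jd] == 'G' && genome[jd + 1] == 'T' &&
              v > runGT) {
            runGT = v; posGT = jd;
          }
        }
      }
      const T sub = srow[gcode[j - 1]];

      // predecessor of the aligned pair (i, j)
      T pb = 0; uint8_t mcode = 0; int dn = 0;
      if (pM[j - 1]  > pb) { pb = pM[j - 1];  mcode = 1; }
      if (pIx[j - 1] > pb) { pb = pIx[j - 1]; mcode = 2; }
      if (pIy[j - 1] > pb) { pb = pIy[j - 1]; mcode = 3; }
      if (use_introns && j >= 3 && genome[j - 3] == 'A' &&
          genome[j - 2] == 'G' && runGT > NEG / 2) {
        const T candC = runGT - intron_penalty;
        if (candC > pb) { pb = candC; mcode = 4; dn = posGT; }
      }
      if (use_introns && runAny > NEG / 2) {
        const T candN = runAny - intron_penalty - noncanon_extra;
        if (candN > pb) { pb = candN; mcode = 5; dn = posAny; }
      }
      const T Mv = pb + sub;

      T Ixv; uint8_t ixcode;
      {
        const T a = cM[j - 1] - gap_open - gap_ext;
        const T b = cIx[j - 1] - gap_ext;
        if (a >= b) { Ixv = a; ixcode = 0; } else { Ixv = b; ixcode = 1; }
      }
      T Iyv; uint8_t iycode;
      {
        const T a = pM[j] - gap_open - gap_ext;
        const T b = pIy[j] - gap_ext;
        if (a >= b) { Iyv = a; iycode = 0; } else { Iyv = b; iycode = 1; }
      }

      cM[j] = Mv; cIx[j] = Ixv; cIy[j] = Iyv;
      prow[j] = (uint8_t)(mcode | (ixcode << 3) | (iycode << 4));
      if (mcode >= 4) drow[j] = dn;

      if (Mv > best) { best = Mv; bi = i; bj = j; }
    }
    std::swap(prevM, curM); std::swap(prevIx, curIx); std::swap(prevIy, curIy);
  }

  // traceback from the best M cell
  std::vector<int> ex_es, ex_ee, ex_gs, ex_ge;          // reversed order
  std::vector<int> in_gs, in_ge; std::vector<bool> in_can;
  std::vector<std::string> in_don, in_acc;
  std::vector<int> mmpos;
  int nmatch = 0, nmismatch = 0, est_gap_cols = 0, genome_gap_cols = 0;
  int max_gap = 0, gap_run = 0;

  if (best > 0) {
    int i = bi, j = bj;
    int state = 0; // 0 = M, 1 = Ix, 2 = Iy
    int cur_ee = -1, cur_ge = -1, cur_es = -1, cur_gs = -1;
    bool done = false;
    while (!done) {
      const size_t off = (size_t)i * W + (size_t)j;
      const uint8_t p = ptr[off];
      if (state == 0) {
        if (gap_run > max_gap) max_gap = gap_run;
        gap_run = 0;
        const bool is_match = (est[i - 1] == genome[j - 1] &&
                               est[i - 1] != 'N' && est[i - 1] != 'X');
        if (is_match) ++nmatch; else { ++nmismatch; mmpos.push_back(j); }
        if (cur_ee < 0) { cur_ee = i; cur_ge = j; }
        cur_es = i; cur_gs = j;
        const uint8_t mcode = p & 7;
        switch (mcode) {
        case 0:
          ex_es.push_back(cur_es); ex_ee.push_back(cur_ee);
          ex_gs.push_back(cur_gs); ex_ge.push_back(cur_ge);
          done = true; break;
        case 1: --i; --j; state = 0; break;
        case 2: --i; --j; state = 1; break;
        case 3: --i; --j; state = 2; break;
        case 4: case 5: {
          const int jp = donor[off];
          ex_es.push_back(cur_es); ex_ee.push_back(cur_ee);
          ex_gs.push_back(cur_gs); ex_ge.push_back(cur_ge);
          std::string don = genome.substr(jp, 2);
          std::string acc = genome.substr(j - 3, 2);
          in_gs.push_back(jp + 1); in_ge.push_back(j - 1);
          in_don.push_back(don); in_acc.push_back(acc);
          in_can.push_back(don == "GT" && acc == "AG");
          cur_ee = -1; cur_ge = -1;
          i = i - 1; j = jp; state = 0;
          break;
        }
        }
      } else if (state == 1) {            // Ix: consumes genome j
        ++genome_gap_cols; ++gap_run;
        cur_gs = j;
        state = ((p >> 3) & 1) ? 1 : 0;
        --j;
      } else {                            // Iy: consumes est i
        ++est_gap_cols; ++gap_run;
        cur_es = i;
        state = ((p >> 4) & 1) ? 2 : 0;
        --i;
      }
    }
  }

  const int ne = (int) ex_es.size();
  IntegerMatrix exons(ne, 4);
  for (int t = 0; t < ne; ++t) {
    const int r = ne - 1 - t;
    exons(t, 0) = ex_es[r]; exons(t, 1) = ex_ee[r];
    exons(t, 2) = ex_gs[r]; exons(t, 3) = ex_ge[r];
  }
  colnames(exons) = CharacterVector::create("est_start", "est_end",
                                            "g_start", "g_end");
  const int ni = (int) in_gs.size();
  IntegerVector igs(ni), ige(ni); LogicalVector ican(ni);
  CharacterVector idon(ni), iacc(ni);
  for (int t = 0; t < ni; ++t) {
    const int r = ni - 1 - t;
    igs[t] = in_gs[r]; ige[t] = in_ge[r];
    idon[t] = in_don[r]; iacc[t] = in_acc[r]; ican[t] = in_can[r];
  }
  std::reverse(mmpos.begin(), mmpos.end());

  return List::create(
    _["score"] = (double) best,
    _["exons"] = exons,
    _["intron_start"] = igs, _["intron_end"] = ige,
    _["donor"] = idon, _["acceptor"] = iacc, _["canonical"] = ican,
    _["nmatch"] = nmatch, _["nmismatch"] = nmismatch,
    _["est_gap_cols"] = est_gap_cols, _["genome_gap_cols"] = genome_gap_cols,
    _["max_gap"] = max_gap,
    _["mismatch_gpos"] = wrap(mmpos));
}

// [[Rcpp::export]]
List spliced_align_dp(std::string est, std::string genome,
                      NumericMatrix submat,
                      double gap_open, double gap_ext,
                      double intron_penalty, double noncanon_extra,
                      int min_intron) {
  const int m = (int) est.size();
  const int n = (int) genome.size();
  if (m < 1 || n < 1) stop("empty sequence");
  const double cells = (double)(m + 1) * (double)(n + 1);
  if (cells > 3e8)
    stop("spliced alignment problem too large (%d x %d cells); narrow the genomic region", m, n);

  // per-character substitution lookup from the matrix dimnames
  std::vector<int> code(256, -1);
  CharacterVector rn = rownames(submat);
  for (int t = 0; t < rn.size(); ++t) {
    std::string ch = as<std::string>(rn[t]);
    if (ch.size() == 1) code[(unsigned char) ch[0]] = t;
  }
  const int nc = submat.nrow();
  std::vector<int> ecode(m), gcode(n);
  for (int t = 0; t < m; ++t) {
    ecode[t] = code[(unsigned char) est[t]];
    if (ecode[t] < 0)
      stop("character '%c' not covered by the scoring matrix", est[t]);
  }
  for (int t = 0; t < n; ++t) {
    gcode[t] = code[(unsigned char) genome[t]];
    if (gcode[t] < 0)
      stop("character '%c' not covered by the scoring matrix", genome[t]);
  }

  bool integral = intron_penalty < 1e8 && noncanon_extra < 1e8 &&
    gap_open == (int) gap_open && gap_ext == (int) gap_ext &&
    intron_penalty == (int) intron_penalty &&
    noncanon_extra == (int) noncanon_extra;
  if (integral)
    for (int t = 0; t < nc * nc && integral; ++t) {
      const double v = submat[t];
      if (v != (int) v) integral = false;
    }

  if (integral) {
    std::vector<int> S(nc * nc);
    for (int a = 0; a < nc; ++a)
      for (int b = 0; b < nc; ++b) S[a * nc + b] = (int) submat(a, b);
    return spliced_core<int>(est, genome, S, nc, ecode, gcode,
                             (int) gap_open, (int) gap_ext,
                             (int) intron_penalty, (int) noncanon_extra,
                             min_intron);
  }
  std::vector<double> S(nc * nc);
  for (int a = 0; a < nc; ++a)
    for (int b = 0; b < nc; ++b) S[a * nc + b] = submat(a, b);
  return spliced_core<double>(est, genome, S, nc, ecode, gcode,
                              gap_open, gap_ext, intron_penalty,
                              noncanon_extra, min_intron);
}
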