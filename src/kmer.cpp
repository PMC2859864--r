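#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Shared-word prescreens used to gate which sequence pairs are handed to
// the quadratic aligners (clustering, redundancy collapse, database search,
// genome location). Words containing characters outside the alphabet and
// single-letter repeats are skipped; words occurring in more than max_occ
// sequences (e.g. poly(A) words) are dropped as uninformative.

static std::vector<int64_t> seq_codes(const std::string &s, int k,
                                      const std::vector<int> &code, int base) {
  std::vector<int64_t> out;
  const int L = (int) s.size();
  if (L < k) return out;
  for (int p = 0; p + k <= L; ++p) {
    int64_t c = 0; bool ok = true, homo = true;
    for (int t = 0; t < k; ++t) {
      const int v = code[(unsigned char) s[p + t]];
      if (v < 0) { ok = false; break; }
      if (t > 0 && s[p + t] != s[p]) homo = false;
      c = c * base + v;
    }
    if (ok && !homo) out.push_back(c);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  return out;
}

static std::vector<int> make_code(const std::string &alphabet) {
  std::vector<int> code(256, -1);
  for (size_t t = 0; t < alphabet.size(); ++t)
    code[(unsigned char) alphabet[t]] = (int) t;
  return code;
}

// Count distinct shared k-words for pairs (query i, subject j).
// If same_set is true, a and b must be the same vector and only pairs
// i < j are reported.
// [[Rcpp::export]]
DataFrame kmer_shared_pairs(CharacterVector a, CharacterVector b, int k,
                            std::string alphabet, int max_occ, bool same_set) {
  const int base = (int) alphabet.size();
  const std::vector<int> code = make_code(alphabet);
  const int na = a.size(), nb = b.size();

  std::unordered_map<int64_t, std::vector<int> > occ; // code -> ids (a: i, b: na+j)
  for (int i = 0; i < na; ++i) {
    const std::string s = as<std::string>(a[i]);
    for (int64_t c : seq_codes(s, k, code, base)) occ[c].push_back(i);
  }
  if (!same_set) {
    for (int j = 0; j < nb; ++j) {
      const std::string s = as<std::string>(b[j]);
      for (int64_t c : seq_codes(s, k, code, base)) occ[c].push_back(na + j);
    }
  }

  std::unordered_map<int64_t, int> pairs;
  for (auto &kv : occ) {
    const std::vector<int> &ids = kv.second;
    if ((int) ids.size() > max_occ) continue;
    if (same_set) {
      for (size_t x = 0; x < ids.size(); ++x)
        for (size_t y = x + 1; y < ids.size(); ++y)
          ++pairs[(int64_t) ids[x] * nb + ids[y]];
    } else {
      for (size_t x = 0; x < ids.size() && ids[x] < na; ++x)
        for (size_t y = 0; y < ids.size(); ++y)
          if (ids[y] >= na)
            ++pairs[(int64_t) ids[x] * nb + (ids[y] - na)];
    }
  }

  const int np = (int) pairs.size();
  IntegerVector qi(np), sj(np), shared(np);
  int t = 0;
  for (auto &kv : pairs) {
    qi[t] = (int)(kv.first / nb) + 1;
    sj[t] = (int)(kv.first % nb) + 1;
    shared[t] = kv.second;
    ++t;
  }
  return DataFrame::create(_["query"] = qi, _["subject"] = sj,
                           _["shared"] = shared);
}

// For each query: shared-word count and matched-position span on every
// subject (used to locate a cDNA on genome scaffolds before spliced
// alignment). Returns one row per (query, subject) with at least min_shared
// shared words. max_occ caps how many subject positions a word may have.
// [[Rcpp::export]]
DataFrame kmer_locate(CharacterVector queries, CharacterVector subjects,
                      int k, std::string alphabet, int max_occ,
                      int min_shared) {
  const int base = (int) alphabet.size();
  const std::vector<int> code = make_code(alphabet);
  const int nq = queries.size(), ns = subjects.size();

  // subject word index: code -> (subject, pos) pairs
  std::unordered_map<int64_t, std::vector<std::pair<int,int> > > idx;
  for (int j = 0; j < ns; ++j) {
    const std::string s = as<std::string>(subjects[j]);
    const int L = (int) s.size();
    for (int p = 0; p + k <= L; ++p) {
      int64_t c = 0; bool ok = true, homo = true;
      for (int t = 0; t < k; ++t) {
        const int v = code[(unsigned char) s[p + t]];
        if (v < 0) { ok = false; break; }
        if (t > 0 && s[p + t] != s[p]) homo = false;
        c = c * base + v;
      }
      if (ok && !homo) idx[c].push_back(std::make_pair(j, p + 1));
    }
  }

  std::vector<int> rq, rs, rcount, rmin, rmax;
  for (int i = 0; i < nq; ++i) {
    const std::string q = as<std::string>(queries[i]);
    std::vector<int> cnt(ns, 0), mn(ns, 0), mx(ns, 0);
    for (int64_t c : seq_codes(q, k, code, base)) {
      auto it = idx.find(c);
      if (it == idx.end()) continue;
      if ((int) it->second.size() > max_occ) continue;
      for (auto &pr : it->second) {
        const int j = pr.first, p = pr.second;
        if (cnt[j] == 0) { mn[j] = p; mx[j] = p; }
        else { if (p < mn[j]) mn[j] = p; if (p > mx[j]) mx[j] = p; }
        ++cnt[j];
      }
    }
    for (int j = 0; j < ns; ++j) {
      if (cnt[j] >= min_shared) {
        rq.push_back(i + 1); rs.push_back(j + 1);
        rcount.push_back(cnt[j]); rmin.push_back(mn[j]);
        rmax.push_back(mx[j] + k - 1);
      }
    }
  }
  return DataFrame::create(_["query"] = wrap(rq), _["subject"] = wrap(rs),
                           _["shared"] = wrap(rcount),
                           _["span_start"] = wrap(rmin),
                           _["span_end"] = wrap(rmax));
}

// reverse complement over the A/C/G/T/N/X alphabet (case-sensitive,
// uppercase input)
// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  std::vector<char> comp(256, 0);
  const std::string from = "ACGTNX", to = "TGCANX";
  for (size_t t = 0; t < from.size(); ++t)
    comp[(unsigned char) from[t]] = to[t];
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i) {
    std::string s = as<std::string>(x[i]);
    std::string r(s.size(), 0);
    for (size_t p = 0; p < s.size(); ++p) {
      const char c = comp[(unsigned char) s[s.size() - 1 - p]];
      if (!c) stop("cannot reverse-complement character '%c'", s[s.size() - 1 - p]);
      r[p] = c;
    }
    out[i] = r;
  }
  out.attr("names") = x.attr("names");
  return out;
}
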