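#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Greedy longest-previous-factor factorization of the concatenation of
// `seqs`.  Copy sources must start strictly before the target, end at or
// before the target start (no self-overlap) and neither source nor target
// may cross a sequence boundary.  Returns one row per phrase:
//   kind (1 = literal, 2 = copy), seq (1-based sequence index),
//   start (1-based position within the sequence), length,
//   src (1-based position of the copy source in the boundary-free
//   concatenation; NA for literals).
// Adjacent single-character literals are merged into literal runs.
// [[Rcpp::export]]
IntegerMatrix lz_parse_cpp(CharacterVector seqs) {
  std::string text;
  std::vector<int> sid, local;
  for (int s = 0; s < seqs.size(); ++s) {
    std::string x = as<std::string>(seqs[s]);
    for (size_t i = 0; i < x.size(); ++i) {
      text += x[i];
      sid.push_back(s + 1);
      local.push_back((int)i + 1);
    }
  }
  const int n = (int)text.size();
  std::vector<int> kind, seq, start, len, src;
  int i = 0;
  while (i < n) {
    int best = 0, bestj = -1;
    for (int j = 0; j < i; ++j) {
      if (i - j <= best) break;  // non-overlap cap: l <= i - j
      if (text[j] != text[i]) continue;
      int cap = i - j;
      int l = 0;
      while (l < cap && i + l < n && text[j + l] == text[i + l] &&
             sid[j + l] == sid[j] && sid[i + l] == sid[i])
        ++l;
      if (l > best) { best = l; bestj = j; }
    }
    if (best >= 1) {
      kind.push_back(2); seq.push_back(sid[i]); start.push_back(local[i]);
      len.push_back(best); src.push_back(bestj + 1);
      i += best;
    } else {
      if (!kind.empty() && kind.back() == 1 && seq.back() == sid[i] &&
          start.back() + len.back() == local[i]) {
        len.back() += 1;
      } else {
        kind.push_back(1); seq.push_back(sid[i]); start.push_back(local[i]);
        len.push_back(1); src.push_back(NA_INTEGER);
      }
      i += 1;
    }
  }
  IntegerMatrix out((int)kind.size(), 5);
  for (int r = 0; r < (int)kind.size(); ++r) {
    out(r, 0) = kind[r]; out(r, 1) = seq[r]; out(r, 2) = start[r];
    out(r, 3) = len[r];  out(r, 4) = src[r];
  }
  colnames(out) = CharacterVector::create("kind", "seq", "start", "length", "src");
  return out;
}

// Unit-cost Levenshtein distance, two-row DP.
// [[Rcpp::export]]
int edit_distance_cpp(std::string a, std::string b) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = sub < del ? (sub < ins ? sub : ins) : (del < ins ? del : ins);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
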