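#include <Rcpp.h>
using namespace Rcpp;

// Hamming distance with 'N' mismatching everything; assumes equal lengths.
static inline int hamming_capped(const char* a, const char* b, int len, int cap) {
  int d = 0;
  for (int i = 0; i < len; ++i) {
    char x = a[i], y = b[i];
    if (x != y || x == 'N' || y == 'N') {
      if (++d > cap) return d;
    }
  }
  return d;
}

// Scan each read for the pattern at every offset, returning the leftmost
// offset (1-based; NA if none) achieving the minimum Hamming distance,
// provided that minimum is <= max_mismatches. anchor0 restricts to offset 0.
// [[Rcpp::export]]
List cpp_scan_pattern(CharacterVector reads, std::string pattern,
                      int max_mismatches, bool anchor0) {
  const int n = reads.size();
  const int plen = (int) pattern.size();
  const char* pat = pattern.c_str();
  IntegerVector offset(n), dist(n);
  for (int r = 0; r < n; ++r) {
    if (reads[r] == NA_STRING) { offset[r] = NA_INTEGER; dist[r] = NA_INTEGER; continue; }
    const char* s = CHAR(STRING_ELT(reads, r));
    int slen = (int) LENGTH(STRING_ELT(reads, r));
    int best_off = NA_INTEGER, best_d = max_mismatches + 1;
    int max_off = anchor0 ? 0 : slen - plen;
    for (int o = 0; o <= max_off && best_d > 0; ++o) {
      if (o + plen > slen) break;
      // cap at best_d - 1: only a strict improvement can change the answer,
      // which also enforces the leftmost tie-break
      int d = hamming_capped(s + o, pat, plen, best_d - 1);
      if (d < best_d) { best_d = d; best_off = o + 1; }
    }
    if (best_d > max_mismatches) { offset[r] = NA_INTEGER; dist[r] = NA_INTEGER; }
    else { offset[r] = best_off; dist[r] = best_d; }
  }
  return List::create(_["offset"] = offset, _["mismatches"] = dist);
}

// Pairwise Hamming distance for equal-length string vectors ('N' never matches).
// [[Rcpp::export]]
IntegerVector cpp_hamming(CharacterVector a, CharacterVector b) {
  const int n = a.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* x = CHAR(STRING_ELT(a, i));
    const char* y = CHAR(STRING_ELT(b, i));
    int len = (int) LENGTH(STRING_ELT(a, i));
    out[i] = hamming_capped(x, y, len, len);
  }
  return out;
}

// Per-base substitution errors at a fixed rate, drawn from R's RNG so results
// are reproducible under set.seed(). Substitutions are uniform over the three
// other bases.
// [[Rcpp::export]]
CharacterVector cpp_mutate_bases(CharacterVector seqs, double rate) {
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  const int n = seqs.size();
  CharacterVector out(n);
  RNGScope scope;
  std::string buf;
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    int len = (int) LENGTH(STRING_ELT(seqs, i));
    buf.assign(s, len);
    for (int j = 0; j < len; ++j) {
      if (unif_rand() < rate) {
        char cur = buf[j];
        char nb;
        do { nb = BASES[(int) (unif_rand() * 4) & 3]; } while (nb == cur);
        buf[j] = nb;
      }
    }
    out[i] = buf;
  }
  return out;
}
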