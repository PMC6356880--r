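#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Best ungapped placement of each read on a reference: exhaustive scan over
// all offsets, minimizing mismatch count (ties broken by smallest offset).
// Offsets with running mismatch count already above both the current best and
// max_mismatch are abandoned early; this cannot change the reported result.
// Returns 0-based offsets (-1 = no placement within max_mismatch) and, for
// placed reads, the 1-based read positions of the mismatches.
// [[Rcpp::export(name = ".align_ungapped_cpp")]]
List align_ungapped_cpp(CharacterVector reads, std::string ref, int max_mismatch) {
  const int nref = (int) ref.size();
  const int n = reads.size();
  IntegerVector best_off(n), best_mm(n);
  List mmpos(n);
  for (int i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    const int len = (int) rd.size();
    int boff = -1, bmm = len + 1;
    if (len <= nref) {
      const int cap0 = max_mismatch;
      for (int off = 0; off + len <= nref; ++off) {
        int cap = bmm - 1 < cap0 ? bmm - 1 : cap0;
        int mm = 0;
        for (int k = 0; k < len; ++k) {
          if (rd[k] != ref[off + k]) {
            if (++mm > cap) break;
          }
        }
        if (mm < bmm) { bmm = mm; boff = off; }
        if (bmm == 0) break;
      }
    }
    if (boff < 0 || bmm > max_mismatch) {
      best_off[i] = -1;
      best_mm[i] = NA_INTEGER;
      mmpos[i] = IntegerVector(0);
    } else {
      best_off[i] = boff;
      best_mm[i] = bmm;
      std::vector<int> pos;
      for (int k = 0; k < len; ++k)
        if (rd[k] != ref[boff + k]) pos.push_back(k + 1);
      mmpos[i] = wrap(pos);
    }
  }
  return List::create(_["offset"] = best_off, _["mismatches"] = best_mm,
                      _["positions"] = mmpos);
}

static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// Nussinov maximum base-pairing dynamic program over AU/GC/GU pairs with a
// minimum hairpin loop. Returns the full DP matrix; the traceback is done in
// R where the deterministic tie-break order is easier to audit.
// [[Rcpp::export(name = ".nussinov_dp_cpp")]]
IntegerMatrix nussinov_dp_cpp(std::string seq, int min_loop) {
  const int n = (int) seq.size();
  IntegerMatrix dp(n, n);
  for (int span = 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = dp(i + 1, j);                      // i unpaired
      if (dp(i, j - 1) > best) best = dp(i, j - 1); // j unpaired
      if (can_pair(seq[i], seq[j]) && j - i - 1 >= min_loop) {
        int v = (i + 1 <= j - 1 ? dp(i + 1, j - 1) : 0) + 1;
        if (v > best) best = v;
      }
      for (int k = i + 1; k < j; ++k) {
        int v = dp(i, k) + dp(k + 1, j);
        if (v > best) best = v;
      }
      dp(i, j) = best;
    }
  }
  return dp;
}
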