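#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Offset-aware placement of a short read on hairpin precursors.
//
// For each mature arm and each 5' offset in [-max_shift5, max_shift5], the
// read is compared to the templated hairpin starting at mature_start +
// offset5; every admissible split of the read into a templated body plus a
// non-templated 3' tail (<= max_tail) is scored. The placement minimizing
// score_key = (n_subst, tail_len, |offset5| + |offset3|) wins; ties break
// by smaller |offset5|, then mature order (callers pass matures sorted
// lexicographically by id), then offset5, then offset3. A tail base that
// matches the template is never preferred over the templated reading
// because tail_len is minimized before the offset term.

struct Candidate {
  int mature;       // index into mature arrays
  int off5, off3;
  int n_subst, tail_len;
  std::vector<int> subst_pos;   // mature-relative (0-based)
  std::vector<char> subst_ref, subst_read;
  bool valid = false;
};

static inline bool better(const Candidate& a, const Candidate& b) {
  // true if a strictly better than b
  if (!b.valid) return a.valid;
  if (!a.valid) return false;
  if (a.n_subst != b.n_subst) return a.n_subst < b.n_subst;
  if (a.tail_len != b.tail_len) return a.tail_len < b.tail_len;
  int ao = std::abs(a.off5) + std::abs(a.off3);
  int bo = std::abs(b.off5) + std::abs(b.off3);
  if (ao != bo) return ao < bo;
  if (std::abs(a.off5) != std::abs(b.off5))
    return std::abs(a.off5) < std::abs(b.off5);
  if (a.mature != b.mature) return a.mature < b.mature;
  if (a.off5 != b.off5) return a.off5 < b.off5;
  return a.off3 < b.off3;
}

// [[Rcpp::export(name = ".align_reads_cpp")]]
DataFrame align_reads_cpp(CharacterVector reads,
                          CharacterVector hairpin_seq,
                          IntegerVector mstart, IntegerVector mend,
                          int max_shift5, int max_shift3,
                          int max_tail, int max_mismatch) {
  int nr = reads.size(), nm = hairpin_seq.size();
  std::vector<std::string> hp(nm);
  for (int j = 0; j < nm; ++j) hp[j] = as<std::string>(hairpin_seq[j]);

  IntegerVector out_mature(nr), out_off5(nr), out_off3(nr),
      out_nsub(nr);
  CharacterVector out_tail(nr), out_subst(nr);
  LogicalVector out_aligned(nr);

  for (int i = 0; i < nr; ++i) {
    std::string read = as<std::string>(reads[i]);
    int L = (int)read.size();
    Candidate best;
    for (int j = 0; j < nm; ++j) {
      const std::string& h = hp[j];
      int hl = (int)h.size();
      int ms = mstart[j], me = mend[j];
      for (int off5 = -max_shift5; off5 <= max_shift5; ++off5) {
        int p0 = ms + off5;
        if (p0 < 0) continue;               // no 5' overhang off the hairpin
        for (int t = 0; t <= max_tail && t < L; ++t) {
          int T = L - t;                    // templated body length
          if (p0 + T > hl) continue;        // tail must absorb any overhang
          int off3 = p0 + T - me;
          if (off3 < -max_shift3 || off3 > max_shift3) continue;
          Candidate c;
          c.mature = j; c.off5 = off5; c.off3 = off3;
          c.tail_len = t; c.n_subst = 0;
          bool ok = true;
          for (int k = 0; k < T; ++k) {
            if (read[k] != h[p0 + k]) {
              if (++c.n_subst > max_mismatch) { ok = false; break; }
              c.subst_pos.push_back(off5 + k);  // mature-relative
              c.subst_ref.push_back(h[p0 + k]);
              c.subst_read.push_back(read[k]);
            }
          }
          if (!ok) continue;
          c.valid = true;
          if (better(c, best)) best = c;
        }
      }
    }
    if (best.valid) {
      out_aligned[i] = true;
      out_mature[i] = best.mature + 1;      // 1-based index for R
      out_off5[i] = best.off5;
      out_off3[i] = best.off3;
      out_nsub[i] = best.n_subst;
      int T = L - best.tail_len;
      std::string rd = as<std::string>(reads[i]);
      out_tail[i] = rd.substr(T);
      std::string sub;
      for (size_t k = 0; k < best.subst_pos.size(); ++k) {
        if (k) sub += ",";
        sub += std::to_string(best.subst_pos[k]);
        sub += ':'; sub += best.subst_ref[k];
        sub += '>'; sub += best.subst_read[k];
      }
      out_subst[i] = sub;
    } else {
      out_aligned[i] = false;
      out_mature[i] = NA_INTEGER;
      out_off5[i] = NA_INTEGER;
      out_off3[i] = NA_INTEGER;
      out_nsub[i] = NA_INTEGER;
      out_tail[i] = NA_STRING;
      out_subst[i] = NA_STRING;
    }
  }
  return DataFrame::create(
      _["aligned"] = out_aligned, _["mature_idx"] = out_mature,
      _["offset5"] = out_off5, _["offset3"] = out_off3,
      _["n_subst"] = out_nsub, _["nta_tail"] = out_tail,
      _["substitutions"] = out_subst,
      _["stringsAsFactors"] = false);
}

// Hamming-window contaminant matcher: does the read occur as a substring
// of any decoy with at most max_mismatch substitutions (no indels)?
// [[Rcpp::export(name = ".match_decoys_cpp")]]
LogicalVector match_decoys_cpp(CharacterVector reads,
                               CharacterVector decoys,
                               int max_mismatch) {
  int nr = reads.size(), nd = decoys.size();
  std::vector<std::string> dec(nd);
  for (int j = 0; j < nd; ++j) dec[j] = as<std::string>(decoys[j]);
  LogicalVector hit(nr);
  for (int i = 0; i < nr; ++i) {
    std::string r = as<std::string>(reads[i]);
    int L = (int)r.size();
    bool found = false;
    for (int j = 0; j < nd && !found; ++j) {
      const std::string& d = dec[j];
      int dl = (int)d.size();
      for (int p = 0; p + L <= dl && !found; ++p) {
        int mm = 0;
        for (int k = 0; k < L; ++k) {
          if (r[k] != d[p + k] && ++mm > max_mismatch) break;
        }
        if (mm <= max_mismatch) found = true;
      }
    }
    hit[i] = found;
  }
  return hit;
}
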