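#include <Rcpp.h>
using namespace Rcpp;

// IUPAC nucleotide codes as 4-bit masks: A=1, C=2, G=4, T=8.
// '\0' (mask 0) marks an invalid symbol and never matches.
static inline int iupac_mask(char c) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 4;
    case 'T': case 't': return 8;
    case 'R': case 'r': return 5;   // A/G
    case 'Y': case 'y': return 10;  // C/T
    case 'S': case 's': return 6;   // C/G
    case 'W': case 'w': return 9;   // A/T
    case 'K': case 'k': return 12;  // G/T
    case 'M': case 'm': return 3;   // A/C
    case 'B': case 'b': return 14;  // C/G/T
    case 'D': case 'd': return 13;  // A/G/T
    case 'H': case 'h': return 11;  // A/C/T
    case 'V': case 'v': return 7;   // A/C/G
    case 'N': case 'n': return 15;
    default: return 0;
  }
}

// [[Rcpp::export(name = ".iupac_masks")]]
IntegerVector iupac_masks_cpp(std::string seq) {
  IntegerVector out(seq.size());
  for (size_t i = 0; i < seq.size(); ++i) out[i] = iupac_mask(seq[i]);
  return out;
}

// Slide `pattern` (IUPAC-degenerate) along `subject`; at every offset count
// positions whose subject base is outside the pattern's degenerate class.
// A subject 'N' matches any pattern symbol when subject_n_matches is true,
// otherwise it counts as a mismatch. Returns 0-based starts, mismatch counts
// and per-window subject-N counts for windows with <= max_mismatch.
// [[Rcpp::export(name = ".scan_iupac")]]
List scan_iupac_cpp(std::string subject, std::string pattern,
                    int max_mismatch, bool subject_n_matches) {
  const int n = subject.size(), m = pattern.size();
  std::vector<int> pmask(m), smask(n);
  std::vector<char> is_n(n);
  for (int j = 0; j < m; ++j) {
    pmask[j] = iupac_mask(pattern[j]);
    if (pmask[j] == 0)
      stop("invalid symbol '%c' in pattern", pattern[j]);
  }
  for (int i = 0; i < n; ++i) {
    char c = subject[i];
    smask[i] = iupac_mask(c);
    is_n[i] = (c == 'N' || c == 'n');
  }
  std::vector<int> starts, mm, ncnt;
  for (int s = 0; s + m <= n; ++s) {
    int bad = 0, nn = 0;
    for (int j = 0; j < m; ++j) {
      const int sm = smask[s + j];
      if (is_n[s + j]) {
        ++nn;
        if (!subject_n_matches) ++bad;
      } else if ((sm & pmask[j]) == 0 || sm == 0) {
        ++bad;
      }
      if (bad > max_mismatch) break;
    }
    if (bad <= max_mismatch) {
      starts.push_back(s);
      mm.push_back(bad);
      ncnt.push_back(nn);
    }
  }
  return List::create(_["start"] = wrap(starts), _["mismatches"] = wrap(mm),
                      _["n_count"] = wrap(ncnt));
}

// Batch version of the scan over many subjects (e.g. all reads at once):
// returns the 1-based subject index alongside each hit.
// [[Rcpp::export(name = ".scan_iupac_many")]]
List scan_iupac_many_cpp(CharacterVector subjects, std::string pattern,
                         int max_mismatch, bool subject_n_matches) {
  const int m = pattern.size();
  std::vector<int> pmask(m);
  for (int j = 0; j < m; ++j) {
    pmask[j] = iupac_mask(pattern[j]);
    if (pmask[j] == 0)
      stop("invalid symbol '%c' in pattern", pattern[j]);
  }
  std::vector<int> oseq, ostart, omm, onn;
  for (int si = 0; si < subjects.size(); ++si) {
    std::string subject = as<std::string>(subjects[si]);
    const int n = subject.size();
    if (n < m) continue;
    std::vector<int> smask(n);
    std::vector<char> is_n(n);
    for (int i = 0; i < n; ++i) {
      smask[i] = iupac_mask(subject[i]);
      is_n[i] = (subject[i] == 'N' || subject[i] == 'n');
    }
    for (int s = 0; s + m <= n; ++s) {
      int bad = 0, nn = 0;
      for (int j = 0; j < m; ++j) {
        const int sm = smask[s + j];
        if (is_n[s + j]) {
          ++nn;
          if (!subject_n_matches) ++bad;
        } else if ((sm & pmask[j]) == 0 || sm == 0) {
          ++bad;
        }
        if (bad > max_mismatch) break;
      }
      if (bad <= max_mismatch) {
        oseq.push_back(si + 1);
        ostart.push_back(s);
        omm.push_back(bad);
        onn.push_back(nn);
      }
    }
  }
  return List::create(_["seq"] = wrap(oseq), _["start"] = wrap(ostart),
                      _["mismatches"] = wrap(omm),
                      _["n_count"] = wrap(onn));
}

// Best ungapped overlap of two concrete sequences: internal gaps disallowed,
// terminal overhangs free. Returns the maximal number of matching positions,
// the offset of b relative to a achieving it, and the overlap length there.
// Ties broken toward larger overlap, then smaller |offset|.
// [[Rcpp::export(name = ".overlap_align")]]
List overlap_align_cpp(std::string a, std::string b) {
  const int na = a.size(), nb = b.size();
  std::vector<int> am(na), bm(nb);
  for (int i = 0; i < na; ++i) am[i] = iupac_mask(a[i]);
  for (int i = 0; i < nb; ++i) bm[i] = iupac_mask(b[i]);
  int best = -1, best_off = 0, best_ov = 0;
  for (int off = -(nb - 1); off <= na - 1; ++off) {
    // b[j] aligns with a[j + off]
    int lo = std::max(0, -off), hi = std::min(nb, na - off);
    int ov = hi - lo;
    if (ov <= 0) continue;
    int match = 0;
    for (int j = lo; j < hi; ++j)
      if ((bm[j] & am[j + off]) != 0 && bm[j] != 0 && am[j + off] != 0)
        ++match;
    bool better = match > best ||
      (match == best && (ov > best_ov ||
        (ov == best_ov && std::abs(off) < std::abs(best_off))));
    if (better) { best = match; best_off = off; best_ov = ov; }
  }
  return List::create(_["matches"] = best, _["offset"] = best_off,
                      _["overlap"] = best_ov);
}

// All-pairs matching of sequences under the "fewer than two mismatches"
// rule. Equal-length pairs (when hamming_if_equal) are compared at offset 0
// only (Hamming); unequal-length pairs by the best ungapped end-gap-free
// overlap subject to total overhang <= max_overhang and overlap >=
// min_overlap. Returns 1-based index pairs i < j with the best mismatch
// count and overlap length for pairs meeting mismatches <= max_mm.
// [[Rcpp::export(name = ".match_pairs")]]
List match_pairs_cpp(CharacterVector seqs, int max_mm, int max_overhang,
                     int min_overlap, bool hamming_if_equal) {
  const int n = seqs.size();
  std::vector<std::vector<int> > masks(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    masks[i].resize(s.size());
    for (size_t k = 0; k < s.size(); ++k) masks[i][k] = iupac_mask(s[k]);
  }
  std::vector<int> oi, oj, omm, oov;
  for (int i = 0; i < n; ++i) {
    const int na = masks[i].size();
    for (int j = i + 1; j < n; ++j) {
      const int nb = masks[j].size();
      int best_mm = -1, best_ov = 0;
      if (na == nb && hamming_if_equal) {
        int d = 0;
        for (int k = 0; k < na; ++k)
          if ((masks[i][k] & masks[j][k]) == 0 || masks[i][k] == 0 ||
              masks[j][k] == 0) ++d;
        if (na >= min_overlap) { best_mm = d; best_ov = na; }
      } else {
        for (int off = -(nb - 1); off <= na - 1; ++off) {
          int lo = std::max(0, -off), hi = std::min(nb, na - off);
          int ov = hi - lo;
          if (ov < min_overlap) continue;
          int overhang = (na - ov) + (nb - ov);
          if (overhang > max_overhang) continue;
          int d = 0;
          for (int k = lo; k < hi; ++k)
            if ((masks[j][k] & masks[i][k + off]) == 0 ||
                masks[j][k] == 0 || masks[i][k + off] == 0) ++d;
          if (best_mm < 0 || d < best_mm ||
              (d == best_mm && ov > best_ov)) {
            best_mm = d; best_ov = ov;
          }
        }
      }
      if (best_mm >= 0 && best_mm <= max_mm) {
        oi.push_back(i + 1); oj.push_back(j + 1);
        omm.push_back(best_mm); oov.push_back(best_ov);
      }
    }
  }
  return List::create(_["i"] = wrap(oi), _["j"] = wrap(oj),
                      _["mismatches"] = wrap(omm),
                      _["overlap"] = wrap(oov));
}

// Hamming distance of equal-length sequences (exact symbol comparison on
// masks; any symbol outside ACGT only matches by class intersection).
// [[Rcpp::export(name = ".hamming")]]
int hamming_cpp(std::string a, std::string b) {
  if (a.size() != b.size()) stop("sequences must have equal length");
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    int am = iupac_mask(a[i]), bm = iupac_mask(b[i]);
    if ((am & bm) == 0 || am == 0 || bm == 0) ++d;
  }
  return d;
}
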