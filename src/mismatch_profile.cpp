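#include <Rcpp.h>
using namespace Rcpp;

// Mismatch count at every start of a fixed run of position sets over a
// sequence of UTF-8 base codes. `bad` has 256 rows (indexed by code) and
// one column per pattern position; free positions (spacer / any-base)
// are all-FALSE columns and contribute nothing.
static std::vector<int> profile(const IntegerVector& ints,
                                const LogicalMatrix& bad) {
  const int L = ints.size();
  const int w = bad.ncol();
  const int n = L - w + 1;
  std::vector<int> mm(n > 0 ? n : 0, 0);
  if (n < 1) return mm;
  for (int j = 0; j < w; ++j) {
    bool informative = false;
    for (int c = 0; c < 256; ++c)
      if (bad(c, j)) { informative = true; break; }
    if (!informative) continue;
    for (int s = 0; s < n; ++s) {
      const int code = ints[s + j];
      if (code >= 0 && code < 256 && bad(code, j)) ++mm[s];
    }
  }
  return mm;
}

// [[Rcpp::export(name = ".mismatch_profile_cpp")]]
IntegerVector mismatch_profile_cpp(IntegerVector ints, LogicalMatrix bad) {
  std::vector<int> mm = profile(ints, bad);
  return wrap(mm);
}

// One-strand scan. For a halfsite pass an all-zero-column badB with
// spMin = spMax = -1: placements are starts where the badA profile is
// within budget. For a direct repeat, placements combine the two halfsite
// profiles at every spacer in [spMin, spMax]. Returns 0-based starts,
// realized spacers (NA for halfsites) and mismatch counts.
// [[Rcpp::export(name = ".scan_kernel_cpp")]]
List scan_kernel_cpp(IntegerVector ints, LogicalMatrix badA,
                     LogicalMatrix badB, int spMin, int spMax, int maxmm) {
  std::vector<int> start0, spacer, mism;
  const std::vector<int> mma = profile(ints, badA);
  if (spMin < 0) {  // halfsite
    for (int s = 0; s < (int)mma.size(); ++s) {
      if (mma[s] <= maxmm) {
        start0.push_back(s);
        spacer.push_back(NA_INTEGER);
        mism.push_back(mma[s]);
      }
    }
  } else {
    const int wa = badA.ncol();
    const int wb = badB.ncol();
    const std::vector<int> mmb = profile(ints, badB);
    const int L = ints.size();
    for (int sp = spMin; sp <= spMax; ++sp) {
      const int w = wa + sp + wb;
      const int n = L - w + 1;
      for (int s = 0; s < n; ++s) {
        const int tot = mma[s] + mmb[s + wa + sp];
        if (tot <= maxmm) {
          start0.push_back(s);
          spacer.push_back(sp);
          mism.push_back(tot);
        }
      }
    }
  }
  return List::create(_["start0"] = wrap(start0),
                      _["spacer"] = wrap(spacer),
                      _["mismatches"] = wrap(mism));
}
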