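#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Semi-global affine-gap alignment: the query (contig) is consumed end-to-end,
// unaligned reference prefix/suffix are free. A gap of length L costs
// gap_open + L * gap_extend. Tie-breaking is frozen for determinism:
// the alignment ends at the leftmost maximal cell of the final row, and
// traceback prefers M, then D (reference-consuming gap), then I.
//
// States: M diagonal, D gap-in-query (consumes reference, CIGAR D),
//         I gap-in-reference (consumes query, CIGAR I).

static const int NEG = -1000000000;

// [[Rcpp::export]]
List semiglobal_align_cpp(const std::string& query, const std::string& ref,
                          int match, int mismatch, int gap_open, int gap_extend) {
  const int m = (int)query.size();
  const int n = (int)ref.size();
  if (m == 0 || n == 0 || m > n)
    return List::create(_["score"] = NA_INTEGER);

  const size_t W = (size_t)n + 1;
  std::vector<int> Mm((size_t)(m + 1) * W, NEG), Dm(Mm), Im(Mm);
  // traceback: 0 = stop/start, 1 = from M, 2 = from D, 3 = from I
  std::vector<unsigned char> tbM((size_t)(m + 1) * W, 0), tbD(tbM), tbI(tbM);

  for (int j = 0; j <= n; ++j) Mm[j] = 0;  // free reference prefix

  for (int i = 1; i <= m; ++i) {
    const size_t ri = (size_t)i * W, pi = (size_t)(i - 1) * W;
    for (int j = 0; j <= n; ++j) {
      if (j > 0) {
        // M: consume query[i-1] against ref[j-1]
        int sub = (query[i - 1] == ref[j - 1]) ? match : -mismatch;
        int best = Mm[pi + j - 1]; unsigned char via = 1;
        if (Dm[pi + j - 1] > best) { best = Dm[pi + j - 1]; via = 2; }
        if (Im[pi + j - 1] > best) { best = Im[pi + j - 1]; via = 3; }
        Mm[ri + j] = (best <= NEG / 2) ? NEG : best + sub;
        tbM[ri + j] = via;
        // D: consume ref[j-1] only (only meaningful once query started)
        int opn = Mm[ri + j - 1]; unsigned char dvia = 1;
        if (Im[ri + j - 1] > opn) { opn = Im[ri + j - 1]; dvia = 3; }
        opn = (opn <= NEG / 2) ? NEG : opn - gap_open - gap_extend;
        int ext = (Dm[ri + j - 1] <= NEG / 2) ? NEG : Dm[ri + j - 1] - gap_extend;
        if (opn >= ext) { Dm[ri + j] = opn; tbD[ri + j] = dvia; }
        else            { Dm[ri + j] = ext; tbD[ri + j] = 2; }
      }
      // I: consume query[i-1] only
      {
        int opn = Mm[pi + j]; unsigned char ivia = 1;
        if (Dm[pi + j] > opn) { opn = Dm[pi + j]; ivia = 2; }
        opn = (opn <= NEG / 2) ? NEG : opn - gap_open - gap_extend;
        int ext = (Im[pi + j] <= NEG / 2) ? NEG : Im[pi + j] - gap_extend;
        if (opn >= ext) { Im[ri + j] = opn; tbI[ri + j] = ivia; }
        else            { Im[ri + j] = ext; tbI[ri + j] = 3; }
      }
    }
  }

  // pick end: leftmost j maximising the final-row score, state order M > D > I
  const size_t rm = (size_t)m * W;
  int bestScore = NEG, bestJ = -1; unsigned char bestState = 0;
  for (int j = 0; j <= n; ++j) {
    int s = Mm[rm + j]; unsigned char st = 1;
    if (Dm[rm + j] > s) { s = Dm[rm + j]; st = 2; }
    if (Im[rm + j] > s) { s = Im[rm + j]; st = 3; }
    if (s > bestScore) { bestScore = s; bestJ = j; bestState = st; }
  }
  if (bestScore <= NEG / 2) return List::create(_["score"] = NA_INTEGER);

  // traceback
  std::string ops; ops.reserve((size_t)m + 16);
  int i = m, j = bestJ; unsigned char st = bestState;
  while (i > 0 || (st == 2 && j > 0)) {
    if (st == 1) {          // M consumed query[i-1], ref[j-1]
      unsigned char via = tbM[(size_t)i * W + j];
      ops.push_back('M'); --i; --j; st = via;
      if (i == 0) break;
    } else if (st == 2) {   // D consumed ref[j-1]
      unsigned char via = tbD[(size_t)i * W + j];
      ops.push_back('D'); --j; st = via;
    } else {                // I consumed query[i-1]
      unsigned char via = tbI[(size_t)i * W + j];
      ops.push_back('I'); --i; st = via;
      if (i == 0) break;
    }
  }
  std::reverse(ops.begin(), ops.end());
  // strip any leading D (free reference prefix should absorb it; defensive)
  size_t lead = 0; while (lead < ops.size() && ops[lead] == 'D') { ++lead; ++j; }
  if (lead) ops.erase(0, lead);

  // run-length encode
  std::string cig;
  size_t p = 0;
  while (p < ops.size()) {
    size_t q = p; while (q < ops.size() && ops[q] == ops[p]) ++q;
    cig += std::to_string(q - p); cig.push_back(ops[p]); p = q;
  }

  return List::create(_["score"] = bestScore,
                      _["start"] = j,      // 0-based ref offset of first column
                      _["cigar"] = cig);
}

// Hamming mismatch counts of `read` laid on `target` at each 0-based offset.
// Offsets placing the read outside the target return NA.
// [[Rcpp::export]]
IntegerVector count_mismatches_cpp(const std::string& read, const std::string& target,
                                   IntegerVector offsets) {
  const int L = (int)read.size(), n = (int)target.size();
  IntegerVector out(offsets.size());
  for (int x = 0; x < offsets.size(); ++x) {
    int off = offsets[x];
    if (off == NA_INTEGER || off < 0 || off + L > n) { out[x] = NA_INTEGER; continue; }
    int mm = 0;
    for (int i = 0; i < L; ++i) if (read[i] != target[off + i]) ++mm;
    out[x] = mm;
  }
  return out;
}
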