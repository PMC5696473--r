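#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Unit-cost semi-global alignment of `adapter` inside each read:
// the adapter must be fully consumed (no free overhang), read flanks are
// free. Errors are substitutions + indels, each costing 1; 'N' in the read
// never matches. Returns an n x 3 integer matrix (start, end, n_errors),
// 0-based with exclusive end, NA-filled when no occurrence stays within
// max_err. Ties resolved by fewest errors, then leftmost start, then
// leftmost end.
// [[Rcpp::export(rng = false)]]
IntegerMatrix cpp_locate_adapter(CharacterVector reads, std::string adapter,
                                 int max_err) {
  const int m = adapter.size();
  const int nreads = reads.size();
  IntegerMatrix out(nreads, 3);

  std::vector<int> D((m + 1)), Dprev((m + 1));
  std::vector<int> S((m + 1)), Sprev((m + 1));

  for (int k = 0; k < nreads; ++k) {
    if (CharacterVector::is_na(reads[k])) {
      out(k, 0) = NA_INTEGER; out(k, 1) = NA_INTEGER; out(k, 2) = NA_INTEGER;
      continue;
    }
    std::string read = as<std::string>(reads[k]);
    const int n = read.size();

    int best_err = INT_MAX, best_start = -1, best_end = -1;

    // column j = 0: adapter prefix aligned before any read base consumed
    for (int i = 0; i <= m; ++i) { Dprev[i] = i; Sprev[i] = 0; }
    if (m <= max_err && Dprev[m] < best_err) {
      best_err = Dprev[m]; best_start = 0; best_end = 0;
    }

    for (int j = 1; j <= n; ++j) {
      D[0] = 0; S[0] = j;  // free read prefix: a match may start at j
      char rj = read[j - 1];
      for (int i = 1; i <= m; ++i) {
        char ai = adapter[i - 1];
        int sub_cost = (rj == ai && rj != 'N') ? 0 : 1;
        int d_diag = Dprev[i - 1] + sub_cost;  // consume both
        int d_up   = D[i - 1] + 1;             // adapter base unmatched
        int d_left = Dprev[i] + 1;             // read base inserted
        int d = d_diag, s = Sprev[i - 1];
        if (d_up < d || (d_up == d && S[i - 1] < s)) { d = d_up; s = S[i - 1]; }
        if (d_left < d || (d_left == d && Sprev[i] < s)) { d = d_left; s = Sprev[i]; }
        D[i] = d; S[i] = s;
      }
      if (D[m] <= max_err) {
        if (D[m] < best_err ||
            (D[m] == best_err && S[m] < best_start)) {
          best_err = D[m]; best_start = S[m]; best_end = j;
        }
      }
      std::swap(D, Dprev); std::swap(S, Sprev);
    }

    if (best_err <= max_err && best_start >= 0) {
      out(k, 0) = best_start; out(k, 1) = best_end; out(k, 2) = best_err;
    } else {
      out(k, 0) = NA_INTEGER; out(k, 1) = NA_INTEGER; out(k, 2) = NA_INTEGER;
    }
  }
  colnames(out) = CharacterVector::create("start", "end", "n_errors");
  return out;
}

static int sw_one(const std::string &a, const std::string &b, int match,
                  int mismatch, int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  const int NEG = INT_MIN / 4;
  std::vector<int> H(m + 1, 0), E(m + 1, NEG), Hprev(m + 1, 0);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    std::swap(H, Hprev);
    H[0] = 0;
    int F = NEG;  // gap in b (vertical) within row i
    for (int j = 1; j <= m; ++j) {
      bool ok = (a[i - 1] == b[j - 1]) && a[i - 1] != 'N';
      int diag = Hprev[j - 1] + (ok ? match : -mismatch);
      E[j] = std::max(E[j] - gap_extend, Hprev[j] - gap_open - gap_extend);
      F = std::max(F - gap_extend, H[j - 1] - gap_open - gap_extend);
      int h = diag;
      if (E[j] > h) h = E[j];
      if (F > h) h = F;
      if (h < 0) h = 0;
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// Smith-Waterman local alignment score with affine gaps (a gap of length
// k costs gap_open + k * gap_extend), elementwise over pairs. 'N' never
// matches.
// [[Rcpp::export(rng = false)]]
IntegerVector cpp_sw_scores(CharacterVector a, CharacterVector b, int match,
                            int mismatch, int gap_open, int gap_extend) {
  if (a.size() != b.size()) stop("length mismatch");
  IntegerVector out(a.size());
  for (int k = 0; k < a.size(); ++k) {
    out[k] = sw_one(as<std::string>(a[k]), as<std::string>(b[k]), match,
                    mismatch, gap_open, gap_extend);
  }
  return out;
}

// Score one candidate against a set of library sequences.
// [[Rcpp::export(rng = false)]]
IntegerVector cpp_sw_score_many(std::string candidate, CharacterVector refs,
                                int match, int mismatch, int gap_open,
                                int gap_extend) {
  IntegerVector out(refs.size());
  for (int k = 0; k < refs.size(); ++k) {
    out[k] = sw_one(candidate, as<std::string>(refs[k]), match, mismatch,
                    gap_open, gap_extend);
  }
  return out;
}
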