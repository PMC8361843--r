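#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Wraparound local alignment of `seq` against an unbounded tandem
// concatenation of `motif` (Benson-style WDP, Smith-Waterman local scoring).
// Columns wrap around the motif, so any number of copies and any phase are
// allowed.  Returns the best-scoring segment of `seq`:
//   start/end : 0-based half-open coordinates in seq
//   score     : local alignment score
//   matches   : matched columns
//   cols      : total aligned columns (matches + mismatches + gaps)
// Ties resolved toward the earliest start, then earliest end (deterministic).

struct WCell {
  int s;      // score
  int start;  // 0-based seq offset where the local segment begins
  int match;  // matched columns so far
  int cols;   // aligned columns so far
};

// [[Rcpp::export]]
List wrap_align_cpp(std::string seq, std::string motif,
                    int match = 1, int mismatch = -1, int indel = -2) {
  const int n = (int)seq.size();
  const int p = (int)motif.size();
  if (n == 0 || p == 0)
    return List::create(_["start"] = 0, _["end"] = 0, _["score"] = 0,
                        _["matches"] = 0, _["cols"] = 0);

  std::vector<WCell> prev(p), cur(p);
  for (int j = 0; j < p; ++j) prev[j] = WCell{0, 0, 0, 0};
  WCell best{0, 0, 0, 0};
  int best_end = 0;

  for (int i = 1; i <= n; ++i) {
    const char c = seq[i - 1];
    // pass A: diagonal + up (previous row) and left (current row, no wrap yet)
    for (int j = 0; j < p; ++j) {
      const int jw = (j == 0) ? p - 1 : j - 1;
      const char m = motif[j];
      const bool is_match = (c == m) && (c == 'A' || c == 'C' || c == 'G' || c == 'T');
      const int subsc = is_match ? match : mismatch;

      // fresh (empty) cell at row i: nothing consumed yet, so a segment
      // extending it begins at 0-based offset i
      WCell cand{0, i, 0, 0};
      // diagonal: consume seq base + motif column
      {
        const WCell &d = prev[jw];
        int v = d.s + subsc;
        if (v > cand.s) cand = WCell{v, d.start, d.match + (is_match ? 1 : 0), d.cols + 1};
      }
      // up: consume seq base, gap in motif
      {
        const WCell &u = prev[j];
        int v = u.s + indel;
        if (v > cand.s) cand = WCell{v, u.start, u.match, u.cols + 1};
      }
      // left: consume motif column, gap in seq (same row, only j>0 here)
      if (j > 0) {
        const WCell &l = cur[j - 1];
        int v = l.s + indel;
        if (v > cand.s) cand = WCell{v, l.start, l.match, l.cols + 1};
      }
      cur[j] = cand;
    }
    // pass B: propagate within-row wraparound left moves (two sweeps suffice
    // because gap scores are negative)
    for (int sweep = 0; sweep < 2; ++sweep) {
      for (int j = 0; j < p; ++j) {
        const int jw = (j == 0) ? p - 1 : j - 1;
        const WCell &l = cur[jw];
        int v = l.s + indel;
        if (v > cur[j].s) cur[j] = WCell{v, l.start, l.match, l.cols + 1};
      }
    }
    for (int j = 0; j < p; ++j) {
      if (cur[j].s > best.s) { best = cur[j]; best_end = i; }
    }
    prev.swap(cur);
  }

  return List::create(_["start"] = best.start, _["end"] = best_end,
                      _["score"] = best.s, _["matches"] = best.match,
                      _["cols"] = best.cols);
}

// Lag-p self-match profile: fraction-style indicator seq[i] == seq[i+p]
// (exported for the candidate-period screen; returns logical vector of
// length n - p).
// [[Rcpp::export]]
LogicalVector lag_profile_cpp(std::string seq, int p) {
  const int n = (int)seq.size();
  if (p <= 0 || p >= n) return LogicalVector(0);
  LogicalVector out(n - p);
  for (int i = 0; i < n - p; ++i) {
    const char a = seq[i], b = seq[i + p];
    out[i] = (a == b) && (a == 'A' || a == 'C' || a == 'G' || a == 'T');
  }
  return out;
}

// Apply i.i.d. per-base sequencing errors to a read and to its per-column
// alignment op string.  `ops` has one character per alignment column
// ('M','I','S' consume a read base; 'D' consumes none).  Uses R's RNG so
// set.seed() governs the outcome.  Returns the mutated read, the mutated op
// string, and an error log in original-read coordinates.
// [[Rcpp::export]]
List mutate_read_cpp(std::string seq, std::string ops,
                     double p_sub, double p_ins, double p_del) {
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  std::string out_seq, out_ops;
  out_seq.reserve(seq.size() + 16);
  out_ops.reserve(ops.size() + 16);
  std::vector<int> log_pos;
  std::vector<std::string> log_op, log_base;

  int ridx = 0;  // index into original read
  for (size_t k = 0; k < ops.size(); ++k) {
    const char op = ops[k];
    if (op == 'D' || op == 'N') { out_ops.push_back(op); continue; }
    const char base = seq[ridx];
    const double u = unif_rand();
    if (u < p_del) {
      // base dropped from the read; an aligned column becomes a deletion
      if (op == 'M' || op == '=' || op == 'X') out_ops.push_back('D');
      log_pos.push_back(ridx); log_op.push_back("del"); log_base.push_back("");
    } else if (u < p_del + p_ins) {
      out_seq.push_back(base); out_ops.push_back(op);
      const char nb = BASES[(int)(unif_rand() * 4) & 3];
      out_seq.push_back(nb);
      out_ops.push_back(op == 'S' ? 'S' : 'I');
      log_pos.push_back(ridx); log_op.push_back("ins");
      log_base.push_back(std::string(1, nb));
    } else if (u < p_del + p_ins + p_sub) {
      int r = (int)(unif_rand() * 3);
      if (r > 2) r = 2;
      char nb = base;
      for (int b = 0, seen = 0; b < 4; ++b) {
        if (BASES[b] == base) continue;
        if (seen++ == r) { nb = BASES[b]; break; }
      }
      out_seq.push_back(nb); out_ops.push_back(op);
      log_pos.push_back(ridx); log_op.push_back("sub");
      log_base.push_back(std::string(1, nb));
    } else {
      out_seq.push_back(base); out_ops.push_back(op);
    }
    ++ridx;
  }

  return List::create(_["seq"] = out_seq, _["ops"] = out_ops,
                      _["log"] = DataFrame::create(
                        _["offset"] = log_pos, _["op"] = log_op,
                        _["base"] = log_base,
                        _["stringsAsFactors"] = false));
}
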