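#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Local ("glocal") alignment of a read against a reference with the mapper's
// cost model: match rewarded +1, mismatch -mismatch_cost, read-insertion
// -ins_cost, reference-deletion -del_cost. Reference flanks are free;
// unaligned read ends are soft-clipped (they count against the length
// fraction, not the score). Equal-scoring optima resolve to the smallest
// read end, then the smallest reference end; traceback prefers diagonal,
// then deletion, then insertion — deterministic leftmost placements.
//
// Returns R_NilValue for an empty read or when no positive-scoring local
// alignment exists.
// [[Rcpp::export]]
SEXP align_read_cpp(std::string read, std::string ref,
                    double mismatch_cost = 2.0, double ins_cost = 3.0,
                    double del_cost = 3.0) {
  const int m = (int)read.size(), n = (int)ref.size();
  if (m == 0 || n == 0) return R_NilValue;

  // exact-substring shortcut: a full-length perfect hit is always optimal
  size_t hit = ref.find(read);
  if (hit != std::string::npos) {
    int start = (int)hit + 1;
    return List::create(
        _["score"] = (double)m, _["cost"] = 0.0, _["ref_start"] = start,
        _["ref_end"] = start + m - 1, _["read_start"] = 1, _["read_end"] = m,
        _["n_match"] = m, _["n_mismatch"] = 0, _["n_ins"] = 0, _["n_del"] = 0,
        _["cigar"] = std::to_string(m) + "M");
  }

  std::vector<double> prev(n + 1, 0.0), cur(n + 1, 0.0);
  // traceback codes: 0 stop, 1 diagonal, 2 deletion (gap in read), 3 insertion
  std::vector<unsigned char> tb((size_t)(m + 1) * (n + 1), 0);
  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= m; ++i) {
    cur[0] = 0.0;
    const char rc = read[i - 1];
    for (int j = 1; j <= n; ++j) {
      double diag = prev[j - 1] + (rc == ref[j - 1] ? 1.0 : -mismatch_cost);
      double del = cur[j - 1] - del_cost;   // consume ref only
      double ins = prev[j] - ins_cost;      // consume read only
      double v = 0.0;
      unsigned char t = 0;
      if (diag >= del && diag >= ins && diag > 0.0) { v = diag; t = 1; }
      else if (del >= ins && del > 0.0) { v = del; t = 2; }
      else if (ins > 0.0) { v = ins; t = 3; }
      cur[j] = v;
      tb[(size_t)i * (n + 1) + j] = t;
      if (v > best) { best = v; bi = i; bj = j; }
    }
    std::swap(prev, cur);
  }
  if (best <= 0.0) return R_NilValue;

  // traceback
  int i = bi, j = bj;
  int n_match = 0, n_mis = 0, n_ins = 0, n_del = 0;
  std::vector<std::pair<char, int>> ops;  // reversed
  auto push = [&ops](char op) {
    if (!ops.empty() && ops.back().first == op) ops.back().second++;
    else ops.push_back(std::make_pair(op, 1));
  };
  while (i > 0 && j > 0) {
    unsigned char t = tb[(size_t)i * (n + 1) + j];
    if (t == 0) break;
    if (t == 1) {
      if (read[i - 1] == ref[j - 1]) n_match++; else n_mis++;
      push('M'); --i; --j;
    } else if (t == 2) {
      n_del++; push('D'); --j;
    } else {
      n_ins++; push('I'); --i;
    }
  }
  const int read_start = i + 1, ref_start = j + 1;

  std::string cigar;
  if (read_start > 1)
    cigar += std::to_string(read_start - 1) + "S";
  for (auto it = ops.rbegin(); it != ops.rend(); ++it)
    cigar += std::to_string(it->second) + it->first;
  if (bi < m) cigar += std::to_string(m - bi) + "S";

  double cost = mismatch_cost * n_mis + ins_cost * n_ins + del_cost * n_del;
  return List::create(
      _["score"] = best, _["cost"] = cost, _["ref_start"] = ref_start,
      _["ref_end"] = bj, _["read_start"] = read_start, _["read_end"] = bi,
      _["n_match"] = n_match, _["n_mismatch"] = n_mis, _["n_ins"] = n_ins,
      _["n_del"] = n_del, _["cigar"] = cigar);
}
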