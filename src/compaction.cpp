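// Hot loops of the compaction module: minimizer scans and the greedy
// spectrum-preserving string-set (path cover) builder. Minimizer order is
// plain lexicographic on the letters (byte order of ACGT), leftmost
// occurrence breaking ties -- these must agree with the R-level oracles.

#include <Rcpp.h>
#include <string>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

// leftmost start of the smallest m-mer among starts lo..hi (inclusive)
static int leftmost_min(const std::string& s, int lo, int hi, int m) {
  int best = lo;
  for (int i = lo + 1; i <= hi; ++i) {
    if (s.compare(i, m, s, best, m) < 0) best = i;
  }
  return best;
}

// [[Rcpp::export(name = ".minimizer_cpp")]]
List minimizer_cpp(std::string seq, int m) {
  int L = (int)seq.size();
  if (L < m) stop("sequence shorter than m");
  int best = leftmost_min(seq, 0, L - m, m);
  return List::create(_["minimizer"] = seq.substr(best, m),
                      _["position"] = best);
}

// Per k-window minimizer positions, collapsed into maximal runs of
// consecutive windows sharing one minimizer occurrence (same absolute
// position, hence same m-mer). Returns a matrix with 0-based columns:
// first window, last window, minimizer position.
// [[Rcpp::export(name = ".superkmer_runs_cpp")]]
IntegerMatrix superkmer_runs_cpp(std::string seq, int k, int m) {
  int L = (int)seq.size();
  if (k < m) stop("k must be >= m");
  if (L < k) stop("sequence shorter than k");
  int nwin = L - k + 1;
  std::vector<int> minpos(nwin);
  int cur = leftmost_min(seq, 0, k - m, m);
  minpos[0] = cur;
  for (int w = 1; w < nwin; ++w) {
    int lo = w, hi = w + k - m;
    if (cur < lo) {
      cur = leftmost_min(seq, lo, hi, m);
    } else if (seq.compare(hi, m, seq, cur, m) < 0) {
      // the new trailing m-mer only displaces a strictly larger minimum,
      // preserving the leftmost tie-break
      cur = hi;
    }
    minpos[w] = cur;
  }
  std::vector<int> starts, ends, pos;
  int run_start = 0;
  for (int w = 1; w <= nwin; ++w) {
    if (w == nwin || minpos[w] != minpos[run_start]) {
      starts.push_back(run_start);
      ends.push_back(w - 1);
      pos.push_back(minpos[run_start]);
      run_start = w;
    }
  }
  IntegerMatrix out((int)starts.size(), 3);
  for (int i = 0; i < (int)starts.size(); ++i) {
    out(i, 0) = starts[i];
    out(i, 1) = ends[i];
    out(i, 2) = pos[i];
  }
  return out;
}

// Greedy path cover of the (k-1)-overlap graph: seed with the first unused
// k-mer in input order, extend right then left, trying extensions in
// A<C<G<T order. Every input k-mer ends up as a window of exactly one
// output string.
// [[Rcpp::export(name = ".greedy_spss_cpp")]]
CharacterVector greedy_spss_cpp(CharacterVector kmers, int k) {
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  int n = kmers.size();
  std::unordered_set<std::string> unused;
  unused.reserve((size_t)(n * 1.4) + 8);
  std::vector<std::string> input(n);
  for (int i = 0; i < n; ++i) {
    input[i] = as<std::string>(kmers[i]);
    if ((int)input[i].size() != k) stop("k-mer %d has length %d, expected %d",
                                        i + 1, (int)input[i].size(), k);
    if (!unused.insert(input[i]).second) stop("duplicate k-mer %s", input[i].c_str());
  }
  std::vector<std::string> contigs;
  std::string cand(k, 'A');
  for (int i = 0; i < n; ++i) {
    auto it = unused.find(input[i]);
    if (it == unused.end()) continue;
    unused.erase(it);
    std::string path = input[i];
    // extend right
    for (;;) {
      bool extended = false;
      cand.assign(path, path.size() - (k - 1), k - 1);
      cand.push_back('A');
      for (int b = 0; b < 4; ++b) {
        cand[k - 1] = BASES[b];
        auto jt = unused.find(cand);
        if (jt != unused.end()) {
          unused.erase(jt);
          path.push_back(BASES[b]);
          extended = true;
          break;
        }
      }
      if (!extended) break;
    }
    // extend left (collect then reverse to avoid quadratic prepends)
    std::string left;
    std::string prefix = path.substr(0, k - 1);
    for (;;) {
      bool extended = false;
      cand.assign(1, 'A');
      cand += prefix;
      for (int b = 0; b < 4; ++b) {
        cand[0] = BASES[b];
        auto jt = unused.find(cand);
        if (jt != unused.end()) {
          unused.erase(jt);
          left.push_back(BASES[b]);
          prefix = cand.substr(0, k - 1);
          extended = true;
          break;
        }
      }
      if (!extended) break;
    }
    if (!left.empty()) {
      std::reverse(left.begin(), left.end());
      path = left + path;
    }
    contigs.push_back(path);
  }
  return wrap(contigs);
}
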