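// Rejection-sampling hot path for baseline generation.
//
// Head vectors are 1-based positions with 0 marking the root word, matching
// the R-side representation. All randomness flows through R's RNG
// (unif_rand), so set.seed() on the R side fully determines the output.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// does `anc` dominate `w` (reflexive-transitive head relation)?
static inline bool dominates(const std::vector<int>& heads, int anc, int w) {
  while (w != 0) {
    if (w == anc) return true;
    w = heads[w - 1];
  }
  return false;
}

// number of non-projective edges (edge-level crossing count)
static int np_count(const std::vector<int>& heads) {
  int n = (int)heads.size(), cnt = 0;
  for (int d = 1; d <= n; ++d) {
    int h = heads[d - 1];
    if (h == 0) continue;
    int lo = std::min(h, d), hi = std::max(h, d);
    for (int w = lo + 1; w < hi; ++w) {
      if (!dominates(heads, h, w)) { ++cnt; break; }
    }
  }
  return cnt;
}

// sorted per-edge dependency lengths
static void dl_sorted(const std::vector<int>& heads, std::vector<int>& out) {
  out.clear();
  int n = (int)heads.size();
  for (int d = 1; d <= n; ++d) {
    int h = heads[d - 1];
    if (h != 0) out.push_back(std::abs(h - d) - 1);
  }
  std::sort(out.begin(), out.end());
}

// sorted per-edge intervener complexities (head = word with >= 1 dependent)
static void ic_sorted(const std::vector<int>& heads, std::vector<int>& out) {
  int n = (int)heads.size();
  std::vector<int> is_head(n, 0);
  for (int d = 0; d < n; ++d)
    if (heads[d] != 0) is_head[heads[d] - 1] = 1;
  out.clear();
  for (int d = 1; d <= n; ++d) {
    int h = heads[d - 1];
    if (h == 0) continue;
    int lo = std::min(h, d), hi = std::max(h, d), ic = 0;
    for (int w = lo + 1; w < hi; ++w) ic += is_head[w - 1];
    out.push_back(ic);
  }
  std::sort(out.begin(), out.end());
}

static inline int unif_int(int n) {  // uniform on 0..n-1 via R's RNG
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// uniform random linear arrangement of ref into cand
static void rla_draw(const std::vector<int>& ref, std::vector<int>& cand,
                     std::vector<int>& perm) {
  int n = (int)ref.size();
  for (int i = 0; i < n; ++i) perm[i] = i + 1;
  for (int i = n - 1; i > 0; --i)
    std::swap(perm[i], perm[unif_int(i + 1)]);
  for (int i = 0; i < n; ++i)
    cand[perm[i] - 1] = ref[i] == 0 ? 0 : perm[ref[i] - 1];
}

// uniform rooted labeled tree on n nodes: Pruefer draw + decode + random root
static void structure_draw(int n, std::vector<int>& cand,
                           std::vector<int>& deg, std::vector<int>& ea,
                           std::vector<int>& eb) {
  std::vector<int> seq(std::max(n - 2, 0));
  for (int k = 0; k < n - 2; ++k) seq[k] = unif_int(n) + 1;
  std::fill(deg.begin(), deg.end(), 1);
  for (int k = 0; k < n - 2; ++k) deg[seq[k] - 1] += 1;
  for (int k = 0; k < n - 2; ++k) {
    int u = 0;
    while (deg[u] != 1) ++u;           // smallest current leaf
    ea[k] = u + 1;
    eb[k] = seq[k];
    deg[u] = 0;
    deg[seq[k] - 1] -= 1;
  }
  int r1 = -1, r2 = -1;
  for (int u = 0; u < n; ++u)
    if (deg[u] == 1) { if (r1 < 0) r1 = u + 1; else r2 = u + 1; }
  ea[n - 2] = r1;
  eb[n - 2] = r2;

  // orient away from a uniformly chosen root (BFS over adjacency lists)
  int root = unif_int(n) + 1;
  std::vector<std::vector<int> > adj(n);
  for (int k = 0; k < n - 1; ++k) {
    adj[ea[k] - 1].push_back(eb[k]);
    adj[eb[k] - 1].push_back(ea[k]);
  }
  std::vector<int> queue;
  std::vector<char> seen(n, 0);
  cand[root - 1] = 0;
  seen[root - 1] = 1;
  queue.push_back(root);
  for (size_t q = 0; q < queue.size(); ++q) {
    int v = queue[q];
    for (size_t a = 0; a < adj[v - 1].size(); ++a) {
      int w = adj[v - 1][a];
      if (!seen[w - 1]) {
        seen[w - 1] = 1;
        cand[w - 1] = v;
        queue.push_back(w);
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_np_count")]]
int cpp_np_count(IntegerVector heads_) {
  std::vector<int> heads(heads_.begin(), heads_.end());
  return np_count(heads);
}

// [[Rcpp::export(name = ".cpp_generate_baseline")]]
List cpp_generate_baseline(IntegerVector ref_heads, std::string kind,
                           int max_attempts) {
  std::vector<int> ref(ref_heads.begin(), ref_heads.end());
  int n = (int)ref.size();
  bool structural = kind.size() >= 17 &&
    kind.compare(kind.size() - 17, 17, "random_structures") == 0;
  bool dl_match = kind.compare(0, 10, "dl_matched") == 0;
  bool ic_match = kind.compare(0, 10, "ic_matched") == 0;

  int ref_cross = np_count(ref);
  std::vector<int> ref_dl, ref_ic, cand_stat;
  if (dl_match) dl_sorted(ref, ref_dl);
  if (ic_match) ic_sorted(ref, ref_ic);

  std::vector<int> cand(n), perm(n), deg(n), ea(std::max(n - 1, 1)),
    eb(std::max(n - 1, 1));
  for (int attempt = 1; attempt <= max_attempts; ++attempt) {
    if (structural) structure_draw(n, cand, deg, ea, eb);
    else rla_draw(ref, cand, perm);
    if (dl_match) {
      dl_sorted(cand, cand_stat);
      if (cand_stat != ref_dl) continue;
    }
    if (ic_match) {
      ic_sorted(cand, cand_stat);
      if (cand_stat != ref_ic) continue;
    }
    if (np_count(cand) != ref_cross) continue;
    return List::create(Named("success") = true,
                        Named("attempts") = attempt,
                        Named("heads") = IntegerVector(cand.begin(), cand.end()));
  }
  return List::create(Named("success") = false,
                      Named("attempts") = max_attempts,
                      Named("heads") = R_NilValue);
}
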