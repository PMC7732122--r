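// Low-level engines: Mott quality trimming, adapter clipping, de Bruijn
// assembly with read-2 bubble resolution, seeded read mapping, exact-diagonal
// HSP discovery and quality-filtered pileup accumulation.
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <map>
#include <string>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

static inline bool clean_window(const std::string& s, size_t pos, int k) {
  for (int i = 0; i < k; i++) {
    char c = s[pos + i];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T') return false;
  }
  return true;
}

static inline std::string canon(const std::string& s) {
  std::string r = revcomp(s);
  return s <= r ? s : r;
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); i++) out[i] = revcomp(as<std::string>(x[i]));
  return out;
}

// ---------------------------------------------------------------------------
// Mott trimming: maximal-scoring segment under per-base score (limit - p_err),
// with p_err = 1 for ambiguous bases so a kept segment can never span an N.
// Returns 1-based [start, end]; start 0 marks a fully discarded read.
// Tie rule: highest score, then smallest start, then smallest end.
// [[Rcpp::export]]
IntegerMatrix mott_trim_cpp(CharacterVector seqs, CharacterVector quals, double limit) {
  R_xlen_t n = seqs.size();
  IntegerMatrix out(n, 2);
  for (R_xlen_t r = 0; r < n; r++) {
    std::string s = as<std::string>(seqs[r]);
    std::string q = as<std::string>(quals[r]);
    int L = s.size();
    double run = 0, best = 0;
    int run_start = 0, bs = -1, be = -1;
    for (int i = 0; i < L; i++) {
      char b = s[i];
      double perr = (b == 'A' || b == 'C' || b == 'G' || b == 'T')
        ? std::pow(10.0, -((double)(q[i] - 33)) / 10.0) : 1.0;
      run += limit - perr;
      if (run < 0) { run = 0; run_start = i + 1; }
      else if (run > best + 1e-15) { best = run; bs = run_start; be = i; }
    }
    if (bs < 0) { out(r, 0) = 0; out(r, 1) = 0; }
    else { out(r, 0) = bs + 1; out(r, 1) = be + 1; }
  }
  return out;
}

// 3' adapter clipping: semi-global match of an adapter prefix starting at any
// read position and running to the read end, minimum overlap and a mismatch
// budget proportional to the compared length. Returns the retained length.
// [[Rcpp::export]]
IntegerVector adapter_trim_cpp(CharacterVector seqs, CharacterVector adapters,
                               int min_overlap, double max_mismatch_frac) {
  std::vector<std::string> ad(adapters.size());
  for (R_xlen_t a = 0; a < adapters.size(); a++) ad[a] = as<std::string>(adapters[a]);
  R_xlen_t n = seqs.size();
  IntegerVector out(n);
  for (R_xlen_t r = 0; r < n; r++) {
    std::string s = as<std::string>(seqs[r]);
    int L = s.size(), cut = L;
    for (auto& A : ad) {
      int alen = A.size();
      for (int p = 0; p <= L - min_overlap; p++) {
        if (p >= cut) break;
        int cmp = std::min(L - p, alen);
        if (cmp < min_overlap) break;
        int allowed = (int)std::floor(max_mismatch_frac * cmp);
        int mm = 0;
        for (int i = 0; i < cmp && mm <= allowed; i++)
          if (s[p + i] != A[i]) mm++;
        if (mm <= allowed) { cut = p; break; }
      }
    }
    out[r] = cut;
  }
  return out;
}

// ---------------------------------------------------------------------------
// de Bruijn assembly
// ---------------------------------------------------------------------------

struct DBG {
  int k;
  std::unordered_map<std::string, double> cnt;   // canonical k-mer -> count
  std::unordered_set<std::string> trusted;       // canonical, pruning-exempt
  bool has(const std::string& oriented) const { return cnt.count(canon(oriented)) > 0; }
  double cov(const std::string& oriented) const {
    auto it = cnt.find(canon(oriented));
    return it == cnt.end() ? 0.0 : it->second;
  }
  int n_succ(const std::string& km, char* which = nullptr) const {
    static const char B[4] = {'A', 'C', 'G', 'T'};
    std::string nxt = km.substr(1) + "A";
    int n = 0;
    for (int i = 0; i < 4; i++) {
      nxt[k - 1] = B[i];
      if (has(nxt)) { if (which) which[n] = B[i]; n++; }
    }
    return n;
  }
  int n_pred(const std::string& km, char* which = nullptr) const {
    static const char B[4] = {'A', 'C', 'G', 'T'};
    std::string prv = "A" + km.substr(0, k - 1);
    int n = 0;
    for (int i = 0; i < 4; i++) {
      prv[0] = B[i];
      if (has(prv)) { if (which) which[n] = B[i]; n++; }
    }
    return n;
  }
};

struct Unitig { std::string seq; double cov; int nk; };

static void count_kmers(const CharacterVector& reads, int k,
                        std::unordered_map<std::string, double>& cnt) {
  for (R_xlen_t r = 0; r < reads.size(); r++) {
    std::string s = as<std::string>(reads[r]);
    if ((int)s.size() < k) continue;
    for (size_t p = 0; p + k <= s.size(); p++) {
      if (!clean_window(s, p, k)) continue;
      cnt[canon(s.substr(p, k))] += 1.0;
    }
  }
}

static std::vector<Unitig> build_unitigs(const DBG& g) {
  std::vector<std::string> keys;
  keys.reserve(g.cnt.size());
  for (auto& kv : g.cnt) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  std::unordered_set<std::string> used;
  std::vector<Unitig> out;
  const int k = g.k;
  for (auto& key : keys) {
    if (used.count(key)) continue;
    std::vector<std::string> path;          // oriented k-mers, left to right
    std::unordered_set<std::string> inpath; // canonical
    path.push_back(key); inpath.insert(key);
    std::string tail = key;
    char wh[4];
    while (true) {
      if (g.n_succ(tail, wh) != 1) break;
      std::string nxt = tail.substr(1) + wh[0];
      if (g.n_pred(nxt) != 1) break;
      std::string cn = canon(nxt);
      if (inpath.count(cn) || used.count(cn)) break;
      path.push_back(nxt); inpath.insert(cn); tail = nxt;
    }
    std::vector<std::string> left;
    std::string head = key;
    while (true) {
      if (g.n_pred(head, wh) != 1) break;
      std::string prv = std::string(1, wh[0]) + head.substr(0, k - 1);
      if (g.n_succ(prv) != 1) break;
      std::string cn = canon(prv);
      if (inpath.count(cn) || used.count(cn)) break;
      left.push_back(prv); inpath.insert(cn); head = prv;
    }
    std::reverse(left.begin(), left.end());
    left.insert(left.end(), path.begin(), path.end());
    std::string seq = left[0];
    double cs = 0;
    for (size_t i = 1; i < left.size(); i++) seq.push_back(left[i][k - 1]);
    for (auto& km : left) { cs += g.cov(km); used.insert(canon(km)); }
    out.push_back({seq, cs / left.size(), (int)left.size()});
  }
  return out;
}

static void erase_unitig(DBG& g, const std::string& seq, bool respect_trusted) {
  const int k = g.k;
  for (size_t p = 0; p + k <= seq.size(); p++) {
    std::string cn = canon(seq.substr(p, k));
    if (respect_trusted && g.trusted.count(cn)) continue;
    g.cnt.erase(cn);
  }
}

static bool unitig_is_trusted(const DBG& g, const std::string& seq) {
  const int k = g.k;
  for (size_t p = 0; p + k <= seq.size(); p++)
    if (g.trusted.count(canon(seq.substr(p, k)))) return true;
  return false;
}

// Remove dead-end unitigs shorter than 2k that compete with another branch at
// their attachment junction. Returns number removed.
static int remove_tips(DBG& g) {
  auto unis = build_unitigs(g);
  const int k = g.k;
  std::vector<const Unitig*> doomed;
  for (auto& u : unis) {
    if ((int)u.seq.size() >= 2 * k) continue;
    if (unitig_is_trusted(g, u.seq)) continue;
    std::string head = u.seq.substr(0, k);
    std::string tail = u.seq.substr(u.seq.size() - k);
    char wh[4];
    int np = g.n_pred(head), ns = g.n_succ(tail);
    bool tip = false;
    if (np == 0 && ns >= 1) {
      // check the junction we attach to on the right competes
      int nj = g.n_succ(tail, wh);
      for (int i = 0; i < nj && !tip; i++) {
        std::string nxt = tail.substr(1) + wh[i];
        if (g.n_pred(nxt) >= 2) tip = true;
      }
    } else if (ns == 0 && np >= 1) {
      int nj = g.n_pred(head, wh);
      for (int i = 0; i < nj && !tip; i++) {
        std::string prv = std::string(1, wh[i]) + head.substr(0, k - 1);
        if (g.n_succ(prv) >= 2) tip = true;
      }
    }
    if (tip) doomed.push_back(&u);
  }
  for (auto* u : doomed) erase_unitig(g, u->seq, false);
  return doomed.size();
}

// Pop simple bubbles: branches sharing both anchor k-mers. A branch is read-2
// supported when every one of its k-mers occurs in the read-2 k-mer set.
// Exactly-one-supported wins; several supported -> higher coverage, then
// lexicographic; none supported -> both kept (unresolved).
static int pop_bubbles(DBG& g, const std::unordered_set<std::string>& r2set) {
  auto unis = build_unitigs(g);
  const int k = g.k;
  struct Branch { std::string seq; double cov; bool supported; bool trusted; };
  std::map<std::string, std::vector<Branch>> groups;
  char wh[4];
  for (auto& u : unis) {
    // branch cap: single-variant bubbles span ~2k nodes, but clustered
    // heterozygous variants closer than k chain into one longer branch
    if ((int)u.seq.size() > 3 * k + 200) continue;
    for (int o = 0; o < 2; o++) {
      std::string s = o == 0 ? u.seq : revcomp(u.seq);
      std::string head = s.substr(0, k), tail = s.substr(s.size() - k);
      if (g.n_pred(head, wh) != 1) continue;
      std::string aL = std::string(1, wh[0]) + head.substr(0, k - 1);
      if (g.n_succ(tail, wh) != 1) continue;
      std::string aR = tail.substr(1) + wh[0];
      // only a true branch if the anchors fork
      if (g.n_succ(aL) < 2 || g.n_pred(aR) < 2) continue;
      bool sup = true;
      for (size_t p = 0; p + k <= s.size() && sup; p++)
        if (!r2set.count(canon(s.substr(p, k)))) sup = false;
      // trust exempts a k-mer from coverage pruning, not from bubble
      // resolution: haplotype branches carried over from earlier guided
      // iterations must stay poppable or bubbles accumulate
      groups[aL + "|" + aR].push_back({canon(s), u.cov, sup, false});
      break; // one orientation is enough per unitig
    }
  }
  int removed = 0;
  std::unordered_set<std::string> gone;
  for (auto& kv : groups) {
    auto& br = kv.second;
    if (br.size() < 2) continue;
    int nsup = 0;
    for (auto& b : br) if (b.supported) nsup++;
    if (nsup == 0) continue;                       // unresolved: keep all
    // winner among supported branches
    const Branch* win = nullptr;
    for (auto& b : br) {
      if (!b.supported) continue;
      if (!win || b.cov > win->cov + 1e-12 ||
          (std::fabs(b.cov - win->cov) <= 1e-12 && b.seq < win->seq)) win = &b;
    }
    for (auto& b : br) {
      if (&b == win || gone.count(b.seq)) continue;
      erase_unitig(g, b.seq, false);
      gone.insert(b.seq);
      removed++;
    }
  }
  return removed;
}

// Resolve superbubbles: sets of >= 2 parallel paths between a fork and a
// reconvergence node. With substitution-only variation all parallel paths
// have equal length, so a layered frontier walk finds the reconvergence;
// the maximum-coverage path (ties: lexicographic) is kept and every other
// interior node is erased. Handles the haplotype-mosaic structures that the
// simple two-branch popper cannot.
static int pop_superbubbles(DBG& g, int max_steps, int max_width) {
  std::vector<std::string> keys;
  keys.reserve(g.cnt.size());
  for (auto& kv : g.cnt) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  const int k = g.k;
  int resolved = 0;
  char wh[4];
  for (auto& key : keys) {
    if (!g.cnt.count(key)) continue;  // may have been erased this round
    for (int o = 0; o < 2; o++) {
      std::string s = o == 0 ? key : revcomp(key);
      int ns = g.n_succ(s, wh);
      if (ns < 2) continue;
      struct Node { std::string km; double score; int prev; };
      std::vector<std::vector<Node>> layers;
      std::vector<Node> frontier;
      for (int i = 0; i < ns; i++) {
        std::string nxt = s.substr(1) + wh[i];
        frontier.push_back({nxt, g.cov(nxt), -1});
      }
      bool ok = false;
      int steps = 0;
      layers.push_back(frontier);
      while (steps++ < max_steps) {
        if (frontier.size() == 1) { ok = true; break; }
        std::map<std::string, Node> nxt;
        for (size_t fi = 0; fi < frontier.size(); fi++) {
          int nn = g.n_succ(frontier[fi].km, wh);
          for (int b = 0; b < nn; b++) {
            std::string nk = frontier[fi].km.substr(1) + wh[b];
            double sc = frontier[fi].score + g.cov(nk);
            auto it = nxt.find(nk);
            if (it == nxt.end() || sc > it->second.score)
              nxt[nk] = {nk, sc, (int)fi};
          }
        }
        if (nxt.empty() || (int)nxt.size() > max_width) break;
        frontier.clear();
        for (auto& kv2 : nxt) frontier.push_back(kv2.second);
        layers.push_back(frontier);
      }
      if (!ok || layers.size() < 2) continue;
      // backtrack the best path into a keep-set
      std::unordered_set<std::string> keep;
      int idx = 0;
      for (int L = (int)layers.size() - 1; L >= 0; L--) {
        keep.insert(canon(layers[L][idx].km));
        idx = layers[L][idx].prev;
        if (L > 0 && (idx < 0 || idx >= (int)layers[L - 1].size())) break;
      }
      int erased = 0;
      for (auto& lay : layers) {
        for (auto& nd : lay) {
          std::string cn = canon(nd.km);
          if (!keep.count(cn) && g.cnt.count(cn)) { g.cnt.erase(cn); erased++; }
        }
      }
      if (erased) resolved++;
    }
  }
  return resolved;
}

// [[Rcpp::export]]
List dbg_assemble_cpp(CharacterVector reads1, CharacterVector reads2, int k,
                      int min_count, int min_len, CharacterVector trusted_seqs) {
  DBG g; g.k = k;
  count_kmers(reads1, k, g.cnt);
  for (R_xlen_t t = 0; t < trusted_seqs.size(); t++) {
    std::string s = as<std::string>(trusted_seqs[t]);
    if ((int)s.size() < k) continue;
    for (size_t p = 0; p + k <= s.size(); p++) {
      if (!clean_window(s, p, k)) continue;
      std::string cn = canon(s.substr(p, k));
      g.trusted.insert(cn);
      if (!g.cnt.count(cn)) g.cnt[cn] = 0.0;
    }
  }
  for (auto it = g.cnt.begin(); it != g.cnt.end();) {
    if (it->second < min_count && !g.trusted.count(it->first)) it = g.cnt.erase(it);
    else ++it;
  }
  std::unordered_set<std::string> r2set;
  for (R_xlen_t r = 0; r < reads2.size(); r++) {
    std::string s = as<std::string>(reads2[r]);
    if ((int)s.size() < k) continue;
    for (size_t p = 0; p + k <= s.size(); p++) {
      if (!clean_window(s, p, k)) continue;
      r2set.insert(canon(s.substr(p, k)));
    }
  }
  for (int round = 0; round < 20; round++) {
    int changed = remove_tips(g);
    changed += pop_bubbles(g, r2set);
    changed += pop_superbubbles(g, 3 * k + 300, 16);
    if (changed == 0) break;
  }
  auto unis = build_unitigs(g);
  std::vector<std::pair<std::string, double>> keep;
  for (auto& u : unis) {
    if ((int)u.seq.size() < min_len) continue;
    std::string r = revcomp(u.seq);
    keep.push_back({u.seq <= r ? u.seq : r, u.cov});
  }
  std::sort(keep.begin(), keep.end(), [](const std::pair<std::string, double>& a,
                                         const std::pair<std::string, double>& b) {
    if (a.first.size() != b.first.size()) return a.first.size() > b.first.size();
    return a.first < b.first;
  });
  CharacterVector seqs(keep.size());
  NumericVector cov(keep.size());
  for (size_t i = 0; i < keep.size(); i++) { seqs[i] = keep[i].first; cov[i] = keep[i].second; }
  return List::create(_["seq"] = seqs, _["coverage"] = cov);
}

// ---------------------------------------------------------------------------
// Seeded read mapping: 15-mer seeds vote for (reference, diagonal) placements;
// each candidate diagonal is scored by ungapped comparison. Substitution-only
// placements suffice because the simulator introduces no indels.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame map_reads_cpp(CharacterVector reads, CharacterVector refs,
                        int seed_len, int stride, int max_seed_hits,
                        int max_candidates) {
  int nr = refs.size();
  std::unordered_map<std::string, std::vector<std::pair<int, int>>> idx;
  std::vector<std::string> R(nr);
  for (int i = 0; i < nr; i++) {
    R[i] = as<std::string>(refs[i]);
    const std::string& s = R[i];
    for (size_t p = 0; p + seed_len <= s.size(); p++) {
      if (!clean_window(s, p, seed_len)) continue;
      idx[s.substr(p, seed_len)].push_back({i, (int)p});
    }
  }
  R_xlen_t n = reads.size();
  IntegerVector o_ref(n), o_pos(n), o_matches(n), o_overlap(n), o_second(n);
  CharacterVector o_strand(n);
  for (R_xlen_t ri = 0; ri < n; ri++) {
    std::string fwd = as<std::string>(reads[ri]);
    int L = fwd.size();
    int best = -1, second = -1, bref = -1, bpos = 0, boverlap = 0;
    char bstrand = '+';
    if (L >= seed_len) {
      for (int sidx = 0; sidx < 2; sidx++) {
        std::string rd = sidx == 0 ? fwd : revcomp(fwd);
        std::map<std::pair<int, int>, int> cand;
        for (int p = 0;; p += stride) {
          if (p + seed_len > L) p = L - seed_len;
          auto it = idx.find(rd.substr(p, seed_len));
          if (it != idx.end() && (int)it->second.size() <= max_seed_hits)
            for (auto& h : it->second) cand[{h.first, h.second - p}]++;
          if (p == L - seed_len) break;
        }
        std::vector<std::pair<std::pair<int, int>, int>> cv(cand.begin(), cand.end());
        if ((int)cv.size() > max_candidates) {
          std::stable_sort(cv.begin(), cv.end(),
                           [](const std::pair<std::pair<int, int>, int>& a,
                              const std::pair<std::pair<int, int>, int>& b) {
                             return a.second > b.second;
                           });
          cv.resize(max_candidates);
          std::sort(cv.begin(), cv.end());
        }
        for (auto& c : cv) {
          int rf = c.first.first, d = c.first.second;
          const std::string& S = R[rf];
          int lo = std::max(0, d), hi = std::min((int)S.size(), d + L);
          if (hi - lo < seed_len) continue;
          int m = 0;
          for (int q = lo; q < hi; q++) if (S[q] == rd[q - d]) m++;
          if (m > best) {
            second = best; best = m; bref = rf; bpos = d;
            bstrand = sidx == 0 ? '+' : '-'; boverlap = hi - lo;
          } else if (m > second) second = m;
        }
      }
    }
    o_ref[ri] = bref + 1; o_pos[ri] = bpos + 1;
    o_matches[ri] = best < 0 ? 0 : best;
    o_overlap[ri] = boverlap; o_second[ri] = second < 0 ? 0 : second;
    o_strand[ri] = bstrand == '+' ? "+" : "-";
  }
  return DataFrame::create(_["ref"] = o_ref, _["pos"] = o_pos, _["strand"] = o_strand,
                           _["matches"] = o_matches, _["overlap"] = o_overlap,
                           _["second"] = o_second, _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// HSP discovery: shared k-mers grouped by (subject, diagonal), runs merged when
// gaps between consecutive seed starts stay below max_gap; match counts by
// direct comparison over the merged span. Query coordinates are reported in
// the oriented query (reverse complement for '-' hits), 0-based half-open.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame find_hsps_cpp(std::string query, CharacterVector subjects, int k, int max_gap) {
  int ns = subjects.size();
  std::unordered_map<std::string, std::vector<std::pair<int, int>>> idx;
  std::vector<std::string> S(ns);
  for (int i = 0; i < ns; i++) {
    S[i] = as<std::string>(subjects[i]);
    for (size_t p = 0; p + k <= S[i].size(); p++) {
      if (!clean_window(S[i], p, k)) continue;
      idx[S[i].substr(p, k)].push_back({i, (int)p});
    }
  }
  std::vector<int> v_subj, v_qs, v_qe, v_ss, v_se, v_match;
  std::vector<std::string> v_strand;
  int Lq = query.size();
  for (int sidx = 0; sidx < 2; sidx++) {
    std::string q = sidx == 0 ? query : revcomp(query);
    std::map<std::pair<int, int>, std::vector<int>> diag; // (subj, d) -> qpos list
    for (int p = 0; p + k <= Lq; p++) {
      if (!clean_window(q, p, k)) continue;
      auto it = idx.find(q.substr(p, k));
      if (it == idx.end()) continue;
      for (auto& h : it->second) diag[{h.first, h.second - p}].push_back(p);
    }
    for (auto& kv : diag) {
      int subj = kv.first.first, d = kv.first.second;
      auto& ps = kv.second; // sorted by construction
      size_t i = 0;
      while (i < ps.size()) {
        size_t j = i;
        while (j + 1 < ps.size() && ps[j + 1] - ps[j] <= max_gap) j++;
        int qs = ps[i], qe = ps[j] + k;
        int ss = qs + d, se = qe + d;
        int m = 0;
        for (int x = qs; x < qe; x++) if (q[x] == S[subj][x + d]) m++;
        v_subj.push_back(subj + 1);
        v_qs.push_back(qs); v_qe.push_back(qe);
        v_ss.push_back(ss); v_se.push_back(se);
        v_match.push_back(m);
        v_strand.push_back(sidx == 0 ? "+" : "-");
        i = j + 1;
      }
    }
  }
  return DataFrame::create(_["subject"] = v_subj, _["strand"] = v_strand,
                           _["qstart"] = v_qs, _["qend"] = v_qe,
                           _["sstart"] = v_ss, _["send"] = v_se,
                           _["matches"] = v_match, _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Pileup accumulation. Reads arrive oriented to the reference forward strand.
// Caller-A view: bases with quality >= minq_a whose 5-base flanking window
// (within the read) also stays >= minq_a, from reads flagged use_a.
// Caller-B view: bases with quality >= minq_b from reads flagged use_b; the
// per-base genotype-likelihood terms are accumulated per observed base:
//   s_hom_match = sum log(1 - e)        (read base equals the hom allele)
//   s_mismatch  = sum log(e / 3)        (read base absent from the genotype)
//   s_het_match = sum log((1-e)/2 + e/6) (read base equals one het allele)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List pileup_cpp(IntegerVector ref_len, IntegerVector p_ref, IntegerVector p_pos,
                CharacterVector p_seq, CharacterVector p_qual,
                LogicalVector use_a, LogicalVector use_b,
                int minq_a, int flank, int minq_b) {
  int nref = ref_len.size();
  List out(nref);
  std::vector<IntegerMatrix> cA(nref), cB(nref);
  std::vector<NumericMatrix> s1(nref), s2(nref), s3(nref);
  std::vector<IntegerVector> dA(nref), dB(nref), dRaw(nref);
  for (int r = 0; r < nref; r++) {
    int L = ref_len[r];
    cA[r] = IntegerMatrix(4, L); cB[r] = IntegerMatrix(4, L);
    s1[r] = NumericMatrix(4, L); s2[r] = NumericMatrix(4, L); s3[r] = NumericMatrix(4, L);
    dA[r] = IntegerVector(L); dB[r] = IntegerVector(L); dRaw[r] = IntegerVector(L);
  }
  R_xlen_t n = p_ref.size();
  std::vector<int> fmin;
  for (R_xlen_t i = 0; i < n; i++) {
    int r = p_ref[i] - 1;
    if (r < 0 || r >= nref) continue;
    std::string s = as<std::string>(p_seq[i]);
    std::string q = as<std::string>(p_qual[i]);
    int L = s.size(), R0 = p_pos[i] - 1, refL = ref_len[r];
    fmin.assign(L, 1000);
    for (int x = 0; x < L; x++) {
      int lo = std::max(0, x - flank), hi = std::min(L - 1, x + flank);
      int mn = 1000;
      for (int y = lo; y <= hi; y++) mn = std::min(mn, (int)(q[y] - 33));
      fmin[x] = mn;
    }
    for (int x = 0; x < L; x++) {
      int rp = R0 + x;
      if (rp < 0 || rp >= refL) continue;
      int b;
      switch (s[x]) {
      case 'A': b = 0; break; case 'C': b = 1; break;
      case 'G': b = 2; break; case 'T': b = 3; break;
      default: b = -1;
      }
      if (b < 0) continue;
      int qv = q[x] - 33;
      dRaw[r][rp]++;
      if (use_a[i] && qv >= minq_a && fmin[x] >= minq_a) {
        cA[r](b, rp)++; dA[r][rp]++;
      }
      if (use_b[i] && qv >= minq_b) {
        double e = std::pow(10.0, -qv / 10.0);
        cB[r](b, rp)++; dB[r][rp]++;
        s1[r](b, rp) += std::log(1.0 - e);
        s2[r](b, rp) += std::log(e / 3.0);
        s3[r](b, rp) += std::log(0.5 * (1.0 - e) + 0.5 * e / 3.0);
      }
    }
  }
  for (int r = 0; r < nref; r++) {
    out[r] = List::create(_["countsA"] = cA[r], _["countsB"] = cB[r],
                          _["homMatch"] = s1[r], _["mismatch"] = s2[r],
                          _["hetMatch"] = s3[r], _["depthA"] = dA[r],
                          _["depthB"] = dB[r], _["depthRaw"] = dRaw[r]);
  }
  return out;
}
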