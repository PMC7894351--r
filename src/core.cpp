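// Sequence-crunching primitives shared by the simulator, assembler, mapper
// and synteny modules. All randomness stays on the R side; everything here
// is deterministic. k-mers are 2-bit packed into uint64, so k <= 31.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

static const int BASE_CODE[256] = {
// 0 = A, 1 = C, 2 = G, 3 = T, -1 = anything else
#define X -1
  X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X, X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,
  X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X, X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,
  X,0,X,1,X,X,X,2,X,X,X,X,X,X,X,X, X,X,X,X,3,X,X,X,X,X,X,X,X,X,X,X,
  X,0,X,1,X,X,X,2,X,X,X,X,X,X,X,X, X,X,X,X,3,X,X,X,X,X,X,X,X,X,X,X,
  X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X, X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,
  X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X, X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,
  X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X, X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,
  X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X, X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X
#undef X
};

static const char BASE_CHAR[4] = {'A', 'C', 'G', 'T'};

static inline uint64_t rc_kmer(uint64_t x, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3ULL - (x & 3ULL));
    x >>= 2;
  }
  return r;
}

static inline std::string decode_kmer(uint64_t x, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = BASE_CHAR[x & 3ULL]; x >>= 2; }
  return s;
}

// Rolling scan: calls f(position, fwd_kmer) for every clean window.
template <typename F>
static void scan_kmers(const std::string& s, int k, F f) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t cur = 0;
  int run = 0;
  const int n = (int)s.size();
  for (int i = 0; i < n; ++i) {
    int c = BASE_CODE[(unsigned char)s[i]];
    if (c < 0) { run = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint64_t)c) & mask;
    if (++run >= k) f(i - k + 1, cur);
  }
}

static std::string rc_string(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    int c = BASE_CODE[(unsigned char)s[s.size() - 1 - i]];
    r[i] = (c < 0) ? 'N' : BASE_CHAR[3 - c];
  }
  return r;
}

// [[Rcpp::export(name = ".rc_cpp")]]
CharacterVector rc_cpp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = rc_string(as<std::string>(seqs[i]));
  out.names() = seqs.names();
  return out;
}

static std::unordered_set<uint64_t> canonical_set(const std::vector<std::string>& seqs, int k) {
  std::unordered_set<uint64_t> set;
  for (const std::string& s : seqs) {
    scan_kmers(s, k, [&](int, uint64_t x) {
      uint64_t r = rc_kmer(x, k);
      set.insert(x < r ? x : r);
    });
  }
  return set;
}

// Number of k-mer windows of each read whose canonical k-mer is in the bait set.
// [[Rcpp::export(name = ".shared_kmer_counts_cpp")]]
IntegerVector shared_kmer_counts_cpp(CharacterVector reads, CharacterVector bait, int k) {
  std::vector<std::string> bs;
  bs.reserve(bait.size());
  for (R_xlen_t i = 0; i < bait.size(); ++i) bs.push_back(as<std::string>(bait[i]));
  std::unordered_set<uint64_t> set = canonical_set(bs, k);
  IntegerVector out(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string r = as<std::string>(reads[i]);
    int n = 0;
    scan_kmers(r, k, [&](int, uint64_t x) {
      uint64_t rc = rc_kmer(x, k);
      if (set.count(x < rc ? x : rc)) ++n;
    });
    out[i] = n;
  }
  return out;
}

// ---------------------------------------------------------------------------
// de Bruijn unitig assembly over solid canonical k-mers.
//
// Both orientations of every solid k-mer are inserted as directed edges over
// (k-1)-mer nodes; unitigs are maximal non-branching paths. Components that
// form perfect cycles are emitted with the first (k-1)-mer duplicated at the
// end, which is the terminal-overlap signature detect_circularity() tests.
// Each double-stranded unitig is emitted once, in canonical orientation.
// ---------------------------------------------------------------------------

struct DbgIndex {
  int k;
  uint64_t node_mask;
  std::unordered_set<uint64_t> edges;   // directed k-mers
  std::unordered_map<uint64_t, int> outdeg, indeg;
};

static inline uint64_t edge_prefix(uint64_t e, const DbgIndex& g) { return e >> 2; }
static inline uint64_t edge_suffix(uint64_t e, const DbgIndex& g) { return e & g.node_mask; }

// [[Rcpp::export(name = ".assemble_cpp")]]
List assemble_cpp(CharacterVector reads, int k, int min_count) {
  std::unordered_map<uint64_t, int> counts;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    scan_kmers(s, k, [&](int, uint64_t x) {
      uint64_t r = rc_kmer(x, k);
      ++counts[x < r ? x : r];
    });
  }
  DbgIndex g;
  g.k = k;
  g.node_mask = (1ULL << (2 * (k - 1))) - 1;
  std::vector<uint64_t> solid;
  for (auto& kv : counts)
    if (kv.second >= min_count) solid.push_back(kv.first);
  std::sort(solid.begin(), solid.end()); // deterministic traversal order
  std::vector<uint64_t> dir;
  dir.reserve(2 * solid.size());
  for (uint64_t c : solid) {
    uint64_t r = rc_kmer(c, k);
    g.edges.insert(c);
    g.edges.insert(r);
    dir.push_back(c);
    if (r != c) dir.push_back(r);
  }
  std::sort(dir.begin(), dir.end());
  for (uint64_t e : dir) {
    ++g.outdeg[edge_prefix(e, g)];
    ++g.indeg[edge_suffix(e, g)];
  }
  auto deg = [&](std::unordered_map<uint64_t, int>& m, uint64_t n) {
    auto it = m.find(n);
    return it == m.end() ? 0 : it->second;
  };
  auto unique_out = [&](uint64_t node) -> uint64_t {
    // assumes outdeg(node) == 1
    for (uint64_t b = 0; b < 4; ++b) {
      uint64_t e = (node << 2) | b;
      if (g.edges.count(e)) return e;
    }
    return 0; // unreachable
  };
  std::unordered_set<uint64_t> visited;
  std::vector<std::string> contigs;
  std::vector<bool> circular;

  auto emit = [&](const std::vector<uint64_t>& path, bool circ) {
    std::string s = decode_kmer(edge_prefix(path[0], g), k - 1);
    s.reserve((k - 1) + path.size());
    for (uint64_t e : path) s.push_back(BASE_CHAR[e & 3ULL]);
    for (uint64_t e : path) { visited.insert(e); visited.insert(rc_kmer(e, k)); }
    if (!circ) {
      std::string r = rc_string(s);
      if (r < s) s = r; // canonical orientation; cycles normalized later in R
    }
    contigs.push_back(s);
    circular.push_back(circ);
  };

  // linear unitigs: start at edges leaving a branching/terminal node
  for (uint64_t e : dir) {
    if (visited.count(e)) continue;
    uint64_t u = edge_prefix(e, g);
    if (deg(g.outdeg, u) == 1 && deg(g.indeg, u) == 1) continue;
    std::vector<uint64_t> path;
    path.push_back(e);
    uint64_t cur = e;
    while (true) {
      uint64_t v = edge_suffix(cur, g);
      if (deg(g.outdeg, v) != 1 || deg(g.indeg, v) != 1) break;
      uint64_t nxt = unique_out(v);
      if (nxt == path.front() || visited.count(nxt)) break;
      path.push_back(nxt);
      cur = nxt;
    }
    emit(path, false);
  }
  // remaining edges lie on perfect cycles (isolated circular components)
  for (uint64_t e : dir) {
    if (visited.count(e)) continue;
    std::vector<uint64_t> path;
    path.push_back(e);
    uint64_t cur = e;
    while (true) {
      uint64_t v = edge_suffix(cur, g);
      uint64_t nxt = unique_out(v);
      if (nxt == e) break;
      path.push_back(nxt);
      cur = nxt;
    }
    emit(path, true);
  }
  return List::create(_["contigs"] = wrap(contigs),
                      _["circular"] = wrap(circular),
                      _["n_solid_kmers"] = (int)solid.size());
}

// Booth's algorithm: index of the lexicographically minimal rotation.
// [[Rcpp::export(name = ".min_rotation_cpp")]]
int min_rotation_cpp(std::string s) {
  const int n = (int)s.size();
  if (n == 0) return 0;
  std::string ss = s + s;
  std::vector<int> f(2 * n, -1);
  int kk = 0;
  for (int j = 1; j < 2 * n; ++j) {
    int i = f[j - kk - 1];
    while (i != -1 && ss[j] != ss[kk + i + 1]) {
      if (ss[j] < ss[kk + i + 1]) kk = j - i - 1;
      i = f[i];
    }
    if (ss[j] != ss[kk + i + 1]) {
      if (ss[j] < ss[kk]) kk = j;
      f[j - kk] = -1;
    } else {
      f[j - kk] = i + 1;
    }
  }
  return kk;
}

// ---------------------------------------------------------------------------
// Ungapped seed-and-extend mapper. Candidate placements come from exact
// k_seed-mer hits; among candidates the placement with the fewest mismatches
// wins (ties: forward strand, then lowest coordinate). Circular references
// are extended by a wrap copy so fragments crossing the origin align.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".map_reads_cpp")]]
List map_reads_cpp(CharacterVector reads, std::string ref, int k_seed,
                   double max_mismatch_frac, bool circular) {
  const int L = (int)ref.size();
  int max_rl = 0;
  std::vector<std::string> rs(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    rs[i] = as<std::string>(reads[i]);
    max_rl = std::max(max_rl, (int)rs[i].size());
  }
  std::string ext = ref;
  if (circular && L > 0) ext += ref.substr(0, std::min(L, max_rl));
  std::unordered_map<uint64_t, std::vector<int>> index;
  scan_kmers(ext, k_seed, [&](int pos, uint64_t x) { index[x].push_back(pos); });

  const R_xlen_t n = reads.size();
  IntegerVector pos_out(n), mm_out(n);
  CharacterVector strand_out(n);
  LogicalVector mapped(n);
  IntegerMatrix pile(4, L);

  for (R_xlen_t i = 0; i < n; ++i) {
    const std::string& fwd = rs[i];
    const int rl = (int)fwd.size();
    if (rl > (int)ext.size()) { mapped[i] = false; pos_out[i] = NA_INTEGER; mm_out[i] = NA_INTEGER; strand_out[i] = NA_STRING; continue; }
    std::string rev = rc_string(fwd);
    int best_mm = rl + 1, best_pos = -1;
    int best_strand = 0; // 0 fwd, 1 rev
    for (int st = 0; st < 2; ++st) {
      const std::string& q = (st == 0) ? fwd : rev;
      std::unordered_set<uint64_t> cand;
      scan_kmers(q, k_seed, [&](int qpos, uint64_t x) {
        auto it = index.find(x);
        if (it == index.end()) return;
        for (int p : it->second) {
          int start = p - qpos;
          if (start < 0) { if (circular) start += L; else continue; }
          if (circular) start %= L;
          if (!circular && start + rl > (int)ext.size()) continue;
          if (circular && start + rl > (int)ext.size()) continue;
          cand.insert((uint64_t)start);
        }
      });
      std::vector<uint64_t> cv(cand.begin(), cand.end());
      std::sort(cv.begin(), cv.end());
      for (uint64_t c : cv) {
        int start = (int)c, mm = 0;
        for (int j = 0; j < rl && mm < best_mm; ++j)
          if (ext[start + j] != q[j]) ++mm;
        if (mm < best_mm) { best_mm = mm; best_pos = start; best_strand = st; }
        // ties: earlier strand (fwd) and lower coordinate win because of scan order
      }
    }
    if (best_pos >= 0 && best_mm <= max_mismatch_frac * rl) {
      mapped[i] = true;
      pos_out[i] = best_pos;
      mm_out[i] = best_mm;
      strand_out[i] = (best_strand == 0) ? "+" : "-";
      const std::string& q = (best_strand == 0) ? fwd : rev;
      // soft-clip: pile only the maximal-scoring subsegment
      // (match +1, mismatch -3), so divergent overhangs -- e.g. reads
      // spanning an inversion breakpoint -- do not pollute the pileup
      int best_s = 0, best_l = 0, best_r = -1, cur_s = 0, cur_l = 0;
      for (int j = 0; j < rl; ++j) {
        int sc = (ext[best_pos + j] == q[j]) ? 1 : -3;
        if (cur_s <= 0) { cur_s = sc; cur_l = j; }
        else cur_s += sc;
        if (cur_s > best_s) { best_s = cur_s; best_l = cur_l; best_r = j; }
      }
      for (int j = best_l; j <= best_r; ++j) {
        int c = BASE_CODE[(unsigned char)q[j]];
        if (c < 0) continue;
        int p = best_pos + j;
        if (p >= L) { if (!circular) continue; p -= L; }
        ++pile(c, p);
      }
    } else {
      mapped[i] = false;
      pos_out[i] = NA_INTEGER;
      mm_out[i] = NA_INTEGER;
      strand_out[i] = NA_STRING;
    }
  }
  return List::create(_["pos"] = pos_out, _["strand"] = strand_out,
                      _["mismatches"] = mm_out, _["mapped"] = mapped,
                      _["pileup"] = pile);
}

// ---------------------------------------------------------------------------
// Unique canonical k-mer anchors between two genomes (MUM-like).
// Circular genomes are scanned with a (k-1)-base wrap so every circular
// k-mer is counted exactly once; positions are on the forward strand.
// ---------------------------------------------------------------------------

struct KmerOcc { int count = 0; int pos = -1; bool fwd = true; };

static std::unordered_map<uint64_t, KmerOcc> occ_map(const std::string& seq, int k, bool circular) {
  std::string s = seq;
  if (circular && (int)seq.size() >= k) s += seq.substr(0, k - 1);
  std::unordered_map<uint64_t, KmerOcc> m;
  scan_kmers(s, k, [&](int pos, uint64_t x) {
    uint64_t r = rc_kmer(x, k);
    uint64_t canon = x < r ? x : r;
    KmerOcc& o = m[canon];
    ++o.count;
    if (o.count == 1) { o.pos = pos; o.fwd = (x <= r); }
  });
  return m;
}

// [[Rcpp::export(name = ".unique_anchors_cpp")]]
DataFrame unique_anchors_cpp(std::string a, std::string b, int k,
                             bool circular_a, bool circular_b) {
  std::unordered_map<uint64_t, KmerOcc> ma = occ_map(a, k, circular_a);
  std::unordered_map<uint64_t, KmerOcc> mb = occ_map(b, k, circular_b);
  std::vector<int> pa, pb;
  std::vector<bool> fw;
  for (auto& kv : ma) {
    if (kv.second.count != 1) continue;
    auto it = mb.find(kv.first);
    if (it == mb.end() || it->second.count != 1) continue;
    pa.push_back(kv.second.pos);
    pb.push_back(it->second.pos);
    fw.push_back(kv.second.fwd == it->second.fwd);
  }
  std::vector<size_t> ord(pa.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t x, size_t y) { return pa[x] < pa[y]; });
  IntegerVector oa(pa.size()), ob(pa.size());
  CharacterVector ori(pa.size());
  for (size_t i = 0; i < ord.size(); ++i) {
    oa[i] = pa[ord[i]];
    ob[i] = pb[ord[i]];
    ori[i] = fw[ord[i]] ? "forward" : "reverse";
  }
  return DataFrame::create(_["position_a"] = oa, _["position_b"] = ob,
                           _["orientation"] = ori, _["stringsAsFactors"] = false);
}

// Mismatch positions between two equal-length strings (1-based).
// [[Rcpp::export(name = ".mismatch_positions_cpp")]]
IntegerVector mismatch_positions_cpp(std::string a, std::string b) {
  if (a.size() != b.size()) stop("sequences must have equal length");
  std::vector<int> pos;
  for (size_t i = 0; i < a.size(); ++i)
    if (a[i] != b[i]) pos.push_back((int)i + 1);
  return wrap(pos);
}
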