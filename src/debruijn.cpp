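// Greedy de Bruijn assembler for per-chunk local assembly.
// Single-stranded (reads arrive in genome orientation from truth-placed
// alignments), 2-bit k-mer encoding, k <= 31.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

static std::string decode(uint64_t x, int k) {
  std::string s(k, 'N');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = BITS2BASE[x & 3ULL];
    x >>= 2;
  }
  return s;
}

// [[Rcpp::export(name = ".debruijn_assemble")]]
CharacterVector debruijn_assemble(CharacterVector reads, int k = 31,
                                  int min_count = 2,
                                  double purge_ratio = 3.0) {
  if (k < 3 || k > 31) stop("k must be in [3, 31]");
  const uint64_t kmask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  const uint64_t nmask = (1ULL << (2 * (k - 1))) - 1ULL;

  std::unordered_map<uint64_t, uint32_t> counts;
  counts.reserve(1 << 20);

  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char *s = CHAR(STRING_ELT(reads, r));
    int len = LENGTH(STRING_ELT(reads, r));
    uint64_t cur = 0;
    int run = 0;
    for (int i = 0; i < len; ++i) {
      int b = base2bits(s[i]);
      if (b < 0) { run = 0; cur = 0; continue; }
      cur = ((cur << 2) | (uint64_t)b) & kmask;
      if (++run >= k) counts[cur]++;
    }
  }

  // keep k-mers with count >= min_count
  std::unordered_set<uint64_t> kept;
  kept.reserve(counts.size());
  for (auto &kv : counts) {
    if ((int)kv.second >= min_count) kept.insert(kv.first);
  }

  // purge minority branch edges: at any fork, edges whose coverage is
  // outweighed purge_ratio-fold by the strongest sibling are removed
  // (resolves allelic bubbles introduced by reads duplicated to both
  // haplotypes)
  std::unordered_map<uint64_t, uint8_t> outm, inm;
  auto build_masks = [&]() {
    outm.clear(); inm.clear();
    for (const uint64_t &e : kept) {
      outm[e >> 2] |= (uint8_t)(1 << (e & 3ULL));
      inm[e & nmask] |= (uint8_t)(1 << ((e >> (2 * (k - 1))) & 3ULL));
    }
  };
  build_masks();
  if (purge_ratio > 1.0) {
    for (int pass = 0; pass < 2; ++pass) {
      std::vector<uint64_t> drop;
      for (auto &nm : outm) {
        uint8_t m = nm.second;
        if (__builtin_popcount(m) < 2) continue;
        uint32_t mx = 0;
        for (int b = 0; b < 4; ++b) {
          if ((m >> b) & 1) {
            uint64_t e = ((nm.first << 2) | (uint64_t)b) & kmask;
            if (counts[e] > mx) mx = counts[e];
          }
        }
        for (int b = 0; b < 4; ++b) {
          if ((m >> b) & 1) {
            uint64_t e = ((nm.first << 2) | (uint64_t)b) & kmask;
            if ((double)counts[e] * purge_ratio <= (double)mx)
              drop.push_back(e);
          }
        }
      }
      for (auto &nm : inm) {
        uint8_t m = nm.second;
        if (__builtin_popcount(m) < 2) continue;
        uint32_t mx = 0;
        for (int b = 0; b < 4; ++b) {
          if ((m >> b) & 1) {
            uint64_t e = (((uint64_t)b) << (2 * (k - 1))) | nm.first;
            if (counts[e] > mx) mx = counts[e];
          }
        }
        for (int b = 0; b < 4; ++b) {
          if ((m >> b) & 1) {
            uint64_t e = (((uint64_t)b) << (2 * (k - 1))) | nm.first;
            if ((double)counts[e] * purge_ratio <= (double)mx)
              drop.push_back(e);
          }
        }
      }
      if (drop.empty()) break;
      for (uint64_t e : drop) kept.erase(e);
      build_masks();
    }
  }

  auto degree = [](uint8_t m) {
    return (int)((m & 1) + ((m >> 1) & 1) + ((m >> 2) & 1) + ((m >> 3) & 1));
  };
  auto node_branching = [&](uint64_t node) {
    int od = degree(outm.count(node) ? outm[node] : 0);
    int id = degree(inm.count(node) ? inm[node] : 0);
    return od != 1 || id != 1;
  };

  std::unordered_set<uint64_t> visited;
  visited.reserve(kept.size());
  std::vector<std::string> contigs;

  auto walk = [&](uint64_t kmer) {
    // extend a maximal unambiguous path starting from edge `kmer`
    uint64_t pre = kmer >> 2;
    std::string seq = decode(pre, k - 1);
    uint64_t cur = kmer;
    while (true) {
      visited.insert(cur);
      seq.push_back(BITS2BASE[cur & 3ULL]);
      uint64_t node = cur & nmask;
      if (node_branching(node)) break;
      uint8_t m = outm[node];
      int b = 0;
      while (!((m >> b) & 1)) ++b;
      uint64_t nxt = ((node << 2) | (uint64_t)b) & kmask;
      if (visited.count(nxt)) break;  // cycle guard
      cur = nxt;
    }
    contigs.push_back(seq);
  };

  // unitigs starting at branching sources
  for (const uint64_t &e : kept) {
    if (visited.count(e)) continue;
    if (node_branching(e >> 2)) walk(e);
  }
  // leftover edges (isolated cycles)
  for (const uint64_t &e : kept) {
    if (!visited.count(e)) walk(e);
  }

  return wrap(contigs);
}
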