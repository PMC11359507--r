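// Seed-and-extend ungapped local alignment between two nucleotide
// sequences: exact word seeds, X-drop extension, greedy merge of
// overlapping extensions on the same diagonal. Scoring is match +1 /
// mismatch -2; E-values are attached in R (Karlin-Altschul).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static inline int baseCode(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

struct Seg {
  int qs, qe;      // query interval, 0-based half-open
  int diag;        // qs - ss
  int matches;
  int score;
};

// Recompute matches/score of a segment [qs,qe) on a fixed diagonal.
static void rescore(const std::string& q, const std::string& s,
                    Seg& seg) {
  int m = 0;
  int ss = seg.qs - seg.diag;
  for (int k = 0; k < seg.qe - seg.qs; ++k)
    if (q[seg.qs + k] == s[ss + k]) ++m;
  seg.matches = m;
  seg.score = m - 2 * ((seg.qe - seg.qs) - m);
}

// [[Rcpp::export(name = ".hsp_scan_cpp")]]
DataFrame hsp_scan_cpp(std::string q, std::string s, int w, double xdrop) {
  const int m = (int)q.size(), n = (int)s.size();
  const int MATCH = 1, MISMATCH = -2;
  std::vector<Seg> segs;

  if (m >= w && n >= w) {
    // hash subject words (skip any window with a non-ACGT char; inputs are
    // validated upstream so this is belt-and-braces)
    std::unordered_multimap<uint64_t, int> index;
    index.reserve(n);
    uint64_t word = 0, mask = (w >= 32) ? ~0ULL : ((1ULL << (2 * w)) - 1);
    int run = 0;
    for (int j = 0; j < n; ++j) {
      int c = baseCode(s[j]);
      if (c < 0) { run = 0; word = 0; continue; }
      word = ((word << 2) | (uint64_t)c) & mask;
      if (++run >= w) index.emplace(word, j - w + 1);
    }

    // per-diagonal coverage: furthest query end already extended
    std::unordered_map<int, int> cover;
    word = 0; run = 0;
    for (int i = 0; i < m; ++i) {
      int c = baseCode(q[i]);
      if (c < 0) { run = 0; word = 0; continue; }
      word = ((word << 2) | (uint64_t)c) & mask;
      if (++run < w) continue;
      int qpos = i - w + 1;
      auto range = index.equal_range(word);
      for (auto it = range.first; it != range.second; ++it) {
        int spos = it->second;
        int d = qpos - spos;
        auto cv = cover.find(d);
        if (cv != cover.end() && cv->second > qpos) continue;

        // seed scores +w (exact match); extend right from the seed end
        int best_score = w * MATCH, score = best_score;
        int best_r = qpos + w;  // query end (exclusive)
        {
          int qi = qpos + w, sj = spos + w;
          while (qi < m && sj < n) {
            score += (q[qi] == s[sj]) ? MATCH : MISMATCH;
            ++qi; ++sj;
            if (score > best_score) { best_score = score; best_r = qi; }
            else if (best_score - score > xdrop) break;
          }
        }
        // extend left from the seed start
        int best_l = qpos;
        {
          int score2 = best_score, best2 = best_score;
          int qi = qpos - 1, sj = spos - 1;
          while (qi >= 0 && sj >= 0) {
            score2 += (q[qi] == s[sj]) ? MATCH : MISMATCH;
            if (score2 > best2) { best2 = score2; best_l = qi; }
            else if (best2 - score2 > xdrop) break;
            --qi; --sj;
          }
          best_score = best2;
        }
        Seg seg; seg.qs = best_l; seg.qe = best_r; seg.diag = d;
        rescore(q, s, seg);
        segs.push_back(seg);
        cover[d] = best_r;
      }
    }
  }

  // greedy merge of overlapping segments on the same diagonal
  std::sort(segs.begin(), segs.end(), [](const Seg& a, const Seg& b) {
    if (a.diag != b.diag) return a.diag < b.diag;
    return a.qs < b.qs;
  });
  std::vector<Seg> merged;
  for (const Seg& seg : segs) {
    if (!merged.empty() && merged.back().diag == seg.diag &&
        seg.qs <= merged.back().qe) {
      if (seg.qe > merged.back().qe) {
        merged.back().qe = seg.qe;
        rescore(q, s, merged.back());
      }
    } else {
      merged.push_back(seg);
    }
  }

  const int N = (int)merged.size();
  IntegerVector qs(N), qe(N), ss(N), se(N), matches(N), score(N);
  for (int k = 0; k < N; ++k) {
    qs[k] = merged[k].qs; qe[k] = merged[k].qe;
    ss[k] = merged[k].qs - merged[k].diag;
    se[k] = merged[k].qe - merged[k].diag;
    matches[k] = merged[k].matches; score[k] = merged[k].score;
  }
  return DataFrame::create(_["q_start"] = qs, _["q_end"] = qe,
                           _["s_start"] = ss, _["s_end"] = se,
                           _["identities"] = matches, _["score"] = score);
}
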