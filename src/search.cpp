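// Seed-and-extend local nucleotide search.
//
// Exact word_size seeds on the given orientation, ungapped X-drop triage,
// then banded affine-gap local alignment around the seed diagonal with full
// traceback.  Gap of length L costs gap_open + L * gap_extend (both
// negative).  N (or any non-ACGT character) never seeds and always scores
// as a mismatch.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <string>
#include <cstdint>

using namespace Rcpp;

static inline int enc(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

struct Aln {
  int score = 0;
  int qs = 0, qe = 0, gs = 0, ge = 0;  // 0-based half-open
  int matches = 0, mismatches = 0, gapcols = 0;
  bool ok = false;
};

// Banded local alignment of the whole query against the genome, restricted
// to diagonals (j - i) within [d0 - band, d0 + band].
static Aln banded_align(const std::vector<int>& q, const std::vector<int>& g,
                        int d0, int band, int match, int mismatch,
                        int gap_open, int gap_extend) {
  const int NEG = -1000000000;
  const int qlen = (int)q.size(), glen = (int)g.size();
  const int W = 2 * band + 1;
  const int dlo = d0 - band;
  std::vector<int> Hprev(W, 0), Hcur(W, 0), Fprev(W, NEG), Fcur(W, NEG);
  std::vector<uint8_t> tbH((size_t)(qlen + 1) * W, 0),
      tbE((size_t)(qlen + 1) * W, 0), tbF((size_t)(qlen + 1) * W, 0);
  int best = 0, bi = -1, bb = -1;

  // row 0: H = 0 along valid cells (local alignment can start anywhere)
  for (int i = 1; i <= qlen; ++i) {
    int Ecur = NEG;
    for (int b = 0; b < W; ++b) {
      int j = i + dlo + b;
      Hcur[b] = 0; Fcur[b] = NEG;
      if (j < 0 || j > glen) { if (j < 0) Ecur = NEG; continue; }
      uint8_t oH = 0;
      int h = 0;
      if (j >= 1) {
        // diagonal: cell (i-1, j-1) is band index b in the previous row
        int hp = Hprev[b];
        int qa = q[i - 1], ga = g[j - 1];
        int s = (qa >= 0 && qa == ga) ? match : mismatch;
        int d = (hp <= NEG / 2) ? NEG : hp + s;
        if (d > h) { h = d; oH = 1; }
        // E: gap consuming genome, from (i, j-1) = band b-1, same row
        int e = NEG;
        uint8_t eext = 0;
        if (b >= 1) {
          int eo = Hcur[b - 1] + gap_open + gap_extend;
          int ee = (Ecur <= NEG / 2) ? NEG : Ecur + gap_extend;
          if (ee > eo) { e = ee; eext = 1; } else e = eo;
        }
        Ecur = e;
        tbE[(size_t)i * W + b] = eext;
        if (e > h) { h = e; oH = 2; }
        // F: gap consuming query, from (i-1, j) = band b+1, previous row
        int f = NEG;
        uint8_t fext = 0;
        if (b + 1 < W) {
          int fo = Hprev[b + 1] + gap_open + gap_extend;
          int fe = (Fprev[b + 1] <= NEG / 2) ? NEG : Fprev[b + 1] + gap_extend;
          if (fe > fo) { f = fe; fext = 1; } else f = fo;
        }
        Fcur[b] = f;
        tbF[(size_t)i * W + b] = fext;
        if (f > h) { h = f; oH = 3; }
      } else {
        Ecur = NEG;
      }
      if (h < 0) { h = 0; oH = 0; }
      Hcur[b] = h;
      tbH[(size_t)i * W + b] = oH;
      if (h > best) { best = h; bi = i; bb = b; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }

  Aln a;
  if (best <= 0) return a;
  a.ok = true;
  a.score = best;
  int i = bi, b = bb;
  a.qe = i; a.ge = i + dlo + b;
  char state = 'H';
  while (true) {
    size_t idx = (size_t)i * W + b;
    if (state == 'H') {
      uint8_t o = tbH[idx];
      if (o == 0) break;
      if (o == 1) {
        int j = i + dlo + b;
        int qa = q[i - 1], ga = g[j - 1];
        if (qa >= 0 && qa == ga) a.matches++; else a.mismatches++;
        i -= 1;  // b unchanged: j also decreases
      } else if (o == 2) state = 'E';
      else state = 'F';
    } else if (state == 'E') {
      a.gapcols++;
      uint8_t ext = tbE[idx];
      b -= 1;  // consume one genome base
      if (!ext) state = 'H';
    } else {  // F
      a.gapcols++;
      uint8_t ext = tbF[idx];
      i -= 1; b += 1;  // consume one query base
      if (!ext) state = 'H';
    }
    if (i == 0 && state == 'H') break;
  }
  a.qs = i; a.gs = i + dlo + b;
  return a;
}

// [[Rcpp::export]]
DataFrame cpp_local_search(std::string query, std::string genome,
                           int word_size, int match, int mismatch,
                           int gap_open, int gap_extend, int min_score,
                           int xdrop, int band, int gap_trigger) {
  const int qlen = (int)query.size(), glen = (int)genome.size();
  if (qlen < word_size) stop("query shorter than word_size");
  std::vector<int> q(qlen), g(glen);
  for (int i = 0; i < qlen; ++i) q[i] = enc(query[i]);
  for (int j = 0; j < glen; ++j) g[j] = enc(genome[j]);

  // index query words
  const int nwords = 1 << (2 * word_size);
  const int wmask = nwords - 1;
  std::vector<std::vector<int>> index(nwords);
  {
    int code = 0, run = 0;
    for (int i = 0; i < qlen; ++i) {
      if (q[i] < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | q[i]) & wmask;
      if (++run >= word_size) index[code].push_back(i - word_size + 1);
    }
  }

  std::unordered_map<long long, int> diag_ext;  // diagonal -> genome pos reached
  std::vector<Aln> hits;

  int code = 0, run = 0;
  for (int jg = 0; jg < glen; ++jg) {
    if (g[jg] < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | g[jg]) & wmask;
    if (++run < word_size) continue;
    int gp = jg - word_size + 1;
    const std::vector<int>& qps = index[code];
    for (size_t t = 0; t < qps.size(); ++t) {
      int qp = qps[t];
      long long diag = (long long)gp - qp;
      auto it = diag_ext.find(diag);
      if (it != diag_ext.end() && gp < it->second) continue;

      // ungapped X-drop extension around the seed
      int sc = word_size * match;
      int bestsc = sc;
      int qi = qp + word_size, gi = gp + word_size;
      int right_reach = gi;
      while (qi < qlen && gi < glen) {
        sc += (q[qi] >= 0 && q[qi] == g[gi]) ? match : mismatch;
        ++qi; ++gi;
        if (sc > bestsc) { bestsc = sc; right_reach = gi; }
        if (bestsc - sc > xdrop) break;
      }
      sc = bestsc;
      qi = qp - 1; gi = gp - 1;
      while (qi >= 0 && gi >= 0) {
        sc += (q[qi] >= 0 && q[qi] == g[gi]) ? match : mismatch;
        if (sc > bestsc) bestsc = sc;
        if (bestsc - sc > xdrop) break;
        --qi; --gi;
      }
      diag_ext[diag] = right_reach;
      if (bestsc < gap_trigger) continue;

      Aln a = banded_align(q, g, (int)diag, band, match, mismatch,
                           gap_open, gap_extend);
      if (!a.ok || a.score < min_score) continue;
      hits.push_back(a);
      long long d1 = (long long)a.gs - a.qs, d2 = (long long)a.ge - a.qe;
      if (d2 < d1) std::swap(d1, d2);
      for (long long d = d1 - band; d <= d2 + band; ++d) {
        auto e = diag_ext.find(d);
        if (e == diag_ext.end() || e->second < a.ge) diag_ext[d] = a.ge;
      }
    }
  }

  int n = (int)hits.size();
  IntegerVector qs(n), qe(n), gs(n), ge(n), score(n), mat(n), mis(n), gap(n);
  for (int i = 0; i < n; ++i) {
    qs[i] = hits[i].qs; qe[i] = hits[i].qe;
    gs[i] = hits[i].gs; ge[i] = hits[i].ge;
    score[i] = hits[i].score; mat[i] = hits[i].matches;
    mis[i] = hits[i].mismatches; gap[i] = hits[i].gapcols;
  }
  return DataFrame::create(
      Named("qstart") = qs, Named("qend") = qe, Named("gstart") = gs,
      Named("gend") = ge, Named("score") = score, Named("matches") = mat,
      Named("mismatches") = mis, Named("gapcols") = gap);
}
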