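#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <functional>
#include <algorithm>
using namespace Rcpp;

// Pixel indexing: column-major R matrix, pix = r + c*nr, 0-based (row, col).

static inline int round_half_down(double x) {
  // nearest integer, exact .5 ties toward the smaller integer
  return (int)std::ceil(x - 0.5);
}

// ---------------------------------------------------------------------------
// Noise-tolerance maxima finding.
//
// A candidate is a plateau: a maximal 8-connected set of equal-valued pixels
// none of which has an 8-neighbour of strictly greater value. A candidate of
// value v is accepted iff every 8-connected path from it to a strictly
// higher pixel descends to <= v - tol somewhere; equivalently, a BFS from
// the plateau restricted to pixels of value > v - tol meets no pixel > v.
// Among equal-valued accepted candidates connected above that floor only
// one point is emitted (smallest rounded centroid, row then col). A plateau
// touching the border whose value equals the global maximum is suppressed
// (a flat field holds no identifiable spot).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_find_maxima(IntegerMatrix img, double tol) {
  const int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
  const int *v = INTEGER(img);

  static const int dr8[8] = {-1,-1,-1, 0, 0, 1, 1, 1};
  static const int dc8[8] = {-1, 0, 1,-1, 1,-1, 0, 1};

  std::vector<int> plat(n, -1);          // plateau id per pixel
  std::vector<int> pval;                 // plateau value
  std::vector<char> is_cand;             // no strictly-greater neighbour
  std::vector<char> border;              // plateau touches image border
  std::vector<int> cen_r, cen_c;         // rounded centroids
  std::vector<int> bfs;
  bfs.reserve(1024);

  int gmax = v[0];
  for (int i = 1; i < n; ++i) if (v[i] > gmax) gmax = v[i];

  int np = 0;
  for (int start = 0; start < n; ++start) {
    if (plat[start] >= 0) continue;
    const int val = v[start];
    bool cand = true, touch = false;
    long long sr = 0, sc = 0; long cnt = 0;
    bfs.clear(); bfs.push_back(start); plat[start] = np;
    for (size_t h = 0; h < bfs.size(); ++h) {
      const int p = bfs[h], r = p % nr, c = p / nr;
      if (r == 0 || r == nr - 1 || c == 0 || c == nc - 1) touch = true;
      sr += r; sc += c; ++cnt;
      for (int k = 0; k < 8; ++k) {
        const int rr = r + dr8[k], cc = c + dc8[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        const int q = rr + cc * nr;
        if (v[q] == val) {
          if (plat[q] < 0) { plat[q] = np; bfs.push_back(q); }
        } else if (v[q] > val) {
          cand = false;
        }
      }
    }
    pval.push_back(val);
    is_cand.push_back(cand ? 1 : 0);
    border.push_back(touch ? 1 : 0);
    cen_r.push_back(round_half_down((double)sr / cnt));
    cen_c.push_back(round_half_down((double)sc / cnt));
    ++np;
  }

  // union-find over plateaus (groups equal-valued candidates reachable
  // above the tolerance floor)
  std::vector<int> uf(np);
  for (int i = 0; i < np; ++i) uf[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (uf[x] != x) { uf[x] = uf[uf[x]]; x = uf[x]; }
    return x;
  };

  std::vector<char> accepted(np, 0);
  std::vector<int> stamp(n, -1);
  int cur = 0;

  // first pixel (raster order in our scan) of each plateau
  std::vector<int> rep(np, -1);
  for (int i = 0; i < n; ++i) if (rep[plat[i]] < 0) rep[plat[i]] = i;

  for (int pi = 0; pi < np; ++pi) {
    if (!is_cand[pi]) continue;
    const int val = pval[pi];
    if (border[pi] && val == gmax) continue;
    const double floor_v = (double)val - tol;
    bool ok = true;
    ++cur;
    bfs.clear();
    bfs.push_back(rep[pi]); stamp[rep[pi]] = cur;
    for (size_t h = 0; h < bfs.size() && ok; ++h) {
      const int p = bfs[h], r = p % nr, c = p / nr;
      for (int k = 0; k < 8; ++k) {
        const int rr = r + dr8[k], cc = c + dc8[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        const int q = rr + cc * nr;
        if (stamp[q] == cur) continue;
        if (v[q] > val) { ok = false; break; }
        if ((double)v[q] > floor_v || plat[q] == pi) {
          // equal-valued plateau pixels always belong (v == val > floor
          // unless tol == 0, where plateau membership admits them)
          stamp[q] = cur;
          bfs.push_back(q);
          if (v[q] == val && plat[q] != pi && is_cand[plat[q]])
            uf[find(plat[q])] = find(pi);
        }
      }
    }
    if (ok) accepted[pi] = 1;
  }

  // one point per union group of accepted candidates: smallest centroid
  std::vector<int> best(np, -1);
  for (int pi = 0; pi < np; ++pi) {
    if (!accepted[pi]) continue;
    int g = find(pi);
    if (best[g] < 0 ||
        cen_r[pi] < cen_r[best[g]] ||
        (cen_r[pi] == cen_r[best[g]] && cen_c[pi] < cen_c[best[g]]))
      best[g] = pi;
  }
  std::vector<std::pair<int,int> > pts;
  for (int g = 0; g < np; ++g)
    if (best[g] >= 0 && find(g) == g)
      pts.push_back(std::make_pair(cen_r[best[g]], cen_c[best[g]]));
  std::sort(pts.begin(), pts.end());

  IntegerMatrix out((int)pts.size(), 2);
  for (size_t i = 0; i < pts.size(); ++i) {
    out(i, 0) = pts[i].first;
    out(i, 1) = pts[i].second;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Seeded watershed: basins flood from seed points in order of decreasing
// intensity; within an intensity level fronts advance by synchronous
// geodesic waves, so mirror-symmetric inputs give mirror-symmetric basins.
// A pixel reached in the same wave by two basins becomes boundary (0).
// 4-connected growth. Unreached pixels (enclosed by boundary) become 0.
// ---------------------------------------------------------------------------

struct WsEntry {
  int v, d, pix, label;
};
struct WsCmp {
  bool operator()(const WsEntry &a, const WsEntry &b) const {
    if (a.v != b.v) return a.v < b.v;      // higher intensity first
    return a.d > b.d;                      // smaller wave distance first
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_watershed(IntegerMatrix img, IntegerMatrix seeds) {
  const int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
  const int *v = INTEGER(img);
  const int ns = seeds.nrow();
  static const int dr4[4] = {-1, 1, 0, 0};
  static const int dc4[4] = { 0, 0,-1, 1};

  std::vector<int> lab(n, -1);   // -1 unassigned; 0 boundary; >0 basin
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCmp> pq;

  for (int i = 0; i < ns; ++i) {
    const int r = seeds(i, 0), c = seeds(i, 1);
    if (r < 0 || r >= nr || c < 0 || c >= nc)
      stop("seed outside image bounds");
    lab[r + c * nr] = i + 1;
  }
  for (int i = 0; i < ns; ++i) {
    const int r = seeds(i, 0), c = seeds(i, 1), L = i + 1;
    for (int k = 0; k < 4; ++k) {
      const int rr = r + dr4[k], cc = c + dc4[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      const int q = rr + cc * nr;
      if (lab[q] < 0) pq.push(WsEntry{v[q], 1, q, L});
    }
  }

  std::vector<int> batch_pix;
  std::vector<int> batch_lab;
  while (!pq.empty()) {
    const int bv = pq.top().v, bd = pq.top().d;
    batch_pix.clear(); batch_lab.clear();
    while (!pq.empty() && pq.top().v == bv && pq.top().d == bd) {
      const WsEntry e = pq.top(); pq.pop();
      if (lab[e.pix] >= 0) continue;
      batch_pix.push_back(e.pix);
      batch_lab.push_back(e.label);
    }
    // per-pixel distinct labels within the batch
    // (batches are small; linear grouping via sort of pairs)
    std::vector<std::pair<int,int> > pl(batch_pix.size());
    for (size_t i = 0; i < batch_pix.size(); ++i)
      pl[i] = std::make_pair(batch_pix[i], batch_lab[i]);
    std::sort(pl.begin(), pl.end());
    std::vector<int> newly;
    for (size_t i = 0; i < pl.size();) {
      size_t j = i;
      int first_lab = pl[i].second;
      bool conflict = false;
      while (j < pl.size() && pl[j].first == pl[i].first) {
        if (pl[j].second != first_lab) conflict = true;
        ++j;
      }
      lab[pl[i].first] = conflict ? 0 : first_lab;
      if (!conflict) newly.push_back(pl[i].first);
      i = j;
    }
    for (size_t i = 0; i < newly.size(); ++i) {
      const int p = newly[i], L = lab[p], r = p % nr, c = p / nr;
      for (int k = 0; k < 4; ++k) {
        const int rr = r + dr4[k], cc = c + dc4[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        const int q = rr + cc * nr;
        if (lab[q] >= 0) continue;
        const int qv = v[q];
        if (qv >= bv) pq.push(WsEntry{bv, bd + 1, q, L});
        else          pq.push(WsEntry{qv, 1, q, L});
      }
    }
  }

  IntegerMatrix out(nr, nc);
  int *o = INTEGER(out);
  for (int i = 0; i < n; ++i) o[i] = lab[i] < 0 ? 0 : lab[i];
  return out;
}

// ---------------------------------------------------------------------------
// 4-connected component labelling of a binary mask (nonzero = foreground).
// Labels assigned 1..k in raster discovery order (column-major R order).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_label4(IntegerMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol(), n = nr * nc;
  const int *m = INTEGER(mask);
  IntegerMatrix out(nr, nc);
  int *lab = INTEGER(out);
  static const int dr4[4] = {-1, 1, 0, 0};
  static const int dc4[4] = { 0, 0,-1, 1};
  std::vector<int> bfs;
  int next = 0;
  for (int s = 0; s < n; ++s) {
    if (!m[s] || lab[s]) continue;
    ++next;
    bfs.clear(); bfs.push_back(s); lab[s] = next;
    for (size_t h = 0; h < bfs.size(); ++h) {
      const int p = bfs[h], r = p % nr, c = p / nr;
      for (int k = 0; k < 4; ++k) {
        const int rr = r + dr4[k], cc = c + dc4[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        const int q = rr + cc * nr;
        if (m[q] && !lab[q]) { lab[q] = next; bfs.push_back(q); }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Fill holes of a binary mask: background (zero) pixels not 4-connected to
// the image border become foreground.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_fill_holes(IntegerMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol(), n = nr * nc;
  const int *m = INTEGER(mask);
  std::vector<char> outside(n, 0);
  static const int dr4[4] = {-1, 1, 0, 0};
  static const int dc4[4] = { 0, 0,-1, 1};
  std::vector<int> bfs;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; r += (nr > 1 ? nr - 1 : 1)) {
      const int p = r + c * nr;
      if (!m[p] && !outside[p]) { outside[p] = 1; bfs.push_back(p); }
      if (nr == 1) break;
    }
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; c += (nc > 1 ? nc - 1 : 1)) {
      const int p = r + c * nr;
      if (!m[p] && !outside[p]) { outside[p] = 1; bfs.push_back(p); }
      if (nc == 1) break;
    }
  for (size_t h = 0; h < bfs.size(); ++h) {
    const int p = bfs[h], r = p % nr, c = p / nr;
    for (int k = 0; k < 4; ++k) {
      const int rr = r + dr4[k], cc = c + dc4[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      const int q = rr + cc * nr;
      if (!m[q] && !outside[q]) { outside[q] = 1; bfs.push_back(q); }
    }
  }
  IntegerMatrix out(nr, nc);
  int *o = INTEGER(out);
  for (int i = 0; i < n; ++i) o[i] = (m[i] || !outside[i]) ? 1 : 0;
  return out;
}
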