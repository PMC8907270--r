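// Cellular Potts engine: Metropolis dynamics on a periodic 2D lattice with
// area/perimeter constraints, differential adhesion and a polarity-driven
// persistence term.  Copy-attempt sources are drawn from the Moore
// neighborhood; perimeter and adhesion interfaces are counted over the von
// Neumann neighborhood.  Incremental caches (area, perimeter, centroid sums
// in unwrapped coordinates) are maintained per cell; tests compare them
// against full recounts and brute-force Hamiltonian differences.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct SplitMix {
  // deterministic 64-bit generator, identical across platforms
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  // [0, n) with negligible modulo bias for n << 2^64
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

inline double wrap_delta(double d, double L) {
  if (d > 0.5 * L) d -= L;
  else if (d < -0.5 * L) d += L;
  return d;
}

} // namespace

// [[Rcpp::export]]
List cpm_run_cpp(IntegerMatrix grid_in,
                 IntegerVector cell_pheno,    // index = cell id (1..K); 1 normal, 2 senescent
                 NumericVector area_target,
                 NumericVector perim_target,
                 NumericVector S_strength,
                 NumericVector px_in,
                 NumericVector py_in,
                 NumericMatrix Emat,          // 3x3 adhesion by phenotype (0 = medium)
                 double lambda_area,
                 double lambda_perim,
                 double temperature,
                 double tau,
                 int n_mcs,
                 double seed,
                 int mcs0,
                 int record_every,
                 bool record_contacts,
                 bool audit,
                 int audit_max) {
  const int W = grid_in.nrow(), H = grid_in.ncol();
  const int N = W * H;
  const int K = cell_pheno.size();

  std::vector<int> g(N);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) g[x + y * W] = grid_in(x, y);

  std::vector<int> xp(W), xm(W), yp(H), ym(H);
  for (int x = 0; x < W; ++x) { xp[x] = (x + 1) % W; xm[x] = (x + W - 1) % W; }
  for (int y = 0; y < H; ++y) { yp[y] = (y + 1) % H; ym[y] = (y + H - 1) % H; }

  // per-cell caches, index by id (0 = medium, unused)
  std::vector<double> area(K + 1, 0), perim(K + 1, 0), sumx(K + 1, 0), sumy(K + 1, 0);
  std::vector<double> px(K + 1, 0), py(K + 1, 0), At(K + 1, 0), Pt(K + 1, 0), Sv(K + 1, 0);
  std::vector<int> ph(K + 1, 0);
  std::vector<double> refx(K + 1, -1), refy(K + 1, -1);
  for (int c = 1; c <= K; ++c) {
    ph[c] = cell_pheno[c - 1];
    At[c] = area_target[c - 1];
    Pt[c] = perim_target[c - 1];
    Sv[c] = S_strength[c - 1];
    px[c] = px_in[c - 1];
    py[c] = py_in[c - 1];
  }

  // initial geometry: areas + centroid sums unwrapped relative to the first
  // site seen per cell (valid while cell diameter < half the domain)
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      int c = g[x + y * W];
      if (c == 0) continue;
      if (c > K) stop("grid contains id not present in the cell table");
      if (refx[c] < 0) { refx[c] = x; refy[c] = y; }
      area[c] += 1.0;
      sumx[c] += refx[c] + wrap_delta(x - refx[c], W);
      sumy[c] += refy[c] + wrap_delta(y - refy[c], H);
    }
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      int c = g[x + y * W];
      if (c == 0) continue;
      int nb[4] = { g[xp[x] + y * W], g[xm[x] + y * W], g[x + yp[y] * W], g[x + ym[y] * W] };
      for (int k = 0; k < 4; ++k) if (nb[k] != c) perim[c] += 1.0;
    }

  const int moore_dx[8] = { 1, -1, 0, 0, 1, 1, -1, -1 };
  const int moore_dy[8] = { 0, 0, 1, -1, 1, -1, 1, -1 };

  SplitMix rng(static_cast<uint64_t>(seed) * 0x5DEECE66DULL + 11ULL);

  // track / contact / audit accumulators
  std::vector<int> tr_mcs, tr_id;
  std::vector<double> tr_area, tr_perim, tr_cx, tr_cy, tr_px, tr_py;
  std::vector<int> ct_mcs, ct_norm, ct_sen, ct_edges;
  std::vector<int> au_x, au_y, au_sx, au_sy, au_a, au_b, au_acc;
  std::vector<double> au_da, au_dp, au_dh_ad, au_dpe;
  double sum_abs_area = 0, sum_abs_perim = 0, sum_abs_adh = 0, sum_abs_pers = 0;
  double n_eval = 0;

  auto record_state = [&](int mcs_now) {
    for (int c = 1; c <= K; ++c) {
      if (area[c] <= 0) continue;
      tr_mcs.push_back(mcs_now);
      tr_id.push_back(c);
      tr_area.push_back(area[c]);
      tr_perim.push_back(perim[c]);
      tr_cx.push_back(sumx[c] / area[c] + 1.0);
      tr_cy.push_back(sumy[c] / area[c] + 1.0);
      tr_px.push_back(px[c]);
      tr_py.push_back(py[c]);
    }
    if (record_contacts) {
      std::map<std::pair<int, int>, int> edges;
      for (int y = 0; y < H; ++y)
        for (int x = 0; x < W; ++x) {
          int a = g[x + y * W];
          int b1 = g[xp[x] + y * W];
          int b2 = g[x + yp[y] * W];
          for (int b : { b1, b2 }) {
            if (a == b || a == 0 || b == 0) continue;
            if (ph[a] == 1 && ph[b] == 2) edges[{a, b}]++;
            else if (ph[a] == 2 && ph[b] == 1) edges[{b, a}]++;
          }
        }
      for (auto& kv : edges) {
        ct_mcs.push_back(mcs_now);
        ct_norm.push_back(kv.first.first);
        ct_sen.push_back(kv.first.second);
        ct_edges.push_back(kv.second);
      }
    }
  };

  record_state(mcs0);

  std::vector<double> cx_prev(K + 1, 0), cy_prev(K + 1, 0);
  for (int c = 1; c <= K; ++c)
    if (area[c] > 0) { cx_prev[c] = sumx[c] / area[c]; cy_prev[c] = sumy[c] / area[c]; }

  for (int mcs = 1; mcs <= n_mcs; ++mcs) {
    for (int att = 0; att < N; ++att) {
      int idx = rng.below(N);
      int x = idx % W, y = idx / W;
      int k = rng.below(8);
      int sx = (x + moore_dx[k] + W) % W;
      int sy = (y + moore_dy[k] + H) % H;
      int a = g[idx];
      int b = g[sx + sy * W];
      if (a == b) continue;

      int nb_id[4] = { g[xp[x] + y * W], g[xm[x] + y * W], g[x + yp[y] * W], g[x + ym[y] * W] };

      // area
      double dH_area = 0;
      if (a != 0) dH_area += lambda_area * ((At[a] - (area[a] - 1)) * (At[a] - (area[a] - 1)) -
                                            (At[a] - area[a]) * (At[a] - area[a]));
      if (b != 0) dH_area += lambda_area * ((At[b] - (area[b] + 1)) * (At[b] - (area[b] + 1)) -
                                            (At[b] - area[b]) * (At[b] - area[b]));

      // perimeter (von Neumann edge counts)
      int na = 0, nbn = 0;
      for (int q = 0; q < 4; ++q) { if (nb_id[q] == a) ++na; if (nb_id[q] == b) ++nbn; }
      int dPa = 2 * na - 4, dPb = 4 - 2 * nbn;
      double dH_perim = 0;
      if (a != 0) dH_perim += lambda_perim * ((Pt[a] - (perim[a] + dPa)) * (Pt[a] - (perim[a] + dPa)) -
                                              (Pt[a] - perim[a]) * (Pt[a] - perim[a]));
      if (b != 0) dH_perim += lambda_perim * ((Pt[b] - (perim[b] + dPb)) * (Pt[b] - (perim[b] + dPb)) -
                                              (Pt[b] - perim[b]) * (Pt[b] - perim[b]));

      // adhesion over the 4 interface edges at the target site
      // adhesion over the 4 von Neumann interface edges at the target site
      double dH_adh = 0;
      int phb = (b == 0) ? 0 : ph[b], pha = (a == 0) ? 0 : ph[a];
      for (int q = 0; q < 4; ++q) {
        int qid = nb_id[q];
        int phq = (qid == 0) ? 0 : ph[qid];
        if (qid != b) dH_adh += Emat(phb, phq);
        if (qid != a) dH_adh -= Emat(pha, phq);
      }

      // persistence: -S * (dx . p_hat) per affected non-medium cell
      double dH_pers = 0;
      double xrep_a = 0, yrep_a = 0, xrep_b = 0, yrep_b = 0;
      if (a != 0) {
        double cx = sumx[a] / area[a], cy = sumy[a] / area[a];
        xrep_a = cx + wrap_delta(x - (cx - W * std::floor(cx / W)), W);
        yrep_a = cy + wrap_delta(y - (cy - H * std::floor(cy / H)), H);
        if (area[a] > 1 && Sv[a] != 0) {
          double nrm = std::sqrt(px[a] * px[a] + py[a] * py[a]);
          if (nrm > 1e-12) {
            // center-of-mass shift scaled by cell area (per-site magnitude)
            double dx = ((sumx[a] - xrep_a) / (area[a] - 1) - cx) * area[a];
            double dy = ((sumy[a] - yrep_a) / (area[a] - 1) - cy) * area[a];
            dH_pers -= Sv[a] * (dx * px[a] + dy * py[a]) / nrm;
          }
        }
      }
      if (b != 0) {
        double cx = sumx[b] / area[b], cy = sumy[b] / area[b];
        xrep_b = cx + wrap_delta(x - (cx - W * std::floor(cx / W)), W);
        yrep_b = cy + wrap_delta(y - (cy - H * std::floor(cy / H)), H);
        if (Sv[b] != 0) {
          double nrm = std::sqrt(px[b] * px[b] + py[b] * py[b]);
          if (nrm > 1e-12) {
            double dx = ((sumx[b] + xrep_b) / (area[b] + 1) - cx) * area[b];
            double dy = ((sumy[b] + yrep_b) / (area[b] + 1) - cy) * area[b];
            dH_pers -= Sv[b] * (dx * px[b] + dy * py[b]) / nrm;
          }
        }
      }

      double dH = dH_area + dH_perim + dH_adh + dH_pers;
      bool accept = (dH <= 0) || (rng.unif() < std::exp(-dH / temperature));

      sum_abs_area += std::fabs(dH_area);
      sum_abs_perim += std::fabs(dH_perim);
      sum_abs_adh += std::fabs(dH_adh);
      sum_abs_pers += std::fabs(dH_pers);
      n_eval += 1;

      if (audit && (int)au_x.size() < audit_max) {
        au_x.push_back(x + 1); au_y.push_back(y + 1);
        au_sx.push_back(sx + 1); au_sy.push_back(sy + 1);
        au_a.push_back(a); au_b.push_back(b);
        au_da.push_back(dH_area); au_dp.push_back(dH_perim);
        au_dh_ad.push_back(dH_adh); au_dpe.push_back(dH_pers);
        au_acc.push_back(accept ? 1 : 0);
      }

      if (!accept) continue;

      g[idx] = b;
      if (a != 0) {
        area[a] -= 1.0; perim[a] += dPa;
        sumx[a] -= xrep_a; sumy[a] -= yrep_a;
        if (area[a] <= 0) { perim[a] = 0; sumx[a] = 0; sumy[a] = 0; }
      }
      if (b != 0) {
        area[b] += 1.0; perim[b] += dPb;
        sumx[b] += xrep_b; sumy[b] += yrep_b;
      }
    }

    // polarity update once per MCS from the net centroid displacement
    for (int c = 1; c <= K; ++c) {
      if (area[c] <= 0) continue;
      double cx = sumx[c] / area[c], cy = sumy[c] / area[c];
      double drx = cx - cx_prev[c], dry = cy - cy_prev[c];
      px[c] += drx - px[c] / tau;
      py[c] += dry - py[c] / tau;
      cx_prev[c] = cx; cy_prev[c] = cy;
    }

    if (mcs % record_every == 0 || mcs == n_mcs) record_state(mcs0 + mcs);
  }

  IntegerMatrix grid_out(W, H);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) grid_out(x, y) = g[x + y * W];

  NumericVector out_area(K), out_perim(K), out_cx(K), out_cy(K), out_px(K), out_py(K);
  for (int c = 1; c <= K; ++c) {
    out_area[c - 1] = area[c];
    out_perim[c - 1] = perim[c];
    out_cx[c - 1] = area[c] > 0 ? sumx[c] / area[c] + 1.0 : NA_REAL;
    out_cy[c - 1] = area[c] > 0 ? sumy[c] / area[c] + 1.0 : NA_REAL;
    out_px[c - 1] = px[c];
    out_py[c - 1] = py[c];
  }

  List tracks = List::create(
    _["mcs"] = tr_mcs, _["cell_id"] = tr_id, _["area"] = tr_area,
    _["perimeter"] = tr_perim, _["cx"] = tr_cx, _["cy"] = tr_cy,
    _["px"] = tr_px, _["py"] = tr_py);
  List contacts = List::create(
    _["mcs"] = ct_mcs, _["normal_id"] = ct_norm, _["sen_id"] = ct_sen,
    _["edges"] = ct_edges);
  List dh_report = List::create(
    _["area"] = n_eval > 0 ? sum_abs_area / n_eval : NA_REAL,
    _["perimeter"] = n_eval > 0 ? sum_abs_perim / n_eval : NA_REAL,
    _["adhesion"] = n_eval > 0 ? sum_abs_adh / n_eval : NA_REAL,
    _["persistence"] = n_eval > 0 ? sum_abs_pers / n_eval : NA_REAL,
    _["n_evaluated"] = n_eval);
  List attempts = List::create(
    _["x"] = au_x, _["y"] = au_y, _["sx"] = au_sx, _["sy"] = au_sy,
    _["source_id"] = au_b, _["target_id"] = au_a,
    _["dh_area"] = au_da, _["dh_perimeter"] = au_dp,
    _["dh_adhesion"] = au_dh_ad, _["dh_persistence"] = au_dpe,
    _["accepted"] = au_acc);

  return List::create(
    _["grid"] = grid_out, _["area"] = out_area, _["perimeter"] = out_perim,
    _["cx"] = out_cx, _["cy"] = out_cy, _["px"] = out_px, _["py"] = out_py,
    _["tracks"] = tracks, _["contacts"] = contacts,
    _["dh_report"] = dh_report, _["attempts"] = attempts,
    _["mcs_elapsed"] = mcs0 + n_mcs);
}
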