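// Core integrator for the attention-limited flocking model.
//
// Agents are self-propelled particles on an L x L torus. Each agent attends to
// its k nearest objects (other agents or danger sites); a danger site inside
// the repulsion radius that occupies an attention slot triggers pure repulsion
// (g = 1), otherwise the agent aligns with the agents in its attention set and,
// if informed, biases toward the preferred direction. Headings follow an
// Euler-Maruyama step with Gaussian angular noise; positions advance with the
// post-update heading at constant speed.
//
// Neighbor queries use a periodic cell list with expanding Chebyshev rings and
// fall back to a brute-force scan when the ring construction would alias
// (small boxes relative to the requested k).
//
// All randomness comes from R's RNG (norm_rand/unif_rand) so that set.seed()
// in R makes whole trajectories reproducible, and so the pure-R reference
// integrator can replay the identical stream: per step, one uniform draw per
// agent inside a repulsion zone (only when p_direct > 0), then one normal
// draw per agent, in agent-index order.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double wrap_pos(double x, double L) {
  double w = x - L * std::floor(x / L);
  if (w >= L) w -= L;   // guard against round-off at the boundary
  if (w < 0) w = 0;
  return w;
}

// shortest displacement component on the torus, result in [-L/2, L/2)
static inline double min_image(double d, double L) {
  double h = 0.5 * L;
  if (d >= h) d -= L;
  else if (d < -h) d += L;
  return d;
}

// wrap angle into (-pi, pi]
static inline double wrap_angle(double a) {
  const double tau = 2.0 * M_PI;
  double s = a + M_PI;
  double w = s - tau * std::floor(s / tau);
  if (w <= 0 || w > tau) w = tau;   // boundary maps to +pi
  return w - M_PI;
}

// simple linked-cell list over a periodic square grid
struct CellList {
  int ng = 0;
  double cell = 0.0;
  std::vector<int> head, nxt;

  void build(const std::vector<double>& x, const std::vector<double>& y,
             double L, int ng_) {
    ng = ng_;
    cell = L / ng;
    head.assign(ng * ng, -1);
    nxt.assign(x.size(), -1);
    for (int i = 0; i < (int)x.size(); ++i) {
      int cx = (int)(x[i] / cell); if (cx >= ng) cx = ng - 1;
      int cy = (int)(y[i] / cell); if (cy >= ng) cy = ng - 1;
      int c = cy * ng + cx;
      nxt[i] = head[c];
      head[c] = i;
    }
  }
};

// ordered k-best insertion keyed on (squared distance, object id); ids break
// exact ties deterministically (agents indexed before danger sites)
static inline void kb_insert(std::vector<double>& bd, std::vector<int>& bi,
                             int& n, int keff, double d2, int id) {
  if (n == keff) {
    double wd = bd[n - 1];
    if (d2 > wd || (d2 == wd && id > bi[n - 1])) return;
  }
  int j = (n < keff) ? n : keff - 1;
  while (j > 0 && (bd[j - 1] > d2 || (bd[j - 1] == d2 && bi[j - 1] > id))) {
    bd[j] = bd[j - 1]; bi[j] = bi[j - 1];
    --j;
  }
  bd[j] = d2; bi[j] = id;
  if (n < keff) ++n;
}

// [[Rcpp::export]]
List simulate_cpp(NumericVector x0, NumericVector y0, NumericVector phi0,
                  IntegerVector informed,
                  NumericVector dsx, NumericVector dsy,
                  double L, double r,
                  double v0, double gamma_s, double gamma_p, double gamma_l,
                  double eta, int k, double dt, double up_angle,
                  int n_steps, int burn_steps, int record_every,
                  double p_direct, bool signaling, bool noninteracting,
                  bool record_edges) {
  const int N = x0.size();
  const int M = dsx.size();
  const double r2 = r * r;

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> phi(phi0.begin(), phi0.end());
  std::vector<double> dx_(dsx.begin(), dsx.end());
  std::vector<double> dy_(dsy.begin(), dsy.end());

  // grid sized so cells are ~1.5 length units but at least 1 cell
  int ng = (int)std::floor(L / 1.5);
  if (ng < 1) ng = 1;

  CellList ag_cl, ds_cl;
  if (M > 0) ds_cl.build(dx_, dy_, L, ng);  // danger sites are static

  const int n_obj = (N - 1) + M;
  const int keff = (k < n_obj) ? k : n_obj;

  // per-agent working arrays (flattened, stride keff)
  const int stride = keff > 0 ? keff : 1;
  std::vector<int> soc(N * stride), act(N * stride);
  std::vector<int> n_soc(N), n_act(N), g(N);
  std::vector<double> bd(stride), rate(N);
  std::vector<int> bi(stride);
  std::vector<int> zone_buf; zone_buf.reserve(M > 0 ? 16 : 1);

  const int cells_span = ds_cl.ng > 0 ? (int)(r / (L / ng)) + 1 : 0;

  // find danger sites whose repulsion zone contains agent i (strict d < r)
  auto zones_containing = [&](int i, std::vector<int>& out) {
    out.clear();
    if (M == 0) return;
    double cell = ds_cl.cell;
    int cx = (int)(x[i] / cell); if (cx >= ng) cx = ng - 1;
    int cy = (int)(y[i] / cell); if (cy >= ng) cy = ng - 1;
    if (2 * cells_span + 1 >= ng) {
      for (int l = 0; l < M; ++l) {
        double ddx = min_image(dx_[l] - x[i], L);
        double ddy = min_image(dy_[l] - y[i], L);
        if (ddx * ddx + ddy * ddy < r2) out.push_back(l);
      }
      return;
    }
    for (int dyc = -cells_span; dyc <= cells_span; ++dyc) {
      int cyy = ((cy + dyc) % ng + ng) % ng;
      for (int dxc = -cells_span; dxc <= cells_span; ++dxc) {
        int cxx = ((cx + dxc) % ng + ng) % ng;
        for (int l = ds_cl.head[cyy * ng + cxx]; l >= 0; l = ds_cl.nxt[l]) {
          double ddx = min_image(dx_[l] - x[i], L);
          double ddy = min_image(dy_[l] - y[i], L);
          if (ddx * ddx + ddy * ddy < r2) out.push_back(l);
        }
      }
    }
  };

  // k-nearest-object query for focal i; fills bd/bi with combined object ids
  // (agents j -> j, danger site l -> N + l), returns count
  auto kno_query = [&](int i) -> int {
    int n = 0;
    if (keff == 0) return 0;
    double cell = ag_cl.cell;
    int cx = (int)(x[i] / cell); if (cx >= ng) cx = ng - 1;
    int cy = (int)(y[i] / cell); if (cy >= ng) cy = ng - 1;
    bool brute = false;

    auto visit_cell = [&](int cxx, int cyy) {
      for (int j = ag_cl.head[cyy * ng + cxx]; j >= 0; j = ag_cl.nxt[j]) {
        if (j == i) continue;
        double ddx = min_image(x[j] - x[i], L);
        double ddy = min_image(y[j] - y[i], L);
        kb_insert(bd, bi, n, keff, ddx * ddx + ddy * ddy, j);
      }
      if (M > 0) {
        for (int l = ds_cl.head[cyy * ng + cxx]; l >= 0; l = ds_cl.nxt[l]) {
          double ddx = min_image(dx_[l] - x[i], L);
          double ddy = min_image(dy_[l] - y[i], L);
          kb_insert(bd, bi, n, keff, ddx * ddx + ddy * ddy, N + l);
        }
      }
    };

    for (int d = 0;; ++d) {
      double low = (d > 1) ? (d - 1) * cell : 0.0;
      if (n >= keff && low * low > bd[n - 1]) break;
      if (2 * d + 1 > ng) { brute = true; break; }
      if (d == 0) {
        visit_cell(cx, cy);
      } else {
        for (int dxc = -d; dxc <= d; ++dxc) {
          int cxx = ((cx + dxc) % ng + ng) % ng;
          visit_cell(cxx, ((cy - d) % ng + ng) % ng);
          visit_cell(cxx, ((cy + d) % ng + ng) % ng);
        }
        for (int dyc = -d + 1; dyc <= d - 1; ++dyc) {
          int cyy = ((cy + dyc) % ng + ng) % ng;
          visit_cell(((cx - d) % ng + ng) % ng, cyy);
          visit_cell(((cx + d) % ng + ng) % ng, cyy);
        }
      }
    }

    if (brute) {
      n = 0;
      for (int j = 0; j < N; ++j) {
        if (j == i) continue;
        double ddx = min_image(x[j] - x[i], L);
        double ddy = min_image(y[j] - y[i], L);
        kb_insert(bd, bi, n, keff, ddx * ddx + ddy * ddy, j);
      }
      for (int l = 0; l < M; ++l) {
        double ddx = min_image(dx_[l] - x[i], L);
        double ddy = min_image(dy_[l] - y[i], L);
        kb_insert(bd, bi, n, keff, ddx * ddx + ddy * ddy, N + l);
      }
    }
    return n;
  };

  // recording setup
  int n_frames = 0;
  if (n_steps > burn_steps)
    n_frames = (n_steps - 1 - burn_steps) / record_every + 1;
  NumericMatrix phi_rec(n_frames, N), x_rec(n_frames, N), y_rec(n_frames, N);
  IntegerMatrix g_rec(n_frames, N);
  NumericVector times(n_frames);
  IntegerVector nrz(n_frames);
  std::vector<int> e_frame, e_from, e_to;

  for (int s = 0; s < n_steps; ++s) {
    // ---- attention phase (from the pre-step configuration) ----
    if (!noninteracting) {
      ag_cl.build(x, y, L, ng);
      for (int i = 0; i < N; ++i) {
        int n = kno_query(i);
        int ns = 0, na = 0;
        for (int e = 0; e < n; ++e) {
          int id = bi[e];
          if (id < N) soc[i * stride + ns++] = id;
          else if (bd[e] < r2) act[i * stride + na++] = id - N;
        }
        n_soc[i] = ns; n_act[i] = na;
        g[i] = (na > 0) ? 1 : 0;
      }
    } else {
      for (int i = 0; i < N; ++i) {
        zones_containing(i, zone_buf);
        int na = 0;
        for (int l : zone_buf) act[i * stride + na++] = l;
        n_soc[i] = 0; n_act[i] = na;
        g[i] = (na > 0) ? 1 : 0;
      }
    }

    // ---- direct-detection override (one uniform draw per in-zone agent) ----
    if (p_direct > 0 && !noninteracting) {
      for (int i = 0; i < N; ++i) {
        zones_containing(i, zone_buf);
        if (zone_buf.empty()) continue;
        if (unif_rand() < p_direct) {
          int na = 0;
          for (int l : zone_buf) act[i * stride + na++] = l;
          n_act[i] = na;
          g[i] = 1;
        }
      }
    }

    // ---- active signaling: non-responders lock onto responding neighbors ----
    if (signaling && !noninteracting) {
      for (int i = 0; i < N; ++i) {
        if (g[i]) continue;
        int nsig = 0;
        for (int e = 0; e < n_soc[i]; ++e)
          if (g[soc[i * stride + e]]) soc[i * stride + nsig++] = soc[i * stride + e];
        if (nsig > 0) n_soc[i] = nsig;
      }
    }

    // ---- record the pre-step configuration with its response flags ----
    if (s >= burn_steps && (s - burn_steps) % record_every == 0) {
      int f = (s - burn_steps) / record_every;
      times[f] = s * dt;
      int in_zone = 0;
      for (int i = 0; i < N; ++i) {
        phi_rec(f, i) = phi[i];
        x_rec(f, i) = x[i];
        y_rec(f, i) = y[i];
        g_rec(f, i) = g[i];
        zones_containing(i, zone_buf);
        if (!zone_buf.empty()) ++in_zone;
        if (record_edges && !g[i]) {
          for (int e = 0; e < n_soc[i]; ++e) {
            e_frame.push_back(f + 1);
            e_from.push_back(i + 1);
            e_to.push_back(soc[i * stride + e] + 1);
          }
        }
      }
      nrz[f] = in_zone;
    }

    // ---- turning rates from the pre-step configuration ----
    for (int i = 0; i < N; ++i) {
      double rt = 0.0;
      if (g[i]) {
        double s_rep = 0.0;
        double cph = std::cos(phi[i]), sph = std::sin(phi[i]);
        for (int e = 0; e < n_act[i]; ++e) {
          int l = act[i * stride + e];
          // alpha_il: polar angle of the displacement from the site to the agent
          double ddx = min_image(x[i] - dx_[l], L);
          double ddy = min_image(y[i] - dy_[l], L);
          double d = std::sqrt(ddx * ddx + ddy * ddy);
          if (d > 0) s_rep += (ddy * cph - ddx * sph) / d;  // sin(alpha - phi)
        }
        rt = gamma_l * s_rep / n_act[i];
      } else {
        if (n_soc[i] > 0) {
          double s_al = 0.0;
          for (int e = 0; e < n_soc[i]; ++e)
            s_al += std::sin(phi[soc[i * stride + e]] - phi[i]);
          rt = gamma_s * s_al / n_soc[i];
        }
        if (informed[i]) rt += gamma_p * std::sin(up_angle - phi[i]);
      }
      rate[i] = rt;
    }

    // ---- synchronous Euler-Maruyama update ----
    const double sq = eta * std::sqrt(dt);
    for (int i = 0; i < N; ++i) {
      double ph = phi[i] + rate[i] * dt + sq * norm_rand();
      ph = wrap_angle(ph);
      phi[i] = ph;
      x[i] = wrap_pos(x[i] + v0 * std::cos(ph) * dt, L);
      y[i] = wrap_pos(y[i] + v0 * std::sin(ph) * dt, L);
      if (!R_finite(x[i]) || !R_finite(y[i]) || !R_finite(ph))
        stop("non-finite state for agent %d at step %d", i + 1, s + 1);
    }
  }

  IntegerMatrix edges(e_frame.size(), 3);
  for (int e = 0; e < (int)e_frame.size(); ++e) {
    edges(e, 0) = e_frame[e];
    edges(e, 1) = e_from[e];
    edges(e, 2) = e_to[e];
  }
  colnames(edges) = CharacterVector::create("frame", "from", "to");

  return List::create(
    _["times"] = times, _["phi"] = phi_rec, _["x"] = x_rec, _["y"] = y_rec,
    _["g"] = g_rec, _["nrz"] = nrz, _["edges"] = edges,
    _["final_x"] = NumericVector(x.begin(), x.end()),
    _["final_y"] = NumericVector(y.begin(), y.end()),
    _["final_phi"] = NumericVector(phi.begin(), phi.end()));
}
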