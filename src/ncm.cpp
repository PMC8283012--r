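// Online training engine for the constructivist two-pathway network.
// Mirrors the R reference implementation step for step (same update order,
// same RNG call order at insertion events) so both engines produce the same
// trajectory from the same seed.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Net {
  int n_in, n_out;
  std::vector<double> W_direct;            // n_out x n_in, column-major
  std::vector<std::vector<double>> W_hidden; // per unit: n_out weights
  std::vector<std::vector<double>> centers;  // per unit: n_in
  std::vector<double> widths, local_error;
  std::vector<int> last_active;
  long long token;

  double &wd(int o, int i) { return W_direct[(size_t)i * n_out + o]; }
};

// winner response; returns index (-1 when empty) and activation via refs
int find_winner(const Net &net, const double *x, double &act, double &d2win) {
  int best = -1;
  double besta = -1.0;
  for (size_t u = 0; u < net.centers.size(); ++u) {
    double d2 = 0.0;
    const std::vector<double> &c = net.centers[u];
    for (int i = 0; i < net.n_in; ++i) {
      double d = c[i] - x[i];
      d2 += d * d;
    }
    double a = std::exp(-d2 / (2.0 * net.widths[u] * net.widths[u]));
    if (a > besta) { besta = a; best = (int)u; d2win = d2; }
  }
  act = best >= 0 ? besta : 0.0;
  return best;
}

} // namespace

// [[Rcpp::export]]
List ncm_train_cpp(NumericMatrix X, NumericMatrix Y, IntegerVector stream,
                   LogicalVector is_irregular, List state_in, List cfg,
                   bool record) {
  RNGScope rng;

  const int n_in = X.nrow(), n_out = Y.nrow(), n_types = X.ncol();

  Net net;
  net.n_in = n_in; net.n_out = n_out;
  {
    NumericMatrix Wd = state_in["W_direct"];
    net.W_direct.assign(Wd.begin(), Wd.end());
    NumericMatrix Wh = state_in["W_hidden"];
    NumericMatrix Ce = state_in["centers"];
    int m = Wh.ncol();
    for (int u = 0; u < m; ++u) {
      net.W_hidden.emplace_back(Wh.column(u).begin(), Wh.column(u).end());
      net.centers.emplace_back(Ce.column(u).begin(), Ce.column(u).end());
    }
    NumericVector wi = state_in["widths"], le = state_in["local_error"];
    IntegerVector la = state_in["last_active"];
    net.widths.assign(wi.begin(), wi.end());
    net.local_error.assign(le.begin(), le.end());
    net.last_active.assign(la.begin(), la.end());
    net.token = (long long)as<double>(state_in["token"]);
  }

  const double lambda = cfg["lambda"], eta_c = cfg["eta_center"],
               eta_w = cfg["eta_width"], sigma_init = cfg["sigma_init"],
               sigma_min = cfg["sigma_min"], sigma_max = cfg["sigma_max"],
               init_w = cfg["init_w"], theta = cfg["theta"];
  const int win_short = cfg["window_short"], win_long = cfg["window_long"],
            insert_k = cfg["insert_k"], prune_T = cfg["prune_T"],
            prune_every = cfg["prune_every"],
            ckpt_int = cfg["checkpoint_interval"];
  const int n_long = win_long / win_short;

  std::vector<double> win_means(
      as<std::vector<double>>(state_in["win_means"]));
  double cur_sum = as<double>(state_in["cur_sum"]);
  int cur_n = as<int>(state_in["cur_n"]);

  // nonzero input positions per verb type (inputs are ternary)
  std::vector<std::vector<int>> nzidx(n_types);
  for (int v = 0; v < n_types; ++v)
    for (int i = 0; i < n_in; ++i)
      if (X(i, v) != 0.0) nzidx[v].push_back(i);

  std::vector<double> e(n_out);

  // checkpoint record
  std::vector<double> rec_token, rec_acc, rec_units, rec_dir_reg, rec_dir_irr,
      rec_ind_reg, rec_ind_irr;
  std::vector<double> ev_token, ev_added, ev_pruned;

  auto checkpoint = [&]() {
    int n_ok = 0;
    double dr = 0, di = 0, ir = 0, ii = 0;
    int nreg = 0, nirr = 0;
    // per-output column sums of |W_hidden| are winner-dependent; direct
    // activation uses per-input column sums of |w_oi|
    std::vector<double> colabs(n_in, 0.0);
    for (int i = 0; i < n_in; ++i)
      for (int o = 0; o < n_out; ++o) colabs[i] += std::fabs(net.wd(o, i));
    for (int v = 0; v < n_types; ++v) {
      const double *x = &X(0, v);
      double act, d2;
      int h = find_winner(net, x, act, d2);
      double direct = 0.0;
      for (int i : nzidx[v]) direct += colabs[i] * std::fabs(x[i]);
      double indirect = 0.0;
      if (h >= 0)
        for (int o = 0; o < n_out; ++o)
          indirect += std::fabs(net.W_hidden[h][o] * act);
      bool ok = true;
      for (int o = 0; o < n_out; ++o) {
        double nv = 0.0;
        for (int i : nzidx[v]) nv += net.wd(o, i) * x[i];
        if (h >= 0) nv += net.W_hidden[h][o] * act;
        double dec = nv > theta ? 1.0 : (nv < -theta ? -1.0 : 0.0);
        if (dec != Y(o, v)) { ok = false; break; }
      }
      n_ok += ok;
      if (is_irregular[v]) { ii += indirect; ir += direct; ++nirr; }
      else { di += indirect; dr += direct; ++nreg; }
    }
    rec_token.push_back((double)net.token);
    rec_acc.push_back((double)n_ok / n_types);
    rec_units.push_back((double)net.centers.size());
    rec_dir_reg.push_back(nreg ? dr / nreg : NA_REAL);
    rec_dir_irr.push_back(nirr ? ir / nirr : NA_REAL);
    rec_ind_reg.push_back(nreg ? di / nreg : NA_REAL);
    rec_ind_irr.push_back(nirr ? ii / nirr : NA_REAL);
  };

  const long long n_tokens = stream.size();
  for (long long t = 0; t < n_tokens; ++t) {
    int v = stream[t] - 1;
    const double *x = &X(0, v);
    net.token += 1;

    double act = 0.0, d2win = 0.0;
    int h = find_winner(net, x, act, d2win);

    // forward + error
    double err = 0.0;
    bool any_err = false;
    for (int o = 0; o < n_out; ++o) {
      double nv = 0.0;
      for (int i : nzidx[v]) nv += net.wd(o, i) * x[i];
      if (h >= 0) nv += net.W_hidden[h][o] * act;
      double dec = nv > theta ? 1.0 : (nv < -theta ? -1.0 : 0.0);
      e[o] = Y(o, v) - dec;
      if (e[o] != 0.0) { any_err = true; err += std::fabs(e[o]); }
    }

    // perceptron updates
    if (any_err) {
      for (int o = 0; o < n_out; ++o) {
        if (e[o] == 0.0) continue;
        double de = lambda * e[o];
        for (int i : nzidx[v]) net.wd(o, i) += de * x[i];
        if (h >= 0) net.W_hidden[h][o] += de * act;
      }
    }

    // winner receptive-field adaptation and bookkeeping
    if (h >= 0) {
      double d = std::sqrt(d2win);
      std::vector<double> &c = net.centers[h];
      for (int i = 0; i < n_in; ++i) c[i] += eta_c * (x[i] - c[i]);
      double w = net.widths[h] + eta_w * (d - net.widths[h]);
      net.widths[h] = std::min(sigma_max, std::max(sigma_min, w));
      net.local_error[h] += err;
      net.last_active[h] = (int)net.token;
    }

    // growth-trigger windows
    cur_sum += err;
    cur_n += 1;
    if (cur_n == win_short) {
      win_means.push_back(cur_sum / cur_n);
      if ((int)win_means.size() > n_long + 1)
        win_means.erase(win_means.begin());
      cur_sum = 0.0; cur_n = 0;
    }

    // insertion
    if ((int)win_means.size() == n_long + 1) {
      double prev = 0.0;
      for (int j = 0; j < n_long; ++j) prev += win_means[j];
      prev /= n_long;
      if (win_means[n_long] > 0.0 && win_means[n_long] >= prev) {
        std::vector<double> site(n_in);
        double new_sigma = sigma_init;
        if (!net.centers.empty()) {
          int donor = 0;
          for (size_t u = 1; u < net.local_error.size(); ++u)
            if (net.local_error[u] > net.local_error[donor]) donor = (int)u;
          site = net.centers[donor];
          new_sigma = net.widths[donor];  // compete with the donor on equal terms
          net.local_error[donor] = 0.0;
        } else {
          for (int i = 0; i < n_in; ++i) site[i] = x[i];
        }
        for (int j = 0; j < insert_k; ++j) {
          std::vector<double> c(n_in);
          for (int i = 0; i < n_in; ++i) c[i] = site[i] + R::rnorm(0.0, 0.01);
          std::vector<double> wcol(n_out);
          for (int o = 0; o < n_out; ++o) wcol[o] = R::runif(-init_w, init_w);
          net.centers.push_back(c);
          net.W_hidden.push_back(wcol);
          net.widths.push_back(new_sigma);
          net.local_error.push_back(0.0);
          net.last_active.push_back((int)net.token);
        }
        win_means.clear();
        cur_sum = 0.0; cur_n = 0;
        ev_token.push_back((double)net.token);
        ev_added.push_back((double)insert_k);
        ev_pruned.push_back(0.0);
      }
    }

    // pruning
    if (prune_every > 0 && net.token % prune_every == 0 &&
        !net.centers.empty()) {
      int removed = 0;
      size_t keep = 0;
      for (size_t u = 0; u < net.centers.size(); ++u) {
        if (net.token - net.last_active[u] < prune_T) {
          if (keep != u) {
            net.centers[keep] = std::move(net.centers[u]);
            net.W_hidden[keep] = std::move(net.W_hidden[u]);
            net.widths[keep] = net.widths[u];
            net.local_error[keep] = net.local_error[u];
            net.last_active[keep] = net.last_active[u];
          }
          ++keep;
        } else {
          ++removed;
        }
      }
      if (removed) {
        net.centers.resize(keep);
        net.W_hidden.resize(keep);
        net.widths.resize(keep);
        net.local_error.resize(keep);
        net.last_active.resize(keep);
        ev_token.push_back((double)net.token);
        ev_added.push_back(0.0);
        ev_pruned.push_back((double)removed);
      }
    }

    if (record && ckpt_int > 0 && net.token % ckpt_int == 0) checkpoint();

    if (t % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  // pack state back
  int m = (int)net.centers.size();
  NumericMatrix Wd(n_out, n_in);
  std::copy(net.W_direct.begin(), net.W_direct.end(), Wd.begin());
  NumericMatrix Wh(n_out, m), Ce(n_in, m);
  NumericVector wi(m), le(m);
  IntegerVector la(m);
  for (int u = 0; u < m; ++u) {
    std::copy(net.W_hidden[u].begin(), net.W_hidden[u].end(),
              Wh.column(u).begin());
    std::copy(net.centers[u].begin(), net.centers[u].end(),
              Ce.column(u).begin());
    wi[u] = net.widths[u];
    le[u] = net.local_error[u];
    la[u] = net.last_active[u];
  }
  List state = List::create(
      _["W_direct"] = Wd, _["W_hidden"] = Wh, _["centers"] = Ce,
      _["widths"] = wi, _["local_error"] = le, _["last_active"] = la,
      _["token"] = (double)net.token, _["win_means"] = wrap(win_means),
      _["cur_sum"] = cur_sum, _["cur_n"] = cur_n);
  DataFrame rec = DataFrame::create(
      _["token"] = rec_token, _["accuracy"] = rec_acc,
      _["n_units"] = rec_units, _["direct_regular"] = rec_dir_reg,
      _["direct_irregular"] = rec_dir_irr, _["indirect_regular"] = rec_ind_reg,
      _["indirect_irregular"] = rec_ind_irr);
  DataFrame ev = DataFrame::create(
      _["token"] = ev_token, _["units_added"] = ev_added,
      _["units_pruned"] = ev_pruned);
  return List::create(_["state"] = state, _["record"] = rec,
                      _["events"] = ev);
}
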