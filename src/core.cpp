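// Compiled simulation core: the per-step event + force-balance loop.
// Semantics are defined by the R reference operations (step_bundle and the
// per-event functions); this engine implements the identical fixed ordering
// (myosin detach, attach, crosslink+merge, dissociation, turnover/severing,
// exact linear solve, Euler advance) with R's RNG for reproducibility.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double wrapd(double x, double L) {
  double r = x - std::floor(x / L) * L;
  if (r >= L) r -= L;
  if (r < 0) r += L;
  return r;
}
static inline double min_imaged(double dx, double L) {
  double m = dx - std::floor(dx / L) * L;
  if (m >= L / 2.0) m -= L;
  return m;
}

// [[Rcpp::export]]
List core_run(List state, List pars, int n_steps, int sample_every,
              bool log_events) {
  const double v    = as<double>(pars["v_tread"]);
  const double gam  = as<double>(pars["gamma"]);
  const double zeta = as<double>(pars["zeta"]);
  const double k0   = as<double>(pars["k0"]);
  const double delta = as<double>(pars["delta"]);
  const double F    = as<double>(pars["F_stall"]);
  const double v0   = as<double>(pars["v_my0"]);
  const double kon  = as<double>(pars["k_on"]);
  const double koff = as<double>(pars["k_off"]);
  const double Lmy  = as<double>(pars["L_my"]);
  const double ellm = as<double>(pars["ell_mean"]);
  const double kto  = as<double>(pars["k_turnover"]);
  const double rsev = as<double>(pars["r_sever"]);
  const double kdiss = as<double>(pars["k_diss"]);
  const double L    = as<double>(pars["L_sys"]);
  const double dt   = as<double>(pars["dt"]);
  const int mode    = as<int>(pars["length_mode_code"]); // 0 mono 1 logn 2 exp 3 sever
  const double mulog = as<double>(pars["meanlog"]);
  const double sdlog = as<double>(pars["sdlog"]);
  double time = as<double>(state["time"]);

  std::vector<double> pos = as<std::vector<double>>(state["plus_pos"]);
  std::vector<int>    sig = as<std::vector<int>>(state["sigma"]);
  std::vector<double> len = as<std::vector<double>>(state["length"]);
  std::vector<int>    cid = as<std::vector<int>>(state["cluster_id"]); // 0-based
  std::vector<double> mc   = as<std::vector<double>>(state["center"]);
  std::vector<int>    b1   = as<std::vector<int>>(state["f1"]); // 0-based, -1 unbound
  std::vector<int>    b2   = as<std::vector<int>>(state["f2"]);
  std::vector<double> off1 = as<std::vector<double>>(state["off1"]);
  std::vector<double> off2 = as<std::vector<double>>(state["off2"]);
  const int nf = (int)pos.size();
  const int nm = (int)mc.size();

  // clusters: cz indexed by cid; rebuilt structures
  int nc0 = 0;
  for (int f = 0; f < nf; ++f) nc0 = std::max(nc0, cid[f] + 1);
  std::vector<double> cz(nc0, 0.0);
  std::vector<int> csize(nc0, 0);
  std::vector<char> alive(nc0, 0);
  std::vector<std::vector<int>> members(nc0);
  for (int f = 0; f < nf; ++f) {
    cz[cid[f]] = pos[f];
    csize[cid[f]]++;
    alive[cid[f]] = 1;
    members[cid[f]].push_back(f);
  }

  const double p_off = (koff > 0) ? 1.0 - std::exp(-koff * dt) : 0.0;
  const double p_on  = (kon > 0) ? 1.0 - std::exp(-kon * dt) : 0.0;
  const double p_diss = (kdiss > 0) ? 1.0 - std::exp(-kdiss * dt) : 0.0;
  const double p_to  = (kto > 0) ? 1.0 - std::exp(-kto * dt) : 0.0;
  const double cutoff = 4.0 * delta;

  // trajectory storage
  std::vector<double> s_time;
  std::vector<int> cl_s, cl_w, my_s, my_nb;
  std::vector<double> cl_z, my_c, s_loc;
  // event log
  std::vector<double> ev_t, ev_aux;
  std::vector<int> ev_kind, ev_i, ev_j;
  double max_resid = 0.0;
  long n_merges = 0, n_attach = 0, n_detach = 0, n_turnover = 0,
       n_sever = 0, n_diss = 0;

  auto logev = [&](int kind, int i, int j, double aux) {
    if (!log_events) return;
    ev_t.push_back(time); ev_kind.push_back(kind);
    ev_i.push_back(i); ev_j.push_back(j); ev_aux.push_back(aux);
  };

  auto draw_len = [&]() -> double {
    if (mode == 1) return sdlog > 0 ? R::rlnorm(mulog, sdlog) : ellm;
    if (mode == 2) return ellm * R::exp_rand();
    return ellm;
  };

  auto detach_sites_on = [&](int f) {
    for (int m = 0; m < nm; ++m) {
      if (b1[m] == f) b1[m] = -1;
      if (b2[m] == f) b2[m] = -1;
    }
  };

  int isample = 0;
  auto record = [&]() {
    s_time.push_back(time);
    for (int c = 0; c < (int)cz.size(); ++c) {
      if (!alive[c] || csize[c] == 0) continue;
      cl_s.push_back(isample); cl_z.push_back(cz[c]); cl_w.push_back(csize[c]);
    }
    double loc = 0.0; int nb_tot = 0;
    for (int m = 0; m < nm; ++m) {
      int nb = (b1[m] >= 0) + (b2[m] >= 0);
      my_s.push_back(isample); my_c.push_back(mc[m]); my_nb.push_back(nb);
      if (b1[m] >= 0) { loc += off1[m] / len[b1[m]]; nb_tot++; }
      if (b2[m] >= 0) { loc += off2[m] / len[b2[m]]; nb_tot++; }
    }
    s_loc.push_back(nb_tot > 0 ? loc / nb_tot : NA_REAL);
    isample++;
  };

  std::vector<int> merged_to, unit_of, ulist, elig;
  std::vector<double> eligoff, Vm(nm, 0.0), W1(nm, 0.0), W2(nm, 0.0);
  std::vector<int> pairsA, pairsB;

  record();  // initial state

  for (int step = 0; step < n_steps; ++step) {
    // (1) myosin detachment
    if (p_off > 0) {
      for (int m = 0; m < nm; ++m) {
        if (b1[m] >= 0 && unif_rand() < p_off) { b1[m] = -1; n_detach++; logev(1, m, 0, 0); }
        if (b2[m] >= 0 && unif_rand() < p_off) { b2[m] = -1; n_detach++; logev(1, m, 1, 0); }
      }
    }
    // (2) myosin attachment (left site binds sigma=-1, right site sigma=+1)
    if (p_on > 0) {
      for (int m = 0; m < nm; ++m) {
        for (int s = 0; s < 2; ++s) {
          int &b = (s == 0) ? b1[m] : b2[m];
          if (b >= 0) continue;
          if (unif_rand() >= p_on) continue;
          double x = wrapd(mc[m] + (s == 0 ? -Lmy / 2 : Lmy / 2), L);
          int want = (s == 0) ? -1 : 1;
          elig.clear(); eligoff.clear();
          for (int f = 0; f < nf; ++f) {
            if (sig[f] != want) continue;
            double d = (want == 1) ? wrapd(pos[f] - x, L) : wrapd(x - pos[f], L);
            if (d <= len[f]) { elig.push_back(f); eligoff.push_back(d); }
          }
          if (elig.empty()) continue;
          int j = (int)(unif_rand() * elig.size());
          if (j >= (int)elig.size()) j = (int)elig.size() - 1;
          b = elig[j];
          ((s == 0) ? off1[m] : off2[m]) = eligoff[j];
          n_attach++; logev(2, m, elig[j], eligoff[j]);
        }
      }
    }
    // (3) plus-end crosslinking and cluster merging
    if (k0 > 0) {
      pairsA.clear(); pairsB.clear();
      const int ncc = (int)cz.size();
      for (int a = 0; a < ncc; ++a) {
        if (!alive[a] || csize[a] == 0) continue;
        for (int b = a + 1; b < ncc; ++b) {
          if (!alive[b] || csize[b] == 0) continue;
          double d = std::fabs(min_imaged(cz[b] - cz[a], L));
          if (d > cutoff) continue;
          double rate = k0 * std::exp(-(d / delta) * (d / delta));
          double p1 = 1.0 - std::exp(-rate * dt);
          // any of the csize[a]*csize[b] independent filament pairs linking
          double P = 1.0 - std::pow(1.0 - p1, (double)csize[a] * (double)csize[b]);
          if (unif_rand() < P) { pairsA.push_back(a); pairsB.push_back(b); }
        }
      }
      if (!pairsA.empty()) {
        merged_to.assign(cz.size(), -1);
        auto find = [&](int c) { while (merged_to[c] >= 0) c = merged_to[c]; return c; };
        for (size_t k = 0; k < pairsA.size(); ++k) {
          int a = find(pairsA[k]), b = find(pairsB[k]);
          if (a == b) continue;
          if (a > b) std::swap(a, b);
          double z = wrapd(cz[a] + (double)csize[b] / (csize[a] + csize[b]) *
                                       min_imaged(cz[b] - cz[a], L), L);
          for (int f : members[b]) { cid[f] = a; members[a].push_back(f); }
          members[b].clear();
          csize[a] += csize[b]; csize[b] = 0; alive[b] = 0; merged_to[b] = a;
          cz[a] = z;
          for (int f : members[a]) pos[f] = z;
          // bound sites on snapped filaments keep their lab position
          for (int m = 0; m < nm; ++m) {
            if (b1[m] >= 0 && cid[b1[m]] == a) {
              double x = wrapd(mc[m] - Lmy / 2, L);
              double d = wrapd(x - pos[b1[m]], L); // sigma = -1
              if (d <= len[b1[m]]) off1[m] = d; else b1[m] = -1;
            }
            if (b2[m] >= 0 && cid[b2[m]] == a) {
              double x = wrapd(mc[m] + Lmy / 2, L);
              double d = wrapd(pos[b2[m]] - x, L); // sigma = +1
              if (d <= len[b2[m]]) off2[m] = d; else b2[m] = -1;
            }
          }
          n_merges++; logev(3, a, b, z);
        }
      }
    }
    // (4) spontaneous dissociation from clusters
    if (p_diss > 0) {
      for (int f = 0; f < nf; ++f) {
        if (csize[cid[f]] < 2) continue;
        if (unif_rand() >= p_diss) continue;
        int c = cid[f];
        members[c].erase(std::find(members[c].begin(), members[c].end(), f));
        csize[c]--;
        cid[f] = (int)cz.size();
        cz.push_back(pos[f]); csize.push_back(1); alive.push_back(1);
        members.push_back(std::vector<int>(1, f));
        n_diss++; logev(4, f, c, 0);
      }
    }
    // (5) turnover or severing
    if (mode == 3 && rsev > 0) {
      for (int f = 0; f < nf; ++f) {
        double pc = 1.0 - std::exp(-rsev * len[f] * dt);
        if (unif_rand() >= pc) continue;
        double newlen = unif_rand() * len[f];
        if (newlen <= 0) newlen = 1e-12;
        len[f] = newlen;
        for (int m = 0; m < nm; ++m) {
          if (b1[m] == f && off1[m] > newlen) b1[m] = -1;
          if (b2[m] == f && off2[m] > newlen) b2[m] = -1;
        }
        n_sever++; logev(6, f, 0, newlen);
      }
    } else if (p_to > 0) {
      for (int f = 0; f < nf; ++f) {
        if (unif_rand() >= p_to) continue;
        detach_sites_on(f);
        int c = cid[f];
        members[c].erase(std::find(members[c].begin(), members[c].end(), f));
        csize[c]--;
        if (csize[c] == 0) alive[c] = 0;
        pos[f] = unif_rand() * L;
        sig[f] = unif_rand() < 0.5 ? 1 : -1;
        len[f] = draw_len();
        cid[f] = (int)cz.size();
        cz.push_back(pos[f]); csize.push_back(1); alive.push_back(1);
        members.push_back(std::vector<int>(1, f));
        n_turnover++; logev(5, f, c, 0);
      }
    }
    // (6) exact force balance on the post-event topology
    unit_of.assign(cz.size(), -1);
    ulist.clear();
    int nu = 0;
    for (int c = 0; c < (int)cz.size(); ++c) {
      if (alive[c] && csize[c] > 0) { unit_of[c] = nu++; ulist.push_back(c); }
    }
    arma::mat A(nu, nu, arma::fill::zeros);
    arma::vec bb(nu, arma::fill::zeros);
    for (int f = 0; f < nf; ++f) {
      int i = unit_of[cid[f]];
      A(i, i) += gam * len[f];
      bb(i) += gam * v * sig[f] * len[f];
    }
    if (zeta > 0) {
      for (int f = 0; f < nf - 1; ++f) {
        for (int g = f + 1; g < nf; ++g) {
          int i = unit_of[cid[f]], j = unit_of[cid[g]];
          if (i == j) continue;
          double c1 = pos[f] - sig[f] * len[f] / 2;
          double c2 = pos[g] - sig[g] * len[g] / 2;
          double dc = std::fabs(min_imaged(c1 - c2, L));
          double cap = std::min(len[f], len[g]);
          double ov = std::min((len[f] + len[g]) / 2 - dc, cap);
          if (ov < 0) ov = 0;
          double second = (len[f] + len[g]) / 2 - (L - dc);
          if (second > 0) ov = std::min(ov + second, cap);
          if (ov <= 0) continue;
          A(i, i) += zeta * ov; A(j, j) += zeta * ov;
          A(i, j) -= zeta * ov; A(j, i) -= zeta * ov;
          double drive = zeta * ov * v * (sig[f] - sig[g]);
          bb(i) += drive; bb(j) -= drive;
        }
      }
    }
    const double kappa = (F > 0 && v0 > 0) ? F / (2 * v0) : 0.0;
    if (kappa > 0) {
      for (int m = 0; m < nm; ++m) {
        if (b1[m] < 0 || b2[m] < 0) continue;
        int i = unit_of[cid[b1[m]]], j = unit_of[cid[b2[m]]];
        if (i == j) continue;
        int sa = sig[b1[m]], sb = sig[b2[m]];
        A(i, i) += kappa; A(j, j) += kappa;
        A(i, j) -= kappa; A(j, i) -= kappa;
        double drive = kappa * (sa - sb) * (v - v0);
        bb(i) += drive; bb(j) -= drive;
      }
    }
    arma::vec V;
    bool ok = arma::solve(V, A, bb, arma::solve_opts::no_approx);
    if (!ok) stop("force-balance solve failed at t = %f (unit count %d)", time, nu);
    if (nu > 0) {
      double resid = arma::abs(A * V - bb).max();
      if (resid > max_resid) max_resid = resid;
    }
    // (7) Euler advance: myosin kinematics use pre-move velocities
    for (int m = 0; m < nm; ++m) {
      if (b1[m] >= 0 && b2[m] >= 0) {
        double ua = V(unit_of[cid[b1[m]]]) - sig[b1[m]] * v;
        double ub = V(unit_of[cid[b2[m]]]) - sig[b2[m]] * v;
        int sa = sig[b1[m]], sb = sig[b2[m]];
        if (F > 0 && v0 > 0) {
          double Fa = F * sa * ((ua - ub) + v0 * (sa - sb)) / (2 * v0);
          double Fb = -sa * sb * Fa;
          W1[m] = v0 * (1 - Fa / F);
          W2[m] = v0 * (1 - Fb / F);
          Vm[m] = ua + sa * W1[m];
        } else {
          W1[m] = v0; W2[m] = v0;
          Vm[m] = 0.5 * ((ua + sa * v0) + (ub + sb * v0));
        }
      } else if (b1[m] >= 0) {
        double ua = V(unit_of[cid[b1[m]]]) - sig[b1[m]] * v;
        W1[m] = v0; Vm[m] = ua + sig[b1[m]] * v0;
      } else if (b2[m] >= 0) {
        double ub = V(unit_of[cid[b2[m]]]) - sig[b2[m]] * v;
        W2[m] = v0; Vm[m] = ub + sig[b2[m]] * v0;
      } else {
        Vm[m] = 0.0;
      }
    }
    for (int c = 0; c < (int)cz.size(); ++c) {
      if (!alive[c] || csize[c] == 0) continue;
      cz[c] = wrapd(cz[c] + V(unit_of[c]) * dt, L);
    }
    for (int f = 0; f < nf; ++f) pos[f] = cz[cid[f]];
    if (mode == 3) {
      for (int f = 0; f < nf; ++f) len[f] += v * dt;
    }
    for (int m = 0; m < nm; ++m) {
      bool any = (b1[m] >= 0) || (b2[m] >= 0);
      if (any) mc[m] = wrapd(mc[m] + Vm[m] * dt, L);
      if (b1[m] >= 0) {
        off1[m] += (v - W1[m]) * dt;
        if (off1[m] < 0 || off1[m] > len[b1[m]]) b1[m] = -1;
      }
      if (b2[m] >= 0) {
        off2[m] += (v - W2[m]) * dt;
        if (off2[m] < 0 || off2[m] > len[b2[m]]) b2[m] = -1;
      }
    }
    time += dt;
    if ((step + 1) % sample_every == 0 || step + 1 == n_steps) record();
    if ((step & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  // compact final cluster table, remap ids to 1..K
  std::vector<int> newid(cz.size(), -1);
  std::vector<double> cz_out;
  std::vector<int> cw_out;
  int K = 0;
  for (int c = 0; c < (int)cz.size(); ++c) {
    if (alive[c] && csize[c] > 0) {
      newid[c] = K++;
      cz_out.push_back(cz[c]);
      cw_out.push_back(csize[c]);
    }
  }
  IntegerVector cid_out(nf);
  for (int f = 0; f < nf; ++f) cid_out[f] = newid[cid[f]] + 1;
  IntegerVector b1_out(nm), b2_out(nm);
  NumericVector off1_out(nm), off2_out(nm);
  for (int m = 0; m < nm; ++m) {
    b1_out[m] = b1[m] >= 0 ? b1[m] + 1 : NA_INTEGER;
    b2_out[m] = b2[m] >= 0 ? b2[m] + 1 : NA_INTEGER;
    off1_out[m] = b1[m] >= 0 ? off1[m] : NA_REAL;
    off2_out[m] = b2[m] >= 0 ? off2[m] : NA_REAL;
  }

  List ev = R_NilValue;
  if (log_events) {
    ev = List::create(_["time"] = ev_t, _["kind"] = ev_kind,
                      _["id1"] = ev_i, _["id2"] = ev_j, _["aux"] = ev_aux);
  }
  return List::create(
    _["sample_time"] = s_time,
    _["cl_sample"] = cl_s, _["cl_z"] = cl_z, _["cl_w"] = cl_w,
    _["my_sample"] = my_s, _["my_center"] = my_c, _["my_nbound"] = my_nb,
    _["localization"] = s_loc,
    _["max_residual"] = max_resid,
    _["final"] = List::create(
      _["time"] = time, _["plus_pos"] = pos, _["sigma"] = sig,
      _["length"] = len, _["cluster_id"] = cid_out,
      _["cluster_z"] = cz_out, _["cluster_w"] = cw_out,
      _["center"] = mc, _["f1"] = b1_out, _["off1"] = off1_out,
      _["f2"] = b2_out, _["off2"] = off2_out),
    _["counts"] = List::create(
      _["merges"] = (double)n_merges, _["attach"] = (double)n_attach,
      _["detach"] = (double)n_detach, _["turnover"] = (double)n_turnover,
      _["sever"] = (double)n_sever, _["dissociate"] = (double)n_diss),
    _["events"] = ev);
}
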