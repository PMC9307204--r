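// Discrete-event Monte Carlo engine for the paired virtual systems.
//
// One call advances a full system state by n_ts time-steps (TS). All
// stochastic decisions draw from R's RNG stream (unif_rand), so a run is
// fully determined by the R-level seed. Agents (compound objects) are
// updated phase-wise each TS: compartment transfers and grid movement,
// hepatocyte entry attempts, bound-compound releases, enzyme binding,
// exits, and central-vein returns. Vectorized bookkeeping is accumulated
// into a per-TS series matrix.
//
// Location codes: 0 Intro, 1 Body/Media, 4 Core, 5 Interface, 6 Endothelial
// space, 7 Space of Disse, 8 inside a vHPC, 9 CV buffer (returned to Body
// at the end of the TS).
//
// Agent types: 0 Marker (non-permeant internal standard), 1 test compound,
// 2 Metabolite (non-permeant, pExit = 1).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

enum Loc { L_INTRO = 0, L_BODY = 1, L_CORE = 4, L_IFACE = 5, L_ENDO = 6, L_DISSE = 7,
           L_INCELL = 8, L_CVBUF = 9 };

// series columns
enum Col { C_INTRO_T, C_BODY_T, C_EXTRA_T, C_CELL_ALL, C_CELL_PP, C_CELL_CL,
           C_CELL_PC, C_MET_TOTAL, C_MET_BODY, C_CUM_METAB, C_ENT_ALL,
           C_ENT_PP, C_ENT_CL, C_ENT_PC, C_INFLOW_T, C_OUTFLOW_T, C_INTRO_M,
           C_BODY_M, C_EXTRA_M, C_INFLOW_M, C_OUTFLOW_M, C_CUM_ENT,
           C_BOUND_T, N_COL };

static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// [[Rcpp::export]]
List run_engine_cpp(List structure, List comp, List flow, int n_ts,
                    List state, bool record, bool check) {
  // --- structure ---------------------------------------------------------
  const bool culture = as<bool>(structure["is_culture"]);
  const int W = as<int>(structure["width"]);
  const IntegerVector ss_layer = structure["ss_layer"];
  const IntegerVector ss_len = structure["ss_len"];
  const IntegerVector goff = structure["goff"];
  const LogicalVector open = structure["open"];
  const IntegerVector nenz = structure["nenz"];
  const IntegerVector band = structure["band"];
  const int n_ss = ss_layer.size();
  IntegerVector layer0, edge_dst, estart, einter, eintra;
  if (!culture) {
    layer0 = structure["layer0"];
    edge_dst = structure["edge_dst"];
    estart = structure["estart"];
    einter = structure["einter"];
    eintra = structure["eintra"];
  }

  // --- compound parameters ----------------------------------------------
  const IntegerVector crossing = comp["crossing"];
  const NumericVector p_enter = comp["p_enter"];
  const NumericVector p_exit = comp["p_exit"];
  const double p_bind = as<double>(comp["p_bind"]);
  const double p_met = as<double>(comp["p_metabolize"]);
  const int bind_cycles = as<int>(comp["bind_cycles"]);

  // --- flow parameters ---------------------------------------------------
  const double ka = as<double>(flow["k_absorption"]);
  const double f_in = as<double>(flow["f_in"]);
  const double ssflow = as<double>(flow["ss_flow_rate"]);
  const double fb = as<double>(flow["forward_bias"]);
  const double lb = as<double>(flow["lateral_bias"]);
  const double core_split = as<double>(flow["core_split"]);
  const int lat_guard = as<int>(flow["lateral_hop_guard"]);

  // --- mutable agent state (cloned: the R-level state is not modified) ---
  int ts = as<int>(state["ts"]);
  IntegerVector typ = clone(as<IntegerVector>(state["typ"]));
  IntegerVector loc = clone(as<IntegerVector>(state["loc"]));
  IntegerVector ssv = clone(as<IntegerVector>(state["ss"]));
  IntegerVector wv = clone(as<IntegerVector>(state["w"]));
  IntegerVector lv = clone(as<IntegerVector>(state["l"]));
  IntegerVector bound = clone(as<IntegerVector>(state["bound"]));
  IntegerVector rel_ts = clone(as<IntegerVector>(state["rel_ts"]));
  IntegerVector metflag = clone(as<IntegerVector>(state["metflag"]));
  IntegerVector lat = clone(as<IntegerVector>(state["lat_hops"]));
  IntegerVector lastent = clone(as<IntegerVector>(state["last_entry_ts"]));
  IntegerVector enz_occ = clone(as<IntegerVector>(state["enz_occ"]));
  NumericVector counters = clone(as<NumericVector>(state["counters"]));
  IntegerVector vhpc_entries = clone(as<IntegerVector>(state["vhpc_entries"]));
  const int N = typ.size();
  const int P = nenz.size();
  if (enz_occ.size() != P || band.size() != P || vhpc_entries.size() != P)
    stop("inconsistent per-vHPC array lengths");

  int n_marker = 0, n_other = 0;
  for (int i = 0; i < N; ++i) (typ[i] == 0 ? n_marker : n_other)++;

  double att_entry = counters["att_entry"], cnt_entry = counters["n_entry"],
         att_exit = counters["att_exit"], cnt_exit = counters["n_exit"],
         att_bind = counters["att_bind"], cnt_bind = counters["n_bind"],
         n_release = counters["n_release"], n_metab = counters["n_metab"];

  NumericMatrix series(record ? n_ts : 0, N_COL);
  std::vector<int> cand;
  cand.reserve(256);

  RNGScope rng;

  for (int step = 0; step < n_ts; ++step) {
    ts += 1;
    double ent_band[4] = {0, 0, 0, 0};
    double inflow_t = 0, inflow_m = 0, outflow_t = 0, outflow_m = 0;

    // downstream SS boundary reached via Core or Interface: move along a
    // randomly selected outgoing graph edge (after `lat_guard` consecutive
    // lateral hops the next exit must use an inter-layer edge)
    auto route_exit = [&](int i) {
      const int s = ssv[i];
      const int ninter = einter[s], nintra = eintra[s];
      int navail = (lat[i] >= lat_guard && ninter > 0) ? ninter
                                                       : ninter + nintra;
      if (navail <= 0) stop("SS %d has no outgoing edges", s + 1);
      int k = runif_int(navail);
      int dst = edge_dst[estart[s] + k];
      if (dst < 0) {                 // central vein -> Body at TS end
        loc[i] = L_CVBUF;
        if (typ[i] == 1) outflow_t++; else if (typ[i] == 0) outflow_m++;
        lat[i] = 0;
      } else {
        if (k >= ninter) lat[i] += 1; else lat[i] = 0;
        ssv[i] = dst;
        lv[i] = 0;
        if (loc[i] != L_CORE) wv[i] = runif_int(W);
      }
    };

    // phase 1: transfers, core flow, biased random walk ------------------
    for (int i = 0; i < N; ++i) {
      const int li = loc[i];
      if (li == L_INTRO) {
        if (unif_rand() < ka) loc[i] = L_BODY;
      } else if (li == L_BODY) {
        if (unif_rand() < f_in) {
          if (typ[i] == 1) inflow_t++; else if (typ[i] == 0) inflow_m++;
          lat[i] = 0;
          if (culture) {
            int s = runif_int(n_ss);
            ssv[i] = s;
            wv[i] = runif_int(W);
            lv[i] = runif_int(ss_len[s]);
            loc[i] = L_IFACE;
          } else {
            int s = layer0[runif_int(layer0.size())];
            ssv[i] = s;
            lv[i] = 0;
            if (unif_rand() < core_split) {
              loc[i] = L_CORE; wv[i] = 0;
            } else {
              loc[i] = L_IFACE; wv[i] = runif_int(W);
            }
          }
        }
      } else if (li == L_CORE) {
        // 1D channel: advance with ssFlowRate, radial to Interface with
        // lateral_bias; stay otherwise. Normalized when weights exceed 1.
        const int len = ss_len[ssv[i]];
        double tot = ssflow + lb;
        double u = unif_rand() * (tot > 1.0 ? tot : 1.0);
        if (u < ssflow) {
          if (lv[i] + 1 < len) lv[i] += 1; else route_exit(i);
        } else if (u < tot) {
          loc[i] = L_IFACE; wv[i] = runif_int(W);
        }
      } else if (li == L_IFACE && culture) {
        // merged Media-Cell Interface: lateral walk plus a return-to-Media
        // move with weight forward_bias (the merged space absorbs PV/CV).
        double tot = fb + 2 * lb;
        double u = unif_rand() * (tot > 1.0 ? tot : 1.0);
        if (u < fb) {
          loc[i] = L_BODY;
          if (typ[i] == 1) outflow_t++; else if (typ[i] == 0) outflow_m++;
        } else if (u < fb + lb) {
          wv[i] = (wv[i] + 1) % W;
        } else if (u < tot) {
          wv[i] = (wv[i] + W - 1) % W;
        }
      } else if (li == L_IFACE) {
        const int s = ssv[i], len = ss_len[s];
        // outward to Endothelial space: non-permeant objects only through
        // open fenestrae at the target location
        const int pos = goff[s] + lv[i] * W + wv[i];
        double w_out = (crossing[typ[i]] || open[pos]) ? lb : 0.0;
        double tot = fb + 2 * lb + lb + w_out; // fwd, lat x2, inward, outward
        double u = unif_rand() * (tot > 1.0 ? tot : 1.0);
        if (u < fb) {
          if (lv[i] + 1 < len) lv[i] += 1; else route_exit(i);
        } else if (u < fb + lb) {
          wv[i] = (wv[i] + 1) % W;
        } else if (u < fb + 2 * lb) {
          wv[i] = (wv[i] + W - 1) % W;
        } else if (u < fb + 3 * lb) {
          loc[i] = L_CORE; wv[i] = 0;
        } else if (u < fb + 3 * lb + w_out) {
          loc[i] = L_ENDO;
        }
      } else if (li == L_ENDO) {
        // at the downstream end the forward move drains radially inward
        // (perisinusoidal fluid rejoins the sinusoid lumen); elsewhere it
        // advances within the grid
        const int s = ssv[i], len = ss_len[s];
        const int base = goff[s] + lv[i] * W;
        const bool cross = crossing[typ[i]] != 0;
        const int wl = (wv[i] + 1) % W, wr = (wv[i] + W - 1) % W;
        const bool at_end = lv[i] + 1 >= len;
        double w_f = (at_end ||
                      cross || open[goff[s] + (lv[i] + 1) * W + wv[i]])
                         ? fb : 0.0;
        double w_l = (cross || open[base + wl]) ? lb : 0.0;
        double w_r = (cross || open[base + wr]) ? lb : 0.0;
        double tot = w_f + w_l + w_r + 2 * lb;  // + inward, outward
        double u = unif_rand() * (tot > 1.0 ? tot : 1.0);
        if (u < w_f) { if (at_end) loc[i] = L_IFACE; else lv[i] += 1; }
        else if (u < w_f + w_l) wv[i] = wl;
        else if (u < w_f + w_l + w_r) wv[i] = wr;
        else if (u < w_f + w_l + w_r + lb) loc[i] = L_IFACE;
        else if (u < tot) loc[i] = L_DISSE;
      } else if (li == L_DISSE) {
        const int s = ssv[i], len = ss_len[s];
        const bool cross = crossing[typ[i]] != 0;
        const bool can_in = cross || open[goff[s] + lv[i] * W + wv[i]];
        const bool at_end = lv[i] + 1 >= len;
        double w_f = (at_end ? can_in : true) ? fb : 0.0;
        double w_in = can_in ? lb : 0.0;
        double tot = w_f + 2 * lb + w_in;
        double u = unif_rand() * (tot > 1.0 ? tot : 1.0);
        if (u < w_f) { if (at_end) loc[i] = L_ENDO; else lv[i] += 1; }
        else if (u < w_f + lb) wv[i] = (wv[i] + 1) % W;
        else if (u < w_f + 2 * lb) wv[i] = (wv[i] + W - 1) % W;
        else if (u < tot) loc[i] = L_ENDO;
      }
    }

    // phase 2: hepatocyte entry attempts ---------------------------------
    const int entry_loc = culture ? L_IFACE : L_DISSE;
    for (int i = 0; i < N; ++i) {
      if (loc[i] != entry_loc || typ[i] != 1 || !crossing[1]) continue;
      att_entry++;
      if (unif_rand() < p_enter[1]) {
        loc[i] = L_INCELL;
        lastent[i] = ts;
        const int pos = goff[ssv[i]] + lv[i] * W + wv[i];
        ent_band[band[pos]]++;
        vhpc_entries[pos]++;
        cnt_entry++;
      }
    }

    // phase 3: scheduled releases (and metabolism) -----------------------
    for (int i = 0; i < N; ++i) {
      if (loc[i] != L_INCELL || !bound[i] || rel_ts[i] != ts) continue;
      bound[i] = 0;
      const int pos = goff[ssv[i]] + lv[i] * W + wv[i];
      enz_occ[pos] -= 1;
      n_release++;
      if (metflag[i]) { typ[i] = 2; metflag[i] = 0; n_metab++; }
    }

    // phase 4: enzyme binding (randomized candidate order) ---------------
    if (p_bind > 0) {
      cand.clear();
      for (int i = 0; i < N; ++i) {
        if (loc[i] != L_INCELL || bound[i] || typ[i] != 1) continue;
        const int pos = goff[ssv[i]] + lv[i] * W + wv[i];
        if (enz_occ[pos] < nenz[pos]) att_bind++;
        if (unif_rand() < p_bind) cand.push_back(i);
      }
      for (int k = (int)cand.size() - 1; k > 0; --k) {
        int j = runif_int(k + 1);
        std::swap(cand[k], cand[j]);
      }
      for (size_t c = 0; c < cand.size(); ++c) {
        const int i = cand[c];
        const int pos = goff[ssv[i]] + lv[i] * W + wv[i];
        if (enz_occ[pos] >= nenz[pos]) continue;  // no unoccupied enzyme
        enz_occ[pos] += 1;
        bound[i] = 1;
        rel_ts[i] = ts + bind_cycles;
        metflag[i] = (unif_rand() < p_met) ? 1 : 0;
        cnt_bind++;
      }
    }

    // phase 5: exits (never in the same TS as the entry) -----------------
    for (int i = 0; i < N; ++i) {
      if (loc[i] != L_INCELL || bound[i] || lastent[i] >= ts) continue;
      const double pe = p_exit[typ[i]];
      if (typ[i] == 1) att_exit++;
      if (unif_rand() < pe) {
        loc[i] = culture ? L_IFACE : L_DISSE;
        if (typ[i] == 1) cnt_exit++;
      }
    }

    // phase 6: CV -> Body at end of TS ------------------------------------
    for (int i = 0; i < N; ++i) if (loc[i] == L_CVBUF) loc[i] = L_BODY;

    if (check) {
      int m = 0, o = 0, b = 0;
      long occ = 0;
      for (int i = 0; i < N; ++i) {
        if (typ[i] == 0) m++; else o++;
        if (bound[i]) b++;
      }
      for (int p = 0; p < P; ++p) {
        occ += enz_occ[p];
        if (enz_occ[p] < 0 || enz_occ[p] > nenz[p])
          stop("enzyme occupancy out of range at vHPC %d, TS %d", p + 1, ts);
      }
      if (m != n_marker || o != n_other)
        stop("conservation violated at TS %d: %d markers, %d others", ts, m, o);
      if (occ != b)
        stop("bound-compound/enzyme mismatch at TS %d", ts);
    }

    // phase 7: record ------------------------------------------------------
    if (record) {
      double row[N_COL] = {0};
      for (int i = 0; i < N; ++i) {
        const int t = typ[i], li = loc[i];
        if (t == 0) {
          if (li == L_INTRO) row[C_INTRO_M]++;
          else if (li == L_BODY) row[C_BODY_M]++;
          else row[C_EXTRA_M]++;
        } else if (t == 1) {
          if (li == L_INTRO) row[C_INTRO_T]++;
          else if (li == L_BODY) row[C_BODY_T]++;
          else if (li == L_INCELL) {
            row[C_CELL_ALL]++;
            const int pos = goff[ssv[i]] + lv[i] * W + wv[i];
            if (band[pos] == 1) row[C_CELL_PP]++;
            else if (band[pos] == 2) row[C_CELL_CL]++;
            else if (band[pos] == 3) row[C_CELL_PC]++;
            if (bound[i]) row[C_BOUND_T]++;
          } else row[C_EXTRA_T]++;
        } else {
          row[C_MET_TOTAL]++;
          if (li == L_BODY) row[C_MET_BODY]++;
        }
      }
      row[C_CUM_METAB] = n_metab;
      row[C_CUM_ENT] = cnt_entry;
      row[C_ENT_ALL] = ent_band[0] + ent_band[1] + ent_band[2] + ent_band[3];
      row[C_ENT_PP] = ent_band[1];
      row[C_ENT_CL] = ent_band[2];
      row[C_ENT_PC] = ent_band[3];
      row[C_INFLOW_T] = inflow_t;
      row[C_OUTFLOW_T] = outflow_t;
      row[C_INFLOW_M] = inflow_m;
      row[C_OUTFLOW_M] = outflow_m;
      for (int c = 0; c < N_COL; ++c) series(step, c) = row[c];
    }
  }

  counters["att_entry"] = att_entry; counters["n_entry"] = cnt_entry;
  counters["att_exit"] = att_exit;   counters["n_exit"] = cnt_exit;
  counters["att_bind"] = att_bind;   counters["n_bind"] = cnt_bind;
  counters["n_release"] = n_release; counters["n_metab"] = n_metab;

  List out_state = List::create(
      _["ts"] = ts, _["typ"] = typ, _["loc"] = loc, _["ss"] = ssv,
      _["w"] = wv, _["l"] = lv, _["bound"] = bound, _["rel_ts"] = rel_ts,
      _["metflag"] = metflag, _["lat_hops"] = lat,
      _["last_entry_ts"] = lastent, _["enz_occ"] = enz_occ,
      _["counters"] = counters, _["vhpc_entries"] = vhpc_entries);
  out_state.attr("class") = "system_state";

  colnames(series) = CharacterVector::create(
      "intro_t", "body_t", "extra_t", "cell_all", "cell_pp", "cell_cl",
      "cell_pc", "met_total", "met_body", "cum_metab", "entries_all",
      "entries_pp", "entries_cl", "entries_pc", "inflow_t", "outflow_t",
      "intro_m", "body_m", "extra_m", "inflow_m", "outflow_m", "cum_entries",
      "bound_t");

  return List::create(_["state"] = out_state, _["series"] = series);
}
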