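#include <Rcpp.h>
using namespace Rcpp;

// Flux-form upwind advection of CO2 through a single-limb leak circuit.
//
// Geometry (1-D chain of well-mixed cells, plug-flow advection only):
//
//   ventilator -- v[nv-1] ... v[0] -- NODE(leak port) -- p[0] ... u[np-1] -- patient
//
// The node has zero volume; the intentional leak (conductance * pressure)
// drains it at every instant. Signs: q_pat > 0 is flow toward the patient
// (inspiration at the patient-side sensor); q_vent > 0 is flow from the
// ventilator limb toward the node/patient. Mass balance at the node gives
// q_vent = q_leak + q_pat.
//
// The scheme is conservative: every cell update is (flux_in - flux_out) and
// every boundary flux is accumulated, so exhaled = leak_out + vent_end_out +
// reinhaled + (change in circuit content) to machine precision.
//
// Concentrations are in %CO2; flows in ml/s; volumes in ml; CO2 bookkeeping
// in ml of pure CO2 (flow * conc/100 * dt).

// [[Rcpp::export(name = ".advect_core")]]
List advect_core(NumericVector q_pat, NumericVector c_src,
                 NumericVector pressure, double leak_k,
                 int n_vent, double vent_vol,
                 int n_pat, double pat_vol, double dt) {
  const int n = q_pat.size();
  if (c_src.size() != n || pressure.size() != n)
    stop("q_pat, c_src and pressure must have equal length");
  if (n_vent < 1 || n_pat < 1) stop("cell counts must be >= 1");
  if (vent_vol <= 0 || pat_vol <= 0) stop("limb volumes must be positive");

  const double vcv = vent_vol / n_vent;   // ml per ventilator-limb cell
  const double vcp = pat_vol / n_pat;     // ml per patient-limb cell

  std::vector<double> v(n_vent, 0.0), p(n_pat, 0.0);

  NumericVector co2_vent(n), co2_pat(n), q_vent_out(n);
  NumericVector exhaled(n), leak_out(n), vent_end(n), reinhaled(n),
      rebreathed(n), content(n);

  double cum_exh = 0, cum_leak = 0, cum_vent_end = 0, cum_reinh = 0,
      cum_rebr = 0;

  for (int i = 0; i < n; ++i) {
    const double qp = q_pat[i];
    const double ql = leak_k * pressure[i];
    const double qv = ql + qp;
    q_vent_out[i] = qv;

    // CFL sub-stepping: at most 90% of a cell volume moved per sub-step.
    const double courant =
        std::max(std::fabs(qv) * dt / vcv, std::fabs(qp) * dt / vcp);
    const int nsub = std::max(1, (int)std::ceil(courant / 0.9));
    const double h = dt / nsub;

    for (int s = 0; s < nsub; ++s) {
      // Node mixing: weighted average of the inflowing streams.
      double c_node;
      if (qp >= 0) {
        // Inspiration (or apnoea): only the ventilator limb feeds the node.
        c_node = (qv > 0) ? v[0] : 0.0;
      } else if (qv > 0) {
        // Both limbs feed the node (late expiration, after flow reversal).
        c_node = (qv * v[0] - qp * p[0]) / (qv - qp);
      } else {
        // Early expiration: patient stream splits into leak + vent limb.
        c_node = p[0];
      }

      // --- patient limb ---
      if (qp > 0) {  // toward patient: node -> p[0] -> ... -> patient
        const double out = qp * p[n_pat - 1] / 100.0 * h;  // ml CO2 inhaled
        cum_reinh += out;
        cum_rebr += qp * c_node / 100.0 * h;  // crossed node toward patient
        for (int j = n_pat - 1; j > 0; --j)
          p[j] += qp * h / vcp * (p[j - 1] - p[j]);
        p[0] += qp * h / vcp * (c_node - p[0]);
      } else if (qp < 0) {  // toward node: patient -> p[np-1] -> ... -> p[0]
        const double qe = -qp;
        cum_exh += qe * c_src[i] / 100.0 * h;
        for (int j = 0; j < n_pat - 1; ++j)
          p[j] += qe * h / vcp * (p[j + 1] - p[j]);
        p[n_pat - 1] += qe * h / vcp * (c_src[i] - p[n_pat - 1]);
      }

      // --- ventilator limb ---
      if (qv > 0) {  // toward node: fresh gas enters at the ventilator end
        for (int j = 0; j < n_vent - 1; ++j)
          v[j] += qv * h / vcv * (v[j + 1] - v[j]);
        v[n_vent - 1] += qv * h / vcv * (0.0 - v[n_vent - 1]);
      } else if (qv < 0) {  // away from node: node gas pushed up the limb
        const double qb = -qv;
        cum_vent_end += qb * v[n_vent - 1] / 100.0 * h;
        for (int j = n_vent - 1; j > 0; --j)
          v[j] += qb * h / vcv * (v[j - 1] - v[j]);
        v[0] += qb * h / vcv * (c_node - v[0]);
      }

      cum_leak += ql * c_node / 100.0 * h;
    }

    // Sensors sit 2 cm from the port: vent side reads the port-adjacent
    // cell; patient side reads the gas streaming past (node gas during
    // inspiration, limb gas during expiration).
    co2_vent[i] = v[0];
    co2_pat[i] = (qp > 0) ? ((qv > 0) ? v[0] : 0.0) : p[0];

    double tot = 0;
    for (int j = 0; j < n_vent; ++j) tot += v[j] / 100.0 * vcv;
    for (int j = 0; j < n_pat; ++j) tot += p[j] / 100.0 * vcp;
    content[i] = tot;
    exhaled[i] = cum_exh;
    leak_out[i] = cum_leak;
    vent_end[i] = cum_vent_end;
    reinhaled[i] = cum_reinh;
    rebreathed[i] = cum_rebr;
  }

  return List::create(
      _["co2_vent"] = co2_vent, _["co2_pat"] = co2_pat,
      _["q_vent"] = q_vent_out, _["exhaled"] = exhaled,
      _["leak_out"] = leak_out, _["vent_end_out"] = vent_end,
      _["reinhaled"] = reinhaled, _["rebreathed"] = rebreathed,
      _["content"] = content);
}
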