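#include <Rcpp.h>
using namespace Rcpp;

// Delta-rule / softmax forward pass over one session.
//
// displayed: n_trials x 3 matrix of 1-based image indices
// chosen:    1-based index of the chosen image, 0 on missed trials
// reward:    obtained reward r(t) in currency-normalized units (0/1)
// familiar:  per-image pre-familiarization flag (indexes match `displayed`)
//
// Every image starts at q_init_familiar or q_init_novel according to its
// class; values only matter once the image is displayed, so eager
// initialization is likelihood-equivalent to lazy creation at first
// appearance. Only the chosen image's value is updated (Q <- Q + alpha*delta);
// missed trials contribute no likelihood term and trigger no update.

static inline void softmax3(const double *q, double beta, double *p) {
    double m = q[0];
    if (q[1] > m) m = q[1];
    if (q[2] > m) m = q[2];
    double e0 = std::exp(beta * (q[0] - m));
    double e1 = std::exp(beta * (q[1] - m));
    double e2 = std::exp(beta * (q[2] - m));
    double s = e0 + e1 + e2;
    p[0] = e0 / s; p[1] = e1 / s; p[2] = e2 / s;
}

// [[Rcpp::export(name = ".rl_forward_nll")]]
List rl_forward_nll(IntegerMatrix displayed, IntegerVector chosen,
                    NumericVector reward, LogicalVector familiar,
                    double alpha, double beta,
                    double q_init_familiar, double q_init_novel) {
    const int n = displayed.nrow();
    const int n_img = familiar.size();
    std::vector<double> q(n_img);
    for (int i = 0; i < n_img; ++i)
        q[i] = familiar[i] ? q_init_familiar : q_init_novel;

    double nll = 0.0;
    int used = 0;
    double qd[3], p[3];
    for (int t = 0; t < n; ++t) {
        int c = chosen[t];
        if (c == 0) continue;               // missed: no term, no update
        int i0 = displayed(t, 0) - 1, i1 = displayed(t, 1) - 1,
            i2 = displayed(t, 2) - 1;
        qd[0] = q[i0]; qd[1] = q[i1]; qd[2] = q[i2];
        softmax3(qd, beta, p);
        int slot = (c - 1 == i0) ? 0 : ((c - 1 == i1) ? 1 : 2);
        nll -= std::log(p[slot]);
        ++used;
        double delta = reward[t] - q[c - 1];
        q[c - 1] += alpha * delta;
    }
    return List::create(_["nll"] = nll, _["n_trials_used"] = used);
}

// [[Rcpp::export(name = ".rl_forward_trace")]]
List rl_forward_trace(IntegerMatrix displayed, IntegerVector chosen,
                      NumericVector reward, LogicalVector familiar,
                      double alpha, double beta,
                      double q_init_familiar, double q_init_novel) {
    const int n = displayed.nrow();
    const int n_img = familiar.size();
    std::vector<double> q(n_img);
    for (int i = 0; i < n_img; ++i)
        q[i] = familiar[i] ? q_init_familiar : q_init_novel;

    NumericMatrix qmat(n, 3), pmat(n, 3);
    NumericMatrix values(n + 1, n_img);      // values[t, ] = Q before trial t+1
    NumericVector delta(n, NA_REAL), p_chosen(n, NA_REAL),
                  q_chosen(n, NA_REAL);
    double nll = 0.0;
    int used = 0;
    double qd[3], p[3];
    for (int i = 0; i < n_img; ++i) values(0, i) = q[i];
    for (int t = 0; t < n; ++t) {
        int i0 = displayed(t, 0) - 1, i1 = displayed(t, 1) - 1,
            i2 = displayed(t, 2) - 1;
        qd[0] = q[i0]; qd[1] = q[i1]; qd[2] = q[i2];
        softmax3(qd, beta, p);
        for (int k = 0; k < 3; ++k) { qmat(t, k) = qd[k]; pmat(t, k) = p[k]; }
        int c = chosen[t];
        if (c != 0) {
            int slot = (c - 1 == i0) ? 0 : ((c - 1 == i1) ? 1 : 2);
            nll -= std::log(p[slot]);
            ++used;
            p_chosen[t] = p[slot];
            q_chosen[t] = q[c - 1];
            delta[t] = reward[t] - q[c - 1];
            q[c - 1] += alpha * delta[t];
        }
        for (int i = 0; i < n_img; ++i) values(t + 1, i) = q[i];
    }
    return List::create(_["nll"] = nll, _["n_trials_used"] = used,
                        _["q_displayed"] = qmat, _["choice_probs"] = pmat,
                        _["q_chosen"] = q_chosen, _["p_chosen"] = p_chosen,
                        _["delta"] = delta, _["values"] = values);
}
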