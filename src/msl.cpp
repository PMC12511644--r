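#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Simulated panel likelihood core.
//
// B:  coefficient values flattened from a (K x n_persons x R) array,
//     indexed B[k + K*(person + n*r)] (k fastest, cache-friendly).
// Xt: transposed design, K x n_rows, xt[k + K*row].
// Tasks are contiguous row blocks. For each draw r the per-task softmax
// over available alternatives is computed with max-subtraction, chosen
// probabilities are multiplied across a person's tasks on the log scale,
// and the panel products are averaged over draws:
//   P_n = (1/R) sum_r prod_t P_ntj*.
// Optional outputs:
//   row_probs: draw-averaged probability of each row (sample enumeration);
//   score: A[k + K*(person + n*r)] = panelprod_nr *
//          sum_t (x_k,chosen - sum_j P_ntj x_k,j), the building block of
//          the analytic simulated-likelihood gradient
//          dLL/dtheta = sum_n (R P_n)^-1 sum_r sum_k A_nrk dbeta_nrk/dtheta.
// [[Rcpp::export]]
List msl_core(NumericVector B, int n_persons, int R, int K,
              NumericMatrix Xt,
              IntegerVector task_start, IntegerVector task_len,
              IntegerVector task_person, IntegerVector chosen_row,
              LogicalVector avail, bool row_probs, bool want_score) {
  const int n_tasks = task_start.size();
  const int n_rows = Xt.ncol();
  const double *b = REAL(B);
  const double *xt = REAL(Xt);

  std::vector<double> logp(n_persons);
  std::vector<double> acc(n_persons, 0.0);
  std::vector<double> rowacc;
  if (row_probs) rowacc.assign(n_rows, 0.0);
  NumericVector score;
  double *sc = nullptr;
  std::vector<double> draw_score;
  if (want_score) {
    score = NumericVector((size_t)K * n_persons * R);
    sc = REAL(score);
    draw_score.assign((size_t)K * n_persons, 0.0);
  }

  int max_len = 0;
  for (int t = 0; t < n_tasks; ++t) if (task_len[t] > max_len) max_len = task_len[t];
  std::vector<double> v(max_len), e(max_len);
  std::vector<double> xbar(K);

  for (int r = 0; r < R; ++r) {
    std::fill(logp.begin(), logp.end(), 0.0);
    if (want_score) std::fill(draw_score.begin(), draw_score.end(), 0.0);
    for (int t = 0; t < n_tasks; ++t) {
      const int s = task_start[t];
      const int len = task_len[t];
      const int per = task_person[t];
      const double *bp = b + (size_t)K * (per + (size_t)n_persons * r);
      double vmax = -INFINITY;
      for (int j = 0; j < len; ++j) {
        const int row = s + j;
        const double *xr = xt + (size_t)K * row;
        double vj = 0.0;
        for (int k = 0; k < K; ++k) vj += xr[k] * bp[k];
        v[j] = vj;
        if (avail[row] && vj > vmax) vmax = vj;
      }
      double denom = 0.0;
      for (int j = 0; j < len; ++j) {
        e[j] = avail[s + j] ? std::exp(v[j] - vmax) : 0.0;
        denom += e[j];
      }
      const int cj = chosen_row[t] - s;  // chosen row's offset in the block
      double pc = e[cj] / denom;
      if (pc < 1e-300) pc = 1e-300;
      logp[per] += std::log(pc);
      if (row_probs) {
        for (int j = 0; j < len; ++j) rowacc[s + j] += e[j] / denom;
      }
      if (want_score) {
        std::fill(xbar.begin(), xbar.end(), 0.0);
        for (int j = 0; j < len; ++j) {
          const double pj = e[j] / denom;
          if (pj == 0.0) continue;
          const double *xr = xt + (size_t)K * (s + j);
          for (int k = 0; k < K; ++k) xbar[k] += pj * xr[k];
        }
        const double *xc = xt + (size_t)K * chosen_row[t];
        double *ds = &draw_score[(size_t)K * per];
        for (int k = 0; k < K; ++k) ds[k] += xc[k] - xbar[k];
      }
    }
    for (int p = 0; p < n_persons; ++p) {
      const double pp = std::exp(logp[p]);
      acc[p] += pp;
      if (want_score) {
        double *out = sc + (size_t)K * (p + (size_t)n_persons * r);
        const double *ds = &draw_score[(size_t)K * p];
        for (int k = 0; k < K; ++k) out[k] = pp * ds[k];
      }
    }
  }

  NumericVector Pn(n_persons);
  for (int p = 0; p < n_persons; ++p) {
    double val = acc[p] / R;
    Pn[p] = (val < 1e-300) ? 1e-300 : val;
  }
  List out = List::create(Named("Pn") = Pn);
  if (row_probs) {
    NumericVector rp(n_rows);
    for (int i = 0; i < n_rows; ++i) rp[i] = rowacc[i] / R;
    out["row_probs"] = rp;
  }
  if (want_score) out["score"] = score;
  return out;
}

// Chain-rule contraction for the gradient: given the score array A
// (K x n x R layout), the per-(n,r) derivative matrix D of one
// coefficient's beta wrt one free parameter (n x R), the coefficient
// index k, and weights w_n = 1/(R P_n), returns
//   sum_{n,r} w_n A[k,n,r] D[n,r].
// [[Rcpp::export]]
double msl_grad_contract(NumericVector score, int n_persons, int R, int K,
                         int k, NumericMatrix D, NumericVector w) {
  const double *sc = REAL(score);
  const double *d = REAL(D);
  const double *wp = REAL(w);
  double total = 0.0;
  for (int r = 0; r < R; ++r) {
    for (int p = 0; p < n_persons; ++p) {
      total += wp[p] * sc[k + (size_t)K * (p + (size_t)n_persons * r)] *
               d[p + (size_t)n_persons * r];
    }
  }
  return total;
}
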