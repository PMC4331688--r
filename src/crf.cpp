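// First-order linear-chain CRF core: penalized negative log-likelihood
// with analytic gradient (forward-backward), and Viterbi decoding with
// per-token label marginals.
//
// Data layout shared by both entry points (all indices 0-based):
//   feat     concatenated feature ids over all tokens
//   tok_ptr  length n_tokens + 1, offsets into feat per token
//   sent_ptr length n_sentences + 1, offsets into tokens per sentence
// Parameter vector: nf * L emission weights (feature-major: f * L + y)
// followed by L * L transition weights (prev * L + next).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double logsumexp(const double* v, int L) {
  double m = v[0];
  for (int i = 1; i < L; ++i) if (v[i] > m) m = v[i];
  if (!std::isfinite(m)) return m;
  double s = 0.0;
  for (int i = 0; i < L; ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

// [[Rcpp::export]]
List crf_nll_grad(NumericVector theta, IntegerVector feat,
                  IntegerVector tok_ptr, IntegerVector sent_ptr,
                  IntegerVector labels, int L, int nf, double l2) {
  const int n_sent = sent_ptr.size() - 1;
  const double* th = theta.begin();
  const double* trans = th + (size_t)nf * L;
  NumericVector grad(theta.size());
  double* g = grad.begin();
  double* gtrans = g + (size_t)nf * L;
  double nll = 0.0;

  std::vector<double> node, alpha, beta, marg;
  for (int s = 0; s < n_sent; ++s) {
    const int t0 = sent_ptr[s], t1 = sent_ptr[s + 1];
    const int T = t1 - t0;
    if (T <= 0) continue;
    node.assign((size_t)T * L, 0.0);
    for (int t = 0; t < T; ++t) {
      for (int k = tok_ptr[t0 + t]; k < tok_ptr[t0 + t + 1]; ++k) {
        const int f = feat[k];
        for (int y = 0; y < L; ++y) node[(size_t)t * L + y] += th[(size_t)f * L + y];
      }
    }
    alpha.assign((size_t)T * L, 0.0);
    beta.assign((size_t)T * L, 0.0);
    for (int y = 0; y < L; ++y) alpha[y] = node[y];
    std::vector<double> tmp(L);
    for (int t = 1; t < T; ++t) {
      for (int y = 0; y < L; ++y) {
        for (int yp = 0; yp < L; ++yp)
          tmp[yp] = alpha[(size_t)(t - 1) * L + yp] + trans[yp * L + y];
        alpha[(size_t)t * L + y] = node[(size_t)t * L + y] + logsumexp(tmp.data(), L);
      }
    }
    const double logZ = logsumexp(&alpha[(size_t)(T - 1) * L], L);
    for (int y = 0; y < L; ++y) beta[(size_t)(T - 1) * L + y] = 0.0;
    for (int t = T - 2; t >= 0; --t) {
      for (int y = 0; y < L; ++y) {
        for (int yn = 0; yn < L; ++yn)
          tmp[yn] = trans[y * L + yn] + node[(size_t)(t + 1) * L + yn] +
                    beta[(size_t)(t + 1) * L + yn];
        beta[(size_t)t * L + y] = logsumexp(tmp.data(), L);
      }
    }
    // gold score
    double score = 0.0;
    for (int t = 0; t < T; ++t) {
      score += node[(size_t)t * L + labels[t0 + t]];
      if (t > 0) score += trans[labels[t0 + t - 1] * L + labels[t0 + t]];
    }
    nll += logZ - score;
    // node marginals -> emission gradient
    marg.assign((size_t)T * L, 0.0);
    for (int t = 0; t < T; ++t)
      for (int y = 0; y < L; ++y)
        marg[(size_t)t * L + y] =
            std::exp(alpha[(size_t)t * L + y] + beta[(size_t)t * L + y] - logZ);
    for (int t = 0; t < T; ++t) {
      const int gold = labels[t0 + t];
      for (int k = tok_ptr[t0 + t]; k < tok_ptr[t0 + t + 1]; ++k) {
        const int f = feat[k];
        for (int y = 0; y < L; ++y)
          g[(size_t)f * L + y] += marg[(size_t)t * L + y];
        g[(size_t)f * L + gold] -= 1.0;
      }
    }
    // pairwise marginals -> transition gradient
    for (int t = 1; t < T; ++t) {
      for (int yp = 0; yp < L; ++yp) {
        for (int y = 0; y < L; ++y) {
          const double lp = alpha[(size_t)(t - 1) * L + yp] + trans[yp * L + y] +
                            node[(size_t)t * L + y] + beta[(size_t)t * L + y] -
                            logZ;
          gtrans[yp * L + y] += std::exp(lp);
        }
      }
      gtrans[labels[t0 + t - 1] * L + labels[t0 + t]] -= 1.0;
    }
  }
  // L2 penalty
  double pen = 0.0;
  for (R_xlen_t i = 0; i < theta.size(); ++i) {
    pen += th[i] * th[i];
    g[i] += l2 * th[i];
  }
  nll += 0.5 * l2 * pen;
  return List::create(_["nll"] = nll, _["grad"] = grad);
}

// [[Rcpp::export]]
List crf_decode(NumericVector theta, IntegerVector feat,
                IntegerVector tok_ptr, IntegerVector sent_ptr,
                int L, int nf) {
  const int n_sent = sent_ptr.size() - 1;
  const int n_tok = tok_ptr.size() - 1;
  const double* th = theta.begin();
  const double* trans = th + (size_t)nf * L;
  IntegerVector path(n_tok);
  NumericMatrix marginals(n_tok, L);

  std::vector<double> node, alpha, beta, delta;
  std::vector<int> back;
  for (int s = 0; s < n_sent; ++s) {
    const int t0 = sent_ptr[s], t1 = sent_ptr[s + 1];
    const int T = t1 - t0;
    if (T <= 0) continue;
    node.assign((size_t)T * L, 0.0);
    for (int t = 0; t < T; ++t)
      for (int k = tok_ptr[t0 + t]; k < tok_ptr[t0 + t + 1]; ++k) {
        const int f = feat[k];
        for (int y = 0; y < L; ++y) node[(size_t)t * L + y] += th[(size_t)f * L + y];
      }
    // Viterbi
    delta.assign((size_t)T * L, 0.0);
    back.assign((size_t)T * L, 0);
    for (int y = 0; y < L; ++y) delta[y] = node[y];
    for (int t = 1; t < T; ++t) {
      for (int y = 0; y < L; ++y) {
        double best = delta[(size_t)(t - 1) * L] + trans[0 * L + y];
        int arg = 0;
        for (int yp = 1; yp < L; ++yp) {
          const double v = delta[(size_t)(t - 1) * L + yp] + trans[yp * L + y];
          if (v > best) { best = v; arg = yp; }
        }
        delta[(size_t)t * L + y] = node[(size_t)t * L + y] + best;
        back[(size_t)t * L + y] = arg;
      }
    }
    int ybest = 0;
    for (int y = 1; y < L; ++y)
      if (delta[(size_t)(T - 1) * L + y] > delta[(size_t)(T - 1) * L + ybest])
        ybest = y;
    path[t0 + T - 1] = ybest;
    for (int t = T - 1; t > 0; --t)
      path[t0 + t - 1] = back[(size_t)t * L + path[t0 + t]];
    // forward-backward marginals
    alpha.assign((size_t)T * L, 0.0);
    beta.assign((size_t)T * L, 0.0);
    std::vector<double> tmp(L);
    for (int y = 0; y < L; ++y) alpha[y] = node[y];
    for (int t = 1; t < T; ++t)
      for (int y = 0; y < L; ++y) {
        for (int yp = 0; yp < L; ++yp)
          tmp[yp] = alpha[(size_t)(t - 1) * L + yp] + trans[yp * L + y];
        alpha[(size_t)t * L + y] = node[(size_t)t * L + y] + logsumexp(tmp.data(), L);
      }
    const double logZ = logsumexp(&alpha[(size_t)(T - 1) * L], L);
    for (int t = T - 2; t >= 0; --t)
      for (int y = 0; y < L; ++y) {
        for (int yn = 0; yn < L; ++yn)
          tmp[yn] = trans[y * L + yn] + node[(size_t)(t + 1) * L + yn] +
                    beta[(size_t)(t + 1) * L + yn];
        beta[(size_t)t * L + y] = logsumexp(tmp.data(), L);
      }
    for (int t = 0; t < T; ++t)
      for (int y = 0; y < L; ++y)
        marginals(t0 + t, y) =
            std::exp(alpha[(size_t)t * L + y] + beta[(size_t)t * L + y] - logZ);
  }
  return List::create(_["path"] = path, _["marginals"] = marginals);
}
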