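// Hot path for training: full forward pass of the hierarchical
// community-pooling regressor plus analytic backpropagation, batched over
// graphs. Mirrors the R reference implementations exactly (same softmax,
// tie-breaking, and aggregation rules); tests assert agreement.
//
// Gradient convention: the hard center selection, the membership assignment
// and the inverse-distance aggregation coefficients 1/(S+eps) are treated
// as constants of the forward pass (stop-gradient). Gradients flow through
// every latent feature term, the readout weights, and the MLP.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct ScaleWork {
  mat Anorm;
  std::vector<mat> H;   // H[0] = block input, H[l] = layer l output (relu'd)
  std::vector<mat> AH;  // AH[l] = Anorm * H[l-1]
  uvec centers;         // 0-based, ordered by descending probability
  uvec membership;      // community index per node
  mat B;                // M x N aggregation matrix
  mat Zhat;             // pooled features
  vec preR;             // readout preactivation
  vec r;                // readout output
};

mat normalize_adj2(const mat& A) {
  mat At = A + eye(A.n_rows, A.n_rows);
  vec dinv = 1.0 / sqrt(sum(At, 1));
  At.each_col() %= dinv;
  At.each_row() %= dinv.t();
  return At;
}

mat pairwise_dist(const mat& Z, int metric) {
  const uword n = Z.n_rows;
  mat S(n, n, fill::zeros);
  for (uword i = 0; i < n; ++i)
    for (uword j = i + 1; j < n; ++j) {
      double d = (metric == 0) ? accu(abs(Z.row(i) - Z.row(j)))
                               : std::sqrt(accu(square(Z.row(i) - Z.row(j))));
      S(i, j) = d;
      S(j, i) = d;
    }
  return S;
}

vec center_probability(const mat& S) {
  vec r = sum(S, 1);
  double lo = r.min(), hi = r.max();
  vec normed = (hi > lo) ? vec((r - lo) / (hi - lo))
                         : vec(r.n_elem, fill::zeros);
  vec logits = 1.0 - normed;
  vec e = exp(logits - logits.max());
  return e / accu(e);
}

uvec select_centers(const vec& P, double ratio) {
  const uword n = P.n_elem;
  uword M = (uword)std::ceil(ratio * (double)n);
  std::vector<uword> idx(n);
  for (uword i = 0; i < n; ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](uword a, uword b) { return P[a] > P[b]; });
  uvec out(M);
  for (uword i = 0; i < M; ++i) out[i] = idx[i];
  return out;
}

uvec assign_members(const mat& S, const uvec& centers) {
  const uword n = S.n_rows, M = centers.n_elem;
  uvec memb(n);
  for (uword j = 0; j < n; ++j) {
    uword best = 0;
    double bd = S(j, centers[0]);
    for (uword k = 1; k < M; ++k) {
      double d = S(j, centers[k]);
      if (d < bd) { bd = d; best = k; }
    }
    memb[j] = best;
  }
  for (uword i = 0; i < M; ++i) memb[centers[i]] = i;
  return memb;
}

mat pooling_matrix(const mat& S, const uvec& centers, const uvec& memb,
                   double eps) {
  const uword n = S.n_rows, M = centers.n_elem;
  mat B(M, n, fill::zeros);
  for (uword j = 0; j < n; ++j) {
    uword i = memb[j];
    if (j == centers[i]) continue;
    B(i, j) = 1.0 / (S(centers[i], j) + eps);
  }
  for (uword i = 0; i < M; ++i) B(i, centers[i]) = 1.0;
  return B;
}

mat coarsen_adj(const mat& A, const uvec& memb, uword M) {
  const uword n = A.n_rows;
  mat Ind(n, M, fill::zeros);
  for (uword j = 0; j < n; ++j) Ind(j, memb[j]) = 1.0;
  mat Ac = Ind.t() * A * Ind;
  for (uword j = 0; j < n; ++j) Ac(memb[j], memb[j]) -= A(j, j);
  return Ac;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_batch(Rcpp::List As, Rcpp::List Xs, arma::vec y,
                     Rcpp::List gcnW, Rcpp::List readW,
                     Rcpp::List mlpW, Rcpp::List mlpb,
                     double ratio, double eps, int metric, int fusion,
                     double eta1, double eta2, bool wantGrad) {
  const int n = As.size();
  const int T = gcnW.size();

  // unpack parameters
  std::vector<std::vector<mat>> W(T);
  std::vector<vec> rw(T);
  for (int t = 0; t < T; ++t) {
    Rcpp::List lw = gcnW[t];
    for (int l = 0; l < lw.size(); ++l)
      W[t].push_back(Rcpp::as<mat>(lw[l]));
    rw[t] = Rcpp::as<vec>(readW[t]);
  }
  const int ML = mlpW.size();
  std::vector<mat> MW(ML);
  std::vector<vec> Mb(ML);
  for (int l = 0; l < ML; ++l) {
    MW[l] = Rcpp::as<mat>(mlpW[l]);
    Mb[l] = Rcpp::as<vec>(mlpb[l]);
  }

  // gradient accumulators
  std::vector<std::vector<mat>> gW(T);
  std::vector<vec> grw(T);
  std::vector<mat> gMW(ML);
  std::vector<vec> gMb(ML);
  if (wantGrad) {
    for (int t = 0; t < T; ++t) {
      for (size_t l = 0; l < W[t].size(); ++l)
        gW[t].push_back(mat(W[t][l].n_rows, W[t][l].n_cols, fill::zeros));
      grw[t] = vec(rw[t].n_elem, fill::zeros);
    }
    for (int l = 0; l < ML; ++l) {
      gMW[l] = mat(MW[l].n_rows, MW[l].n_cols, fill::zeros);
      gMb[l] = vec(Mb[l].n_elem, fill::zeros);
    }
  }

  const int c = W[0].back().n_cols;
  vec preds(n);
  double sse = 0.0, commSum = 0.0;

  for (int g = 0; g < n; ++g) {
    mat A = Rcpp::as<mat>(As[g]);
    mat X = Rcpp::as<mat>(Xs[g]);

    std::vector<ScaleWork> work(T);
    double commG = 0.0;

    for (int t = 0; t < T; ++t) {
      ScaleWork& w = work[t];
      w.Anorm = normalize_adj2(A);
      w.H.resize(W[t].size() + 1);
      w.AH.resize(W[t].size() + 1);
      w.H[0] = X;
      for (size_t l = 1; l <= W[t].size(); ++l) {
        w.AH[l] = w.Anorm * w.H[l - 1];
        w.H[l] = w.AH[l] * W[t][l - 1];
        w.H[l].transform([](double v) { return v > 0.0 ? v : 0.0; });
      }
      const mat& Z = w.H.back();
      mat S = pairwise_dist(Z, metric);
      vec P = center_probability(S);
      w.centers = select_centers(P, ratio);
      w.membership = assign_members(S, w.centers);
      w.B = pooling_matrix(S, w.centers, w.membership, eps);
      w.Zhat = w.B * Z;
      w.preR = w.Zhat.t() * rw[t];
      w.r = w.preR;
      w.r.transform([](double v) { return v > 0.0 ? v : 0.0; });

      // community-coherence loss at this scale
      for (uword j = 0; j < Z.n_rows; ++j) {
        uword i = w.membership[j];
        if (j == w.centers[i]) continue;
        rowvec d = Z.row(j) - Z.row(w.centers[i]);
        commG += accu(square(d)) / (double)Z.n_cols;
      }

      A = coarsen_adj(A, w.membership, w.centers.n_elem);
      X = w.Zhat;
    }
    commSum += commG;

    // fusion
    vec fused;
    if (fusion == 0) {
      fused.set_size(c * T);
      for (int t = 0; t < T; ++t)
        fused.subvec(t * c, (t + 1) * c - 1) = work[t].r;
    } else {
      fused = vec(c, fill::zeros);
      for (int t = 0; t < T; ++t) fused += work[t].r;
      if (fusion == 2) fused /= (double)T;
    }

    // MLP head
    std::vector<vec> a(ML + 1), pre(ML + 1);
    a[0] = fused;
    for (int l = 0; l < ML; ++l) {
      pre[l + 1] = MW[l] * a[l] + Mb[l];
      a[l + 1] = pre[l + 1];
      if (l < ML - 1)
        a[l + 1].transform([](double v) { return v > 0.0 ? v : 0.0; });
    }
    double yhat = a[ML][0];
    preds[g] = yhat;
    double err = yhat - y[g];
    sse += err * err;

    if (!wantGrad) continue;

    // ---- backward ----
    double dyhat = eta1 * 2.0 * err / (double)n;
    vec da(1);
    da[0] = dyhat;
    for (int l = ML - 1; l >= 0; --l) {
      vec dpre = da;
      if (l < ML - 1) {
        dpre = da % conv_to<vec>::from(pre[l + 1] > 0.0);
      }
      gMW[l] += dpre * a[l].t();
      gMb[l] += dpre;
      da = MW[l].t() * dpre;
    }
    // da == dfused
    mat dXnext;  // gradient on the next scale's block input (= Zhat of t)
    for (int t = T - 1; t >= 0; --t) {
      ScaleWork& w = work[t];
      vec dr;
      if (fusion == 0) dr = da.subvec(t * c, (t + 1) * c - 1);
      else if (fusion == 1) dr = da;
      else dr = da / (double)T;
      vec dpreR = dr % conv_to<vec>::from(w.preR > 0.0);
      grw[t] += w.Zhat * dpreR;
      mat dZhat = rw[t] * dpreR.t();
      if (t < T - 1) dZhat += dXnext;
      mat dZ = w.B.t() * dZhat;

      // community loss gradient (membership fixed)
      const mat& Z = w.H.back();
      double cf = eta2 * 2.0 / ((double)Z.n_cols * (double)n);
      for (uword j = 0; j < Z.n_rows; ++j) {
        uword i = w.membership[j];
        if (j == w.centers[i]) continue;
        rowvec dd = cf * (Z.row(j) - Z.row(w.centers[i]));
        dZ.row(j) += dd;
        dZ.row(w.centers[i]) -= dd;
      }

      // block backward
      mat dH = dZ;
      for (int l = (int)W[t].size(); l >= 1; --l) {
        mat dpre = dH % conv_to<mat>::from(w.H[l] > 0.0);
        gW[t][l - 1] += w.AH[l].t() * dpre;
        dH = w.Anorm * (dpre * W[t][l - 1].t());
      }
      dXnext = dH;  // gradient on block input = previous scale's Zhat
    }
  }

  double mse = sse / (double)n;
  double comm = commSum / (double)n;
  double total = eta1 * mse + eta2 * comm;

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("total") = total,
      Rcpp::Named("mse") = mse,
      Rcpp::Named("community") = comm,
      Rcpp::Named("preds") = preds);
  if (wantGrad) {
    Rcpp::List ogW(T), ogr(T), ogMW(ML), ogMb(ML);
    for (int t = 0; t < T; ++t) {
      Rcpp::List lw(W[t].size());
      for (size_t l = 0; l < W[t].size(); ++l) lw[l] = gW[t][l];
      ogW[t] = lw;
      ogr[t] = grw[t];
    }
    for (int l = 0; l < ML; ++l) {
      ogMW[l] = gMW[l];
      ogMb[l] = gMb[l];
    }
    out["gradGcn"] = ogW;
    out["gradReadout"] = ogr;
    out["gradMlpW"] = ogMW;
    out["gradMlpB"] = ogMb;
  }
  return out;
}
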