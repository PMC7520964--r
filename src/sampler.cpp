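#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Binomial log-likelihood contribution of one cell, binomial coefficient
// omitted: Y*eta - n*log(1+exp(eta)), evaluated stably for large |eta|.
static inline double cellLoglik(double Y, double n, double eta) {
  double lse = (eta > 0.0) ? eta + std::log1p(std::exp(-eta))
                           : std::log1p(std::exp(eta));
  return Y * eta - n * lse;
}

// Sum of squared first differences of an effect vector.
static inline double ssd(const std::vector<double>& e) {
  double s = 0.0;
  for (size_t i = 1; i < e.size(); ++i) {
    double d = e[i] - e[i - 1];
    s += d * d;
  }
  return s;
}

// RW1 (intrinsic CAR) log prior kernel at fixed sd, up to a constant:
// -(K-1) log sd - SSD / (2 sd^2).
static inline double rwLogPriorKernel(double ssdVal, double sdv, int K) {
  return -(K - 1) * std::log(sdv) - ssdVal / (2.0 * sdv * sdv);
}

// One adaptive single-site Metropolis-within-Gibbs chain for the
// binomial-logit model with RW1 age priors. Cells are the non-empty rows
// of the count table; mIdx/pIdx give each cell's 0-based age-level index
// on the maternal/paternal axis (ignored when the axis is absent);
// mAge/pAge give the ages of those levels in years. In joint models the
// single-site sweep mixes very slowly along smooth "exchange" directions
// (maternal curve tilted up, paternal curve tilted down) because the two
// ages are strongly correlated; dedicated directional Metropolis moves
// along centered linear and quadratic age functions fix that.
// [[Rcpp::export(name = ".runMwgChain")]]
List runMwgChain(NumericVector Y, NumericVector n,
                 IntegerVector mIdx, IntegerVector pIdx,
                 int nM, int nP,
                 NumericVector mAge, NumericVector pAge,
                 double alphaInit,
                 NumericVector mInit, NumericVector pInit,
                 double sdMInit, double sdPInit,
                 double sdLoM, double sdHiM,
                 double sdLoP, double sdHiP,
                 int burnIn, int iterations, int thin,
                 bool adapt, double targetAcc) {
  const int nCells = Y.size();
  const bool hasM = nM > 0, hasP = nP > 0;
  const bool fixedSdM = hasM && (sdHiM - sdLoM) < 1e-12;
  const bool fixedSdP = hasP && (sdHiP - sdLoP) < 1e-12;

  std::vector<std::vector<int>> cellsM(hasM ? nM : 0), cellsP(hasP ? nP : 0);
  for (int c = 0; c < nCells; ++c) {
    if (hasM) cellsM[mIdx[c]].push_back(c);
    if (hasP) cellsP[pIdx[c]].push_back(c);
  }

  double alpha = alphaInit;
  std::vector<double> m(hasM ? nM : 0), p(hasP ? nP : 0);
  for (int i = 0; i < nM; ++i) m[i] = mInit[i];
  for (int j = 0; j < nP; ++j) p[j] = pInit[j];
  double sdM = sdMInit, sdP = sdPInit;

  std::vector<double> eta(nCells), ll(nCells);
  for (int c = 0; c < nCells; ++c) {
    eta[c] = alpha + (hasM ? m[mIdx[c]] : 0.0) + (hasP ? p[pIdx[c]] : 0.0);
    ll[c] = cellLoglik(Y[c], n[c], eta[c]);
  }

  // directional exchange moves (joint models only): centered linear and
  // quadratic age functions, aligned across axes in age units so that the
  // proposal's eta change depends only on each cell's parental age-gap
  // deviation -- the weakly identified direction
  const bool hasEx = hasM && hasP;
  const int nEx = 2;
  std::vector<std::vector<double>> phiM(nEx), phiP(nEx);
  if (hasEx) {
    double wM = 0.0, muM = 0.0, wP = 0.0, muP = 0.0;
    for (int c = 0; c < nCells; ++c) {
      wM += n[c]; muM += n[c] * mAge[mIdx[c]];
      wP += n[c]; muP += n[c] * pAge[pIdx[c]];
    }
    muM = wM > 0 ? muM / wM : 0.0;
    muP = wP > 0 ? muP / wP : 0.0;
    const double scale = 10.0;
    for (int k = 0; k < nEx; ++k) {
      phiM[k].resize(nM);
      phiP[k].resize(nP);
    }
    for (int i = 0; i < nM; ++i) {
      double x = (mAge[i] - muM) / scale;
      phiM[0][i] = x;
      phiM[1][i] = x * x;
    }
    for (int j = 0; j < nP; ++j) {
      double x = (pAge[j] - muP) / scale;
      phiP[0][j] = x;
      phiP[1][j] = x * x;
    }
  }

  // proposal scales, adapted in batches of 50 during burn-in only
  double sAlpha = 0.1, sSdM = 0.5, sSdP = 0.5;
  std::vector<double> sM(hasM ? nM : 0, 0.1), sP(hasP ? nP : 0, 0.1);
  std::vector<double> sEx(nEx, 0.1);
  const int batch = 50;
  int batchCount = 0;
  double accAlphaB = 0.0, accSdMB = 0.0, accSdPB = 0.0;
  std::vector<double> accMB(hasM ? nM : 0, 0.0), accPB(hasP ? nP : 0, 0.0);
  std::vector<double> accExB(nEx, 0.0);

  // post-burn-in acceptance bookkeeping
  double accAlpha = 0.0, accSdM = 0.0, accSdP = 0.0;
  double accM = 0.0, accP = 0.0, accEx = 0.0;
  long attAlpha = 0, attSdM = 0, attSdP = 0, attM = 0, attP = 0, attEx = 0;

  const int nStore = iterations / thin;
  const int nPar = 1 + nM + nP + (hasM ? 1 : 0) + (hasP ? 1 : 0);
  NumericMatrix draws(nStore, nPar);
  int stored = 0;

  const int total = burnIn + iterations;
  for (int iter = 0; iter < total; ++iter) {
    const bool inBurn = iter < burnIn;

    // intercept: full-conditional Metropolis over all cells
    {
      double prop = alpha + R::norm_rand() * sAlpha;
      double dll = 0.0;
      for (int c = 0; c < nCells; ++c) {
        dll += cellLoglik(Y[c], n[c], eta[c] + (prop - alpha)) - ll[c];
      }
      bool acc = std::log(R::unif_rand()) < dll;
      if (acc) {
        double shift = prop - alpha;
        alpha = prop;
        for (int c = 0; c < nCells; ++c) {
          eta[c] += shift;
          ll[c] = cellLoglik(Y[c], n[c], eta[c]);
        }
      }
      if (inBurn) accAlphaB += acc;
      else { accAlpha += acc; ++attAlpha; }
    }

    // per-age effects, one axis at a time
    for (int axis = 0; axis < 2; ++axis) {
      bool isM = axis == 0;
      if (isM && !hasM) continue;
      if (!isM && !hasP) continue;
      std::vector<double>& e = isM ? m : p;
      std::vector<double>& se = isM ? sM : sP;
      std::vector<double>& accB = isM ? accMB : accPB;
      std::vector<std::vector<int>>& cells = isM ? cellsM : cellsP;
      double sdv = isM ? sdM : sdP;
      int K = isM ? nM : nP;
      double inv2s2 = 1.0 / (2.0 * sdv * sdv);
      for (int i = 0; i < K; ++i) {
        double prop = e[i] + R::norm_rand() * se[i];
        double dlp = 0.0;
        if (i > 0) {
          double d0 = e[i] - e[i - 1], d1 = prop - e[i - 1];
          dlp -= (d1 * d1 - d0 * d0) * inv2s2;
        }
        if (i < K - 1) {
          double d0 = e[i + 1] - e[i], d1 = e[i + 1] - prop;
          dlp -= (d1 * d1 - d0 * d0) * inv2s2;
        }
        double dll = 0.0, shift = prop - e[i];
        for (int c : cells[i]) {
          dll += cellLoglik(Y[c], n[c], eta[c] + shift) - ll[c];
        }
        bool acc = std::log(R::unif_rand()) < dll + dlp;
        if (acc) {
          e[i] = prop;
          for (int c : cells[i]) {
            eta[c] += shift;
            ll[c] = cellLoglik(Y[c], n[c], eta[c]);
          }
        }
        if (inBurn) accB[i] += acc;
        else if (isM) { accM += acc; ++attM; }
        else { accP += acc; ++attP; }
      }
    }

    // directional exchange moves: m += c*phiM_k, p -= c*phiP_k
    if (hasEx) {
      for (int k = 0; k < nEx; ++k) {
        double c0 = R::norm_rand() * sEx[k];
        double dll = 0.0;
        for (int c = 0; c < nCells; ++c) {
          double de = c0 * (phiM[k][mIdx[c]] - phiP[k][pIdx[c]]);
          dll += cellLoglik(Y[c], n[c], eta[c] + de) - ll[c];
        }
        // RW1 prior change on both axes
        double dlp = 0.0;
        {
          double inv2s2 = 1.0 / (2.0 * sdM * sdM);
          for (int i = 1; i < nM; ++i) {
            double d0 = m[i] - m[i - 1];
            double d1 = d0 + c0 * (phiM[k][i] - phiM[k][i - 1]);
            dlp -= (d1 * d1 - d0 * d0) * inv2s2;
          }
        }
        {
          double inv2s2 = 1.0 / (2.0 * sdP * sdP);
          for (int j = 1; j < nP; ++j) {
            double d0 = p[j] - p[j - 1];
            double d1 = d0 - c0 * (phiP[k][j] - phiP[k][j - 1]);
            dlp -= (d1 * d1 - d0 * d0) * inv2s2;
          }
        }
        bool acc = std::log(R::unif_rand()) < dll + dlp;
        if (acc) {
          for (int i = 0; i < nM; ++i) m[i] += c0 * phiM[k][i];
          for (int j = 0; j < nP; ++j) p[j] -= c0 * phiP[k][j];
          for (int c = 0; c < nCells; ++c) {
            eta[c] += c0 * (phiM[k][mIdx[c]] - phiP[k][pIdx[c]]);
            ll[c] = cellLoglik(Y[c], n[c], eta[c]);
          }
        }
        if (inBurn) accExB[k] += acc;
        else { accEx += acc; ++attEx; }
      }
    }

    // random-walk SDs: log-scale Metropolis with hard rejection at the
    // uniform prior bounds; Jacobian term for the log transform
    for (int axis = 0; axis < 2; ++axis) {
      bool isM = axis == 0;
      if (isM && (!hasM || fixedSdM)) continue;
      if (!isM && (!hasP || fixedSdP)) continue;
      double& sdv = isM ? sdM : sdP;
      double& ss = isM ? sSdM : sSdP;
      double lo = isM ? sdLoM : sdLoP, hi = isM ? sdHiM : sdHiP;
      int K = isM ? nM : nP;
      double ssdVal = ssd(isM ? m : p);
      double lsd = std::log(sdv);
      double lsdProp = lsd + R::norm_rand() * ss;
      double sdProp = std::exp(lsdProp);
      bool acc = false;
      if (sdProp > lo && sdProp < hi) {
        double lr = rwLogPriorKernel(ssdVal, sdProp, K) -
                    rwLogPriorKernel(ssdVal, sdv, K) + (lsdProp - lsd);
        acc = std::log(R::unif_rand()) < lr;
        if (acc) sdv = sdProp;
      }
      if (inBurn) { if (isM) accSdMB += acc; else accSdPB += acc; }
      else if (isM) { accSdM += acc; ++attSdM; }
      else { accSdP += acc; ++attSdP; }
    }

    // recentre each axis to sum to zero, absorbing the mean into alpha;
    // leaves every eta (hence the likelihood) unchanged
    if (hasM) {
      double mu = 0.0;
      for (double v : m) mu += v;
      mu /= nM;
      for (double& v : m) v -= mu;
      alpha += mu;
    }
    if (hasP) {
      double mu = 0.0;
      for (double v : p) mu += v;
      mu /= nP;
      for (double& v : p) v -= mu;
      alpha += mu;
    }

    // batch adaptation (burn-in only)
    if (inBurn && adapt && (iter + 1) % batch == 0) {
      ++batchCount;
      double delta = std::min(0.05, 1.0 / std::sqrt((double)batchCount));
      sAlpha *= std::exp(accAlphaB / batch > targetAcc ? delta : -delta);
      accAlphaB = 0.0;
      for (int i = 0; i < nM; ++i) {
        sM[i] *= std::exp(accMB[i] / batch > targetAcc ? delta : -delta);
        accMB[i] = 0.0;
      }
      for (int j = 0; j < nP; ++j) {
        sP[j] *= std::exp(accPB[j] / batch > targetAcc ? delta : -delta);
        accPB[j] = 0.0;
      }
      if (hasM && !fixedSdM) {
        sSdM *= std::exp(accSdMB / batch > targetAcc ? delta : -delta);
        accSdMB = 0.0;
      }
      if (hasP && !fixedSdP) {
        sSdP *= std::exp(accSdPB / batch > targetAcc ? delta : -delta);
        accSdPB = 0.0;
      }
      if (hasEx) {
        for (int k = 0; k < nEx; ++k) {
          sEx[k] *= std::exp(accExB[k] / batch > targetAcc ? delta : -delta);
          accExB[k] = 0.0;
        }
      }
    }

    // thinned storage after burn-in
    if (!inBurn && (iter - burnIn + 1) % thin == 0) {
      int col = 0;
      draws(stored, col++) = alpha;
      for (int i = 0; i < nM; ++i) draws(stored, col++) = m[i];
      for (int j = 0; j < nP; ++j) draws(stored, col++) = p[j];
      if (hasM) draws(stored, col++) = sdM;
      if (hasP) draws(stored, col++) = sdP;
      ++stored;
    }
  }

  NumericVector accRates = NumericVector::create(
    Named("alpha") = attAlpha ? accAlpha / attAlpha : NA_REAL,
    Named("maternal") = attM ? accM / attM : NA_REAL,
    Named("paternal") = attP ? accP / attP : NA_REAL,
    Named("sd_maternal") = attSdM ? accSdM / attSdM : NA_REAL,
    Named("sd_paternal") = attSdP ? accSdP / attSdP : NA_REAL,
    Named("exchange") = attEx ? accEx / attEx : NA_REAL);

  return List::create(Named("draws") = draws,
                      Named("acceptance") = accRates);
}
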