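// Two-stage BM3D collaborative filter.
//
// Stage 1 (hard): group blocks similar to each reference block, apply a 2D
// orthonormal DCT per block and a 1D orthonormal Haar transform along the
// group axis, zero coefficients below lambda3d * sigma, invert, and
// aggregate with per-group weights 1 / (sigma^2 * N_retained).
// Stage 2 (wiener): re-match on the stage-1 estimate, shrink the noisy
// group's 3D coefficients by the empirical Wiener factor built from the
// pilot's coefficient energies, aggregate with weights
// 1 / (sigma^2 * sum(w^2)).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat dct_matrix(int n) {
  arma::mat D(n, n);
  for (int i = 0; i < n; ++i) {
    double c = (i == 0) ? std::sqrt(1.0 / n) : std::sqrt(2.0 / n);
    for (int j = 0; j < n; ++j) {
      D(i, j) = c * std::cos(M_PI * (2.0 * j + 1.0) * i / (2.0 * n));
    }
  }
  return D;
}

// in-place orthonormal Haar transform along a vector of length 2^m
static void haar_fwd(arma::vec& x) {
  int len = x.n_elem;
  arma::vec tmp(len);
  const double s = std::sqrt(0.5);
  while (len > 1) {
    int half = len / 2;
    for (int i = 0; i < half; ++i) {
      tmp[i] = s * (x[2 * i] + x[2 * i + 1]);
      tmp[half + i] = s * (x[2 * i] - x[2 * i + 1]);
    }
    for (int i = 0; i < len; ++i) x[i] = tmp[i];
    len = half;
  }
}

static void haar_inv(arma::vec& x) {
  int n = x.n_elem;
  if (n <= 1) return;
  arma::vec tmp(n);
  const double s = std::sqrt(0.5);
  int len = 2;
  while (len <= n) {
    int half = len / 2;
    for (int i = 0; i < half; ++i) {
      tmp[2 * i] = s * (x[i] + x[half + i]);
      tmp[2 * i + 1] = s * (x[i] - x[half + i]);
    }
    for (int i = 0; i < len; ++i) x[i] = tmp[i];
    len *= 2;
  }
}

struct Cand {
  double d;
  int r, c;
};

// candidates within the search window ranked by squared-difference distance
// (mean per pixel); reference first, ties broken by raster order.
static std::vector<Cand> match_group(const arma::mat& img, int ref_r,
                                     int ref_c, int block, int window,
                                     int max_group, double thresh) {
  const int H = img.n_rows, W = img.n_cols;
  const int halo = (window - block) / 2;
  const int r0 = std::max(0, ref_r - halo), r1 = std::min(H - block, ref_r + halo);
  const int c0 = std::max(0, ref_c - halo), c1 = std::min(W - block, ref_c + halo);
  std::vector<Cand> cands;
  cands.reserve((r1 - r0 + 1) * (c1 - c0 + 1));
  const double npix = block * block;
  for (int r = r0; r <= r1; ++r) {
    for (int c = c0; c <= c1; ++c) {
      if (r == ref_r && c == ref_c) continue;
      double d = 0.0;
      for (int j = 0; j < block; ++j) {
        const double* a = img.colptr(ref_c + j) + ref_r;
        const double* b = img.colptr(c + j) + r;
        for (int i = 0; i < block; ++i) {
          double diff = a[i] - b[i];
          d += diff * diff;
        }
      }
      d /= npix;
      if (d <= thresh) cands.push_back({d, r, c});
    }
  }
  // raster order = row-major scan: key r * W + c
  std::stable_sort(cands.begin(), cands.end(), [W](const Cand& a, const Cand& b) {
    if (a.d != b.d) return a.d < b.d;
    return (a.r * (long)W + a.c) < (b.r * (long)W + b.c);
  });
  std::vector<Cand> out;
  out.push_back({0.0, ref_r, ref_c});
  for (size_t i = 0; i < cands.size() && (int)out.size() < max_group; ++i) {
    out.push_back(cands[i]);
  }
  return out;
}

// [[Rcpp::export(name = ".bm3d_block_match_cpp")]]
List bm3d_block_match_cpp(const arma::mat& img, int ref_r, int ref_c,
                          int block, int window, int max_group,
                          double thresh) {
  std::vector<Cand> g = match_group(img, ref_r, ref_c, block, window,
                                    max_group, thresh);
  int n = g.size();
  IntegerMatrix coords(n, 2);
  NumericVector dist(n);
  arma::cube stack(block, block, n);
  for (int i = 0; i < n; ++i) {
    coords(i, 0) = g[i].r + 1;  // 1-based for R
    coords(i, 1) = g[i].c + 1;
    dist[i] = g[i].d;
    stack.slice(i) = img.submat(g[i].r, g[i].c, g[i].r + block - 1,
                                g[i].c + block - 1);
  }
  return List::create(_["coords"] = coords, _["distance"] = dist,
                      _["stack"] = stack, _["reference_index"] = 1);
}

static int pow2_floor(int n) {
  int p = 1;
  while (p * 2 <= n) p *= 2;
  return p;
}

// [[Rcpp::export(name = ".bm3d_stage_cpp")]]
arma::mat bm3d_stage_cpp(const arma::mat& noisy, const arma::mat& match_img,
                         bool wiener, const arma::mat& pilot, int block,
                         int window, int max_group, double thresh,
                         double lambda3d, double sigma, int step) {
  const int H = noisy.n_rows, W = noisy.n_cols;
  arma::mat D = dct_matrix(block);
  arma::mat Dt = D.t();
  arma::mat num(H, W, arma::fill::zeros), den(H, W, arma::fill::zeros);

  std::vector<int> refs_r, refs_c;
  for (int r = 0; r <= H - block; r += step) refs_r.push_back(r);
  if (refs_r.back() != H - block) refs_r.push_back(H - block);
  for (int c = 0; c <= W - block; c += step) refs_c.push_back(c);
  if (refs_c.back() != W - block) refs_c.push_back(W - block);

  const double thr = lambda3d * sigma;
  const int nf = block * block;

  for (int ri : refs_r) {
    for (int ci : refs_c) {
      std::vector<Cand> g = match_group(match_img, ri, ci, block, window,
                                        max_group, thresh);
      int n = pow2_floor((int)g.size());
      // 3D spectra: per-block 2D DCT, then Haar along the group axis
      arma::mat spec(nf, n), pspec;
      for (int i = 0; i < n; ++i) {
        arma::mat B = noisy.submat(g[i].r, g[i].c, g[i].r + block - 1,
                                   g[i].c + block - 1);
        spec.col(i) = arma::vectorise(D * B * Dt);
      }
      if (wiener) {
        pspec.set_size(nf, n);
        for (int i = 0; i < n; ++i) {
          arma::mat B = pilot.submat(g[i].r, g[i].c, g[i].r + block - 1,
                                     g[i].c + block - 1);
          pspec.col(i) = arma::vectorise(D * B * Dt);
        }
      }
      double weight;
      if (n > 1) {
        for (int f = 0; f < nf; ++f) {
          arma::vec row = spec.row(f).t();
          haar_fwd(row);
          spec.row(f) = row.t();
        }
        if (wiener) {
          for (int f = 0; f < nf; ++f) {
            arma::vec row = pspec.row(f).t();
            haar_fwd(row);
            pspec.row(f) = row.t();
          }
        }
      }
      if (!wiener) {
        int nret = 0;
        for (int f = 0; f < nf; ++f) {
          for (int i = 0; i < n; ++i) {
            if (std::abs(spec(f, i)) < thr) spec(f, i) = 0.0;
            else ++nret;
          }
        }
        weight = (sigma > 0) ? 1.0 / (sigma * sigma * std::max(nret, 1)) : 1.0;
      } else {
        double wsum = 0.0;
        for (int f = 0; f < nf; ++f) {
          for (int i = 0; i < n; ++i) {
            double p2 = pspec(f, i) * pspec(f, i);
            double denom = p2 + sigma * sigma;
            double w = (denom > 0) ? p2 / denom : 1.0;  // sigma 0: identity
            spec(f, i) *= w;
            wsum += w * w;
          }
        }
        weight = (sigma > 0 && wsum > 0) ? 1.0 / (sigma * sigma * wsum) : 1.0;
      }
      if (n > 1) {
        for (int f = 0; f < nf; ++f) {
          arma::vec row = spec.row(f).t();
          haar_inv(row);
          spec.row(f) = row.t();
        }
      }
      for (int i = 0; i < n; ++i) {
        arma::mat B = Dt * arma::reshape(spec.col(i), block, block) * D;
        num.submat(g[i].r, g[i].c, g[i].r + block - 1, g[i].c + block - 1) +=
          weight * B;
        den.submat(g[i].r, g[i].c, g[i].r + block - 1, g[i].c + block - 1) +=
          weight;
      }
    }
  }
  return num / den;
}
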