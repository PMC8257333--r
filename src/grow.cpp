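#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Seeded region growing over an 8-connected lattice with online (Welford)
// region statistics. Regions are grown sequentially in seed order; pixels
// accepted by an earlier region are never reassigned (first-claim), but a
// pixel rejected by one region may still be tested by a later one.
//
// Similarity criteria against the CURRENT region statistics (strict
// inequalities):
//   sd:   mu - x_sd * sigma_eff < I < mu + x_sd * sigma_eff
//   mean: mu - x_mean          < I < mu + x_mean
// sigma_eff = max(sigma, sigma_floor) while n < floor_until, else sigma.
// Degenerate window (sigma_eff == 0) accepts exactly I == mu, the limit of
// the strict window as sigma -> 0 on a constant region.
//
// mode: 0 = sd only, 1 = mean only, 2 = both (conjunction).

static inline bool sd_ok(double mu, double sigma_eff, double x_sd, double I) {
  if (sigma_eff == 0.0) return I == mu;
  return (mu - x_sd * sigma_eff < I) && (I < mu + x_sd * sigma_eff);
}

static inline bool mean_ok(double mu, double x_mean, double I) {
  return (mu - x_mean < I) && (I < mu + x_mean);
}

// [[Rcpp::export]]
List grow_all_cpp(NumericMatrix img, IntegerMatrix seeds, double x_sd,
                  double x_mean, int mode, double max_region_fraction,
                  double sigma_floor, int floor_until) {
  const int H = img.nrow(), W = img.ncol();
  const int n_seeds = seeds.nrow();
  const R_xlen_t npix = (R_xlen_t)H * W;
  R_xlen_t cap = (R_xlen_t)std::floor(max_region_fraction * (double)npix + 1e-9);
  if (cap < 1) cap = 1;

  IntegerMatrix labels(H, W);              // 0 = background, r = region id
  std::vector<int> tested(npix, 0);        // last region id that tested pixel
  NumericVector out_n(n_seeds), out_mu(n_seeds), out_m2(n_seeds);
  LogicalVector skipped(n_seeds);

  // neighbour order: N, NE, E, SE, S, SW, W, NW
  const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};

  for (int s = 0; s < n_seeds; ++s) {
    const int sr = seeds(s, 0) - 1, sc = seeds(s, 1) - 1; // to 0-based
    if (sr < 0 || sr >= H || sc < 0 || sc >= W)
      stop("seed %d out of bounds", s + 1);
    const int region = s + 1;
    if (labels(sr, sc) != 0) { // seed falls inside an existing region
      skipped[s] = true;
      out_n[s] = 0.0;
      continue;
    }
    // Welford accumulators, seeded with the seed pixel itself.
    double n = 1.0, mu = img(sr, sc), m2 = 0.0;
    labels(sr, sc) = region;
    std::queue<R_xlen_t> frontier;
    frontier.push((R_xlen_t)sc * H + sr);
    bool capped = ((R_xlen_t)n >= cap);

    while (!frontier.empty() && !capped) {
      R_xlen_t idx = frontier.front();
      frontier.pop();
      const int r = (int)(idx % H), c = (int)(idx / H);
      for (int k = 0; k < 8; ++k) {
        const int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        if (labels(rr, cc) != 0) continue;
        const R_xlen_t nidx = (R_xlen_t)cc * H + rr;
        if (tested[nidx] == region) continue; // already rejected by us
        tested[nidx] = region;
        const double I = img(rr, cc);
        const double sigma = n > 1.0 ? std::sqrt(m2 / (n - 1.0)) : 0.0;
        const double sigma_eff =
            (n < (double)floor_until && sigma < sigma_floor) ? sigma_floor
                                                             : sigma;
        bool ok;
        if (mode == 0) {
          ok = sd_ok(mu, sigma_eff, x_sd, I);
        } else if (mode == 1) {
          ok = mean_ok(mu, x_mean, I);
        } else {
          ok = sd_ok(mu, sigma_eff, x_sd, I) && mean_ok(mu, x_mean, I);
        }
        if (!ok) continue;
        // accept: online stats update, then push
        n += 1.0;
        const double delta = I - mu;
        mu += delta / n;
        m2 += delta * (I - mu);
        labels(rr, cc) = region;
        frontier.push(nidx);
        if ((R_xlen_t)n >= cap) { capped = true; break; }
      }
    }
    out_n[s] = n;
    out_mu[s] = mu;
    out_m2[s] = m2;
  }

  return List::create(_["labels"] = labels, _["n"] = out_n, _["mu"] = out_mu,
                      _["m2"] = out_m2, _["skipped"] = skipped);
}
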