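// Rigid-body docking hot loop: AIR + soft-sphere clash energy and the
// deterministic coordinate-wise pose minimizer. Mirrors the R-level
// semantics in docking.R; the R wrappers own all bookkeeping.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Air {
  std::vector<int> ia;  // 0-based mobile rows
  std::vector<int> ib;  // 0-based receptor rows
  double target;
  double upperPad;
  double k;
};

// Energy of a posed mobile chain against the receptor: flat-bottom
// upper-bound AIR terms on the r^-6 effective distance plus soft-sphere
// clash sum over all cross pairs.
double dockEnergyImpl(const std::vector<double>& mob, int nm,
                      const NumericMatrix& rec,
                      const std::vector<Air>& airs, double sigma) {
  const int nr = rec.nrow();
  double e = 0.0;
  // clash over all pairs + cache squared distances
  std::vector<double> d2(static_cast<size_t>(nm) * nr);
  for (int i = 0; i < nm; ++i) {
    const double xi = mob[i], yi = mob[i + nm], zi = mob[i + 2 * nm];
    for (int j = 0; j < nr; ++j) {
      const double dx = xi - rec(j, 0), dy = yi - rec(j, 1),
                   dz = zi - rec(j, 2);
      const double dd = dx * dx + dy * dy + dz * dz;
      d2[static_cast<size_t>(i) * nr + j] = dd;
      if (dd < sigma * sigma) {
        const double v = sigma - std::sqrt(dd);
        e += v * v;
      }
    }
  }
  for (const Air& a : airs) {
    double s = 0.0;
    bool zero = false;
    for (int i : a.ia) {
      for (int j : a.ib) {
        const double dd = d2[static_cast<size_t>(i) * nr + j];
        if (dd <= 0.0) { zero = true; break; }
        s += 1.0 / (dd * dd * dd);
      }
      if (zero) break;
    }
    const double deff = zero ? 0.0 : std::pow(s, -1.0 / 6.0);
    const double v = deff - a.target - a.upperPad;
    if (v > 0) e += a.k * v * v;
  }
  return e;
}

std::vector<Air> buildAirs(const List& airList) {
  std::vector<Air> airs;
  for (int r = 0; r < airList.size(); ++r) {
    List one = airList[r];
    IntegerVector ia = one["ia"], ib = one["ib"];
    Air a;
    for (int v : ia) a.ia.push_back(v - 1);
    for (int v : ib) a.ib.push_back(v - 1);
    a.target = as<double>(one["target"]);
    a.upperPad = as<double>(one["upperPad"]);
    a.k = as<double>(one["k"]);
    airs.push_back(a);
  }
  return airs;
}

// pose the centred reference: out = ref * R^T + t (row vectors)
void applyPose(const NumericMatrix& ref, const double* R, const double* t,
               std::vector<double>& out) {
  const int n = ref.nrow();
  for (int i = 0; i < n; ++i) {
    const double x = ref(i, 0), y = ref(i, 1), z = ref(i, 2);
    out[i] = R[0] * x + R[1] * y + R[2] * z + t[0];
    out[i + n] = R[3] * x + R[4] * y + R[5] * z + t[1];
    out[i + 2 * n] = R[6] * x + R[7] * y + R[8] * z + t[2];
  }
}

// 3x3 multiply: C = A * B (row-major 9-vectors)
void mat3mul(const double* A, const double* B, double* C) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      C[3 * i + j] = A[3 * i] * B[j] + A[3 * i + 1] * B[3 + j] +
                     A[3 * i + 2] * B[6 + j];
}

// axis-angle rotation about coordinate axis k (0=x,1=y,2=z), row-major
void axisRot(int k, double ang, double* R) {
  const double c = std::cos(ang), s = std::sin(ang);
  for (int i = 0; i < 9; ++i) R[i] = 0.0;
  if (k == 0) {
    R[0] = 1; R[4] = c; R[5] = -s; R[7] = s; R[8] = c;
  } else if (k == 1) {
    R[0] = c; R[2] = s; R[4] = 1; R[6] = -s; R[8] = c;
  } else {
    R[0] = c; R[1] = -s; R[3] = s; R[4] = c; R[8] = 1;
  }
}

}  // namespace

// [[Rcpp::export(name = ".dockEnergyCpp")]]
double dockEnergyCpp(NumericMatrix mobile, NumericMatrix receptor,
                     List airList, double sigma) {
  std::vector<Air> airs = buildAirs(airList);
  const int nm = mobile.nrow();
  std::vector<double> mob(static_cast<size_t>(nm) * 3);
  for (int i = 0; i < nm; ++i) {
    mob[i] = mobile(i, 0);
    mob[i + nm] = mobile(i, 1);
    mob[i + 2 * nm] = mobile(i, 2);
  }
  return dockEnergyImpl(mob, nm, receptor, airs, sigma);
}

// Deterministic coordinate-wise rigid-body minimization; see
// minimizePose() in docking.R for the contract.
// [[Rcpp::export(name = ".minimizePoseCpp")]]
List minimizePoseCpp(NumericMatrix ref, NumericMatrix receptor,
                     List airList, NumericMatrix R0, NumericVector t0,
                     double stepRot, double stepTrans, int maxSweeps,
                     double sigma) {
  std::vector<Air> airs = buildAirs(airList);
  const int nm = ref.nrow();
  double R[9], Rc[9], Rp[9];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) R[3 * i + j] = R0(i, j);
  double t[3] = { t0[0], t0[1], t0[2] };
  std::vector<double> mob(static_cast<size_t>(nm) * 3);
  applyPose(ref, R, t, mob);
  double e = dockEnergyImpl(mob, nm, receptor, airs, sigma);
  for (int sweep = 0; sweep < maxSweeps; ++sweep) {
    bool improved = false;
    for (int ax = 0; ax < 3; ++ax) {
      for (int sgn = 1; sgn >= -1; sgn -= 2) {
        axisRot(ax, sgn * stepRot, Rc);
        mat3mul(Rc, R, Rp);
        applyPose(ref, Rp, t, mob);
        const double ec = dockEnergyImpl(mob, nm, receptor, airs, sigma);
        if (ec < e - 1e-12) {
          for (int i = 0; i < 9; ++i) R[i] = Rp[i];
          e = ec;
          improved = true;
          break;
        }
      }
    }
    for (int ax = 0; ax < 3; ++ax) {
      for (int sgn = 1; sgn >= -1; sgn -= 2) {
        double tp[3] = { t[0], t[1], t[2] };
        tp[ax] += sgn * stepTrans;
        applyPose(ref, R, tp, mob);
        const double ec = dockEnergyImpl(mob, nm, receptor, airs, sigma);
        if (ec < e - 1e-12) {
          t[ax] = tp[ax];
          e = ec;
          improved = true;
          break;
        }
      }
    }
    if (!improved) {
      stepRot *= 0.7;
      stepTrans *= 0.7;
      if (stepRot < 1e-3 && stepTrans < 1e-3) break;
    }
  }
  NumericMatrix Rout(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) Rout(i, j) = R[3 * i + j];
  return List::create(_["R"] = Rout,
                      _["t"] = NumericVector::create(t[0], t[1], t[2]),
                      _["energy"] = e);
}
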