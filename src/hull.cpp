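// Incremental construction of convex point clouds in up to 5 dimensions.
//
// The cloud is grown from a seed simplex, one point at a time: facets the
// new point lies beyond are removed and replaced by the cone from the point
// to the horizon ridges.  Facets are stored as half-spaces (unit outward
// normal, offset); the hull is their intersection.  Volume is the sum of
// simplices spanned by each facet and a fixed interior reference point.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Facet {
  std::vector<int> verts;   // d vertex indices (0-based)
  arma::rowvec normal;      // unit outward normal
  double offset;            // normal . x <= offset inside
};

// Outward-oriented hyperplane through the d facet vertices; `interior`
// must lie strictly inside the hull.  Returns false when the vertices are
// affinely dependent (no unique normal).
bool make_facet(const arma::mat& pts, const std::vector<int>& verts,
                const arma::rowvec& interior, Facet& out) {
  const int d = pts.n_cols;
  arma::mat E(d - 1, d);
  for (int i = 1; i < d; ++i)
    E.row(i - 1) = pts.row(verts[i]) - pts.row(verts[0]);
  arma::mat N;
  if (d == 1) {
    N = arma::mat(1, 1, arma::fill::ones);
  } else {
    N = arma::null(E);
    if (N.n_cols != 1) return false;
  }
  arma::rowvec n = N.col(0).t();
  double nn = arma::norm(n);
  if (nn <= 0) return false;
  n /= nn;
  double off = arma::dot(n, pts.row(verts[0]));
  if (arma::dot(n, interior) - off > 0) { n = -n; off = -off; }
  out.verts = verts;
  out.normal = n;
  out.offset = off;
  return true;
}

} // namespace

// [[Rcpp::export(name = ".hull_build_cpp")]]
List hull_build_cpp(const arma::mat& pts, double eps) {
  const int n = pts.n_rows, d = pts.n_cols;
  if (n < d + 1) return List::create(Named("ok") = false);

  // --- seed simplex: greedily pick affinely independent points -----------
  std::vector<int> simp;
  simp.push_back(0);
  {
    arma::rowvec v0 = pts.row(0);
    // farthest point from v0
    int best = -1; double bd = eps;
    for (int i = 1; i < n; ++i) {
      double di = arma::norm(pts.row(i) - v0);
      if (di > bd) { bd = di; best = i; }
    }
    if (best < 0) return List::create(Named("ok") = false);
    simp.push_back(best);
    arma::mat B((pts.row(best) - v0).t() / bd); // d x k orthonormal basis
    while ((int)simp.size() < d + 1) {
      int pick = -1; double pd = eps;
      arma::colvec keep;
      for (int i = 0; i < n; ++i) {
        arma::colvec r = (pts.row(i) - v0).t();
        r -= B * (B.t() * r);
        double rn = arma::norm(r);
        if (rn > pd) { pd = rn; pick = i; keep = r / rn; }
      }
      if (pick < 0) return List::create(Named("ok") = false);
      simp.push_back(pick);
      B = arma::join_rows(B, keep);
    }
  }

  arma::rowvec interior(d, arma::fill::zeros);
  for (int i = 0; i <= d; ++i) interior += pts.row(simp[i]);
  interior /= (d + 1);

  std::vector<Facet> facets;
  for (int drop = 0; drop <= d; ++drop) {
    std::vector<int> v;
    for (int i = 0; i <= d; ++i) if (i != drop) v.push_back(simp[i]);
    Facet f;
    if (!make_facet(pts, v, interior, f))
      return List::create(Named("ok") = false);
    facets.push_back(f);
  }

  // --- incremental insertion ---------------------------------------------
  std::vector<bool> in_simplex(n, false);
  for (int i = 0; i <= d; ++i) in_simplex[simp[i]] = true;

  for (int p = 0; p < n; ++p) {
    if (in_simplex[p]) continue;
    arma::rowvec x = pts.row(p);
    std::vector<int> vis;
    for (size_t f = 0; f < facets.size(); ++f)
      if (arma::dot(facets[f].normal, x) - facets[f].offset > eps)
        vis.push_back((int)f);
    if (vis.empty()) continue;

    // horizon ridges: (d-1)-faces belonging to exactly one visible facet
    std::map<std::vector<int>, int> ridge_count;
    for (int fi : vis) {
      const std::vector<int>& fv = facets[fi].verts;
      for (int drop = 0; drop < d; ++drop) {
        std::vector<int> r;
        for (int i = 0; i < d; ++i) if (i != drop) r.push_back(fv[i]);
        std::sort(r.begin(), r.end());
        ridge_count[r]++;
      }
    }
    std::vector<Facet> fresh;
    bool bad = false;
    for (std::map<std::vector<int>, int>::iterator it = ridge_count.begin();
         it != ridge_count.end(); ++it) {
      if (it->second != 1) continue;
      std::vector<int> v = it->first;
      v.push_back(p);
      Facet f;
      if (!make_facet(pts, v, interior, f)) { bad = true; continue; }
      fresh.push_back(f);
    }
    if (fresh.empty() && bad) continue; // point numerically on the boundary
    std::vector<Facet> next;
    next.reserve(facets.size());
    std::vector<bool> isvis(facets.size(), false);
    for (int fi : vis) isvis[fi] = true;
    for (size_t f = 0; f < facets.size(); ++f)
      if (!isvis[f]) next.push_back(facets[f]);
    for (size_t f = 0; f < fresh.size(); ++f) next.push_back(fresh[f]);
    facets.swap(next);
  }

  // --- outputs ------------------------------------------------------------
  const int m = (int)facets.size();
  arma::mat normals(m, d);
  arma::vec offsets(m);
  IntegerMatrix fverts(m, d);
  std::set<int> bset;
  double vol = 0.0;
  double dfact = 1.0;
  for (int i = 2; i <= d; ++i) dfact *= i;
  arma::mat M(d, d);
  for (int f = 0; f < m; ++f) {
    normals.row(f) = facets[f].normal;
    offsets(f) = facets[f].offset;
    for (int i = 0; i < d; ++i) {
      fverts(f, i) = facets[f].verts[i] + 1; // 1-based for R
      bset.insert(facets[f].verts[i]);
      M.row(i) = pts.row(facets[f].verts[i]) - interior;
    }
    vol += std::abs(arma::det(M));
  }
  vol /= dfact;
  IntegerVector bidx(bset.size());
  int j = 0;
  for (std::set<int>::iterator it = bset.begin(); it != bset.end(); ++it)
    bidx[j++] = *it + 1;

  return List::create(
    Named("ok") = true,
    Named("normals") = normals,
    Named("offsets") = offsets,
    Named("facet_verts") = fverts,
    Named("boundary_idx") = bidx,
    Named("volume") = vol);
}

// [[Rcpp::export(name = ".hull_contains_cpp")]]
LogicalVector hull_contains_cpp(const arma::mat& normals,
                                const arma::vec& offsets,
                                const arma::mat& query, double tol) {
  const int m = normals.n_rows, k = query.n_rows;
  LogicalVector out(k);
  for (int i = 0; i < k; ++i) {
    bool inside = true;
    for (int f = 0; f < m; ++f) {
      if (arma::dot(normals.row(f), query.row(i)) - offsets(f) > tol) {
        inside = false;
        break;
      }
    }
    out[i] = inside;
  }
  return out;
}
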