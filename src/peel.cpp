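// Pedigree likelihood engine: sum-product variable elimination over
// genotypes {aa, Aa, AA} of a single biallelic autosomal locus. With the
// (precomputed) min-degree elimination order this is the Elston-Stewart
// peeling recursion, linear in family size for loop-free pedigrees.
//
// Factor tables are iterated with an odometer over the union scope;
// per-factor indices are updated incrementally via strides, so each table
// entry costs one add per participating factor.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Factor {
  std::vector<int> vars;    // sorted ascending, local individual indices
  std::vector<double> tab;  // vars[0] varies fastest; 3 states per variable
};

// Peel one family. rows: 0-based row of each member in the phenotype matrix;
// mother/father: local 0-based parent indices (-1 for founders); order: an
// elimination order covering all members. Returns the log-likelihood.
double peel_one(const IntegerVector& rows, const IntegerVector& mother,
                const IntegerVector& father, const IntegerVector& order,
                const NumericMatrix& pheno, const NumericVector& fprior,
                const NumericVector& trans) {
  const int n = rows.size();
  std::vector<Factor> facs;
  facs.reserve(3 * n);
  std::vector<std::vector<int> > by_var(n);  // active factor ids per variable

  for (int i = 0; i < n; ++i) {
    Factor f;
    f.vars.assign(1, i);
    f.tab.resize(3);
    const int r = rows[i];
    for (int g = 0; g < 3; ++g) f.tab[g] = pheno(r, g);
    if (mother[i] < 0)
      for (int g = 0; g < 3; ++g) f.tab[g] *= fprior[g];
    by_var[i].push_back((int)facs.size());
    facs.push_back(f);
    if (mother[i] >= 0) {
      Factor t;
      t.vars.assign(3, 0);
      t.vars[0] = i; t.vars[1] = mother[i]; t.vars[2] = father[i];
      std::sort(t.vars.begin(), t.vars.end());
      t.tab.assign(27, 0.0);
      int pos[3];  // position of child/mother/father within sorted vars
      for (int k = 0; k < 3; ++k) {
        if (t.vars[k] == i) pos[0] = k;
        if (t.vars[k] == mother[i]) pos[1] = k;
        if (t.vars[k] == father[i]) pos[2] = k;
      }
      const int st[3] = {1, 3, 9};
      for (int c = 0; c < 3; ++c)
        for (int m = 0; m < 3; ++m)
          for (int fa = 0; fa < 3; ++fa)
            t.tab[c * st[pos[0]] + m * st[pos[1]] + fa * st[pos[2]]] =
              trans[c + 3 * m + 9 * fa];
      const int id = (int)facs.size();
      by_var[i].push_back(id);
      by_var[mother[i]].push_back(id);
      by_var[father[i]].push_back(id);
      facs.push_back(t);
    }
  }

  double logscale = 0.0;
  std::vector<int> U, RV, ctr;
  std::vector<double> res;

  for (int k = 0; k < n; ++k) {
    const int v = order[k];
    const std::vector<int> in = by_var[v];  // copy: by_var gets rewritten
    if (in.empty()) continue;
    const int nin = (int)in.size();
    U.clear();
    for (int q = 0; q < nin; ++q) {
      const std::vector<int>& vv = facs[in[q]].vars;
      for (size_t w = 0; w < vv.size(); ++w)
        if (std::find(U.begin(), U.end(), vv[w]) == U.end()) U.push_back(vv[w]);
    }
    std::sort(U.begin(), U.end());
    const int m = (int)U.size();
    RV.clear();
    for (int w = 0; w < m; ++w)
      if (U[w] != v) RV.push_back(U[w]);

    // strides of each in-factor and of the result over the union scope
    std::vector<int> fstride(nin * m, 0);
    for (int q = 0; q < nin; ++q) {
      const std::vector<int>& vv = facs[in[q]].vars;
      for (int t = 0; t < m; ++t) {
        std::vector<int>::const_iterator it =
          std::find(vv.begin(), vv.end(), U[t]);
        if (it != vv.end()) {
          int p = (int)(it - vv.begin());
          int s = 1;
          while (p-- > 0) s *= 3;
          fstride[q * m + t] = s;
        }
      }
    }
    std::vector<int> rstride(m, 0);
    {
      int s = 1;
      for (int t = 0; t < m; ++t) {
        if (U[t] == v) continue;
        rstride[t] = s;
        s *= 3;
      }
    }
    int total = 1;
    for (int t = 0; t < m; ++t) total *= 3;
    res.assign(total / 3, 0.0);

    ctr.assign(m, 0);
    std::vector<int> fidx(nin, 0);
    int ridx = 0;
    for (int it = 0; it < total; ++it) {
      double prod = 1.0;
      for (int q = 0; q < nin; ++q) prod *= facs[in[q]].tab[fidx[q]];
      res[ridx] += prod;
      // odometer increment with incremental index updates
      for (int t = 0; t < m; ++t) {
        if (++ctr[t] < 3) {
          for (int q = 0; q < nin; ++q) fidx[q] += fstride[q * m + t];
          ridx += rstride[t];
          break;
        }
        ctr[t] = 0;
        for (int q = 0; q < nin; ++q) fidx[q] -= 2 * fstride[q * m + t];
        ridx -= 2 * rstride[t];
      }
    }

    double mx = 0.0;
    for (size_t w = 0; w < res.size(); ++w)
      if (res[w] > mx) mx = res[w];
    if (mx <= 0.0) return R_NegInf;  // data have probability zero
    Factor out;
    out.vars = RV;
    out.tab.resize(res.size());
    for (size_t w = 0; w < res.size(); ++w) out.tab[w] = res[w] / mx;
    logscale += std::log(mx);

    // retire consumed factors, register the new one
    const int newid = (int)facs.size();
    for (size_t w = 0; w < RV.size(); ++w) {
      std::vector<int>& lst = by_var[RV[w]];
      std::vector<int> kept;
      kept.reserve(lst.size());
      for (size_t z = 0; z < lst.size(); ++z)
        if (std::find(in.begin(), in.end(), lst[z]) == in.end())
          kept.push_back(lst[z]);
      kept.push_back(newid);
      lst.swap(kept);
    }
    by_var[v].clear();
    facs.push_back(out);
  }
  // leftovers are scalar factors normalized to 1; their logs were accumulated
  return logscale;
}

}  // namespace

//' Peel a list of families (internal engine)
//'
//' @param fams list; each element a list with integer vectors `rows`
//'   (0-based rows into `pheno`), `mother`, `father` (local 0-based, -1 for
//'   founders) and `order` (elimination order, local 0-based).
//' @param pheno numeric matrix, one row per individual (globally indexed),
//'   columns = per-genotype phenotype likelihoods for (aa, Aa, AA).
//' @param fprior founder genotype prior, length 3.
//' @param trans Mendelian transmission array flattened as
//'   `child + 3*mother + 9*father`.
//' @return numeric vector of per-family log-likelihoods.
//' @keywords internal
// [[Rcpp::export]]
NumericVector peel_families_cpp(List fams, NumericMatrix pheno,
                                NumericVector fprior, NumericVector trans) {
  const int nf = fams.size();
  NumericVector out(nf);
  for (int f = 0; f < nf; ++f) {
    List fm = fams[f];
    out[f] = peel_one(fm["rows"], fm["mother"], fm["father"], fm["order"],
                      pheno, fprior, trans);
  }
  return out;
}
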