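#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// log(exp(a) + exp(b)) without overflow
static inline double lse2(double a, double b) {
    if (a == NEG_INF) return b;
    if (b == NEG_INF) return a;
    if (a < b) std::swap(a, b);
    return a + std::log1p(std::exp(b - a));
}

static inline double lse3(double a, double b, double c) {
    return lse2(lse2(a, b), c);
}

// Pair-HMM posterior by forward-backward over a 3-state model
// (M emits a residue pair, X emits a residue of x against a gap,
//  Y emits a residue of y against a gap).  Transitions: M->X = M->Y = delta,
//  X->X = Y->Y = epsilon, X->M = Y->M = 1 - epsilon; X<->Y forbidden.
// Start distribution (1 - 2 delta, delta, delta); flat end weight.
// xi, yi are 1-based residue codes into logMatch / logIns.
// [[Rcpp::export]]
NumericMatrix pairhmm_posterior_cpp(IntegerVector xi, IntegerVector yi,
                                    NumericMatrix logMatch,
                                    NumericVector logIns,
                                    double delta, double epsilon) {
    const int n = xi.size(), m = yi.size();
    const double tMM = std::log(1.0 - 2.0 * delta);
    const double tMX = std::log(delta);
    const double tXX = std::log(epsilon);
    const double tXM = std::log(1.0 - epsilon);
    const double piM = tMM, piX = tMX;  // start distribution mirrors M-row

    // forward: index [i][j], i residues of x and j of y consumed
    const int dim = (n + 1) * (m + 1);
    std::vector<double> fM(dim, NEG_INF), fX(dim, NEG_INF), fY(dim, NEG_INF);
    std::vector<double> bM(dim, NEG_INF), bX(dim, NEG_INF), bY(dim, NEG_INF);
    auto at = [m](int i, int j) { return i * (m + 1) + j; };

    for (int i = 0; i <= n; ++i) {
        for (int j = 0; j <= m; ++j) {
            if (i == 0 && j == 0) continue;
            const int ij = at(i, j);
            if (i >= 1 && j >= 1) {
                double prev;
                if (i == 1 && j == 1) {
                    prev = piM;
                } else {
                    prev = lse3(fM[at(i - 1, j - 1)] + tMM,
                                fX[at(i - 1, j - 1)] + tXM,
                                fY[at(i - 1, j - 1)] + tXM);
                }
                fM[ij] = prev + logMatch(xi[i - 1] - 1, yi[j - 1] - 1);
            }
            if (i >= 1) {
                double prev = (i == 1 && j == 0)
                    ? piX
                    : lse2(fM[at(i - 1, j)] + tMX, fX[at(i - 1, j)] + tXX);
                fX[ij] = prev + logIns[xi[i - 1] - 1];
            }
            if (j >= 1) {
                double prev = (i == 0 && j == 1)
                    ? piX
                    : lse2(fM[at(i, j - 1)] + tMX, fY[at(i, j - 1)] + tXX);
                fY[ij] = prev + logIns[yi[j - 1] - 1];
            }
        }
    }
    const double logZ = lse3(fM[at(n, m)], fX[at(n, m)], fY[at(n, m)]);

    // backward: b*[i][j] = log weight of completing the alignment given the
    // last emitted column ended at (i, j) in the given state
    bM[at(n, m)] = bX[at(n, m)] = bY[at(n, m)] = 0.0;
    for (int i = n; i >= 0; --i) {
        for (int j = m; j >= 0; --j) {
            if (i == n && j == m) continue;
            const int ij = at(i, j);
            double vM = NEG_INF, vX = NEG_INF, vY = NEG_INF;
            if (i < n && j < m) {
                const double em = logMatch(xi[i] - 1, yi[j] - 1) + bM[at(i + 1, j + 1)];
                vM = lse2(vM, tMM + em);
                vX = lse2(vX, tXM + em);
                vY = lse2(vY, tXM + em);
            }
            if (i < n) {
                const double ex = logIns[xi[i] - 1] + bX[at(i + 1, j)];
                vM = lse2(vM, tMX + ex);
                vX = lse2(vX, tXX + ex);
            }
            if (j < m) {
                const double ey = logIns[yi[j] - 1] + bY[at(i, j + 1)];
                vM = lse2(vM, tMX + ey);
                vY = lse2(vY, tXX + ey);
            }
            bM[ij] = vM; bX[ij] = vX; bY[ij] = vY;
        }
    }

    NumericMatrix post(n, m);
    for (int i = 1; i <= n; ++i)
        for (int j = 1; j <= m; ++j)
            post(i - 1, j - 1) = std::exp(fM[at(i, j)] + bM[at(i, j)] - logZ);
    return post;
}

// Affine-gap partition-function posterior.  An alignment is a column
// sequence; its Boltzmann log-weight is beta * (sum of substitution scores
// - gap costs), a gap run of length k costing gapOpen + (k-1)*gapExtend
// (penalties passed as positive costs).  All column orders are distinct
// alignments, so X->Y and Y->X transitions each open a new gap.
// [[Rcpp::export]]
NumericMatrix partition_posterior_cpp(IntegerVector xi, IntegerVector yi,
                                      NumericMatrix score,
                                      double gapOpen, double gapExtend,
                                      double beta) {
    const int n = xi.size(), m = yi.size();
    const double go = -beta * gapOpen;   // log-weight of opening a gap
    const double ge = -beta * gapExtend; // log-weight of extending it
    const int dim = (n + 1) * (m + 1);
    std::vector<double> zM(dim, NEG_INF), zX(dim, NEG_INF), zY(dim, NEG_INF);
    std::vector<double> bM(dim, NEG_INF), bX(dim, NEG_INF), bY(dim, NEG_INF);
    auto at = [m](int i, int j) { return i * (m + 1) + j; };
    auto sc = [&](int i, int j) { return beta * score(xi[i - 1] - 1, yi[j - 1] - 1); };

    for (int i = 0; i <= n; ++i) {
        for (int j = 0; j <= m; ++j) {
            if (i == 0 && j == 0) continue;
            const int ij = at(i, j);
            if (i >= 1 && j >= 1) {
                double prev = (i == 1 && j == 1)
                    ? 0.0
                    : lse3(zM[at(i - 1, j - 1)], zX[at(i - 1, j - 1)],
                           zY[at(i - 1, j - 1)]);
                zM[ij] = prev + sc(i, j);
            }
            if (i >= 1) {
                double open = (i == 1 && j == 0)
                    ? go
                    : lse2(zM[at(i - 1, j)] + go, zY[at(i - 1, j)] + go);
                zX[ij] = lse2(open, zX[at(i - 1, j)] + ge);
            }
            if (j >= 1) {
                double open = (i == 0 && j == 1)
                    ? go
                    : lse2(zM[at(i, j - 1)] + go, zX[at(i, j - 1)] + go);
                zY[ij] = lse2(open, zY[at(i, j - 1)] + ge);
            }
        }
    }
    const double logZ = lse3(zM[at(n, m)], zX[at(n, m)], zY[at(n, m)]);

    bM[at(n, m)] = bX[at(n, m)] = bY[at(n, m)] = 0.0;
    for (int i = n; i >= 0; --i) {
        for (int j = m; j >= 0; --j) {
            if (i == n && j == m) continue;
            const int ij = at(i, j);
            double vM = NEG_INF, vX = NEG_INF, vY = NEG_INF;
            if (i < n && j < m) {
                const double em = sc(i + 1, j + 1) + bM[at(i + 1, j + 1)];
                vM = lse2(vM, em); vX = lse2(vX, em); vY = lse2(vY, em);
            }
            if (i < n) {
                vM = lse2(vM, go + bX[at(i + 1, j)]);
                vX = lse2(vX, ge + bX[at(i + 1, j)]);
                vY = lse2(vY, go + bX[at(i + 1, j)]);
            }
            if (j < m) {
                vM = lse2(vM, go + bY[at(i, j + 1)]);
                vX = lse2(vX, go + bY[at(i, j + 1)]);
                vY = lse2(vY, ge + bY[at(i, j + 1)]);
            }
            bM[ij] = vM; bX[ij] = vX; bY[ij] = vY;
        }
    }

    NumericMatrix post(n, m);
    for (int i = 1; i <= n; ++i)
        for (int j = 1; j <= m; ++j)
            post(i - 1, j - 1) = std::exp(zM[at(i, j)] + bM[at(i, j)] - logZ);
    return post;
}

// Maximum-expected-accuracy DP: maximize the sum of S over matched cells
// along a monotone path; unmatched rows/columns cost nothing.
// Traceback preference on ties: match, then consume a column of S's column
// dimension alone (gap in the row profile), then a row alone.
// ops: 1 = match (consume row+col), 2 = consume row only, 3 = consume col only.
// [[Rcpp::export]]
List mea_dp_cpp(NumericMatrix S) {
    const int n = S.nrow(), m = S.ncol();
    NumericMatrix D(n + 1, m + 1);
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            double best = D(i - 1, j - 1) + S(i - 1, j - 1);
            if (D(i, j - 1) > best) best = D(i, j - 1);
            if (D(i - 1, j) > best) best = D(i - 1, j);
            D(i, j) = best;
        }
    }
    // traceback
    std::vector<int> ops;
    int i = n, j = m;
    while (i > 0 || j > 0) {
        if (i > 0 && j > 0 &&
            D(i, j) == D(i - 1, j - 1) + S(i - 1, j - 1)) {
            ops.push_back(1); --i; --j;
        } else if (j > 0 && D(i, j) == D(i, j - 1)) {
            ops.push_back(3); --j;
        } else {
            ops.push_back(2); --i;
        }
    }
    std::reverse(ops.begin(), ops.end());
    return List::create(_["score"] = D(n, m),
                        _["ops"] = IntegerVector(ops.begin(), ops.end()));
}
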