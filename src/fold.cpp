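#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
using namespace Rcpp;

// Secondary-structure prediction by free-energy minimisation with a
// simplified nearest-neighbour parameter set: Watson-Crick and G:U pairs,
// stacking energies, tabulated hairpin / bulge / interior-loop penalties,
// and exterior-loop bifurcation.  Closed substructures are simple stem-loops
// (no internal multiloops) -- sufficient for pre-miRNA-sized windows, where
// branched structures are rare and never score as candidate hairpins anyway.

static const double INF = 1e9;
static const int MAXLOOP = 30;   // max unpaired bases in one interior loop
static const int MINHAIRPIN = 3; // min hairpin loop size

// base codes: A=0, C=1, G=2, U/T=3, other=-1
static inline int bcode(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'U': case 'u': case 'T': case 't': return 3;
    default: return -1;
    }
}

// pair types: CG=0, GC=1, AU=2, UA=3, GU=4, UG=5, none=-1
static inline int ptype(int a, int b) {
    if (a == 1 && b == 2) return 0;
    if (a == 2 && b == 1) return 1;
    if (a == 0 && b == 3) return 2;
    if (a == 3 && b == 0) return 3;
    if (a == 2 && b == 3) return 4;
    if (a == 3 && b == 2) return 5;
    return -1;
}

// stack[p1][p2]: pair (i,j) of type p1 stacked on inner pair (i+1,j-1) of
// type p2, kcal/mol
static const double STACK[6][6] = {
    /* CG */ {-3.3, -3.4, -2.1, -2.1, -1.4, -2.1},
    /* GC */ {-2.4, -3.3, -2.2, -2.4, -1.5, -2.5},
    /* AU */ {-2.1, -2.2, -0.9, -1.1, -0.6, -1.4},
    /* UA */ {-2.4, -2.1, -1.3, -0.9, -1.0, -1.3},
    /* GU */ {-2.5, -2.1, -1.3, -1.4, -0.5,  1.3},
    /* UG */ {-1.4, -1.5, -0.6, -1.0,  0.3, -0.5}
};

static double hairpinE(int n) {
    static const double tab[] = {INF, INF, INF, 5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4};
    if (n < 3) return INF;
    if (n <= 9) return tab[n];
    return 6.4 + 1.08 * std::log((double)n / 9.0);
}

static double bulgeE(int n) {
    static const double tab[] = {0.0, 3.8, 2.8, 3.2, 3.6, 4.0, 4.4};
    if (n <= 6) return tab[n];
    return 4.4 + 1.08 * std::log((double)n / 6.0);
}

static double interiorE(int n1, int n2) {
    int n = n1 + n2;
    static const double tab[] = {0.0, 0.0, 1.5, 2.0, 2.5, 3.0, 3.3};
    double e = (n <= 6) ? tab[n] : 3.3 + 1.08 * std::log((double)n / 6.0);
    double asym = 0.5 * std::abs(n1 - n2);
    if (asym > 3.0) asym = 3.0;
    return e + asym;
}

// loop energy for closing pair (i,j) with inner pair (k,l)
static inline double loopE(int i, int j, int k, int l, int pi, int pk) {
    int n1 = k - i - 1, n2 = j - l - 1;
    if (n1 == 0 && n2 == 0) return STACK[pi][pk];
    if (n1 == 0 || n2 == 0) return bulgeE(n1 + n2);
    return interiorE(n1, n2);
}

//' @name foldRNA
//' @noRd
// [[Rcpp::export(name = ".fold_rna")]]
List fold_rna(std::string seq) {
    int n = (int)seq.size();
    std::vector<int> b(n);
    for (int i = 0; i < n; ++i) b[i] = bcode(seq[i]);

    if (n < MINHAIRPIN + 2) {
        return List::create(_["structure"] = std::string(n, '.'),
                            _["mfe"] = 0.0);
    }

    // V[i][j]: min energy given (i,j) paired
    std::vector<std::vector<double> > V(n, std::vector<double>(n, INF));
    // inner branch traceback: -1 = hairpin, else k*n+l
    std::vector<std::vector<int> > Vtr(n, std::vector<int>(n, -1));

    for (int len = MINHAIRPIN + 2; len <= n; ++len) {
        for (int i = 0; i + len - 1 < n; ++i) {
            int j = i + len - 1;
            if (b[i] < 0 || b[j] < 0) continue;
            int pi = ptype(b[i], b[j]);
            if (pi < 0) continue;
            double best = hairpinE(j - i - 1);
            int btr = -1;
            int kmax = std::min(i + MAXLOOP + 1, j - 2);
            for (int k = i + 1; k <= kmax; ++k) {
                if (b[k] < 0) continue;
                int lmin = k + MINHAIRPIN + 1;
                int lmin2 = j - 1 - (MAXLOOP - (k - i - 1));
                if (lmin2 > lmin) lmin = lmin2;
                for (int l = j - 1; l >= lmin; --l) {
                    if (V[k][l] >= INF) continue;
                    int pk = ptype(b[k], b[l]);
                    double e = V[k][l] + loopE(i, j, k, l, pi, pk);
                    if (e < best - 1e-12) { best = e; btr = k * n + l; }
                }
            }
            V[i][j] = best;
            Vtr[i][j] = btr;
        }
    }

    // exterior loop: W[j] = min energy over prefix [0..j]
    std::vector<double> W(n + 1, 0.0);
    std::vector<int> Wtr(n + 1, -1); // i such that (i, j-1) closes, else -1
    for (int j = 1; j <= n; ++j) {
        W[j] = W[j - 1];
        Wtr[j] = -1;
        for (int i = 0; i <= j - MINHAIRPIN - 2; ++i) {
            if (V[i][j - 1] >= INF) continue;
            double e = W[i] + V[i][j - 1];
            if (e < W[j] - 1e-12) { W[j] = e; Wtr[j] = i; }
        }
    }

    // traceback
    std::string db(n, '.');
    std::vector<std::pair<int,int> > stack;
    int j = n;
    while (j > 0) {
        if (Wtr[j] < 0) { --j; continue; }
        int i = Wtr[j];
        stack.push_back(std::make_pair(i, j - 1));
        j = i;
    }
    while (!stack.empty()) {
        std::pair<int,int> ij = stack.back(); stack.pop_back();
        int i = ij.first, jj = ij.second;
        db[i] = '('; db[jj] = ')';
        int tr = Vtr[i][jj];
        if (tr >= 0) stack.push_back(std::make_pair(tr / n, tr % n));
    }

    double mfe = W[n];
    if (mfe > 0) mfe = 0.0; // open chain is always available
    return List::create(_["structure"] = db, _["mfe"] = mfe);
}
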