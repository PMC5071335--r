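#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Plant miRNA target-site penalty scoring.  The miRNA (5'->3') is aligned
// against the reverse complement of the mRNA site so that position i of the
// miRNA faces position i of the transformed site.  Per-position penalties:
// mismatch 1.0, G:U wobble 0.5, gap 2.0; penalties at miRNA positions 2-13
// (1-based from the miRNA 5' end) are doubled.  At most one gap (either a
// bulged target base or an unpaired miRNA base) is allowed.

static inline char norm_base(char c) {
    switch (c) {
    case 'a': case 'A': return 'A';
    case 'c': case 'C': return 'C';
    case 'g': case 'G': return 'G';
    case 't': case 'T': case 'u': case 'U': return 'T';
    default: return 'N';
    }
}

// pairing state of miRNA base m against reverse-complemented site base r:
// 0 = Watson-Crick, 1 = G:U wobble, 2 = mismatch
static inline int pair_state(char m, char r) {
    if (m == 'N' || r == 'N') return 2;
    if (m == r) return 0;
    if ((m == 'G' && r == 'A') || (m == 'T' && r == 'C')) return 1;
    return 2;
}

static inline double pos_weight(int pos1b) {
    return (pos1b >= 2 && pos1b <= 13) ? 2.0 : 1.0;
}

struct Aln {
    double S;
    int gap_kind;   // 0 none, 1 gap in target (unpaired miRNA base), 2 bulged target base
    int gap_pos;    // miRNA position (1-based) carrying the gap penalty; 0 if none
    std::vector<int> state; // per miRNA position: 0 WC, 1 GU, 2 mismatch, 3 gap
};

static Aln score_one(const std::string &m, const std::string &rc) {
    int lm = (int)m.size(), lt = (int)rc.size();
    Aln best; best.S = 1e9; best.gap_kind = -1; best.gap_pos = 0;
    if (lt == lm) {
        Aln a; a.gap_kind = 0; a.gap_pos = 0; a.S = 0.0; a.state.resize(lm);
        for (int i = 0; i < lm; ++i) {
            int st = pair_state(m[i], rc[i]);
            a.state[i] = st;
            a.S += (st == 1 ? 0.5 : (st == 2 ? 1.0 : 0.0)) * pos_weight(i + 1);
        }
        if (a.S < best.S) best = a;
    } else if (lt == lm - 1) {
        // one miRNA base g (1-based) left unpaired (gap in target)
        for (int g = 1; g <= lm; ++g) {
            Aln a; a.gap_kind = 1; a.gap_pos = g; a.S = 2.0 * pos_weight(g);
            a.state.resize(lm);
            for (int i = 0; i < lm; ++i) {
                if (i + 1 == g) { a.state[i] = 3; continue; }
                int ti = (i + 1 < g) ? i : i - 1;
                int st = pair_state(m[i], rc[ti]);
                a.state[i] = st;
                a.S += (st == 1 ? 0.5 : (st == 2 ? 1.0 : 0.0)) * pos_weight(i + 1);
            }
            if (a.S < best.S - 1e-12) best = a;
        }
    } else if (lt == lm + 1) {
        // one bulged target base between miRNA positions g-1 and g; the
        // penalty is carried by miRNA position g (1-based), g in 2..lm
        for (int g = 2; g <= lm; ++g) {
            Aln a; a.gap_kind = 2; a.gap_pos = g; a.S = 2.0 * pos_weight(g);
            a.state.resize(lm);
            for (int i = 0; i < lm; ++i) {
                int ti = (i + 1 < g) ? i : i + 1;
                int st = pair_state(m[i], rc[ti]);
                a.state[i] = st;
                a.S += (st == 1 ? 0.5 : (st == 2 ? 1.0 : 0.0)) * pos_weight(i + 1);
            }
            if (a.S < best.S - 1e-12) best = a;
        }
    }
    return best;
}

// [[Rcpp::export(name = ".score_duplex")]]
List score_duplex(std::string mirna, std::string site_rc) {
    std::string m = mirna, rc = site_rc;
    for (size_t i = 0; i < m.size(); ++i) m[i] = norm_base(m[i]);
    for (size_t i = 0; i < rc.size(); ++i) rc[i] = norm_base(rc[i]);
    Aln a = score_one(m, rc);
    if (a.gap_kind < 0)
        return List::create(_["S"] = NA_REAL);
    IntegerVector st(a.state.begin(), a.state.end());
    return List::create(_["S"] = a.S,
                        _["state"] = st,
                        _["gap_kind"] = a.gap_kind,
                        _["gap_pos"] = a.gap_pos);
}

// Scan one transcript (given 5'->3') for candidate sites of one miRNA.
// Returns 0-based starts, window lengths and scores for windows with
// S <= max_s.  rc_tx must be the reverse complement of tx so that the
// window reverse complement can be sliced without repeated reversal.
// [[Rcpp::export(name = ".scan_transcript")]]
DataFrame scan_transcript(std::string mirna, std::string tx, double max_s) {
    std::string m = mirna;
    for (size_t i = 0; i < m.size(); ++i) m[i] = norm_base(m[i]);
    int lm = (int)m.size(), lt = (int)tx.size();
    std::string txn = tx;
    for (int i = 0; i < lt; ++i) txn[i] = norm_base(txn[i]);
    // reverse complement of full transcript
    std::string rc(lt, 'N');
    for (int i = 0; i < lt; ++i) {
        char c = txn[lt - 1 - i];
        rc[i] = (c == 'A') ? 'T' : (c == 'T') ? 'A' : (c == 'C') ? 'G' : (c == 'G') ? 'C' : 'N';
    }
    std::vector<int> starts, lens;
    std::vector<double> scores;
    for (int wl = lm - 1; wl <= lm + 1; ++wl) {
        if (wl < 1) continue;
        for (int s = 0; s + wl <= lt; ++s) {
            // window tx[s, s+wl); its revcomp is rc[lt-s-wl, lt-s)
            std::string wrc = rc.substr(lt - s - wl, wl);
            Aln a = score_one(m, wrc);
            if (a.gap_kind >= 0 && a.S <= max_s + 1e-9) {
                starts.push_back(s);
                lens.push_back(wl);
                scores.push_back(a.S);
            }
        }
    }
    return DataFrame::create(_["start"] = starts, _["width"] = lens,
                             _["S"] = scores);
}
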