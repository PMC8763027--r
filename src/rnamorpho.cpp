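#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static inline bool can_pair(char a, char b) {
    return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
           (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
           (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// Maximum base-pairing fold (Nussinov-style DP) with a minimum hairpin
// length constraint.  Tie-breaking in the traceback is fixed so spectra are
// bit-reproducible: leaving position i unpaired is preferred over pairing,
// and among pairings the smallest partner index is taken.
// [[Rcpp::export]]
CharacterVector fold_maxpair_cpp(CharacterVector seqs, int min_hairpin) {
    int nseq = seqs.size();
    CharacterVector out(nseq);
    for (int s = 0; s < nseq; ++s) {
        std::string seq = as<std::string>(seqs[s]);
        int L = (int) seq.size();
        std::string db(L, '.');
        if (L >= min_hairpin + 2) {
            // M[i][j] = max pairs on closed interval [i, j] (0-based)
            std::vector< std::vector<int> > M(L, std::vector<int>(L, 0));
            for (int len = min_hairpin + 2; len <= L; ++len) {
                for (int i = 0; i + len - 1 < L; ++i) {
                    int j = i + len - 1;
                    int best = M[i + 1][j];          // i unpaired
                    for (int k = i + min_hairpin + 1; k <= j; ++k) {
                        if (!can_pair(seq[i], seq[k])) continue;
                        int v = 1 + M[i + 1][k - 1];
                        if (k + 1 <= j) v += M[k + 1][j];
                        if (v > best) best = v;
                    }
                    M[i][j] = best;
                }
            }
            // traceback (explicit stack of intervals)
            std::vector< std::pair<int, int> > todo;
            todo.push_back(std::make_pair(0, L - 1));
            while (!todo.empty()) {
                int i = todo.back().first, j = todo.back().second;
                todo.pop_back();
                if (j - i < min_hairpin + 1) continue;
                if (M[i][j] == M[i + 1][j]) {       // prefer i unpaired
                    todo.push_back(std::make_pair(i + 1, j));
                    continue;
                }
                for (int k = i + min_hairpin + 1; k <= j; ++k) {
                    if (!can_pair(seq[i], seq[k])) continue;
                    int v = 1 + M[i + 1][k - 1];
                    if (k + 1 <= j) v += M[k + 1][j];
                    if (v == M[i][j]) {             // smallest partner k
                        db[i] = '(';
                        db[k] = ')';
                        todo.push_back(std::make_pair(i + 1, k - 1));
                        if (k + 1 <= j) todo.push_back(std::make_pair(k + 1, j));
                        break;
                    }
                }
            }
        }
        out[s] = db;
    }
    return out;
}

// Level-1 abstract shape of each dot-bracket string: one bracket pair per
// maximal uninterrupted helix, one '_' per maximal unpaired run.  A pair
// (i,j) continues the helix of (i-1,j+1); anything else starts a new one.
// [[Rcpp::export]]
CharacterVector shape_level1_cpp(CharacterVector dbs) {
    int n = dbs.size();
    CharacterVector out(n);
    std::vector<int> pt;
    std::vector<int> stack;
    for (int s = 0; s < n; ++s) {
        std::string db = as<std::string>(dbs[s]);
        int L = (int) db.size();
        pt.assign(L, -1);
        stack.clear();
        for (int i = 0; i < L; ++i) {
            char c = db[i];
            if (c == '(') {
                stack.push_back(i);
            } else if (c == ')') {
                if (stack.empty())
                    stop("unbalanced dot-bracket at position %d", i + 1);
                pt[i] = stack.back();
                pt[stack.back()] = i;
                stack.pop_back();
            } else if (c != '.') {
                stop("invalid dot-bracket character '%c' at position %d", c, i + 1);
            }
        }
        if (!stack.empty())
            stop("unbalanced dot-bracket at position %d", stack.back() + 1);
        std::string shp;
        for (int i = 0; i < L; ++i) {
            if (db[i] == '.') {
                if (i == 0 || db[i - 1] != '.') shp += '_';
            } else if (db[i] == '(') {
                bool cont = (i > 0 && db[i - 1] == '(' && pt[i - 1] == pt[i] + 1);
                if (!cont) shp += '[';
            } else {
                bool cont = (i + 1 < L && db[i + 1] == ')' && pt[i + 1] == pt[i] - 1);
                if (!cont) shp += ']';
            }
        }
        if (shp.empty()) shp = "_";
        out[s] = shp;
    }
    return out;
}
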