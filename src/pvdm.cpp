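// Distributed-memory paragraph-vector training core.
//
// Each sentence i supplies contexts t = 1..T_i - m; the m context word
// vectors and the sentence (document) vector form the predictor h for
// the next token c_{t+m}, under one of two context compositions:
//   concat: h = (w_{c_t}, ..., w_{c_{t+m-1}}, x_i) in R^((m+1)d)
//   mean:   h = (w_{c_t} + ... + w_{c_{t+m-1}} + x_i) / (m+1) in R^d
// The output layer is either a hierarchical softmax over a binary
// Huffman tree (leaf probability = product of branch sigmoids on the
// root path) or the exact softmax y = b + U h.  Parameters are updated
// by SGD with a linearly decaying learning rate; the document vector is
// shared across the contexts of its own sentence only, word vectors
// corpus-wide.  Single-threaded: runs are bit-reproducible for a seed.
// Parameters are held in single precision internally (the word2vec
// convention): SGD noise dwarfs float rounding and the smaller
// footprint halves memory traffic on the output vectors.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const int EXP_TABLE_SIZE = 4000;
static const float MAX_EXP = 8.0f;

struct SigTable {
    float tab[EXP_TABLE_SIZE];
    SigTable() {
        for (int i = 0; i < EXP_TABLE_SIZE; ++i) {
            double z = (2.0 * i / EXP_TABLE_SIZE - 1.0) * MAX_EXP;
            tab[i] = (float)(1.0 / (1.0 + std::exp(-z)));
        }
    }
    inline float operator()(float z) const {
        if (z >= MAX_EXP) return 1.0f - 1e-7f;
        if (z <= -MAX_EXP) return 1e-7f;
        int i = (int)((z + MAX_EXP) * (EXP_TABLE_SIZE / (2.0f * MAX_EXP)));
        return tab[i];
    }
};
static SigTable SIG;

// xorshift64* PRNG: deterministic, independent of R's RNG stream.
struct XRng {
    uint64_t state;
    explicit XRng(uint64_t seed) : state(seed ? seed : 88172645463325252ULL) {}
    inline uint64_t next() {
        uint64_t x = state;
        x ^= x >> 12; x ^= x << 25; x ^= x >> 27;
        state = x;
        return x * 2685821657736338717ULL;
    }
    inline int below(int n) { return (int)(next() % (uint64_t)n); }
};

struct Corpus {
    std::vector<std::vector<int>> sent;  // 0-based word-vector columns
    std::vector<int> doc;                // 0-based doc-vector column
    int unkCol;
};

static Corpus buildCorpus(const List& sentences, const IntegerVector& docIndex,
                          int V) {
    Corpus c;
    c.unkCol = V;  // column V (0-based) of W is the UNK context vector
    int n = sentences.size();
    c.sent.resize(n);
    c.doc.resize(n);
    for (int i = 0; i < n; ++i) {
        IntegerVector s = sentences[i];
        std::vector<int>& v = c.sent[i];
        v.resize(s.size());
        for (int j = 0; j < s.size(); ++j)
            v[j] = (s[j] == 0) ? c.unkCol : s[j] - 1;
        c.doc[i] = docIndex[i] - 1;
    }
    return c;
}

struct Tree {
    std::vector<std::vector<int>> code;  // 0/1 bits per leaf
    std::vector<std::vector<int>> node;  // 0-based internal-node columns
};

static Tree buildTree(const List& codes, const List& paths) {
    Tree t;
    int V = codes.size();
    t.code.resize(V);
    t.node.resize(V);
    for (int i = 0; i < V; ++i) {
        IntegerVector c = codes[i], p = paths[i];
        t.code[i].assign(c.begin(), c.end());
        t.node[i].resize(p.size());
        for (int j = 0; j < p.size(); ++j) t.node[i][j] = p[j] - 1;
    }
    return t;
}

static std::vector<float> toFloat(const NumericMatrix& m) {
    std::vector<float> v((size_t)m.nrow() * m.ncol());
    const double* p = m.begin();
    for (size_t i = 0; i < v.size(); ++i) v[i] = (float)p[i];
    return v;
}

static NumericMatrix toMatrix(const std::vector<float>& v, int nr, int nc) {
    NumericMatrix m(nr, nc);
    double* p = m.begin();
    for (size_t i = 0; i < v.size(); ++i) p[i] = (double)v[i];
    return m;
}

static inline float fdot(const float* a, const float* b, int n) {
    float s = 0.0f;
    for (int i = 0; i < n; ++i) s += a[i] * b[i];
    return s;
}

static inline void faxpy(float g, const float* x, float* y, int n) {
    for (int i = 0; i < n; ++i) y[i] += g * x[i];
}

// Gather the predictor h for the context starting at position t.
static inline void gatherH(const std::vector<int>& sn, int t, int m, int d,
                           bool concat, const std::vector<float>& W,
                           const float* dv, std::vector<float>& h) {
    if (concat) {
        for (int l = 0; l < m; ++l) {
            const float* wv = &W[(size_t)sn[t + l] * d];
            std::copy(wv, wv + d, h.begin() + (size_t)l * d);
        }
        std::copy(dv, dv + d, h.begin() + (size_t)m * d);
    } else {
        std::copy(dv, dv + d, h.begin());
        for (int l = 0; l < m; ++l)
            faxpy(1.0f, &W[(size_t)sn[t + l] * d], h.data(), d);
        float inv = 1.0f / (float)(m + 1);
        for (int q = 0; q < d; ++q) h[q] *= inv;
    }
}

// [[Rcpp::export]]
List cppTrainPVDM(List sentences, IntegerVector docIndex,
                  NumericMatrix W0, NumericMatrix D0,
                  NumericMatrix S0, NumericVector b0,
                  List codes, List paths, bool hierarchical, bool concat,
                  int m, int epochs, double alpha0, double alphaMin,
                  int seed, bool freezeShared) {
    const int d = W0.nrow();
    const int V = W0.ncol() - 1;    // last column is UNK
    const int hdim = concat ? (m + 1) * d : d;
    if (S0.nrow() != hdim)
        stop("output vectors have %d rows; expected %d for this composition",
             S0.nrow(), hdim);
    std::vector<float> W = toFloat(W0), D = toFloat(D0), S = toFloat(S0);
    std::vector<double> b(b0.begin(), b0.end());
    Corpus corp = buildCorpus(sentences, docIndex, V);
    Tree tree;
    if (hierarchical) tree = buildTree(codes, paths);
    const int nSent = (int)corp.sent.size();

    // total targets per epoch, for the linear learning-rate schedule
    long long perEpoch = 0;
    for (int i = 0; i < nSent; ++i) {
        long long T = (long long)corp.sent[i].size();
        if (T > m) perEpoch += T - m;
    }
    if (perEpoch == 0)
        stop("no sentence has more than m = %d tokens; lower m", m);
    const long long total = perEpoch * (long long)epochs;
    long long done = 0;

    std::vector<float> h(hdim), neu1e(hdim);
    std::vector<double> y;
    if (!hierarchical) y.resize(V);
    std::vector<int> order(nSent);
    for (int i = 0; i < nSent; ++i) order[i] = i;
    XRng rng((uint64_t)seed * 6364136223846793005ULL + 1442695040888963407ULL);

    for (int ep = 0; ep < epochs; ++ep) {
        // Fisher-Yates shuffle of sentence order, seeded
        for (int i = nSent - 1; i > 0; --i) {
            int j = rng.below(i + 1);
            std::swap(order[i], order[j]);
        }
        for (int si = 0; si < nSent; ++si) {
            const std::vector<int>& sn = corp.sent[order[si]];
            const int di = corp.doc[order[si]];
            const int T = (int)sn.size();
            if (T <= m) continue;
            float* dv = &D[(size_t)di * d];
            for (int t = 0; t + m < T; ++t) {
                float alpha = (float)(alpha0 -
                    (alpha0 - alphaMin) * ((double)done / (double)total));
                if (alpha < (float)alphaMin) alpha = (float)alphaMin;
                ++done;
                const int target = sn[t + m];
                if (target == corp.unkCol) continue;  // UNK never a target
                gatherH(sn, t, m, d, concat, W, dv, h);
                std::fill(neu1e.begin(), neu1e.end(), 0.0f);

                if (hierarchical) {
                    const std::vector<int>& nd = tree.node[target];
                    const std::vector<int>& cd = tree.code[target];
                    for (size_t j = 0; j < nd.size(); ++j) {
                        float* sv = &S[(size_t)nd[j] * hdim];
                        float f = SIG(fdot(sv, h.data(), hdim));
                        float g = (1.0f - (float)cd[j] - f) * alpha;
                        if (freezeShared) {
                            faxpy(g, sv, neu1e.data(), hdim);
                        } else {
                            // fused: neu1e += g*sv; sv += g*h
                            float* ne = neu1e.data();
                            const float* hp = h.data();
                            for (int q = 0; q < hdim; ++q) {
                                ne[q] += g * sv[q];
                                sv[q] += g * hp[q];
                            }
                        }
                    }
                } else {
                    double ymax = -1e300;
                    for (int j = 0; j < V; ++j) {
                        y[j] = b[j] + (double)fdot(&S[(size_t)j * hdim],
                                                   h.data(), hdim);
                        if (y[j] > ymax) ymax = y[j];
                    }
                    double Z = 0.0;
                    for (int j = 0; j < V; ++j) {
                        y[j] = std::exp(y[j] - ymax);
                        Z += y[j];
                    }
                    for (int j = 0; j < V; ++j) {
                        double p = y[j] / Z;
                        float g = (float)((((j == target) ? 1.0 : 0.0) - p) *
                                          alpha);
                        float* uj = &S[(size_t)j * hdim];
                        faxpy(g, uj, neu1e.data(), hdim);
                        if (!freezeShared) {
                            faxpy(g, h.data(), uj, hdim);
                            b[j] += g;
                        }
                    }
                }
                // distribute the accumulated error gradient
                if (concat) {
                    if (!freezeShared)
                        for (int l = 0; l < m; ++l)
                            faxpy(1.0f, neu1e.data() + (size_t)l * d,
                                  &W[(size_t)sn[t + l] * d], d);
                    faxpy(1.0f, neu1e.data() + (size_t)m * d, dv, d);
                } else {
                    // word2vec CBOW convention: the full d-dimensional
                    // error gradient is applied to every contributor
                    if (!freezeShared)
                        for (int l = 0; l < m; ++l)
                            faxpy(1.0f, neu1e.data(),
                                  &W[(size_t)sn[t + l] * d], d);
                    faxpy(1.0f, neu1e.data(), dv, d);
                }
            }
        }
    }
    return List::create(
        _["wordVectors"] = toMatrix(W, d, V + 1),
        _["docVectors"] = toMatrix(D, d, D0.ncol()),
        _["outputVectors"] = toMatrix(S, S0.nrow(), S0.ncol()),
        _["bias"] = NumericVector(b.begin(), b.end()));
}

// Mean per-context log-probability of the corpus under the current
// parameters (the training objective; with `perSentence` every
// sentence is weighted equally via its 1/(T_i - m) factor).
// [[Rcpp::export]]
double cppMeanLogProb(List sentences, IntegerVector docIndex,
                      NumericMatrix Wm, NumericMatrix Dm,
                      NumericMatrix Sm, NumericVector b,
                      List codes, List paths, bool hierarchical, bool concat,
                      int m, bool perSentence) {
    const int d = Wm.nrow();
    const int V = Wm.ncol() - 1;
    const int hdim = concat ? (m + 1) * d : d;
    std::vector<float> W = toFloat(Wm), D = toFloat(Dm), S = toFloat(Sm);
    Corpus corp = buildCorpus(sentences, docIndex, V);
    Tree tree;
    if (hierarchical) tree = buildTree(codes, paths);
    std::vector<float> h(hdim);
    std::vector<double> y;
    if (!hierarchical) y.resize(V);
    double grand = 0.0;
    long long nCtx = 0;
    double sentSum = 0.0;
    int nSentUsed = 0;

    for (size_t i = 0; i < corp.sent.size(); ++i) {
        const std::vector<int>& sn = corp.sent[i];
        int T = (int)sn.size();
        if (T <= m) continue;
        const float* dv = &D[(size_t)corp.doc[i] * d];
        double sSum = 0.0;
        int sCtx = 0;
        for (int t = 0; t + m < T; ++t) {
            int target = sn[t + m];
            if (target == corp.unkCol) continue;
            gatherH(sn, t, m, d, concat, W, dv, h);
            double lp = 0.0;
            if (hierarchical) {
                const std::vector<int>& nd = tree.node[target];
                const std::vector<int>& cd = tree.code[target];
                for (size_t j = 0; j < nd.size(); ++j) {
                    double z = (double)fdot(&S[(size_t)nd[j] * hdim],
                                            h.data(), hdim);
                    double f = 1.0 / (1.0 + std::exp(-(cd[j] ? -z : z)));
                    lp += std::log(f > 1e-300 ? f : 1e-300);
                }
            } else {
                double ymax = -1e300;
                for (int j = 0; j < V; ++j) {
                    y[j] = b[j] + (double)fdot(&S[(size_t)j * hdim],
                                               h.data(), hdim);
                    if (y[j] > ymax) ymax = y[j];
                }
                double Z = 0.0;
                for (int j = 0; j < V; ++j) Z += std::exp(y[j] - ymax);
                lp = (y[target] - ymax) - std::log(Z);
            }
            sSum += lp;
            ++sCtx;
        }
        if (sCtx > 0) {
            grand += sSum;
            nCtx += sCtx;
            sentSum += sSum / sCtx;
            ++nSentUsed;
        }
    }
    if (nCtx == 0) stop("no usable contexts (all sentences have T <= m)");
    return perSentence ? sentSum / nSentUsed : grand / nCtx;
}
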