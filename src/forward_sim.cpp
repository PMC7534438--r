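// Minimal forward-in-time diploid Wright-Fisher admixture simulator with
// ancestry-junction tracking on a continuous chromosome (lengths in
// Morgans). One selected site; additive fitness 1, 1+s/2, 1+s by the
// number of donor (A) alleles carried. Chromosomes are stored as the
// ancestry of the leftmost segment plus the sorted internal junction
// positions; ancestry alternates across junctions, so adjacent segments
// always differ. Intervals follow the half-open [start, end) convention.
//
// Two performance devices matter at the population sizes used for
// validation: (i) individuals that are pure recipient (both chromosomes
// junction-free, ancestry 0) always transmit a pure recipient gamete,
// so such parent draws collapse to a single uniform; (ii) an internal
// xoshiro256++ generator, seeded from R's RNG stream so results remain
// reproducible under set.seed(), replaces per-draw calls into R.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <cmath>

namespace {

// ---- fast RNG (xoshiro256++), seeded from R's RNG ----
struct FastRng {
    uint64_t s[4];

    static uint64_t splitmix64(uint64_t &x) {
        x += 0x9E3779B97f4A7C15ULL;
        uint64_t z = x;
        z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
        z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
        return z ^ (z >> 31);
    }
    explicit FastRng() {
        // derive 64-bit state from R's stream: reproducible given set.seed
        uint64_t seed = (uint64_t)(unif_rand() * 9007199254740992.0);
        seed ^= (uint64_t)(unif_rand() * 9007199254740992.0) << 11;
        for (int i = 0; i < 4; ++i) s[i] = splitmix64(seed);
    }
    static uint64_t rotl(uint64_t x, int k) {
        return (x << k) | (x >> (64 - k));
    }
    uint64_t next() {
        uint64_t r = rotl(s[0] + s[3], 23) + s[0];
        uint64_t t = s[1] << 17;
        s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
        s[2] ^= t; s[3] = rotl(s[3], 45);
        return r;
    }
    double unif() { // in (0, 1)
        return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
    }
    int rpois(double lambda) { // inversion; lambda is O(1) here
        double p = std::exp(-lambda), cum = p, u = unif();
        int k = 0;
        while (u > cum && k < 1000) {
            ++k;
            p *= lambda / k;
            cum += p;
        }
        return k;
    }
};

struct Chrom {
    uint8_t anc0;
    std::vector<double> brk;

    bool pure0() const { return anc0 == 0 && brk.empty(); }
    int anc_at(double x) const {
        if (brk.empty()) return anc0;
        size_t idx = std::upper_bound(brk.begin(), brk.end(), x) - brk.begin();
        return static_cast<int>(anc0 ^ (idx & 1u));
    }
};

typedef std::vector<Chrom> Pop;

// one recombinant gamete from a diploid parent
void make_gamete(const Chrom &c0, const Chrom &c1, double L, FastRng &rng,
                 Chrom &out)
{
    // ancestry-homogeneous, junction-free parents transmit themselves
    if (c0.brk.empty() && c1.brk.empty() && c0.anc0 == c1.anc0) {
        out.anc0 = c0.anc0;
        out.brk.clear();
        return;
    }
    int nx = rng.rpois(L);
    int cur = (rng.unif() < 0.5) ? 0 : 1;
    const Chrom *cc[2] = { &c0, &c1 };
    if (nx == 0) {
        out = *cc[cur];
        return;
    }
    static std::vector<double> xs; // single-threaded scratch buffer
    xs.resize(nx);
    for (int i = 0; i < nx; ++i) xs[i] = rng.unif() * L;
    std::sort(xs.begin(), xs.end());

    out.brk.clear();
    double segstart = 0.0;
    int emit = cc[cur]->anc_at(0.0);
    out.anc0 = static_cast<uint8_t>(emit);
    for (int k = 0; k <= nx; ++k) {
        double segend = (k < nx) ? xs[k] : L;
        const std::vector<double> &b = cc[cur]->brk;
        size_t idx = std::upper_bound(b.begin(), b.end(), segstart) -
            b.begin();
        int anc_here = cc[cur]->anc0 ^ (idx & 1u);
        if (anc_here != emit && segstart > 0.0) {
            out.brk.push_back(segstart);
            emit = anc_here;
        }
        for (; idx < b.size() && b[idx] < segend; ++idx) {
            out.brk.push_back(b[idx]);
            emit ^= 1;
        }
        segstart = segend;
        cur ^= 1;
    }
}

struct Sim {
    int N;
    double L, psel, s;
    Pop cur, nxt;
    std::vector<uint8_t> allele;      // per chromosome, A=1 at selected site
    std::vector<int> cls[3];          // impure individuals by genotype
    int n_pure;                       // pure-recipient individuals
    Chrom pure_chrom;

    void init(int N_, double L_, double psel_, double omega1)
    {
        N = N_; L = L_; psel = psel_;
        int ndon = static_cast<int>(std::lround(omega1 * N));
        if (ndon < 1) ndon = 1;
        if (ndon > N) ndon = N;
        cur.assign(2 * N, Chrom());
        nxt.assign(2 * N, Chrom());
        for (int i = 0; i < 2 * N; ++i) {
            cur[i].anc0 = (i < 2 * ndon) ? 1 : 0;
            cur[i].brk.clear();
        }
        allele.assign(2 * N, 0);
        pure_chrom.anc0 = 0;
        pure_chrom.brk.clear();
    }

    // classify individuals; returns selected-allele count
    int classify()
    {
        cls[0].clear(); cls[1].clear(); cls[2].clear();
        n_pure = 0;
        int k = 0;
        for (int i = 0; i < 2 * N; ++i) {
            allele[i] = static_cast<uint8_t>(cur[i].anc_at(psel));
            k += allele[i];
        }
        for (int i = 0; i < N; ++i) {
            const Chrom &a = cur[2 * i], &b = cur[2 * i + 1];
            if (a.pure0() && b.pure0()) {
                ++n_pure;
                continue;
            }
            cls[allele[2 * i] + allele[2 * i + 1]].push_back(i);
        }
        return k;
    }

    // advance one generation using the current classification
    void step(FastRng &rng)
    {
        double Wp = n_pure;
        double W0 = cls[0].size();
        double W1 = cls[1].size() * (1.0 + s / 2.0);
        double W2 = cls[2].size() * (1.0 + s);
        double Wtot = Wp + W0 + W1 + W2;
        for (int slot = 0; slot < 2 * N; ++slot) {
            double u = rng.unif() * Wtot;
            if (u < Wp) { // pure parent transmits a pure gamete
                nxt[slot].anc0 = 0;
                nxt[slot].brk.clear();
                continue;
            }
            u -= Wp;
            int g;
            if (u < W0) g = 0;
            else if (u < W0 + W1) g = 1;
            else g = 2;
            const std::vector<int> &v = cls[g];
            int j = static_cast<int>(rng.unif() * v.size());
            if (j >= static_cast<int>(v.size()))
                j = static_cast<int>(v.size()) - 1;
            int p = v[j];
            make_gamete(cur[2 * p], cur[2 * p + 1], L, rng, nxt[slot]);
        }
        cur.swap(nxt);
    }
};

} // namespace

using namespace Rcpp;

// Run one replicate for T generations; return the final population as
// junction lists plus the selected-allele frequency path (generations
// 0..T, frequency among 2N chromosomes).
extern "C" SEXP C_simulate_admixture(SEXP sN, SEXP sL, SEXP sPsel,
                                     SEXP sOmega1, SEXP sS, SEXP sT)
{
    BEGIN_RCPP
    RNGScope rngscope;
    FastRng rng;
    Sim sim;
    sim.s = as<double>(sS);
    sim.init(as<int>(sN), as<double>(sL), as<double>(sPsel),
             as<double>(sOmega1));
    int T = as<int>(sT);
    NumericVector freq(T + 1);
    int k = sim.classify();
    freq[0] = k / (2.0 * sim.N);
    for (int g = 1; g <= T; ++g) {
        sim.step(rng);
        k = sim.classify();
        freq[g] = k / (2.0 * sim.N);
    }
    int n = 2 * sim.N;
    IntegerVector anc0(n);
    List brk(n);
    for (int i = 0; i < n; ++i) {
        anc0[i] = sim.cur[i].anc0;
        brk[i] = NumericVector(sim.cur[i].brk.begin(), sim.cur[i].brk.end());
    }
    return List::create(_["anc0"] = anc0, _["breaks"] = brk,
                        _["allele"] = IntegerVector(sim.allele.begin(),
                                                    sim.allele.end()),
                        _["freq_path"] = freq);
    END_RCPP
}

// Validation driver: n_reps replicates advanced to max(snapshots); at each
// snapshot generation, record the length of the ancestry tract covering the
// selected site for every A-carrying chromosome (or a per-replicate cap).
// Returns, per snapshot, the tract lengths and their replicate index.
extern "C" SEXP C_focal_tracts(SEXP sN, SEXP sL, SEXP sPsel, SEXP sOmega1,
                               SEXP sS, SEXP sSnapshots, SEXP sNreps,
                               SEXP sMaxPerRep)
{
    BEGIN_RCPP
    RNGScope rngscope;
    FastRng rng;
    IntegerVector snaps(sSnapshots);
    int nsnap = snaps.size(), n_reps = as<int>(sNreps);
    int cap = as<int>(sMaxPerRep);
    int Tmax = *std::max_element(snaps.begin(), snaps.end());
    double L = as<double>(sL), psel = as<double>(sPsel);

    std::vector<std::vector<double> > lens(nsnap);
    std::vector<std::vector<int> > reps(nsnap);

    Sim sim;
    sim.s = as<double>(sS);
    for (int rep = 0; rep < n_reps; ++rep) {
        sim.init(as<int>(sN), L, psel, as<double>(sOmega1));
        int k = sim.classify();
        for (int g = 1; g <= Tmax; ++g) {
            sim.step(rng);
            k = sim.classify();
            for (int sI = 0; sI < nsnap; ++sI) {
                if (snaps[sI] != g) continue;
                int taken = 0;
                for (int i = 0; i < 2 * sim.N && taken < cap; ++i) {
                    if (!sim.allele[i]) continue;
                    const std::vector<double> &b = sim.cur[i].brk;
                    size_t idx = std::upper_bound(b.begin(), b.end(), psel)
                        - b.begin();
                    double lo = (idx == 0) ? 0.0 : b[idx - 1];
                    double hi = (idx == b.size()) ? L : b[idx];
                    lens[sI].push_back(hi - lo);
                    reps[sI].push_back(rep + 1);
                    ++taken;
                }
            }
            if (k == 0) break; // loss is absorbing: later snapshots are empty
        }
    }
    List out(nsnap);
    for (int sI = 0; sI < nsnap; ++sI) {
        out[sI] = List::create(
            _["length"] = NumericVector(lens[sI].begin(), lens[sI].end()),
            _["replicate"] = IntegerVector(reps[sI].begin(), reps[sI].end()));
    }
    return out;
    END_RCPP
}
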