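// Forward Wright-Fisher engine for a non-recombining haploid chromosome.
//
// Selected mutations are carried per-individual (ids into a registry of
// fitness deficits s); haploid fitness is multiplicative, w = prod(1 - s).
// Neutral variation is NOT carried forward: the full pedigree (parent index
// per individual per generation) is recorded, the sampled chromosomes'
// genealogy is traced back through it after the run, and neutral mutations
// are overlaid on that genealogy in R as Poisson(mu * T) under infinite
// sites -- distributionally identical to carrying them forward, since the
// chromosome does not recombine.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct MutRegistry {
    std::vector<double> s;        // fitness deficit per mutation id
    std::vector<int> cnt;         // carrier count, rebuilt each generation
    std::vector<char> fixedMark;  // marked fixed, purged on next copy pass
    std::vector<int> freeIds;
    std::vector<int> active;

    int newId(double sval) {
        int id;
        if (!freeIds.empty()) {
            id = freeIds.back();
            freeIds.pop_back();
            s[id] = sval; cnt[id] = 0; fixedMark[id] = 0;
        } else {
            id = (int) s.size();
            s.push_back(sval); cnt.push_back(0); fixedMark.push_back(0);
        }
        active.push_back(id);
        return id;
    }
};

// Marsaglia-Tsang gamma sampler (with the U^(1/a) boost for shape < 1),
// driven by R's RNG; much cheaper than R::rgamma for the small fixed
// shapes used here
double rgamma_mt(double shape, double scale) {
    double a = shape, boost = 1.0;
    if (a < 1.0) {
        boost = std::pow(unif_rand(), 1.0 / a);
        a += 1.0;
    }
    const double d = a - 1.0 / 3.0;
    const double c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
        double x, v;
        do {
            x = norm_rand();
            v = 1.0 + c * x;
        } while (v <= 0.0);
        v = v * v * v;
        double u = unif_rand();
        if (u < 1.0 - 0.0331 * x * x * x * x) return d * v * boost * scale;
        if (std::log(u) < 0.5 * x * x + d * (1.0 - v + std::log(v)))
            return d * v * boost * scale;
    }
}

// distinct sample without replacement via partial Fisher-Yates, R's RNG
std::vector<int> sampleDistinct(int n, int k) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    for (int i = 0; i < k; ++i) {
        int j = i + (int) std::floor(unif_rand() * (n - i));
        if (j >= n) j = n - 1;
        std::swap(idx[i], idx[j]);
    }
    idx.resize(k);
    return idx;
}

} // namespace

// Run one forward replicate. Epochs are given present-first in generations
// ago with HAPLOID chromosome counts; burnInGens generations at the
// ancestral size precede the oldest epoch. Returns total genealogy branch
// length of the sample, the merge table (time ago, a, b, new cluster id),
// per-cluster branch lengths/leaf counts (root excluded), and selected-site
// bookkeeping.
// [[Rcpp::export]]
List wf_run_replicate(NumericVector epochStartsAgo,
                      NumericVector epochSizesHap,
                      double burnInGens, double muSelRegion,
                      double dfeShape, double dfeScale, double nHapRef,
                      int sampleN, bool returnCounts = false,
                      bool trackSelected = true) {
    if (returnCounts) trackSelected = true;
    const int J = epochStartsAgo.size();
    if (J < 1 || epochSizesHap.size() != J)
        stop("epoch vectors must be non-empty and of equal length");
    std::vector<long> sizes(J);
    for (int j = 0; j < J; ++j) {
        long N = (long) std::lround(epochSizesHap[j]);
        if (N < 2) N = 2;
        sizes[j] = N;
    }
    const double oldest = epochStartsAgo[J - 1];
    const long G = (long) std::llround(burnInGens + oldest);
    const long burnG = (long) std::llround(burnInGens);
    const long Nanc = sizes[J - 1];
    if (sampleN < 2) stop("sampleN must be >= 2");

    // population size at generation g (1..G); g=0 is the clonal founder pop
    std::vector<long> Nsched(G + 1);
    Nsched[0] = Nanc;
    for (long g = 1; g <= G; ++g) {
        double ago = (double) (G - g);
        int j = 0;
        while (j + 1 < J && ago >= epochStartsAgo[j + 1]) ++j;
        // epochs are present-first: find epoch whose [start, next) holds ago
        // (above loop walks from present outward)
        Nsched[g] = sizes[j];
        if (g <= burnG) Nsched[g] = Nanc;
    }
    long maxN = *std::max_element(Nsched.begin(), Nsched.end());
    if (sampleN > Nsched[G]) stop("sampleN exceeds final population size");

    // double-buffered population
    std::vector<std::vector<int>> mutsA(maxN), mutsB(maxN);
    std::vector<double> wA(maxN, 1.0), wB(maxN, 1.0);
    std::vector<std::vector<int>>* cur = &mutsA;
    std::vector<std::vector<int>>* nxt = &mutsB;
    std::vector<double>* wcur = &wA;
    std::vector<double>* wnxt = &wB;
    long Ncur = Nanc;
    for (long i = 0; i < Ncur; ++i) { (*cur)[i].clear(); (*wcur)[i] = 1.0; }

    MutRegistry reg;
    std::vector<int> pendingFree;
    long nFixedDel = 0;

    // pedigree: parent index of individual i of generation g
    std::vector<int> pedigree;
    pedigree.reserve((size_t) (G + 1) * (size_t) ((maxN + Nanc) / 2));
    std::vector<size_t> genOff(G + 2);
    genOff[0] = 0; genOff[1] = 0; // generation 0 has no parents recorded

    std::vector<double> cumw(maxN);
    const double clampS = 0.999999;

    for (long g = 1; g <= G; ++g) {
        const long Nnext = Nsched[g];
        // cumulative fitness weights of current generation
        bool uniform = true;
        for (long i = 0; i < Ncur; ++i)
            if ((*wcur)[i] != (*wcur)[0]) { uniform = false; break; }
        if (!uniform) {
            double acc = 0.0;
            for (long i = 0; i < Ncur; ++i) {
                acc += (*wcur)[i];
                cumw[i] = acc;
            }
        }
        // zero carrier counts of active mutations
        if (trackSelected)
            for (int id : reg.active) reg.cnt[id] = 0;

        // offspring: choose parent, inherit (purging marked-fixed ids)
        double wmax = 0.0;
        for (long c = 0; c < Nnext; ++c) {
            long p;
            if (uniform) {
                p = (long) std::floor(unif_rand() * Ncur);
                if (p >= Ncur) p = Ncur - 1;
            } else {
                double u = unif_rand() * cumw[Ncur - 1];
                p = std::upper_bound(cumw.begin(), cumw.begin() + Ncur, u)
                    - cumw.begin();
                if (p >= Ncur) p = Ncur - 1;
            }
            pedigree.push_back((int) p);
            if (trackSelected) {
                std::vector<int>& child = (*nxt)[c];
                child.clear();
                const std::vector<int>& par = (*cur)[p];
                for (int id : par) {
                    if (!reg.fixedMark[id]) {
                        child.push_back(id);
                        ++reg.cnt[id];
                    }
                }
            }
            (*wnxt)[c] = (*wcur)[p];
            if ((*wnxt)[c] > wmax) wmax = (*wnxt)[c];
        }
        genOff[g + 1] = pedigree.size();

        // marked-fixed ids have now been purged from every lineage
        for (int id : pendingFree) {
            reg.fixedMark[id] = 0;
            reg.freeIds.push_back(id);
        }
        pendingFree.clear();

        // new selected mutations
        if (muSelRegion > 0) {
            long K = (long) R::rpois(muSelRegion * (double) Nnext);
            for (long m = 0; m < K; ++m) {
                long c = (long) std::floor(unif_rand() * Nnext);
                if (c >= Nnext) c = Nnext - 1;
                double gamma = rgamma_mt(dfeShape, dfeScale);
                double s = gamma / nHapRef;
                if (s > clampS) s = clampS;
                if (trackSelected) {
                    int id = reg.newId(s);
                    (*nxt)[c].push_back(id);
                    reg.cnt[id] = 1;
                }
                (*wnxt)[c] *= (1.0 - s);
            }
            // wmax may have shrunk only; renormalization below still fine
        }

        // classify active mutations: lost -> recycle; fixed -> mark
        size_t keep = 0;
        if (trackSelected)
        for (size_t a = 0; a < reg.active.size(); ++a) {
            int id = reg.active[a];
            int cnt = reg.cnt[id];
            if (cnt == 0) {
                reg.freeIds.push_back(id);
            } else if (cnt == (int) Nnext && Nnext > 1) {
                reg.fixedMark[id] = 1;
                pendingFree.push_back(id);
                if (reg.s[id] > 0 && g > burnG) ++nFixedDel;
            } else {
                reg.active[keep++] = id;
            }
        }
        reg.active.resize(keep);

        // renormalize fitness to avoid underflow (relative w is all that
        // matters under multinomial resampling)
        if (wmax > 0 && wmax != 1.0) {
            double inv = 1.0 / wmax;
            for (long c = 0; c < Nnext; ++c) (*wnxt)[c] *= inv;
        }

        std::swap(cur, nxt);
        std::swap(wcur, wnxt);
        Ncur = Nnext;
    }

    // ---- trace the sample genealogy through the pedigree ----
    std::vector<int> samp = sampleDistinct((int) Ncur, sampleN);
    const int nNode = 2 * sampleN - 1;
    std::vector<double> birth(nNode + 1, 0.0), death(nNode + 1, -1.0);
    std::vector<int> csize(nNode + 1, 0);
    for (int i = 1; i <= sampleN; ++i) csize[i] = 1;

    std::vector<int> linInd(samp.begin(), samp.end()); // individual index
    std::vector<int> linClu(sampleN);                  // cluster id
    for (int i = 0; i < sampleN; ++i) linClu[i] = i + 1;
    int nextClu = sampleN + 1;
    int nLin = sampleN;
    double Ttotal = 0.0;
    std::vector<double> mTime; std::vector<int> mA, mB, mNew;
    std::vector<int> parentOf(maxN, -1);

    for (long g = G; g >= 1 && nLin > 1; --g) {
        Ttotal += nLin;
        const int* par = pedigree.data() + genOff[g];
        double agoParent = (double) (G - g + 1);
        // map to parents, merging lineages that share one
        for (int i = 0; i < nLin; ++i) linInd[i] = par[linInd[i]];
        int w = 0;
        for (int i = 0; i < nLin; ++i) {
            int p = linInd[i];
            int seen = parentOf[p];
            if (seen < 0) {
                parentOf[p] = w;
                linInd[w] = p;
                linClu[w] = linClu[i];
                ++w;
            } else {
                int a = linClu[seen], b = linClu[i];
                death[a] = agoParent; death[b] = agoParent;
                birth[nextClu] = agoParent;
                csize[nextClu] = csize[a] + csize[b];
                mTime.push_back(agoParent);
                mA.push_back(a); mB.push_back(b); mNew.push_back(nextClu);
                linClu[seen] = nextClu;
                ++nextClu;
            }
        }
        for (int i = 0; i < w; ++i) parentOf[linInd[i]] = -1;
        nLin = w;
    }
    if (nLin > 1) {
        // incomplete coalescence within the recorded history: join the
        // remaining lineages in a star at the founder generation
        double agoRoot = (double) G;
        while (nLin > 1) {
            int a = linClu[0], b = linClu[1];
            death[a] = agoRoot; death[b] = agoRoot;
            birth[nextClu] = agoRoot;
            csize[nextClu] = csize[a] + csize[b];
            mTime.push_back(agoRoot);
            mA.push_back(a); mB.push_back(b); mNew.push_back(nextClu);
            linClu[0] = nextClu;
            for (int i = 1; i + 1 < nLin; ++i) linClu[i] = linClu[i + 1];
            ++nextClu;
            --nLin;
        }
    }

    int nMerge = (int) mTime.size();
    NumericMatrix merges(nMerge, 4);
    for (int i = 0; i < nMerge; ++i) {
        merges(i, 0) = mTime[i];
        merges(i, 1) = mA[i];
        merges(i, 2) = mB[i];
        merges(i, 3) = mNew[i];
    }
    colnames(merges) = CharacterVector::create("time", "a", "b", "new");

    NumericVector branchLen(nNode - 1);
    IntegerVector branchSize(nNode - 1);
    for (int id = 1; id <= nNode - 1; ++id) {
        branchLen[id - 1] = (death[id] >= 0 ? death[id] : (double) G)
            - birth[id];
        branchSize[id - 1] = csize[id];
    }

    List out = List::create(
        _["n"] = sampleN,
        _["Ttotal"] = Ttotal,
        _["tmrca"] = nMerge ? mTime[nMerge - 1] : 0.0,
        _["merges"] = merges,
        _["branchLen"] = branchLen,
        _["branchSize"] = branchSize,
        _["nSegSelected"] = trackSelected ? (int) reg.active.size()
                                          : NA_INTEGER,
        _["nFixedDeleterious"] = trackSelected ? (double) nFixedDel
                                               : NA_REAL,
        _["finalN"] = (double) Ncur);
    if (returnCounts) {
        IntegerVector segCounts(reg.active.size());
        NumericVector segS(reg.active.size());
        for (size_t a = 0; a < reg.active.size(); ++a) {
            segCounts[a] = reg.cnt[reg.active[a]];
            segS[a] = reg.s[reg.active[a]];
        }
        out["segCounts"] = segCounts;
        out["segS"] = segS;
        out["finalNint"] = (int) Ncur;
    }
    return out;
}

// Fitness-weighted multinomial offspring counts for one generation;
// exposed for unit tests of the resampling core.
// [[Rcpp::export]]
IntegerVector wf_offspring_counts(NumericVector w, int Nnext) {
    int N = w.size();
    if (N < 1) stop("empty parent generation");
    std::vector<double> cumw(N);
    double acc = 0.0;
    for (int i = 0; i < N; ++i) { acc += w[i]; cumw[i] = acc; }
    if (acc <= 0) stop("total fitness must be positive");
    IntegerVector counts(N);
    for (int c = 0; c < Nnext; ++c) {
        double u = unif_rand() * acc;
        int p = (int) (std::upper_bound(cumw.begin(), cumw.end(), u)
                       - cumw.begin());
        if (p >= N) p = N - 1;
        ++counts[p];
    }
    return counts;
}
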