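#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>
using namespace Rcpp;

// Seed-and-extend matching of color-space reads against reference contigs.
//
// Reads and contigs are given as "internal" color strings (transitions
// between adjacent bases, chars '0'..'3'). A read of n bases has n-1
// internal colors; a window match over colors j..j+L-1 of a contig with m
// bases corresponds to bases j+1 .. j+1+L (1-based) on the plus strand.
// Minus-strand matches are found against the reversed contig colors
// (colors are complement-invariant).
//
// Mismatch budget: at most seed_mm mismatches within the first
// min(seed_len, L) colors, and at most tail_mm in the remainder.
// Candidate positions come from exact k-mer lookups: the seed region is
// split into seed_mm+1 non-overlapping k-mers, of which at least one must
// be error-free (pigeonhole); each candidate is then verified in full.

namespace {

const int K = 7; // index k-mer length (4^7 = 16384 buckets)

struct RefStrand {
    int contig;      // 0-based contig index
    char strand;     // '+' or '-'
    std::string col; // internal colors as stored for this strand
    int nbases;      // contig length in bases
};

struct Index {
    std::vector<std::vector<int> > pos;   // bucket -> flat positions
    std::vector<std::vector<int> > ref;   // bucket -> ref-strand ids
    Index() : pos(1 << (2 * K)), ref(1 << (2 * K)) {}
};

inline int kmer_key(const std::string& s, int off) {
    int key = 0;
    for (int i = 0; i < K; i++) {
        int c = s[off + i] - '0';
        if (c < 0 || c > 3) return -1;
        key = (key << 2) | c;
    }
    return key;
}

// count mismatches against ref string r at offset j; return false if over budget
inline bool verify(const std::string& s, const std::string& r, int j,
                   int seedpart, int seed_mm, int tail_mm,
                   int* mm_seed, int* mm_tail) {
    int L = (int)s.size();
    int ms = 0, mt = 0;
    for (int t = 0; t < seedpart; t++) {
        if (s[t] != r[j + t] && ++ms > seed_mm) return false;
    }
    for (int t = seedpart; t < L; t++) {
        if (s[t] != r[j + t] && ++mt > tail_mm) return false;
    }
    *mm_seed = ms;
    *mm_tail = mt;
    return true;
}

} // namespace

// [[Rcpp::export]]
DataFrame cs_match_block(CharacterVector read_colors, LogicalVector rev,
                         CharacterVector contig_colors,
                         IntegerVector contig_nbases,
                         int seed_len, int seed_mm, int tail_mm) {
    int ncontig = contig_colors.size();
    std::vector<RefStrand> refs;
    refs.reserve(2 * ncontig);
    for (int c = 0; c < ncontig; c++) {
        std::string f = as<std::string>(contig_colors[c]);
        RefStrand fw; fw.contig = c; fw.strand = '+'; fw.col = f;
        fw.nbases = contig_nbases[c];
        refs.push_back(fw);
        RefStrand rv = fw; rv.strand = '-';
        std::reverse(rv.col.begin(), rv.col.end());
        refs.push_back(rv);
    }

    Index idx;
    for (size_t rid = 0; rid < refs.size(); rid++) {
        const std::string& s = refs[rid].col;
        int n = (int)s.size();
        for (int i = 0; i + K <= n; i++) {
            int key = kmer_key(s, i);
            if (key >= 0) {
                idx.pos[key].push_back(i);
                idx.ref[key].push_back((int)rid);
            }
        }
    }

    std::vector<int> out_read, out_contig, out_start, out_end;
    std::vector<int> out_ms, out_mt;
    std::vector<char> out_strand;

    int nreads = read_colors.size();
    std::vector<std::pair<int, int> > cand; // (refid, start)
    for (int r = 0; r < nreads; r++) {
        std::string s = as<std::string>(read_colors[r]);
        if (rev[r]) std::reverse(s.begin(), s.end());
        int L = (int)s.size();
        if (L == 0) continue;
        int seedpart = std::min(seed_len, L);
        int npieces = seed_mm + 1;
        cand.clear();
        bool pigeonhole = (npieces * K <= seedpart);
        if (pigeonhole) {
            for (int p = 0; p < npieces; p++) {
                int off = p * K;
                int key = kmer_key(s, off);
                if (key < 0) continue;
                const std::vector<int>& pp = idx.pos[key];
                const std::vector<int>& rr = idx.ref[key];
                for (size_t h = 0; h < pp.size(); h++) {
                    int start = pp[h] - off;
                    int rid = rr[h];
                    if (start >= 0 && start + L <= (int)refs[rid].col.size())
                        cand.push_back(std::make_pair(rid, start));
                }
            }
            std::sort(cand.begin(), cand.end());
            cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
        } else {
            // budgets/lengths outside the pigeonhole guarantee: scan all offsets
            for (size_t rid = 0; rid < refs.size(); rid++) {
                int n = (int)refs[rid].col.size();
                for (int j = 0; j + L <= n; j++)
                    cand.push_back(std::make_pair((int)rid, j));
            }
        }
        for (size_t cix = 0; cix < cand.size(); cix++) {
            int rid = cand[cix].first;
            int j = cand[cix].second;
            int ms, mt;
            if (!verify(s, refs[rid].col, j, seedpart, seed_mm, tail_mm,
                        &ms, &mt))
                continue;
            const RefStrand& rf = refs[rid];
            int start1, end1;
            if (rf.strand == '+') {
                start1 = j + 1;            // first base of window, 1-based
                end1 = j + 1 + L;          // window spans L+1 bases
            } else {
                int m = rf.nbases;
                start1 = m - j - L;
                end1 = m - j;
            }
            out_read.push_back(r + 1);
            out_contig.push_back(rf.contig + 1);
            out_start.push_back(start1);
            out_end.push_back(end1);
            out_strand.push_back(rf.strand);
            out_ms.push_back(ms);
            out_mt.push_back(mt);
        }
    }

    int nh = (int)out_read.size();
    CharacterVector strand(nh);
    for (int i = 0; i < nh; i++)
        strand[i] = (out_strand[i] == '+') ? "+" : "-";
    return DataFrame::create(
        _["read"] = IntegerVector(out_read.begin(), out_read.end()),
        _["contig"] = IntegerVector(out_contig.begin(), out_contig.end()),
        _["start"] = IntegerVector(out_start.begin(), out_start.end()),
        _["end"] = IntegerVector(out_end.begin(), out_end.end()),
        _["strand"] = strand,
        _["mm_seed"] = IntegerVector(out_ms.begin(), out_ms.end()),
        _["mm_tail"] = IntegerVector(out_mt.begin(), out_mt.end()),
        _["stringsAsFactors"] = false);
}
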