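// Sequence kernels: k-mer seeded ungapped comparison, greedy clustering,
// read placement, base-count pileups, pair merging, quality trimming.
// Substitution-only semantics throughout (the simulator emits no indels and
// the locus comparisons the toolkit needs are diagonal alignments); gaps at
// sequence ends are free, internal gaps are not modelled.
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

static inline int base2code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static inline char compbase(char c) {
    switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
    }
}

static std::string revcomp_str(const std::string& s) {
    std::string r(s.rbegin(), s.rend());
    for (size_t i = 0; i < r.size(); ++i) r[i] = compbase(r[i]);
    return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
    int n = x.size();
    CharacterVector out(n);
    for (int i = 0; i < n; ++i) {
        if (CharacterVector::is_na(x[i])) { out[i] = NA_STRING; continue; }
        out[i] = revcomp_str(as<std::string>(x[i]));
    }
    return out;
}

// Enumerate valid k-mers of s as (code, position); positions 0-based.
static void collect_kmers(const std::string& s, int k,
                          std::vector<std::pair<uint64_t,int> >& out,
                          int step = 1) {
    int n = (int)s.size();
    if (n < k) return;
    uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    uint64_t enc = 0;
    int run = 0;
    for (int i = 0; i < n; ++i) {
        int c = base2code(s[i]);
        if (c < 0) { run = 0; enc = 0; continue; }
        enc = ((enc << 2) | (uint64_t)c) & mask;
        if (++run >= k) {
            int pos = i - k + 1;
            if (pos % step == 0) out.push_back(std::make_pair(enc, pos));
        }
    }
}

struct Cand { int id; int diag; int votes; };

static bool cand_order(const Cand& a, const Cand& b) {
    if (a.votes != b.votes) return a.votes > b.votes;
    if (a.id != b.id) return a.id < b.id;
    return a.diag < b.diag;
}

// Count mismatches of q against s when q's origin sits at seed coordinate
// `diag` (may be negative).  Returns overlap length; mism via reference.
static int diag_overlap(const std::string& q, const std::string& s, int diag,
                        int& mism) {
    int ql = (int)q.size(), sl = (int)s.size();
    int s0 = std::max(0, diag);
    int s1 = std::min(sl, ql + diag);
    int ov = s1 - s0;
    mism = 0;
    for (int sc = s0; sc < s1; ++sc)
        if (q[sc - diag] != s[sc]) ++mism;
    return ov;
}

// Greedy (uclust-style) clustering.  Sequences are visited in the given
// order; the first member of each cluster is its seed.  With
// allow_offsets = FALSE the comparison is the diagonal-0 alignment and
// identity = matches / max(len) (terminal length difference counts as
// mismatch, as does any internal difference); mism_eff = max(len) - matches.
// With allow_offsets = TRUE the best shared-kmer diagonal is used and
// identity = matches / overlap, requiring overlap >= min_overlap.
// max_mismatch < 0 disables the mismatch cap.  With both_strands = TRUE the
// reverse complement of each query is also tried; `strand` records the
// joining orientation and `offset` is the start of the oriented query in
// seed coordinates (may be negative).
// [[Rcpp::export]]
List cpp_greedy_cluster(CharacterVector seqs, int k, double min_ident,
                        int max_mismatch, int min_overlap, bool allow_offsets,
                        bool both_strands = false, int max_candidates = 64) {
    int n = seqs.size();
    IntegerVector assign(n), offset(n);
    CharacterVector strand(n);
    std::vector<std::string> seeds;
    std::unordered_map<uint64_t, std::vector<std::pair<int,int> > > idx;
    std::vector<std::pair<uint64_t,int> > kms;
    for (int i = 0; i < n; ++i) {
        std::string fw = as<std::string>(seqs[i]);
        double best_ident = -1.0;
        int best_seed = -1, best_diag = 0;
        char best_strand = '+';
        int nstr = both_strands ? 2 : 1;
        for (int sidx = 0; sidx < nstr; ++sidx) {
            std::string q = (sidx == 0) ? fw : revcomp_str(fw);
            kms.clear();
            collect_kmers(q, k, kms);
            std::unordered_map<int64_t,int> votes;
            for (size_t j = 0; j < kms.size(); ++j) {
                std::unordered_map<uint64_t, std::vector<std::pair<int,int> > >::iterator
                    it = idx.find(kms[j].first);
                if (it == idx.end()) continue;
                const std::vector<std::pair<int,int> >& hits = it->second;
                for (size_t h = 0; h < hits.size(); ++h) {
                    int diag = hits[h].second - kms[j].second;
                    if (!allow_offsets && diag != 0) continue;
                    int64_t key = (int64_t)hits[h].first * 2000003LL +
                        (diag + 1000000);
                    votes[key]++;
                }
            }
            std::vector<Cand> cands;
            for (std::unordered_map<int64_t,int>::iterator v = votes.begin();
                 v != votes.end(); ++v) {
                Cand c;
                c.id = (int)(v->first / 2000003LL);
                c.diag = (int)(v->first % 2000003LL) - 1000000;
                c.votes = v->second;
                cands.push_back(c);
            }
            std::sort(cands.begin(), cands.end(), cand_order);
            if ((int)cands.size() > max_candidates)
                cands.resize(max_candidates);
            for (size_t ci = 0; ci < cands.size(); ++ci) {
                const std::string& s = seeds[cands[ci].id];
                int mism = 0;
                int ov = diag_overlap(q, s, cands[ci].diag, mism);
                if (ov <= 0) continue;
                int matches = ov - mism;
                double ident;
                int mism_eff;
                if (allow_offsets) {
                    if (ov < min_overlap) continue;
                    ident = (double)matches / (double)ov;
                    mism_eff = mism;
                } else {
                    int denom = std::max((int)q.size(), (int)s.size());
                    ident = (double)matches / (double)denom;
                    mism_eff = denom - matches;
                }
                if (ident < min_ident) continue;
                if (max_mismatch >= 0 && mism_eff > max_mismatch) continue;
                if (ident > best_ident) {
                    best_ident = ident;
                    best_seed = cands[ci].id;
                    best_diag = cands[ci].diag;
                    best_strand = (sidx == 0) ? '+' : '-';
                }
            }
        }
        if (best_seed >= 0) {
            assign[i] = best_seed + 1;
            offset[i] = best_diag;
            strand[i] = std::string(1, best_strand);
        } else {
            int id = (int)seeds.size();
            seeds.push_back(fw);
            kms.clear();
            collect_kmers(fw, k, kms);
            for (size_t j = 0; j < kms.size(); ++j)
                idx[kms[j].first].push_back(std::make_pair(id, kms[j].second));
            assign[i] = id + 1;
            offset[i] = 0;
            strand[i] = "+";
        }
    }
    return List::create(_["cluster"] = assign, _["offset"] = offset,
                        _["strand"] = strand);
}

struct RefIndex {
    std::unordered_map<uint64_t, std::vector<std::pair<int,int> > > idx;
    std::vector<std::string> seqs;
};

static void build_ref_index(CharacterVector refs, int k, RefIndex& ri) {
    std::vector<std::pair<uint64_t,int> > kms;
    for (int r = 0; r < refs.size(); ++r) {
        ri.seqs.push_back(as<std::string>(refs[r]));
        kms.clear();
        collect_kmers(ri.seqs[r], k, kms);
        for (size_t j = 0; j < kms.size(); ++j)
            ri.idx[kms[j].first].push_back(std::make_pair(r, kms[j].second));
    }
}

// Seed-and-extend placement of reads on reference loci.  For each read both
// strands are tried; candidate (ref, diagonal) pairs come from shared k-mers
// and are scored ungapped as matches - mismatches over the overlap.  The
// mapping quality is min(60, best - second_best) where second_best is the
// best score on any other reference locus (ties across loci give maQ 0).
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector refs, int k,
                        int seed_step = 4, int max_candidates = 64) {
    RefIndex ri;
    build_ref_index(refs, k, ri);
    int n = reads.size();
    IntegerVector ref_out(n), pos_out(n), mism_out(n), ov_out(n), maq_out(n),
        score_out(n);
    CharacterVector strand_out(n);
    std::vector<std::pair<uint64_t,int> > kms;
    for (int i = 0; i < n; ++i) {
        std::string fw = as<std::string>(reads[i]);
        std::string rc = revcomp_str(fw);
        int best_score = INT_MIN, best_ref = -1, best_diag = 0, best_mism = 0,
            best_ov = 0;
        char best_strand = '+';
        std::unordered_map<int,int> per_ref_best;
        for (int sidx = 0; sidx < 2; ++sidx) {
            const std::string& q = (sidx == 0) ? fw : rc;
            kms.clear();
            collect_kmers(q, k, kms, seed_step);
            std::unordered_map<int64_t,int> votes;
            for (size_t j = 0; j < kms.size(); ++j) {
                std::unordered_map<uint64_t, std::vector<std::pair<int,int> > >::iterator
                    it = ri.idx.find(kms[j].first);
                if (it == ri.idx.end()) continue;
                for (size_t h = 0; h < it->second.size(); ++h) {
                    int diag = it->second[h].second - kms[j].second;
                    int64_t key = (int64_t)it->second[h].first * 2000003LL +
                        (diag + 1000000);
                    votes[key]++;
                }
            }
            std::vector<Cand> cands;
            for (std::unordered_map<int64_t,int>::iterator v = votes.begin();
                 v != votes.end(); ++v) {
                Cand c;
                c.id = (int)(v->first / 2000003LL);
                c.diag = (int)(v->first % 2000003LL) - 1000000;
                c.votes = v->second;
                cands.push_back(c);
            }
            std::sort(cands.begin(), cands.end(), cand_order);
            if ((int)cands.size() > max_candidates) cands.resize(max_candidates);
            for (size_t ci = 0; ci < cands.size(); ++ci) {
                int mism = 0;
                int ov = diag_overlap(q, ri.seqs[cands[ci].id], cands[ci].diag,
                                      mism);
                if (ov < k) continue;
                int score = (ov - mism) - mism;
                std::unordered_map<int,int>::iterator pb =
                    per_ref_best.find(cands[ci].id);
                if (pb == per_ref_best.end() || score > pb->second)
                    per_ref_best[cands[ci].id] = score;
                // strict improvement only: candidates are visited in a
                // deterministic order, so ties keep the first hit
                if (score > best_score) {
                    best_score = score;
                    best_ref = cands[ci].id;
                    best_diag = cands[ci].diag;
                    best_mism = mism;
                    best_ov = ov;
                    best_strand = (sidx == 0) ? '+' : '-';
                }
            }
        }
        if (best_ref < 0) {
            ref_out[i] = NA_INTEGER; pos_out[i] = NA_INTEGER;
            mism_out[i] = NA_INTEGER; ov_out[i] = NA_INTEGER;
            maq_out[i] = NA_INTEGER; score_out[i] = NA_INTEGER;
            strand_out[i] = NA_STRING;
            continue;
        }
        int second = INT_MIN;
        for (std::unordered_map<int,int>::iterator pb = per_ref_best.begin();
             pb != per_ref_best.end(); ++pb)
            if (pb->first != best_ref && pb->second > second)
                second = pb->second;
        int maq = (second == INT_MIN) ? 60 :
            std::min(60, std::max(0, best_score - second));
        ref_out[i] = best_ref + 1;
        pos_out[i] = best_diag;
        mism_out[i] = best_mism;
        ov_out[i] = best_ov;
        maq_out[i] = maq;
        score_out[i] = best_score;
        strand_out[i] = std::string(1, best_strand);
    }
    return DataFrame::create(_["ref"] = ref_out, _["pos"] = pos_out,
                             _["strand"] = strand_out,
                             _["n_mismatch"] = mism_out,
                             _["overlap"] = ov_out, _["score"] = score_out,
                             _["maq"] = maq_out,
                             _["stringsAsFactors"] = false);
}

// All query-vs-reference hits above nothing (thresholding is done in R):
// for every (query, ref, strand) combination sharing at least one k-mer the
// best-voted diagonal is evaluated ungapped; identity = matches / overlap.
// [[Rcpp::export]]
DataFrame cpp_pair_hits(CharacterVector queries, CharacterVector refs, int k,
                        bool both_strands = true) {
    RefIndex ri;
    build_ref_index(refs, k, ri);
    std::vector<int> qi_v, ri_v, mism_v, ov_v;
    std::vector<std::string> strand_v;
    std::vector<std::pair<uint64_t,int> > kms;
    for (int i = 0; i < queries.size(); ++i) {
        std::string fw = as<std::string>(queries[i]);
        int nstr = both_strands ? 2 : 1;
        for (int sidx = 0; sidx < nstr; ++sidx) {
            std::string q = (sidx == 0) ? fw : revcomp_str(fw);
            kms.clear();
            collect_kmers(q, k, kms);
            std::unordered_map<int64_t,int> votes;
            for (size_t j = 0; j < kms.size(); ++j) {
                std::unordered_map<uint64_t, std::vector<std::pair<int,int> > >::iterator
                    it = ri.idx.find(kms[j].first);
                if (it == ri.idx.end()) continue;
                for (size_t h = 0; h < it->second.size(); ++h) {
                    int diag = it->second[h].second - kms[j].second;
                    int64_t key = (int64_t)it->second[h].first * 2000003LL +
                        (diag + 1000000);
                    votes[key]++;
                }
            }
            // best diagonal per ref
            std::unordered_map<int, std::pair<int,int> > best; // ref -> (votes, diag)
            for (std::unordered_map<int64_t,int>::iterator v = votes.begin();
                 v != votes.end(); ++v) {
                int rid = (int)(v->first / 2000003LL);
                int diag = (int)(v->first % 2000003LL) - 1000000;
                std::unordered_map<int, std::pair<int,int> >::iterator b =
                    best.find(rid);
                if (b == best.end() || v->second > b->second.first ||
                    (v->second == b->second.first && diag < b->second.second))
                    best[rid] = std::make_pair(v->second, diag);
            }
            std::vector<int> rids;
            for (std::unordered_map<int, std::pair<int,int> >::iterator b =
                     best.begin(); b != best.end(); ++b)
                rids.push_back(b->first);
            std::sort(rids.begin(), rids.end());
            for (size_t bi = 0; bi < rids.size(); ++bi) {
                int rid = rids[bi];
                int diag = best[rid].second;
                int mism = 0;
                int ov = diag_overlap(q, ri.seqs[rid], diag, mism);
                if (ov < k) continue;
                qi_v.push_back(i + 1);
                ri_v.push_back(rid + 1);
                strand_v.push_back(sidx == 0 ? "+" : "-");
                mism_v.push_back(mism);
                ov_v.push_back(ov);
            }
        }
    }
    return DataFrame::create(_["qi"] = wrap(qi_v), _["ri"] = wrap(ri_v),
                             _["strand"] = wrap(strand_v),
                             _["n_mismatch"] = wrap(mism_v),
                             _["overlap"] = wrap(ov_v),
                             _["stringsAsFactors"] = false);
}

// Per-column base counts of offset-placed sequences (offsets 0-based, >= 0).
// Rows: A, C, G, T, other.  `weights` multiplies each sequence's contribution
// (use dereplication counts).
// [[Rcpp::export]]
IntegerMatrix cpp_base_counts(CharacterVector seqs, IntegerVector offsets,
                              IntegerVector weights, int width) {
    IntegerMatrix out(5, width);
    for (int i = 0; i < seqs.size(); ++i) {
        std::string s = as<std::string>(seqs[i]);
        int off = offsets[i];
        int w = weights[i];
        for (int j = 0; j < (int)s.size(); ++j) {
            int col = off + j;
            if (col < 0 || col >= width) continue;
            int c = base2code(s[j]);
            out((c < 0) ? 4 : c, col) += w;
        }
    }
    return out;
}

// Overlap-merge mate pairs.  seq2/qual2 are given as sequenced (reverse
// strand); they are reverse-complemented internally.  The best overlap o in
// [min_overlap, min(l1, l2)] with mismatch fraction <= max_mm_frac and
// maximal score (matches - mismatches; ties -> larger o) is used; overlap
// bases take the higher-quality call (tie -> read 1).  Merged fragments are
// truncated to max_len from the 3' end.
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector seq1, CharacterVector qual1,
                     CharacterVector seq2, CharacterVector qual2,
                     int min_overlap, double max_mm_frac, int max_len) {
    int n = seq1.size();
    CharacterVector mseq(n), mqual(n);
    LogicalVector ok(n);
    for (int i = 0; i < n; ++i) {
        std::string s1 = as<std::string>(seq1[i]);
        std::string q1 = as<std::string>(qual1[i]);
        std::string s2 = revcomp_str(as<std::string>(seq2[i]));
        std::string q2 = as<std::string>(qual2[i]);
        std::reverse(q2.begin(), q2.end());
        int l1 = (int)s1.size(), l2 = (int)s2.size();
        int best_o = -1, best_score = INT_MIN;
        int maxo = std::min(l1, l2);
        for (int o = maxo; o >= min_overlap; --o) {
            int mism = 0;
            for (int j = 0; j < o; ++j)
                if (s1[l1 - o + j] != s2[j]) ++mism;
            if ((double)mism > max_mm_frac * o) continue;
            int score = (o - mism) - mism;
            if (score > best_score) { best_score = score; best_o = o; }
        }
        if (best_o < 0) {
            mseq[i] = NA_STRING; mqual[i] = NA_STRING; ok[i] = false;
            continue;
        }
        int o = best_o;
        std::string ms = s1.substr(0, l1 - o);
        std::string mq = q1.substr(0, l1 - o);
        for (int j = 0; j < o; ++j) {
            char b1 = s1[l1 - o + j], b2 = s2[j];
            char c1 = q1[l1 - o + j], c2 = q2[j];
            if (c2 > c1) { ms += b2; mq += c2; }
            else { ms += b1; mq += c1; }
        }
        ms += s2.substr(o);
        mq += q2.substr(o);
        if ((int)ms.size() > max_len) {
            ms = ms.substr(0, max_len);
            mq = mq.substr(0, max_len);
        }
        mseq[i] = ms; mqual[i] = mq; ok[i] = true;
    }
    return List::create(_["seq"] = mseq, _["qual"] = mqual, _["merged"] = ok);
}

// Adapter (3' suffix, semi-global prefix match with >= 5 bp overlap and
// mismatch fraction <= adapter_mm_frac) removal followed by 3' trimming of
// bases below tail_q.  Qualities are Phred+33.
// [[Rcpp::export]]
List cpp_quality_trim(CharacterVector seqs, CharacterVector quals,
                      int tail_q, CharacterVector adapters,
                      double adapter_mm_frac = 0.1) {
    int n = seqs.size();
    CharacterVector oseq(n), oqual(n);
    NumericVector meanq(n);
    std::vector<std::string> ads;
    for (int a = 0; a < adapters.size(); ++a)
        ads.push_back(as<std::string>(adapters[a]));
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(seqs[i]);
        std::string q = as<std::string>(quals[i]);
        int len = (int)s.size();
        // adapter: leftmost start such that the read suffix matches an
        // adapter prefix
        int cut = len;
        for (size_t a = 0; a < ads.size(); ++a) {
            const std::string& ad = ads[a];
            for (int p = 0; p <= len - 5; ++p) {
                int ov = std::min(len - p, (int)ad.size());
                if (ov < 5) break;
                int mism = 0;
                for (int j = 0; j < ov; ++j)
                    if (s[p + j] != ad[j]) ++mism;
                if ((double)mism <= adapter_mm_frac * ov) {
                    if (p < cut) cut = p;
                    break;
                }
            }
        }
        len = cut;
        while (len > 0 && (int)q[len - 1] - 33 < tail_q) --len;
        oseq[i] = s.substr(0, len);
        oqual[i] = q.substr(0, len);
        double sum = 0;
        for (int j = 0; j < len; ++j) sum += (int)q[j] - 33;
        meanq[i] = (len > 0) ? sum / len : 0.0;
    }
    return List::create(_["seq"] = oseq, _["qual"] = oqual,
                        _["mean_q"] = meanq);
}

// Fraction of each read's canonical k-mers present in the canonical k-mer
// set of the reference sequences.  Reads shorter than k get NA.
// [[Rcpp::export]]
NumericVector cpp_kmer_fraction(CharacterVector reads, CharacterVector refs,
                                int k) {
    std::unordered_set<uint64_t> refset;
    std::vector<std::pair<uint64_t,int> > kms;
    for (int r = 0; r < refs.size(); ++r) {
        std::string s = as<std::string>(refs[r]);
        kms.clear();
        collect_kmers(s, k, kms);
        for (size_t j = 0; j < kms.size(); ++j) refset.insert(kms[j].first);
        std::string rc = revcomp_str(s);
        kms.clear();
        collect_kmers(rc, k, kms);
        for (size_t j = 0; j < kms.size(); ++j) refset.insert(kms[j].first);
    }
    int n = reads.size();
    NumericVector out(n);
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(reads[i]);
        kms.clear();
        collect_kmers(s, k, kms);
        if (kms.empty()) { out[i] = NA_REAL; continue; }
        int hit = 0;
        for (size_t j = 0; j < kms.size(); ++j)
            if (refset.count(kms[j].first)) ++hit;
        out[i] = (double)hit / (double)kms.size();
    }
    return out;
}

// Hamming distance over the common prefix plus the length difference
// (i.e. mismatches of the diagonal-0 alignment with end gaps as mismatches).
// [[Rcpp::export]]
IntegerVector cpp_hamming(CharacterVector a, CharacterVector b) {
    int n = std::max(a.size(), b.size());
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
        std::string x = as<std::string>(a[a.size() == 1 ? 0 : i]);
        std::string y = as<std::string>(b[b.size() == 1 ? 0 : i]);
        int m = (int)std::min(x.size(), y.size());
        int d = (int)(std::max(x.size(), y.size()) - m);
        for (int j = 0; j < m; ++j) if (x[j] != y[j]) ++d;
        out[i] = d;
    }
    return out;
}
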