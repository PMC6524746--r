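// k-mer index and equivalence-class assignment for error-free reads.
// Transcript indices are 0-based internally, 1-based at the R boundary.
#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

namespace {

// 2-bit encoding; k <= 31 so a k-mer fits in 62 bits.
inline int base2bits(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

struct EcIndex {
    int k;
    int n_tx;
    std::vector<std::string> tx_names;
    std::vector<std::vector<int> > sets;        // deduplicated transcript sets, sorted
    std::unordered_map<uint64_t, int> kmer2set; // k-mer -> index into sets
};

// Enumerate valid k-mer codes of seq; cb(pos, code). Positions with non-ACGT
// characters inside the window are skipped (no valid code).
template <typename F>
void for_each_kmer(const std::string& seq, int k, F cb, bool error_on_bad = false) {
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    uint64_t code = 0;
    int run = 0; // number of consecutive valid bases ending here
    for (size_t i = 0; i < seq.size(); ++i) {
        int b = base2bits(seq[i]);
        if (b < 0) {
            if (error_on_bad)
                stop("non-ACGT character '%s' at position %d",
                     std::string(1, seq[i]).c_str(), (int)(i + 1));
            run = 0;
            code = 0;
            continue;
        }
        code = ((code << 2) | (uint64_t)b) & mask;
        if (++run >= k) cb((int)(i + 1 - k), code);
    }
}

std::string decode_kmer(uint64_t code, int k) {
    static const char* b = "ACGT";
    std::string s(k, 'A');
    for (int i = k - 1; i >= 0; --i) {
        s[i] = b[code & 3ULL];
        code >>= 2;
    }
    return s;
}

// Intersect sorted int vectors.
std::vector<int> intersect_sorted(const std::vector<int>& a, const std::vector<int>& b) {
    std::vector<int> out;
    size_t i = 0, j = 0;
    while (i < a.size() && j < b.size()) {
        if (a[i] < b[j]) ++i;
        else if (b[j] < a[i]) ++j;
        else { out.push_back(a[i]); ++i; ++j; }
    }
    return out;
}

// Registry that deduplicates result transcript sets and hands out 1-based ids.
struct SetRegistry {
    std::map<std::vector<int>, int> ids;
    std::vector<const std::vector<int>*> order;
    int id_for(const std::vector<int>& s) {
        auto it = ids.find(s);
        if (it != ids.end()) return it->second;
        int id = (int)ids.size() + 1;
        auto res = ids.emplace(s, id);
        order.push_back(&res.first->first);
        return id;
    }
    List as_list() const {
        List out(order.size());
        for (size_t i = 0; i < order.size(); ++i) {
            const std::vector<int>& s = *order[i];
            IntegerVector v(s.size());
            for (size_t j = 0; j < s.size(); ++j) v[j] = s[j] + 1; // 1-based
            out[i] = v;
        }
        return out;
    }
};

// Assign one sequence: intersection of index sets over its k-mers present in
// the index; absent k-mers are skipped. Returns empty vector if unassigned.
std::vector<int> assign_seq(const EcIndex& idx, const std::string& seq) {
    std::vector<int> cur;
    bool any = false, empty = false;
    std::vector<int> seen_sets; // small cache of set ids already intersected
    for_each_kmer(seq, idx.k, [&](int, uint64_t code) {
        if (empty) return;
        auto it = idx.kmer2set.find(code);
        if (it == idx.kmer2set.end()) return; // skip-absent rule
        int sid = it->second;
        for (size_t i = 0; i < seen_sets.size(); ++i)
            if (seen_sets[i] == sid) return;
        seen_sets.push_back(sid);
        if (!any) { cur = idx.sets[sid]; any = true; }
        else cur = intersect_sorted(cur, idx.sets[sid]);
        if (cur.empty()) empty = true;
    });
    if (!any || empty) return std::vector<int>();
    return cur;
}

EcIndex* get_index(SEXP xp) {
    Rcpp::XPtr<EcIndex> p(xp);
    if (!p) stop("invalid k-mer index pointer (was it saved and reloaded?)");
    return p.get();
}

} // namespace

// [[Rcpp::export(name = ".cpp_build_index")]]
SEXP cpp_build_index(CharacterVector seqs, CharacterVector names, int k) {
    if (k < 3 || k > 31) stop("k must be between 3 and 31");
    EcIndex* idx = new EcIndex();
    idx->k = k;
    idx->n_tx = seqs.size();
    std::unordered_map<uint64_t, std::vector<int> > table;
    std::vector<bool> skipped(seqs.size(), false);
    for (int t = 0; t < seqs.size(); ++t) {
        std::string s = as<std::string>(seqs[t]);
        idx->tx_names.push_back(as<std::string>(names[t]));
        if ((int)s.size() < k) { skipped[t] = true; continue; }
        for_each_kmer(s, k, [&](int, uint64_t code) {
            std::vector<int>& v = table[code];
            if (v.empty() || v.back() != t) v.push_back(t);
        }, /*error_on_bad=*/true);
    }
    int n_skipped = 0;
    for (size_t t = 0; t < skipped.size(); ++t) if (skipped[t]) ++n_skipped;
    if (n_skipped > 0)
        warning("%d transcript(s) shorter than k = %d were skipped", n_skipped, k);
    // Deduplicate transcript sets.
    std::map<std::vector<int>, int> set_ids;
    for (auto& kv : table) {
        auto it = set_ids.find(kv.second);
        int sid;
        if (it == set_ids.end()) {
            sid = (int)idx->sets.size();
            set_ids.emplace(kv.second, sid);
            idx->sets.push_back(kv.second);
        } else sid = it->second;
        idx->kmer2set.emplace(kv.first, sid);
    }
    Rcpp::XPtr<EcIndex> ptr(idx, true);
    return ptr;
}

// [[Rcpp::export(name = ".cpp_index_info")]]
List cpp_index_info(SEXP xp) {
    EcIndex* idx = get_index(xp);
    return List::create(_["k"] = idx->k,
                        _["n_kmers"] = (double)idx->kmer2set.size(),
                        _["n_sets"] = (int)idx->sets.size(),
                        _["n_transcripts"] = idx->n_tx);
}

// Full k-mer -> transcript-set table; intended for small toy indices.
// [[Rcpp::export(name = ".cpp_dump_table")]]
List cpp_dump_table(SEXP xp) {
    EcIndex* idx = get_index(xp);
    if (idx->kmer2set.size() > 2000000) stop("index too large to dump");
    size_t n = idx->kmer2set.size();
    CharacterVector kmers(n);
    List sets(n);
    size_t i = 0;
    for (auto& kv : idx->kmer2set) {
        kmers[i] = decode_kmer(kv.first, idx->k);
        const std::vector<int>& s = idx->sets[kv.second];
        IntegerVector v(s.size());
        for (size_t j = 0; j < s.size(); ++j) v[j] = s[j] + 1;
        sets[i] = v;
        ++i;
    }
    return List::create(_["kmer"] = kmers, _["transcripts"] = sets);
}

// Assign reads; returns ids (1-based into sets, NA = unassigned) and the
// distinct assigned transcript sets.
// [[Rcpp::export(name = ".cpp_assign_reads")]]
List cpp_assign_reads(SEXP xp, CharacterVector reads) {
    EcIndex* idx = get_index(xp);
    SetRegistry reg;
    IntegerVector ids(reads.size());
    for (int i = 0; i < reads.size(); ++i) {
        std::string s = as<std::string>(reads[i]);
        std::vector<int> res = assign_seq(*idx, s);
        ids[i] = res.empty() ? NA_INTEGER : reg.id_for(res);
    }
    return List::create(_["id"] = ids, _["sets"] = reg.as_list());
}

// Paired-end: intersect the mates' compatibility sets; a mate with no
// informative k-mer contributes no constraint.
// [[Rcpp::export(name = ".cpp_assign_pairs")]]
List cpp_assign_pairs(SEXP xp, CharacterVector r1, CharacterVector r2) {
    EcIndex* idx = get_index(xp);
    if (r1.size() != r2.size()) stop("mate vectors differ in length");
    SetRegistry reg;
    IntegerVector ids(r1.size());
    for (int i = 0; i < r1.size(); ++i) {
        std::vector<int> a = assign_seq(*idx, as<std::string>(r1[i]));
        std::vector<int> b = assign_seq(*idx, as<std::string>(r2[i]));
        std::vector<int> res;
        if (!a.empty() && !b.empty()) res = intersect_sorted(a, b);
        else if (!a.empty()) res = a;
        else res = b;
        ids[i] = res.empty() ? NA_INTEGER : reg.id_for(res);
    }
    return List::create(_["id"] = ids, _["sets"] = reg.as_list());
}

// For every read start position of every transcript, the equivalence class a
// read of length read_len starting there is assigned to. Fast path for the
// simulator: EC probabilities per transcript without materialising reads.
// [[Rcpp::export(name = ".cpp_position_sets")]]
List cpp_position_sets(SEXP xp, CharacterVector seqs, int read_len) {
    EcIndex* idx = get_index(xp);
    int k = idx->k;
    if (read_len < k) stop("read_len must be >= k");
    SetRegistry reg;
    List per_tx(seqs.size());
    for (int t = 0; t < seqs.size(); ++t) {
        std::string s = as<std::string>(seqs[t]);
        int L = (int)s.size();
        int n_pos = L - read_len + 1;
        if (n_pos < 1) { per_tx[t] = IntegerVector(0); continue; }
        int n_kpos = L - k + 1;
        // set id per k-mer position (-1 = absent from index)
        std::vector<int> sid(n_kpos, -1);
        for_each_kmer(s, k, [&](int pos, uint64_t code) {
            auto it = idx->kmer2set.find(code);
            if (it != idx->kmer2set.end()) sid[pos] = it->second;
        });
        IntegerVector out(n_pos);
        int w = read_len - k + 1; // k-mers per window
        std::vector<int> prev_ids;
        int prev_res = NA_INTEGER;
        std::vector<int> cur_ids;
        for (int p = 0; p < n_pos; ++p) {
            cur_ids.clear();
            for (int j = p; j < p + w; ++j) {
                int id = sid[j];
                if (id < 0) continue;
                bool seen = false;
                for (size_t q = 0; q < cur_ids.size(); ++q)
                    if (cur_ids[q] == id) { seen = true; break; }
                if (!seen) cur_ids.push_back(id);
            }
            if (p > 0 && cur_ids == prev_ids) { out[p] = prev_res; continue; }
            if (cur_ids.empty()) out[p] = NA_INTEGER;
            else {
                std::vector<int> res = idx->sets[cur_ids[0]];
                for (size_t q = 1; q < cur_ids.size() && !res.empty(); ++q)
                    res = intersect_sorted(res, idx->sets[cur_ids[q]]);
                out[p] = res.empty() ? NA_INTEGER : reg.id_for(res);
            }
            prev_ids = cur_ids;
            prev_res = out[p];
        }
        per_tx[t] = out;
    }
    return List::create(_["positions"] = per_tx, _["sets"] = reg.as_list());
}
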