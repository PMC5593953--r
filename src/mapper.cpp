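// Minimal seed-and-extend read mapper over a composite (genome + vector)
// reference. Seeds are exact k-mers sampled along the read; each candidate
// diagonal is scored by an ungapped best-local-segment scan (match +1,
// mismatch -4), so reads overhanging a junction come back end-clipped.
// No gapped alignment: the simulator's error model is substitution-only.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <unordered_map>
#include <algorithm>

using namespace Rcpp;

namespace {

const int MATCH_SCORE = 1;
const int MISMATCH_SCORE = -4;

inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
  }
  return 'N';
}

std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) c = comp(c);
  return r;
}

struct SeedIndexCpp {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  // k-mer -> packed (contig << 40 | position); forward strand of the
  // reference only, query strand recovered by aligning the reverse
  // complement of the read.
  std::unordered_map<uint64_t, std::vector<uint64_t>> tab;
  uint64_t n_positions;
};

// one candidate ungapped placement of (possibly reverse-complemented) read
struct Placement {
  int contig;
  int pos;        // 0-based leftmost reference position of aligned segment
  int strand;     // +1 forward, -1 reverse
  int qs, qe;     // aligned query interval, reference orientation, half-open
  int nm;         // mismatches within the aligned segment
  int score;
  bool unique;
  int rank;
};

// best-scoring contiguous segment of the read along one diagonal
void scan_diagonal(const std::string& q, const std::string& ref, long diag,
                   int& best_qs, int& best_qe, int& best_nm, int& best_score) {
  const int L = (int)q.size();
  const long clen = (long)ref.size();
  int cur = 0, cur_start = 0, cur_nm = 0;
  best_score = 0; best_qs = 0; best_qe = 0; best_nm = 0;
  for (int i = 0; i < L; ++i) {
    long rp = diag + i;
    if (rp < 0 || rp >= clen) {        // off-contig: hard barrier
      cur = 0; cur_start = i + 1; cur_nm = 0;
      continue;
    }
    if (cur <= 0) { cur = 0; cur_start = i; cur_nm = 0; }
    if (q[i] == ref[(size_t)rp]) {
      cur += MATCH_SCORE;
    } else {
      cur += MISMATCH_SCORE;
      cur_nm++;
    }
    if (cur > best_score) {
      best_score = cur;
      best_qs = cur_start;
      best_qe = i + 1;
      // mismatches counted since cur_start, minus any trailing run that a
      // later reset would drop; recompute below for exactness
      best_nm = cur_nm;
    }
  }
  // trim mismatches at segment edges cannot occur (segment ends on a match
  // by construction of the maximum), but best_nm may include mismatches
  // before a dip that stayed positive; it is exact for this scan because
  // cur_nm resets only when cur resets.
}

}  // namespace

// [[Rcpp::export(name = ".cpp_build_index")]]
SEXP cpp_build_index(CharacterVector names, CharacterVector seqs, int k) {
  SeedIndexCpp* idx = new SeedIndexCpp();
  idx->k = k;
  idx->n_positions = 0;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int c = 0; c < names.size(); ++c) {
    idx->names.push_back(as<std::string>(names[c]));
    idx->seqs.push_back(as<std::string>(seqs[c]));
  }
  for (size_t c = 0; c < idx->seqs.size(); ++c) {
    const std::string& s = idx->seqs[c];
    if ((int)s.size() < k) continue;
    uint64_t kmer = 0;
    int valid = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)b) & mask;
      valid++;
      if (valid >= k) {
        uint64_t pos = i + 1 - k;
        idx->tab[kmer].push_back(((uint64_t)c << 40) | pos);
        idx->n_positions++;
      }
    }
  }
  XPtr<SeedIndexCpp> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export(name = ".cpp_index_info")]]
List cpp_index_info(SEXP xp) {
  XPtr<SeedIndexCpp> idx(xp);
  IntegerVector lens(idx->names.size());
  for (size_t i = 0; i < idx->seqs.size(); ++i) lens[i] = (int)idx->seqs[i].size();
  return List::create(
    _["k"] = idx->k,
    _["contig"] = wrap(idx->names),
    _["length"] = lens,
    _["n_positions"] = (double)idx->n_positions,
    _["n_kmers"] = (double)idx->tab.size());
}

// [[Rcpp::export(name = ".cpp_index_lookup")]]
DataFrame cpp_index_lookup(SEXP xp, std::string kmer) {
  XPtr<SeedIndexCpp> idx(xp);
  std::vector<std::string> contig;
  std::vector<int> pos;
  if ((int)kmer.size() == idx->k) {
    uint64_t key = 0;
    bool ok = true;
    for (char c : kmer) {
      int b = base2bit(c);
      if (b < 0) { ok = false; break; }
      key = (key << 2) | (uint64_t)b;
    }
    if (ok) {
      auto it = idx->tab.find(key);
      if (it != idx->tab.end()) {
        for (uint64_t p : it->second) {
          contig.push_back(idx->names[p >> 40]);
          pos.push_back((int)(p & ((1ULL << 40) - 1)));
        }
      }
    }
  }
  return DataFrame::create(_["contig"] = contig, _["pos"] = pos,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export(name = ".cpp_align_batch")]]
DataFrame cpp_align_batch(SEXP xp, CharacterVector reads,
                          int seed_step, int margin, double max_mismatch_rate,
                          int min_seg, int max_hits_per_seed, int max_records) {
  XPtr<SeedIndexCpp> idx(xp);
  const int k = idx->k;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  std::vector<int> out_qid, out_contig, out_pos, out_clip5, out_clip3,
      out_alen, out_nm, out_score, out_rank;
  std::vector<int> out_strand;
  std::vector<int> out_unique;

  std::vector<std::pair<uint64_t, long>> cand;  // (contig<<1|strandbit, diag)
  std::vector<Placement> placements, picked;

  for (int r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    const int L = (int)fwd.size();
    if (L < k) continue;
    std::string rev = revcomp(fwd);
    cand.clear();
    placements.clear();
    picked.clear();

    for (int strand = 0; strand < 2; ++strand) {
      const std::string& q = strand == 0 ? fwd : rev;
      // seed offsets every seed_step, always including the final offset
      for (int o = 0; o <= L - k; o += seed_step) {
        int off = o;
        bool last_extra = false;
        if (o + seed_step > L - k && o != L - k) { last_extra = true; }
        for (int rep = 0; rep < (last_extra ? 2 : 1); ++rep) {
          if (rep == 1) off = L - k;
          uint64_t key = 0;
          bool ok = true;
          for (int i = 0; i < k; ++i) {
            int b = base2bit(q[off + i]);
            if (b < 0) { ok = false; break; }
            key = ((key << 2) | (uint64_t)b) & mask;
          }
          if (!ok) continue;
          auto it = idx->tab.find(key);
          if (it == idx->tab.end()) continue;
          if ((int)it->second.size() > max_hits_per_seed) continue;
          for (uint64_t p : it->second) {
            uint64_t contig = p >> 40;
            long pos = (long)(p & ((1ULL << 40) - 1));
            cand.push_back({(contig << 1) | (uint64_t)strand, pos - off});
          }
        }
      }
    }
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());

    for (auto& cd : cand) {
      int contig = (int)(cd.first >> 1);
      int strand = (int)(cd.first & 1);
      const std::string& q = strand == 0 ? fwd : rev;
      int qs, qe, nm, score;
      scan_diagonal(q, idx->seqs[contig], cd.second, qs, qe, nm, score);
      int alen = qe - qs;
      if (alen < min_seg) continue;
      if (nm > max_mismatch_rate * alen) continue;
      Placement pl;
      pl.contig = contig;
      pl.pos = (int)(cd.second + qs);
      pl.strand = strand == 0 ? 1 : -1;
      pl.qs = qs; pl.qe = qe; pl.nm = nm; pl.score = score;
      pl.unique = false; pl.rank = 0;
      placements.push_back(pl);
    }
    if (placements.empty()) continue;

    std::sort(placements.begin(), placements.end(),
              [](const Placement& a, const Placement& b) {
                if (a.score != b.score) return a.score > b.score;
                if (a.contig != b.contig) return a.contig < b.contig;
                if (a.pos != b.pos) return a.pos < b.pos;
                return a.strand > b.strand;
              });

    // query-interval overlap in the original read orientation
    auto orig_iv = [L](const Placement& p, int& s, int& e) {
      if (p.strand > 0) { s = p.qs; e = p.qe; }
      else { s = L - p.qe; e = L - p.qs; }
    };
    auto overlaps = [&](const Placement& a, const Placement& b) {
      int as, ae, bs, be;
      orig_iv(a, as, ae); orig_iv(b, bs, be);
      int ov = std::min(ae, be) - std::max(as, bs);
      int shorter = std::min(ae - as, be - bs);
      return ov * 2 > shorter;  // > 50% of the shorter segment
    };

    // greedy primary + non-overlapping supplementary placements
    std::vector<bool> used(placements.size(), false);
    for (int rank = 1; rank <= max_records; ++rank) {
      int pick = -1;
      for (size_t i = 0; i < placements.size(); ++i) {
        if (used[i]) continue;
        bool clash = false;
        for (auto& pk : picked)
          if (overlaps(placements[i], pk)) { clash = true; break; }
        if (!clash) { pick = (int)i; break; }
      }
      if (pick < 0) break;
      Placement pl = placements[pick];
      pl.rank = rank;
      // unique iff no competing (query-overlapping) placement scores within
      // `margin` of this one
      pl.unique = true;
      for (size_t i = 0; i < placements.size(); ++i) {
        if ((int)i == pick) continue;
        if (placements[i].score > pl.score - margin &&
            overlaps(placements[i], pl)) { pl.unique = false; break; }
      }
      picked.push_back(pl);
      for (size_t i = 0; i < placements.size(); ++i)
        if (!used[i] && overlaps(placements[i], picked.back())) used[i] = true;
    }

    for (auto& pl : picked) {
      out_qid.push_back(r + 1);
      out_contig.push_back(pl.contig + 1);
      out_pos.push_back(pl.pos);
      out_strand.push_back(pl.strand);
      out_clip5.push_back(pl.qs);            // reference orientation
      out_clip3.push_back(L - pl.qe);
      out_alen.push_back(pl.qe - pl.qs);
      out_nm.push_back(pl.nm);
      out_score.push_back(pl.score);
      out_unique.push_back(pl.unique ? 1 : 0);
      out_rank.push_back(pl.rank);
    }
  }

  return DataFrame::create(
    _["qid"] = out_qid, _["contig_id"] = out_contig, _["pos"] = out_pos,
    _["strand"] = out_strand, _["clip5"] = out_clip5, _["clip3"] = out_clip3,
    _["alen"] = out_alen, _["nm"] = out_nm, _["score"] = out_score,
    _["unique"] = out_unique, _["rank"] = out_rank,
    _["stringsAsFactors"] = false);
}
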