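#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// 2-bit encode A/C/G/T; anything else (ambiguity codes, N in reads) -> -1.
static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  case 'N': return 'N';
  default:  return 'N'; // ambiguity codes in reads are not resolved; they
                        // simply mismatch during extension
  }
}

// Ungapped seed-and-extend alignment of short reads against a catalog of
// gap-free genomes. Exact-match seeding on non-overlapping k-mers of the
// read (plus one k-mer anchored at the read end), both strands, against a
// hash index of all genome k-mers; candidates extended by full-length
// Hamming comparison. With n_seeds >= max_mismatches + 1 at least one seed
// is uncontaminated, so every locus within that mismatch budget is found.
// [[Rcpp::export]]
List cpp_builtin_align(CharacterVector read_ids, CharacterVector reads,
                       CharacterVector genome_ids, CharacterVector genomes,
                       int k) {
  const int ng = genomes.size();
  const int nr = reads.size();

  std::vector<std::string> gseq(ng);
  for (int g = 0; g < ng; ++g) gseq[g] = as<std::string>(genomes[g]);

  // k-mer index: 2-bit packed k-mer -> list of (genome, 0-based start)
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>> index;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  {
    size_t total = 0;
    for (int g = 0; g < ng; ++g)
      if ((int)gseq[g].size() >= k) total += gseq[g].size() - k + 1;
    index.reserve(total * 13 / 10);
  }
  for (int g = 0; g < ng; ++g) {
    const std::string &s = gseq[g];
    uint64_t key = 0;
    int valid = 0;
    for (int i = 0; i < (int)s.size(); ++i) {
      int c = base_code(s[i]);
      if (c < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++valid >= k) index[key].emplace_back(g, i - k + 1);
    }
  }

  std::vector<std::string> out_read;
  std::vector<int> out_gidx;   // 1-based genome index, NA = 0
  std::vector<int> out_pos;    // 1-based
  std::vector<int> out_mm;
  std::vector<int> out_score;
  std::vector<int> out_len;
  std::vector<bool> out_rev;
  std::vector<bool> out_mapped;
  out_read.reserve(nr * 2);

  for (int r = 0; r < nr; ++r) {
    const std::string fwd = as<std::string>(reads[r]);
    const int len = (int)fwd.size();
    const std::string rid = as<std::string>(read_ids[r]);
    bool any = false;

    if (len >= k) {
      std::string rev(len, 'N');
      for (int i = 0; i < len; ++i) rev[i] = comp_base(fwd[len - 1 - i]);

      // distinct candidate loci across both strands
      std::unordered_set<uint64_t> seen;

      for (int strand = 0; strand < 2; ++strand) {
        const std::string &q = strand ? rev : fwd;

        std::vector<int> offsets;
        for (int o = 0; o + k <= len; o += k) offsets.push_back(o);
        if (offsets.empty() || offsets.back() != len - k)
          offsets.push_back(len - k);

        for (int o : offsets) {
          uint64_t key = 0;
          bool ok = true;
          for (int j = 0; j < k; ++j) {
            int c = base_code(q[o + j]);
            if (c < 0) { ok = false; break; }
            key = ((key << 2) | (uint64_t)c) & mask;
          }
          if (!ok) continue;
          auto it = index.find(key);
          if (it == index.end()) continue;
          for (auto &hit : it->second) {
            const int g = hit.first;
            const long start = (long)hit.second - o; // 0-based
            if (start < 0 || start + len > (long)gseq[g].size()) continue;
            uint64_t ck = ((uint64_t)g << 33) | ((uint64_t)start << 1) |
                          (uint64_t)strand;
            if (!seen.insert(ck).second) continue;
            // full-read Hamming extension
            const std::string &s = gseq[g];
            int mm = 0;
            for (int j = 0; j < len; ++j)
              if (s[start + j] != q[j]) ++mm;
            out_read.push_back(rid);
            out_gidx.push_back(g + 1);
            out_pos.push_back((int)start + 1);
            out_mm.push_back(mm);
            out_score.push_back(len - 5 * mm);
            out_len.push_back(len);
            out_rev.push_back(strand == 1);
            out_mapped.push_back(true);
            any = true;
          }
        }
      }
    }

    if (!any) {
      out_read.push_back(rid);
      out_gidx.push_back(0);
      out_pos.push_back(NA_INTEGER);
      out_mm.push_back(NA_INTEGER);
      out_score.push_back(NA_INTEGER);
      out_len.push_back(len);
      out_rev.push_back(false);
      out_mapped.push_back(false);
    }
  }

  const int n = (int)out_read.size();
  CharacterVector rcol(n), gcol(n);
  IntegerVector pos(n), mm(n), score(n), rlen(n);
  LogicalVector rev(n), mapped(n);
  for (int i = 0; i < n; ++i) {
    rcol[i] = out_read[i];
    gcol[i] = out_gidx[i] > 0 ? genome_ids[out_gidx[i] - 1] : NA_STRING;
    pos[i] = out_pos[i];
    mm[i] = out_mm[i];
    score[i] = out_score[i];
    rlen[i] = out_len[i];
    rev[i] = out_rev[i];
    mapped[i] = out_mapped[i];
  }
  return List::create(_["read_id"] = rcol, _["genome_id"] = gcol,
                      _["pos"] = pos, _["mismatches"] = mm,
                      _["align_score"] = score, _["read_len"] = rlen,
                      _["is_reverse"] = rev, _["is_mapped"] = mapped);
}

// Plant i.i.d. substitutions at given (read, position) pairs; replacement
// bases are provided by the caller (drawn from R's RNG for determinism).
// [[Rcpp::export]]
CharacterVector cpp_apply_substitutions(CharacterVector seqs,
                                        IntegerVector read_idx,
                                        IntegerVector pos,
                                        CharacterVector bases) {
  CharacterVector out = clone(seqs);
  // group consecutive edits to the same read to avoid repeated conversion
  int i = 0;
  const int n = read_idx.size();
  while (i < n) {
    int j = i;
    const int r = read_idx[i];
    std::string s = as<std::string>(out[r - 1]);
    while (j < n && read_idx[j] == r) {
      const char b = as<std::string>(bases[j])[0];
      const int p = pos[j] - 1;
      if (p >= 0 && p < (int)s.size()) {
        if (s[p] == b) {
          // substitute with a different base deterministically (cyclic shift)
          const char *acgt = "ACGT";
          int c = base_code(s[p]);
          s[p] = (c < 0) ? b : acgt[(c + 1) % 4];
        } else {
          s[p] = b;
        }
      }
      ++j;
    }
    out[r - 1] = s;
    i = j;
  }
  return out;
}
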