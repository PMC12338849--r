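// Byte-level subword tokenizer kernels: BPE (greedy pair merging) and a
// unigram language model (EM over a substring seed vocabulary with Viterbi
// segmentation). Both operate on raw UTF-8 bytes with the 256 single-byte
// tokens permanently in the vocabulary, so any string round-trips exactly.
#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

typedef std::vector<int> Seq;

static std::vector<Seq> seqs_from_list(List seqs) {
  std::vector<Seq> out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    RawVector r = seqs[i];
    Seq s(r.size());
    for (R_xlen_t j = 0; j < r.size(); ++j) s[j] = (int)r[j];
    out[i] = s;
  }
  return out;
}

// ---------------------------------------------------------------- BPE ----

static inline uint64_t pair_key(int a, int b) {
  return ((uint64_t)(uint32_t)a << 32) | (uint32_t)b;
}

// seqs: unique corpus lines as raw vectors; counts: line multiplicities.
// Returns the ordered merge table; merge row k creates token id 256 + k.
// Pair counts are maintained incrementally with an occurrence index
// (pair -> sequences possibly containing it), so each merge only rescans
// the affected lines.
// [[Rcpp::export(name = ".bpe_train")]]
IntegerMatrix bpe_train_(List seqs, IntegerVector counts, int vocab_size,
                         int min_pair_count = 2) {
  std::vector<Seq> corpus = seqs_from_list(seqs);
  int max_merges = vocab_size - 256;
  if (max_merges < 0) max_merges = 0;
  std::vector<std::pair<int, int> > merges;
  merges.reserve(max_merges);

  std::unordered_map<uint64_t, long long> pairs;
  std::unordered_map<uint64_t, std::vector<int> > occ; // may hold stale entries
  for (size_t i = 0; i < corpus.size(); ++i) {
    const Seq& s = corpus[i];
    long long w = counts[i];
    for (size_t j = 0; j + 1 < s.size(); ++j) {
      uint64_t key = pair_key(s[j], s[j + 1]);
      if (pairs[key] == 0 || occ[key].empty() || occ[key].back() != (int)i)
        occ[key].push_back((int)i);
      pairs[key] += w;
    }
  }

  while ((int)merges.size() < max_merges && !pairs.empty()) {
    uint64_t best_key = 0;
    long long best_count = -1;
    for (std::unordered_map<uint64_t, long long>::const_iterator it = pairs.begin();
         it != pairs.end(); ++it) {
      // deterministic tie-break: smaller (left, right) id pair wins
      if (it->second > best_count ||
          (it->second == best_count && it->first < best_key)) {
        best_count = it->second;
        best_key = it->first;
      }
    }
    if (best_count < min_pair_count) break;
    int a = (int)(best_key >> 32), b = (int)(best_key & 0xffffffffu);
    int new_id = 256 + (int)merges.size();
    merges.push_back(std::make_pair(a, b));

    std::vector<int> hits;
    std::unordered_map<uint64_t, std::vector<int> >::iterator oit = occ.find(best_key);
    if (oit != occ.end()) { hits.swap(oit->second); occ.erase(oit); }
    std::sort(hits.begin(), hits.end());
    hits.erase(std::unique(hits.begin(), hits.end()), hits.end());
    for (size_t hi = 0; hi < hits.size(); ++hi) {
      Seq& s = corpus[hits[hi]];
      long long w = counts[hits[hi]];
      if (s.size() < 2) continue;
      bool present = false;
      for (size_t j = 0; j + 1 < s.size(); ++j)
        if (s[j] == a && s[j + 1] == b) { present = true; break; }
      if (!present) continue;
      // retire this line's old pair counts, merge, then re-add
      for (size_t j = 0; j + 1 < s.size(); ++j) {
        uint64_t key = pair_key(s[j], s[j + 1]);
        std::unordered_map<uint64_t, long long>::iterator pit = pairs.find(key);
        if (pit != pairs.end() && (pit->second -= w) <= 0) pairs.erase(pit);
      }
      size_t wr = 0;
      for (size_t j = 0; j < s.size(); ++j) {
        if (j + 1 < s.size() && s[j] == a && s[j + 1] == b) {
          s[wr++] = new_id;
          ++j;
        } else {
          s[wr++] = s[j];
        }
      }
      s.resize(wr);
      for (size_t j = 0; j + 1 < s.size(); ++j) {
        uint64_t key = pair_key(s[j], s[j + 1]);
        std::vector<int>& v = occ[key];
        if (v.empty() || v.back() != hits[hi]) v.push_back(hits[hi]);
        pairs[key] += w;
      }
    }
    pairs.erase(best_key);
  }
  IntegerMatrix out(merges.size(), 2);
  for (size_t k = 0; k < merges.size(); ++k) {
    out(k, 0) = merges[k].first;
    out(k, 1) = merges[k].second;
  }
  return out;
}

// Apply merges in training order (rank = priority), lowest rank first.
// [[Rcpp::export(name = ".bpe_encode_many")]]
List bpe_encode_many_(List texts, IntegerMatrix merges) {
  std::unordered_map<uint64_t, std::pair<int, int> > rank; // pair -> (rank, new id)
  for (int k = 0; k < merges.nrow(); ++k) {
    uint64_t key = ((uint64_t)(uint32_t)merges(k, 0) << 32) | (uint32_t)merges(k, 1);
    if (rank.find(key) == rank.end())
      rank[key] = std::make_pair(k, 256 + k);
  }
  std::vector<Seq> corpus = seqs_from_list(texts);
  List out(corpus.size());
  for (size_t i = 0; i < corpus.size(); ++i) {
    Seq& s = corpus[i];
    while (s.size() >= 2) {
      int best_rank = INT_MAX, best_id = -1;
      for (size_t j = 0; j + 1 < s.size(); ++j) {
        uint64_t key = ((uint64_t)(uint32_t)s[j] << 32) | (uint32_t)s[j + 1];
        std::unordered_map<uint64_t, std::pair<int, int> >::const_iterator it =
            rank.find(key);
        if (it != rank.end() && it->second.first < best_rank) {
          best_rank = it->second.first;
          best_id = it->second.second;
        }
      }
      if (best_id < 0) break;
      int a = merges(best_rank, 0), b = merges(best_rank, 1);
      size_t w = 0;
      for (size_t j = 0; j < s.size(); ++j) {
        if (j + 1 < s.size() && s[j] == a && s[j + 1] == b) {
          s[w++] = best_id;
          ++j;
        } else {
          s[w++] = s[j];
        }
      }
      s.resize(w);
    }
    IntegerVector ids(s.size());
    for (size_t j = 0; j < s.size(); ++j) ids[j] = s[j];
    out[i] = ids;
  }
  return out;
}

// ------------------------------------------------------------- unigram ----

struct PieceTable {
  // pieces indexed by id; lookup by byte string
  std::unordered_map<std::string, int> index;
  std::vector<std::string> pieces;
  std::vector<double> scores;
  size_t max_len;
};

static PieceTable table_from_r(List pieces, NumericVector scores) {
  PieceTable t;
  t.max_len = 1;
  t.pieces.resize(pieces.size());
  t.scores.resize(pieces.size());
  for (R_xlen_t i = 0; i < pieces.size(); ++i) {
    RawVector r = pieces[i];
    std::string s((const char*)&r[0], r.size());
    t.pieces[i] = s;
    t.scores[i] = scores[i];
    t.index[s] = (int)i;
    t.max_len = std::max(t.max_len, s.size());
  }
  return t;
}

static void viterbi(const std::string& s, const PieceTable& t, Seq& out) {
  size_t n = s.size();
  std::vector<double> best(n + 1, -1e300);
  std::vector<int> back_piece(n + 1, -1);
  std::vector<size_t> back_pos(n + 1, 0);
  best[0] = 0.0;
  for (size_t i = 1; i <= n; ++i) {
    size_t lo = i > t.max_len ? i - t.max_len : 0;
    for (size_t j = lo; j < i; ++j) {
      if (best[j] <= -1e299) continue;
      std::unordered_map<std::string, int>::const_iterator it =
          t.index.find(s.substr(j, i - j));
      if (it == t.index.end()) continue;
      double sc = best[j] + t.scores[it->second];
      if (sc > best[i]) {
        best[i] = sc;
        back_piece[i] = it->second;
        back_pos[i] = j;
      }
    }
  }
  out.clear();
  size_t pos = n;
  while (pos > 0) {
    out.push_back(back_piece[pos]);
    pos = back_pos[pos];
  }
  std::reverse(out.begin(), out.end());
}

// Train a unigram model: seed with frequent substrings, run EM rounds of
// Viterbi counting + probability re-estimation, prune to vocab_size keeping
// all 256 byte tokens. Returns pieces (raw list) and log-prob scores.
// [[Rcpp::export(name = ".unigram_train")]]
List unigram_train_(List seqs, IntegerVector counts, int vocab_size,
                    int max_piece_len = 12, int n_iters = 3) {
  std::vector<Seq> corpus = seqs_from_list(seqs);
  std::vector<std::string> lines(corpus.size());
  for (size_t i = 0; i < corpus.size(); ++i) {
    std::string s(corpus[i].size(), '\0');
    for (size_t j = 0; j < corpus[i].size(); ++j) s[j] = (char)(uint8_t)corpus[i][j];
    lines[i] = s;
  }
  // substring seed candidates weighted by frequency x (length - 1)
  std::unordered_map<std::string, double> cand;
  for (size_t i = 0; i < lines.size(); ++i) {
    const std::string& s = lines[i];
    double w = counts[i];
    for (size_t j = 0; j < s.size(); ++j)
      for (size_t l = 2; l <= (size_t)max_piece_len && j + l <= s.size(); ++l)
        cand[s.substr(j, l)] += w;
  }
  std::vector<std::pair<double, std::string> > scored;
  scored.reserve(cand.size());
  for (std::unordered_map<std::string, double>::const_iterator it = cand.begin();
       it != cand.end(); ++it)
    if (it->second >= 2)
      scored.push_back(std::make_pair(it->second * (it->first.size() - 1), it->first));
  std::sort(scored.begin(), scored.end());
  std::reverse(scored.begin(), scored.end());
  size_t n_seed = std::min(scored.size(), (size_t)std::max(0, (vocab_size - 256) * 3));

  PieceTable t;
  t.max_len = 1;
  for (int b = 0; b < 256; ++b) {
    std::string s(1, (char)(uint8_t)b);
    t.index[s] = (int)t.pieces.size();
    t.pieces.push_back(s);
    t.scores.push_back(std::log(0.5 / 256));
  }
  for (size_t k = 0; k < n_seed; ++k) {
    const std::string& s = scored[k].second;
    if (t.index.find(s) != t.index.end()) continue;
    t.index[s] = (int)t.pieces.size();
    t.pieces.push_back(s);
    t.scores.push_back(std::log(scored[k].first) - std::log(1e6));
    t.max_len = std::max(t.max_len, s.size());
  }

  Seq seg;
  for (int iter = 0; iter < n_iters; ++iter) {
    std::vector<double> usage(t.pieces.size(), 0.0);
    double total = 0.0;
    for (size_t i = 0; i < lines.size(); ++i) {
      viterbi(lines[i], t, seg);
      for (size_t j = 0; j < seg.size(); ++j) {
        usage[seg[j]] += counts[i];
        total += counts[i];
      }
    }
    if (total <= 0) break;
    bool final_round = (iter == n_iters - 1);
    // prune: keep byte tokens plus the most-used multibyte pieces
    std::vector<std::pair<double, int> > used;
    for (size_t p = 256; p < t.pieces.size(); ++p)
      if (usage[p] > 0) used.push_back(std::make_pair(usage[p], (int)p));
    std::sort(used.begin(), used.end());
    std::reverse(used.begin(), used.end());
    size_t keep = (size_t)std::max(0, vocab_size - 256);
    if (!final_round) keep = keep * 2; // anneal the vocabulary down gradually
    if (used.size() > keep) used.resize(keep);
    PieceTable nt;
    nt.max_len = 1;
    for (int b = 0; b < 256; ++b) {
      std::string s(1, (char)(uint8_t)b);
      nt.index[s] = (int)nt.pieces.size();
      nt.pieces.push_back(s);
      double u = std::max(usage[b], 0.1);
      nt.scores.push_back(std::log(u) - std::log(total));
    }
    for (size_t k = 0; k < used.size(); ++k) {
      const std::string& s = t.pieces[used[k].second];
      nt.index[s] = (int)nt.pieces.size();
      nt.pieces.push_back(s);
      nt.scores.push_back(std::log(used[k].first) - std::log(total));
      nt.max_len = std::max(nt.max_len, s.size());
    }
    t = nt;
  }

  List pieces(t.pieces.size());
  NumericVector scores(t.pieces.size());
  for (size_t i = 0; i < t.pieces.size(); ++i) {
    const std::string& s = t.pieces[i];
    RawVector r(s.size());
    std::memcpy(r.size() ? &r[0] : (Rbyte*)NULL, s.data(), s.size());
    pieces[i] = r;
    scores[i] = t.scores[i];
  }
  return List::create(_["pieces"] = pieces, _["scores"] = scores);
}

// [[Rcpp::export(name = ".unigram_encode_many")]]
List unigram_encode_many_(List texts, List pieces, NumericVector scores) {
  PieceTable t = table_from_r(pieces, scores);
  std::vector<Seq> corpus = seqs_from_list(texts);
  List out(corpus.size());
  Seq seg;
  for (size_t i = 0; i < corpus.size(); ++i) {
    std::string s(corpus[i].size(), '\0');
    for (size_t j = 0; j < corpus[i].size(); ++j) s[j] = (char)(uint8_t)corpus[i][j];
    viterbi(s, t, seg);
    IntegerVector ids(seg.size());
    for (size_t j = 0; j < seg.size(); ++j) ids[j] = seg[j];
    out[i] = ids;
  }
  return out;
}
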