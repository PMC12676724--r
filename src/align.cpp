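#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>

using namespace Rcpp;

// Affine-gap local alignment (Gotoh). A gap of length L costs open + L * ext.
// Tie-breaking: the first maximal cell in row-major order is reported; during
// traceback diagonal is preferred over vertical (gap in reference) over
// horizontal (gap in query).

struct AlnResult {
  int score = 0;
  int qstart = 0, qend = 0;   // 0-based half-open on query
  int sstart = 0, send = 0;   // 0-based half-open on subject
  int matches = 0, columns = 0;
};

static inline int lut_score(const int* lut, unsigned char a, unsigned char b) {
  return lut[(int)a * 128 + (int)b];
}

static const int NEG_INF = -1000000000;

// Full DP with traceback. Intended for modest problem sizes (reads, proteins,
// rRNA genes); guard against accidental quadratic blowups.
static AlnResult sw_full(const std::string& q, const std::string& s,
                         const int* lut, int go, int ge) {
  const int n = (int)q.size(), m = (int)s.size();
  if ((double)(n + 1) * (double)(m + 1) > 6.4e7)
    stop("sequences too long for full dynamic programming; use seeded alignment");

  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0);
  std::vector<int> Fcol(m + 1, NEG_INF);
  // direction matrices: H 0=stop 1=diag 2=vert(F) 3=horiz(E); E/F 1=open 0=extend
  std::vector<unsigned char> Hdir((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> Edir((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> Fdir((size_t)(n + 1) * (m + 1), 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    int Ei = NEG_INF; // E for current row, column-wise running
    for (int j = 1; j <= m; ++j) {
      size_t idx = (size_t)i * (m + 1) + j;
      // E: horizontal, gap in query (consumes s[j-1])
      int e_open = Hcur[j - 1] - go - ge;
      int e_ext  = Ei - ge;
      if (e_open >= e_ext) { Ei = e_open; Edir[idx] = 1; }
      else                 { Ei = e_ext;  Edir[idx] = 0; }
      // F: vertical, gap in subject (consumes q[i-1])
      int f_open = Hprev[j] - go - ge;
      int f_ext  = Fcol[j] - ge;
      if (f_open >= f_ext) { Fcol[j] = f_open; Fdir[idx] = 1; }
      else                 { Fcol[j] = f_ext;  Fdir[idx] = 0; }

      int diag = Hprev[j - 1] + lut_score(lut, q[i - 1], s[j - 1]);
      int h = 0; unsigned char dir = 0;
      if (diag > h)    { h = diag;    dir = 1; }
      if (Fcol[j] > h) { h = Fcol[j]; dir = 2; }
      if (Ei > h)      { h = Ei;      dir = 3; }
      Hcur[j] = h; Hdir[idx] = dir;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    Hcur[0] = 0;
  }

  AlnResult r;
  r.score = best;
  if (best <= 0) return r;

  // traceback
  int i = bi, j = bj;
  int state = 0; // 0 = in H
  r.qend = bi; r.send = bj;
  while (true) {
    size_t idx = (size_t)i * (m + 1) + j;
    if (state == 0) {
      unsigned char d = Hdir[idx];
      if (d == 0) break;
      if (d == 1) {
        r.columns++;
        if (q[i - 1] == s[j - 1]) r.matches++;
        --i; --j;
      } else if (d == 2) { state = 2; }
      else               { state = 3; }
    } else if (state == 2) { // F: consumes q[i-1]
      r.columns++;
      unsigned char d = Fdir[idx];
      --i;
      if (d == 1) state = 0;
    } else { // E: consumes s[j-1]
      r.columns++;
      unsigned char d = Edir[idx];
      --j;
      if (d == 1) state = 0;
    }
  }
  r.qstart = i; r.sstart = j;
  return r;
}

// score-only, linear memory
static int sw_score_only(const std::string& q, const std::string& s,
                         const int* lut, int go, int ge) {
  const int n = (int)q.size(), m = (int)s.size();
  std::vector<int> Hprev(m + 1, 0), F(m + 1, NEG_INF);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int Hdiag = 0;       // H[i-1][j-1]
    int Hleft = 0;       // H[i][j-1]
    int E = NEG_INF;
    const unsigned char qc = q[i - 1];
    const int* row = lut + (int)qc * 128;
    for (int j = 1; j <= m; ++j) {
      int e_open = Hleft - go - ge;
      E = std::max(e_open, E - ge);
      int f_open = Hprev[j] - go - ge;
      F[j] = std::max(f_open, F[j] - ge);
      int h = Hdiag + row[(unsigned char)s[j - 1]];
      if (h < 0) h = 0;
      if (F[j] > h) h = F[j];
      if (E > h) h = E;
      Hdiag = Hprev[j];
      Hprev[j] = h;
      Hleft = h;
      if (h > best) best = h;
    }
  }
  return best;
}

static void check_lut(const IntegerMatrix& lut) {
  if (lut.nrow() != 128 || lut.ncol() != 128)
    stop("scoring lookup must be 128 x 128");
}

// [[Rcpp::export]]
List cpp_sw_align(std::string q, std::string s, IntegerMatrix lut,
                  int gap_open, int gap_extend) {
  check_lut(lut);
  AlnResult r = sw_full(q, s, lut.begin(), gap_open, gap_extend);
  double ident = r.columns > 0 ? (double)r.matches / r.columns : 0.0;
  return List::create(_["score"] = r.score,
                      _["qstart"] = r.qstart, _["qend"] = r.qend,
                      _["sstart"] = r.sstart, _["send"] = r.send,
                      _["identity"] = ident, _["columns"] = r.columns,
                      _["matches"] = r.matches);
}

// [[Rcpp::export]]
IntegerVector cpp_sw_score_batch(CharacterVector qs, std::string s,
                                 IntegerMatrix lut, int gap_open, int gap_extend) {
  check_lut(lut);
  const int* L = lut.begin();
  int n = qs.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string q = as<std::string>(qs[i]);
    out[i] = q.empty() ? 0 : sw_score_only(q, s, L, gap_open, gap_extend);
  }
  return out;
}

// Substitution-only mutator driven by R's RNG (deterministic under set.seed).
// Returns the mutated sequence and 0-based positions of the substitutions.
// [[Rcpp::export]]
List cpp_mutate(std::string seq, double rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::vector<int> pos;
  if (rate > 0) {
    for (size_t i = 0; i < seq.size(); ++i) {
      if (unif_rand() < rate) {
        char cur = seq[i];
        char alt = cur;
        while (alt == cur) alt = bases[(int)(unif_rand() * 4) % 4];
        seq[i] = alt;
        pos.push_back((int)i);
      }
    }
  }
  return List::create(_["seq"] = seq, _["positions"] = wrap(pos));
}

static inline int enc_base(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      default: break;
    }
  }
  return r;
}

struct SeedHit {
  bool found = false;
  AlnResult aln;
  int strand = 1; // +1 forward, -1 reverse
};

// Ungapped extension along a fixed diagonal (Kadane over match/mismatch run),
// then optional gapped refinement with full DP on a bounded reference window.
static void try_diagonal(const std::string& q, const std::string& ref,
                         long diag, int match, int mismatch,
                         const int* lut, int go, int ge, int refine_max,
                         AlnResult& bestAln) {
  const long n = (long)q.size(), m = (long)ref.size();
  long j0 = std::max(0L, diag);             // subject start of overlap
  long i0 = j0 - diag;                      // query start of overlap
  long len = std::min(n - i0, m - j0);
  if (len <= 0) return;

  // Kadane for the best-scoring ungapped segment
  int run = 0, bestScore = 0, matches = 0, runMatches = 0;
  long runStart = 0, bestStart = 0, bestEnd = -1;
  for (long t = 0; t < len; ++t) {
    int sc = (q[i0 + t] == ref[j0 + t]) ? match : mismatch;
    int mt = (q[i0 + t] == ref[j0 + t]) ? 1 : 0;
    if (run <= 0) { run = 0; runMatches = 0; runStart = t; }
    run += sc; runMatches += mt;
    if (run > bestScore) {
      bestScore = run; matches = runMatches; bestStart = runStart; bestEnd = t;
    }
  }
  if (bestScore <= 0) return;

  AlnResult cand;
  cand.score = bestScore;
  cand.qstart = (int)(i0 + bestStart); cand.qend = (int)(i0 + bestEnd + 1);
  cand.sstart = (int)(j0 + bestStart); cand.send = (int)(j0 + bestEnd + 1);
  cand.matches = matches; cand.columns = (int)(bestEnd - bestStart + 1);

  if ((int)q.size() <= refine_max) {
    // gapped refinement on a window of the subject around the diagonal
    long pad = 2L * go + 8;
    long w0 = std::max(0L, diag - pad);
    long w1 = std::min(m, diag + n + pad);
    if (w1 > w0) {
      AlnResult ref_aln = sw_full(q, ref.substr(w0, w1 - w0), lut, go, ge);
      if (ref_aln.score > cand.score) {
        ref_aln.sstart += (int)w0; ref_aln.send += (int)w0;
        cand = ref_aln;
      }
    }
  }
  if (cand.score > bestAln.score) bestAln = cand;
}

// Translate many sequences in one frame offset. code64 maps the 2-bit codon
// index (16*b1 + 4*b2 + b3 with A,C,G,T = 0..3) to an amino-acid character;
// codons containing other letters translate to 'X'.
// [[Rcpp::export]]
CharacterVector cpp_translate_many(CharacterVector seqs, int offset,
                                   std::string code64) {
  if (code64.size() != 64) stop("code64 must have 64 entries");
  int n = seqs.size();
  CharacterVector out(n);
  std::string prot;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int m = (int)s.size();
    int nc = (m - offset) / 3;
    prot.clear();
    if (nc > 0) {
      prot.reserve(nc);
      for (int c = 0; c < nc; ++c) {
        int p = offset + 3 * c;
        int b1 = enc_base(s[p]), b2 = enc_base(s[p + 1]), b3 = enc_base(s[p + 2]);
        prot.push_back((b1 < 0 || b2 < 0 || b3 < 0) ? 'X'
                       : code64[16 * b1 + 4 * b2 + b3]);
      }
    }
    out[i] = prot;
  }
  return out;
}

// Sum of diagonal lookup scores: the best self-alignment score under a
// diagonal-dominant scheme.
// [[Rcpp::export]]
IntegerVector cpp_self_scores(CharacterVector seqs, IntegerMatrix lut) {
  check_lut(lut);
  const int* L = lut.begin();
  int n = seqs.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    long acc = 0;
    for (char c : s) acc += lut_score(L, (unsigned char)c, (unsigned char)c);
    out[i] = (int)acc;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp_many(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) out[i] = revcomp(as<std::string>(seqs[i]));
  return out;
}

// Exact k-mer seeded mapping of many queries onto one reference.
// Circular references are looked up on the doubled sequence; reported subject
// coordinates have sstart in [0, L) and send may exceed L for wrapped hits.
// [[Rcpp::export]]
DataFrame cpp_seeded_map(CharacterVector queries, std::string ref, int k,
                         int match, int mismatch, int gap_open, int gap_extend,
                         bool circular, int refine_max, bool both_strands) {
  if (k < 8) stop("seed length k must be >= 8");
  if (k > 31) stop("seed length k must be <= 31");
  const long L = (long)ref.size();
  std::string refdb = circular ? ref + ref : ref;

  // 2-bit rolling k-mer index
  std::unordered_map<uint64_t, std::vector<int>> index;
  index.reserve(refdb.size());
  {
    uint64_t kmer = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    int valid = 0;
    for (long i = 0; i < (long)refdb.size(); ++i) {
      int e = enc_base(refdb[i]);
      if (e < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)e) & mask;
      if (++valid >= k) {
        auto& v = index[kmer];
        if ((int)v.size() < 64) v.push_back((int)(i - k + 1));
      }
    }
  }

  // nucleotide lookup for the refinement DP
  IntegerMatrix lutM(128, 128);
  for (const char* a = "ACGT"; *a; ++a)
    for (const char* b = "ACGT"; *b; ++b)
      lutM((unsigned char)*a, (unsigned char)*b) = (*a == *b) ? match : mismatch;
  const int* lut = lutM.begin();

  int nq = queries.size();
  std::vector<int> o_query; std::vector<int> o_qs, o_qe;
  std::vector<double> o_ss, o_se;
  std::vector<int> o_strand, o_score, o_cols;
  std::vector<double> o_ident;

  for (int qi = 0; qi < nq; ++qi) {
    std::string fwd = as<std::string>(queries[qi]);
    int qlen = (int)fwd.size();
    if (qlen < k) continue;
    AlnResult bestAln; int bestStrand = 1;
    for (int st = 0; st < (both_strands ? 2 : 1); ++st) {
      std::string q = (st == 0) ? fwd : revcomp(fwd);
      // seed offsets: stride k, plus the final k-mer; candidate diagonals
      // ranked by seed support so repeat-induced diagonals cannot crowd out
      // the true one
      std::unordered_map<long, int> votes;
      for (int off = 0; off + k <= qlen; off += k) {
        int last = (off + 2 * k > qlen) ? (qlen - k) : off;
        uint64_t kmer = 0; bool ok = true;
        for (int t = 0; t < k; ++t) {
          int e = enc_base(q[last + t]);
          if (e < 0) { ok = false; break; }
          kmer = (kmer << 2) | (uint64_t)e;
        }
        if (!ok) continue;
        auto it = index.find(kmer);
        if (it == index.end()) continue;
        for (int p : it->second) votes[(long)p - last]++;
        if (last == qlen - k) break;
      }
      std::vector<std::pair<int, long>> ranked;
      ranked.reserve(votes.size());
      for (auto& kv : votes) ranked.push_back({-kv.second, kv.first});
      std::sort(ranked.begin(), ranked.end());
      if (ranked.size() > 64) ranked.resize(64);
      std::vector<long> diags;
      diags.reserve(ranked.size());
      for (auto& pr : ranked) diags.push_back(pr.second);
      AlnResult strandBest;
      for (long d : diags)
        try_diagonal(q, refdb, d, match, mismatch, lut, gap_open, gap_extend,
                     refine_max, strandBest);
      if (strandBest.score > bestAln.score) {
        bestAln = strandBest; bestStrand = (st == 0) ? 1 : -1;
      }
    }
    if (bestAln.score <= 0) continue;
    int qs = bestAln.qstart, qe = bestAln.qend;
    if (bestStrand == -1) { // back to original read coordinates
      qs = qlen - bestAln.qend; qe = qlen - bestAln.qstart;
    }
    long ss = bestAln.sstart, se = bestAln.send;
    if (circular && ss >= L) { ss -= L; se -= L; }
    o_query.push_back(qi + 1);
    o_qs.push_back(qs); o_qe.push_back(qe);
    o_ss.push_back((double)ss); o_se.push_back((double)se);
    o_strand.push_back(bestStrand);
    o_score.push_back(bestAln.score);
    o_cols.push_back(bestAln.columns);
    o_ident.push_back(bestAln.columns ? (double)bestAln.matches / bestAln.columns : 0.0);
  }

  return DataFrame::create(_["query"] = wrap(o_query),
                           _["qstart"] = wrap(o_qs), _["qend"] = wrap(o_qe),
                           _["sstart"] = wrap(o_ss), _["send"] = wrap(o_se),
                           _["strand"] = wrap(o_strand),
                           _["score"] = wrap(o_score),
                           _["identity"] = wrap(o_ident),
                           _["columns"] = wrap(o_cols),
                           _["stringsAsFactors"] = false);
}
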