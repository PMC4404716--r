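// Alignment and string kernels.
//
// All coordinates are 0-based half-open.  The Smith-Waterman implementation
// is affine-gap (Gotoh) local alignment over an optional diagonal band
// [dlo, dhi] on d = j - i (query index i, subject index j); a full matrix is
// the special case dlo = -(n-1), dhi = m-1.  Gap of length L costs
// gap_open + gap_extend * L.

#include <Rcpp.h>
#include <cstdint>
#include <climits>
#include <algorithm>
#include <unordered_map>
#include <map>
#include <vector>
#include <string>

using namespace Rcpp;

static const int NEG = INT_MIN / 4;

struct Scorer {
  bool protein;
  int match, mismatch;
  int lut[256];
  std::vector<int> sm;  // n x n, column-major
  int n;
  inline int sc(char a, char b) const {
    if (!protein) {
      if (a == b && a != 'N' && a != 'n') return match;
      return mismatch;
    }
    int ia = lut[(unsigned char)a], ib = lut[(unsigned char)b];
    if (ia < 0 || ib < 0) return mismatch;
    return sm[ia + n * ib];
  }
};

static Scorer make_scorer(int match, int mismatch, bool protein,
                          Nullable<IntegerMatrix> submat,
                          const std::string& alphabet) {
  Scorer s;
  s.protein = protein;
  s.match = match;
  s.mismatch = mismatch;
  std::fill(s.lut, s.lut + 256, -1);
  if (protein) {
    if (submat.isNull()) stop("protein mode requires a substitution matrix");
    IntegerMatrix m(submat);
    s.n = m.nrow();
    s.sm.assign(m.begin(), m.end());
    if ((int)alphabet.size() != s.n)
      stop("alphabet length must match substitution matrix dimension");
    for (int i = 0; i < s.n; ++i) s.lut[(unsigned char)alphabet[i]] = i;
  } else {
    s.n = 0;
  }
  return s;
}

struct AlnResult {
  int score, q0, q1, s0, s1, matches, cols;
  std::string cigar, proj;
};

// traceback byte: bits 0-1 H-source (0 stop, 1 diag, 2 E, 3 F),
// bit 2 E extends E, bit 3 F extends F.
static AlnResult sw_band(const std::string& a, const std::string& b,
                         int dlo, int dhi, int go, int ge,
                         const Scorer& sc, bool want_proj) {
  int n = a.size(), m = b.size();
  AlnResult res;
  res.score = 0; res.q0 = res.q1 = res.s0 = res.s1 = 0;
  res.matches = 0; res.cols = 0;
  if (n == 0 || m == 0) return res;
  if (dlo < -(n - 1)) dlo = -(n - 1);
  if (dhi > m - 1) dhi = m - 1;
  if (dlo > dhi) return res;
  long long W = (long long)dhi - dlo + 1;
  if ((long long)n * W > 400000000LL)
    stop("alignment problem too large (%d x %lld band cells)", n, W);
  std::vector<uint8_t> tb((size_t)n * W, 0);
  std::vector<int> Hprev(W + 2, NEG), Hcur(W + 2, NEG);
  std::vector<int> Fprev(W + 2, NEG), Fcur(W + 2, NEG);
  std::vector<int> Erow(W + 2, NEG);
  int best = 0, bi = -1, bj = -1;
  int gape = go + ge;
  for (int i = 0; i < n; ++i) {
    int jlo = std::max(0, i + dlo), jhi = std::min(m - 1, i + dhi);
    std::fill(Hcur.begin(), Hcur.end(), NEG);
    std::fill(Fcur.begin(), Fcur.end(), NEG);
    std::fill(Erow.begin(), Erow.end(), NEG);
    for (int j = jlo; j <= jhi; ++j) {
      int w = j - i - dlo;          // 0..W-1
      int u = w + 1;                // padded index
      int diag = Hprev[u];          // (i-1, j-1), same u in previous row
      int diag_base = (diag < 0) ? 0 : diag;  // fresh local start allowed
      int dsc = diag_base + sc.sc(a[i], b[j]);
      int hl = Hcur[u - 1], el = Erow[u - 1];
      int e_open = (hl <= NEG / 2) ? NEG : hl - gape;
      int e_ext = (el <= NEG / 2) ? NEG : el - ge;
      int e = std::max(e_open, e_ext);
      int hu = Hprev[u + 1], fu = Fprev[u + 1];
      int f_open = (hu <= NEG / 2) ? NEG : hu - gape;
      int f_ext = (fu <= NEG / 2) ? NEG : fu - ge;
      int f = std::max(f_open, f_ext);
      uint8_t byte = 0;
      if (e_ext > e_open) byte |= 4;
      if (f_ext > f_open) byte |= 8;
      int h = 0; uint8_t src = 0;
      if (dsc > h) { h = dsc; src = 1; }
      if (e > h) { h = e; src = 2; }
      if (f > h) { h = f; src = 3; }
      byte |= src;
      Hcur[u] = h;
      Erow[u] = e;
      Fcur[u] = f;
      tb[(size_t)i * W + w] = byte;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }
  res.score = best;
  if (best <= 0 || bi < 0) return res;
  // traceback
  std::string ops;                 // reversed op chars
  std::string proj;                // reversed subject-projected query
  int i = bi, j = bj, matches = 0;
  int state = 0;                   // 0 = H, 1 = E, 2 = F
  while (i >= 0 && j >= 0) {
    int w = j - i - dlo;
    if (w < 0 || w >= W) break;
    uint8_t byte = tb[(size_t)i * W + w];
    if (state == 0) {
      uint8_t src = byte & 3;
      if (src == 0) break;
      if (src == 1) {
        ops.push_back('M');
        if (want_proj) proj.push_back(a[i]);
        if (a[i] == b[j]) ++matches;
        --i; --j;
      } else if (src == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {       // E: gap in query, consumes subject
      ops.push_back('D');
      if (want_proj) proj.push_back('-');
      bool ext = (byte & 4) != 0;
      --j;
      state = ext ? 1 : 0;
    } else {                       // F: consumes query
      ops.push_back('I');
      bool ext = (byte & 8) != 0;
      --i;
      state = ext ? 2 : 0;
    }
  }
  res.q0 = i + 1; res.q1 = bi + 1;
  res.s0 = j + 1; res.s1 = bj + 1;
  res.matches = matches;
  res.cols = ops.size();
  // compress cigar
  std::string cig;
  size_t p = ops.size();
  while (p > 0) {
    char op = ops[p - 1];
    size_t q = p;
    while (q > 0 && ops[q - 1] == op) --q;
    cig += std::to_string(p - q) + op;
    p = q;
  }
  res.cigar = cig;
  if (want_proj) std::reverse(proj.begin(), proj.end());
  res.proj = proj;
  return res;
}

// [[Rcpp::export]]
DataFrame cpp_align_pairs(CharacterVector qseq, CharacterVector sseq,
                          IntegerVector qi, IntegerVector si,
                          IntegerVector dlo, IntegerVector dhi,
                          int match, int mismatch, int gap_open, int gap_extend,
                          bool protein, Nullable<IntegerMatrix> submat,
                          std::string alphabet, bool want_proj) {
  int np = qi.size();
  if (si.size() != np || dlo.size() != np || dhi.size() != np)
    stop("pair vectors must have equal length");
  std::vector<std::string> qs(qseq.size()), ss(sseq.size());
  for (int i = 0; i < qseq.size(); ++i) qs[i] = as<std::string>(qseq[i]);
  for (int i = 0; i < sseq.size(); ++i) ss[i] = as<std::string>(sseq[i]);
  Scorer sc = make_scorer(match, mismatch, protein, submat, alphabet);
  IntegerVector score(np), q0(np), q1(np), s0(np), s1(np), matches(np), cols(np);
  CharacterVector cigar(np), proj(np);
  for (int p = 0; p < np; ++p) {
    const std::string& a = qs[qi[p] - 1];
    const std::string& b = ss[si[p] - 1];
    int lo = (dlo[p] == NA_INTEGER) ? -((int)a.size() - 1) : dlo[p];
    int hi = (dhi[p] == NA_INTEGER) ? (int)b.size() - 1 : dhi[p];
    AlnResult r = sw_band(a, b, lo, hi, gap_open, gap_extend, sc, want_proj);
    score[p] = r.score; q0[p] = r.q0; q1[p] = r.q1;
    s0[p] = r.s0; s1[p] = r.s1; matches[p] = r.matches; cols[p] = r.cols;
    cigar[p] = r.cigar; proj[p] = r.proj;
  }
  return DataFrame::create(
      _["qi"] = qi, _["si"] = si, _["score"] = score,
      _["q0"] = q0, _["q1"] = q1, _["s0"] = s0, _["s1"] = s1,
      _["matches"] = matches, _["cols"] = cols,
      _["cigar"] = cigar, _["proj"] = proj,
      _["stringsAsFactors"] = false);
}

static inline char comp_base(char c) {
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
  for (auto& c : r) c = comp_base(c);
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i)
    out[i] = revcomp_str(as<std::string>(seqs[i]));
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_reverse(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::reverse(s.begin(), s.end());
    out[i] = s;
  }
  return out;
}

// Shared k-mer seeding.  Returns one row per (query, subject, strand,
// diagonal cluster); diagonals d = spos - qpos are clustered greedily with
// gaps > band_gap splitting clusters.  strand -1 rows refer to the reverse
// complement of the query.
// [[Rcpp::export]]
DataFrame cpp_seed_pairs(CharacterVector qseq, CharacterVector sseq, int k,
                         bool both_strands, std::string alphabet,
                         int band_gap, int min_seeds) {
  int B = alphabet.size();
  if (k < 1) stop("k must be >= 1");
  double span = 1.0;
  for (int i = 0; i < k; ++i) {
    span *= B;
    if (span > 9e17) stop("k too large for alphabet");
  }
  int code[256];
  std::fill(code, code + 256, -1);
  for (int i = 0; i < B; ++i) code[(unsigned char)alphabet[i]] = i;
  uint64_t lead = 1;
  for (int t = 0; t < k; ++t) lead *= B;

  // index subjects
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> idx;
  std::vector<std::string> ss(sseq.size());
  for (int s = 0; s < sseq.size(); ++s) {
    ss[s] = as<std::string>(sseq[s]);
    const std::string& seq = ss[s];
    int L = seq.size();
    uint64_t val = 0; int run = 0;
    for (int p = 0; p < L; ++p) {
      int c = code[(unsigned char)seq[p]];
      if (c < 0) { run = 0; val = 0; continue; }
      val = val * B + c;
      if (++run >= k) {
        if (run > k) val %= lead;
        idx[val].push_back(std::make_pair(s, p - k + 1));
      }
    }
  }

  std::vector<int> out_qi, out_si, out_strand, out_nseed, out_dmin, out_dmax;
  std::vector<std::string> qbuf(2);
  for (int q = 0; q < qseq.size(); ++q) {
    std::string fwd = as<std::string>(qseq[q]);
    int nstr = both_strands ? 2 : 1;
    qbuf[0] = fwd;
    if (both_strands) qbuf[1] = revcomp_str(fwd);
    // key: (subject, strand) -> diags
    std::map<std::pair<int, int>, std::vector<int>> hits;
    for (int st = 0; st < nstr; ++st) {
      const std::string& seq = qbuf[st];
      int L = seq.size();
      uint64_t val = 0; int run = 0;
      for (int p = 0; p < L; ++p) {
        int c = code[(unsigned char)seq[p]];
        if (c < 0) { run = 0; val = 0; continue; }
        val = val * B + c;
        if (++run >= k) {
          if (run > k) val %= lead;
          auto it = idx.find(val);
          if (it != idx.end()) {
            int qpos = p - k + 1;
            for (auto& pr : it->second)
              hits[std::make_pair(pr.first, st)].push_back(pr.second - qpos);
          }
        }
      }
    }
    for (auto& kv : hits) {
      std::vector<int>& d = kv.second;
      std::sort(d.begin(), d.end());
      size_t i0 = 0;
      for (size_t i1 = 1; i1 <= d.size(); ++i1) {
        if (i1 == d.size() || d[i1] - d[i1 - 1] > band_gap) {
          int nseed = (int)(i1 - i0);
          if (nseed >= min_seeds) {
            out_qi.push_back(q + 1);
            out_si.push_back(kv.first.first + 1);
            out_strand.push_back(kv.first.second == 0 ? 1 : -1);
            out_nseed.push_back(nseed);
            out_dmin.push_back(d[i0]);
            out_dmax.push_back(d[i1 - 1]);
          }
          i0 = i1;
        }
      }
    }
  }
  return DataFrame::create(
      _["qi"] = out_qi, _["si"] = out_si, _["strand"] = out_strand,
      _["nseed"] = out_nseed, _["dmin"] = out_dmin, _["dmax"] = out_dmax,
      _["stringsAsFactors"] = false);
}

// Base counts per reference position from subject-projected reads.
// Rows: A, C, G, T, N, '-' (deletion).
// [[Rcpp::export]]
IntegerMatrix cpp_pileup(int ref_len, IntegerVector s0, CharacterVector proj) {
  IntegerMatrix out(6, ref_len);
  for (int r = 0; r < s0.size(); ++r) {
    std::string p = as<std::string>(proj[r]);
    int start = s0[r];
    for (size_t t = 0; t < p.size(); ++t) {
      int pos = start + (int)t;
      if (pos < 0 || pos >= ref_len) continue;
      int row;
      switch (p[t]) {
        case 'A': row = 0; break; case 'C': row = 1; break;
        case 'G': row = 2; break; case 'T': row = 3; break;
        case '-': row = 5; break; default: row = 4; break;
      }
      out(row, pos) += 1;
    }
  }
  return out;
}

// Per-read allele at selected reference positions ("" when not covered).
// [[Rcpp::export]]
CharacterMatrix cpp_alleles_at(IntegerVector s0, CharacterVector proj,
                               IntegerVector pos) {
  int nr = s0.size(), np = pos.size();
  CharacterMatrix out(nr, np);
  for (int r = 0; r < nr; ++r) {
    std::string p = as<std::string>(proj[r]);
    int start = s0[r], len = (int)p.size();
    for (int c = 0; c < np; ++c) {
      int q = pos[c] - start;
      if (q >= 0 && q < len) out(r, c) = std::string(1, p[q]);
      else out(r, c) = "";
    }
  }
  return out;
}

// Classic DUST-style low-complexity score: max over sliding windows of
// sum_t c_t (c_t - 1) / 2 / (w - 3), triplet counts c_t over the window.
// [[Rcpp::export]]
NumericVector cpp_dust(CharacterVector seqs, int window = 64) {
  int code[256];
  std::fill(code, code + 256, -1);
  code['A'] = 0; code['C'] = 1; code['G'] = 2; code['T'] = 3;
  NumericVector out(seqs.size());
  for (int s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    int L = seq.size();
    if (L < 3) { out[s] = 0.0; continue; }
    // triplet codes, -1 for triplets containing non-ACGT
    int nt = L - 2;
    std::vector<int> tri(nt, -1);
    for (int i = 0; i < nt; ++i) {
      int a = code[(unsigned char)seq[i]], b = code[(unsigned char)seq[i + 1]],
          c = code[(unsigned char)seq[i + 2]];
      if (a >= 0 && b >= 0 && c >= 0) tri[i] = a * 16 + b * 4 + c;
    }
    int w = std::min(window, L);
    int wt = w - 2;                 // triplets per window
    double denom = (w > 3) ? (double)(w - 3) : 1.0;
    std::vector<int> cnt(64, 0);
    double best = 0.0, cur = 0.0;
    for (int i = 0; i < nt; ++i) {
      if (i >= wt) {
        int old = tri[i - wt];
        if (old >= 0) { cnt[old] -= 1; cur -= cnt[old]; }
      }
      int t = tri[i];
      if (t >= 0) { cur += cnt[t]; cnt[t] += 1; }
      if (i >= wt - 1) {
        double sc = cur / denom;
        if (sc > best) best = sc;
      }
    }
    out[s] = best;
  }
  return out;
}

// First/last 1-based positions whose phred+33 quality is >= min_phred.
// Returns 0/-1 when no base passes.
// [[Rcpp::export]]
IntegerMatrix cpp_qtrim(CharacterVector qual, int min_phred) {
  int n = qual.size();
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    std::string q = as<std::string>(qual[i]);
    int L = q.size(), a = -1, b = -2;
    for (int p = 0; p < L; ++p)
      if ((int)q[p] - 33 >= min_phred) { a = p; break; }
    for (int p = L - 1; p >= 0; --p)
      if ((int)q[p] - 33 >= min_phred) { b = p; break; }
    out(i, 0) = a + 1;
    out(i, 1) = b + 1;
  }
  return out;
}

// Overlap-merge of read pairs (mate 2 in sequencing orientation, reverse
// complemented internally).  Candidate suffix(r1)/prefix(rc(r2)) overlaps of
// length >= min_overlap with mismatch rate <= max_mismatch_rate; the best
// (most matches, ties to longer overlap) wins.  Conflicting bases take the
// higher-quality call, ties the mate-1 base.
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector seq1, CharacterVector qual1,
                     CharacterVector seq2, CharacterVector qual2,
                     int min_overlap, double max_mismatch_rate) {
  int n = seq1.size();
  CharacterVector mseq(n), mqual(n);
  LogicalVector merged(n);
  IntegerVector ov_len(n);
  for (int i = 0; i < n; ++i) {
    std::string a = as<std::string>(seq1[i]);
    std::string qa = as<std::string>(qual1[i]);
    std::string b = revcomp_str(as<std::string>(seq2[i]));
    std::string qb = as<std::string>(qual2[i]);
    std::reverse(qb.begin(), qb.end());
    int n1 = a.size(), n2 = b.size();
    int best_score = INT_MIN, best_L = 0, best_mm = 0;
    int maxL = std::min(n1, n2);
    for (int L = min_overlap; L <= maxL; ++L) {
      int mm = 0;
      bool bad = false;
      for (int t = 0; t < L; ++t) {
        if (a[n1 - L + t] != b[t]) {
          if (++mm > max_mismatch_rate * L) { bad = true; break; }
        }
      }
      if (bad) continue;
      int score = (L - mm) - 4 * mm;
      if (score > best_score || (score == best_score && L > best_L)) {
        best_score = score; best_L = L; best_mm = mm;
      }
    }
    if (best_L == 0) {
      merged[i] = false; mseq[i] = ""; mqual[i] = ""; ov_len[i] = 0;
      continue;
    }
    (void)best_mm;
    std::string ms = a.substr(0, n1 - best_L);
    std::string mq = qa.substr(0, n1 - best_L);
    for (int t = 0; t < best_L; ++t) {
      char ca = a[n1 - best_L + t], cb = b[t];
      char qca = qa[n1 - best_L + t], qcb = qb[t];
      if (ca == cb) { ms.push_back(ca); mq.push_back(std::max(qca, qcb)); }
      else if (qcb > qca) { ms.push_back(cb); mq.push_back(qcb); }
      else { ms.push_back(ca); mq.push_back(qca); }
    }
    ms += b.substr(best_L);
    mq += qb.substr(best_L);
    merged[i] = true; mseq[i] = ms; mqual[i] = mq; ov_len[i] = best_L;
  }
  return List::create(_["merged"] = merged, _["seq"] = mseq,
                      _["qual"] = mqual, _["overlap"] = ov_len);
}

// Standard-code translation; '*' at stops, 'X' for codons with ambiguous
// bases. Input length is truncated to a codon multiple.
// [[Rcpp::export]]
CharacterVector cpp_translate(CharacterVector seqs) {
  static const char* B = "TCAG";
  static char aa_tab[64];
  static bool init = false;
  if (!init) {
    const char* aas =
      "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG";
    for (int i = 0; i < 64; ++i) aa_tab[i] = aas[i];
    init = true;
  }
  int code[256];
  std::fill(code, code + 256, -1);
  for (int i = 0; i < 4; ++i) {
    code[(unsigned char)B[i]] = i;
    code[(unsigned char)tolower(B[i])] = i;
  }
  CharacterVector out(seqs.size());
  for (int s = 0; s < seqs.size(); ++s) {
    std::string nt = as<std::string>(seqs[s]);
    int ncod = nt.size() / 3;
    std::string aa(ncod, 'X');
    for (int c = 0; c < ncod; ++c) {
      int a = code[(unsigned char)nt[3 * c]],
          b = code[(unsigned char)nt[3 * c + 1]],
          d = code[(unsigned char)nt[3 * c + 2]];
      if (a >= 0 && b >= 0 && d >= 0) aa[c] = aa_tab[a * 16 + b * 4 + d];
    }
    out[s] = aa;
  }
  return out;
}

// Random substitutions/indels using R's RNG (deterministic under set.seed).
// [[Rcpp::export]]
CharacterVector cpp_mutate(CharacterVector seqs, double sub_rate,
                           double ins_rate, double del_rate) {
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  CharacterVector out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string r;
    r.reserve(s.size() + 8);
    for (size_t p = 0; p < s.size(); ++p) {
      double u = unif_rand();
      if (u < del_rate) {
        // deleted
      } else if (u < del_rate + sub_rate) {
        char c = s[p];
        int ci;
        switch (c) {
          case 'A': ci = 0; break; case 'C': ci = 1; break;
          case 'G': ci = 2; break; case 'T': ci = 3; break;
          default: ci = -1; break;
        }
        if (ci < 0) r.push_back(c);
        else {
          int alt = (ci + 1 + (int)(unif_rand() * 3)) % 4;
          r.push_back(BASES[alt]);
        }
      } else {
        r.push_back(s[p]);
      }
      if (ins_rate > 0 && unif_rand() < ins_rate)
        r.push_back(BASES[(int)(unif_rand() * 4)]);
    }
    out[i] = r;
  }
  return out;
}
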