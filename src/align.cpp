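// Alignment kernels: banded affine-gap dynamic programming with traceback,
// exact k-mer seeding with a two-hit trigger, and dovetail overlap detection.
// All coordinates returned here are 0-based half-open in the frames of the
// sequences as passed in; strand bookkeeping is done by the R callers.
#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

static const int NEG = -100000000;

struct AlnRes {
  bool found;
  int score, a_start, a_end, b_start, b_end, n_match, align_len;
  std::string ops; // 'M' both advance, 'D' gap in b (a consumed), 'I' gap in a
};

// Encode a sequence with a character->code map; unknown chars get code
// (ncode-1), which should be the wildcard row of the scoring matrix.
static std::vector<int> encode_seq(const std::string &s, const int *charmap,
                                   int ncode) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int c = charmap[(unsigned char)s[i]];
    v[i] = (c < 0) ? ncode - 1 : c;
  }
  return v;
}

static void build_charmap(const std::string &alphabet, int *charmap) {
  for (int i = 0; i < 256; ++i) charmap[i] = -1;
  for (size_t i = 0; i < alphabet.size(); ++i)
    charmap[(unsigned char)alphabet[i]] = (int)i;
}

// Banded Gotoh alignment. Band: j - i in [lo, hi] (i indexes A rows, j
// indexes B cols). local=true: Smith-Waterman with floor 0; local=false:
// overlap (ends-free) alignment, starts on row 0 / col 0, ends on last row
// or col. Gap of length L costs gap_open + L * gap_extend.
static AlnRes band_align(const std::vector<int> &A, const std::vector<int> &B,
                         const int *S, int ncode, int gap_open, int gap_extend,
                         int lo, int hi, bool local) {
  AlnRes res;
  res.found = false;
  res.score = 0;
  const int la = (int)A.size(), lb = (int)B.size();
  if (la == 0 || lb == 0) return res;
  if (lo < -la) lo = -la;
  if (hi > lb) hi = lb;
  if (lo > hi) return res;
  const int w = hi - lo + 1;

  // rows where the band intersects [0, lb]: i + lo <= lb and i + hi >= 0
  const int ifirst = std::max(1, -hi);
  const int ilast = std::min(la, lb - lo);
  if (ifirst > ilast + 1) return res;

  // rolling score rows; full traceback bytes
  std::vector<int> Hp(w), Ep(w), Fp(w), Hc(w), Ec(w), Fc(w);
  // tb byte layout: bits 0-1 H-source (0 stop, 1 diag, 2 E, 3 F);
  // bit 2: E from E (else from H); bit 3: F from F (else from H)
  std::vector<unsigned char> TB((size_t)(ilast + 1) * w, 0);

  int best = local ? 0 : NEG, bi = -1, bj = -1;

  // previous row = row (ifirst - 1); only row 0 offers a free start there
  for (int idx = 0; idx < w; ++idx) {
    int j = (ifirst - 1) + lo + idx;
    if (ifirst - 1 == 0 && j >= 0 && j <= lb) {
      Hp[idx] = 0; Ep[idx] = NEG; Fp[idx] = NEG;
      if (!local && j == lb && Hp[idx] > best) { best = 0; bi = 0; bj = j; }
    } else { Hp[idx] = NEG; Ep[idx] = NEG; Fp[idx] = NEG; }
  }

  for (int i = ifirst; i <= ilast; ++i) {
    const int off = i + lo; // j at idx 0
    for (int idx = 0; idx < w; ++idx) {
      int j = off + idx;
      if (j < 0 || j > lb) { Hc[idx] = NEG; Ec[idx] = NEG; Fc[idx] = NEG; continue; }
      unsigned char tb = 0;
      int h, e, f;
      if (j == 0) {
        // col 0: free start in both modes
        h = 0; e = NEG; f = NEG;
      } else {
        // E: gap in A, from (i, j-1) = same row idx-1
        e = NEG;
        if (idx - 1 >= 0 && Hc[idx - 1] > NEG / 2) {
          int fromH = Hc[idx - 1] - gap_open - gap_extend;
          int fromE = (Ec[idx - 1] > NEG / 2) ? Ec[idx - 1] - gap_extend : NEG;
          if (fromE > fromH) { e = fromE; tb |= 4; } else e = fromH;
        } else if (idx - 1 >= 0 && Ec[idx - 1] > NEG / 2) {
          e = Ec[idx - 1] - gap_extend; tb |= 4;
        }
        // F: gap in B, from (i-1, j) = prev row idx+1
        f = NEG;
        if (idx + 1 < w) {
          int fromH = (Hp[idx + 1] > NEG / 2) ? Hp[idx + 1] - gap_open - gap_extend : NEG;
          int fromF = (Fp[idx + 1] > NEG / 2) ? Fp[idx + 1] - gap_extend : NEG;
          if (fromF > fromH) { f = fromF; tb |= 8; } else f = fromH;
        }
        // H: diagonal from (i-1, j-1) = prev row same idx
        int diag = NEG;
        if (Hp[idx] > NEG / 2)
          diag = Hp[idx] + S[A[i - 1] * ncode + B[j - 1]];
        h = diag; int code = 1;
        if (e > h) { h = e; code = 2; }
        if (f > h) { h = f; code = 3; }
        if (local && h <= 0) { h = 0; code = 0; }
        if (!local && h < NEG / 2) { h = NEG; code = 0; }
        tb |= code;
      }
      Hc[idx] = h; Ec[idx] = e; Fc[idx] = f;
      TB[(size_t)i * w + idx] = tb;
      if (local) {
        if (h > best) { best = h; bi = i; bj = j; }
      } else {
        if ((i == la || j == lb) && h > best) { best = h; bi = i; bj = j; }
      }
    }
    std::swap(Hp, Hc); std::swap(Ep, Ec); std::swap(Fp, Fc);
  }

  if (bi < 0 || (local && best <= 0)) return res;

  // traceback
  std::string ops;
  int i = bi, j = bj, state = 0; // 0=H, 1=E, 2=F
  int nm = 0;
  while (i >= 0 && j >= 0) {
    if (state == 0) {
      if (i == 0 || j == 0) break;
      unsigned char tb = TB[(size_t)i * w + (j - (i + lo))];
      int code = tb & 3;
      if (code == 0) break;
      if (code == 1) {
        ops.push_back('M');
        if (A[i - 1] == B[j - 1]) ++nm;
        --i; --j;
      } else if (code == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      unsigned char tb = TB[(size_t)i * w + (j - (i + lo))];
      ops.push_back('I');
      --j;
      if (!(tb & 4)) state = 0;
      else if (j == 0 || j - (i + lo) < 0) break;
    } else {
      unsigned char tb = TB[(size_t)i * w + (j - (i + lo))];
      ops.push_back('D');
      --i;
      if (!(tb & 8)) state = 0;
      else if (i == 0 || j - (i + lo) >= w) break;
    }
  }
  std::reverse(ops.begin(), ops.end());
  res.found = true;
  res.score = best;
  res.a_start = i; res.a_end = bi;
  res.b_start = j; res.b_end = bj;
  res.n_match = nm;
  res.align_len = (int)ops.size();
  res.ops = ops;
  return res;
}

// ---- k-mer seeding -------------------------------------------------------

typedef std::unordered_map<uint64_t, std::vector<int> > KmerMap;

static bool kmer_code(const std::vector<int> &v, int pos, int k, int base,
                      int wild, uint64_t *out) {
  uint64_t h = 0;
  for (int t = 0; t < k; ++t) {
    int c = v[pos + t];
    if (c >= wild) return false; // skip k-mers containing N/X
    h = h * (uint64_t)base + (uint64_t)c;
  }
  *out = h;
  return true;
}

static void index_kmers(const std::vector<int> &v, int k, int base, int wild,
                        KmerMap &map) {
  if ((int)v.size() < k) return;
  for (int p = 0; p + k <= (int)v.size(); ++p) {
    uint64_t h;
    if (kmer_code(v, p, k, base, wild, &h)) map[h].push_back(p);
  }
}

struct Seed { int d, qpos; };

// Collect seed diagonals of A (query rows) vs B (subject cols): d = spos-qpos.
static void collect_seeds(const KmerMap &qmap, const std::vector<int> &B,
                          int k, int base, int wild, std::vector<Seed> &seeds) {
  if ((int)B.size() < k) return;
  for (int p = 0; p + k <= (int)B.size(); ++p) {
    uint64_t h;
    if (!kmer_code(B, p, k, base, wild, &h)) continue;
    KmerMap::const_iterator it = qmap.find(h);
    if (it == qmap.end()) continue;
    for (size_t t = 0; t < it->second.size(); ++t) {
      Seed s; s.d = p - it->second[t]; s.qpos = it->second[t];
      seeds.push_back(s);
    }
  }
}

// Cluster seed diagonals and apply the two-hit rule: a cluster triggers
// extension only if it holds two seeds whose query positions differ by >= k.
static void seed_bands(std::vector<Seed> &seeds, int k, bool two_hit,
                       int join, int pad,
                       std::vector<std::pair<int, int> > &bands) {
  if (seeds.empty()) return;
  std::sort(seeds.begin(), seeds.end(),
            [](const Seed &a, const Seed &b) { return a.d < b.d; });
  size_t start = 0;
  for (size_t i = 1; i <= seeds.size(); ++i) {
    if (i == seeds.size() || seeds[i].d - seeds[i - 1].d > join) {
      int qmin = seeds[start].qpos, qmax = seeds[start].qpos;
      for (size_t t = start; t < i; ++t) {
        qmin = std::min(qmin, seeds[t].qpos);
        qmax = std::max(qmax, seeds[t].qpos);
      }
      if (!two_hit || qmax - qmin >= k)
        bands.push_back(std::make_pair(seeds[start].d - pad,
                                       seeds[i - 1].d + pad));
      start = i;
    }
  }
  // merge overlapping bands
  if (bands.size() > 1) {
    std::sort(bands.begin(), bands.end());
    std::vector<std::pair<int, int> > merged;
    merged.push_back(bands[0]);
    for (size_t i = 1; i < bands.size(); ++i) {
      if (bands[i].first <= merged.back().second)
        merged.back().second = std::max(merged.back().second, bands[i].second);
      else merged.push_back(bands[i]);
    }
    bands.swap(merged);
  }
}

// ---- exported entry points ----------------------------------------------

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    std::string s = as<std::string>(x[i]);
    std::string r(s.rbegin(), s.rend());
    for (size_t t = 0; t < r.size(); ++t) {
      switch (r[t]) {
        case 'A': r[t] = 'T'; break; case 'C': r[t] = 'G'; break;
        case 'G': r[t] = 'C'; break; case 'T': r[t] = 'A'; break;
        case 'a': r[t] = 't'; break; case 'c': r[t] = 'g'; break;
        case 'g': r[t] = 'c'; break; case 't': r[t] = 'a'; break;
        default: break;
      }
    }
    out[i] = r;
  }
  out.attr("names") = x.attr("names");
  return out;
}

// Seed-and-extend local alignment of one query against many subjects.
// Returns one row per (subject, band) hit above min_raw score.
// [[Rcpp::export]]
DataFrame search_hits_cpp(std::string query, CharacterVector subjects,
                          IntegerMatrix submat, std::string alphabet,
                          int k, int gap_open, int gap_extend,
                          bool two_hit, int band_pad, int min_raw,
                          bool want_path) {
  int charmap[256];
  build_charmap(alphabet, charmap);
  const int ncode = (int)alphabet.size();
  const int wild = ncode - 1;
  std::vector<int> S(ncode * ncode);
  for (int a = 0; a < ncode; ++a)
    for (int b = 0; b < ncode; ++b) S[a * ncode + b] = submat(a, b);

  std::vector<int> Q = encode_seq(query, charmap, ncode);
  KmerMap qmap;
  index_kmers(Q, k, ncode, wild, qmap);

  std::vector<int> o_sidx, o_score, o_nm, o_len, o_qs, o_qe, o_ss, o_se;
  std::vector<std::string> o_ops;

  for (R_xlen_t si = 0; si < subjects.size(); ++si) {
    std::string sub = as<std::string>(subjects[si]);
    std::vector<int> B = encode_seq(sub, charmap, ncode);
    std::vector<Seed> seeds;
    collect_seeds(qmap, B, k, ncode, wild, seeds);
    std::vector<std::pair<int, int> > bands;
    seed_bands(seeds, k, two_hit, 2 * k, band_pad, bands);
    for (size_t bi = 0; bi < bands.size(); ++bi) {
      AlnRes r = band_align(Q, B, S.data(), ncode, gap_open, gap_extend,
                            bands[bi].first, bands[bi].second, true);
      if (!r.found || r.score < min_raw) continue;
      o_sidx.push_back((int)si + 1);
      o_score.push_back(r.score); o_nm.push_back(r.n_match);
      o_len.push_back(r.align_len);
      o_qs.push_back(r.a_start); o_qe.push_back(r.a_end);
      o_ss.push_back(r.b_start); o_se.push_back(r.b_end);
      o_ops.push_back(want_path ? r.ops : std::string());
    }
  }
  return DataFrame::create(
      _["sidx"] = o_sidx, _["score"] = o_score, _["n_match"] = o_nm,
      _["align_len"] = o_len, _["q_start"] = o_qs, _["q_end"] = o_qe,
      _["s_start"] = o_ss, _["s_end"] = o_se, _["path"] = o_ops,
      _["stringsAsFactors"] = false);
}

// Direct banded pairwise alignment (local or overlap mode) with explicit band.
// [[Rcpp::export]]
List pair_align_cpp(std::string a, std::string b, IntegerMatrix submat,
                    std::string alphabet, int gap_open, int gap_extend,
                    int band_lo, int band_hi, bool local) {
  int charmap[256];
  build_charmap(alphabet, charmap);
  const int ncode = (int)alphabet.size();
  std::vector<int> S(ncode * ncode);
  for (int x = 0; x < ncode; ++x)
    for (int y = 0; y < ncode; ++y) S[x * ncode + y] = submat(x, y);
  std::vector<int> A = encode_seq(a, charmap, ncode);
  std::vector<int> B = encode_seq(b, charmap, ncode);
  AlnRes r = band_align(A, B, S.data(), ncode, gap_open, gap_extend,
                        band_lo, band_hi, local);
  return List::create(
      _["found"] = r.found, _["score"] = r.score, _["n_match"] = r.n_match,
      _["align_len"] = r.align_len, _["a_start"] = r.a_start,
      _["a_end"] = r.a_end, _["b_start"] = r.b_start, _["b_end"] = r.b_end,
      _["path"] = r.ops);
}

static const std::string NUC_ALPHA = "ACGTN";

// Best dovetail/containment overlap of sequence a against each of `others`,
// in both orientations. Returns at most one row per (other, orientation).
// [[Rcpp::export]]
DataFrame overlaps_vs_cpp(std::string a, CharacterVector others,
                          int k, int min_overlap, double min_identity,
                          int match, int mismatch, int gap_open,
                          int gap_extend, int band_pad) {
  int charmap[256];
  build_charmap(NUC_ALPHA, charmap);
  const int ncode = 5, wild = 4;
  std::vector<int> S(25);
  for (int x = 0; x < 5; ++x)
    for (int y = 0; y < 5; ++y)
      S[x * 5 + y] = (x == y && x < 4) ? match : mismatch;

  std::vector<int> A = encode_seq(a, charmap, ncode);
  KmerMap amap;
  index_kmers(A, k, ncode, wild, amap);

  std::vector<int> o_j, o_score, o_nm, o_len, o_as, o_ae, o_bs, o_be;
  std::vector<std::string> o_orient, o_ops;
  std::vector<double> o_id;

  for (R_xlen_t j = 0; j < others.size(); ++j) {
    std::string bseq = as<std::string>(others[j]);
    for (int rc = 0; rc < 2; ++rc) {
      std::string bs = rc ? as<std::string>(revcomp_cpp(
                                CharacterVector::create(bseq))[0])
                          : bseq;
      std::vector<int> B = encode_seq(bs, charmap, ncode);
      std::vector<Seed> seeds;
      collect_seeds(amap, B, k, ncode, wild, seeds);
      if (seeds.empty()) continue;
      std::vector<std::pair<int, int> > bands;
      seed_bands(seeds, k, false, 2 * k, band_pad, bands);
      AlnRes bestr; bestr.found = false; bestr.score = NEG;
      for (size_t bi = 0; bi < bands.size(); ++bi) {
        AlnRes r = band_align(A, B, S.data(), ncode, gap_open, gap_extend,
                              bands[bi].first, bands[bi].second, false);
        if (r.found && r.score > bestr.score) bestr = r;
      }
      if (!bestr.found) continue;
      int len = bestr.a_end - bestr.a_start;
      double ident = bestr.align_len > 0
                         ? (double)bestr.n_match / bestr.align_len : 0.0;
      if (len < min_overlap || ident < min_identity) continue;
      o_j.push_back((int)j + 1);
      o_orient.push_back(rc ? "reverse" : "same");
      o_score.push_back(bestr.score); o_nm.push_back(bestr.n_match);
      o_len.push_back(len); o_id.push_back(ident);
      o_as.push_back(bestr.a_start); o_ae.push_back(bestr.a_end);
      o_bs.push_back(bestr.b_start); o_be.push_back(bestr.b_end);
      o_ops.push_back(bestr.ops);
    }
  }
  return DataFrame::create(
      _["j"] = o_j, _["orientation"] = o_orient, _["score"] = o_score,
      _["length"] = o_len, _["identity"] = o_id, _["n_match"] = o_nm,
      _["a_start"] = o_as, _["a_end"] = o_ae, _["b_start"] = o_bs,
      _["b_end"] = o_be, _["path"] = o_ops,
      _["stringsAsFactors"] = false);
}

// All-pairs overlap detection over a read set via a shared k-mer index.
// Only pairs sharing at least one k-mer (in either orientation) are aligned.
// [[Rcpp::export]]
DataFrame overlap_pairs_cpp(CharacterVector seqs, int k, int min_overlap,
                            double min_identity, int match, int mismatch,
                            int gap_open, int gap_extend, int band_pad) {
  int charmap[256];
  build_charmap(NUC_ALPHA, charmap);
  const int ncode = 5, wild = 4;
  const int n = (int)seqs.size();

  // global k-mer index over forward strands
  std::vector<std::vector<int> > enc(n);
  std::vector<std::string> fwd(n);
  for (int i = 0; i < n; ++i) {
    fwd[i] = as<std::string>(seqs[i]);
    enc[i] = encode_seq(fwd[i], charmap, ncode);
  }
  std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > idx;
  for (int i = 0; i < n; ++i) {
    if ((int)enc[i].size() < k) continue;
    for (int p = 0; p + k <= (int)enc[i].size(); ++p) {
      uint64_t h;
      if (kmer_code(enc[i], p, k, ncode, wild, &h))
        idx[h].push_back(std::make_pair(i, p));
    }
  }

  std::vector<int> o_i, o_j, o_score, o_nm, o_len, o_as, o_ae, o_bs, o_be;
  std::vector<std::string> o_orient, o_ops;
  std::vector<double> o_id;

  std::vector<int> S(25);
  for (int x = 0; x < 5; ++x)
    for (int y = 0; y < 5; ++y)
      S[x * 5 + y] = (x == y && x < 4) ? match : mismatch;

  for (int i = 0; i < n; ++i) {
    // candidate partners j > i, same orientation: shared forward k-mers;
    // reverse orientation: k-mers of rc(i) shared with forward j.
    std::map<std::pair<int, int>, std::vector<Seed> > cand; // (j, rc) -> seeds
    int li = (int)enc[i].size();
    if (li >= k) {
      for (int p = 0; p + k <= li; ++p) {
        uint64_t h;
        if (!kmer_code(enc[i], p, k, ncode, wild, &h)) continue;
        std::unordered_map<uint64_t,
            std::vector<std::pair<int, int> > >::iterator it = idx.find(h);
        if (it == idx.end()) continue;
        for (size_t t = 0; t < it->second.size(); ++t) {
          int j = it->second[t].first, pj = it->second[t].second;
          if (j <= i) continue;
          Seed s; s.d = pj - p; s.qpos = p;
          cand[std::make_pair(j, 0)].push_back(s);
        }
      }
      // reverse: k-mer of i at p, reversed-complemented, equals a forward
      // k-mer of j at pj  <=>  in the frame (i vs rc(j)) the seed sits at
      // qpos = p with spos = lj - k - pj.
      std::vector<int> rci(li);
      for (int t = 0; t < li; ++t) {
        int c = enc[i][li - 1 - t];
        rci[t] = (c < 4) ? 3 - c : c;
      }
      for (int p = 0; p + k <= li; ++p) {
        uint64_t h;
        if (!kmer_code(rci, p, k, ncode, wild, &h)) continue;
        std::unordered_map<uint64_t,
            std::vector<std::pair<int, int> > >::iterator it = idx.find(h);
        if (it == idx.end()) continue;
        for (size_t t = 0; t < it->second.size(); ++t) {
          int j = it->second[t].first, pj = it->second[t].second;
          if (j <= i) continue;
          int lj = (int)enc[j].size();
          // rc(i) kmer at p matches j fwd at pj => i fwd kmer at li-k-p
          // matches rc(j) at lj-k-pj
          Seed s; s.qpos = li - k - p; s.d = (lj - k - pj) - s.qpos;
          cand[std::make_pair(j, 1)].push_back(s);
        }
      }
    }
    for (std::map<std::pair<int, int>, std::vector<Seed> >::iterator ct =
             cand.begin(); ct != cand.end(); ++ct) {
      int j = ct->first.first, rc = ct->first.second;
      std::vector<int> B;
      if (rc) {
        int lj = (int)enc[j].size();
        B.resize(lj);
        for (int t = 0; t < lj; ++t) {
          int c = enc[j][lj - 1 - t];
          B[t] = (c < 4) ? 3 - c : c;
        }
      } else B = enc[j];
      std::vector<std::pair<int, int> > bands;
      seed_bands(ct->second, k, false, 2 * k, band_pad, bands);
      AlnRes bestr; bestr.found = false; bestr.score = NEG;
      for (size_t bi = 0; bi < bands.size(); ++bi) {
        AlnRes r = band_align(enc[i], B, S.data(), ncode, gap_open,
                              gap_extend, bands[bi].first, bands[bi].second,
                              false);
        if (r.found && r.score > bestr.score) bestr = r;
      }
      if (!bestr.found) continue;
      int len = bestr.a_end - bestr.a_start;
      double ident = bestr.align_len > 0
                         ? (double)bestr.n_match / bestr.align_len : 0.0;
      if (len < min_overlap || ident < min_identity) continue;
      o_i.push_back(i + 1); o_j.push_back(j + 1);
      o_orient.push_back(rc ? "reverse" : "same");
      o_score.push_back(bestr.score); o_nm.push_back(bestr.n_match);
      o_len.push_back(len); o_id.push_back(ident);
      o_as.push_back(bestr.a_start); o_ae.push_back(bestr.a_end);
      o_bs.push_back(bestr.b_start); o_be.push_back(bestr.b_end);
      o_ops.push_back(bestr.ops);
    }
  }
  return DataFrame::create(
      _["i"] = o_i, _["j"] = o_j, _["orientation"] = o_orient,
      _["score"] = o_score, _["length"] = o_len, _["identity"] = o_id,
      _["n_match"] = o_nm, _["a_start"] = o_as, _["a_end"] = o_ae,
      _["b_start"] = o_bs, _["b_end"] = o_be, _["path"] = o_ops,
      _["stringsAsFactors"] = false);
}
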