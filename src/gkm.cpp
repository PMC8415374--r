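// Gapped k-mer feature machinery.
//
// A feature is a (mask, letters) pair: a choice of k informative positions
// within an L-bp window plus the bases at those positions.  Features are
// canonicalized against reverse complementation (min of the feature and the
// reverse-complement feature under the reversed mask, in a fixed total order)
// so that featurization, and hence any linear model over the features, is
// exactly strand-symmetric.
//
// Feature code layout: mask_index * 4^k + kmer_code, kmer_code msb-first over
// the masked positions.  Word (full L-mer) codes are msb-first base-4.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// all C(L, k) masks in lexicographic (combn) order, each a sorted position list
static std::vector< std::vector<int> > make_masks(int L, int k) {
  std::vector< std::vector<int> > masks;
  std::vector<int> idx(k);
  for (int i = 0; i < k; ++i) idx[i] = i;
  while (true) {
    masks.push_back(idx);
    int i = k - 1;
    while (i >= 0 && idx[i] == L - k + i) --i;
    if (i < 0) break;
    ++idx[i];
    for (int j = i + 1; j < k; ++j) idx[j] = idx[j - 1] + 1;
  }
  return masks;
}

struct GkmSpace {
  int L, k, n_masks;
  int64_t P;                               // 4^k
  std::vector< std::vector<int> > masks;   // positions, ascending
  std::vector<int> rc_mask;                // index of reverse-complement mask
  GkmSpace(int L_, int k_) : L(L_), k(k_) {
    masks = make_masks(L, k);
    n_masks = (int) masks.size();
    P = 1; for (int i = 0; i < k; ++i) P *= 4;
    // bitmask -> index lookup for rc mask resolution
    std::vector<int> lookup(1 << L, -1);
    for (int m = 0; m < n_masks; ++m) {
      int bits = 0;
      for (int p : masks[m]) bits |= (1 << p);
      lookup[bits] = m;
    }
    rc_mask.resize(n_masks);
    for (int m = 0; m < n_masks; ++m) {
      int bits = 0;
      for (int p : masks[m]) bits |= (1 << (L - 1 - p));
      rc_mask[m] = lookup[bits];
    }
  }
  // canonical feature code for window bases b[0..L-1] under mask m
  inline int64_t canonical(const int *b, int m) const {
    const std::vector<int> &pos = masks[m];
    int64_t code = 0, rc = 0;
    for (int i = 0; i < k; ++i) code = code * 4 + b[pos[i]];
    // letters of revcomp window at positions of rc_mask, ascending, are
    // complement of letters at mask positions taken in descending order
    for (int i = k - 1; i >= 0; --i) rc = rc * 4 + (3 - b[pos[i]]);
    int64_t a = (int64_t) m * P + code;
    int64_t bb = (int64_t) rc_mask[m] * P + rc;
    return a < bb ? a : bb;
  }
  // canonical code given the k masked digits only (msb-first) for mask m
  inline int64_t canonical_digits(const int *d, int m) const {
    int64_t code = 0, rc = 0;
    for (int i = 0; i < k; ++i) code = code * 4 + d[i];
    for (int i = k - 1; i >= 0; --i) rc = rc * 4 + (3 - d[i]);
    int64_t a = (int64_t) m * P + code;
    int64_t bb = (int64_t) rc_mask[m] * P + rc;
    return a < bb ? a : bb;
  }
};

// [[Rcpp::export]]
List gkm_space_info(int L, int k) {
  GkmSpace sp(L, k);
  return List::create(_["n_masks"] = sp.n_masks,
                      _["n_features"] = (double) sp.n_masks * (double) sp.P);
}

// Featurize sequences into canonical gapped k-mer counts.
// Returns triplet vectors (1-based i over sequences, 1-based j over features)
// plus per-sequence skipped-window counts (windows containing non-ACGT).
// [[Rcpp::export]]
List gkm_featurize_cpp(CharacterVector seqs, int L, int k) {
  GkmSpace sp(L, k);
  std::vector<int> out_i;
  std::vector<double> out_j, out_x;
  IntegerVector skipped(seqs.size());
  std::vector<int64_t> codes;
  for (int s = 0; s < seqs.size(); ++s) {
    const char *str = CHAR(STRING_ELT(seqs, s));
    int n = (int) LENGTH(STRING_ELT(seqs, s));
    if (n < L) stop("sequence %d is shorter than L = %d", s + 1, L);
    std::vector<int> b(n);
    for (int i = 0; i < n; ++i) b[i] = base_code(str[i]);
    codes.clear();
    int skip = 0;
    for (int w = 0; w + L <= n; ++w) {
      bool ok = true;
      for (int i = 0; i < L; ++i) if (b[w + i] < 0) { ok = false; break; }
      if (!ok) { ++skip; continue; }
      for (int m = 0; m < sp.n_masks; ++m)
        codes.push_back(sp.canonical(&b[w], m));
    }
    skipped[s] = skip;
    std::sort(codes.begin(), codes.end());
    for (size_t i = 0; i < codes.size();) {
      size_t j = i;
      while (j < codes.size() && codes[j] == codes[i]) ++j;
      out_i.push_back(s + 1);
      out_j.push_back((double) (codes[i] + 1));
      out_x.push_back((double) (j - i));
      i = j;
    }
  }
  return List::create(_["i"] = wrap(out_i), _["j"] = wrap(out_j),
                      _["x"] = wrap(out_x), _["skipped"] = skipped,
                      _["n_features"] = (double) sp.n_masks * (double) sp.P);
}

// Expand canonical-feature weights into a dense table over all 4^L words:
// table[word] = sum over masks of w[canonical(mask, word-at-mask)].
// By construction table[word] == table[revcomp(word)] exactly.
// [[Rcpp::export]]
NumericVector gkm_weight_table_cpp(NumericVector w, int L, int k) {
  if (L > 12) stop("weight table only supported for L <= 12");
  GkmSpace sp(L, k);
  int64_t nw = 1; for (int i = 0; i < L; ++i) nw *= 4;
  if ((double) sp.n_masks * (double) sp.P != (double) w.size())
    stop("weight vector has wrong length");
  NumericVector table(nw);
  int fk = L - k;
  int64_t nfill = 1; for (int i = 0; i < fk; ++i) nfill *= 4;
  std::vector<int64_t> spreadK(sp.P), spreadF(nfill);
  std::vector<int64_t> pow4(L);
  pow4[L - 1] = 1;
  for (int i = L - 2; i >= 0; --i) pow4[i] = pow4[i + 1] * 4;
  int dig[32];
  for (int m = 0; m < sp.n_masks; ++m) {
    const std::vector<int> &pos = sp.masks[m];
    std::vector<int> fpos;
    { std::vector<bool> in(L, false);
      for (int p : pos) in[p] = true;
      for (int p = 0; p < L; ++p) if (!in[p]) fpos.push_back(p); }
    for (int64_t c = 0; c < sp.P; ++c) {
      int64_t sprd = 0, cc = c;
      for (int i = k - 1; i >= 0; --i) { sprd += (cc & 3) * pow4[pos[i]]; cc >>= 2; }
      spreadK[c] = sprd;
    }
    for (int64_t f = 0; f < nfill; ++f) {
      int64_t sprd = 0, ff = f;
      for (int i = fk - 1; i >= 0; --i) { sprd += (ff & 3) * pow4[fpos[i]]; ff >>= 2; }
      spreadF[f] = sprd;
    }
    for (int64_t c = 0; c < sp.P; ++c) {
      int64_t cc = c;
      for (int i = k - 1; i >= 0; --i) { dig[i] = (int) (cc & 3); cc >>= 2; }
      double wc = w[sp.canonical_digits(dig, m)];
      if (wc == 0.0) continue;
      int64_t base = spreadK[c];
      for (int64_t f = 0; f < nfill; ++f) table[base + spreadF[f]] += wc;
    }
  }
  // enforce exact reverse-complement symmetry: the two sums contain the same
  // addends but in different order, so equalize them bit-for-bit
  for (int64_t wdc = 0; wdc < nw; ++wdc) {
    int64_t rc = 0, x = wdc;
    for (int i = 0; i < L; ++i) { rc = rc * 4 + (3 - (x & 3)); x >>= 2; }
    if (rc > wdc) table[rc] = table[wdc];
  }
  return table;
}

// Sum of table[word] over all valid (ACGT-only) L-windows of each sequence.
// [[Rcpp::export]]
NumericVector gkm_score_cpp(CharacterVector seqs, NumericVector table, int L) {
  int64_t nw = 1; for (int i = 0; i < L; ++i) nw *= 4;
  if ((int64_t) table.size() != nw) stop("table has wrong length for L");
  int64_t mask = nw / 4;  // weight of the leading digit
  NumericVector out(seqs.size());
  for (int s = 0; s < seqs.size(); ++s) {
    const char *str = CHAR(STRING_ELT(seqs, s));
    int n = (int) LENGTH(STRING_ELT(seqs, s));
    if (n < L) stop("sequence %d is shorter than L = %d", s + 1, L);
    std::vector<double> vals;
    vals.reserve(n);
    int64_t code = 0;
    int valid = 0;  // length of current run of ACGT bases
    for (int i = 0; i < n; ++i) {
      int b = base_code(str[i]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = (code % mask) * 4 + b;
      if (++valid >= L) vals.push_back(table[code]);
    }
    // order-independent summation so score(seq) == score(revcomp(seq)) exactly
    std::sort(vals.begin(), vals.end());
    double acc = 0.0;
    for (double v : vals) acc += v;
    out[s] = acc;
  }
  return out;
}

static inline int64_t window_code(const int *b, int L) {
  int64_t code = 0;
  for (int i = 0; i < L; ++i) {
    if (b[i] < 0) return -1;
    code = code * 4 + b[i];
  }
  return code;
}

// Batch deltaSVM for substitution sets introduced into one ancestor sequence.
// anc: base codes (0..3, -1 for non-ACGT); pos/bases: n_perm x n_sub matrices,
// pos 0-based.  Each row's delta = sum over windows overlapping any
// substituted position of (table[mutated window] - table[ancestral window]).
// Windows containing non-ACGT ancestor bases are skipped (as in scoring).
// [[Rcpp::export]]
NumericVector gkm_delta_batch_cpp(IntegerVector anc, NumericVector table,
                                  int L, IntegerMatrix pos, IntegerMatrix bases) {
  int n = anc.size();
  int n_perm = pos.nrow(), n_sub = pos.ncol();
  if (bases.nrow() != n_perm || bases.ncol() != n_sub)
    stop("pos and bases dimensions differ");
  std::vector<int> b(anc.begin(), anc.end());
  std::vector<int> stamp(std::max(0, n - L + 1), -1);
  NumericVector out(n_perm);
  std::vector<int> starts;
  for (int r = 0; r < n_perm; ++r) {
    double delta = 0.0;
    starts.clear();
    for (int s = 0; s < n_sub; ++s) {
      int p = pos(r, s);
      if (p < 0 || p >= n) stop("substitution position out of range");
      int lo = std::max(0, p - L + 1), hi = std::min(p, n - L);
      for (int w = lo; w <= hi; ++w)
        if (stamp[w] != r) { stamp[w] = r; starts.push_back(w); }
    }
    // ancestral windows
    for (int w : starts) {
      int64_t c = window_code(&b[w], L);
      if (c >= 0) delta -= table[c];
    }
    // apply substitutions
    for (int s = 0; s < n_sub; ++s) b[pos(r, s)] = bases(r, s);
    for (int w : starts) {
      int64_t c = window_code(&b[w], L);
      if (c >= 0) delta += table[c];
    }
    // restore
    for (int s = 0; s < n_sub; ++s) b[pos(r, s)] = anc[pos(r, s)];
    out[r] = delta;
  }
  return out;
}

// Ground-truth PWM scorer: per motif, the best log-odds window score over
// both strands; motifs with no valid (ACGT-only) window contribute 0.
// logodds: list of 4 x width matrices (column-major, rows A,C,G,T).
// [[Rcpp::export]]
double pwm_true_score_cpp(IntegerVector codes, List logodds) {
  int n = codes.size();
  double total = 0.0;
  for (int m = 0; m < logodds.size(); ++m) {
    NumericMatrix lo = logodds[m];
    int w = lo.ncol();
    if (n < w) continue;
    double best = R_NegInf;
    for (int s = 0; s + w <= n; ++s) {
      double fwd = 0.0, rev = 0.0;
      bool ok = true;
      for (int j = 0; j < w; ++j) {
        int b = codes[s + j];
        if (b < 0) { ok = false; break; }
        fwd += lo(b, j);
        rev += lo(3 - b, w - 1 - j);  // revcomp window against the motif
      }
      if (!ok) continue;
      if (fwd > best) best = fwd;
      if (rev > best) best = rev;
    }
    if (best > R_NegInf) total += best;
  }
  return total;
}
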