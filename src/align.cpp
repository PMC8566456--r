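#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

// Semi-global (glocal) alignment: the read is aligned end-to-end, reference
// overhangs on either side are free. Affine gaps: a run of k gapped bases
// scores gap_open + (k - 1) * gap_extend, i.e. gap_open already includes the
// first base of the run. 'N' never matches anything (scores as mismatch).

static const int NEG_INF = std::numeric_limits<int>::min() / 4;

static inline int base_score(char a, char b, int match, int mismatch) {
  if (a == 'N' || b == 'N') return mismatch;
  return (a == b) ? match : mismatch;
}

struct AlnResult {
  int score;
  int ref_start;   // 0-based first reference column covered
  int ref_end;     // 0-based half-open end of covered reference span
  std::string ref_aln;
  std::string read_aln;
};

// One left-alignment pass over maximal gap runs; returns true if anything
// moved. A run shifts one column left when the displaced base is identical to
// the one entering the run, so aligned base content is unchanged.
static bool left_shift_pass(std::string &a, std::string &b) {
  bool moved = false;
  const size_t L = a.size();
  for (int which = 0; which < 2; ++which) {
    std::string &g = (which == 0) ? b : a;  // row carrying the gap
    std::string &o = (which == 0) ? a : b;  // opposite row
    size_t i = 0;
    while (i < L) {
      if (g[i] != '-') { ++i; continue; }
      size_t s = i, e = i;
      while (e + 1 < L && g[e + 1] == '-') ++e;
      // shift the run [s, e] left as far as content allows
      while (s > 0 && g[s - 1] != '-' && o[s - 1] != '-' && o[s - 1] == o[e]) {
        g[e] = g[s - 1];
        g[s - 1] = '-';
        --s; --e;
        moved = true;
      }
      i = e + 1;
    }
  }
  return moved;
}

static void canonicalize(std::string &a, std::string &b) {
  while (left_shift_pass(a, b)) {
  }
}

static AlnResult align_one(const std::string &read, const std::string &ref,
                           int match, int mismatch, int gap_open,
                           int gap_extend, bool traceback) {
  const int n = (int)ref.size();   // reference length
  const int m = (int)read.size();  // read length
  const int W = m + 1;

  std::vector<int> H((size_t)(n + 1) * W, NEG_INF);
  std::vector<int> E((size_t)(n + 1) * W, NEG_INF);  // gap in read (deletion)
  std::vector<int> F((size_t)(n + 1) * W, NEG_INF);  // gap in ref (insertion)

  for (int i = 0; i <= n; ++i) H[(size_t)i * W] = 0;  // free ref prefix
  for (int j = 1; j <= m; ++j) {
    F[j] = gap_open + (j - 1) * gap_extend;  // leading read bases inserted
    H[j] = F[j];
  }

  for (int i = 1; i <= n; ++i) {
    const size_t row = (size_t)i * W, up = (size_t)(i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      int e = std::max(H[up + j] + gap_open, E[up + j] + gap_extend);
      int f = std::max(H[row + j - 1] + gap_open, F[row + j - 1] + gap_extend);
      int d = H[up + j - 1] + base_score(ref[i - 1], read[j - 1], match, mismatch);
      E[row + j] = e;
      F[row + j] = f;
      int h = d;
      if (e > h) h = e;
      if (f > h) h = f;
      H[row + j] = h;
    }
  }

  int best = NEG_INF, best_i = 0;
  for (int i = 0; i <= n; ++i) {  // strictly greater keeps the leftmost end
    int v = H[(size_t)i * W + m];
    if (v > best) { best = v; best_i = i; }
  }

  AlnResult res;
  res.score = best;
  if (!traceback) {
    res.ref_start = res.ref_end = 0;
    return res;
  }

  // Traceback from (best_i, m) until the read is exhausted. Tie order in H:
  // diagonal (match/substitution) first, then deletion, then insertion.
  std::string ra, ba;  // reversed
  int i = best_i, j = m;
  char state = 'H';
  while (j > 0) {
    const size_t row = (size_t)i * W, up = (size_t)(i - 1) * W;
    if (state == 'H') {
      int h = H[row + j];
      if (i > 0 && h == H[up + j - 1] + base_score(ref[i - 1], read[j - 1], match, mismatch)) {
        ra.push_back(ref[i - 1]);
        ba.push_back(read[j - 1]);
        --i; --j;
      } else if (i > 0 && h == E[row + j]) {
        state = 'E';
      } else {
        state = 'F';
      }
    } else if (state == 'E') {
      ra.push_back(ref[i - 1]);
      ba.push_back('-');
      bool close = (E[row + j] == H[up + j] + gap_open);
      bool extend = (i > 1) && (E[row + j] == E[up + j] + gap_extend);
      --i;
      if (close || !extend) state = 'H';
    } else {  // F
      ra.push_back('-');
      ba.push_back(read[j - 1]);
      bool close = (F[row + j] == H[row + j - 1] + gap_open);
      bool extend = (j > 1) && (F[row + j] == F[row + j - 1] + gap_extend);
      --j;
      if (close || !extend) state = 'H';
    }
  }

  std::reverse(ra.begin(), ra.end());
  std::reverse(ba.begin(), ba.end());
  canonicalize(ra, ba);

  res.ref_start = i;
  res.ref_end = best_i;
  res.ref_aln = ra;
  res.read_aln = ba;
  return res;
}

// [[Rcpp::export(name = ".cpp_align_semiglobal")]]
List cpp_align_semiglobal(CharacterVector reads, std::string reference,
                          int match, int mismatch, int gap_open,
                          int gap_extend) {
  const int nr = reads.size();
  IntegerVector score(nr), ref_start(nr), ref_end(nr);
  CharacterVector ref_aln(nr), read_aln(nr);
  for (int k = 0; k < nr; ++k) {
    std::string rd = as<std::string>(reads[k]);
    AlnResult r = align_one(rd, reference, match, mismatch, gap_open,
                            gap_extend, true);
    score[k] = r.score;
    ref_start[k] = r.ref_start;
    ref_end[k] = r.ref_end;
    ref_aln[k] = r.ref_aln;
    read_aln[k] = r.read_aln;
  }
  return List::create(_["score"] = score, _["ref_start"] = ref_start,
                      _["ref_end"] = ref_end, _["ref_aln"] = ref_aln,
                      _["read_aln"] = read_aln);
}

// [[Rcpp::export(name = ".cpp_semiglobal_score")]]
IntegerVector cpp_semiglobal_score(CharacterVector reads,
                                   CharacterVector references, int match,
                                   int mismatch, int gap_open,
                                   int gap_extend) {
  const int nr = reads.size();
  if (references.size() != nr) stop("reads and references must have equal length");
  IntegerVector score(nr);
  for (int k = 0; k < nr; ++k) {
    std::string rd = as<std::string>(reads[k]);
    std::string rf = as<std::string>(references[k]);
    score[k] = align_one(rd, rf, match, mismatch, gap_open, gap_extend,
                         false).score;
  }
  return score;
}

// [[Rcpp::export(name = ".cpp_left_align")]]
List cpp_left_align(std::string ref_aln, std::string read_aln) {
  if (ref_aln.size() != read_aln.size())
    stop("aligned rows must have equal length");
  canonicalize(ref_aln, read_aln);
  return List::create(_["ref_aln"] = ref_aln, _["read_aln"] = read_aln);
}
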