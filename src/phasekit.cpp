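#include <Rcpp.h>
using namespace Rcpp;

// Ungapped all-offsets local matcher and trigger-site complementarity
// scanner. Queries are short (18-28 nt) so per-diagonal work is bounded;
// window feasibility is checked with prefix match counts.

static inline char comp_base(char b) {
  switch (b) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

struct Hit {
  int subject;      // 0-based index into subject list
  int strand;       // +1 / -1
  int q_off;        // 0-based offset in query (plus-strand query coords)
  int s_off;        // 0-based offset in subject
  int len;
  int ident;
};

// Best accepted window on one diagonal, maximising (identities, len),
// leftmost on ties. Returns len 0 when no window passes.
static void best_window(const std::string &q, const std::string &s,
                        int diag, double min_ident, int min_len,
                        int &b_qo, int &b_len, int &b_id) {
  int m = (int)q.size(), n = (int)s.size();
  int q0 = std::max(0, -diag);           // first query index on diagonal
  int q1 = std::min(m, n - diag);        // one past last
  int L = q1 - q0;
  b_len = 0; b_id = -1; b_qo = 0;
  if (L < min_len) return;
  std::vector<int> pref(L + 1, 0);
  for (int i = 0; i < L; ++i)
    pref[i + 1] = pref[i] + (q[q0 + i] == s[q0 + i + diag] ? 1 : 0);
  for (int len = L; len >= min_len; --len) {
    int need = (int)std::ceil(min_ident * len - 1e-9);
    for (int a = 0; a + len <= L; ++a) {
      int id = pref[a + len] - pref[a];
      if (id < need) continue;
      if (id > b_id || (id == b_id && len > b_len)) {
        b_id = id; b_len = len; b_qo = q0 + a;
      }
    }
  }
  if (b_id < 0) { b_len = 0; b_id = 0; }
}

// [[Rcpp::export]]
DataFrame cpp_local_match(CharacterVector queries, CharacterVector subjects,
                          double min_ident, double min_cov, int min_len,
                          bool first_only) {
  std::vector<std::string> subj(subjects.size());
  for (int j = 0; j < subjects.size(); ++j)
    subj[j] = as<std::string>(subjects[j]);
  std::vector<int> r_query, r_subject, r_strand, r_qoff, r_soff, r_len, r_id;
  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string qp = as<std::string>(queries[qi]);
    int m = (int)qp.size();
    int need_len = std::max(min_len, (int)std::ceil(min_cov * m - 1e-9));
    std::string qm = revcomp(qp);
    bool done = false;
    for (int j = 0; j < (int)subj.size() && !done; ++j) {
      const std::string &s = subj[j];
      int n = (int)s.size();
      if (n < need_len) continue;
      for (int strand = 0; strand < 2 && !done; ++strand) {
        const std::string &q = strand == 0 ? qp : qm;
        for (int diag = -(m - need_len); diag <= n - need_len; ++diag) {
          int qo, len, id;
          best_window(q, s, diag, min_ident, need_len, qo, len, id);
          if (len == 0) continue;
          int qoff = strand == 0 ? qo : m - qo - len; // plus-strand query coords
          r_query.push_back(qi + 1);
          r_subject.push_back(j + 1);
          r_strand.push_back(strand == 0 ? 1 : -1);
          r_qoff.push_back(qoff);
          r_soff.push_back(qo + diag);
          r_len.push_back(len);
          r_id.push_back(id);
          if (first_only) { done = true; break; }
        }
      }
    }
  }
  return DataFrame::create(
    _["query"] = r_query, _["subject"] = r_subject, _["strand"] = r_strand,
    _["query_offset"] = r_qoff, _["subject_offset"] = r_soff,
    _["aligned_len"] = r_len, _["identities"] = r_id);
}

// Complementarity penalty of a trigger against one site placement.
// Trigger position i (1-based from the trigger 5' end) pairs, for a
// plus-strand transcript site, the window base at offset L-i; penalties:
// Watson-Crick 0, G:U wobble 0.5, mismatch 1, doubled for i in
// [core_from, core_to].
static double site_score_plus(const std::string &g, int w,
                              const std::string &trig,
                              int core_from, int core_to) {
  int L = (int)trig.size();
  double sc = 0.0;
  for (int i = 1; i <= L; ++i) {
    char t = trig[i - 1];
    char b = g[w + L - i];
    double pen;
    if (b == comp_base(t)) pen = 0.0;
    else if ((t == 'G' && b == 'T') || (t == 'T' && b == 'G')) pen = 0.5;
    else pen = 1.0;
    if (i >= core_from && i <= core_to) pen *= 2.0;
    sc += pen;
  }
  return sc;
}

// Minus-strand transcript: the site read 5'->3' is the reverse complement
// of the genomic window, so trigger position i pairs comp(g[w+i-1]).
static double site_score_minus(const std::string &g, int w,
                               const std::string &trig,
                               int core_from, int core_to) {
  int L = (int)trig.size();
  double sc = 0.0;
  for (int i = 1; i <= L; ++i) {
    char t = trig[i - 1];
    char b = g[w + i - 1];
    double pen;
    if (b == t) pen = 0.0; // comp(b) == comp(t) Watson-Crick
    else if ((t == 'G' && b == 'A') || (t == 'T' && b == 'C')) pen = 0.5;
    else pen = 1.0;
    if (i >= core_from && i <= core_to) pen *= 2.0;
    sc += pen;
  }
  return sc;
}

// Scan a sequence window for the best-scoring placement of each trigger on
// both transcript strands. Returns one row per trigger with the best hit
// (position is the 0-based leftmost coordinate within `seq`).
// [[Rcpp::export]]
DataFrame cpp_trigger_scan(std::string seq, CharacterVector triggers,
                           int core_from, int core_to) {
  int nt = triggers.size();
  IntegerVector pos(nt);
  IntegerVector strand(nt);
  NumericVector score(nt);
  for (int k = 0; k < nt; ++k) {
    std::string trig = as<std::string>(triggers[k]);
    int L = (int)trig.size();
    double best = R_PosInf;
    int bpos = NA_INTEGER, bstr = 0;
    int last = (int)seq.size() - L;
    for (int w = 0; w <= last; ++w) {
      double sp = site_score_plus(seq, w, trig, core_from, core_to);
      if (sp < best) { best = sp; bpos = w; bstr = 1; }
      double sm = site_score_minus(seq, w, trig, core_from, core_to);
      if (sm < best) { best = sm; bpos = w; bstr = -1; }
    }
    pos[k] = bpos; strand[k] = bstr;
    score[k] = R_FINITE(best) ? best : NA_REAL;
  }
  return DataFrame::create(_["position"] = pos, _["strand"] = strand,
                           _["score"] = score);
}
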