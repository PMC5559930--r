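#include <Rcpp.h>
#include <vector>
#include <map>
using namespace Rcpp;

// Gap-constrained containment: pattern tags must match at strictly
// increasing positions i_1 < ... < i_k with i_{j+1} - i_j <= max_gap.
// Positions are index differences, so max_gap = 1 means adjacent.
static bool contains_impl(const std::vector<int>& seq,
                          const std::vector<int>& pat,
                          int max_gap) {
  const int n = (int)seq.size(), k = (int)pat.size();
  if (k == 0 || k > n) return k == 0 ? false : false;
  // reachable end positions after matching a prefix of pat
  std::vector<int> ends;
  for (int i = 0; i < n; ++i) if (seq[i] == pat[0]) ends.push_back(i);
  for (int j = 1; j < k && !ends.empty(); ++j) {
    std::vector<int> next;
    for (int i = 0; i < n; ++i) {
      if (seq[i] != pat[j]) continue;
      for (int e : ends) {
        if (i > e && i - e <= max_gap) { next.push_back(i); break; }
      }
    }
    ends.swap(next);
  }
  return !ends.empty();
}

// [[Rcpp::export]]
bool seq_contains_cpp(IntegerVector seq, IntegerVector pattern, int max_gap) {
  std::vector<int> s = as< std::vector<int> >(seq);
  std::vector<int> p = as< std::vector<int> >(pattern);
  return contains_impl(s, p, max_gap);
}

// [[Rcpp::export]]
LogicalVector db_contains_cpp(List db, IntegerVector pattern, int max_gap) {
  const int N = db.size();
  std::vector<int> p = as< std::vector<int> >(pattern);
  LogicalVector out(N);
  for (int i = 0; i < N; ++i) {
    std::vector<int> s = as< std::vector<int> >((IntegerVector)db[i]);
    out[i] = contains_impl(s, p, max_gap);
  }
  return out;
}

// [[Rcpp::export]]
LogicalMatrix db_contains_multi_cpp(List db, List patterns, int max_gap) {
  const int N = db.size(), K = patterns.size();
  std::vector< std::vector<int> > seqs(N);
  for (int i = 0; i < N; ++i)
    seqs[i] = as< std::vector<int> >((IntegerVector)db[i]);
  LogicalMatrix out(N, K);
  for (int k = 0; k < K; ++k) {
    std::vector<int> p = as< std::vector<int> >((IntegerVector)patterns[k]);
    for (int i = 0; i < N; ++i) out(i, k) = contains_impl(seqs[i], p, max_gap);
  }
  return out;
}

struct MineState {
  std::vector< std::vector<int> > seqs;
  int max_gap, max_len, min_count, n_tags;
  std::vector< std::vector<int> > out_patterns;
  std::vector<int> out_counts;
};

// occ: for each containing sequence (by index), the set of feasible match
// end positions of the current pattern. Keeping every end position makes
// the extension step complete under the max-gap constraint.
static void grow(MineState& st,
                 std::vector<int>& pattern,
                 const std::vector<int>& seq_ids,
                 const std::vector< std::vector<int> >& occ) {
  st.out_patterns.push_back(pattern);
  st.out_counts.push_back((int)seq_ids.size());
  if ((int)pattern.size() >= st.max_len) return;

  // candidate extensions: tag -> (seq_ids, end positions)
  std::map<int, std::vector<int> > ext_ids;
  std::map<int, std::vector< std::vector<int> > > ext_occ;
  for (size_t si = 0; si < seq_ids.size(); ++si) {
    const std::vector<int>& s = st.seqs[seq_ids[si]];
    const std::vector<int>& ends = occ[si];
    std::map<int, std::vector<int> > local; // tag -> new ends in this seq
    for (int i = 0; i < (int)s.size(); ++i) {
      bool reach = false;
      for (int e : ends) if (i > e && i - e <= st.max_gap) { reach = true; break; }
      if (reach) local[s[i]].push_back(i);
    }
    for (std::map<int, std::vector<int> >::iterator it = local.begin();
         it != local.end(); ++it) {
      ext_ids[it->first].push_back(seq_ids[si]);
      ext_occ[it->first].push_back(it->second);
    }
  }
  for (std::map<int, std::vector<int> >::iterator it = ext_ids.begin();
       it != ext_ids.end(); ++it) {
    if ((int)it->second.size() < st.min_count) continue;
    pattern.push_back(it->first);
    grow(st, pattern, it->second, ext_occ[it->first]);
    pattern.pop_back();
  }
}

// [[Rcpp::export]]
List mine_fsps_cpp(List db, int n_tags, double min_support,
                   int max_gap, int max_len) {
  MineState st;
  const int N = db.size();
  st.seqs.reserve(N);
  for (int i = 0; i < N; ++i)
    st.seqs.push_back(as< std::vector<int> >((IntegerVector)db[i]));
  st.max_gap = max_gap;
  st.max_len = max_len;
  st.n_tags = n_tags;
  // smallest integer count c with c / N >= min_support
  st.min_count = (int)std::ceil(min_support * N - 1e-9);
  if (st.min_count < 1) st.min_count = 1;

  // length-1 seeds
  std::map<int, std::vector<int> > ids1;
  std::map<int, std::vector< std::vector<int> > > occ1;
  for (int i = 0; i < N; ++i) {
    std::map<int, std::vector<int> > local;
    for (int j = 0; j < (int)st.seqs[i].size(); ++j)
      local[st.seqs[i][j]].push_back(j);
    for (std::map<int, std::vector<int> >::iterator it = local.begin();
         it != local.end(); ++it) {
      ids1[it->first].push_back(i);
      occ1[it->first].push_back(it->second);
    }
  }
  std::vector<int> pattern;
  for (std::map<int, std::vector<int> >::iterator it = ids1.begin();
       it != ids1.end(); ++it) {
    if ((int)it->second.size() < st.min_count) continue;
    pattern.push_back(it->first);
    grow(st, pattern, it->second, occ1[it->first]);
    pattern.pop_back();
  }

  List pats(st.out_patterns.size());
  for (size_t i = 0; i < st.out_patterns.size(); ++i)
    pats[i] = wrap(st.out_patterns[i]);
  return List::create(_["patterns"] = pats,
                      _["counts"] = wrap(st.out_counts));
}
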