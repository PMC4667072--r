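#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Characters match only if equal and unambiguous; 'N' mismatches everything.
static inline bool base_match(char a, char b) {
  if (a == 'N' || b == 'N') return false;
  return a == b;
}

// Semi-global (infix) alignment of `guide` against `insert`: the whole guide
// is aligned to some substring of the insert, unit-cost Levenshtein.
// Returns every end position whose minimal distance is <= max_edits, with the
// traceback start, edit counts, and an op string in guide coordinates
// ("S<pos>:<observed>" substitution, "D<pos>:<base>" guide base deleted from
// the insert, "I<pos>:<base>" extra insert base after guide position <pos>).
// [[Rcpp::export]]
DataFrame cpp_semiglobal_hits(std::string insert, std::string guide,
                              int max_edits) {
  const int m = guide.size(), n = insert.size();
  if (m == 0) stop("guide must be non-empty");
  // full DP matrix: small problems only (guide ~22, insert <= ~80)
  std::vector<int> D((m + 1) * (n + 1));
  for (int j = 0; j <= n; ++j) D[j] = 0;              // free start in insert
  for (int i = 1; i <= m; ++i) D[i * (n + 1)] = i;    // guide prefix deleted
  for (int i = 1; i <= m; ++i) {
    const char g = guide[i - 1];
    int *row = &D[i * (n + 1)], *prev = &D[(i - 1) * (n + 1)];
    for (int j = 1; j <= n; ++j) {
      int diag = prev[j - 1] + (base_match(g, insert[j - 1]) ? 0 : 1);
      int up = prev[j] + 1;    // guide base deleted
      int left = row[j - 1] + 1;  // insert base inserted
      int best = diag < up ? diag : up;
      if (left < best) best = left;
      row[j] = best;
    }
  }
  std::vector<int> starts, ends, dists, nsubs, ndels, nins;
  std::vector<std::string> opss;
  for (int j_end = 0; j_end <= n; ++j_end) {
    int d = D[m * (n + 1) + j_end];
    if (d > max_edits) continue;
    if (j_end == 0) continue;  // empty span: guide entirely deleted
    // traceback; prefer diagonal, then up (deletion), then left (insertion)
    int i = m, j = j_end, s = 0, del = 0, ins = 0;
    std::string ops;
    while (i > 0) {
      int cur = D[i * (n + 1) + j];
      if (j > 0) {
        int diag = D[(i - 1) * (n + 1) + j - 1] +
                   (base_match(guide[i - 1], insert[j - 1]) ? 0 : 1);
        if (diag == cur) {
          if (!base_match(guide[i - 1], insert[j - 1])) {
            ++s;
            ops = "S" + std::to_string(i) + ":" + insert[j - 1] +
                  (ops.empty() ? "" : ";") + ops;
          }
          --i; --j;
          continue;
        }
      }
      if (D[(i - 1) * (n + 1) + j] + 1 == cur) {
        ++del;
        ops = "D" + std::to_string(i) + ":" + guide[i - 1] +
              (ops.empty() ? "" : ";") + ops;
        --i;
        continue;
      }
      // left move: extra insert base
      ++ins;
      ops = "I" + std::to_string(i) + ":" + insert[j - 1] +
            (ops.empty() ? "" : ";") + ops;
      --j;
    }
    starts.push_back(j + 1);  // 1-based; start > end possible only if empty span
    ends.push_back(j_end);
    dists.push_back(d);
    nsubs.push_back(s);
    ndels.push_back(del);
    nins.push_back(ins);
    opss.push_back(ops);
  }
  return DataFrame::create(_["start"] = starts, _["end"] = ends,
                           _["dist"] = dists, _["nsub"] = nsubs,
                           _["ndel"] = ndels, _["nins"] = nins,
                           _["ops"] = opss,
                           _["stringsAsFactors"] = false);
}

// Minimal semi-global distance only (used for fast screening).
// [[Rcpp::export]]
int cpp_semiglobal_min(std::string insert, std::string guide) {
  const int m = guide.size(), n = insert.size();
  std::vector<int> prev(n + 1, 0), cur(n + 1);
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    const char g = guide[i - 1];
    for (int j = 1; j <= n; ++j) {
      int best = prev[j - 1] + (base_match(g, insert[j - 1]) ? 0 : 1);
      if (prev[j] + 1 < best) best = prev[j] + 1;
      if (cur[j - 1] + 1 < best) best = cur[j - 1] + 1;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  int d = prev[0];
  for (int j = 1; j <= n; ++j) if (prev[j] < d) d = prev[j];
  return d;
}

// 3'-anchored adapter removal: the best (longest) suffix of each read that
// matches a prefix of the adapter with mismatch rate <= max_error_rate and
// overlap >= min_overlap. Returns insert lengths; length(read) if no match.
// [[Rcpp::export]]
List cpp_trim_adapter(CharacterVector reads, std::string adapter,
                      int min_overlap, double max_error_rate) {
  const int nr = reads.size(), alen = adapter.size();
  IntegerVector ins_len(nr);
  LogicalVector trimmed(nr);
  for (int r = 0; r < nr; ++r) {
    std::string rd = as<std::string>(reads[r]);
    const int L = rd.size();
    int keep = L;
    bool hit = false;
    int omax = std::min(L, alen);
    for (int o = omax; o >= min_overlap; --o) {
      int mm = 0;
      int allowed = (int)std::floor(max_error_rate * o + 1e-9);
      for (int k = 0; k < o && mm <= allowed; ++k)
        if (!base_match(rd[L - o + k], adapter[k])) ++mm;
      if (mm <= allowed) { keep = L - o; hit = true; break; }
    }
    ins_len[r] = keep;
    trimmed[r] = hit;
  }
  return List::create(_["insert_length"] = ins_len, _["trimmed"] = trimmed);
}
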