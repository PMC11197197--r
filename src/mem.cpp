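#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
using namespace Rcpp;

// Forward-strand maximal exact matches of length >= min_len between a and b.
// Seeds of length min_len are hashed from a and scanned along b; each seed is
// extended maximally in both directions. Seeds falling inside a match already
// emitted on the same diagonal are skipped, so every MEM is reported once.
// Coordinates 0-based half-open.
// [[Rcpp::export(name = ".mems_fwd")]]
IntegerMatrix mems_fwd(std::string a, std::string b, int min_len) {
  const int n = a.size(), m = b.size(), k = min_len;
  std::vector<int> ra, re, rb;
  if (n >= k && m >= k) {
    std::unordered_map<std::string, std::vector<int>> idx;
    idx.reserve(n);
    for (int i = 0; i + k <= n; ++i) idx[a.substr(i, k)].push_back(i);
    std::unordered_map<long long, int> diag_bend; // diagonal -> b end covered
    for (int j = 0; j + k <= m; ++j) {
      auto it = idx.find(b.substr(j, k));
      if (it == idx.end()) continue;
      for (int i : it->second) {
        long long diag = (long long)i - j + m; // shift to keep positive-ish keys
        auto d = diag_bend.find(diag);
        if (d != diag_bend.end() && j + k <= d->second) continue; // inside prior MEM
        int li = i, lj = j;
        while (li > 0 && lj > 0 && a[li - 1] == b[lj - 1]) { --li; --lj; }
        int ei = i + k, ej = j + k;
        while (ei < n && ej < m && a[ei] == b[ej]) { ++ei; ++ej; }
        diag_bend[diag] = ej;
        if (ei - li >= k) { ra.push_back(li); re.push_back(ei); rb.push_back(lj); }
      }
    }
  }
  IntegerMatrix out(ra.size(), 4);
  for (size_t r = 0; r < ra.size(); ++r) {
    out(r, 0) = ra[r]; out(r, 1) = re[r];
    out(r, 2) = rb[r]; out(r, 3) = rb[r] + (re[r] - ra[r]);
  }
  colnames(out) = CharacterVector::create("a_start", "a_end", "b_start", "b_end");
  return out;
}
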