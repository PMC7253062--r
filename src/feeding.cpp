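#include <Rcpp.h>
using namespace Rcpp;

// Sequential all-or-nothing feeding within a timepoint.
//
// Individuals are processed in the caller-supplied (seeded, randomized)
// order `ord` (1-based indices into the other vectors). Individual i is
// fed iff the food currently left in its cell is at least need[i]; a fed
// individual removes take[i] units (take = 0 encodes a non-consuming
// probe by an arrested stage). Starved individuals remove nothing, so a
// later, cheaper consumer can still feed from the same cell.
//
// [[Rcpp::export]]
List resolve_feeding(IntegerVector ord, IntegerVector cell,
                     NumericVector need, NumericVector take,
                     NumericVector food) {
  int n = ord.size();
  NumericVector food_out = clone(food);
  LogicalVector fed(cell.size());
  for (int k = 0; k < n; ++k) {
    int i = ord[k] - 1;
    int c = cell[i] - 1;
    if (food_out[c] >= need[i]) {
      fed[i] = true;
      food_out[c] -= take[i];
    }
  }
  return List::create(_["fed"] = fed, _["food"] = food_out);
}
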