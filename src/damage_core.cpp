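#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <functional>
#include <map>
#include <vector>

using namespace Rcpp;

// Category codes share one ordering everywhere:
// 0 BD, 1 SSB, 2 SSBp, 3 twoSSB, 4 DSB, 5 DSBp, 6 DSBpp

// ---- classification -------------------------------------------------------

// Greedy left-to-right count of disjoint opposite-strand break pairs with
// position difference <= gap. Breaks must be sorted by position.
static int greedy_ndsb(const std::vector<int> &bpos, const std::vector<int> &bstr,
                       int gap) {
  int n = (int)bpos.size();
  std::vector<char> used(n, 0);
  int ndsb = 0;
  for (int i = 0; i < n; ++i) {
    if (used[i]) continue;
    for (int j = i + 1; j < n; ++j) {
      if (used[j] || bstr[j] == bstr[i]) continue;
      if (bpos[j] - bpos[i] <= gap) {
        used[i] = used[j] = 1;
        ++ndsb;
        break;
      }
    }
  }
  return ndsb;
}

// Classify one cluster given sorted lesion arrays. kind: 1 strand break, 0 BD.
static int classify_core(const std::vector<int> &pos, const std::vector<int> &strand,
                         const std::vector<int> &kind, int gap) {
  std::vector<int> bpos, bstr;
  for (size_t i = 0; i < pos.size(); ++i) {
    if (kind[i] == 1) {
      bpos.push_back(pos[i]);
      bstr.push_back(strand[i]);
    }
  }
  int nb = (int)bpos.size();
  if (nb == 0) return 0;  // BD
  if (nb == 1) return 1;  // SSB
  int ndsb = greedy_ndsb(bpos, bstr, gap);
  if (ndsb >= 2) return 6;               // DSBpp
  if (ndsb == 1 && nb >= 3) return 5;    // DSBp
  if (ndsb == 1) return 4;               // DSB
  bool s0 = false, s1 = false;
  for (int i = 0; i < nb; ++i) (bstr[i] == 0 ? s0 : s1) = true;
  if (s0 && s1) return 3;  // twoSSB
  return 2;                // SSBp
}

// [[Rcpp::export]]
int cpp_classify_cluster(IntegerVector position, IntegerVector strand,
                         IntegerVector kind, int gap) {
  int n = position.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (position[a] != position[b]) return position[a] < position[b];
    return strand[a] < strand[b];
  });
  std::vector<int> p(n), s(n), k(n);
  for (int i = 0; i < n; ++i) {
    p[i] = position[idx[i]];
    s[i] = strand[idx[i]];
    k[i] = kind[idx[i]];
  }
  return classify_core(p, s, k, gap);
}

// ---- induction simulator --------------------------------------------------

// Simulate n_sites damage sites and return per-category cluster counts plus
// the total number of clusters and lesions. Uses R's RNG.
// [[Rcpp::export]]
NumericVector cpp_sim_damage(int n_sites, double lambda, double sb_fraction,
                             int segment_length, int gap) {
  NumericVector out(9);  // 7 categories, n_clusters, n_lesions
  std::vector<int> pos, str, kin, idx;
  for (int site = 0; site < n_sites; ++site) {
    int k = 1 + (int)R::rpois(lambda);
    if (k > segment_length) k = segment_length;  // degenerate guard
    out[8] += k;
    if (k == 1) {
      int cat = (unif_rand() < sb_fraction) ? 1 : 0;
      out[cat] += 1.0;
      out[7] += 1.0;
      continue;
    }
    pos.assign(k, 0);
    str.assign(k, 0);
    kin.assign(k, 0);
    for (int i = 0; i < k; ++i) {
      str[i] = (unif_rand() < 0.5) ? 0 : 1;
      kin[i] = (unif_rand() < sb_fraction) ? 1 : 0;
      bool ok = false;
      while (!ok) {
        pos[i] = (int)(unif_rand() * segment_length);
        if (pos[i] >= segment_length) pos[i] = segment_length - 1;
        ok = true;
        for (int j = 0; j < i; ++j) {
          if (pos[j] == pos[i] && str[j] == str[i]) { ok = false; break; }
        }
      }
    }
    idx.assign(k, 0);
    for (int i = 0; i < k; ++i) idx[i] = i;
    std::sort(idx.begin(), idx.end(), [&](int a, int b) {
      if (pos[a] != pos[b]) return pos[a] < pos[b];
      return str[a] < str[b];
    });
    // chain clusters: split where consecutive sorted positions differ > gap
    int start = 0;
    for (int i = 1; i <= k; ++i) {
      if (i == k || pos[idx[i]] - pos[idx[i - 1]] > gap) {
        std::vector<int> cp, cs, ck;
        for (int j = start; j < i; ++j) {
          cp.push_back(pos[idx[j]]);
          cs.push_back(str[idx[j]]);
          ck.push_back(kin[idx[j]]);
        }
        out[classify_core(cp, cs, ck, gap)] += 1.0;
        out[7] += 1.0;
        start = i;
      }
    }
  }
  return out;
}

// ---- independent brute-force oracle ---------------------------------------

// Maximum number of disjoint opposite-strand pairs by explicit enumeration.
static int brute_max_pairs(std::vector<int> &bpos, std::vector<int> &bstr,
                           std::vector<char> &used, int gap) {
  int n = (int)bpos.size();
  int best = 0;
  for (int i = 0; i < n; ++i) {
    if (used[i]) continue;
    for (int j = 0; j < n; ++j) {
      if (j == i || used[j] || bstr[j] == bstr[i]) continue;
      if (std::abs(bpos[j] - bpos[i]) <= gap) {
        used[i] = used[j] = 1;
        int v = 1 + brute_max_pairs(bpos, bstr, used, gap);
        used[i] = used[j] = 0;
        if (v > best) best = v;
      }
    }
  }
  return best;
}

static int classify_brute(const std::vector<int> &pos, const std::vector<int> &strand,
                          const std::vector<int> &kind, int gap) {
  std::vector<int> bpos, bstr;
  for (size_t i = 0; i < pos.size(); ++i)
    if (kind[i] == 1) { bpos.push_back(pos[i]); bstr.push_back(strand[i]); }
  int nb = (int)bpos.size();
  std::vector<char> used(nb, 0);
  int ndsb = brute_max_pairs(bpos, bstr, used, gap);
  int n0 = 0, n1 = 0;
  for (int i = 0; i < nb; ++i) (bstr[i] == 0 ? n0 : n1)++;
  if (ndsb >= 2) return 6;
  if (ndsb == 1) return (nb > 2) ? 5 : 4;
  if (n0 > 0 && n1 > 0) return 3;
  if (nb >= 2) return 2;
  if (nb == 1) return 1;
  return 0;
}

// Union-find clustering (oracle side).
static int uf_find(std::vector<int> &par, int i) {
  while (par[i] != i) { par[i] = par[par[i]]; i = par[i]; }
  return i;
}

// [[Rcpp::export]]
int cpp_classify_cluster_brute(IntegerVector position, IntegerVector strand,
                               IntegerVector kind, int gap) {
  std::vector<int> p(position.begin(), position.end());
  std::vector<int> s(strand.begin(), strand.end());
  std::vector<int> k(kind.begin(), kind.end());
  return classify_brute(p, s, k, gap);
}

// Exhaustive comparison of the production pipeline (chain clustering +
// greedy pairing) against the brute-force oracle (union-find clustering +
// enumerated maximum matching) over every configuration of 1..max_lesions
// lesions on a window of `window` base pairs, both strands, both kinds.
// [[Rcpp::export]]
List cpp_exhaustive_classifier_check(int window, int max_lesions, int gap) {
  long long checked = 0, mismatch = 0;
  List first_bad = R_NilValue;
  int nslots = 2 * window;
  std::vector<int> slots(max_lesions);

  std::function<void(int, int, int)> recurse = [&](int m, int depth, int start) {
    if (depth == m) {
      // kinds: 2^m assignments
      for (int mask = 0; mask < (1 << m); ++mask) {
        std::vector<int> pos(m), str(m), kin(m);
        for (int i = 0; i < m; ++i) {
          pos[i] = slots[i] / 2;   // slots ascending => positions sorted
          str[i] = slots[i] % 2;
          kin[i] = (mask >> i) & 1;
        }
        // production path: chain clustering + greedy classification
        std::vector<int> cat_prod, cat_oracle;
        int s0 = 0;
        for (int i = 1; i <= m; ++i) {
          if (i == m || pos[i] - pos[i - 1] > gap) {
            std::vector<int> cp(pos.begin() + s0, pos.begin() + i);
            std::vector<int> cs(str.begin() + s0, str.begin() + i);
            std::vector<int> ck(kin.begin() + s0, kin.begin() + i);
            cat_prod.push_back(classify_core(cp, cs, ck, gap));
            s0 = i;
          }
        }
        // oracle path: union-find over all pairs, brute-force matching
        std::vector<int> par(m);
        for (int i = 0; i < m; ++i) par[i] = i;
        for (int i = 0; i < m; ++i)
          for (int j = i + 1; j < m; ++j)
            if (std::abs(pos[j] - pos[i]) <= gap)
              par[uf_find(par, i)] = uf_find(par, j);
        std::map<int, std::vector<int>> groups;
        for (int i = 0; i < m; ++i) groups[uf_find(par, i)].push_back(i);
        std::vector<std::pair<int, int>> ordered;  // (leftmost pos, root)
        for (auto &g : groups) {
          int lo = pos[g.second[0]];
          for (int i : g.second) lo = std::min(lo, pos[i]);
          ordered.push_back({lo, g.first});
        }
        std::sort(ordered.begin(), ordered.end());
        for (auto &og : ordered) {
          std::vector<int> cp, cs, ck;
          for (int i : groups[og.second]) {
            cp.push_back(pos[i]); cs.push_back(str[i]); ck.push_back(kin[i]);
          }
          cat_oracle.push_back(classify_brute(cp, cs, ck, gap));
        }
        ++checked;
        if (cat_prod != cat_oracle) {
          ++mismatch;
          if (first_bad.isNULL()) {
            first_bad = List::create(_["position"] = wrap(pos),
                                     _["strand"] = wrap(str),
                                     _["kind"] = wrap(kin));
          }
        }
      }
      return;
    }
    for (int s = start; s < nslots; ++s) {
      slots[depth] = s;
      recurse(m, depth + 1, s + 1);
    }
  };

  for (int m = 1; m <= max_lesions; ++m) recurse(m, 0, 0);
  return List::create(_["n_checked"] = (double)checked,
                      _["n_mismatch"] = (double)mismatch,
                      _["first_mismatch"] = first_bad);
}

// ---- excision repair state machine ----------------------------------------

// Pathway codes: 0 SP_BER, 1 LP_BER, 2 NER_SP_BER, 3 NER_LP_BER
// Outcome codes: 0 correct repair, 1 mutation, 2 DSB conversion

static int repair_once(const std::vector<int> &pos, const std::vector<int> &str,
                       const std::vector<int> &kin, int pathway, int inhibition,
                       double p_first, double err_sp, double err_lp_ner,
                       double p_mis_damaged, int lp_min, int lp_max) {
  int n = (int)pos.size();
  std::vector<char> alive(n, 1);
  bool mis = false;
  int n_alive = n;
  while (n_alive > 0) {
    // split alive lesions by kind
    std::vector<int> brk, bd;
    for (int i = 0; i < n; ++i) {
      if (!alive[i]) continue;
      (kin[i] == 1 ? brk : bd).push_back(i);
    }
    bool pick_break;
    if (!brk.empty() && !bd.empty())
      pick_break = unif_rand() < p_first;
    else
      pick_break = !brk.empty();
    const std::vector<int> &cls = pick_break ? brk : bd;
    int sel = cls[std::min((int)(unif_rand() * cls.size()), (int)cls.size() - 1)];

    // excision mode: SP (1 nt, 3'), LP (patch, 3'), NER (patch, two-sided)
    bool is_sp, is_ner;
    if (pathway == 0) { is_sp = true; is_ner = false; }
    else if (pathway == 1) { is_sp = false; is_ner = false; }
    else if (pathway == 2) { is_ner = (kin[sel] == 0); is_sp = !is_ner; }
    else { is_ner = (kin[sel] == 0); is_sp = false; }

    int L = 1, left = 0;
    if (!is_sp) {
      L = lp_min + (int)(unif_rand() * (lp_max - lp_min + 1));
      if (L > lp_max) L = lp_max;
      if (is_ner) left = (L - 1) / 2;
    }
    int a = pos[sel] - left, b = a + L - 1;
    double fill_err = is_sp ? err_sp : err_lp_ner;

    // co-excision: same-strand alive lesions inside the patch are removed
    for (int i = 0; i < n; ++i) {
      if (alive[i] && str[i] == str[sel] && pos[i] >= a && pos[i] <= b) {
        alive[i] = 0;
        --n_alive;
      }
    }
    // DSB conversion: opposite-strand break within inhibition distance of gap
    for (int i = 0; i < n; ++i) {
      if (!alive[i] || str[i] == str[sel] || kin[i] != 1) continue;
      int d = (pos[i] < a) ? a - pos[i] : (pos[i] > b ? pos[i] - b : 0);
      if (d <= inhibition) return 2;
    }
    // gap filling: damaged base in template span raises mis-insertion rate
    double p_mis = fill_err;
    for (int i = 0; i < n; ++i) {
      if (alive[i] && str[i] != str[sel] && kin[i] == 0 && pos[i] >= a &&
          pos[i] <= b) {
        p_mis = p_mis_damaged;
        break;
      }
    }
    if (unif_rand() < p_mis) mis = true;
  }
  return mis ? 1 : 0;
}

// [[Rcpp::export]]
NumericVector cpp_repair_mc(IntegerVector position, IntegerVector strand,
                            IntegerVector kind, int pathway, int n_trials,
                            int inhibition, double p_first, double err_sp,
                            double err_lp_ner, double p_mis_damaged,
                            int lp_min, int lp_max) {
  std::vector<int> p(position.begin(), position.end());
  std::vector<int> s(strand.begin(), strand.end());
  std::vector<int> k(kind.begin(), kind.end());
  NumericVector out(3);
  for (int t = 0; t < n_trials; ++t) {
    out[repair_once(p, s, k, pathway, inhibition, p_first, err_sp, err_lp_ner,
                    p_mis_damaged, lp_min, lp_max)] += 1.0;
  }
  return out;
}
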