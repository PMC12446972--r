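#include <Rcpp.h>
using namespace Rcpp;

// terminus status codes: 0 enzymatic, 1 nonenzymatic, 2 protein_terminal
// class codes: 0 full, 1 semi_N, 2 semi_C, 3 nonspecific

static inline int classRank(int cls) {
  switch (cls) {
  case 0: return 3;        // full
  case 1: case 2: return 2; // semi
  default: return 1;       // nonspecific
  }
}

static inline int specClass(int nstat, int cstat) {
  bool nNon = nstat == 1, cNon = cstat == 1;
  if (!nNon && !cNon) return 0;
  if (nNon && !cNon) return 1;
  if (!nNon && cNon) return 2;
  return 3;
}

// Batch enzymatic-specificity classification. For each peptide, all exact
// occurrences in each of its mapped proteins are scored and the
// most-specific one kept (full > semi > nonspecific; ties -> earliest
// occurrence in the first-listed protein).
// [[Rcpp::export]]
List classify_batch(CharacterVector peptides, List protein_idx,
                    CharacterVector protein_seqs, std::string cleave_after,
                    bool proline_block, int nterm_window) {
  const int n = peptides.size();
  bool cleave[256] = {false};
  for (size_t i = 0; i < cleave_after.size(); ++i)
    cleave[(unsigned char)cleave_after[i]] = true;

  IntegerVector out_start(n, NA_INTEGER), out_end(n, NA_INTEGER),
    out_nstat(n, NA_INTEGER), out_cstat(n, NA_INTEGER),
    out_class(n, NA_INTEGER), out_prot(n, NA_INTEGER);
  LogicalVector out_found(n, false), out_excl(n, false);

  std::vector<std::string> seqs(protein_seqs.size());
  for (int j = 0; j < protein_seqs.size(); ++j)
    seqs[j] = as<std::string>(protein_seqs[j]);

  for (int i = 0; i < n; ++i) {
    std::string pep = as<std::string>(peptides[i]);
    IntegerVector prots = protein_idx[i];
    int bestRank = -1;
    for (int pj = 0; pj < prots.size(); ++pj) {
      const std::string &sq = seqs[prots[pj] - 1];
      size_t pos = sq.find(pep);
      while (pos != std::string::npos) {
        int s = (int)pos + 1;                 // 1-based
        int e = s + (int)pep.size() - 1;
        int L = (int)sq.size();
        int nstat, cstat;
        if (s <= nterm_window) nstat = 2;
        else {
          char prev = sq[s - 2], first = sq[s - 1];
          nstat = (cleave[(unsigned char)prev] &&
                   !(proline_block && first == 'P')) ? 0 : 1;
        }
        if (e == L) cstat = 2;
        else {
          char last = sq[e - 1], next = sq[e];
          cstat = (cleave[(unsigned char)last] &&
                   !(proline_block && next == 'P')) ? 0 : 1;
        }
        int cls = specClass(nstat, cstat);
        int rank = classRank(cls);
        if (rank > bestRank) {
          bestRank = rank;
          out_start[i] = s; out_end[i] = e;
          out_nstat[i] = nstat; out_cstat[i] = cstat;
          out_class[i] = cls; out_prot[i] = prots[pj];
          out_excl[i] = (nstat == 2) || (cstat == 2);
          out_found[i] = true;
        }
        pos = sq.find(pep, pos + 1);
      }
    }
  }
  return List::create(_["start"] = out_start, _["end"] = out_end,
                      _["nstat"] = out_nstat, _["cstat"] = out_cstat,
                      _["class"] = out_class, _["protein"] = out_prot,
                      _["excluded"] = out_excl, _["found"] = out_found);
}
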