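#include <Rcpp.h>
using namespace Rcpp;

// Semi-global alignment of a position-specific profile against a protein.
//
// All match states of the profile must be consumed (matched or deleted);
// the protein contributes an arbitrary substring, i.e. leading and trailing
// residues outside the aligned span are free.  Affine gap costs: the first
// position of a deletion (skipped state) or insertion (unmatched residue
// between consumed states) run costs `gap_open`, each further position
// `gap_extend`; both are positive penalties subtracted from the score.
//
// emissions: m x 20 matrix of log-odds (bits), rows = match states.
// protein:   integer vector, 0..19 = residue index, -1 = unknown (scores 0).
//
// Returns score plus the 1-based protein positions of the first and last
// residue consumed by the alignment (0 if every state was deleted).
// [[Rcpp::export]]
List profile_align_cpp(NumericMatrix emissions, IntegerVector protein,
                       double gap_open, double gap_extend) {
  const int m = emissions.nrow();
  const int n = protein.size();
  const double NEG = -1e30;

  // Rolling rows over states; index j = number of residues consumed (0..n).
  std::vector<double> Mp(n + 1, NEG), Dp(n + 1, NEG), Ip(n + 1, NEG);
  std::vector<double> Mc(n + 1, NEG), Dc(n + 1, NEG), Ic(n + 1, NEG);
  // Track the start (first consumed residue) of the optimal path per cell.
  std::vector<int> sMp(n + 1, 0), sDp(n + 1, 0), sIp(n + 1, 0);
  std::vector<int> sMc(n + 1, 0), sDc(n + 1, 0), sIc(n + 1, 0);

  for (int i = 1; i <= m; ++i) {
    std::fill(Mc.begin(), Mc.end(), NEG);
    std::fill(Dc.begin(), Dc.end(), NEG);
    std::fill(Ic.begin(), Ic.end(), NEG);

    for (int j = 0; j <= n; ++j) {
      // M: state i matched to residue j (requires j >= 1).
      if (j >= 1) {
        int aa = protein[j - 1];
        double e = (aa >= 0) ? emissions(i - 1, aa) : 0.0;
        double best;
        int start;
        if (i == 1) {
          best = 0.0;          // free leading flank
          start = j;
        } else {
          best = Mp[j - 1]; start = sMp[j - 1];
          if (Dp[j - 1] > best) { best = Dp[j - 1]; start = sDp[j - 1]; }
          if (Ip[j - 1] > best) { best = Ip[j - 1]; start = sIp[j - 1]; }
          if (start == 0) start = j; // path so far consumed nothing
        }
        if (best > NEG / 2) { Mc[j] = best + e; sMc[j] = start; }
      }
      // D: state i deleted.
      {
        double best; int start;
        if (i == 1) {
          best = -gap_open; start = 0;
        } else {
          best = Mp[j] - gap_open; start = sMp[j];
          if (Dp[j] - gap_extend > best) { best = Dp[j] - gap_extend; start = sDp[j]; }
          if (Ip[j] - gap_open > best) { best = Ip[j] - gap_open; start = sIp[j]; }
        }
        if (best > NEG / 2) { Dc[j] = best; sDc[j] = start; }
      }
      // I: insertion after state i (only meaningful while states remain).
      if (j >= 1 && i < m) {
        double best = Mc[j - 1] - gap_open; int start = sMc[j - 1];
        if (Ic[j - 1] - gap_extend > best) { best = Ic[j - 1] - gap_extend; start = sIc[j - 1]; }
        if (Dc[j - 1] - gap_open > best) { best = Dc[j - 1] - gap_open; start = sDc[j - 1]; }
        if (best > NEG / 2) { Ic[j] = best; sIc[j] = start; }
      }
    }
    std::swap(Mp, Mc); std::swap(Dp, Dc); std::swap(Ip, Ic);
    std::swap(sMp, sMc); std::swap(sDp, sDc); std::swap(sIp, sIc);
  }

  double best = NEG; int end = 0, start = 0;
  for (int j = 0; j <= n; ++j) {
    if (Mp[j] > best) { best = Mp[j]; end = j; start = sMp[j]; }
    if (Dp[j] > best) { best = Dp[j]; end = j; start = sDp[j]; }
  }
  // `end` counts consumed residues; trailing flank is free, so the last
  // consumed residue is the alignment end (0 when nothing was consumed).
  return List::create(_["score"] = best, _["start"] = start, _["end"] = end);
}

// Score-only variant of the same recurrence (no span tracking), used for
// the proteome scan and threshold calibration where only the score matters.
static double score_only(const double* em, int m, const int* prot, int n,
                         double gap_open, double gap_extend,
                         std::vector<double>& Mp, std::vector<double>& Dp,
                         std::vector<double>& Ip, std::vector<double>& Mc,
                         std::vector<double>& Dc, std::vector<double>& Ic) {
  const double NEG = -1e30;
  Mp.assign(n + 1, NEG); Dp.assign(n + 1, NEG); Ip.assign(n + 1, NEG);
  Mc.resize(n + 1); Dc.resize(n + 1); Ic.resize(n + 1);
  for (int i = 1; i <= m; ++i) {
    const double* erow = em + (i - 1);        // column-major: stride m
    const bool first = (i == 1), last = (i == m);
    Mc[0] = NEG;
    Dc[0] = first ? -gap_open
                  : std::max(Mp[0] - gap_open,
                             std::max(Dp[0] - gap_extend, Ip[0] - gap_open));
    Ic[0] = NEG;
    for (int j = 1; j <= n; ++j) {
      int aa = prot[j - 1];
      double e = (aa >= 0) ? erow[(size_t)aa * m] : 0.0;
      double bm = first ? 0.0
                        : std::max(Mp[j - 1],
                                   std::max(Dp[j - 1], Ip[j - 1]));
      Mc[j] = (bm > NEG / 2) ? bm + e : NEG;
      double bd = first ? -gap_open
                        : std::max(Mp[j] - gap_open,
                                   std::max(Dp[j] - gap_extend, Ip[j] - gap_open));
      Dc[j] = bd;
      if (!last) {
        double bi = std::max(Mc[j - 1] - gap_open,
                             std::max(Ic[j - 1] - gap_extend, Dc[j - 1] - gap_open));
        Ic[j] = bi;
      } else {
        Ic[j] = NEG;
      }
    }
    std::swap(Mp, Mc); std::swap(Dp, Dc); std::swap(Ip, Ic);
  }
  double best = NEG;
  for (int j = 0; j <= n; ++j) {
    if (Mp[j] > best) best = Mp[j];
    if (Dp[j] > best) best = Dp[j];
  }
  return best;
}

// Score many proteins against one profile.
// [[Rcpp::export]]
NumericVector profile_score_many_cpp(NumericMatrix emissions, List proteins,
                                     double gap_open, double gap_extend) {
  const int np = proteins.size();
  const int m = emissions.nrow();
  const double* em = REAL(emissions);
  NumericVector out(np);
  std::vector<double> Mp, Dp, Ip, Mc, Dc, Ic;
  for (int p = 0; p < np; ++p) {
    IntegerVector prot = proteins[p];
    out[p] = score_only(em, m, INTEGER(prot), prot.size(),
                        gap_open, gap_extend, Mp, Dp, Ip, Mc, Dc, Ic);
  }
  return out;
}
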