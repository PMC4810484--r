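#include <Rcpp.h>
using namespace Rcpp;

// Alignment and profile-HMM dynamic programming kernels.
// Sequences arrive as 0-based integer vectors indexing the amino-acid
// alphabet; an index equal to the alphabet size denotes the ambiguity
// letter X (scored 0 against everything, emitted at background odds 1).
//
// Gap convention (BLAST-style): a gap of length k costs open + k * extend,
// i.e. the first gapped residue pays open + extend, each further one extend.

static const double NEG_INF = -1e300;

// ---------------------------------------------------------------- local SW

// Rolling-row Smith-Waterman that carries path statistics (matches, aligned
// columns, start coordinates) alongside each state's score, so no traceback
// matrices are needed. Ties between predecessors are broken deterministically
// (start < M < X < Y on strict improvement order below), which selects one
// of the co-optimal paths.

struct SWCell {
  double s;          // score
  int matches, alen, qs, ts;
};

struct SWResult {
  double score;
  int matches, alen, qs, qe, ts, te;
};

static SWResult sw_core(const int *a, int n, const int *b, int m,
                        const double *sub, int asz, double gap_open,
                        double gap_extend, std::vector<SWCell> &rowM,
                        std::vector<SWCell> &rowX, std::vector<SWCell> &rowY) {
  const double og = gap_open + gap_extend, eg = gap_extend;
  if ((int)rowM.size() < m + 1) {
    rowM.resize(m + 1); rowX.resize(m + 1); rowY.resize(m + 1);
  }
  const SWCell dead = {NEG_INF, 0, 0, 0, 0};
  for (int j = 0; j <= m; ++j) { rowM[j] = dead; rowX[j] = dead; rowY[j] = dead; }
  SWResult best = {0.0, 0, 0, 0, 0, 0, 0};
  SWCell diagM = dead, diagX = dead, diagY = dead;  // (i-1, j-1) values
  for (int i = 1; i <= n; ++i) {
    const double *srow = sub + (size_t)a[i - 1] * asz;
    diagM = rowM[0]; diagX = rowX[0]; diagY = rowY[0];
    rowM[0] = dead; rowX[0] = dead; rowY[0] = dead;
    SWCell leftM = dead, leftX = dead, leftY = dead;  // (i, j-1)
    for (int j = 1; j <= m; ++j) {
      const SWCell upM = rowM[j], upX = rowX[j], upY = rowY[j];
      // M: start a new alignment or extend the best predecessor
      SWCell cm;
      if (diagM.s >= diagX.s && diagM.s >= diagY.s && diagM.s > 0) cm = diagM;
      else if (diagX.s >= diagY.s && diagX.s > 0) cm = diagX;
      else if (diagY.s > 0) cm = diagY;
      else { cm.s = 0; cm.matches = 0; cm.alen = 0; cm.qs = i - 1; cm.ts = j - 1; }
      cm.s += srow[b[j - 1]];
      cm.matches += (a[i - 1] == b[j - 1]);
      cm.alen += 1;
      // X: gap in b, consumes a_i (from row i-1, same j)
      SWCell cx;
      if (upM.s - og >= upX.s - eg) { cx = upM; cx.s -= og; }
      else { cx = upX; cx.s -= eg; }
      cx.alen += 1;
      // Y: gap in a, consumes b_j (same row, j-1)
      SWCell cy;
      if (leftM.s - og >= leftY.s - eg) { cy = leftM; cy.s -= og; }
      else { cy = leftY; cy.s -= eg; }
      cy.alen += 1;

      if (cm.s > best.score) {
        best.score = cm.s; best.matches = cm.matches; best.alen = cm.alen;
        best.qs = cm.qs; best.ts = cm.ts; best.qe = i; best.te = j;
      }
      diagM = upM; diagX = upX; diagY = upY;
      rowM[j] = cm; rowX[j] = cx; rowY[j] = cy;
      leftM = cm; leftX = cx; leftY = cy;
    }
  }
  return best;
}

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix submat,
                  double gap_open, double gap_extend) {
  std::vector<SWCell> r1, r2, r3;
  SWResult r = sw_core(INTEGER(a), a.size(), INTEGER(b), b.size(),
                       REAL(submat), submat.nrow(), gap_open, gap_extend,
                       r1, r2, r3);
  if (r.score <= 0.0)
    return List::create(_["score"] = 0.0, _["none"] = true);
  return List::create(
      _["score"] = r.score, _["none"] = false, _["matches"] = r.matches,
      _["aligned_length"] = r.alen, _["qstart"] = r.qs, _["qend"] = r.qe,
      _["tstart"] = r.ts, _["tend"] = r.te);
}

// batch scan of one query against many targets (shared row buffers)
// [[Rcpp::export]]
NumericMatrix sw_batch_cpp(IntegerVector query, List targets,
                           NumericMatrix submat, double gap_open,
                           double gap_extend) {
  const int nt = targets.size();
  NumericMatrix out(nt, 7);
  colnames(out) = CharacterVector::create("score", "matches", "aligned_length",
                                          "qstart", "qend", "tstart", "tend");
  std::vector<SWCell> r1, r2, r3;
  for (int t = 0; t < nt; ++t) {
    IntegerVector tg = targets[t];
    SWResult r = sw_core(INTEGER(query), query.size(), INTEGER(tg), tg.size(),
                         REAL(submat), submat.nrow(), gap_open, gap_extend,
                         r1, r2, r3);
    if (r.score <= 0.0) {
      out(t, 0) = 0.0;
      for (int c = 1; c < 7; ++c) out(t, c) = NA_REAL;
    } else {
      out(t, 0) = r.score; out(t, 1) = r.matches; out(t, 2) = r.alen;
      out(t, 3) = r.qs; out(t, 4) = r.qe; out(t, 5) = r.ts; out(t, 6) = r.te;
    }
  }
  return out;
}

// ------------------------------------------------- global affine alignment
// Needleman-Wunsch with affine gaps over an arbitrary pairwise score matrix
// S (n x m), end gaps penalized. Returns the aligned index paths (0 = gap).

// [[Rcpp::export]]
List nw_path_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double og = gap_open + gap_extend, eg = gap_extend;
  std::vector<double> M((n + 1) * (m + 1), NEG_INF), X((n + 1) * (m + 1), NEG_INF),
      Y((n + 1) * (m + 1), NEG_INF);
  std::vector<unsigned char> tbM((n + 1) * (m + 1), 0),
      tbX((n + 1) * (m + 1), 0), tbY((n + 1) * (m + 1), 0);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = -(gap_open + i * eg);
    tbX[at(i, 0)] = (i == 1) ? 1 : 2;
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = -(gap_open + j * eg);
    tbY[at(0, j)] = (j == 1) ? 1 : 3;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int d = at(i - 1, j - 1);
      double vM = M[d];
      unsigned char pM = 1;
      if (X[d] > vM) { vM = X[d]; pM = 2; }
      if (Y[d] > vM) { vM = Y[d]; pM = 3; }
      M[at(i, j)] = vM + S(i - 1, j - 1);
      tbM[at(i, j)] = pM;
      const int u = at(i - 1, j);
      double openX = std::max(M[u], Y[u]) - og, extX = X[u] - eg;
      unsigned char pX = (M[u] >= Y[u]) ? 1 : 3;
      if (openX >= extX) { X[at(i, j)] = openX; tbX[at(i, j)] = pX; }
      else               { X[at(i, j)] = extX;  tbX[at(i, j)] = 2; }
      const int l = at(i, j - 1);
      double openY = std::max(M[l], X[l]) - og, extY = Y[l] - eg;
      unsigned char pY = (M[l] >= X[l]) ? 1 : 2;
      if (openY >= extY) { Y[at(i, j)] = openY; tbY[at(i, j)] = pY; }
      else               { Y[at(i, j)] = extY;  tbY[at(i, j)] = 3; }
    }
  }
  const int e = at(n, m);
  double best = M[e];
  int state = 1;
  if (X[e] > best) { best = X[e]; state = 2; }
  if (Y[e] > best) { best = Y[e]; state = 3; }

  std::vector<int> ai, bi;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 1) {
      ai.push_back(i); bi.push_back(j);
      state = tbM[at(i, j)];
      --i; --j;
    } else if (state == 2) {
      ai.push_back(i); bi.push_back(0);
      unsigned char p = tbX[at(i, j)];
      --i;
      state = (p == 2) ? 2 : p;
    } else {
      ai.push_back(0); bi.push_back(j);
      unsigned char p = tbY[at(i, j)];
      --j;
      state = (p == 3) ? 3 : p;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = best, _["a"] = wrap(ai), _["b"] = wrap(bi));
}

// ----------------------------------------------------- profile HMM forward
// Plan7-lite local architecture: N -> B -> (M/I/D core) -> E -> C -> T with
// self-looping background flanks N and C (loop probability eta). All
// quantities are odds ratios against an i.i.d. background null with the same
// per-residue length factor eta, so flank and insert emissions cancel.
// Transition vectors are 0-based by source match/insert/delete state; the
// match rows already include the exit mass (tMM+tMI+tMD+exitp = 1). The last
// delete state exits to E with probability 1.

static double core_dp(const IntegerVector &seq, const NumericMatrix &ematch,
                      const NumericVector &bg, const NumericVector &tMM,
                      const NumericVector &tMI, const NumericVector &tMD,
                      const NumericVector &tIM, const NumericVector &tII,
                      const NumericVector &tDM, const NumericVector &tDD,
                      const NumericVector &entry, const NumericVector &exitp,
                      double eta, bool viterbi) {
  const int L = seq.size(), m = ematch.nrow(), A = ematch.ncol();
  std::vector<double> Mbuf(2 * m, 0.0), Ibuf(2 * m, 0.0), Dbuf(2 * m, 0.0);
  double *Mv = Mbuf.data(), *nM = Mbuf.data() + m;
  double *Iv = Ibuf.data(), *nI = Ibuf.data() + m;
  double *Dv = Dbuf.data(), *nD = Dbuf.data() + m;
  const double *em = REAL(ematch), *pbg = REAL(bg);
  const double *aMM = REAL(tMM), *aMI = REAL(tMI), *aMD = REAL(tMD),
               *aIM = REAL(tIM), *aII = REAL(tII), *aDM = REAL(tDM),
               *aDD = REAL(tDD), *aEn = REAL(entry), *aEx = REAL(exitp);
  double N = 1.0, B = 1.0 - eta, C = 0.0, logscale = 0.0;
  const double inv_eta = 1.0 / eta;

  for (int i = 0; i < L; ++i) {
    const int x = seq[i];
    const double *ecol = (x < A) ? (em + (size_t)x * m) : nullptr;
    const double fscale = (x < A) ? 1.0 / (pbg[x] * eta) : 1.0;
    double runmax = 0.0, E = 0.0, dprev = 0.0, mprev = 0.0;
    for (int k = 0; k < m; ++k) {
      const double er = (ecol ? ecol[k] : 1.0) * fscale;
      double v = B * aEn[k];
      if (k > 0) {
        const double a1 = Mv[k - 1] * aMM[k - 1], a2 = Iv[k - 1] * aIM[k - 1],
                     a3 = Dv[k - 1] * aDM[k - 1];
        v = viterbi ? std::max(std::max(a1, a2), std::max(a3, v))
                    : (a1 + a2 + a3 + v);
      }
      const double mk = er * v;
      nM[k] = mk;
      if (mk > runmax) runmax = mk;
      // insert after match k emits at background odds (ratio 1/eta)
      const double b1 = Mv[k] * aMI[k], b2 = Iv[k] * aII[k];
      nI[k] = (viterbi ? std::max(b1, b2) : (b1 + b2)) * inv_eta;
      // silent delete chain, same position
      double dk = 0.0;
      if (k > 0) {
        const double c1 = mprev * aMD[k - 1], c2 = dprev * aDD[k - 1];
        dk = viterbi ? std::max(c1, c2) : (c1 + c2);
      }
      nD[k] = dk;
      dprev = dk;
      mprev = mk;
      const double t = mk * aEx[k];
      E = viterbi ? std::max(E, t) : (E + t);
    }
    if (m > 0) E = viterbi ? std::max(E, nD[m - 1]) : (E + nD[m - 1]);
    C = viterbi ? std::max(C, E) : (C + E);

    std::swap(Mv, nM); std::swap(Iv, nI); std::swap(Dv, nD);

    // rescale only when values threaten the double range; paths still
    // waiting in the flanks are negligible once scores are this large
    if (runmax > 1e100 || C > 1e100) {
      const double mx = std::max(runmax, C);
      const double inv = 1.0 / mx;
      for (int k = 0; k < m; ++k) { Mv[k] *= inv; Iv[k] *= inv; Dv[k] *= inv; }
      N *= inv; B *= inv; C *= inv;
      logscale += std::log2(mx);
    }
  }
  if (C <= 0.0) return R_NegInf;
  return std::log2(C) + logscale;
}

// [[Rcpp::export]]
double forward_cpp(IntegerVector seq, NumericMatrix ematch, NumericVector bg,
                   NumericVector tMM, NumericVector tMI, NumericVector tMD,
                   NumericVector tIM, NumericVector tII, NumericVector tDM,
                   NumericVector tDD, NumericVector entry, NumericVector exitp,
                   double eta) {
  return core_dp(seq, ematch, bg, tMM, tMI, tMD, tIM, tII, tDM, tDD, entry,
                 exitp, eta, false);
}

// [[Rcpp::export]]
double viterbi_cpp(IntegerVector seq, NumericMatrix ematch, NumericVector bg,
                   NumericVector tMM, NumericVector tMI, NumericVector tMD,
                   NumericVector tIM, NumericVector tII, NumericVector tDM,
                   NumericVector tDD, NumericVector entry, NumericVector exitp,
                   double eta) {
  return core_dp(seq, ematch, bg, tMM, tMI, tMD, tIM, tII, tDM, tDD, entry,
                 exitp, eta, true);
}

// [[Rcpp::export]]
NumericVector forward_batch_cpp(List seqs, NumericMatrix ematch,
                                NumericVector bg, NumericVector tMM,
                                NumericVector tMI, NumericVector tMD,
                                NumericVector tIM, NumericVector tII,
                                NumericVector tDM, NumericVector tDD,
                                NumericVector entry, NumericVector exitp,
                                NumericVector etas) {
  const int n = seqs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector s = seqs[i];
    out[i] = core_dp(s, ematch, bg, tMM, tMI, tMD, tIM, tII, tDM, tDD, entry,
                     exitp, etas[i], false);
  }
  return out;
}
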