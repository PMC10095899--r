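// Banded glocal affine-gap alignment (global in the read, local in the
// reference) and pileup accumulation for short single-amplicon references.
//
// Scoring: match/mismatch per base; a gap of length L costs
// gap_open + L * gap_ext (both supplied as positive penalties). The band
// is applied around candidate diagonals found by exact-seed lookup, with
// the amplicon ends as fallback anchors. Traceback ties prefer match over
// deletion over insertion, yielding leftmost indel placement.

#include <Rcpp.h>
#include <climits>
#include <map>
#include <string>
#include <vector>
using namespace Rcpp;

static const int NEG = INT_MIN / 4;

struct Aln {
  int score = NEG;
  int ref_start = -1;
  std::string cigar;
};

// collapse op runs and convert boundary insertions to soft clips
static std::string ops_to_cigar(const std::vector<char>& ops) {
  std::vector<std::pair<char, int>> runs;
  for (char o : ops) {
    if (!runs.empty() && runs.back().first == o)
      runs.back().second++;
    else
      runs.push_back({o, 1});
  }
  if (!runs.empty() && runs.front().first == 'I') runs.front().first = 'S';
  if (runs.size() > 1 && runs.back().first == 'I') runs.back().first = 'S';
  std::string cg;
  for (auto& r : runs) cg += std::to_string(r.second) + r.first;
  return cg;
}

// one banded DP pass; band: |j - i - center| <= band (j ref col, i read row)
static Aln band_pass(const std::string& read, const std::string& ref,
                     int match, int mismatch, int gap_open, int gap_ext,
                     int band, int center) {
  const int m = (int)read.size(), n = (int)ref.size();
  const int W = n + 1;
  std::vector<int> H((m + 1) * W, NEG), E((m + 1) * W, NEG),
      F((m + 1) * W, NEG);
  std::vector<unsigned char> tbH((m + 1) * W, 0), tbE((m + 1) * W, 0),
      tbF((m + 1) * W, 0);
  auto lo_of = [&](int i) { return std::max(0, i + center - band); };
  auto hi_of = [&](int i) { return std::min(n, i + center + band); };

  for (int j = lo_of(0); j <= hi_of(0); ++j) H[j] = 0;  // free ref prefix
  for (int i = 1; i <= m; ++i) {
    const int lo = lo_of(i), hi = hi_of(i);
    if (lo > hi) break;
    const int row = i * W, prow = (i - 1) * W;
    for (int j = lo; j <= hi; ++j) {
      // E: gap in read (deletion, consumes ref)
      if (j > 0 && j - 1 >= lo) {
        int open = (H[row + j - 1] == NEG) ? NEG
                                           : H[row + j - 1] - gap_open - gap_ext;
        int ext = (E[row + j - 1] == NEG) ? NEG : E[row + j - 1] - gap_ext;
        if (open >= ext) { E[row + j] = open; tbE[row + j] = 0; }
        else             { E[row + j] = ext;  tbE[row + j] = 1; }
      }
      // F: gap in ref (insertion, consumes read)
      if (j >= lo_of(i - 1) && j <= hi_of(i - 1)) {
        int open = (H[prow + j] == NEG) ? NEG : H[prow + j] - gap_open - gap_ext;
        int ext = (F[prow + j] == NEG) ? NEG : F[prow + j] - gap_ext;
        if (open >= ext) { F[row + j] = open; tbF[row + j] = 0; }
        else             { F[row + j] = ext;  tbF[row + j] = 1; }
      }
      // H: best of diagonal / E / F
      int best = NEG; unsigned char tb = 3;
      if (j > 0 && j - 1 >= lo_of(i - 1) && j - 1 <= hi_of(i - 1) &&
          H[prow + j - 1] != NEG) {
        int s = (read[i - 1] == ref[j - 1]) ? match : mismatch;
        best = H[prow + j - 1] + s; tb = 0;
      }
      if (E[row + j] != NEG && E[row + j] > best) { best = E[row + j]; tb = 1; }
      if (F[row + j] != NEG && F[row + j] > best) { best = F[row + j]; tb = 2; }
      H[row + j] = best; tbH[row + j] = tb;
    }
  }

  Aln res;
  int bj = -1;
  for (int j = lo_of(m); j <= hi_of(m); ++j) {  // free ref suffix
    if (H[m * W + j] > res.score) { res.score = H[m * W + j]; bj = j; }
  }
  if (bj < 0 || res.score <= NEG / 2) return res;

  // traceback
  std::vector<char> ops;
  int i = m, j = bj, state = 0;  // 0=H,1=E,2=F
  while (i > 0) {
    int cell = i * W + j;
    if (state == 0) {
      unsigned char tb = tbH[cell];
      if (tb == 0) { ops.push_back('M'); --i; --j; }
      else if (tb == 1) state = 1;
      else if (tb == 2) state = 2;
      else break;  // unreachable
    } else if (state == 1) {
      ops.push_back('D');
      state = tbE[cell] == 0 ? 0 : 1;
      --j;
    } else {
      ops.push_back('I');
      state = tbF[cell] == 0 ? 0 : 2;
      --i;
    }
  }
  std::reverse(ops.begin(), ops.end());
  res.ref_start = j;
  // boundary deletions carry no read bases; fold them into the free
  // reference prefix/suffix (score already reflects the chosen path)
  size_t a = 0;
  while (a < ops.size() && ops[a] == 'D') { ++a; ++res.ref_start; }
  size_t b = ops.size();
  while (b > a && ops[b - 1] == 'D') --b;
  res.cigar = ops_to_cigar(std::vector<char>(ops.begin() + a, ops.begin() + b));
  return res;
}

// candidate band centers from exact seed matches plus amplicon-end anchors
static std::vector<int> seed_centers(const std::string& read,
                                     const std::string& ref) {
  const int m = (int)read.size(), n = (int)ref.size();
  std::vector<int> centers;
  auto add = [&](int c) {
    c = std::max(-((int)read.size()), std::min(c, n));
    for (int x : centers) if (x == c) return;
    centers.push_back(c);
  };
  add(0);
  if (n > m) add(n - m);
  const int K = 12;
  if (m >= K) {
    for (int off = 0; off <= m - K; off += 4) {
      std::string seed = read.substr(off, K);
      size_t pos = ref.find(seed);
      int hits = 0;
      while (pos != std::string::npos && hits < 4) {
        add((int)pos - off);
        ++hits;
        pos = ref.find(seed, pos + 1);
      }
      if ((int)centers.size() >= 16) break;
    }
  }
  return centers;
}

// [[Rcpp::export]]
List align_reads_cpp(CharacterVector reads, std::string ref, int match,
                     int mismatch, int gap_open, int gap_ext, int band,
                     double floor_frac) {
  const int nreads = reads.size();
  IntegerVector score(nreads), ref_start(nreads);
  CharacterVector cigar(nreads);
  LogicalVector aligned(nreads);
  const int n = (int)ref.size();
  for (int r = 0; r < nreads; ++r) {
    std::string rd = as<std::string>(reads[r]);
    const int m = (int)rd.size();
    Aln best;
    if (m == 0) {
      score[r] = 0; ref_start[r] = NA_INTEGER; cigar[r] = "";
      aligned[r] = false; continue;
    }
    int perfect = match * m;
    if (band >= n + m) {
      best = band_pass(rd, ref, match, mismatch, gap_open, gap_ext, n + m, 0);
    } else {
      for (int c : seed_centers(rd, ref)) {
        Aln a = band_pass(rd, ref, match, mismatch, gap_open, gap_ext, band, c);
        if (a.score > best.score) best = a;
        if (best.score == perfect) break;
      }
      // full-matrix rescue when no seeded band reaches the acceptance
      // floor (e.g. dense errors wiping out every exact seed)
      if (best.score < (int)std::ceil(floor_frac * perfect)) {
        Aln a = band_pass(rd, ref, match, mismatch, gap_open, gap_ext,
                          n + m, 0);
        if (a.score > best.score) best = a;
      }
    }
    bool ok = best.ref_start >= 0 &&
              best.score >= (int)std::ceil(floor_frac * perfect);
    score[r] = best.ref_start >= 0 ? best.score : NA_INTEGER;
    ref_start[r] = ok ? best.ref_start : NA_INTEGER;
    cigar[r] = ok ? best.cigar : "";
    aligned[r] = ok;
  }
  return List::create(_["score"] = score, _["ref_start"] = ref_start,
                      _["cigar"] = cigar, _["aligned"] = aligned);
}

// [[Rcpp::export]]
CharacterVector reverse_strings_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i) {
    std::string s = as<std::string>(x[i]);
    std::reverse(s.begin(), s.end());
    out[i] = s;
  }
  return out;
}

static int base_index(char b) {
  switch (b) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// Walk CIGARs over the reference, accumulating depth (reads spanning each
// position via M or D), quality-filtered base counts with quality sums,
// deletion spans, and keyed insertion/deletion events. Bases below
// min_base_qual count toward depth but not toward allele counts.
// [[Rcpp::export]]
List pileup_cpp(CharacterVector reads, CharacterVector quals,
                IntegerVector ref_start, CharacterVector cigars,
                std::string ref, int min_base_qual) {
  const int n = (int)ref.size();
  IntegerVector depth(n, 0), del_span(n, 0);
  IntegerMatrix base_counts(4, n);
  NumericMatrix qual_sums(4, n);
  std::map<std::pair<int, std::string>, std::pair<int, double>> ins;
  std::map<std::pair<int, int>, std::pair<int, double>> del;

  for (int r = 0; r < reads.size(); ++r) {
    if (ref_start[r] == NA_INTEGER) continue;
    std::string rd = as<std::string>(reads[r]);
    std::string qu = as<std::string>(quals[r]);
    std::string cg = as<std::string>(cigars[r]);
    int rp = ref_start[r], qp = 0;
    size_t ci = 0;
    while (ci < cg.size()) {
      int len = 0;
      while (ci < cg.size() && isdigit(cg[ci])) len = len * 10 + (cg[ci++] - '0');
      char op = cg[ci++];
      if (op == 'M') {
        for (int t = 0; t < len; ++t, ++rp, ++qp) {
          if (rp < 0 || rp >= n) continue;
          depth[rp]++;
          int q = qu[qp] - 33;
          int b = base_index(rd[qp]);
          if (q >= min_base_qual && b >= 0) {
            base_counts(b, rp)++;
            qual_sums(b, rp) += q;
          }
        }
      } else if (op == 'D') {
        double fq = qp > 0 ? qu[qp - 1] - 33
                           : (qp < (int)qu.size() ? qu[qp] - 33 : 0);
        if (qp < (int)qu.size()) fq = (fq + (qu[qp] - 33)) / 2.0;
        auto key = std::make_pair(rp, len);
        if (fq >= min_base_qual) {
          auto& e = del[key];
          e.first++; e.second += fq;
        }
        for (int t = 0; t < len; ++t, ++rp) {
          if (rp < 0 || rp >= n) continue;
          depth[rp]++;
          del_span[rp]++;
        }
      } else if (op == 'I') {
        double mq = 0;
        for (int t = 0; t < len; ++t) mq += qu[qp + t] - 33;
        mq /= len;
        if (rp > 0 && mq >= min_base_qual) {
          auto& e = ins[std::make_pair(rp - 1, rd.substr(qp, len))];
          e.first++; e.second += mq;
        }
        qp += len;
      } else if (op == 'S') {
        qp += len;
      }
    }
  }

  int ni = (int)ins.size(), nd = (int)del.size();
  IntegerVector ins_anchor(ni), ins_count(ni), del_start(nd), del_len(nd),
      del_count(nd);
  CharacterVector ins_seq(ni);
  NumericVector ins_qual(ni), del_qual(nd);
  int t = 0;
  for (auto& kv : ins) {
    ins_anchor[t] = kv.first.first;
    ins_seq[t] = kv.first.second;
    ins_count[t] = kv.second.first;
    ins_qual[t] = kv.second.second / kv.second.first;
    ++t;
  }
  t = 0;
  for (auto& kv : del) {
    del_start[t] = kv.first.first;
    del_len[t] = kv.first.second;
    del_count[t] = kv.second.first;
    del_qual[t] = kv.second.second / kv.second.first;
    ++t;
  }
  return List::create(
      _["depth"] = depth, _["base_counts"] = base_counts,
      _["qual_sums"] = qual_sums, _["del_span"] = del_span,
      _["ins_anchor0"] = ins_anchor, _["ins_seq"] = ins_seq,
      _["ins_count"] = ins_count, _["ins_qual"] = ins_qual,
      _["del_start0"] = del_start, _["del_len"] = del_len,
      _["del_count"] = del_count, _["del_qual"] = del_qual);
}
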