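// Core positional Burrows-Wheeler transform machinery: the forward sweep
// over sites maintaining the positional prefix array a, the divergence
// array d, and the per-column allele ranks; the byte-oriented run-length
// codec for PBWT columns; and the three fast exact-matching sweeps
// (long matches, set-maximal matches within a panel, batch query matching).
//
// Conventions shared with the R layer:
//   * panels are raw matrices with M haplotype rows and N site columns,
//     allele bytes 0x00 / 0x01;
//   * sites are 0-based, match intervals half-open [start, end);
//   * d[i] is the first position from which sorted neighbours i-1 and i
//     agree through the current position k; d[0] == k by construction and
//     a virtual d[M] == k is used at the upper boundary.

#include <Rcpp.h>
#include <cstdint>
#include <cstdlib>
#include <cstring>
#include <fstream>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// run-length codec
//
// One byte per token: bit 7 = allele value, bits 6-5 = unit selector
// (00 -> 1, 01 -> 64, 10 -> 2048, 11 reserved), bits 4-0 = unit count
// (1..31).  A maximal run of length r is decomposed greedily, largest
// unit first, so the encoding of a column is canonical.

static void push_run(std::vector<uint8_t> &out, int value, R_xlen_t r) {
  static const R_xlen_t units[3] = {2048, 64, 1};
  static const uint8_t ucode[3] = {2, 1, 0};
  for (int u = 0; u < 3; ++u) {
    R_xlen_t n = r / units[u];
    r -= n * units[u];
    while (n > 0) {
      int cnt = n > 31 ? 31 : (int)n;
      out.push_back((uint8_t)((value << 7) | (ucode[u] << 5) | cnt));
      n -= cnt;
    }
  }
}

static void encode_column(const uint8_t *col, R_xlen_t M,
                          std::vector<uint8_t> &out) {
  out.clear();
  R_xlen_t i = 0;
  while (i < M) {
    uint8_t v = col[i];
    if (v > 1)
      stop("non-binary allele value %d in column", (int)v);
    R_xlen_t j = i + 1;
    while (j < M && col[j] == v)
      ++j;
    push_run(out, v, j - i);
    i = j;
  }
}

// [[Rcpp::export]]
RawVector cpp_rle_encode(RawVector column) {
  std::vector<uint8_t> out;
  encode_column((const uint8_t *)RAW(column), column.size(), out);
  return RawVector(out.begin(), out.end());
}

static void decode_column(const uint8_t *payload, R_xlen_t nbytes,
                          R_xlen_t M, uint8_t *col) {
  R_xlen_t pos = 0;
  for (R_xlen_t b = 0; b < nbytes; ++b) {
    uint8_t byte = payload[b];
    int value = byte >> 7;
    int ucode = (byte >> 5) & 3;
    int count = byte & 31;
    if (ucode == 3)
      stop("reserved unit code 11 at payload byte %d", (int)b);
    if (count == 0)
      stop("illegal zero unit count at payload byte %d", (int)b);
    R_xlen_t unit = ucode == 0 ? 1 : (ucode == 1 ? 64 : 2048);
    R_xlen_t len = unit * (R_xlen_t)count;
    if (pos + len > M)
      stop("payload decodes to more than %g values", (double)M);
    std::memset(col + pos, value, (size_t)len);
    pos += len;
  }
  if (pos != M)
    stop("payload decodes to %g of %g values", (double)pos, (double)M);
}

// [[Rcpp::export]]
RawVector cpp_rle_decode(RawVector payload, double M) {
  R_xlen_t m = (R_xlen_t)M;
  RawVector col(m);
  decode_column((const uint8_t *)RAW(payload), payload.size(), m,
                (uint8_t *)RAW(col));
  return col;
}

// ---------------------------------------------------------------------------
// forward sweep state

struct Sweep {
  int M;
  std::vector<int32_t> a, d, a0, a1, d0, d1;
  std::vector<uint8_t> y;
  double ops; // counted per processed sorted entry

  void init(int M_) {
    M = M_;
    a.resize(M);
    d.assign(M, 0);
    for (int i = 0; i < M; ++i)
      a[i] = i;
    y.resize(M);
    a0.reserve(M);
    a1.reserve(M);
    d0.reserve(M);
    d1.reserve(M);
    ops = 0;
  }

  // pull the alleles of column `col` (indexed by original sequence id)
  // into sorted order
  void gather(const uint8_t *col) {
    for (int i = 0; i < M; ++i) {
      uint8_t v = col[a[i]];
      if (v > 1)
        stop("non-binary allele value %d in panel", (int)v);
      y[i] = v;
    }
    ops += M;
  }

  // advance a and d from position k to k+1 using the gathered column y
  void step(int k) {
    a0.clear();
    a1.clear();
    d0.clear();
    d1.clear();
    int32_t p = k + 1, q = k + 1;
    for (int i = 0; i < M; ++i) {
      int32_t di = d[i];
      if (di > p)
        p = di;
      if (di > q)
        q = di;
      if (y[i] == 0) {
        a0.push_back(a[i]);
        d0.push_back(p);
        p = 0;
      } else {
        a1.push_back(a[i]);
        d1.push_back(q);
        q = 0;
      }
    }
    size_t n0 = a0.size();
    std::copy(a0.begin(), a0.end(), a.begin());
    std::copy(a1.begin(), a1.end(), a.begin() + n0);
    std::copy(d0.begin(), d0.end(), d.begin());
    std::copy(d1.begin(), d1.end(), d.begin() + n0);
    ops += M;
  }
};

// ---------------------------------------------------------------------------
// index construction: one O(NM) sweep emitting RLE columns, zero counts
// and a/d checkpoints

// [[Rcpp::export]]
List cpp_build_index(RawMatrix X, int C) {
  int M = X.nrow(), N = X.ncol();
  const uint8_t *base = (const uint8_t *)RAW(X);
  Sweep s;
  s.init(M);

  List payloads(N);
  IntegerVector cvec(N);
  std::vector<int> cp_pos;
  List cp_a, cp_d;
  std::vector<uint8_t> buf;

  for (int k = 0; k <= N; ++k) {
    if (k % C == 0 || k == N) {
      cp_pos.push_back(k);
      cp_a.push_back(IntegerVector(s.a.begin(), s.a.end()));
      cp_d.push_back(IntegerVector(s.d.begin(), s.d.end()));
    }
    if (k == N)
      break;
    s.gather(base + (size_t)k * M);
    int c = 0;
    for (int i = 0; i < M; ++i)
      if (s.y[i] == 0)
        ++c;
    encode_column(s.y.data(), M, buf);
    payloads[k] = RawVector(buf.begin(), buf.end());
    cvec[k] = c;
    s.step(k);
  }

  return List::create(
      _["payloads"] = payloads, _["c"] = cvec,
      _["cp_pos"] = IntegerVector(cp_pos.begin(), cp_pos.end()),
      _["cp_a"] = cp_a, _["cp_d"] = cp_d, _["n_ops"] = s.ops);
}

// Run the sweep and return a_k / d_k at every position (k = 0..N) --
// used by tests to compare against brute-force construction at small scale.
// [[Rcpp::export]]
List cpp_sweep_all(RawMatrix X) {
  int M = X.nrow(), N = X.ncol();
  const uint8_t *base = (const uint8_t *)RAW(X);
  Sweep s;
  s.init(M);
  List as(N + 1), ds(N + 1);
  for (int k = 0; k <= N; ++k) {
    as[k] = IntegerVector(s.a.begin(), s.a.end());
    ds[k] = IntegerVector(s.d.begin(), s.d.end());
    if (k == N)
      break;
    s.gather(base + (size_t)k * M);
    s.step(k);
  }
  return List::create(_["a"] = as, _["d"] = ds, _["n_ops"] = s.ops);
}

// ---------------------------------------------------------------------------
// match collectors

struct MatchSink {
  bool collect;
  std::vector<int> sa, sb, st, en;
  double count, sum_sites, sum_bp;
  double n_events, event_sum_sites, event_sum_bp;
  const double *pos; // site positions in bp, or NULL
  MatchSink(bool collect_, const double *pos_)
      : collect(collect_), count(0), sum_sites(0), sum_bp(0), n_events(0),
        event_sum_sites(0), event_sum_bp(0), pos(pos_) {}
  void report(int a, int b, int start, int end) {
    if (collect) {
      sa.push_back(a);
      sb.push_back(b);
      st.push_back(start);
      en.push_back(end);
    }
    count += 1;
    sum_sites += end - start;
    if (pos)
      sum_bp += pos[end - 1] - pos[start];
  }
  // one reporting event = one (target, interval) block, ties collapsed
  void event(int start, int end) {
    n_events += 1;
    event_sum_sites += end - start;
    if (pos)
      event_sum_bp += pos[end - 1] - pos[start];
  }
  List result(double n_ops, int state_ints) {
    return List::create(
        _["seq_a"] = IntegerVector(sa.begin(), sa.end()),
        _["seq_b"] = IntegerVector(sb.begin(), sb.end()),
        _["start"] = IntegerVector(st.begin(), st.end()),
        _["end"] = IntegerVector(en.begin(), en.end()), _["count"] = count,
        _["sum_sites"] = sum_sites, _["sum_bp"] = sum_bp,
        _["n_events"] = n_events, _["event_sum_sites"] = event_sum_sites,
        _["event_sum_bp"] = event_sum_bp, _["n_ops"] = n_ops,
        _["state_ints"] = state_ints);
  }
};

// ---------------------------------------------------------------------------
// all locally maximal matches of length >= L within the panel, each
// unordered pair reported once, at the position where the match ends

// [[Rcpp::export]]
List cpp_long_matches(RawMatrix X, int L, bool collect,
                      Nullable<NumericVector> positions = R_NilValue) {
  int M = X.nrow(), N = X.ncol();
  const uint8_t *base = (const uint8_t *)RAW(X);
  NumericVector posv;
  const double *pos = NULL;
  if (positions.isNotNull()) {
    posv = positions.get();
    pos = REAL(posv);
  }
  Sweep s;
  s.init(M);
  MatchSink sink(collect, pos);

  for (int k = 0; k <= N; ++k) {
    if (k < N)
      s.gather(base + (size_t)k * M);
    if (k >= L) {
      int thresh = k - L;
      int bs = 0; // current block start
      for (int i = 1; i <= M; ++i) {
        bool brk = (i == M) || (s.d[i] > thresh);
        s.ops += 1;
        if (!brk)
          continue;
        if (i - bs >= 2) {
          for (int qq = bs + 1; qq < i; ++qq) {
            int32_t m = 0;
            for (int pp = qq - 1; pp >= bs; --pp) {
              if (s.d[pp + 1] > m)
                m = s.d[pp + 1];
              s.ops += 1;
              if (k == N || s.y[pp] != s.y[qq]) {
                int u = s.a[pp], v = s.a[qq];
                sink.report(u < v ? u : v, u < v ? v : u, m, k);
              }
            }
          }
        }
        bs = i;
      }
    }
    if (k < N)
      s.step(k);
  }
  return sink.result(s.ops, 2 * M);
}

// ---------------------------------------------------------------------------
// set-maximal matches within the panel: for each target sequence i at
// each position k, the longest matches ending at k run to a contiguous
// block of sorted neighbours; they are reported when no member of that
// block carries the target's allele at k (i.e. no extension exists)

// [[Rcpp::export]]
List cpp_set_maximal(RawMatrix X, bool collect,
                     Nullable<NumericVector> positions = R_NilValue) {
  int M = X.nrow(), N = X.ncol();
  const uint8_t *base = (const uint8_t *)RAW(X);
  NumericVector posv;
  const double *pos = NULL;
  if (positions.isNotNull()) {
    posv = positions.get();
    pos = REAL(posv);
  }
  Sweep s;
  s.init(M);
  MatchSink sink(collect, pos);
  const int32_t *d = s.d.data();

  for (int k = 0; k <= N; ++k) {
    if (k < N)
      s.gather(base + (size_t)k * M);
    for (int i = 0; i < M; ++i) {
      s.ops += 1;
      int32_t dc = d[i];           // d[0] == k by construction
      int32_t dn = (i + 1 < M) ? d[i + 1] : k; // virtual d[M] == k
      int32_t e = dc < dn ? dc : dn;
      if (e >= k)
        continue; // no non-empty match ending at k
      int f = i;
      while (f > 0 && d[f] <= e) {
        --f;
        s.ops += 1;
      }
      int g = i + 1;
      while (g < M && d[g] <= e) {
        ++g;
        s.ops += 1;
      }
      if (k < N) {
        bool ext = false;
        for (int j = f; j < g; ++j) {
          if (j != i && s.y[j] == s.y[i]) {
            ext = true;
            break;
          }
          s.ops += 1;
        }
        if (ext)
          continue; // match extends through k, not set-maximal here
      }
      if (g - f > 1)
        sink.event(e, k);
      for (int j = f; j < g; ++j)
        if (j != i)
          sink.report(s.a[i], s.a[j], e, k);
    }
    if (k < N)
      s.step(k);
  }
  return sink.result(s.ops, 2 * M);
}

// ---------------------------------------------------------------------------
// batch query matching: one joint sweep over panel and query sequences,
// reporting set-maximal matches of each query to the panel only.
// Query rows are appended after the M panel rows; in the scans below the
// divergence chain runs over all sequences (queries included) but only
// panel sequences count as match partners.

// [[Rcpp::export]]
List cpp_query_batch(RawMatrix X, RawMatrix Z, bool collect,
                     Nullable<NumericVector> positions = R_NilValue) {
  int M = X.nrow(), Q = Z.nrow(), N = X.ncol();
  if (Z.ncol() != N)
    stop("query sequences have %d sites, panel has %d", Z.ncol(), N);
  int Mt = M + Q;
  const uint8_t *bx = (const uint8_t *)RAW(X);
  const uint8_t *bz = (const uint8_t *)RAW(Z);
  NumericVector posv;
  const double *pos = NULL;
  if (positions.isNotNull()) {
    posv = positions.get();
    pos = REAL(posv);
  }
  Sweep s;
  s.init(Mt);
  MatchSink sink(collect, pos);
  const int32_t *d = s.d.data();
  std::vector<int> part; // sorted indices of current partner block

  for (int k = 0; k <= N; ++k) {
    if (k < N) {
      // gather combined column
      const uint8_t *cx = bx + (size_t)k * M;
      const uint8_t *cz = bz + (size_t)k * Q;
      for (int i = 0; i < Mt; ++i) {
        int id = s.a[i];
        uint8_t v = id < M ? cx[id] : cz[id - M];
        if (v > 1)
          stop("non-binary allele value in panel or query");
        s.y[i] = v;
      }
      s.ops += Mt;
    }
    for (int i = 0; i < Mt; ++i) {
      s.ops += 1;
      int qid = s.a[i] - M;
      if (qid < 0)
        continue;
      // longest match to a panel sequence below / above
      int32_t sd = k, su = k, m;
      m = 0;
      for (int j = i - 1; j >= 0; --j) {
        if (d[j + 1] > m)
          m = d[j + 1];
        s.ops += 1;
        if (m >= k)
          break;
        if (s.a[j] < M) {
          sd = m;
          break;
        }
      }
      m = 0;
      for (int j = i + 1; j < Mt; ++j) {
        if (d[j] > m)
          m = d[j];
        s.ops += 1;
        if (m >= k)
          break;
        if (s.a[j] < M) {
          su = m;
          break;
        }
      }
      int32_t e = sd < su ? sd : su;
      if (e >= k)
        continue;
      // collect panel partners matching the query from e
      part.clear();
      m = 0;
      for (int j = i - 1; j >= 0; --j) {
        if (d[j + 1] > m)
          m = d[j + 1];
        if (m > e)
          break;
        if (s.a[j] < M)
          part.push_back(j);
        s.ops += 1;
      }
      m = 0;
      for (int j = i + 1; j < Mt; ++j) {
        if (d[j] > m)
          m = d[j];
        if (m > e)
          break;
        if (s.a[j] < M)
          part.push_back(j);
        s.ops += 1;
      }
      if (part.empty())
        continue;
      if (k < N) {
        bool ext = false;
        for (size_t t = 0; t < part.size(); ++t)
          if (s.y[part[t]] == s.y[i]) {
            ext = true;
            break;
          }
        if (ext)
          continue;
      }
      sink.event(e, k);
      for (size_t t = 0; t < part.size(); ++t)
        sink.report(qid, s.a[part[t]], e, k);
    }
    if (k < N)
      s.step(k);
  }
  return sink.result(s.ops, 2 * Mt);
}

// ---------------------------------------------------------------------------
// small helpers used by the R layer

// largest byte value in a raw vector/matrix (panel validity check that
// avoids materialising an integer copy of large allele matrices)
// [[Rcpp::export]]
int cpp_max_byte(RawVector x) {
  uint8_t m = 0;
  const uint8_t *p = (const uint8_t *)RAW(x);
  for (R_xlen_t i = 0; i < x.size(); ++i)
    if (p[i] > m)
      m = p[i];
  return (int)m;
}

// per-column count of 1 alleles (for allele frequencies at scale)
// [[Rcpp::export]]
IntegerVector cpp_col_ones(RawMatrix X) {
  int M = X.nrow(), N = X.ncol();
  const uint8_t *base = (const uint8_t *)RAW(X);
  IntegerVector out(N);
  for (int k = 0; k < N; ++k) {
    const uint8_t *col = base + (size_t)k * M;
    int c = 0;
    for (int i = 0; i < M; ++i)
      c += col[i];
    out[k] = c;
  }
  return out;
}

// render a panel as '0'/'1' text, one row (sequence) per line
// [[Rcpp::export]]
RawVector cpp_matrix_text(RawMatrix X) {
  R_xlen_t M = X.nrow(), N = X.ncol();
  const uint8_t *base = (const uint8_t *)RAW(X);
  RawVector out(M * (N + 1));
  uint8_t *o = (uint8_t *)RAW(out);
  for (R_xlen_t i = 0; i < M; ++i) {
    for (R_xlen_t k = 0; k < N; ++k)
      o[i * (N + 1) + k] = (uint8_t)('0' + base[k * M + i]);
    o[i * (N + 1) + N] = '\n';
  }
  return out;
}

// read site-major 0/1 text: one line per site, optionally led by
// whitespace-separated fields of which the last numeric one before the
// allele string is taken as the position; the final token is the allele
// string.  Two passes: the first sizes the panel so the allele matrix is
// filled in place without a staging buffer.
static bool split_site_line(const std::string &line, size_t &abeg,
                            size_t &aend, double &pos, bool &has_pos) {
  size_t end = line.find_last_not_of(" \t\r");
  if (end == std::string::npos)
    return false;
  size_t beg = line.find_last_of(" \t", end);
  abeg = beg == std::string::npos ? 0 : beg + 1;
  aend = end + 1;
  has_pos = false;
  pos = NA_REAL;
  if (beg != std::string::npos) {
    size_t he = line.find_last_not_of(" \t", beg);
    if (he != std::string::npos) {
      size_t hb = line.find_last_of(" \t", he);
      std::string tok = line.substr(hb == std::string::npos ? 0 : hb + 1,
                                    he - (hb == std::string::npos ? 0 : hb + 1) + 1);
      char *endp = NULL;
      double v = strtod(tok.c_str(), &endp);
      if (endp && *endp == '\0') {
        pos = v;
        has_pos = true;
      }
    }
  }
  return true;
}

// [[Rcpp::export]]
List cpp_read_sitemajor(std::string path) {
  std::ifstream in(path.c_str());
  if (!in)
    stop("cannot open '%s'", path.c_str());
  std::string line;
  R_xlen_t M = -1, N = 0;
  size_t abeg, aend;
  double pos;
  bool has_pos;
  while (std::getline(in, line)) {
    if (!split_site_line(line, abeg, aend, pos, has_pos))
      continue;
    if (M < 0)
      M = (R_xlen_t)(aend - abeg);
    ++N;
  }
  if (M <= 0)
    stop("no haplotype data found in '%s'", path.c_str());
  RawMatrix X(M, N); // site-major lines are column-major for an M x N panel
  NumericVector posv(N);
  uint8_t *base = (uint8_t *)RAW(X);
  in.clear();
  in.seekg(0);
  R_xlen_t k = 0, lineno = 0;
  bool any_pos = false;
  while (std::getline(in, line)) {
    ++lineno;
    if (!split_site_line(line, abeg, aend, pos, has_pos))
      continue;
    if ((R_xlen_t)(aend - abeg) != M)
      stop("ragged site line %g: %d haplotypes, expected %d",
           (double)lineno, (int)(aend - abeg), (int)M);
    uint8_t *col = base + (size_t)k * M;
    for (R_xlen_t t = 0; t < M; ++t) {
      char ch = line[abeg + t];
      if (ch != '0' && ch != '1')
        stop("illegal character '%c' on line %g", ch, (double)lineno);
      col[t] = (uint8_t)(ch - '0');
    }
    posv[k] = pos;
    if (has_pos)
      any_pos = true;
    ++k;
  }
  return List::create(_["X"] = X,
                      _["pos"] = any_pos ? posv : NumericVector(0));
}

// CRC-32 (IEEE 802.3, reflected) of a raw vector, for container integrity
// [[Rcpp::export]]
int cpp_crc32(RawVector data) {
  static uint32_t table[256];
  static bool have_table = false;
  if (!have_table) {
    for (uint32_t n = 0; n < 256; ++n) {
      uint32_t c = n;
      for (int k = 0; k < 8; ++k)
        c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      table[n] = c;
    }
    have_table = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  const uint8_t *p = (const uint8_t *)RAW(data);
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ p[i]) & 0xFF] ^ (crc >> 8);
  crc ^= 0xFFFFFFFFu;
  return (int)(int32_t)crc;
}
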