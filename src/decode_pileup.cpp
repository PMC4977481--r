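#include <Rcpp.h>
using namespace Rcpp;

// Decode SAMtools mpileup read-base strings into per-observation records.
//
// Dialect handled per column string:
//   '.' / ','          reference base on forward / reverse strand
//   'ACGT' / 'acgt'    substitution on forward / reverse strand
//   '^X'               read start; X encodes the read's mapping quality
//                      (Phred+33), used when no mapping-quality column exists
//   '$'                read end marker (no observation)
//   '+nSEQ' / '-nSEQ'  insertion/deletion attached to the preceding read
//   '*' / '#'          deletion placeholder: consumes a quality char, counts
//                      toward raw depth only, never an observation
//   '>' / '<'          reference skip: treated like '*'
//   'N' / 'n'          ambiguous base: consumes a quality char, dropped
//
// Every retained or placeholder base consumes one char of the base-quality
// string (and of the mapping-quality string when present); a length mismatch
// is reported as a parse error with the offending line number.

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 3;
    case 'T': case 't': return 4;
  }
  return 0;
}

// [[Rcpp::export]]
List decode_pileup_cpp(CharacterVector bases, CharacterVector quals,
                       CharacterVector mapquals, CharacterVector refs,
                       int default_mq) {
  const int n = bases.size();
  const bool has_mqcol = mapquals.size() == n;

  std::vector<int> o_site, o_base, o_bq, o_mq, o_ord;
  std::vector<int> o_strand; // 1 forward, 0 reverse
  std::vector<int> i_site, i_kind, i_after;
  std::vector<int> i_strand;
  std::vector<std::string> i_seq;
  o_site.reserve(n * 30);
  o_base.reserve(n * 30);

  int err_line = 0;
  std::string err_msg;

  for (int line = 0; line < n; ++line) {
    const char *b = CHAR(STRING_ELT(bases, line));
    const char *q = CHAR(STRING_ELT(quals, line));
    const char *mqs = has_mqcol ? CHAR(STRING_ELT(mapquals, line)) : NULL;
    const char *rf = CHAR(STRING_ELT(refs, line));
    const int ref = base_code(rf[0]);
    const size_t nb = strlen(b);
    const size_t nq = strlen(q);
    const size_t nmq = mqs ? strlen(mqs) : 0;

    size_t qi = 0;       // index into quality strings
    int ord = 0;         // within-line ordinal of retained observations
    int pending_mq = -1; // from a '^X' read-start marker
    int last_strand = 1;

    for (size_t k = 0; k < nb; ++k) {
      const char c = b[k];
      if (c == '^') {
        if (k + 1 >= nb) { err_line = line + 1; err_msg = "dangling '^'"; break; }
        pending_mq = (int)((unsigned char)b[k + 1]) - 33;
        ++k;
        continue;
      }
      if (c == '$') continue;
      if (c == '+' || c == '-') {
        size_t j = k + 1;
        long len = 0;
        while (j < nb && b[j] >= '0' && b[j] <= '9') {
          len = len * 10 + (b[j] - '0');
          ++j;
        }
        if (len <= 0 || j + (size_t)len > nb) {
          err_line = line + 1; err_msg = "malformed indel field"; break;
        }
        std::string seq(b + j, b + j + len);
        bool fwd = seq.empty() ? true : !(seq[0] >= 'a' && seq[0] <= 'z');
        for (auto &ch : seq) ch = toupper(ch);
        i_site.push_back(line + 1);
        i_kind.push_back(c == '+' ? 1 : 2);
        i_seq.push_back(seq);
        i_strand.push_back(fwd ? 1 : 0);
        i_after.push_back(ord); // attached to the ord-th retained observation
        (void)last_strand;
        k = j + len - 1;
        continue;
      }

      // everything below consumes one quality char
      if (qi >= nq || (mqs && qi >= nmq)) {
        err_line = line + 1; err_msg = "more bases than quality characters";
        break;
      }
      const int bq = (int)((unsigned char)q[qi]) - 33;
      const int mq = mqs ? (int)((unsigned char)mqs[qi]) - 33
                         : (pending_mq >= 0 ? pending_mq : default_mq);
      ++qi;
      pending_mq = -1;

      int code = 0, fwd = 1;
      if (c == '.') { code = ref; fwd = 1; }
      else if (c == ',') { code = ref; fwd = 0; }
      else if (c == '*' || c == '#' || c == '>' || c == '<') continue;
      else if (c == 'N' || c == 'n') continue;
      else {
        code = base_code(c);
        if (code == 0) { err_line = line + 1; err_msg = std::string("unexpected character '") + c + "'"; break; }
        fwd = (c >= 'A' && c <= 'Z') ? 1 : 0;
      }
      if (code == 0) { err_line = line + 1; err_msg = "reference base is not A/C/G/T"; break; }
      last_strand = fwd;
      ++ord;
      o_site.push_back(line + 1);
      o_base.push_back(code);
      o_strand.push_back(fwd);
      o_bq.push_back(bq);
      o_mq.push_back(mq);
      o_ord.push_back(ord);
    }
    if (err_line) break;
    if (qi != nq) {
      err_line = line + 1;
      err_msg = "base and quality strings disagree in length";
      break;
    }
  }

  return List::create(
    _["site"] = wrap(o_site), _["base"] = wrap(o_base),
    _["strand"] = wrap(o_strand), _["bq"] = wrap(o_bq),
    _["mq"] = wrap(o_mq), _["ord"] = wrap(o_ord),
    _["indel_site"] = wrap(i_site), _["indel_kind"] = wrap(i_kind),
    _["indel_seq"] = wrap(i_seq), _["indel_strand"] = wrap(i_strand),
    _["indel_after"] = wrap(i_after),
    _["err_line"] = err_line, _["err_msg"] = err_msg);
}
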