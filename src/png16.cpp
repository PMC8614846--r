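#include <Rcpp.h>
#include <zlib.h>
#include <cstdio>
#include <vector>
using namespace Rcpp;

static void put_u32(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back((x >> 24) & 0xff);
  v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);
  v.push_back(x & 0xff);
}

static void put_chunk(std::vector<unsigned char>& out, const char* type,
                      const std::vector<unsigned char>& data) {
  put_u32(out, (uint32_t)data.size());
  size_t start = out.size();
  for (int i = 0; i < 4; ++i) out.push_back((unsigned char)type[i]);
  out.insert(out.end(), data.begin(), data.end());
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, out.data() + start, (uInt)(out.size() - start));
  put_u32(out, (uint32_t)crc);
}

// Writes a 16-bit greyscale PNG. `pix` holds integers in [0, 65535],
// dimensioned H x W (rows are image rows).
// [[Rcpp::export]]
void kj_write_png16(const std::string& path, const IntegerMatrix& pix) {
  const int H = pix.nrow(), W = pix.ncol();
  // raw scanlines: filter byte 0 + W big-endian 16-bit samples per row
  std::vector<unsigned char> raw;
  raw.reserve((size_t)H * (1 + 2 * (size_t)W));
  for (int r = 0; r < H; ++r) {
    raw.push_back(0);
    for (int c = 0; c < W; ++c) {
      int v = pix(r, c);
      if (v < 0) v = 0;
      if (v > 65535) v = 65535;
      raw.push_back((v >> 8) & 0xff);
      raw.push_back(v & 0xff);
    }
  }
  uLongf zlen = compressBound((uLong)raw.size());
  std::vector<unsigned char> zbuf(zlen);
  if (compress2(zbuf.data(), &zlen, raw.data(), (uLong)raw.size(), 9) != Z_OK)
    stop("PNG deflate failed");
  zbuf.resize(zlen);

  std::vector<unsigned char> out;
  const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  out.insert(out.end(), sig, sig + 8);
  std::vector<unsigned char> ihdr;
  put_u32(ihdr, (uint32_t)W);
  put_u32(ihdr, (uint32_t)H);
  ihdr.push_back(16); // bit depth
  ihdr.push_back(0);  // greyscale
  ihdr.push_back(0);  // compression
  ihdr.push_back(0);  // filter
  ihdr.push_back(0);  // no interlace
  put_chunk(out, "IHDR", ihdr);
  put_chunk(out, "IDAT", zbuf);
  put_chunk(out, "IEND", std::vector<unsigned char>());

  FILE* f = std::fopen(path.c_str(), "wb");
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  size_t n = std::fwrite(out.data(), 1, out.size(), f);
  std::fclose(f);
  if (n != out.size()) stop("short write to '%s'", path.c_str());
}
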