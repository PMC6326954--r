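#ifndef RELAPSERF_RNG_H
#define RELAPSERF_RNG_H

#include <cstdint>

// Small deterministic PRNG (xoshiro256** seeded through splitmix64).
// Used instead of R's RNG so forest fits are bit-reproducible given a
// seed regardless of the caller's .Random.seed state.
namespace rrf {

inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

class Rng {
 public:
  explicit Rng(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) s_[i] = splitmix64(sm);
  }
  uint64_t next() {
    const uint64_t result = rotl(s_[1] * 5, 7) * 9;
    const uint64_t t = s_[1] << 17;
    s_[2] ^= s_[0];
    s_[3] ^= s_[1];
    s_[1] ^= s_[2];
    s_[0] ^= s_[3];
    s_[2] ^= t;
    s_[3] = rotl(s_[3], 45);
    return result;
  }
  // uniform double in [0, 1)
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  // uniform integer in [0, n), n > 0 (128-bit multiply, no modulo bias
  // worth worrying about at these n)
  int unif_int(int n) {
    return (int)(((__uint128_t)next() * (__uint128_t)n) >> 64);
  }

 private:
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t s_[4];
};

}  // namespace rrf

#endif
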