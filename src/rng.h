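#ifndef MIRDAP_RNG_H
#define MIRDAP_RNG_H

#include <cstdint>

// splitmix64: small, fast, platform-independent; seeded from a single int so
// identical seeds reproduce walks/training bit-for-bit across OS/compilers.
struct Splitmix {
  uint64_t s;
  explicit Splitmix(uint64_t seed) : s(seed) {}
  uint64_t nextu() {
    s += 0x9E3779B97f4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in [0, 1)
  double unif() { return (nextu() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  int randint(int n) {
    int k = (int)(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

#endif
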