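/* Interposable stand-ins for the wall-clock entropy sources used by the
 * coordinate builder of the conversion subprocess (loaded via LD_PRELOAD).
 * Pinning them makes 3D embedding a pure function of its input, which the
 * descriptor pipeline requires for bit-exact reruns. */
#include <time.h>

time_t time(time_t *t) {
  if (t) *t = (time_t)1234567890;
  return (time_t)1234567890;
}

void srand(unsigned int seed) { (void)seed; }
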