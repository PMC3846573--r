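#!/usr/bin/env python
"""Exact-arithmetic oracle for the two-library tag-count statistic.

For library-size ratio r = a/b (b ~ N1, a ~ N2) the equal-expression
probability of seeing y tags given x is

    P(y|x) = C(x+y, y) * a^y * b^(x+1) / (a+b)^(x+y+1)

All quantities below are exact integers/fractions; floats are emitted
only at print time (Fraction -> float is correctly rounded), so the
output is the reference against which a log-gamma implementation is
checked. Pure stdlib; no third-party imports.

usage: python ac_oracle.py XMAX YMAX OUT_TSV
columns: a b x y pmf lower twosided
(lower = P(Y <= y | x); twosided = min(1, 2*min(lower, 1 - P(Y <= y-1))))
"""
import sys
from fractions import Fraction

def main(xmax, ymax, out):
    ratios = [(1, 2), (1, 1), (2, 1)]  # r = N2/N1 = a/b
    with open(out, "w") as fh:
        fh.write("a\tb\tx\ty\tpmf\tlower\ttwosided\n")
        for a, b in ratios:
            ab = a + b
            for x in range(xmax + 1):
                bpow = b ** (x + 1)
                binom = 1          # C(x+y, y), starts at y = 0
                apow = 1           # a^y
                abpow = ab ** (x + 1)   # (a+b)^(x+y+1)
                s_int = 0          # lower tail numerator vs abpow
                s_prev = 0         # numerator of P(Y <= y-1) vs (a+b)^(x+y)
                for y in range(ymax + 1):
                    if y > 0:
                        binom = binom * (x + y) // y
                        apow *= a
                        s_prev = s_int          # scale matches (a+b)^(x+y)
                        abpow *= ab
                    num = binom * apow * bpow
                    s_int = s_int * ab + num if y > 0 else num
                    pmf = Fraction(num, abpow)
                    lower = Fraction(s_int, abpow)
                    if y == 0:
                        upper = Fraction(1)
                    else:
                        upper = 1 - Fraction(s_prev, abpow // ab)
                    two = min(Fraction(1), 2 * min(lower, upper))
                    fh.write("%d\t%d\t%d\t%d\t%.17e\t%.17e\t%.17e\n"
                             % (a, b, x, y, float(pmf), float(lower),
                                float(two)))

if __name__ == "__main__":
    main(int(sys.argv[1]), int(sys.argv[2]), sys.argv[3])
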