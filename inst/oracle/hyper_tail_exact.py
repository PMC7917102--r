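#!/usr/bin/env python
"""Big-integer hypergeometric upper-tail oracle.

Reads whitespace-separated "N m n k" tuples from the file given as the
single argument (or stdin), sums the pmf term-by-term with exact rational
arithmetic (fractions.Fraction over math.comb), and prints one tail
probability per line with 17 significant digits.
"""
import sys
from fractions import Fraction
from math import comb


def tail(N, m, n, k):
    denom = comb(N, n)
    total = Fraction(0)
    for x in range(k, min(n, m) + 1):
        total += Fraction(comb(m, x) * comb(N - m, n - x), denom)
    return total


def main():
    src = open(sys.argv[1]) if len(sys.argv) > 1 else sys.stdin
    for line in src:
        parts = line.split()
        if not parts:
            continue
        N, m, n, k = map(int, parts)
        p = tail(N, m, n, k)
        print("%.17e" % float(p))


if __name__ == "__main__":
    main()
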