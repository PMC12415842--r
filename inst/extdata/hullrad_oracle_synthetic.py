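"""Synthetic stand-in oracle for the convex-hull hydrodynamic radius.

Independent re-implementation of the documented hull-based Rh algorithm
(scipy ConvexHull + Perrin prolate shape factor + 2.8 A hydration shell),
used only to cross-check the R implementation on small coordinate sets.
It is NOT the published reference program, which is unavailable offline;
it validates the hull computation and downstream arithmetic through an
independent code path and hull library.

Usage: python hullrad_oracle_synthetic.py coords.txt
where coords.txt holds one "x y z" triple per line (Angstrom).
Prints: rh hull_volume axial_ratio
"""
import sys

import numpy as np
from scipy.spatial import ConvexHull

HYDRATION_SHELL = 2.8  # Angstrom, one water diameter


def perrin_factor(p):
    if p <= 1.0 + 1e-9:
        return 1.0
    return np.sqrt(p * p - 1.0) / (p ** (1.0 / 3.0)
                                   * np.log(p + np.sqrt(p * p - 1.0)))


def main(path):
    xyz = np.loadtxt(path)
    hull = ConvexHull(xyz)
    r0 = (3.0 * hull.volume / (4.0 * np.pi)) ** (1.0 / 3.0)
    ev = np.sort(np.linalg.eigvalsh(np.cov(xyz.T)))[::-1]
    p = np.sqrt(ev[0] / np.mean(ev[1:3]))
    rh = perrin_factor(p) * (r0 + HYDRATION_SHELL)
    print("%.10f %.10f %.10f" % (rh, hull.volume, p))


if __name__ == "__main__":
    main(sys.argv[1])
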