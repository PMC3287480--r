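"""Independent LAD reconciliation oracle.

Builds the deviation-variable LP from scratch (its own formulation, not the
package's) and solves it with scipy's HiGHS interface. Input/output: JSON.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog

BIG = 1e29


def solve(inst):
    S = np.array(inst["S"], dtype=float)
    if S.ndim == 1:
        S = S.reshape(1, -1)
    m, n = S.shape
    lo = np.array(inst["lower"], dtype=float)
    hi = np.array(inst["upper"], dtype=float)
    k = [int(i) - 1 for i in np.atleast_1d(inst["kidx"])]
    t = np.atleast_1d(np.array(inst["targets"], dtype=float))
    K = len(k)
    c = np.concatenate([np.zeros(n), np.ones(2 * K)])
    A = np.zeros((m + K, n + 2 * K))
    A[:m, :n] = S
    for r, (ki, _) in enumerate(zip(k, t)):
        A[m + r, ki] = 1.0
        A[m + r, n + r] = -1.0
        A[m + r, n + K + r] = 1.0
    b = np.concatenate([np.zeros(m), t])
    bounds = [(None if lo[i] < -BIG else lo[i], None if hi[i] > BIG else hi[i])
              for i in range(n)] + [(0, None)] * (2 * K)
    res = linprog(c, A_eq=A, b_eq=b, bounds=bounds, method="highs")
    return {"status": int(res.status),
            "residual": float(res.fun) if res.status == 0 else None}


def main():
    with open(sys.argv[1]) as fh:
        instances = json.load(fh)
    out = [solve(inst) for inst in instances]
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
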