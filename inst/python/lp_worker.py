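"""Batch LP worker: reads a JSON list of problems, solves each with
scipy.optimize.linprog (HiGHS), writes a JSON list of results.

Problem fields: n, obj, lb, ub, maximize, and two row blocks `eq` and `le`,
each sparse triplets {i, j, x, rhs, m}. Bounds with |value| >= 1e30 are
treated as infinite.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog
from scipy.sparse import coo_matrix

INF = 1e30
STATUS = {0: "optimal", 1: "iteration_limit", 2: "infeasible", 3: "unbounded"}


def sc(v):
    return v[0] if isinstance(v, list) else v


def arr(v):
    if v is None:
        return np.array([], dtype=float)
    return np.atleast_1d(np.asarray(v, dtype=float))


def block(b, n):
    m = int(sc(b.get("m", 0)) or 0)
    if m == 0:
        return None, None
    A = coo_matrix(
        (arr(b["x"]), (arr(b["i"]).astype(int), arr(b["j"]).astype(int))),
        shape=(m, n),
    ).tocsr()
    return A, arr(b["rhs"])


def solve(p):
    n = int(sc(p["n"]))
    c = arr(p["obj"])
    maximize = bool(sc(p["maximize"]))
    if maximize:
        c = -c
    lb = arr(p["lb"])
    ub = arr(p["ub"])
    bounds = [
        (None if l <= -INF else l, None if u >= INF else u)
        for l, u in zip(lb, ub)
    ]
    A_eq, b_eq = block(p.get("eq", {}), n)
    A_ub, b_ub = block(p.get("le", {}), n)
    r = linprog(c, A_ub=A_ub, b_ub=b_ub, A_eq=A_eq, b_eq=b_eq, bounds=bounds,
                method="highs")
    status = STATUS.get(r.status, "error")
    if status != "optimal":
        return {"status": status, "objective": None, "x": None}
    obj = -r.fun if maximize else r.fun
    return {"status": "optimal", "objective": float(obj), "x": [float(v) for v in r.x]}


def main():
    with open(sys.argv[1]) as fh:
        problems = json.load(fh)
    results = [solve(p) for p in problems]
    with open(sys.argv[2], "w") as fh:
        json.dump(results, fh)


if __name__ == "__main__":
    main()
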