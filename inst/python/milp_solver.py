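"""Mixed-integer linear programming backend.

Reads a JSON file holding a batch of MILP problems in sparse triplet form,
solves each with scipy's HiGHS interface, and writes a JSON file with one
result per problem.  Usage: python milp_solver.py IN.json OUT.json
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp

BIG = 1e29  # values beyond this encode +/- infinity in the JSON exchange


def _inf(arr):
    a = np.asarray(arr, dtype=float)
    a[a >= BIG] = np.inf
    a[a <= -BIG] = -np.inf
    return a


def solve_one(p):
    c = np.asarray(p["obj"], dtype=float)
    n = c.size
    lb = _inf(p["lb"])
    ub = _inf(p["ub"])
    integrality = np.asarray(p["integrality"], dtype=int)
    options = {"presolve": True}
    if p.get("time_limit") is not None:
        options["time_limit"] = float(p["time_limit"])
    if p.get("mip_rel_gap") is not None:
        options["mip_rel_gap"] = float(p["mip_rel_gap"])
    constraints = []
    if len(np.atleast_1d(p.get("con_lb", []))):
        A = sparse.csr_matrix(
            (np.asarray(p["A_x"], dtype=float),
             (np.asarray(p["A_i"], dtype=int) - 1,
              np.asarray(p["A_j"], dtype=int) - 1)),
            shape=(len(p["con_lb"]), n))
        constraints.append(LinearConstraint(A, _inf(p["con_lb"]),
                                            _inf(p["con_ub"])))
    res = milp(c=c, constraints=constraints, integrality=integrality,
               bounds=Bounds(lb, ub), options=options)
    out = {"status": int(res.status), "success": bool(res.success),
           "message": str(res.message)}
    if res.x is not None:
        out["x"] = [float(v) for v in res.x]
        out["objective"] = float(res.fun)
        gap = getattr(res, "mip_gap", None)
        if gap is not None and np.isfinite(gap):
            out["mip_gap"] = float(gap)
        db = getattr(res, "mip_dual_bound", None)
        if db is not None and np.isfinite(db):
            out["dual_bound"] = float(db)
    return out


def main(path_in, path_out):
    with open(path_in) as fh:
        batch = json.load(fh)
    results = [solve_one(p) for p in batch["problems"]]
    with open(path_out, "w") as fh:
        json.dump({"results": results}, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
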