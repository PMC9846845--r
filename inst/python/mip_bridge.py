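#!/usr/bin/env python
"""Batch MILP/LP solving bridge.

Reads a JSON document from the path given as argv[1] and writes solutions as
JSON to argv[2].  Input schema:

{
  "problems": [
    {
      "n": <int, number of variables>,
      "obj": [c_1, ..., c_n],
      "lb": [...], "ub": [...],            # variable bounds ("-inf"/"inf" allowed)
      "integrality": [0/1, ...],           # 1 = integer-constrained
      "rows": {"i": [...], "j": [...], "v": [...]},   # 1-based triplets
      "rel": ["<=", "=", ">=", ...],       # one per constraint row
      "rhs": [...],
      "maximize": false,                   # optional
      "time_limit": <seconds, optional>
    }, ...
  ]
}

Output: {"solutions": [{"status": "optimal"|"infeasible"|"feasible-time-limit"|
"unbounded"|"error", "objective": <num or null>, "x": [...]}, ...]}

Solved with HiGHS via scipy.optimize.milp (deterministic, single thread).
"""
import json
import sys
import warnings

import numpy as np
from scipy.optimize import Bounds, LinearConstraint, milp
from scipy.sparse import coo_matrix

STATUS = {0: "optimal", 1: "feasible-time-limit", 2: "infeasible", 3: "unbounded"}


def _num(x):
    if x == "inf":
        return np.inf
    if x == "-inf":
        return -np.inf
    return float(x)


def solve_one(p):
    n = int(p["n"])
    obj = np.atleast_1d(np.asarray(p["obj"], dtype=float))
    if p.get("maximize", False):
        obj = -obj
    lb = np.array([_num(x) for x in p["lb"]])
    ub = np.array([_num(x) for x in p["ub"]])
    integrality = np.atleast_1d(
        np.asarray(p.get("integrality", [0] * n), dtype=int))

    rel = p.get("rel", [])
    if isinstance(rel, str):  # a single row serializes unboxed
        rel = [rel]
    m = len(rel)
    constraints = []
    if m > 0:
        rows = p["rows"]
        i = np.atleast_1d(np.asarray(rows["i"], dtype=int)) - 1
        j = np.atleast_1d(np.asarray(rows["j"], dtype=int)) - 1
        v = np.atleast_1d(np.asarray(rows["v"], dtype=float))
        A = coo_matrix((v, (i, j)), shape=(m, n)).tocsr()
        rhs = np.array([_num(x) for x in p["rhs"]])
        clb = np.where(np.isin(rel, ["=", ">="]), rhs, -np.inf)
        cub = np.where(np.isin(rel, ["=", "<="]), rhs, np.inf)
        constraints = [LinearConstraint(A, clb, cub)]

    # Tight feasibility tolerances: callers compare objectives across
    # independent solvers at 1e-6, and HiGHS's default integrality
    # tolerance (1e-6) otherwise leaks into the objective; 1e-9
    # triggers spurious HiGHS solve errors, so 1e-8 is used.
    options = {
        "mip_rel_gap": 0.0,
        "presolve": True,
        "primal_feasibility_tolerance": 1e-8,
        "dual_feasibility_tolerance": 1e-8,
        "mip_feasibility_tolerance": 1e-8,
    }
    if "time_limit" in p and p["time_limit"] is not None:
        options["time_limit"] = float(p["time_limit"])

    if n == 0:
        return {"status": "optimal", "objective": 0.0, "x": []}

    with warnings.catch_warnings():
        warnings.simplefilter("ignore")
        res = milp(c=obj, constraints=constraints, integrality=integrality,
                   bounds=Bounds(lb, ub), options=options)
        if res.status not in STATUS:
            # HiGHS occasionally reports a solve error that disappears
            # without presolve; retry once before giving up.
            res = milp(c=obj, constraints=constraints,
                       integrality=integrality, bounds=Bounds(lb, ub),
                       options={**options, "presolve": False})
    status = STATUS.get(res.status, "error")
    out = {"status": status, "objective": None, "x": None}
    if res.x is not None:
        val = float(res.fun)
        if p.get("maximize", False):
            val = -val
        out["objective"] = val
        out["x"] = [float(z) for z in res.x]
    return out


def main():
    with open(sys.argv[1]) as fh:
        payload = json.load(fh)
    sols = [solve_one(p) for p in payload["problems"]]
    with open(sys.argv[2], "w") as fh:
        json.dump({"solutions": sols}, fh)


if __name__ == "__main__":
    main()
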