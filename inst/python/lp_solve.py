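"""Batch linear-program solver backing the flux module.

Reads a JSON file with a list of LPs, solves each with scipy's HiGHS
interface, writes a JSON list of results. Sparse constraint matrices are
passed as COO triplets (1-based indices). Deterministic: HiGHS with fixed
options, no randomization.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog
from scipy.sparse import coo_matrix

STATUS = {0: "optimal", 1: "iteration_limit", 2: "infeasible",
          3: "unbounded", 4: "numerical"}


def to_sparse(spec):
    if spec is None:
        return None
    return coo_matrix(
        (np.asarray(spec["x"], dtype=float),
         (np.asarray(spec["i"], dtype=int) - 1,
          np.asarray(spec["j"], dtype=int) - 1)),
        shape=(spec["nrow"], spec["ncol"])).tocsr()


def solve(problem):
    c = np.asarray(problem["c"], dtype=float)
    sense = problem.get("sense", "min")
    sign = -1.0 if sense == "max" else 1.0
    lb = np.asarray(problem["lb"], dtype=float)
    ub = np.asarray(problem["ub"], dtype=float)
    res = linprog(
        sign * c,
        A_eq=to_sparse(problem.get("A_eq")),
        b_eq=problem.get("b_eq"),
        A_ub=to_sparse(problem.get("A_ub")),
        b_ub=problem.get("b_ub"),
        bounds=list(zip(lb, ub)),
        method="highs")
    status = STATUS.get(res.status, "numerical")
    out = {"status": status}
    if status == "optimal":
        out["objective"] = float(sign * res.fun)
        out["x"] = [float(v) for v in res.x]
    return out


def main():
    with open(sys.argv[1]) as fh:
        payload = json.load(fh)
    results = [solve(p) for p in payload["problems"]]
    with open(sys.argv[2], "w") as fh:
        json.dump(results, fh)


if __name__ == "__main__":
    main()
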