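"""Batch linear-programming helper.

Reads a JSON file holding a list of LP problems, solves each with
scipy.optimize.linprog (HiGHS), and writes a JSON list of solutions.

Problem fields (0-based triplet indices):
  n            number of variables
  c            objective coefficients (length n); always MINIMIZED
  lb, ub       variable bounds (length n); null entries mean +/-inf
  eq_i/eq_j/eq_x/eq_rhs   equality rows  A_eq x = eq_rhs
  ub_i/ub_j/ub_x/ub_rhs   inequality rows A_ub x <= ub_rhs

Solution fields: status (optimal|infeasible|unbounded|failed),
objective (min value), x.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog
from scipy.sparse import coo_matrix

STATUS = {0: "optimal", 1: "failed", 2: "infeasible", 3: "unbounded", 4: "failed"}


def build(ii, jj, xx, nrow, ncol):
    if nrow == 0:
        return None
    return coo_matrix(
        (np.asarray(xx, float), (np.asarray(ii, int), np.asarray(jj, int))),
        shape=(nrow, ncol),
    ).tocsr()


def solve(p):
    n = int(p["n"])
    c = np.asarray(p["c"], float)
    lb = np.asarray([-np.inf if v is None else v for v in p["lb"]], float)
    ub = np.asarray([np.inf if v is None else v for v in p["ub"]], float)
    beq = np.asarray(p.get("eq_rhs") or [], float)
    bub = np.asarray(p.get("ub_rhs") or [], float)
    Aeq = build(p.get("eq_i") or [], p.get("eq_j") or [], p.get("eq_x") or [],
                len(beq), n)
    Aub = build(p.get("ub_i") or [], p.get("ub_j") or [], p.get("ub_x") or [],
                len(bub), n)
    res = linprog(c, A_ub=Aub, b_ub=bub if len(bub) else None,
                  A_eq=Aeq, b_eq=beq if len(beq) else None,
                  bounds=np.c_[lb, ub], method="highs")
    status = STATUS.get(res.status, "failed")
    out = {"status": status}
    if status == "optimal":
        out["objective"] = float(res.fun)
        out["x"] = [float(v) for v in res.x]
    return out


def main(infile, outfile):
    with open(infile) as fh:
        problems = json.load(fh)
    solutions = [solve(p) for p in problems]
    with open(outfile, "w") as fh:
        json.dump(solutions, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
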