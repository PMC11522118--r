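#!/usr/bin/env python
"""Independent brute-force oracle for the 75 second-order texture features.

Reads per-lesion voxel CSVs (columns x,y,z,intensity; 0-based integer
coordinates) and recomputes every matrix family and feature directly from
the published definitions with plain dictionaries and loops -- no shared
code with the R implementation. Used once to freeze conformance values:

    python tools/texture_oracle.py tests/testthat/fixtures/lesion*.csv \
        > tests/testthat/fixtures/texture_oracle_features.csv

Conventions (documented in the package):
  * fixed bin width 25 anchored at the lesion minimum, level i covers
    [min+(i-1)w, min+iw), Ng = floor((max-min)/w)+1
  * 13 unique 3-D directions at Chebyshev distance 1; GLCM symmetrised and
    normalised per angle; GLCM/GLRLM features averaged over angles
  * GLSZM zones / lesion splitting via 26-connectivity
  * GLDM dependence = #26-neighbours with |level diff| <= alpha (0), column
    index dependence+1
  * NGTDM over voxels with >= 1 in-mask 26-neighbour
  * entropies sum -p log2 p over positive entries
  * degenerate caps: NGTDM Coarseness 1e6 on zero denominator, Busyness and
    Strength 0, NGTDM Contrast 0 for a single level, GLCM Correlation and
    MCC 1 on a single level
"""
import csv
import math
import sys
from itertools import product

BIN_WIDTH = 25.0
GLDM_ALPHA = 0.0

DIRS13 = [(1, 0, 0), (0, 1, 0), (0, 0, 1),
          (1, 1, 0), (1, -1, 0), (1, 0, 1), (1, 0, -1), (0, 1, 1),
          (0, 1, -1),
          (1, 1, 1), (1, 1, -1), (1, -1, 1), (1, -1, -1)]
NEIGH26 = [d for d in product((-1, 0, 1), repeat=3) if d != (0, 0, 0)]


def read_lesion(path):
    vox = {}
    with open(path) as fh:
        for row in csv.DictReader(fh):
            vox[(int(row["x"]), int(row["y"]), int(row["z"]))] = \
                float(row["intensity"])
    return vox


def discretize(vox):
    lo = min(vox.values())
    hi = max(vox.values())
    lev = {c: int(math.floor((v - lo) / BIN_WIDTH)) + 1
           for c, v in vox.items()}
    ng = int(math.floor((hi - lo) / BIN_WIDTH)) + 1
    ng = max(ng, max(lev.values()))
    return lev, ng


def entropy(ps):
    return -sum(p * math.log2(p) for p in ps if p > 0)


# --- GLCM -------------------------------------------------------------------

def glcm_features_single(P, ng):
    lev = range(1, ng + 1)
    px = {i: sum(P.get((i, j), 0.0) for j in lev) for i in lev}
    py = {j: sum(P.get((i, j), 0.0) for i in lev) for j in lev}
    mux = sum(i * px[i] for i in lev)
    muy = sum(j * py[j] for j in lev)
    sigx = math.sqrt(sum((i - mux) ** 2 * px[i] for i in lev))
    sigy = math.sqrt(sum((j - muy) ** 2 * py[j] for j in lev))
    pplus = {k: 0.0 for k in range(2, 2 * ng + 1)}
    pminus = {k: 0.0 for k in range(0, ng)}
    for (i, j), p in P.items():
        pplus[i + j] += p
        pminus[abs(i - j)] += p
    hx = entropy(px.values())
    hy = entropy(py.values())
    hxy = entropy(P.values())
    hxy1 = -sum(p * math.log2(px[i] * py[j])
                for (i, j), p in P.items() if px[i] * py[j] > 0 and p > 0)
    hxy2 = entropy([px[i] * py[j] for i in lev for j in lev])
    da = sum(k * p for k, p in pminus.items())

    if sigx * sigy == 0:
        corr = 1.0
    else:
        corr = (sum(i * j * p for (i, j), p in P.items()) - mux * muy) \
            / (sigx * sigy)

    if ng == 1:
        mcc = 1.0
    else:
        eps = 2.220446049250313e-16
        # Q = A t(C), A = P/px rows, C = P/py cols
        Q = [[sum((P.get((i, k), 0.0) / (px[i] + eps)) *
                  (P.get((j, k), 0.0) / (py[k] + eps))
                  for k in lev) for j in lev] for i in lev]
        import numpy as np
        ev = sorted(np.real(np.linalg.eigvals(np.array(Q))), reverse=True)
        mcc = math.sqrt(max(0.0, ev[1]))

    f = {}
    f["Autocorrelation"] = sum(i * j * p for (i, j), p in P.items())
    f["ClusterProminence"] = sum((i + j - mux - muy) ** 4 * p
                                 for (i, j), p in P.items())
    f["ClusterShade"] = sum((i + j - mux - muy) ** 3 * p
                            for (i, j), p in P.items())
    f["ClusterTendency"] = sum((i + j - mux - muy) ** 2 * p
                               for (i, j), p in P.items())
    f["Contrast"] = sum((i - j) ** 2 * p for (i, j), p in P.items())
    f["Correlation"] = corr
    f["DifferenceAverage"] = da
    f["DifferenceEntropy"] = entropy(pminus.values())
    f["DifferenceVariance"] = sum((k - da) ** 2 * p
                                  for k, p in pminus.items())
    f["Id"] = sum(p / (1 + k) for k, p in pminus.items())
    f["Idm"] = sum(p / (1 + k * k) for k, p in pminus.items())
    f["Idmn"] = sum(p / (1 + k * k / ng ** 2) for k, p in pminus.items())
    f["Idn"] = sum(p / (1 + k / ng) for k, p in pminus.items())
    f["Imc1"] = 0.0 if max(hx, hy) == 0 else (hxy - hxy1) / max(hx, hy)
    f["Imc2"] = math.sqrt(max(0.0, 1 - math.exp(-2 * (hxy2 - hxy))))
    f["InverseVariance"] = sum(p / (k * k)
                               for k, p in pminus.items() if k > 0)
    f["JointAverage"] = mux
    f["JointEnergy"] = sum(p * p for p in P.values())
    f["JointEntropy"] = hxy
    f["MCC"] = mcc
    f["MaximumProbability"] = max(P.values()) if P else 0.0
    f["SumAverage"] = sum(k * p for k, p in pplus.items())
    f["SumEntropy"] = entropy(pplus.values())
    f["SumSquares"] = sum((i - mux) ** 2 * p for (i, j), p in P.items())
    return f


def glcm_features(lev, ng):
    per_angle = []
    for d in DIRS13:
        counts = {}
        for c, li in lev.items():
            n = (c[0] + d[0], c[1] + d[1], c[2] + d[2])
            if n in lev:
                counts[(li, lev[n])] = counts.get((li, lev[n]), 0) + 1
        if not counts:
            continue
        sym = {}
        for (i, j), v in counts.items():
            sym[(i, j)] = sym.get((i, j), 0) + v
            sym[(j, i)] = sym.get((j, i), 0) + v
        tot = sum(sym.values())
        P = {k: v / tot for k, v in sym.items()}
        per_angle.append(glcm_features_single(P, ng))
    if not per_angle:
        n = len(lev)
        freq = {}
        for li in lev.values():
            freq[li] = freq.get(li, 0) + 1
        P = {(i, i): c / n for i, c in freq.items()}
        per_angle.append(glcm_features_single(P, ng))
    keys = per_angle[0].keys()
    return {"original_glcm_" + k:
            sum(a[k] for a in per_angle) / len(per_angle) for k in keys}


# --- GLRLM ------------------------------------------------------------------

def rl_sz_core(cells, np_):
    """cells: dict (level, size) -> count. Returns the 16 shared stats."""
    nr = sum(cells.values())
    gl = {}
    sz = {}
    for (i, j), c in cells.items():
        gl[i] = gl.get(i, 0) + c
        sz[j] = sz.get(j, 0) + c
    mug = sum(i * c for i, c in gl.items()) / nr
    mus = sum(j * c for j, c in sz.items()) / nr
    out = {}
    out["GLN"] = sum(c * c for c in gl.values()) / nr
    out["GLNN"] = sum(c * c for c in gl.values()) / nr ** 2
    out["GLV"] = sum((i - mug) ** 2 * c for i, c in gl.items()) / nr
    out["High"] = sum(c * i * i for (i, j), c in cells.items()) / nr
    out["Long"] = sum(c * j * j for (i, j), c in cells.items()) / nr
    out["LongHigh"] = sum(c * i * i * j * j
                          for (i, j), c in cells.items()) / nr
    out["LongLow"] = sum(c * j * j / (i * i)
                         for (i, j), c in cells.items()) / nr
    out["Low"] = sum(c / (i * i) for (i, j), c in cells.items()) / nr
    out["Entropy"] = entropy([c / nr for c in cells.values()])
    out["SN"] = sum(c * c for c in sz.values()) / nr
    out["SNN"] = sum(c * c for c in sz.values()) / nr ** 2
    out["Pct"] = nr / np_
    out["SV"] = sum((j - mus) ** 2 * c for j, c in sz.items()) / nr
    out["Short"] = sum(c / (j * j) for (i, j), c in cells.items()) / nr
    out["ShortHigh"] = sum(c * i * i / (j * j)
                           for (i, j), c in cells.items()) / nr
    out["ShortLow"] = sum(c / (i * i * j * j)
                          for (i, j), c in cells.items()) / nr
    return out


GLRLM_MAP = [
    ("GrayLevelNonUniformity", "GLN"),
    ("GrayLevelNonUniformityNormalized", "GLNN"),
    ("GrayLevelVariance", "GLV"),
    ("HighGrayLevelRunEmphasis", "High"),
    ("LongRunEmphasis", "Long"),
    ("LongRunHighGrayLevelEmphasis", "LongHigh"),
    ("LongRunLowGrayLevelEmphasis", "LongLow"),
    ("LowGrayLevelRunEmphasis", "Low"),
    ("RunEntropy", "Entropy"),
    ("RunLengthNonUniformity", "SN"),
    ("RunLengthNonUniformityNormalized", "SNN"),
    ("RunPercentage", "Pct"),
    ("RunVariance", "SV"),
    ("ShortRunEmphasis", "Short"),
    ("ShortRunHighGrayLevelEmphasis", "ShortHigh"),
    ("ShortRunLowGrayLevelEmphasis", "ShortLow")]


def glrlm_features(lev):
    np_ = len(lev)
    per_angle = []
    for d in DIRS13:
        runs = {}
        for c, li in lev.items():
            prev = (c[0] - d[0], c[1] - d[1], c[2] - d[2])
            if lev.get(prev) == li:
                continue  # interior of a run
            length = 1
            cur = (c[0] + d[0], c[1] + d[1], c[2] + d[2])
            while lev.get(cur) == li:
                length += 1
                cur = (cur[0] + d[0], cur[1] + d[1], cur[2] + d[2])
            runs[(li, length)] = runs.get((li, length), 0) + 1
        per_angle.append(rl_sz_core(runs, np_))
    keys = per_angle[0].keys()
    avg = {k: sum(a[k] for a in per_angle) / len(per_angle) for k in keys}
    return {"original_glrlm_" + name: avg[k] for name, k in GLRLM_MAP}


# --- GLSZM ------------------------------------------------------------------

GLSZM_MAP = [
    ("GrayLevelNonUniformity", "GLN"),
    ("GrayLevelNonUniformityNormalized", "GLNN"),
    ("GrayLevelVariance", "GLV"),
    ("HighGrayLevelZoneEmphasis", "High"),
    ("LargeAreaEmphasis", "Long"),
    ("LargeAreaHighGrayLevelEmphasis", "LongHigh"),
    ("LargeAreaLowGrayLevelEmphasis", "LongLow"),
    ("LowGrayLevelZoneEmphasis", "Low"),
    ("SizeZoneNonUniformity", "SN"),
    ("SizeZoneNonUniformityNormalized", "SNN"),
    ("SmallAreaEmphasis", "Short"),
    ("SmallAreaHighGrayLevelEmphasis", "ShortHigh"),
    ("SmallAreaLowGrayLevelEmphasis", "ShortLow"),
    ("ZoneEntropy", "Entropy"),
    ("ZonePercentage", "Pct"),
    ("ZoneVariance", "SV")]


def zones26(lev):
    seen = set()
    zones = {}
    for start, li in lev.items():
        if start in seen:
            continue
        stack = [start]
        seen.add(start)
        size = 0
        while stack:
            c = stack.pop()
            size += 1
            for d in NEIGH26:
                n = (c[0] + d[0], c[1] + d[1], c[2] + d[2])
                if n not in seen and lev.get(n) == li:
                    seen.add(n)
                    stack.append(n)
        zones[(li, size)] = zones.get((li, size), 0) + 1
    return zones


def glszm_features(lev):
    core = rl_sz_core(zones26(lev), len(lev))
    return {"original_glszm_" + name: core[k] for name, k in GLSZM_MAP}


# --- GLDM -------------------------------------------------------------------

GLDM_MAP = [
    ("DependenceEntropy", "Entropy"),
    ("DependenceNonUniformity", "SN"),
    ("DependenceNonUniformityNormalized", "SNN"),
    ("DependenceVariance", "SV"),
    ("GrayLevelNonUniformity", "GLN"),
    ("GrayLevelVariance", "GLV"),
    ("HighGrayLevelEmphasis", "High"),
    ("LargeDependenceEmphasis", "Long"),
    ("LargeDependenceHighGrayLevelEmphasis", "LongHigh"),
    ("LargeDependenceLowGrayLevelEmphasis", "LongLow"),
    ("LowGrayLevelEmphasis", "Low"),
    ("SmallDependenceEmphasis", "Short"),
    ("SmallDependenceHighGrayLevelEmphasis", "ShortHigh"),
    ("SmallDependenceLowGrayLevelEmphasis", "ShortLow")]


def gldm_features(lev):
    cells = {}
    for c, li in lev.items():
        dep = 0
        for d in NEIGH26:
            n = (c[0] + d[0], c[1] + d[1], c[2] + d[2])
            if n in lev and abs(li - lev[n]) <= GLDM_ALPHA:
                dep += 1
        cells[(li, dep + 1)] = cells.get((li, dep + 1), 0) + 1
    core = rl_sz_core(cells, len(lev))
    return {"original_gldm_" + name: core[k] for name, k in GLDM_MAP}


# --- NGTDM ------------------------------------------------------------------

def ngtdm_features(lev, ng):
    n = {i: 0 for i in range(1, ng + 1)}
    s = {i: 0.0 for i in range(1, ng + 1)}
    for c, li in lev.items():
        neigh = [lev[(c[0] + d[0], c[1] + d[1], c[2] + d[2])]
                 for d in NEIGH26
                 if (c[0] + d[0], c[1] + d[1], c[2] + d[2]) in lev]
        if not neigh:
            continue
        n[li] += 1
        s[li] += abs(li - sum(neigh) / len(neigh))
    nvp = sum(n.values())
    if nvp == 0:
        return {"original_ngtdm_Busyness": 0.0,
                "original_ngtdm_Coarseness": 1e6,
                "original_ngtdm_Complexity": 0.0,
                "original_ngtdm_Contrast": 0.0,
                "original_ngtdm_Strength": 0.0}
    present = [i for i in n if n[i] > 0]
    p = {i: n[i] / nvp for i in present}
    ngp = len(present)
    den_c = sum(p[i] * s[i] for i in present)
    coarse = 1e6 if den_c == 0 else 1.0 / den_c
    if ngp <= 1:
        contrast = 0.0
    else:
        contrast = (sum(p[i] * p[j] * (i - j) ** 2
                        for i in present for j in present)
                    / (ngp * (ngp - 1))) * sum(s[i] for i in present) / nvp
    den_b = sum(abs(i * p[i] - j * p[j])
                for i in present for j in present)
    busy = 0.0 if den_b == 0 else den_c / den_b
    cplx = sum(abs(i - j) * (p[i] * s[i] + p[j] * s[j]) / (p[i] + p[j])
               for i in present for j in present) / nvp
    den_s = sum(s[i] for i in present)
    strength = 0.0 if den_s == 0 else \
        sum((p[i] + p[j]) * (i - j) ** 2
            for i in present for j in present) / den_s
    return {"original_ngtdm_Busyness": busy,
            "original_ngtdm_Coarseness": coarse,
            "original_ngtdm_Complexity": cplx,
            "original_ngtdm_Contrast": contrast,
            "original_ngtdm_Strength": strength}


def main(paths):
    w = csv.writer(sys.stdout)
    w.writerow(["lesion", "feature", "value"])
    for path in paths:
        vox = read_lesion(path)
        lev, ng = discretize(vox)
        feats = {}
        feats.update(glcm_features(lev, ng))
        feats.update(glrlm_features(lev))
        feats.update(glszm_features(lev))
        feats.update(gldm_features(lev))
        feats.update(ngtdm_features(lev, ng))
        name = path.split("/")[-1].rsplit(".", 1)[0]
        for k in sorted(feats):
            w.writerow([name, k, repr(feats[k])])


if __name__ == "__main__":
    main(sys.argv[1:])
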