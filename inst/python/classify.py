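"""Classifier backend for the MT-versus-ST benchmark.

Called as:  python classify.py <input.json> <output.json>

Input:
  n_bits      fingerprint length
  rows        list of on-bit index lists (0-based), one per compound
  labels      list of 0/1 class labels (1 = multi-target compound)
  trials      list of {train: [...], test: [...], seed: int} with 0-based
              row indices; the train/test partition is decided by the caller
  classifiers subset of {"svm", "knn", "rf"}
  params      {"svm_cost": float, "knn_k": int, "rf_trees": int}

Output: {"trials": [{"svm": [...], "knn": [...], "rf": [...]}, ...]}
with 0/1 predictions for the test rows of each trial. Only fit/predict
happens here; splitting, down-sampling and scoring stay on the R side.
"""

import json
import sys

import numpy as np
from sklearn.ensemble import RandomForestClassifier
from sklearn.neighbors import KNeighborsClassifier
from sklearn.svm import SVC


def dense(rows, n_bits):
    x = np.zeros((len(rows), n_bits), dtype=bool)
    for i, bits in enumerate(rows):
        if bits:
            x[i, np.asarray(bits, dtype=int)] = True
    return x


def make_model(name, params, seed):
    if name == "svm":
        return SVC(kernel="rbf", C=float(params.get("svm_cost", 1.0)))
    if name == "knn":
        # Jaccard distance on binary fingerprints == 1 - Tanimoto similarity
        return KNeighborsClassifier(
            n_neighbors=int(params.get("knn_k", 1)), metric="jaccard"
        )
    if name == "rf":
        return RandomForestClassifier(
            n_estimators=int(params.get("rf_trees", 100)), random_state=seed
        )
    raise ValueError("unknown classifier: " + name)


def main(argv):
    if len(argv) != 3:
        sys.stderr.write("usage: classify.py in.json out.json\n")
        return 2
    with open(argv[1]) as fh:
        payload = json.load(fh)
    x = dense(payload["rows"], int(payload["n_bits"]))
    y = np.asarray(payload["labels"], dtype=int)
    params = payload.get("params", {})
    out = []
    for trial in payload["trials"]:
        tr = np.asarray(trial["train"], dtype=int)
        te = np.asarray(trial["test"], dtype=int)
        seed = int(trial.get("seed", 0))
        # a trial may override the global labels (e.g. permutation control)
        yt = np.asarray(trial["labels"], dtype=int) if "labels" in trial else y
        preds = {}
        for name in payload["classifiers"]:
            model = make_model(name, params, seed)
            model.fit(x[tr], yt[tr])
            preds[name] = [int(p) for p in model.predict(x[te])]
        out.append(preds)
    with open(argv[2], "w") as fh:
        json.dump({"trials": out}, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
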