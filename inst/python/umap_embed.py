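"""UMAP embedding helper invoked by mitoifc::embed_umap().

Reads a JSON config {input_csv, output_csv, n_neighbors, min_dist, metric,
seeds}, fits umap-learn once per seed in a single process (amortizing the
numba JIT cost), and writes a long-format CSV: seed, row, x, y.
"""
import json
import sys
import warnings

import numpy as np


def main(cfg_path):
    with open(cfg_path) as fh:
        cfg = json.load(fh)
    warnings.filterwarnings("ignore")
    import umap  # deferred: slow import

    X = np.loadtxt(cfg["input_csv"], delimiter=",", ndmin=2)
    seeds = cfg["seeds"]
    if isinstance(seeds, int):
        seeds = [seeds]
    rows = []
    for seed in seeds:
        emb = umap.UMAP(
            n_neighbors=int(cfg["n_neighbors"]),
            min_dist=float(cfg["min_dist"]),
            metric=cfg["metric"],
            n_components=2,
            random_state=int(seed),
        ).fit_transform(X)
        for i, (x, y) in enumerate(emb):
            rows.append((int(seed), i + 1, float(x), float(y)))
    with open(cfg["output_csv"], "w") as fh:
        fh.write("seed,row,x,y\n")
        for r in rows:
            fh.write("%d,%d,%.10g,%.10g\n" % r)


if __name__ == "__main__":
    main(sys.argv[1])
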