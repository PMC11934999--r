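"""Convert between an .h5ad single-cell container and a MatrixMarket directory.

Used by the R package as a thin bridge; the mtx directory follows the
genes-by-barcodes convention (matrix.mtx, barcodes.tsv, features.tsv).
"""
import sys
import os


def to_mtx(src, dst):
    import anndata
    import scipy.sparse as sp
    import scipy.io as sio
    ad = anndata.read_h5ad(src)
    x = ad.X
    if not sp.issparse(x):
        x = sp.csr_matrix(x)
    os.makedirs(dst, exist_ok=True)
    sio.mmwrite(os.path.join(dst, "matrix.mtx"), x.T.tocoo())
    with open(os.path.join(dst, "barcodes.tsv"), "w") as fh:
        fh.write("\n".join(map(str, ad.obs_names)) + "\n")
    with open(os.path.join(dst, "features.tsv"), "w") as fh:
        fh.write("\n".join(map(str, ad.var_names)) + "\n")


def from_mtx(src, dst):
    import anndata
    import pandas as pd
    import scipy.io as sio
    x = sio.mmread(os.path.join(src, "matrix.mtx")).tocsr().T
    with open(os.path.join(src, "barcodes.tsv")) as fh:
        obs = [l.strip() for l in fh if l.strip()]
    with open(os.path.join(src, "features.tsv")) as fh:
        var = [l.strip().split("\t")[0] for l in fh if l.strip()]
    ad = anndata.AnnData(
        X=x.tocsr(),
        obs=pd.DataFrame(index=obs),
        var=pd.DataFrame(index=var),
    )
    ad.write_h5ad(dst)


def main():
    action, src, dst = sys.argv[1:4]
    if action == "to_mtx":
        to_mtx(src, dst)
    elif action == "from_mtx":
        from_mtx(src, dst)
    else:
        raise SystemExit(f"unknown action: {action}")


if __name__ == "__main__":
    main()
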