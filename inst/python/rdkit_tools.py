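"""Batch RDKit helper driven by the R package.

Reads SMILES (one per line) from --in, writes TSV to --out. Every
subcommand is line-aligned with its input so the caller can join results
back by position. Invalid SMILES yield empty fields, never a crash.
"""

import argparse
import os
import sys

from rdkit import Chem, RDConfig, RDLogger
from rdkit.Chem import Descriptors, QED

RDLogger.DisableLog("rdApp.*")

sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
import sascorer  # noqa: E402


def read_lines(path):
    with open(path) as fh:
        return [line.rstrip("\n") for line in fh]


def mol_of(smi):
    if not smi:
        return None
    return Chem.MolFromSmiles(smi)


def cmd_canon(args):
    out = []
    for smi in read_lines(args.infile):
        mol = mol_of(smi)
        out.append(Chem.MolToSmiles(mol) if mol is not None else "")
    write(args.outfile, ["canonical"], [[c] for c in out])


def cmd_descriptors(args):
    rows = []
    for smi in read_lines(args.infile):
        mol = mol_of(smi)
        if mol is None:
            rows.append([""] * 8)
            continue
        rows.append([
            "%.6f" % Descriptors.MolLogP(mol),
            "%.6f" % Descriptors.MolWt(mol),
            "%d" % Descriptors.NumHDonors(mol),
            "%d" % Descriptors.NumHAcceptors(mol),
            "%d" % Descriptors.NumRotatableBonds(mol),
            "%.6f" % Descriptors.TPSA(mol),
            "%.6f" % QED.qed(mol),
            "%.6f" % sascorer.calculateScore(mol),
        ])
    write(args.outfile,
          ["logP", "mol_weight_Da", "n_h_donors", "n_h_acceptors",
           "n_rotatable_bonds", "tpsa_A2", "qed", "sas"], rows)


def fingerprint(mol, kind, n_bits):
    if kind == "morgan":
        from rdkit.Chem import rdFingerprintGenerator
        gen = rdFingerprintGenerator.GetMorganGenerator(radius=2, fpSize=n_bits)
        return gen.GetFingerprint(mol)
    return Chem.RDKFingerprint(mol, fpSize=n_bits)


def cmd_nn_tanimoto(args):
    from rdkit import DataStructs
    ref_fps = []
    for smi in read_lines(args.reffile):
        mol = mol_of(smi)
        if mol is not None:
            ref_fps.append(fingerprint(mol, args.fingerprint, args.n_bits))
    rows = []
    for smi in read_lines(args.infile):
        mol = mol_of(smi)
        if mol is None or not ref_fps:
            rows.append([""])
            continue
        fp = fingerprint(mol, args.fingerprint, args.n_bits)
        sims = DataStructs.BulkTanimotoSimilarity(fp, ref_fps)
        rows.append(["%.10f" % max(sims)])
    write(args.outfile, ["nn_tanimoto"], rows)


def write(path, header, rows):
    with open(path, "w") as fh:
        fh.write("\t".join(header) + "\n")
        for row in rows:
            fh.write("\t".join(row) + "\n")


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("command", choices=["canon", "descriptors", "nn_tanimoto"])
    ap.add_argument("--in", dest="infile", required=True)
    ap.add_argument("--out", dest="outfile", required=True)
    ap.add_argument("--ref", dest="reffile")
    ap.add_argument("--fingerprint", default="path", choices=["path", "morgan"])
    ap.add_argument("--n-bits", dest="n_bits", type=int, default=2048)
    args = ap.parse_args()
    {"canon": cmd_canon,
     "descriptors": cmd_descriptors,
     "nn_tanimoto": cmd_nn_tanimoto}[args.command](args)


if __name__ == "__main__":
    main()
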