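"""RDKit helper for the chemmaps R package.

Reads a tab-separated file of (identifier, SMILES) pairs and writes, per
molecule, either the canonical SMILES or a fingerprint bit string. Invalid
SMILES yield an empty field (canon) and are expected to be filtered out by
the caller before fingerprinting.
"""
import argparse
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import MACCSkeys
from rdkit.Chem import rdFingerprintGenerator

RDLogger.DisableLog("rdApp.*")


def read_records(path):
    with open(path) as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            ident, smiles = line.split("\t", 1)
            yield ident, smiles


def cmd_canon(args):
    with open(args.output, "w") as out:
        for ident, smiles in read_records(args.input):
            mol = Chem.MolFromSmiles(smiles)
            canon = Chem.MolToSmiles(mol) if mol is not None else ""
            out.write(f"{ident}\t{canon}\n")


def fingerprint_fn(family):
    if family == "maccs":
        # RDKit emits 167 positions with bit 0 unused; drop it -> 166 keys
        return lambda mol: MACCSkeys.GenMACCSKeys(mol).ToBitString()[1:]
    if family == "ecfp4":
        gen = rdFingerprintGenerator.GetMorganGenerator(radius=2, fpSize=1024)
    elif family == "rdkit":
        gen = rdFingerprintGenerator.GetRDKitFPGenerator(fpSize=2048)
    else:
        raise SystemExit(f"unknown fingerprint family: {family}")
    return lambda mol: gen.GetFingerprint(mol).ToBitString()


def cmd_fp(args):
    fp = fingerprint_fn(args.family)
    with open(args.output, "w") as out:
        for ident, smiles in read_records(args.input):
            mol = Chem.MolFromSmiles(smiles)
            if mol is None:
                print(f"cannot parse SMILES for {ident}", file=sys.stderr)
                raise SystemExit(1)
            out.write(f"{ident}\t{fp(mol)}\n")


def main():
    ap = argparse.ArgumentParser()
    sub = ap.add_subparsers(dest="cmd", required=True)
    p = sub.add_parser("canon")
    p.add_argument("input")
    p.add_argument("output")
    p.set_defaults(fn=cmd_canon)
    p = sub.add_parser("fp")
    p.add_argument("input")
    p.add_argument("output")
    p.add_argument("--family", required=True,
                   choices=["maccs", "ecfp4", "rdkit"])
    p.set_defaults(fn=cmd_fp)
    args = ap.parse_args()
    args.fn(args)


if __name__ == "__main__":
    main()
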