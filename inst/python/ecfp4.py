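"""ECFP4 (Morgan radius 2) folded fingerprints via RDKit.

Usage: python ecfp4.py <smiles_file> <out_file> [nbits]

One SMILES per input line; one output line per input: space-separated
on-bit indices, "EMPTY" for a molecule with no bits set, or "ERROR" for
an unparseable SMILES.
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import rdFingerprintGenerator

RDLogger.DisableLog("rdApp.*")


def main():
    smi_path, out_path = sys.argv[1], sys.argv[2]
    nbits = int(sys.argv[3]) if len(sys.argv) > 3 else 2048
    gen = rdFingerprintGenerator.GetMorganGenerator(radius=2, fpSize=nbits)
    with open(smi_path) as fh:
        smiles = [line.rstrip("\n") for line in fh]
    out = []
    for smi in smiles:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append("ERROR")
            continue
        bits = list(gen.GetFingerprint(mol).GetOnBits())
        out.append(" ".join(str(b) for b in bits) if bits else "EMPTY")
    with open(out_path, "w") as fh:
        fh.write("\n".join(out) + "\n")


if __name__ == "__main__":
    main()
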