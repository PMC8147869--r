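"""Molecule utilities backing the R package: canonicalization, Morgan
fingerprints, SMARTS substructure matching.

Called as:  python chemtools.py <command> <input.json> <output.json>

All commands are batch-oriented; one process handles one batch. Input and
output are plain JSON so the R side stays dependency-light.
"""

import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import rdFingerprintGenerator

RDLogger.DisableLog("rdApp.*")


def _mol_nostereo(smiles):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return None
    Chem.RemoveStereochemistry(mol)
    return mol


def cmd_canon(payload):
    out = []
    for smi in payload["smiles"]:
        mol = _mol_nostereo(smi)
        out.append(None if mol is None else Chem.MolToSmiles(mol))
    return {"canonical": out}


def cmd_fp(payload):
    radius = int(payload.get("radius", 2))
    n_bits = int(payload.get("n_bits", 2048))
    gen = rdFingerprintGenerator.GetMorganGenerator(radius=radius, fpSize=n_bits)
    bits = []
    for smi in payload["smiles"]:
        mol = _mol_nostereo(smi)
        if mol is None:
            bits.append(None)
        else:
            bv = gen.GetFingerprint(mol)
            bits.append(sorted(bv.GetOnBits()))
    return {"bits": bits, "radius": radius, "n_bits": n_bits}


def cmd_validate_smarts(payload):
    errors = []
    for pat in payload["patterns"]:
        if Chem.MolFromSmarts(pat) is None:
            errors.append(pat)
    return {"invalid": errors}


def cmd_match(payload):
    queries = []
    for pat in payload["patterns"]:
        q = Chem.MolFromSmarts(pat)
        if q is None:
            raise ValueError("invalid SMARTS pattern: " + pat)
        queries.append(q)
    hits = []
    for smi in payload["smiles"]:
        mol = _mol_nostereo(smi)
        if mol is None:
            hits.append(None)
        else:
            hits.append([bool(mol.HasSubstructMatch(q)) for q in queries])
    return {"matches": hits}


COMMANDS = {
    "canon": cmd_canon,
    "fp": cmd_fp,
    "match": cmd_match,
    "validate_smarts": cmd_validate_smarts,
}


def main(argv):
    if len(argv) != 4 or argv[1] not in COMMANDS:
        sys.stderr.write("usage: chemtools.py {canon|fp|match|validate_smarts} in.json out.json\n")
        return 2
    with open(argv[2]) as fh:
        payload = json.load(fh)
    result = COMMANDS[argv[1]](payload)
    with open(argv[3], "w") as fh:
        json.dump(result, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
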