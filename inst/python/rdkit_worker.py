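#!/usr/bin/env python
"""Batch RDKit helper for the gensmiles R package.

Reads one SMILES per line on stdin, writes one tab-separated record per
input line on stdout. Invoked as:

    python rdkit_worker.py analyze
    python rdkit_worker.py canon
    python rdkit_worker.py random <n_attempts> <seed>
    python rdkit_worker.py props

All RDKit warnings are silenced; failures are reported per-record (ok=0),
never as a crash, so record counts always match line counts.
"""

import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Crippen, Descriptors, inchi

RDLogger.DisableLog("rdApp.*")

ORGANIC = {"H", "B", "C", "N", "O", "F", "S", "Cl", "Br", "I"}


def mol_from(smi):
    if not smi:
        return None
    return Chem.MolFromSmiles(smi)


def inchikey_of(mol):
    try:
        key = inchi.MolToInchiKey(mol)
    except Exception:
        return ""
    return key or ""


def cmd_analyze(lines):
    # ok, organic, canonical, inchikey, hac
    for smi in lines:
        mol = mol_from(smi)
        if mol is None:
            print("0\t0\t\t\t0")
            continue
        organic = int(
            any(a.GetSymbol() == "C" for a in mol.GetAtoms())
            and all(a.GetSymbol() in ORGANIC for a in mol.GetAtoms())
        )
        print("1\t%d\t%s\t%s\t%d" % (organic, Chem.MolToSmiles(mol),
                                     inchikey_of(mol), mol.GetNumHeavyAtoms()))


def cmd_canon(lines):
    # ok, canonical, inchikey
    for smi in lines:
        mol = mol_from(smi)
        if mol is None:
            print("0\t\t")
        else:
            print("1\t%s\t%s" % (Chem.MolToSmiles(mol), inchikey_of(mol)))


def cmd_random(lines, n_attempts, seed):
    # one line per input: tab-joined randomized SMILES (empty if unparseable)
    for i, smi in enumerate(lines):
        mol = mol_from(smi)
        if mol is None:
            print("")
            continue
        variants = Chem.MolToRandomSmilesVect(
            mol, n_attempts, randomSeed=(seed + 7919 * i) % (2**31 - 1))
        print("\t".join(variants))


def cmd_props(lines):
    # ok + the 12-property panel, in fixed column order
    header = ("ok\tsmiles_length\thac\tmw\tlogp\ttpsa\trot_bonds\t"
              "frac_cyclic\tfrac_conjugated\tfrac_aromatic\t"
              "frac_c\tfrac_n\tfrac_o")
    print(header)
    for smi in lines:
        mol = mol_from(smi)
        if mol is None:
            print("0" + "\tnan" * 12)
            continue
        atoms = list(mol.GetAtoms())
        hac = mol.GetNumHeavyAtoms()
        conj = set()
        for b in mol.GetBonds():
            if b.GetIsConjugated():
                conj.add(b.GetBeginAtomIdx())
                conj.add(b.GetEndAtomIdx())
        n_cyc = sum(1 for a in atoms if a.IsInRing())
        n_aro = sum(1 for a in atoms if a.GetIsAromatic())
        n_c = sum(1 for a in atoms if a.GetSymbol() == "C")
        n_n = sum(1 for a in atoms if a.GetSymbol() == "N")
        n_o = sum(1 for a in atoms if a.GetSymbol() == "O")
        row = [
            len(Chem.MolToSmiles(mol)),
            hac,
            Descriptors.MolWt(mol),
            Crippen.MolLogP(mol),
            Descriptors.TPSA(mol),
            Descriptors.NumRotatableBonds(mol),
            n_cyc / hac,
            len(conj) / hac,
            n_aro / hac,
            n_c / hac,
            n_n / hac,
            n_o / hac,
        ]
        print("1\t" + "\t".join(repr(float(v)) for v in row))


def main():
    op = sys.argv[1]
    lines = [ln.rstrip("\n") for ln in sys.stdin]
    if op == "analyze":
        cmd_analyze(lines)
    elif op == "canon":
        cmd_canon(lines)
    elif op == "random":
        cmd_random(lines, int(sys.argv[2]), int(sys.argv[3]))
    elif op == "props":
        cmd_props(lines)
    else:
        sys.stderr.write("unknown op: %s\n" % op)
        return 2
    return 0


if __name__ == "__main__":
    sys.exit(main())
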