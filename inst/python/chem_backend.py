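#!/usr/bin/env python
"""Batch cheminformatics backend for the molforge R package.

Reads SMILES (one per line) on stdin, writes a JSON array on stdout, one
object per input line in order.  All heavy lifting is delegated to RDKit;
this script deliberately contains no scoring logic — the R side owns that.

Subcommands:
  props   [--strip-salts]                canonical SMILES, MW, cLogP
  fp      --kinds K1,K2 [--nbits N] [--maxpath P]   on-bit indices per kind
  brics   [--cleave-amides] [--keep-isotopes]       BRICS fragments + bond labels
  pains                                  PAINS A/B/C filter-catalog matches
  smarts  --file F                       matches against named SMARTS file
  murcko                                 Bemis-Murcko scaffold SMILES
  sdf     --file F                       read an SDF, emit id + SMILES
"""

import sys
import json
import argparse

from rdkit import Chem, RDLogger
from rdkit.Chem import Descriptors, Crippen, MACCSkeys, BRICS
from rdkit.Chem import rdFingerprintGenerator as rfg
from rdkit.Chem.Scaffolds import MurckoScaffold

RDLogger.DisableLog("rdApp.*")

FP_KINDS = ("PATH", "MACCS166", "ATOMPAIR", "TORSION", "CIRCULAR", "CIRCULAR_FEAT")


def read_lines():
    return [ln.rstrip("\n").rstrip("\r") for ln in sys.stdin]


def parse(smiles):
    if not smiles or not smiles.strip():
        return None, "empty SMILES"
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return None, "unparseable SMILES"
    return mol, None


def largest_fragment(mol):
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=True)
    return max(frags, key=lambda m: m.GetNumHeavyAtoms())


def cmd_props(args):
    out = []
    for smi in read_lines():
        mol, err = parse(smi)
        if mol is None:
            out.append({"ok": False, "error": err, "input": smi})
            continue
        if args.strip_salts:
            mol = largest_fragment(mol)
        out.append({
            "ok": True,
            "canonical": Chem.MolToSmiles(mol),
            "mw": Descriptors.MolWt(mol),
            "logp": Crippen.MolLogP(mol),
            "n_heavy": mol.GetNumHeavyAtoms(),
        })
    return out


def make_generators(kinds, nbits, maxpath):
    gens = {}
    for k in kinds:
        if k == "PATH":
            gens[k] = rfg.GetRDKitFPGenerator(maxPath=maxpath, fpSize=nbits)
        elif k == "ATOMPAIR":
            gens[k] = rfg.GetAtomPairGenerator(fpSize=nbits)
        elif k == "TORSION":
            gens[k] = rfg.GetTopologicalTorsionGenerator(fpSize=nbits)
        elif k == "CIRCULAR":
            gens[k] = rfg.GetMorganGenerator(radius=2, fpSize=nbits)
        elif k == "CIRCULAR_FEAT":
            gens[k] = rfg.GetMorganGenerator(
                radius=2, fpSize=nbits,
                atomInvariantsGenerator=rfg.GetMorganFeatureAtomInvGen())
        elif k == "MACCS166":
            gens[k] = None  # special-cased below
        else:
            sys.stderr.write("unknown fingerprint kind: %s\n" % k)
            sys.exit(2)
    return gens


def cmd_fp(args):
    kinds = args.kinds.split(",")
    gens = make_generators(kinds, args.nbits, args.maxpath)
    out = []
    for smi in read_lines():
        mol, err = parse(smi)
        if mol is None:
            out.append({"ok": False, "error": err, "input": smi})
            continue
        fps = {}
        for k in kinds:
            if k == "MACCS166":
                # RDKit MACCS is 167 bits with bit 0 unused; shift to 0..165
                bits = [b - 1 for b in MACCSkeys.GenMACCSKeys(mol).GetOnBits()]
                fps[k] = {"nbits": 166, "bits": bits}
            else:
                bits = list(gens[k].GetFingerprint(mol).GetOnBits())
                fps[k] = {"nbits": args.nbits, "bits": bits}
        out.append({"ok": True, "fps": fps})
    return out


AMIDE_SMARTS = Chem.MolFromSmarts("[C;!R](=O)-[N;!R]")


def fragment_one(mol, cleave_amides, keep_isotopes):
    bonds = list(BRICS.FindBRICSBonds(mol))
    labels = sorted("L%s-L%s" % tuple(sorted(lbl, key=str)) for (_, lbl) in bonds)
    broken = BRICS.BreakBRICSBonds(mol)
    frag_mols = list(Chem.GetMolFrags(broken, asMols=True, sanitizeFrags=True))
    if cleave_amides:
        extra = []
        for fm in frag_mols:
            bidx = []
            for (i, j) in [m[:2] for m in fm.GetSubstructMatches(AMIDE_SMARTS)]:
                b = fm.GetBondBetweenAtoms(i, j)
                a1, a2 = b.GetBeginAtom(), b.GetEndAtom()
                if a1.GetAtomicNum() > 0 and a2.GetAtomicNum() > 0:
                    bidx.append(b.GetIdx())
            if bidx:
                cut = Chem.FragmentOnBonds(fm, bidx, dummyLabels=[(0, 0)] * len(bidx))
                extra.extend(Chem.GetMolFrags(cut, asMols=True, sanitizeFrags=True))
                labels.extend(["AMIDE-AMIDE"] * len(bidx))
            else:
                extra.append(fm)
        frag_mols = extra
    frags = []
    for fm in frag_mols:
        if not keep_isotopes:
            for at in fm.GetAtoms():
                if at.GetAtomicNum() == 0:
                    at.SetIsotope(0)
        frags.append(Chem.MolToSmiles(fm))
    return frags, labels


def cmd_brics(args):
    out = []
    for smi in read_lines():
        mol, err = parse(smi)
        if mol is None:
            out.append({"ok": False, "error": err, "input": smi})
            continue
        frags, labels = fragment_one(mol, args.cleave_amides, args.keep_isotopes)
        out.append({"ok": True, "fragments": frags, "bonds": labels})
    return out


def cmd_pains(args):
    from rdkit.Chem.FilterCatalog import FilterCatalog, FilterCatalogParams
    params = FilterCatalogParams()
    params.AddCatalog(FilterCatalogParams.FilterCatalogs.PAINS)
    catalog = FilterCatalog(params)
    out = []
    for smi in read_lines():
        mol, err = parse(smi)
        if mol is None:
            out.append({"ok": False, "error": err, "input": smi})
            continue
        names = [e.GetDescription() for e in catalog.GetMatches(mol)]
        out.append({"ok": True, "alerts": names})
    return out


def cmd_smarts(args):
    patterns = []
    with open(args.file) as fh:
        for ln in fh:
            ln = ln.rstrip("\n")
            if not ln or ln.startswith("#"):
                continue
            parts = ln.split("\t", 1)
            if len(parts) != 2:
                sys.stderr.write("malformed alert line (need name<TAB>SMARTS): %s\n" % ln)
                sys.exit(2)
            name, smarts = parts
            q = Chem.MolFromSmarts(smarts)
            if q is None:
                sys.stderr.write("uncompilable SMARTS pattern '%s': %s\n" % (name, smarts))
                sys.exit(2)
            patterns.append((name, q))
    out = []
    for smi in read_lines():
        mol, err = parse(smi)
        if mol is None:
            out.append({"ok": False, "error": err, "input": smi})
            continue
        names = [n for (n, q) in patterns if mol.HasSubstructMatch(q)]
        out.append({"ok": True, "alerts": names})
    return out


def cmd_murcko(args):
    out = []
    for smi in read_lines():
        mol, err = parse(smi)
        if mol is None:
            out.append({"ok": False, "error": err, "input": smi})
            continue
        out.append({"ok": True, "scaffold": MurckoScaffold.MurckoScaffoldSmiles(mol=mol)})
    return out


def cmd_sdf(args):
    out = []
    supplier = Chem.SDMolSupplier(args.file)
    for i, mol in enumerate(supplier):
        if mol is None:
            out.append({"ok": False, "error": "unparseable SDF record", "input": str(i)})
            continue
        name = mol.GetProp("_Name") if mol.HasProp("_Name") else ""
        out.append({"ok": True, "id": name, "smiles": Chem.MolToSmiles(mol)})
    return out


def main():
    ap = argparse.ArgumentParser(prog="chem_backend")
    sub = ap.add_subparsers(dest="cmd", required=True)
    p = sub.add_parser("props")
    p.add_argument("--strip-salts", action="store_true")
    p = sub.add_parser("fp")
    p.add_argument("--kinds", required=True)
    p.add_argument("--nbits", type=int, default=2048)
    p.add_argument("--maxpath", type=int, default=7)
    p = sub.add_parser("brics")
    p.add_argument("--cleave-amides", action="store_true")
    p.add_argument("--keep-isotopes", action="store_true")
    sub.add_parser("pains")
    p = sub.add_parser("smarts")
    p.add_argument("--file", required=True)
    sub.add_parser("murcko")
    p = sub.add_parser("sdf")
    p.add_argument("--file", required=True)
    args = ap.parse_args()
    fn = {"props": cmd_props, "fp": cmd_fp, "brics": cmd_brics, "pains": cmd_pains,
          "smarts": cmd_smarts, "murcko": cmd_murcko, "sdf": cmd_sdf}[args.cmd]
    json.dump(fn(args), sys.stdout)
    sys.stdout.write("\n")


if __name__ == "__main__":
    main()
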