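"""Batch molecular descriptor backend.

Reads SMILES (one per line) and emits one JSON object per input line with
canonical SMILES, QED, Crippen logP, Ertl SA score (native 1-10 scale),
SSSR ring sizes, Morgan fingerprint on-bits and, when an alert file is
given, the number of distinct alert SMARTS with at least one match.

Invalid SMILES yield {"valid": false} records; the caller decides policy.
"""
import argparse
import json
import os
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import QED, Crippen, RDConfig
from rdkit.Chem import rdFingerprintGenerator

sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
import sascorer  # noqa: E402

RDLogger.DisableLog("rdApp.*")


def read_lines(path):
    with open(path, "r", encoding="utf-8") as fh:
        return [ln.rstrip("\n") for ln in fh]


def load_alerts(path):
    """Return (patterns, errors); errors are (line_no, smarts, message)."""
    patterns, errors = [], []
    for i, raw in enumerate(read_lines(path), start=1):
        line = raw.strip()
        if not line or line.startswith("#"):
            continue
        smarts = line.split("\t")[0].strip()
        patt = Chem.MolFromSmarts(smarts)
        if patt is None:
            errors.append((i, smarts, "SMARTS failed to compile"))
        else:
            patterns.append(patt)
    return patterns, errors


def cmd_alerts(args):
    _, errors = load_alerts(args.alerts)
    out = {"ok": not errors,
           "errors": [{"line": l, "smarts": s, "message": m}
                      for l, s, m in errors]}
    json.dump(out, sys.stdout)
    sys.stdout.write("\n")
    return 0


def cmd_desc(args):
    alerts = None
    if args.alerts:
        alerts, errors = load_alerts(args.alerts)
        if errors:
            sys.stderr.write("bad alert SMARTS at line %d: %s\n"
                             % (errors[0][0], errors[0][1]))
            return 2
    fpgen = rdFingerprintGenerator.GetMorganGenerator(
        radius=args.fp_radius, fpSize=args.fp_bits)
    out = open(args.out, "w", encoding="utf-8") if args.out else sys.stdout
    for smi in read_lines(args.smiles_file):
        rec = {"smiles": smi, "valid": False}
        mol = Chem.MolFromSmiles(smi) if smi else None
        if mol is not None:
            try:
                rec["valid"] = True
                rec["canonical"] = Chem.MolToSmiles(mol)
                rec["qed"] = QED.qed(mol)
                rec["logp"] = Crippen.MolLogP(mol)
                rec["sa"] = sascorer.calculateScore(mol)
                rec["ring_sizes"] = sorted(
                    len(r) for r in mol.GetRingInfo().AtomRings())
                if not args.no_fp:
                    fp = fpgen.GetFingerprint(mol)
                    rec["fp"] = list(fp.GetOnBits())
                if alerts is not None:
                    rec["n_alerts"] = sum(
                        1 for p in alerts if mol.HasSubstructMatch(p))
            except Exception as exc:  # descriptor failure on a parsed mol
                rec = {"smiles": smi, "valid": True, "error": str(exc)}
        json.dump(rec, out)
        out.write("\n")
    if args.out:
        out.close()
    return 0


def main():
    ap = argparse.ArgumentParser(description=__doc__)
    sub = ap.add_subparsers(dest="cmd", required=True)
    d = sub.add_parser("desc", help="compute descriptors for a SMILES file")
    d.add_argument("--smiles-file", required=True)
    d.add_argument("--alerts", default=None)
    d.add_argument("--fp-radius", type=int, default=2)
    d.add_argument("--fp-bits", type=int, default=2048)
    d.add_argument("--no-fp", action="store_true")
    d.add_argument("--out", default=None)
    d.set_defaults(fn=cmd_desc)
    a = sub.add_parser("alerts", help="validate an alert SMARTS file")
    a.add_argument("--alerts", required=True)
    a.set_defaults(fn=cmd_alerts)
    args = ap.parse_args()
    sys.exit(args.fn(args))


if __name__ == "__main__":
    main()
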