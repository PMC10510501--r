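#!/usr/bin/env python
"""Line-JSON chemistry worker.

Reads one JSON request per line on stdin, writes one JSON response per line
on stdout.  Request: {"op": <name>, ...op-specific fields...}.
Response: {"ok": true, "result": ...} or {"ok": false, "error": "..."}.

Only chemistry primitives live here (parsing, canonicalisation, InChI,
substructure matching, reaction-SMIRKS application, descriptors, Morgan
fingerprints, PAINS catalog).  All pairing/enumeration/selection logic is
on the R side.
"""

import sys
import json
import traceback

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Crippen, Descriptors, rdMolDescriptors, inchi
from rdkit.Chem.MolStandardize import rdMolStandardize

RDLogger.DisableLog("rdApp.*")

_LFC = rdMolStandardize.LargestFragmentChooser(preferOrganic=True)
_UNCHARGER = rdMolStandardize.Uncharger()

_PAINS_CATALOG = None


def _pains_catalog():
    global _PAINS_CATALOG
    if _PAINS_CATALOG is None:
        from rdkit.Chem import FilterCatalog
        params = FilterCatalog.FilterCatalogParams()
        for fam in ("PAINS_A", "PAINS_B", "PAINS_C"):
            params.AddCatalog(
                getattr(FilterCatalog.FilterCatalogParams.FilterCatalogs, fam))
        _PAINS_CATALOG = FilterCatalog.FilterCatalog(params)
    return _PAINS_CATALOG


def _formula_counts(mol):
    """Element -> count including implicit hydrogens."""
    counts = {}
    for atom in mol.GetAtoms():
        sym = atom.GetSymbol()
        counts[sym] = counts.get(sym, 0) + 1
        nh = atom.GetTotalNumHs()
        if nh:
            counts["H"] = counts.get("H", 0) + nh
    return counts


def _standardize_mol(mol):
    mol = _LFC.choose(mol)
    mol = rdMolStandardize.Cleanup(mol)
    mol = _UNCHARGER.uncharge(mol)
    Chem.SanitizeMol(mol)
    return mol


def _mol_record(mol):
    return {
        "canonical_smiles": Chem.MolToSmiles(mol),
        "inchi": inchi.MolToInchi(mol),
        "formula": _formula_counts(mol),
        "n_fragments": len(Chem.GetMolFrags(mol)),
    }


def op_ping(req):
    import rdkit
    return {"rdkit": rdkit.__version__}


def op_standardize(req):
    out = []
    for smi in req["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append({"ok": False, "error": "unparseable SMILES: %s" % smi})
            continue
        try:
            mol = _standardize_mol(mol)
            rec = _mol_record(mol)
            rec["ok"] = True
            out.append(rec)
        except Exception as exc:  # sanitisation failures etc.
            out.append({"ok": False, "error": "%s: %s" % (smi, exc)})
    return out


def _unique_matches(mol, patt):
    """Substructure matches collapsed to unique atom sets, sorted."""
    seen = set()
    out = []
    for match in mol.GetSubstructMatches(patt, uniquify=True, maxMatches=512):
        key = tuple(sorted(match))
        if key not in seen:
            seen.add(key)
            out.append(sorted(match))
    out.sort()
    return out


def _compile_patterns(entries):
    compiled = []
    for ent in entries:
        patt = Chem.MolFromSmarts(ent["smarts"])
        if patt is None:
            raise ValueError("malformed SMARTS for '%s': %s"
                             % (ent["id"], ent["smarts"]))
        compiled.append((ent["id"], patt))
    return compiled


def op_scan(req):
    patterns = _compile_patterns(req["patterns"])
    out = []
    for smi in req["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append({"ok": False, "error": "unparseable SMILES: %s" % smi})
            continue
        hits = {}
        for pid, patt in patterns:
            matches = _unique_matches(mol, patt)
            if matches:
                hits[pid] = matches
        out.append({"ok": True, "hits": hits})
    return out


def op_match_counts(req):
    """Unique-atom-set match count per pattern per molecule."""
    patterns = _compile_patterns(req["patterns"])
    out = []
    for smi in req["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append({"ok": False, "error": "unparseable SMILES: %s" % smi})
            continue
        counts = {pid: len(_unique_matches(mol, patt)) for pid, patt in patterns}
        out.append({"ok": True, "counts": counts})
    return out


_RXN_CACHE = {}


def _reaction(smirks):
    rxn = _RXN_CACHE.get(smirks)
    if rxn is None:
        rxn = AllChem.ReactionFromSmarts(smirks)
        if rxn is None:
            raise ValueError("malformed SMIRKS: %s" % smirks)
        rxn.Initialize()
        _RXN_CACHE[smirks] = rxn
    return rxn


def op_validate_smirks(req):
    out = []
    for smirks in req["smirks"]:
        try:
            rxn = _reaction(smirks)
            out.append({"ok": True,
                        "n_reactants": rxn.GetNumReactantTemplates(),
                        "n_products": rxn.GetNumProductTemplates()})
        except Exception as exc:
            out.append({"ok": False, "error": str(exc)})
    return out


def op_react(req):
    """Apply rule SMIRKS to oriented reagent pairs.

    jobs: [{"a": smiles, "b": smiles, "smirks": ...}]; one product record per
    distinct (by InChI) sanitisable product, capped at max_products.
    """
    max_products = int(req.get("max_products", 8))
    mol_cache = {}

    def get_mol(smi):
        mol = mol_cache.get(smi)
        if mol is None:
            mol = Chem.MolFromSmiles(smi)
            mol_cache[smi] = mol
        return mol

    out = []
    for job in req["jobs"]:
        ma, mb = get_mol(job["a"]), get_mol(job["b"])
        if ma is None or mb is None:
            out.append({"ok": False, "error": "unparseable reagent"})
            continue
        try:
            rxn = _reaction(job["smirks"])
            raw = rxn.RunReactants((ma, mb))
        except Exception as exc:
            out.append({"ok": False, "error": str(exc)})
            continue
        products, seen, dropped = [], set(), 0
        for prod_tuple in raw:
            if len(products) >= max_products:
                break
            for prod in prod_tuple:
                try:
                    Chem.SanitizeMol(prod)
                    prod = _standardize_mol(prod)
                    rec = _mol_record(prod)
                except Exception:
                    dropped += 1
                    continue
                if rec["n_fragments"] != 1:
                    dropped += 1
                    continue
                if rec["inchi"] in seen:
                    continue
                seen.add(rec["inchi"])
                products.append(rec)
        out.append({"ok": True, "products": products, "dropped": dropped})
    return out


def op_profile(req):
    """19-descriptor physicochemical panel."""
    acidic = _compile_patterns(req["acidic_patterns"])
    basic = _compile_patterns(req["basic_patterns"])
    amide_patt = Chem.MolFromSmarts("[CX3;!R](=[OX1])[NX3;!R]")
    hba_mode = req.get("hba_mode", "acceptor")
    out = []
    for smi in req["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append({"ok": False, "error": "unparseable SMILES: %s" % smi})
            continue
        heavy = mol.GetNumHeavyAtoms()
        n_on = sum(1 for a in mol.GetAtoms() if a.GetSymbol() in ("N", "O"))
        n_het = sum(1 for a in mol.GetAtoms() if a.GetSymbol() not in ("C", "H"))
        n_acid = sum(len(_unique_matches(mol, p)) for _, p in acidic)
        n_base = sum(len(_unique_matches(mol, p)) for _, p in basic)
        if hba_mode == "lipinski":
            n_hba = rdMolDescriptors.CalcNumLipinskiHBA(mol)
        else:
            n_hba = rdMolDescriptors.CalcNumHBA(mol)
        chiral = Chem.FindMolChiralCenters(
            mol, includeUnassigned=True, useLegacyImplementation=False)
        out.append({
            "ok": True,
            "molar_mass": Descriptors.MolWt(mol),
            "logp": Crippen.MolLogP(mol),
            # extended Ertl TPSA (S and P contributions included)
            "psa": rdMolDescriptors.CalcTPSA(mol, includeSandP=True),
            "n_hba": n_hba,
            "n_hbd": rdMolDescriptors.CalcNumHBD(mol),
            "n_rotb": rdMolDescriptors.CalcNumRotatableBonds(mol),
            "hac": heavy,
            "n_rings": rdMolDescriptors.CalcNumRings(mol),
            "fsp3": rdMolDescriptors.CalcFractionCSP3(mol),
            "refractivity": Crippen.MolMR(mol),
            "n_aromatic_rings": rdMolDescriptors.CalcNumAromaticRings(mol),
            "n_aliphatic_rings": rdMolDescriptors.CalcNumAliphaticRings(mol),
            "n_chiral_centers": len(chiral),
            "n_acidic": n_acid,
            "n_basic": n_base,
            "n_acid_base": n_acid + n_base,
            "n_noncyclic_amide": len(_unique_matches(mol, amide_patt)),
            "n_o_plus_n": n_on,
            "heteroatom_ratio": (float(n_het) / heavy) if heavy else 0.0,
        })
    return out


def op_fingerprint(req):
    radius = int(req.get("radius", 2))
    n_bits = int(req.get("n_bits", 2048))
    gen = AllChem.GetMorganGenerator(radius=radius, fpSize=n_bits)
    out = []
    for smi in req["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append({"ok": False, "error": "unparseable SMILES: %s" % smi})
            continue
        fp = gen.GetFingerprint(mol)
        out.append({"ok": True, "on_bits": sorted(fp.GetOnBits())})
    return out


def op_pains(req):
    cat = _pains_catalog()
    out = []
    for smi in req["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append({"ok": False, "error": "unparseable SMILES: %s" % smi})
            continue
        names = [e.GetDescription() for e in cat.GetMatches(mol)]
        out.append({"ok": True, "matches": names})
    return out


def op_read_sdf(req):
    """Parse SDF text; return SMILES + named properties per record."""
    supplier = Chem.SDMolSupplier()
    supplier.SetData(req["text"], sanitize=True)
    out = []
    for mol in supplier:
        if mol is None:
            out.append({"ok": False, "error": "unparseable SDF record"})
            continue
        props = {k: mol.GetProp(k) for k in mol.GetPropNames()}
        name = mol.GetProp("_Name") if mol.HasProp("_Name") else ""
        out.append({"ok": True, "smiles": Chem.MolToSmiles(mol),
                    "name": name, "props": props})
    return out


def op_write_sdf(req):
    """Render molecules + properties as SDF text."""
    chunks = []
    for rec in req["records"]:
        mol = Chem.MolFromSmiles(rec["smiles"])
        if mol is None:
            return {"error": "unparseable SMILES: %s" % rec["smiles"]}
        mol.SetProp("_Name", str(rec.get("name", "")))
        block = Chem.MolToMolBlock(mol)
        props = rec.get("props", {})
        for key in props:
            block += ">  <%s>\n%s\n\n" % (key, props[key])
        chunks.append(block + "$$$$\n")
    return {"text": "".join(chunks)}


OPS = {
    "ping": op_ping,
    "read_sdf": op_read_sdf,
    "write_sdf": op_write_sdf,
    "standardize": op_standardize,
    "scan": op_scan,
    "match_counts": op_match_counts,
    "validate_smirks": op_validate_smirks,
    "react": op_react,
    "profile": op_profile,
    "fingerprint": op_fingerprint,
    "pains": op_pains,
}


def main():
    for line in sys.stdin:
        line = line.strip()
        if not line:
            continue
        try:
            req = json.loads(line)
            handler = OPS.get(req.get("op"))
            if handler is None:
                resp = {"ok": False, "error": "unknown op: %r" % req.get("op")}
            else:
                resp = {"ok": True, "result": handler(req)}
        except Exception:
            resp = {"ok": False, "error": traceback.format_exc(limit=5)}
        sys.stdout.write(json.dumps(resp) + "\n")
        sys.stdout.flush()


if __name__ == "__main__":
    main()
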