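"""Chemistry bridge for the bamanno R package.

Invoked as:  python chem_bridge.py <request.json> <response.json>

The request is a JSON object {"op": <name>, ...payload}; the response is
{"ok": true, "result": ...} or {"ok": false, "error": "..."}.  All operations
are batched so that one process launch serves a whole vector of molecules.

RDKit supplies parsing, canonicalization, InChI, MCS and molecular editing;
the reaction-center delimitation, atom-type coding, edit serialization and
site-matched edit application implemented here are the package's own.
"""

import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Descriptors, rdFMCS
from rdkit.Chem.rdMolDescriptors import CalcMolFormula

RDLogger.DisableLog("rdApp.*")

PROTON = 1.007276466
FP_RADIUS = 2
FP_NBITS = 2048

BOND_CHAR = {
    Chem.BondType.SINGLE: "s",
    Chem.BondType.DOUBLE: "d",
    Chem.BondType.TRIPLE: "t",
    Chem.BondType.AROMATIC: "a",
}
CHAR_BOND = {
    "s": Chem.BondType.SINGLE,
    "d": Chem.BondType.DOUBLE,
    "t": Chem.BondType.TRIPLE,
    "a": Chem.BondType.AROMATIC,
}
BOND_VALENCE = {"s": 1, "d": 2, "t": 3, "a": 1}


# ---------------------------------------------------------------- atom typing

def atom_code(mol, idx):
    """Atom-type code: element + environment class + sorted neighbor profile.

    Two atoms with identical element, aromaticity, ring membership and sorted
    neighbor-element-with-bond-order list receive identical codes (a compact
    stand-in for KEGG atom types; it only needs to be self-consistent between
    rule extraction and rule application).
    """
    a = mol.GetAtomWithIdx(idx)
    if a.GetIsAromatic():
        env = "a"
    elif a.IsInRing():
        env = "r"
    else:
        env = "c"
    nb = []
    for b in a.GetBonds():
        o = b.GetOtherAtom(a)
        nb.append(BOND_CHAR.get(b.GetBondType(), "?") + o.GetSymbol())
    return "%s%s[%s]" % (a.GetSymbol(), env, ",".join(sorted(nb)))


def atom_codes(mol):
    return [atom_code(mol, i) for i in range(mol.GetNumAtoms())]


# ---------------------------------------------------------------- basic ops

def parse_mol(smi):
    """Returns (mol, error_type, message). Distinguishes parse vs valence errors."""
    mol = Chem.MolFromSmiles(smi, sanitize=False)
    if mol is None:
        return None, "parse", "cannot parse SMILES: %r" % smi
    try:
        Chem.SanitizeMol(mol)
    except Exception as e:  # noqa: BLE001
        msg = str(e)
        kind = "valence" if "valence" in msg.lower() else "sanitize"
        return None, kind, "%s: %r" % (msg, smi)
    return mol, None, None


def mol_record(mol):
    csmi = Chem.MolToSmiles(mol)
    # re-parse so atom order equals canonical-SMILES order; every later op
    # that receives this SMILES sees the same 0-based heavy-atom indexing
    cmol = Chem.MolFromSmiles(csmi)
    fp = AllChem.GetMorganFingerprintAsBitVect(cmol, FP_RADIUS, nBits=FP_NBITS)
    return {
        "ok": True,
        "canonical_smiles": csmi,
        "inchikey": Chem.MolToInchiKey(cmol),
        "monoisotopic_mass": Descriptors.ExactMolWt(cmol),
        "formula": CalcMolFormula(cmol),
        "n_heavy": cmol.GetNumHeavyAtoms(),
        "fp_bits": sorted(fp.GetOnBits()),
        "atom_codes": atom_codes(cmol),
    }


def op_canonicalize(req):
    out = []
    for smi in req["smiles"]:
        mol, etype, msg = parse_mol(smi)
        if mol is None:
            out.append({"ok": False, "error_type": etype, "message": msg})
        else:
            out.append(mol_record(mol))
    return out


# ------------------------------------------------------------- fragmentation

def breakable_bonds(mol):
    for b in mol.GetBonds():
        if b.GetBondType() == Chem.BondType.SINGLE and not b.IsInRing():
            yield b


def op_fragment(req):
    """Pseudo-fragmentation: break each acyclic single bond, H-cap both pieces."""
    out = []
    for smi in req["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append({"ok": False, "message": "cannot parse %r" % smi})
            continue
        frags = {}
        for b in breakable_bonds(mol):
            em = Chem.RWMol(mol)
            em.RemoveBond(b.GetBeginAtomIdx(), b.GetEndAtomIdx())
            try:
                m2 = em.GetMol()
                Chem.SanitizeMol(m2)
            except Exception:  # noqa: BLE001
                continue
            for piece in Chem.GetMolFrags(m2, asMols=True):
                fsmi = Chem.MolToSmiles(piece)
                if fsmi not in frags:
                    frags[fsmi] = Descriptors.ExactMolWt(piece)
        out.append({
            "ok": True,
            "precursor_mass": Descriptors.ExactMolWt(mol),
            "fragments": [{"smiles": k, "mass": v}
                          for k, v in sorted(frags.items())],
        })
    return out


# ------------------------------------------------------------ rule extraction

def subtree_atoms(mol, root, blocked):
    """Atoms reachable from `root` without passing through atom `blocked`."""
    seen = {root}
    stack = [root]
    while stack:
        cur = stack.pop()
        for o in mol.GetAtomWithIdx(cur).GetNeighbors():
            j = o.GetIdx()
            if j != blocked and j not in seen:
                seen.add(j)
                stack.append(j)
    return seen


def capped_fragment(mol, cut_a, cut_b, keep_root, rooted=False):
    """Canonical SMILES of the H-capped piece containing keep_root after
    cutting bond (cut_a, cut_b).  Returns None for ring bonds (no split)."""
    if mol.GetBondBetweenAtoms(cut_a, cut_b).IsInRing():
        return None
    em = Chem.RWMol(mol)
    em.GetAtomWithIdx(keep_root).SetIntProp("_bam_root", 1)
    em.RemoveBond(cut_a, cut_b)
    try:
        m2 = em.GetMol()
        Chem.SanitizeMol(m2)
    except Exception:  # noqa: BLE001
        return None
    for piece in Chem.GetMolFrags(m2, asMols=True):
        ridx = None
        for a in piece.GetAtoms():
            if a.HasProp("_bam_root"):
                ridx = a.GetIdx()
        if ridx is None:
            continue
        if rooted:
            return Chem.MolToSmiles(piece, rootedAtAtom=ridx)
        return Chem.MolToSmiles(piece)
    return None


def changed_atoms(rmol, pmol, r2p):
    """Sets of changed atom indices on each side under mapping r2p."""
    p2r = {v: k for k, v in r2p.items()}
    r_changed = set(i for i in range(rmol.GetNumAtoms()) if i not in r2p)
    p_changed = set(j for j in range(pmol.GetNumAtoms()) if j not in p2r)
    for ra, pa in r2p.items():
        rA, pA = rmol.GetAtomWithIdx(ra), pmol.GetAtomWithIdx(pa)
        if rA.GetFormalCharge() != pA.GetFormalCharge():
            r_changed.add(ra)
        if rA.GetTotalNumHs() != pA.GetTotalNumHs():
            r_changed.add(ra)
        for b in rA.GetBonds():
            rb = b.GetOtherAtomIdx(ra)
            if rb not in r2p:
                r_changed.add(ra)
                continue
            pb = pmol.GetBondBetweenAtoms(pa, r2p[rb])
            if pb is None or pb.GetBondType() != b.GetBondType():
                r_changed.add(ra)
                r_changed.add(rb)
        for b in pA.GetBonds():
            pb = b.GetOtherAtomIdx(pa)
            if pb not in p2r:
                r_changed.add(ra)
            elif rmol.GetBondBetweenAtoms(ra, p2r[pb]) is None:
                r_changed.add(ra)
                r_changed.add(p2r[pb])
    return r_changed, p_changed


def best_mapping(rmol, pmol, mcs_query, max_matches=24):
    """MCS match pair minimizing the number of changed atoms (deterministic)."""
    rms = rmol.GetSubstructMatches(mcs_query, uniquify=False,
                                   maxMatches=max_matches)
    pms = pmol.GetSubstructMatches(mcs_query, uniquify=False,
                                   maxMatches=max_matches)
    best, best_n = None, None
    n_combo = 0
    for rm in rms:
        for pm in pms:
            n_combo += 1
            if n_combo > 96:
                break
            r2p = dict(zip(rm, pm))
            rc, pc = changed_atoms(rmol, pmol, r2p)
            n = len(rc) + len(pc)
            if best_n is None or n < best_n:
                best, best_n = r2p, n
        if n_combo > 96:
            break
    return best


def components(rmol, pmol, r2p, r_changed, p_changed_unmapped):
    """Connected components over changed atoms, joined through bonds on either
    side.  Nodes: ("r", i) for changed reactant atoms, ("p", j) for unmapped
    product atoms."""
    nodes = [("r", i) for i in sorted(r_changed)]
    nodes += [("p", j) for j in sorted(p_changed_unmapped)]
    nodeset = set(nodes)
    adj = {n: set() for n in nodes}

    def link(a, b):
        if a in nodeset and b in nodeset:
            adj[a].add(b)
            adj[b].add(a)

    for b in rmol.GetBonds():
        link(("r", b.GetBeginAtomIdx()), ("r", b.GetEndAtomIdx()))
    p2r = {v: k for k, v in r2p.items()}

    def pnode(j):
        if j in p2r:
            return ("r", p2r[j])
        return ("p", j)

    for b in pmol.GetBonds():
        link(pnode(b.GetBeginAtomIdx()), pnode(b.GetEndAtomIdx()))
    comps, seen = [], set()
    for n in nodes:
        if n in seen:
            continue
        comp, stack = set(), [n]
        seen.add(n)
        while stack:
            cur = stack.pop()
            comp.add(cur)
            for o in adj[cur]:
                if o not in seen:
                    seen.add(o)
                    stack.append(o)
        comps.append(comp)
    return comps


def build_rule_for_component(rmol, pmol, r2p, comp):
    """One rule per connected reaction center; returns (rule, reason)."""
    p2r = {v: k for k, v in r2p.items()}
    rside = sorted(i for (s, i) in comp if s == "r")
    pside = sorted(j for (s, j) in comp if s == "p")
    mapped = [i for i in rside if i in r2p]
    if not mapped:
        return None, "no persistent atom in reaction center"
    ranks = list(Chem.CanonicalRankAtoms(rmol, breakTies=True))
    center = min(mapped,
                 key=lambda i: (-rmol.GetAtomWithIdx(i).GetDegree(), ranks[i]))
    cp = r2p[center]
    ops = []
    covered_r = {center}
    covered_p = set()

    for nb in rmol.GetAtomWithIdx(center).GetNeighbors():
        n = nb.GetIdx()
        bond = rmol.GetBondBetweenAtoms(center, n)
        if n not in r2p:
            if bond.IsInRing():
                return None, "removed piece attached through a ring bond"
            sub = subtree_atoms(rmol, n, center)
            if any(x in r2p for x in sub):
                return None, "removed subtree contains persistent atoms"
            frag = capped_fragment(rmol, center, n, n)
            if frag is None:
                return None, "cannot cap removed subtree"
            ops.append({"kind": "remove", "ncode": atom_code(rmol, n),
                        "frag": frag})
            covered_r |= sub
        elif ("r", n) in comp:
            pb = pmol.GetBondBetweenAtoms(cp, r2p[n])
            if pb is None:
                return None, "bond removed between persistent atoms"
            oldc = BOND_CHAR.get(bond.GetBondType(), "?")
            newc = BOND_CHAR.get(pb.GetBondType(), "?")
            if oldc != newc:
                ops.append({"kind": "bond", "ncode": atom_code(rmol, n),
                            "old": oldc, "new": newc})
            # the neighbor may change only in its bond to the center (+ H)
            nA, nP = rmol.GetAtomWithIdx(n), pmol.GetAtomWithIdx(r2p[n])
            if nA.GetFormalCharge() != nP.GetFormalCharge():
                return None, "charge change away from center"
            for ob in nA.GetBonds():
                m = ob.GetOtherAtomIdx(n)
                if m == center:
                    continue
                if m not in r2p:
                    return None, "non-center atom loses a neighbor"
                qb = pmol.GetBondBetweenAtoms(r2p[n], r2p[m])
                if qb is None or qb.GetBondType() != ob.GetBondType():
                    return None, "bond change away from center"
            for ob in nP.GetBonds():
                m = ob.GetOtherAtomIdx(r2p[n])
                if m != cp and m not in p2r:
                    return None, "non-center atom gains a neighbor"
            covered_r.add(n)

    for nb in pmol.GetAtomWithIdx(cp).GetNeighbors():
        q = nb.GetIdx()
        bond = pmol.GetBondBetweenAtoms(cp, q)
        if q not in p2r:
            if bond.IsInRing():
                return None, "added piece attached through a ring bond"
            sub = subtree_atoms(pmol, q, cp)
            if any(x in p2r for x in sub):
                return None, "added subtree contains persistent atoms"
            frag = capped_fragment(pmol, cp, q, q, rooted=True)
            if frag is None:
                return None, "cannot cap added subtree"
            ops.append({"kind": "add", "frag": frag, "attach": 0,
                        "order": BOND_CHAR.get(bond.GetBondType(), "?")})
            covered_p |= sub
        elif rmol.GetBondBetweenAtoms(center, p2r[q]) is None:
            return None, "bond formed between persistent atoms"

    if set(rside) - covered_r:
        return None, "changes not local to the reaction center"
    if set(pside) - covered_p:
        return None, "added atoms not attached to the reaction center"
    if not ops:
        return None, "empty edit"
    ops.sort(key=lambda o: json.dumps(o, sort_keys=True))
    ncodes = sorted(atom_code(rmol, nb.GetIdx())
                    for nb in rmol.GetAtomWithIdx(center).GetNeighbors())
    rule = {
        "center_code": atom_code(rmol, center),
        "neighbor_codes": ncodes,
        "ops": ops,
        "center_atom": center,
    }
    return rule, None


def extract_pair(r_smi, p_smi, min_mcs_frac, timeout):
    rmol = Chem.MolFromSmiles(r_smi)
    pmol = Chem.MolFromSmiles(p_smi)
    if rmol is None or pmol is None:
        return [], "unparseable structure"
    mcs = rdFMCS.FindMCS([rmol, pmol], ringMatchesRingOnly=True,
                         timeout=int(timeout))
    nmin = min(rmol.GetNumHeavyAtoms(), pmol.GetNumHeavyAtoms())
    if mcs.numAtoms < min_mcs_frac * nmin:
        return [], "MCS covers %d/%d atoms (< %.2f of smaller molecule)" % (
            mcs.numAtoms, nmin, min_mcs_frac)
    q = Chem.MolFromSmarts(mcs.smartsString)
    r2p = best_mapping(rmol, pmol, q)
    if r2p is None:
        return [], "no MCS embedding found"
    r_changed, p_changed = changed_atoms(rmol, pmol, r2p)
    p2r = {v: k for k, v in r2p.items()}
    p_unmapped = set(j for j in p_changed if j not in p2r)
    if not r_changed and not p_unmapped:
        return [], "identical under mapping"
    rules, reasons = [], []
    for comp in components(rmol, pmol, r2p, r_changed, p_unmapped):
        rule, reason = build_rule_for_component(rmol, pmol, r2p, comp)
        if rule is None:
            reasons.append(reason)
            continue
        # realized mass delta: apply the rule to its own reactant at the
        # center it was extracted from
        prods = apply_at_site(rmol, rule, rule["center_atom"])
        if not prods:
            reasons.append("rule does not re-apply to its own reactant")
            continue
        rule["mass_delta"] = prods[0]["mass"] - Descriptors.ExactMolWt(rmol)
        rules.append(rule)
    if not rules:
        return [], "; ".join(reasons) if reasons else "no usable center"
    return rules, None


def op_extract_rules(req):
    min_frac = req.get("min_mcs_frac", 0.5)
    timeout = req.get("timeout", 10)
    out = []
    for task in req["pairs"]:
        rules, reason = extract_pair(task["reactant"], task["product"],
                                     min_frac, timeout)
        out.append({"ok": True, "rules": rules, "skipped_reason": reason})
    return out


# ----------------------------------------------------------- rule application

def neighbor_candidates(mol, site, ncode, frag=None, old=None, used=()):
    """Neighbors of `site` matching an op's code / severed-subtree / bond-order
    requirements, in ascending index order."""
    res = []
    for nb in mol.GetAtomWithIdx(site).GetNeighbors():
        n = nb.GetIdx()
        if n in used:
            continue
        if atom_code(mol, n) != ncode:
            continue
        bond = mol.GetBondBetweenAtoms(site, n)
        if old is not None and BOND_CHAR.get(bond.GetBondType()) != old:
            continue
        if frag is not None:
            if bond.IsInRing():
                continue
            if capped_fragment(mol, site, n, n) != frag:
                continue
        res.append(n)
    return res


def apply_at_site(mol, rule, site):
    """Apply the rule's edit at `site`; returns a list of product records
    (one per resolution of neighbor ambiguity), possibly empty."""
    removes = [o for o in rule["ops"] if o["kind"] == "remove"]
    bonds = [o for o in rule["ops"] if o["kind"] == "bond"]
    adds = [o for o in rule["ops"] if o["kind"] == "add"]

    # removals: identical severed subtrees give isomorphic products, so a
    # deterministic greedy assignment suffices
    used = set()
    remove_roots = []
    for o in removes:
        cands = [n for n in neighbor_candidates(mol, site, o["ncode"],
                                                frag=o["frag"]) if n not in used]
        if not cands:
            return []
        used.add(cands[0])
        remove_roots.append(cands[0])

    # bond-order changes: same-code neighbors may differ beyond radius 1, so
    # enumerate assignments (capped; almost always a single choice)
    assignments = [[]]
    for o in bonds:
        cands = neighbor_candidates(mol, site, o["ncode"], old=o["old"])
        new_assign = []
        for partial in assignments:
            for n in cands:
                if n not in partial and n not in used:
                    new_assign.append(partial + [n])
        assignments = new_assign[:8]
        if not assignments:
            return []

    products = {}
    for assign in assignments:
        em = Chem.RWMol(mol)
        # additions first (indices of existing atoms stay valid)
        for o in adds:
            fragmol = Chem.MolFromSmiles(o["frag"])
            if fragmol is None:
                return []
            offset = em.GetNumAtoms()
            em.InsertMol(fragmol)
            order = CHAR_BOND[o["order"]]
            a = em.GetAtomWithIdx(site)
            val = BOND_VALENCE[o["order"]]
            if a.GetNumExplicitHs() > 0:
                a.SetNumExplicitHs(max(0, a.GetNumExplicitHs() - val))
            em.AddBond(site, offset + o["attach"], order)
        for o, n in zip(bonds, assign):
            b = em.GetBondBetweenAtoms(site, n)
            b.SetBondType(CHAR_BOND[o["new"]])
            dval = BOND_VALENCE[o["new"]] - BOND_VALENCE[o["old"]]
            if dval > 0:
                for idx in (site, n):
                    a = em.GetAtomWithIdx(idx)
                    if a.GetNumExplicitHs() > 0:
                        a.SetNumExplicitHs(max(0, a.GetNumExplicitHs() - dval))
        doomed = set()
        for root in remove_roots:
            doomed |= subtree_atoms(mol, root, site)
        for idx in sorted(doomed, reverse=True):
            em.RemoveAtom(idx)
        try:
            prod = em.GetMol()
            Chem.SanitizeMol(prod)
        except Exception:  # noqa: BLE001
            continue
        smi = Chem.MolToSmiles(prod)
        if smi and smi not in products:
            products[smi] = {
                "smiles": smi,
                "inchikey": Chem.MolToInchiKey(prod),
                "mass": Descriptors.ExactMolWt(prod),
            }
    return [products[k] for k in sorted(products)]


def op_apply_rules(req):
    max_sites = req.get("max_sites", 64)
    out = []
    for task in req["tasks"]:
        mol = Chem.MolFromSmiles(task["anchor"])
        if mol is None:
            out.append({"ok": False, "message": "cannot parse anchor"})
            continue
        codes = atom_codes(mol)
        hits = []
        capped = False
        for rule in task["rules"]:
            want = sorted(rule["neighbor_codes"])
            sites = []
            for i in range(mol.GetNumAtoms()):
                if codes[i] != rule["center_code"]:
                    continue
                have = sorted(codes[nb.GetIdx()]
                              for nb in mol.GetAtomWithIdx(i).GetNeighbors())
                if have == want:
                    sites.append(i)
            if len(sites) > max_sites:
                sites = sites[:max_sites]
                capped = True
            for site in sites:
                for prod in apply_at_site(mol, rule, site):
                    hits.append({"rule_id": rule["id"], "site_atom": site,
                                 "smiles": prod["smiles"],
                                 "inchikey": prod["inchikey"],
                                 "mass": prod["mass"]})
        out.append({"ok": True, "candidates": hits, "site_cap_hit": capped})
    return out


# ----------------------------------------------------- fixture transformation

def _family_sites(mol, family):
    """Legal sites (atom indices) for a built-in biotransformation family."""
    sites = []
    for a in mol.GetAtoms():
        i = a.GetIdx()
        if family == "hydroxylation":
            if a.GetSymbol() == "C" and a.GetTotalNumHs() >= 1:
                sites.append(i)
        elif family == "methylation":
            if a.GetSymbol() in ("C", "N", "O") and a.GetTotalNumHs() >= 1:
                sites.append(i)
        elif family == "dehydrogenation":
            if a.GetSymbol() == "C" and not a.GetIsAromatic() \
                    and a.GetTotalNumHs() >= 1:
                for nb in a.GetNeighbors():
                    b = mol.GetBondBetweenAtoms(i, nb.GetIdx())
                    if nb.GetSymbol() == "O" and nb.GetDegree() == 1 \
                            and nb.GetTotalNumHs() >= 1 \
                            and b.GetBondType() == Chem.BondType.SINGLE:
                        sites.append(i)
                        break
        elif family == "demethylation":
            for nb in a.GetNeighbors():
                if nb.GetSymbol() == "C" and nb.GetDegree() == 1 \
                        and nb.GetTotalNumHs() == 3 \
                        and not mol.GetBondBetweenAtoms(
                            i, nb.GetIdx()).IsInRing():
                    sites.append(i)
                    break
        elif family == "acetylation":
            if a.GetSymbol() == "O" and a.GetTotalNumHs() >= 1:
                sites.append(i)
        else:
            raise ValueError("unknown family: %r" % family)
    return sites


FAMILY_RULE = {
    "hydroxylation": [{"kind": "add", "frag": "O", "attach": 0, "order": "s"}],
    "methylation": [{"kind": "add", "frag": "C", "attach": 0, "order": "s"}],
    "acetylation": [{"kind": "add", "frag": "C(C)=O", "attach": 0,
                     "order": "s"}],
}


def _family_product(mol, family, site):
    if family in FAMILY_RULE:
        rule = {"ops": FAMILY_RULE[family]}
        prods = apply_at_site(mol, rule, site)
        return prods[0]["smiles"] if prods else None
    if family == "dehydrogenation":
        a = mol.GetAtomWithIdx(site)
        for nb in a.GetNeighbors():
            b = mol.GetBondBetweenAtoms(site, nb.GetIdx())
            if nb.GetSymbol() == "O" and nb.GetDegree() == 1 \
                    and nb.GetTotalNumHs() >= 1 \
                    and b.GetBondType() == Chem.BondType.SINGLE:
                rule = {"ops": [{"kind": "bond", "ncode": atom_code(mol, nb.GetIdx()),
                                 "old": "s", "new": "d"}]}
                prods = apply_at_site(mol, rule, site)
                return prods[0]["smiles"] if prods else None
        return None
    if family == "demethylation":
        a = mol.GetAtomWithIdx(site)
        for nb in a.GetNeighbors():
            if nb.GetSymbol() == "C" and nb.GetDegree() == 1 \
                    and nb.GetTotalNumHs() == 3 \
                    and not mol.GetBondBetweenAtoms(site, nb.GetIdx()).IsInRing():
                rule = {"ops": [{"kind": "remove",
                                 "ncode": atom_code(mol, nb.GetIdx()),
                                 "frag": "C"}]}
                prods = apply_at_site(mol, rule, site)
                return prods[0]["smiles"] if prods else None
        return None
    raise ValueError("unknown family: %r" % family)


def op_family_products(req):
    """All legal (site, product) applications of each family to each scaffold."""
    out = []
    for task in req["tasks"]:
        mol = Chem.MolFromSmiles(task["scaffold"])
        if mol is None:
            out.append({"ok": False, "message": "cannot parse scaffold"})
            continue
        res = []
        for site in _family_sites(mol, task["family"]):
            smi = _family_product(mol, task["family"], site)
            if smi is not None:
                res.append({"site": site, "product": smi})
        out.append({"ok": True, "sites": res})
    return out


# -------------------------------------------------------------------- driver

OPS = {
    "ping": lambda req: {"pong": True},
    "canonicalize": op_canonicalize,
    "fragment": op_fragment,
    "extract_rules": op_extract_rules,
    "apply_rules": op_apply_rules,
    "family_products": op_family_products,
}


def main():
    req_path, resp_path = sys.argv[1], sys.argv[2]
    with open(req_path) as fh:
        req = json.load(fh)
    try:
        fn = OPS[req["op"]]
        resp = {"ok": True, "result": fn(req)}
    except Exception as e:  # noqa: BLE001
        import traceback
        resp = {"ok": False,
                "error": "%s: %s" % (type(e).__name__, e),
                "traceback": traceback.format_exc()}
    with open(resp_path, "w") as fh:
        json.dump(resp, fh)


if __name__ == "__main__":
    main()
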