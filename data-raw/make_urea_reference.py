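"""Generate the packaged urea HF/6-31+G* reference single-point data.

Steps: RDKit MMFF94 starting structure -> L-BFGS geometry optimization on
the RHF/6-31+G* surface (numerical gradients) -> final single point ->
plain-text fixture files under inst/extdata/urea_hf/.
"""

import json
import sys
import time

import numpy as np
from scipy.optimize import minimize

from minihf import Molecule, rhf, mulliken_per_mo, ANG2BOHR

EV = 27.211386

SYMS = ["C", "O", "N", "N", "H", "H", "H", "H"]


def mmff_start():
    from rdkit import Chem
    from rdkit.Chem import AllChem
    mol = Chem.AddHs(Chem.MolFromSmiles("NC(=O)N"))
    AllChem.EmbedMolecule(mol, randomSeed=11)
    AllChem.MMFFOptimizeMolecule(mol)
    conf = mol.GetConformer()
    syms = [a.GetSymbol() for a in mol.GetAtoms()]
    xyz = np.array([[conf.GetAtomPosition(i).x, conf.GetAtomPosition(i).y,
                     conf.GetAtomPosition(i).z] for i in range(mol.GetNumAtoms())])
    # reorder to C, O, N, N, H...
    order = ([i for i, s in enumerate(syms) if s == "C"]
             + [i for i, s in enumerate(syms) if s == "O"]
             + [i for i, s in enumerate(syms) if s == "N"]
             + [i for i, s in enumerate(syms) if s == "H"])
    return xyz[order]


_neval = [0]


def energy(flat, basis="6-31+G*"):
    xyz = flat.reshape(-1, 3)
    mol = Molecule(SYMS, xyz, basis=basis)
    res = rhf(mol, conv=1e-8)
    if not res["converged"]:
        print("WARN: SCF not converged at eval", _neval[0], flush=True)
    _neval[0] += 1
    return res["E"]


def main():
    t0 = time.time()
    x0 = mmff_start()
    print("MMFF start geometry:\n", np.round(x0, 4), flush=True)
    print("E(start) =", energy(x0.ravel()), f"[{time.time()-t0:.1f}s]", flush=True)

    x = x0.ravel()
    for basis, mi in [("6-31G", 50), ("6-31G*", 25), ("6-31+G*", 12)]:
        opt = minimize(energy, x, args=(basis,), method="L-BFGS-B",
                       options=dict(eps=2e-3, maxiter=mi, ftol=1e-10, gtol=2e-4))
        x = opt.x
        print(f"stage {basis}: {opt.message} E = {opt.fun:.8f} "
              f"nfev = {opt.nfev} [{(time.time()-t0)/60:.1f} min]", flush=True)
    xyz = x.reshape(-1, 3)
    xyz -= xyz.mean(axis=0)

    mol = Molecule(SYMS, xyz, basis="6-31+G*")
    res = rhf(mol, conv=1e-9)
    nocc = res["nocc"]
    eps = res["eps"]
    C = res["C"]
    S = res["S"]
    D3 = res["D3"]
    ao_atom = mol.shmeta["ao_atom"]

    pops = mulliken_per_mo(res, ao_atom, len(SYMS))
    print("\noccupied orbital energies (hartree):", np.round(eps[:nocc], 5))
    print("binding energies HOMO..HOMO-2 (eV):",
          [round(-eps[nocc - 1 - k] * EV, 3) for k in range(3)])
    for i in range(4):
        a = int(np.argmax(pops[i]))
        print(f"core MO {i}: eps={eps[i]:.4f} -> atom {a} ({SYMS[a]}), "
              f"pop {pops[i, a]:.3f}, BE {-eps[i]*EV:.1f} eV")

    # MO-basis dipole blocks: <core | r | occ> for all occupied pairs
    dip_mo = np.einsum("kpq,pi,qj->kij", D3, C[:, :nocc], C[:, :nocc])

    import os
    out = os.path.join(os.path.dirname(__file__), "..", "inst", "extdata", "urea_hf")
    os.makedirs(out, exist_ok=True)

    with open(os.path.join(out, "header.json"), "w") as f:
        json.dump(dict(
            engine="minihf (restricted Hartree-Fock, McMurchie-Davidson integrals)",
            basis="6-31+G*", charge=0, multiplicity=1,
            symbols=SYMS,
            coords_angstrom=[[round(v, 8) for v in row] for row in xyz],
            e_hf_hartree=res["E"],
            eps_occ_hartree=list(eps[:nocc]),
            n_occ=int(nocc), n_basis=int(C.shape[0]),
            ao_atom=[int(a) + 1 for a in ao_atom],
            core_dipoles_note="core_dipoles.txt rows: (core MO, occ MO) pairs "
                              "in row-major order, columns x y z (a.u.)",
        ), f, indent=1)

    np.savetxt(os.path.join(out, "mo_occ_coeff.txt"), C[:, :nocc], fmt="%.8e",
               header="MO coefficients, rows = AO (n_basis), cols = occupied MO")
    iu = np.triu_indices(S.shape[0])
    np.savetxt(os.path.join(out, "overlap_utri.txt"), S[iu][None, :].T,
               fmt="%.8e", header="AO overlap, upper triangle row-major")
    rows = dip_mo[:, :4, :].transpose(1, 2, 0).reshape(-1, 3)
    np.savetxt(os.path.join(out, "core_dipoles.txt"), rows, fmt="%.8e",
               header="<core MO | r | occupied MO>, 4 cores x n_occ rows, x y z")
    print("fixture written to", out, f"[{(time.time()-t0)/60:.1f} min total]")


if __name__ == "__main__":
    main()
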