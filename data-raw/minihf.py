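"""Minimal restricted Hartree-Fock engine used to generate the packaged
reference single-point data (data-raw only; not part of the R package).

McMurchie-Davidson integrals over contracted Cartesian Gaussians (s, p, d),
numba-accelerated, with DIIS-converged RHF.  Validated by the oracles in
validate_minihf.py (numerical quadrature, center-derivative relations,
rotation/translation invariance, textbook H2/STO-3G energies).
"""

import numpy as np
from numba import njit

ANG2BOHR = 1.0 / 0.52917721
CHARGES = {"H": 1, "C": 6, "N": 7, "O": 8}

# ----------------------------------------------------------------------
# Basis set data: standard published 6-31G tables, plus diffuse sp (+)
# and single-primitive d polarization (*) exponents for heavy atoms.
# sp shells are stored as separate s and p shells sharing exponents.
# ----------------------------------------------------------------------

BASIS_631G = {
    "H": [
        ("s", [18.7311370, 2.8253937, 0.6401217],
              [0.03349460, 0.23472695, 0.81375733]),
        ("s", [0.1612778], [1.0]),
    ],
    "C": [
        ("s", [3047.5249, 457.36951, 103.94869, 29.210155, 9.2866630, 3.1639270],
              [0.0018347, 0.0140373, 0.0688426, 0.2321844, 0.4679413, 0.3623120]),
        ("s", [7.8682724, 1.8812885, 0.5442493],
              [-0.1193324, -0.1608542, 1.1434564]),
        ("p", [7.8682724, 1.8812885, 0.5442493],
              [0.0689991, 0.3164240, 0.7443083]),
        ("s", [0.1687144], [1.0]),
        ("p", [0.1687144], [1.0]),
    ],
    "N": [
        ("s", [4173.5110, 627.45790, 142.90210, 40.234330, 12.820210, 4.3904370],
              [0.00183477, 0.01399463, 0.06858655, 0.23224087, 0.46906995, 0.36045520]),
        ("s", [11.626358, 2.7162800, 0.7722180],
              [-0.1149612, -0.1691180, 1.1458520]),
        ("p", [11.626358, 2.7162800, 0.7722180],
              [0.0675797, 0.3239073, 0.7408951]),
        ("s", [0.2120313], [1.0]),
        ("p", [0.2120313], [1.0]),
    ],
    "O": [
        ("s", [5484.6717, 825.23495, 188.04696, 52.964500, 16.897570, 5.7996353],
              [0.0018311, 0.0139501, 0.0684451, 0.2327143, 0.4701930, 0.3585209]),
        ("s", [15.539616, 3.5999336, 1.0137618],
              [-0.1107775, -0.1480263, 1.1307670]),
        ("p", [15.539616, 3.5999336, 1.0137618],
              [0.0708743, 0.3397528, 0.7271586]),
        ("s", [0.2700058], [1.0]),
        ("p", [0.2700058], [1.0]),
    ],
}

DIFFUSE_SP = {"C": 0.0438, "N": 0.0639, "O": 0.0845}
POLAR_D = {"C": 0.8, "N": 0.8, "O": 0.8}

STO3G = {
    "H": [("s", [3.42525091, 0.62391373, 0.16885540],
                [0.15432897, 0.53532814, 0.44463454])],
}


def build_shells(symbols, coords_bohr, basis="6-31+G*"):
    """Return flat shell arrays for the integral driver.

    coords_bohr: (N,3) array.  Returns dict of arrays plus AO metadata.
    """
    shells = []
    for ia, sym in enumerate(symbols):
        if basis == "STO-3G":
            entries = list(STO3G[sym])
        else:
            entries = list(BASIS_631G[sym])
            if sym != "H" and basis in ("6-31+G*", "6-31+G"):
                a = DIFFUSE_SP[sym]
                entries += [("s", [a], [1.0]), ("p", [a], [1.0])]
            if sym != "H" and basis in ("6-31G*", "6-31+G*"):
                entries += [("d", [POLAR_D[sym]], [1.0])]
        for (ltype, exps, coefs) in entries:
            L = {"s": 0, "p": 1, "d": 2}[ltype]
            shells.append((ia, L, np.array(exps), np.array(coefs)))

    n_sh = len(shells)
    sh_L = np.zeros(n_sh, dtype=np.int64)
    sh_atom = np.zeros(n_sh, dtype=np.int64)
    sh_cen = np.zeros((n_sh, 3))
    sh_ps = np.zeros(n_sh, dtype=np.int64)
    sh_np = np.zeros(n_sh, dtype=np.int64)
    pexp, pcoef = [], []
    for i, (ia, L, exps, coefs) in enumerate(shells):
        sh_L[i] = L
        sh_atom[i] = ia
        sh_cen[i] = coords_bohr[ia]
        sh_ps[i] = len(pexp)
        sh_np[i] = len(exps)
        for a, c in zip(exps, coefs):
            pexp.append(a)
            # common primitive norm of the (L,0,0) component
            pcoef.append(c * (2.0 * a / np.pi) ** 0.75 * (4.0 * a) ** (L / 2.0))
    ao_atom, ao_shell = [], []
    for i in range(n_sh):
        ncart = (sh_L[i] + 1) * (sh_L[i] + 2) // 2
        ao_atom += [sh_atom[i]] * ncart
        ao_shell += [i] * ncart
    return dict(sh_L=sh_L, sh_atom=sh_atom, sh_cen=sh_cen, sh_ps=sh_ps,
                sh_np=sh_np, pexp=np.array(pexp), pcoef=np.array(pcoef),
                ao_atom=np.array(ao_atom), ao_shell=np.array(ao_shell),
                nbf=len(ao_atom))


CART = {
    0: [(0, 0, 0)],
    1: [(1, 0, 0), (0, 1, 0), (0, 0, 1)],
    2: [(2, 0, 0), (1, 1, 0), (1, 0, 1), (0, 2, 0), (0, 1, 1), (0, 0, 2)],
}
CART_FLAT = np.array([c for L in range(3) for c in CART[L]], dtype=np.int64)
CART_OFF = np.array([0, 1, 4], dtype=np.int64)  # offsets into CART_FLAT per L


@njit(cache=True)
def _boys(mmax, T, out):
    if T < 1e-13:
        for m in range(mmax + 1):
            out[m] = 1.0 / (2.0 * m + 1.0)
        return
    if T > 35.0:
        out[0] = 0.5 * np.sqrt(np.pi / T)
        eT = np.exp(-T)
        for m in range(mmax):
            out[m + 1] = ((2 * m + 1) * out[m] - eT) / (2.0 * T)
        return
    # series for F_mmax, then downward recursion
    eT = np.exp(-T)
    s = 0.0
    term = 1.0 / (2.0 * mmax + 1.0)
    k = 0
    while True:
        s += term
        k += 1
        term *= 2.0 * T / (2.0 * mmax + 2.0 * k + 1.0)
        if term < 1e-17 * s or k > 300:
            break
    out[mmax] = s * eT
    for m in range(mmax, 0, -1):
        out[m - 1] = (2.0 * T * out[m] + eT) / (2.0 * m - 1.0)


@njit(cache=True)
def _ecoef(la, lb, a, b, AB, E):
    """Hermite expansion coefficients E[i,j,t] for one dimension."""
    p = a + b
    mu = a * b / p
    E[:, :, :] = 0.0
    E[0, 0, 0] = np.exp(-mu * AB * AB)
    # build up in i then j; P - A = -b/p * AB ; P - B = a/p * AB
    XPA = -b / p * AB
    XPB = a / p * AB
    for i in range(la):
        for t in range(i + 2):
            v = XPA * E[i, 0, t]
            if t > 0:
                v += E[i, 0, t - 1] / (2.0 * p) * 1.0
            if t + 1 <= i:
                v += (t + 1) * E[i, 0, t + 1]
            E[i + 1, 0, t] = v
    for i in range(la + 1):
        for j in range(lb):
            for t in range(i + j + 2):
                v = XPB * E[i, j, t]
                if t > 0:
                    v += E[i, j, t - 1] / (2.0 * p)
                if t + 1 <= i + j:
                    v += (t + 1) * E[i, j, t + 1]
                E[i, j + 1, t] = v


@njit(cache=True)
def _rtensor(ltot, p, PC, R):
    """Hermite Coulomb integrals R[t,u,v] at total order ltot."""
    T = p * (PC[0] * PC[0] + PC[1] * PC[1] + PC[2] * PC[2])
    F = np.zeros(ltot + 1)
    _boys(ltot, T, F)
    mdim = ltot + 1
    Rm = np.zeros((mdim, mdim, mdim, mdim))
    for m in range(ltot + 1):
        Rm[m, 0, 0, 0] = (-2.0 * p) ** m * F[m]
    for total in range(1, ltot + 1):
        for t in range(total + 1):
            for u in range(total - t + 1):
                v = total - t - u
                for m in range(ltot - total, -1, -1):
                    if t > 0:
                        val = PC[0] * Rm[m + 1, t - 1, u, v]
                        if t > 1:
                            val += (t - 1) * Rm[m + 1, t - 2, u, v]
                    elif u > 0:
                        val = PC[1] * Rm[m + 1, t, u - 1, v]
                        if u > 1:
                            val += (u - 1) * Rm[m + 1, t, u - 2, v]
                    else:
                        val = PC[2] * Rm[m + 1, t, u, v - 1]
                        if v > 1:
                            val += (v - 1) * Rm[m + 1, t, u, v - 2]
                    Rm[m, t, u, v] = val
    for t in range(ltot + 1):
        for u in range(ltot + 1 - t):
            for v in range(ltot + 1 - t - u):
                R[t, u, v] = Rm[0, t, u, v]


@njit(cache=True)
def _one_electron(sh_L, sh_cen, sh_ps, sh_np, pexp, pcoef, charges, atpos,
                  cart_flat, cart_off):
    """Raw (unnormalized-AO) S, T, V and dipole matrices."""
    n_sh = sh_L.shape[0]
    ao_of = np.zeros(n_sh + 1, dtype=np.int64)
    for i in range(n_sh):
        ao_of[i + 1] = ao_of[i] + (sh_L[i] + 1) * (sh_L[i] + 2) // 2
    nbf = ao_of[n_sh]
    S = np.zeros((nbf, nbf))
    T = np.zeros((nbf, nbf))
    V = np.zeros((nbf, nbf))
    D3 = np.zeros((3, nbf, nbf))
    Ex = np.zeros((5, 5, 9))
    Ey = np.zeros((5, 5, 9))
    Ez = np.zeros((5, 5, 9))
    Rt = np.zeros((9, 9, 9))
    for I in range(n_sh):
        lA = sh_L[I]
        A = sh_cen[I]
        for J in range(I + 1):
            lB = sh_L[J]
            B = sh_cen[J]
            ltot = lA + lB + 2
            nA = (lA + 1) * (lA + 2) // 2
            nB = (lB + 1) * (lB + 2) // 2
            Sblk = np.zeros((nA, nB))
            Tblk = np.zeros((nA, nB))
            Vblk = np.zeros((nA, nB))
            Dblk = np.zeros((3, nA, nB))
            for ip in range(sh_np[I]):
                a = pexp[sh_ps[I] + ip]
                ca = pcoef[sh_ps[I] + ip]
                for jp in range(sh_np[J]):
                    b = pexp[sh_ps[J] + jp]
                    cb = pcoef[sh_ps[J] + jp]
                    p = a + b
                    cc = ca * cb
                    P = (a * A + b * B) / p
                    _ecoef(lA + 2, lB + 2, a, b, A[0] - B[0], Ex)
                    _ecoef(lA + 2, lB + 2, a, b, A[1] - B[1], Ey)
                    _ecoef(lA + 2, lB + 2, a, b, A[2] - B[2], Ez)
                    pref = (np.pi / p) ** 1.5
                    for ca_i in range(nA):
                        ix = cart_flat[cart_off[lA] + ca_i, 0]
                        iy = cart_flat[cart_off[lA] + ca_i, 1]
                        iz = cart_flat[cart_off[lA] + ca_i, 2]
                        for cb_j in range(nB):
                            jx = cart_flat[cart_off[lB] + cb_j, 0]
                            jy = cart_flat[cart_off[lB] + cb_j, 1]
                            jz = cart_flat[cart_off[lB] + cb_j, 2]
                            sx = Ex[ix, jx, 0]
                            sy = Ey[iy, jy, 0]
                            sz = Ez[iz, jz, 0]
                            Sblk[ca_i, cb_j] += cc * pref * sx * sy * sz
                            # kinetic: per-dimension T then product rule
                            tx = b * (2 * jx + 1) * Ex[ix, jx, 0] - 2.0 * b * b * Ex[ix, jx + 2, 0]
                            if jx > 1:
                                tx -= 0.5 * jx * (jx - 1) * Ex[ix, jx - 2, 0]
                            ty = b * (2 * jy + 1) * Ey[iy, jy, 0] - 2.0 * b * b * Ey[iy, jy + 2, 0]
                            if jy > 1:
                                ty -= 0.5 * jy * (jy - 1) * Ey[iy, jy - 2, 0]
                            tz = b * (2 * jz + 1) * Ez[iz, jz, 0] - 2.0 * b * b * Ez[iz, jz + 2, 0]
                            if jz > 1:
                                tz -= 0.5 * jz * (jz - 1) * Ez[iz, jz - 2, 0]
                            Tblk[ca_i, cb_j] += cc * pref * (tx * sy * sz + sx * ty * sz + sx * sy * tz)
                            # dipole (about origin)
                            dx = Ex[ix, jx, 1] + P[0] * Ex[ix, jx, 0]
                            dy = Ey[iy, jy, 1] + P[1] * Ey[iy, jy, 0]
                            dz = Ez[iz, jz, 1] + P[2] * Ez[iz, jz, 0]
                            Dblk[0, ca_i, cb_j] += cc * pref * dx * sy * sz
                            Dblk[1, ca_i, cb_j] += cc * pref * sx * dy * sz
                            Dblk[2, ca_i, cb_j] += cc * pref * sx * sy * dz
                    # nuclear attraction
                    for ic in range(charges.shape[0]):
                        PC = P - atpos[ic]
                        _rtensor(lA + lB, p, PC, Rt)
                        for ca_i in range(nA):
                            ix = cart_flat[cart_off[lA] + ca_i, 0]
                            iy = cart_flat[cart_off[lA] + ca_i, 1]
                            iz = cart_flat[cart_off[lA] + ca_i, 2]
                            for cb_j in range(nB):
                                jx = cart_flat[cart_off[lB] + cb_j, 0]
                                jy = cart_flat[cart_off[lB] + cb_j, 1]
                                jz = cart_flat[cart_off[lB] + cb_j, 2]
                                acc = 0.0
                                for t in range(ix + jx + 1):
                                    for u in range(iy + jy + 1):
                                        for v in range(iz + jz + 1):
                                            acc += Ex[ix, jx, t] * Ey[iy, jy, u] * Ez[iz, jz, v] * Rt[t, u, v]
                                Vblk[ca_i, cb_j] -= charges[ic] * cc * 2.0 * np.pi / p * acc
            for ca_i in range(nA):
                for cb_j in range(nB):
                    mu = ao_of[I] + ca_i
                    nu = ao_of[J] + cb_j
                    S[mu, nu] = Sblk[ca_i, cb_j]
                    S[nu, mu] = Sblk[ca_i, cb_j]
                    T[mu, nu] = Tblk[ca_i, cb_j]
                    T[nu, mu] = Tblk[ca_i, cb_j]
                    V[mu, nu] = Vblk[ca_i, cb_j]
                    V[nu, mu] = Vblk[ca_i, cb_j]
                    for k in range(3):
                        D3[k, mu, nu] = Dblk[k, ca_i, cb_j]
                        D3[k, nu, mu] = Dblk[k, ca_i, cb_j]
    return S, T, V, D3


@njit(cache=True)
def _eri(sh_L, sh_cen, sh_ps, sh_np, pexp, pcoef, cart_flat, cart_off,
         screen_thresh):
    n_sh = sh_L.shape[0]
    ao_of = np.zeros(n_sh + 1, dtype=np.int64)
    for i in range(n_sh):
        ao_of[i + 1] = ao_of[i] + (sh_L[i] + 1) * (sh_L[i] + 2) // 2
    nbf = ao_of[n_sh]
    eri = np.zeros((nbf, nbf, nbf, nbf))
    EA = np.zeros((3, 3, 3, 5))
    EB = np.zeros((3, 3, 3, 5))
    Rt = np.zeros((9, 9, 9))
    maxn = 6
    # Schwarz bounds per shell pair
    npair = n_sh * (n_sh + 1) // 2
    qbound = np.zeros(npair)

    # first pass: diagonal (ab|ab) bounds
    for I in range(n_sh):
        for J in range(I + 1):
            lA, lB = sh_L[I], sh_L[J]
            A, B = sh_cen[I], sh_cen[J]
            nA = (lA + 1) * (lA + 2) // 2
            nB = (lB + 1) * (lB + 2) // 2
            blk = np.zeros((nA, nB, nA, nB))
            for ip in range(sh_np[I]):
                a = pexp[sh_ps[I] + ip]
                ca = pcoef[sh_ps[I] + ip]
                for jp in range(sh_np[J]):
                    b = pexp[sh_ps[J] + jp]
                    cb = pcoef[sh_ps[J] + jp]
                    p = a + b
                    P = (a * A + b * B) / p
                    _ecoef(lA, lB, a, b, A[0] - B[0], EA[0])
                    _ecoef(lA, lB, a, b, A[1] - B[1], EA[1])
                    _ecoef(lA, lB, a, b, A[2] - B[2], EA[2])
                    for kp in range(sh_np[I]):
                        c = pexp[sh_ps[I] + kp]
                        cc_ = pcoef[sh_ps[I] + kp]
                        for lp in range(sh_np[J]):
                            d = pexp[sh_ps[J] + lp]
                            cd = pcoef[sh_ps[J] + lp]
                            q = c + d
                            Q = (c * A + d * B) / q
                            _ecoef(lA, lB, c, d, A[0] - B[0], EB[0])
                            _ecoef(lA, lB, c, d, A[1] - B[1], EB[1])
                            _ecoef(lA, lB, c, d, A[2] - B[2], EB[2])
                            alpha = p * q / (p + q)
                            _rtensor(2 * (lA + lB), alpha, P - Q, Rt)
                            pref = 2.0 * np.pi ** 2.5 / (p * q * np.sqrt(p + q)) * ca * cb * cc_ * cd
                            for ai in range(nA):
                                ix = cart_flat[cart_off[lA] + ai, 0]
                                iy = cart_flat[cart_off[lA] + ai, 1]
                                iz = cart_flat[cart_off[lA] + ai, 2]
                                for bj in range(nB):
                                    jx = cart_flat[cart_off[lB] + bj, 0]
                                    jy = cart_flat[cart_off[lB] + bj, 1]
                                    jz = cart_flat[cart_off[lB] + bj, 2]
                                    for ak in range(nA):
                                        kx = cart_flat[cart_off[lA] + ak, 0]
                                        ky = cart_flat[cart_off[lA] + ak, 1]
                                        kz = cart_flat[cart_off[lA] + ak, 2]
                                        for bl in range(nB):
                                            lx = cart_flat[cart_off[lB] + bl, 0]
                                            ly = cart_flat[cart_off[lB] + bl, 1]
                                            lz = cart_flat[cart_off[lB] + bl, 2]
                                            acc = 0.0
                                            for t in range(ix + jx + 1):
                                                for u in range(iy + jy + 1):
                                                    for v in range(iz + jz + 1):
                                                        e1 = EA[0, ix, jx, t] * EA[1, iy, jy, u] * EA[2, iz, jz, v]
                                                        if e1 == 0.0:
                                                            continue
                                                        for t2 in range(kx + lx + 1):
                                                            for u2 in range(ky + ly + 1):
                                                                for v2 in range(kz + lz + 1):
                                                                    e2 = EB[0, kx, lx, t2] * EB[1, ky, ly, u2] * EB[2, kz, lz, v2]
                                                                    if e2 == 0.0:
                                                                        continue
                                                                    sgn = 1.0 if (t2 + u2 + v2) % 2 == 0 else -1.0
                                                                    acc += e1 * e2 * sgn * Rt[t + t2, u + u2, v + v2]
                                            blk[ai, bj, ak, bl] += pref * acc
            m = 0.0
            for ai in range(nA):
                for bj in range(nB):
                    if blk[ai, bj, ai, bj] > m:
                        m = blk[ai, bj, ai, bj]
            qbound[I * (I + 1) // 2 + J] = np.sqrt(m)
    # main pass
    for I in range(n_sh):
        for J in range(I + 1):
            qIJ = qbound[I * (I + 1) // 2 + J]
            for K in range(I + 1):
                for Lsh in range(K + 1):
                    if K == I and Lsh > J:
                        continue
                    if qIJ * qbound[K * (K + 1) // 2 + Lsh] < screen_thresh:
                        continue
                    lA, lB, lC, lD = sh_L[I], sh_L[J], sh_L[K], sh_L[Lsh]
                    A, B, C, D = sh_cen[I], sh_cen[J], sh_cen[K], sh_cen[Lsh]
                    nA = (lA + 1) * (lA + 2) // 2
                    nB = (lB + 1) * (lB + 2) // 2
                    nC = (lC + 1) * (lC + 2) // 2
                    nD = (lD + 1) * (lD + 2) // 2
                    blk = np.zeros((nA, nB, nC, nD))
                    for ip in range(sh_np[I]):
                        a = pexp[sh_ps[I] + ip]
                        ca = pcoef[sh_ps[I] + ip]
                        for jp in range(sh_np[J]):
                            b = pexp[sh_ps[J] + jp]
                            cb = pcoef[sh_ps[J] + jp]
                            p = a + b
                            P = (a * A + b * B) / p
                            _ecoef(lA, lB, a, b, A[0] - B[0], EA[0])
                            _ecoef(lA, lB, a, b, A[1] - B[1], EA[1])
                            _ecoef(lA, lB, a, b, A[2] - B[2], EA[2])
                            for kp in range(sh_np[K]):
                                c = pexp[sh_ps[K] + kp]
                                cc_ = pcoef[sh_ps[K] + kp]
                                for lp in range(sh_np[Lsh]):
                                    d = pexp[sh_ps[Lsh] + lp]
                                    cd = pcoef[sh_ps[Lsh] + lp]
                                    q = c + d
                                    Q = (c * C + d * D) / q
                                    _ecoef(lC, lD, c, d, C[0] - D[0], EB[0])
                                    _ecoef(lC, lD, c, d, C[1] - D[1], EB[1])
                                    _ecoef(lC, lD, c, d, C[2] - D[2], EB[2])
                                    alpha = p * q / (p + q)
                                    _rtensor(lA + lB + lC + lD, alpha, P - Q, Rt)
                                    pref = 2.0 * np.pi ** 2.5 / (p * q * np.sqrt(p + q)) * ca * cb * cc_ * cd
                                    for ai in range(nA):
                                        ix = cart_flat[cart_off[lA] + ai, 0]
                                        iy = cart_flat[cart_off[lA] + ai, 1]
                                        iz = cart_flat[cart_off[lA] + ai, 2]
                                        for bj in range(nB):
                                            jx = cart_flat[cart_off[lB] + bj, 0]
                                            jy = cart_flat[cart_off[lB] + bj, 1]
                                            jz = cart_flat[cart_off[lB] + bj, 2]
                                            for ak in range(nC):
                                                kx = cart_flat[cart_off[lC] + ak, 0]
                                                ky = cart_flat[cart_off[lC] + ak, 1]
                                                kz = cart_flat[cart_off[lC] + ak, 2]
                                                for bl in range(nD):
                                                    lx = cart_flat[cart_off[lD] + bl, 0]
                                                    ly = cart_flat[cart_off[lD] + bl, 1]
                                                    lz = cart_flat[cart_off[lD] + bl, 2]
                                                    acc = 0.0
                                                    for t in range(ix + jx + 1):
                                                        for u in range(iy + jy + 1):
                                                            for v in range(iz + jz + 1):
                                                                e1 = EA[0, ix, jx, t] * EA[1, iy, jy, u] * EA[2, iz, jz, v]
                                                                if e1 == 0.0:
                                                                    continue
                                                                for t2 in range(kx + lx + 1):
                                                                    for u2 in range(ky + ly + 1):
                                                                        for v2 in range(kz + lz + 1):
                                                                            e2 = EB[0, kx, lx, t2] * EB[1, ky, ly, u2] * EB[2, kz, lz, v2]
                                                                            if e2 == 0.0:
                                                                                continue
                                                                            sgn = 1.0 if (t2 + u2 + v2) % 2 == 0 else -1.0
                                                                            acc += e1 * e2 * sgn * Rt[t + t2, u + u2, v + v2]
                                                    blk[ai, bj, ak, bl] += pref * acc
                    for ai in range(nA):
                        for bj in range(nB):
                            for ak in range(nC):
                                for bl in range(nD):
                                    mu = ao_of[I] + ai
                                    nu = ao_of[J] + bj
                                    rho = ao_of[K] + ak
                                    sig = ao_of[Lsh] + bl
                                    v = blk[ai, bj, ak, bl]
                                    eri[mu, nu, rho, sig] = v
                                    eri[nu, mu, rho, sig] = v
                                    eri[mu, nu, sig, rho] = v
                                    eri[nu, mu, sig, rho] = v
                                    eri[rho, sig, mu, nu] = v
                                    eri[sig, rho, mu, nu] = v
                                    eri[rho, sig, nu, mu] = v
                                    eri[sig, rho, nu, mu] = v
    return eri


class Molecule:
    def __init__(self, symbols, coords_ang, basis="6-31+G*", charge=0):
        self.symbols = list(symbols)
        self.coords = np.asarray(coords_ang, float)
        self.basis = basis
        self.charge = charge
        self.Z = np.array([CHARGES[s] for s in self.symbols], float)
        self.nelec = int(self.Z.sum()) - charge

    def integrals(self):
        xyz = self.coords * ANG2BOHR
        sh = build_shells(self.symbols, xyz, self.basis)
        S, T, V, D3 = _one_electron(sh["sh_L"], sh["sh_cen"], sh["sh_ps"],
                                    sh["sh_np"], sh["pexp"], sh["pcoef"],
                                    self.Z, xyz, CART_FLAT, CART_OFF)
        eri = _eri(sh["sh_L"], sh["sh_cen"], sh["sh_ps"], sh["sh_np"],
                   sh["pexp"], sh["pcoef"], CART_FLAT, CART_OFF, 1e-11)
        # normalize each contracted AO by its raw self-overlap
        nu = 1.0 / np.sqrt(np.diag(S))
        S = S * nu[:, None] * nu[None, :]
        T = T * nu[:, None] * nu[None, :]
        V = V * nu[:, None] * nu[None, :]
        D3 = D3 * nu[None, :, None] * nu[None, None, :]
        eri = np.einsum("pqrs,p,q,r,s->pqrs", eri, nu, nu, nu, nu)
        self.shmeta = sh
        return S, T, V, D3, eri

    def e_nuc(self):
        xyz = self.coords * ANG2BOHR
        e = 0.0
        for i in range(len(self.Z)):
            for j in range(i):
                e += self.Z[i] * self.Z[j] / np.linalg.norm(xyz[i] - xyz[j])
        return e


def rhf(mol, conv=1e-9, maxiter=200, verbose=False):
    S, T, V, D3, eri = mol.integrals()
    H = T + V
    nocc = mol.nelec // 2
    assert mol.nelec % 2 == 0
    # symmetric orthogonalization
    w, U = np.linalg.eigh(S)
    keep = w > 1e-7
    X = U[:, keep] / np.sqrt(w[keep])
    F = H.copy()
    Dm = None
    errs, focks = [], []
    E_old = 0.0
    for it in range(maxiter):
        Fo = X.T @ F @ X
        eps, Co = np.linalg.eigh(Fo)
        Cmo = X @ Co
        Cocc = Cmo[:, :nocc]
        Dm = 2.0 * Cocc @ Cocc.T
        J = np.einsum("pqrs,rs->pq", eri, Dm, optimize=True)
        K = np.einsum("prqs,rs->pq", eri, Dm, optimize=True)
        F = H + J - 0.5 * K
        E = 0.5 * np.sum(Dm * (H + F)) + mol.e_nuc()
        err = F @ Dm @ S - S @ Dm @ F
        errs.append(err)
        focks.append(F.copy())
        if len(errs) > 8:
            errs.pop(0)
            focks.pop(0)
        enorm = np.max(np.abs(err))
        if verbose:
            print(f"  iter {it:3d}  E = {E:.10f}  |err| = {enorm:.2e}")
        if enorm < conv and abs(E - E_old) < conv:
            return dict(E=E, eps=eps, C=Cmo, S=S, D3=D3, nocc=nocc,
                        converged=True, niter=it)
        E_old = E
        # DIIS extrapolation
        n = len(errs)
        if n > 1:
            Bm = np.empty((n + 1, n + 1))
            Bm[-1, :] = -1.0
            Bm[:, -1] = -1.0
            Bm[-1, -1] = 0.0
            for i in range(n):
                for j in range(n):
                    Bm[i, j] = np.sum(errs[i] * errs[j])
            rhs = np.zeros(n + 1)
            rhs[-1] = -1.0
            try:
                cdi = np.linalg.solve(Bm, rhs)[:n]
                F = sum(c * f for c, f in zip(cdi, focks))
            except np.linalg.LinAlgError:
                pass
    return dict(E=E, eps=eps, C=Cmo, S=S, D3=D3, nocc=nocc,
                converged=False, niter=maxiter)


def mulliken_per_mo(res, ao_atom, natom):
    """Gross Mulliken population of each occupied MO on each atom."""
    C = res["C"][:, :res["nocc"]]
    SC = res["S"] @ C
    pop = np.zeros((res["nocc"], natom))
    for i in range(res["nocc"]):
        contrib = C[:, i] * SC[:, i]
        for mu, a in enumerate(ao_atom):
            pop[i, a] += contrib[mu]
    return pop
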