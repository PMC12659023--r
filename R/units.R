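#' Unit conventions and conversion constants
#'
#' The package uses a single internal unit system throughout:
#' length in angstrom (\eqn{\AA}), time in picoseconds (ps), charge in
#' elementary charges (e), voltage in millivolts (mV).  Derived units are
#' current in nanoampere (nA), water flux in molecules/ns, conductance in
#' nanosiemens (nS) and conductivity in S/m.
#'
#' The bridge between the mechanical and the electrical units is the
#' elementary charge, e = 1.602176634e-19 C, so that a charge flux of
#' 1 e/ps equals 160.2176634 nA.
#'
#' @name poreflux-units
#' @keywords internal
NULL

## 1 e/ps in nA (exact, from the 2019 SI definition of e)
E_PER_PS_TO_NA <- 160.2176634

## 1 molecule/ps in molecules/ns
PER_PS_TO_PER_NS <- 1000

## conductance: slope of I[nA] vs V[mV] is nA/mV = 1e-6 S = 1000 nS
NA_PER_MV_TO_NS <- 1000

## sigma = G * Lz / (Lx*Ly): nS * A / A^2 -> S/m carries a factor 10
##   (1e-9 S * 1e-10 m / 1e-20 m^2 = 10 S/m per nS/A)
NS_PER_ANG_TO_S_PER_M <- 10

## mobility-mode conductivity: n[1/A^3] * q[e] * mu[A^2/(ps mV)] is in
## e/(A ps mV); 1 e/(A ps mV) = 1.602176634e-7 A / (1e-10 m * 1e-3 V)
##            = 1.602176634e6 S/m
E_PER_A_PS_MV_TO_S_PER_M <- E_PER_PS_TO_NA * 1e-9 / (1e-10 * 1e-3)

## particles per A^3 -> mol/L  (1/A^3 = 1e27 / L, / Avogadro)
PER_A3_TO_MOL_PER_L <- 1e27 / 6.02214076e23
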