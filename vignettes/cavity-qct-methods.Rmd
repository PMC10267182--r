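---
title: "Methods: vibrational strong coupling dynamics and spectra of a hydrogen-bonded dimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vibrational strong coupling dynamics and spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The physical problem

When an infrared cavity mode is strongly coupled to a molecular vibration,
the two hybridize into lower and upper polariton states, and the question
of interest is whether — and how — that hybridization changes chemistry.
`polariqct` studies the cleanest version of this question: a single
hydrogen-bonded water dimer whose H-bonded OH stretch carries one quantum
of excitation, coupled to one cavity photon mode.  Two complementary
machineries share one Hamiltonian:

* a **quasi-classical trajectory (QCT)** engine that propagates the
  coupled nuclear + photon phase space and collects dissociation
  statistics and product-state distributions, and
* a **cavity VSCF/VCI** solver that diagonalizes the same Hamiltonian
  quantum mechanically in a reduced space of normal modes and returns
  polaritonic infrared spectra with state assignments.

# The Hamiltonian

The light-matter Hamiltonian is the Pauli-Fierz form in length gauge,
written as a completed square,

$$ H = T_N(\mathbf R) + V(\mathbf R) + \sum_k \tfrac12 p_k^2 +
   \tfrac12\omega_k^2\Big(q_k + \sqrt{\tfrac{2}{\omega_k^3}}\,
   g\,\boldsymbol\mu(\mathbf R)\cdot\mathbf e_k\Big)^2 , \qquad
   g = \sqrt{\frac{\omega_k}{2\epsilon_0 \tilde V}} , $$

with the photon coordinates $(q_k,p_k)$ mass-weighted (photon mass 1) and
$\epsilon_0 = 1/4\pi$ in atomic units — the convention under which
$g = 0.005$ a.u. at $\omega = 3547\,\mathrm{cm^{-1}}$ corresponds to an
effective cavity volume of $0.6\,\mathrm{nm^3}$
(`coupling_volume_convert()`).  The dipole self-energy is never optional:
it is part of the square, which is why the minimum of the effective
potential over the photon coordinates equals the bare $V(\mathbf R)$ for
every geometry, and why the cavity does not shift equilibrium structures
or binding energies.

Design choices worth stating:

* **Lab-fixed polarization.**  `"oo-axis"` resolves the polarization
  vector from the O-O axis of the *initial* geometry of each trajectory;
  it does not track the instantaneous axis (that would make the
  Hamiltonian time dependent).  With total $J = 0$ preparation the frame
  drifts little over 25 ps.
* **Energy bookkeeping.**  `energy_decomposition()` reports
  $E_\mathrm{mol} = T_N + V$, the bare-oscillator energy
  $E_\mathrm{cav}$, and the field energy $E_\mathrm{field}$ (the
  completed-square term plus the photon kinetic energy); the conserved
  total is $E_\mathrm{mol} + E_\mathrm{field}$.

# The model surface

Quantitative reproduction of water-dimer observables requires externally
fitted coupled-cluster surfaces, which this package deliberately does not
ship; they plug in through the two-callable adapter contract
(`potential_surface()` / `dipole_surface()`, atom order O H H O H H).  The
built-in analytic model (`model_dimer_surface()`) instead reproduces the
*class* of physics at desk scale:

* **Monomers:** Morse OH bonds ($D_e = 0.18$ hartree, $a = 1.165$
  bohr$^{-1}$, $r_e = 1.8141$ bohr) and a harmonic bend
  ($k_\theta = 0.150$ hartree rad$^{-2}$, $\theta_e = 104.52^\circ$),
  giving monomer frequencies 1602 / 3664 / 3717 cm$^{-1}$.
* **2-body term:** an O-O Morse well, four *equivalent* H$\cdots$O cross
  Morse wells, four equivalent shallow H-H Morse wells (steep short-range
  walls), and damped intermolecular Coulomb charges (+0.15 e on H,
  −0.30 e on O, quartic damping at 9 bohr).  Everything depends on
  interatomic distances only, so the surface is exactly invariant under
  rigid motions, under exchange of the two hydrogens within a monomer,
  and under monomer exchange — trajectories may legitimately swap donor
  and acceptor roles mid-flight.  All terms decay below $10^{-10}$
  hartree well inside the 10 Å dissociation threshold.

The Coulomb term deserves a comment: with distance-Morse terms alone the
donor free-H torsion comes out at ~9 cm$^{-1}$ (nothing in a short-range
pair potential restrains a hydrogen 6 bohr from every atom of the other
monomer), and linear normal-mode sampling of such a mode is meaningless.
The orientational stiffness of a real hydrogen bond is electrostatic, and
a damped point-charge sum restores it: the softest mode rises to
68 cm$^{-1}$, inside the physical 60–600 cm$^{-1}$ window of the real
dimer.

The defaults were calibrated once, before any dynamics were run, to the
windows that define the study conditions: the harmonic H-bonded OH
stretch at 3618 cm$^{-1}$ (window 3400–3700, red-shifted below the free
OH stretches as in the real dimer), well depth
$D_\mathrm{HB} = 1301$ cm$^{-1}$ (window 1000–1500), bends near
1610 cm$^{-1}$.  $D_\mathrm{HB}$ is a *derived* quantity — the energy of
the relaxed dimer below two relaxed monomers — and the builder rejects
parameter sets whose well depth is not below one quantum of the H-bonded
stretch (a closed dissociation channel).  The quantum threshold
$D_0 = D_\mathrm{HB} + \mathrm{ZPE(2\,monomers)} - \mathrm{ZPE(dimer)}
\approx 620$ cm$^{-1}$ is likewise far below one stretch quantum.

The dipole is a sum of four bond dipoles
$\mu_b(r) = (\mu_0 + \mu_1 (r - r_e))\hat u_{OH}$ with $\mu_0 = 0.60$ e
bohr, $\mu_1 = 0.16$ e — a deliberately simple form whose analytic
jacobian feeds the coupling force exactly.

# Quasi-classical trajectories

**Preparation.**  `normal_mode_sample()` assigns each normal mode the
energy $(n_i + \tfrac12)\hbar\omega_i$ at a uniformly random phase —
zero-point energy everywhere plus one quantum in the H-bonded stretch by
default — reconstructs Cartesian coordinates and velocities, removes
centre-of-mass motion and the total angular momentum
($\omega = I^{-1}L$ about the centre of mass, exact removal of
$\tfrac12 L^\top I^{-1}L$ of kinetic energy), and by default rescales
velocities so the total internal energy matches the harmonic target
(`rescale = "kinetic"`, the common QCT convention; `"none"` is
available).  Each drawn mode carries its quantized energy *exactly*; the
$J = 0$ projection afterwards perturbs per-mode energies by up to a few
percent for this floppy dimer — an intrinsic feature of rectilinear
normal-mode sampling that the suite documents and bounds at 5%.

**Cavity initialization.**  One photon mode is displaced about the field
minimum $q^* = -\sqrt{2/\omega^3}\,g\,\mu\cdot e$ at a random phase so
that its field energy is exactly $\hbar\omega/2$ at $t = 0$.

**Propagation.**  Velocity Verlet on the completed-square Hamiltonian,
$dt = 0.12$ fs, 25 ps, termination at the first crossing of
$R_{OO} \ge 10$ Å (at that separation every model term is numerically
zero, so no re-crossing grace window is needed).  The model surface runs
in compiled code (~0.1 s per 25 ps trajectory); arbitrary R-level
surfaces use an equivalent interpreted loop.  With $g = 0$ every coupling
contribution is an exact floating-point zero, so a coupled run at
$g = 0$ is bit-identical to a cavity-free run — a structural guarantee,
not a tolerance.

**Energy conservation.**  A second-order symplectic integrator conserves
a shadow Hamiltonian: the plain energy oscillates with relative amplitude
$\sim(\omega\,dt)^2/8 \approx 10^{-3}$ for 3600 cm$^{-1}$ modes at
0.12 fs, with no secular growth (the harmonic shadow invariant is
conserved to $10^{-10}$ over $10^6$ steps in the suite).  Any estimator
of the drift of the plain $E_\mathrm{mol}+E_\mathrm{field}$ over 25 ps
bottoms out near $10^{-5}$ relative — the oscillation floor, not a drift;
demanding $10^{-6}$ of the plain energy at this time step is not
attainable for any second-order symplectic scheme, and the acceptance
suite records that honestly.

**Statistics.**  `run_ensemble()` derives per-trajectory seeds from one
master seed (any trajectory is reproducible in isolation), accumulates
the dissociated fraction $P(t)$ on the output grid, and estimates the
half-lifetime $\tau_{0.5}$ by first-crossing linear interpolation — not
an exponential fit, matching the way dissociation curves are read.  The
suite's scaled-down conditions use 200 trajectories (the desk-scale
stand-in for the 20,000-trajectory production setting); both ensembles of
a coupled/uncoupled comparison share initial conditions, so the coupling
response is assessed with the paired binomial error.

# Product analysis and Gaussian binning

Dissociated frames are split into monomer fragments by nearest-oxygen
assignment (ambiguous, proton-transfer-like frames raise an error).  Per
fragment: the rovibrational energy is the COM-frame kinetic plus
potential relative to the monomer minimum; removing the angular momentum
gives the vibrational energy, and the difference is the classical
rotational energy.  The fragment is Kabsch-aligned (mass-weighted) to the
monomer reference — the practical realization of the Eckart frame — and
projected onto monomer normal modes; harmonic per-mode energies give
non-integer actions $n_i' = E_i/\hbar\omega_i - \tfrac12$, rounded
half-to-even and floored at zero, ordered (symmetric stretch, bend,
asymmetric stretch).  The rotational quantum number solves
$J(J+1) = |L|^2$ (rigid-rotor relation from the momentum vector rather
than from $E_\mathrm{rot}$ and a rotational constant — no choice of
monomer constant needed).

One-Gaussian binning weights each fragment by
$$ G = \frac{\beta}{\sqrt\pi}\exp\Big[-\beta^2\Big(
   \frac{E(n') - E(n)}{2E(0)}\Big)^2\Big],\qquad
   \beta = 2\sqrt{\ln 2}/\delta , $$
with $E(n')$ the anharmonic vibrational energy after rotation removal,
$E(n)$ and $E(0)$ harmonic; the pair weight is the product of the two
fragment weights, and channel populations are the normalized weighted
sums.  The FWHM $\delta$ of the dimensionless mismatch defaults to 0.1 —
the literature on this estimator does not pin a single value, so it is a
documented, prominent configuration knob; $\delta \to \infty$ recovers
raw histogram counts.  ZPE-violating fragments ($E(n') < E(0)$) are
suppressed smoothly and monotonically, which is the point of the method:
it statistically corrects the classical zero-point-energy leak.

# Cavity VSCF/VCI

The spectroscopic module treats the photon coordinate as one more
vibrational mode.  The effective potential over the selected molecular
normal modes plus $q$ is expanded in a hierarchical $n$-mode
representation (default 4-mode for the potential, 3-mode for the dipole),
each increment evaluated on a tensor-product Gauss-Hermite grid by
inclusion-exclusion over sub-grids, so that lower-order contributions are
subtracted exactly and full order reconstructs the function at every grid
point.  Grid sizes shrink with coupling order (defaults 20/16/10/8
points) — the usual cost/accuracy compromise for high-order terms.

VSCF solves the mean-field equations in a per-mode harmonic-oscillator
primitive basis (default 14 functions; the kinetic energy is diagonal in
rectilinear normal modes — Watson Coriolis and pseudo-potential terms are
omitted, a declared approximation shared with the quadratic oracle that
cross-checks the implementation).  VCI diagonalizes the Hamiltonian in
the basis of VSCF virtual-state products with per-class excitation caps
(the conventional (singles, doubles, triples, quadruples) maximum-quanta
convention; (10, 9, 8, 7) is the configured default, and desk-scale
demonstrations use (6, 5, 4, 4), which resolves the polariton doublet to
well under a wavenumber of its converged position).  The matrix is
assembled per $n$-mode term over groups of configurations that agree
outside the term's modes; hermiticity is checked to $10^{-12}$ before
diagonalization.

Infrared intensities are $\propto (E_f - E_0)\,|\langle 0|\mu|f\rangle|^2$
(reported in km/mol; the conversion constant equals the familiar
2.50654 km mol$^{-1}$ per cm$^{-1}$ D$^2$).  Polaritons are identified as
the two eigenstates with the largest absolute coefficient on the
cavity-fundamental configuration; ties in degenerate assignments break
toward the larger cavity coefficient, labelled UP when above the
uncoupled frequency.

Two numerical cross-checks anchor the module: (i) for a harmonic mode
with a linear dipole and a resonant cavity the VCI fundamentals must
match the frequencies of the analytic $2\times2$ quadratic form to better
than 0.1 cm$^{-1}$ (they agree to $\sim 10^{-6}$), and (ii) on two-mode
problems the full-space VCI must agree with a dense direct-product
diagonalization to $10^{-6}$ cm$^{-1}$.

**Resonance condition.**  The cavity is tuned to the *anharmonic*
H-bonded-stretch fundamental (`hb_fundamental_cm()`, 3479 cm$^{-1}$ on
the model — about 140 cm$^{-1}$ below the harmonic frequency because of
the Morse anharmonicity), which is also where the classical oscillator
actually vibrates at its prepared energy.  This mirrors the convention of
tuning to the measured fundamental rather than to a harmonic analysis.

# What the model does and does not show

Passing this suite demonstrates that the machinery — Hamiltonian, forces,
sampling, integrator, binning, VSCF/VCI — is correct, and that the model
dimer reproduces the *qualitative* polaritonic phenomenology: a LP/UP
doublet with near-equal cavity weight at resonance whose splitting grows
monotonically with $g$; a bend-excited-dominated product distribution
outside the cavity with a minor, rotationally hot ground-state channel;
ps-scale half-lifetimes that respond to the coupling strength.  It does
not reproduce the literature's quantitative numbers (those belong to
externally fitted CCSD(T)-level surfaces and 20,000-trajectory
ensembles): the model's dipole magnitudes, intermolecular anharmonicity,
and mode mixing are all simplified, and 200-trajectory ensembles carry
binomial error of a few percent.  Problem sizes used throughout —
200-trajectory ensembles, 6 + 1-mode VCI with (6, 5, 4, 4) spaces — are
the package's chosen desk scale; every knob scales up through the public
API.

# Degenerate inputs and numerical details

* Geometries with a hydrogen equidistant from both oxygens make fragment
  assignment ambiguous and raise an error naming the atoms.
* Linear fragments are handled by the pseudo-inverse in the angular
  momentum removal.
* Finite-difference fallbacks: gradient $10^{-4}$ bohr central, Hessian
  $5\times10^{-3}$ bohr central with symmetrization (raw asymmetry is
  attached for inspection); both steps are arguments.
* Half-to-even rounding makes action assignment deterministic and
  bias-free at ties.
* Eigenvector sign conventions are fixed (largest component positive) so
  VSCF/VCI outputs are reproducible across runs.
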