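---
title: "Where does ligand binding move protein fluctuations? The gnmflux model and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Where does ligand binding move protein fluctuations? The gnmflux model and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`gnmflux` asks a narrowly defined question: when a ligand binds a protein,
where do the equilibrium fluctuations shrink and where do they grow?  It
answers it with the Gaussian network model (GNM), the simplest elastic
network model of protein dynamics.  Each amino acid is reduced to its
C&#945; atom; each ligand contributes one node per heavy atom.  Every pair
of nodes within a cutoff distance $r_c$ (default 7.5 &#8491;) is joined by
an identical Hookean spring with spring constant $\gamma$.  The network
topology is encoded in the Kirchhoff (connectivity) matrix $\Gamma$:

$$\Gamma_{ij} = \begin{cases}
-1 & i \ne j,\ R_{ij} \le r_c\\
0 & i \ne j,\ R_{ij} > r_c\\
-\sum_{k \ne i} \Gamma_{ik} & i = j
\end{cases}$$

$\Gamma$ is a graph Laplacian: symmetric, positive semidefinite, rows
summing to zero, with one zero eigenvalue per connected component.
Its eigendecomposition $\Gamma = \sum_m \lambda_m \upsilon_m
\upsilon_m^\top$ gives the vibrational modes; the scalar fluctuation of
node $i$ sums the inverse-eigenvalue-weighted mode amplitudes over all
nonzero modes,

$$f_i = \sum_{m:\ \lambda_m > 0} \frac{\upsilon_{mi}^2}{\lambda_m},$$

which is exactly the $i$-th diagonal entry of the Moore–Penrose
pseudoinverse of $\Gamma$ (in graph terms, a quantity determined by
effective resistances).  No mode truncation is applied: nothing in the
analysis requires choosing a mode subset, so the full nonzero spectrum is
used.

The perturbation analysis compares two networks built from the same
coordinates: the *bound* network (residues plus ligand nodes) and the
*unbound* network, obtained by deleting the ligand residues from the
structure.  The per-residue difference

$$\Delta f_i = f_i(\mathrm{bound}) - f_i(\mathrm{unbound})$$

is negative where binding rigidifies the chain (invariably the binding
pocket, which gains spring connections) and positive where mobility grows.
The consistent observation this package is built to expose is that the
gains concentrate at sites *remote* from the pocket — an allosteric
redistribution of flexibility, with direct implications for the entropic
side of binding thermodynamics.

Two summary devices condense a $\Delta f$ profile:

* **Ratio statistic.** Residues are partitioned by the sign of
  $\Delta f_i$ (exact zeros, $|\Delta f_i| \le 10^{-12}$, belong to
  neither set).  The statistic is $100 \cdot \bar{\Delta f}^{+} /
  \overline{|\Delta f|}^{-}$: the mean gain over gaining residues divided
  by the mean magnitude of loss over losing residues, as a percentage.  A
  magnitude-based denominator keeps the ratio positive; it is invariant
  under any positive rescaling of $f$, which is why fixing $\gamma = 1$
  (the model gives no physical value for it) loses nothing.  If either set
  is empty the ratio is reported as undefined (`NA`), never as 0 or
  infinity.
* **Decoy control.** To show that the redistribution is specific to the
  real ligand and not an artifact of adding *any* node, the full ligand is
  replaced by a single atom drawn uniformly at random from the "bonded"
  pool — the ligand atoms within $r_c$ of at least one residue.  The decoy
  analysis reports the mean of the decoy's $\Delta f$ over exactly the
  residues where the real ligand *increased* fluctuations.  This
  set-restricted mean may legitimately be negative (the decoy can rigidify
  where the ligand mobilized); we chose this reading deliberately, because
  the alternative — relabelling ligand atoms while keeping all their
  positions — would leave the network, and hence the statistic, unchanged,
  and could never produce a distinct control value.

A radial profile (mean $\Delta f$ binned by each residue's minimum
distance to the ligand, default bin width 2.5 &#8491;, commensurate with
the 7.5 &#8491; cutoff) exposes the decay of the perturbation with
distance from the pocket.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| cutoff $r_c$ | 7.5 | &#8491; | the customary GNM contact radius for C&#945; networks; applied inclusively ($R_{ij} \le r_c$) to residue–residue, residue–ligand and ligand–ligand pairs alike |
| spring constant $\gamma$ | 1 | — | sets only the global fluctuation scale; every reported ratio is scale-free |
| zero-mode tolerance | $\max(N,1)\,\varepsilon\,\lambda_{\max}$, floor $10^{-10}$ | — | standard rank tolerance, robust from 10 to thousands of nodes |
| decoy seed | 20210901 | — | the decoy is stochastic; the seed is a required, logged input so every control is reproducible |
| radial bin width | 2.5 | &#8491; | resolves the near/far transition at the scale of the contact cutoff |
| zero-difference tolerance | $10^{-12}$ | 1/$\gamma$ | residues with $|\Delta f|$ below this join neither the increase nor the decrease set |

Structure preparation follows fixed, deterministic conventions: the first
coordinate model unless another is requested (crystal structures have only
one); alternate locations resolved to the highest-occupancy copy, ties to
the lexicographically smallest altloc; ligand nodes are heavy atoms only
(H/D excluded), waters are never ligand-selectable; all chains are
included unless a chain filter is given, since the interesting cases are
whole assemblies; insertion-code ordering follows file order.  By default
only the named ligand codes are removed to create the unbound form —
crystallographic waters and incidental hetero groups (glycerol, buffer
ions) are retained in *both* forms, so they cancel in $\Delta f$.

A disconnected contact network is a hard error that names the component
sizes: in practice it means a preparation mistake (wrong chain filter, a
detached fragment), and silently applying pseudoinverse semantics would
average fluctuations across networks that share no springs.  An explicit
`allow_disconnected` flag overrides this when disconnection is intended.

## Numerical choices

The spectrum comes from `eigen(symmetric = TRUE)` (LAPACK's symmetric
eigensolver); for a symmetric positive-semidefinite matrix this coincides
with singular value decomposition up to sign conventions.  The fluctuation
vector is validated against an independent route — the diagonal of
`MASS::ginv(gamma)`, an SVD-based rank-revealing pseudoinverse — on every
kind of model the package can generate; the acceptance suite requires
agreement to $10^{-8}$ across 100 seeded models of 10–300 nodes, along
with the trace identity $\sum_i f_i = \sum_{\lambda_m > 0} 1/\lambda_m$.
Degenerate eigenvalues need no tie-breaking: $f$ depends on eigenspaces,
not on the arbitrary basis chosen inside a degenerate block, and a
regression test asserts this by permuting nodes of a complete graph.
Fluctuations are invariant under rigid motion of all coordinates, since
only distances enter $\Gamma$.

Superposition (for transplanting a ligand between structures over paired
anchor residues) uses the Kabsch algorithm via SVD of the cross-covariance
matrix, with the determinant correction that guarantees a proper rotation;
it is tested against a brute-force minimization over rotations.
Collinear anchor configurations are rejected rather than silently fitted,
because the in-plane rotation is then unconstrained.

## What the synthetic generators emulate — and what they do not

Real input is any PDB file plus the het codes of its ligand.  For
development and validation the package generates its own inputs:

* `make_analytic_model()` builds geometries whose GNM has a closed-form
  solution: collinear nodes 5 &#8491; apart (the path graph, solvable
  through effective resistances $R_{ij} = |i-j|$) and lattice points
  packed inside a 3.75 &#8491; ball (the complete graph, $f_i =
  (n-1)/n^2$).
* `make_helix_chain()` produces an ideal &#945;-helical C&#945; trace
  (1.5 &#8491; rise, 100&#176; turn, 2.3 &#8491; radius), giving the
  canonical ~3.8 &#8491; consecutive spacing.
* `make_two_domain_structure()` emulates the architecture the analysis
  targets: two compact domains (self-avoiding 3.8 &#8491;-step random
  walks confined to ~10 &#8491; spheres) joined by an extended 5-residue
  linker, with a small ligand cluster placed in a surface pocket of domain
  1 such that every ligand atom touches at least 3 pocket residues within
  5 &#8491; and stays at least 25 &#8491; from every domain-2 residue —
  so "near" and "remote" are unambiguous by construction.  Placement keeps
  the first feasible configuration under the seed (no optimization), and
  generation is a pure function of `(n_residues, ligand_atom_count,
  seed)`.  The default fixture (80 residues, 5 ligand atoms, seed 1337)
  is the package's standing regression case: pocket mean $\Delta f < 0$,
  at least one residue beyond 20 &#8491; with $\Delta f > 0$, and a decoy
  increase-set mean strictly below the real ligand's mean increase.

These fixtures have correct contact topology, realistic spacing and a
genuine pocket, but they are not proteins: no secondary-structure packing
beyond the helix generator, no side chains, no sequence, no crystal-lattice
artifacts, and domain sizes (tens of residues) an order of magnitude below
GroEL-scale assemblies.  Passing the synthetic suite therefore
demonstrates that the machinery — parsing, stripping, network building,
spectra, statistics — is correct, and that the qualitative
pocket-suppression/remote-gain pattern emerges from network topology
alone; it does not certify quantitative agreement on any particular
crystal structure, which additionally depends on preparation choices
(retained chains, altlocs, which hetero groups count as "the ligand") that
published analyses rarely pin down.  For that reason the batch screen
records such choices explicitly in its manifest.

Test problem sizes (10–300 nodes, 100-model sweeps, an 80-residue
fixture) were chosen as the smallest models that exercise every regime —
paths, complete graphs, degenerate spectra, multi-component errors, a
genuinely two-domain geometry; the full suite runs in seconds.

## Known limitations

* The GNM yields scalar fluctuation magnitudes only; directions of motion
  (anisotropic models) are out of scope by design.
* Fluctuations are relative (units of $1/\gamma$); converting them to
  absolute mean-square displacements or to entropies requires a calibrated
  $\gamma$ and a thermodynamic model that this package deliberately does
  not supply.
* No statistical significance test accompanies the decoy comparison; the
  interface instead supports running many decoy seeds and reporting each.
* Comparing a bound and an apo structure from *different* PDB entries
  requires the user to supply the residue pairing; the package aligns
  profiles by chain/residue-number/insertion-code labels and refuses
  mismatches rather than guessing.
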