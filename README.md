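# gnmflux

Ligand binding rigidifies a protein's binding pocket — but the lost
mobility does not simply vanish. Elastic-network calculations show it
reappearing at sites far from the pocket, an allosteric redistribution of
flexibility with direct consequences for the entropic side of binding
thermodynamics and, in machines like the GroEL chaperonin, for mechanism.
`gnmflux` is an R package for computing and quantifying that
redistribution. It is aimed at structural bioinformaticians who have a
ligand-bound PDB structure and want to know *where* binding moves the
fluctuations.

## The model

The protein is coarse-grained to one node per residue (its Cα atom) plus
one node per ligand heavy atom. All node pairs within a cutoff
*r<sub>c</sub>* (default 7.5 Å) are joined by identical springs, giving
the Kirchhoff (graph-Laplacian) matrix **Γ**:

- Γ<sub>ij</sub> = −1 if *i* ≠ *j* and R<sub>ij</sub> ≤ r<sub>c</sub>, else 0
- Γ<sub>ii</sub> = node degree (rows sum to zero)

The scalar fluctuation of node *i* is the inverse-spectrum mode sum

  f<sub>i</sub> = Σ<sub>m: λ<sub>m</sub>>0</sub> υ<sub>mi</sub>² / λ<sub>m</sub>,

equal to the *i*-th diagonal entry of the Moore–Penrose pseudoinverse of
**Γ** (the package computes it both ways and cross-checks). The analysis
contrasts the ligand-bound network against the ligand-stripped one:

  Δf<sub>i</sub> = f<sub>i</sub>(bound) − f<sub>i</sub>(unbound)

Negative Δf marks rigidified residues (the pocket); positive Δf marks
mobility gains (typically remote). Summaries include the ratio statistic
(mean increase over mean magnitude of decrease, as a percent), a
seeded single-atom **decoy-ligand control** for specificity, and a radial
profile of Δf versus distance from the ligand.

## Worked example

The package generates its own test structures, so the example needs no
downloads: an 80-residue two-domain protein with a 5-atom ligand in a
surface pocket of domain 1.

```r
library(gnmflux)

structure <- make_two_domain_structure(n_residues = 80,
                                       ligand_atom_count = 5, seed = 1337)
spec    <- ligand_spec("LIG")
bound   <- build_coarse_model(structure, spec)    # 80 residue + 5 ligand nodes
unbound <- build_coarse_model(strip_ligands(structure, spec), NULL)

delta <- delta_fluctuations(gnm_fluctuations(bound),
                            gnm_fluctuations(unbound))
delta
#> <delta_profile> 80 residues: 40 increase, 40 decrease

decoy   <- make_decoy(bound, seed = 20210901)
d_decoy <- delta_fluctuations(gnm_fluctuations(decoy$model),
                              gnm_fluctuations(unbound))
decoy_comparison(delta, d_decoy, seed = 20210901)
#> <perturbation_summary> ratio 98.80% (mean +0.05517 over 40, mean -0.05584 over 40)
#>   decoy mean on increase set: 0.01131 (seed 20210901)

rad <- radial_profile(delta, bound)
round(rad$mean_delta[2:6], 4)
#> [1] -0.1006 -0.0656 -0.0541 -0.0532 -0.0516
```

Reading the numbers: binding splits the 80 residues into 40 gaining and 40
losing mobility. The mean gain (+0.0552, units of 1/γ) is 98.80% of the
mean loss — fluctuations lost at the pocket are almost fully compensated
elsewhere. The decoy control shows the effect is ligand-specific: a single
random bonded atom produces a mean gain of only 0.0113 on the very
residues the real ligand mobilized, five-fold smaller. The radial profile
confirms the spatial pattern: strong suppression in the 2.5–5 Å bin next
to the ligand, decaying with distance (and turning positive far away).

The same pipeline runs on real structures — `run_single()` for one
bound PDB file plus its ligand het codes, `run_manifest()` for a batch
screen across many (PDB path, ligand codes) pairs — writing a per-residue
TSV, a summary TSV, and a PDB with Δf painted into the B-factor column
for coloring in a molecular viewer. A thin command-line front end,
`exec/gnmflux`, exposes `gnm`, `delta`, `synth` and `screen` subcommands.

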