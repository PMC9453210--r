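# distfluct

Comparative analysis of protein internal dynamics from conformational
ensembles (molecular-dynamics trajectories or synthetic ensembles), built
for the question: *does a perturbation — a bound metal ion, a mutation — pin
a mobile loop and rigidify the region around a catalytic site?* The
motivating system is the gate/capping loop of collagen lysyl hydroxylase
(LH3/PLOD3), whose conformation controls access to the Fe²⁺/2-oxoglutarate
catalytic site, but the machinery applies to any pair of ensembles sharing
one topology.

## What it computes

For residues *i*, *j* with Cα–Cα distance *d<sub>ij</sub>(t)*:

- **Distance-fluctuation (DF) matrix** — DF<sub>ij</sub> = ⟨(d<sub>ij</sub> −
  ⟨d<sub>ij</sub>⟩)²⟩, the variance over frames of the inter-residue
  distance (Å²). Superposition-free and invariant under rigid-body motion;
  small DF marks quasi-rigid, coordinated pairs. Computed on the
  *meta-trajectory* (replicas concatenated, pooled variance).
- **Local-fluctuation (LF) profile** — LF<sub>i</sub> = mean of
  DF<sub>i,i+w</sub> over sequence neighbors w ∈ {−2, −1, +1, +2}; a
  per-residue flexibility profile.
- **F-test comparison** of two systems' DF matrices (F =
  DF<sup>test</sup>/DF<sup>ref</sup>, two-sided p), with optional
  multiple-testing correction and summarization of significant pairs into
  contiguous residue regions.
- **Loop RMSD series and open/closed classification** after Kabsch
  superposition on a non-loop fit set (threshold 3 Å, ≤ → closed), with
  state occupancies.
- **Catalytic-site SASA** per frame (Shrake–Rupley, probe 1.4 Å, 960
  points; site = residues within 6 Å of the ligand, frozen on the
  reference).
- **Contact persistence** (native and new steady contacts at 4.5 Å minimum
  heavy-atom distance) and **hydrogen-bond/salt-bridge tracking** between a
  loop residue and the ligand.
- A **synthetic two-chain ensemble generator** with a two-state Markov gate
  loop and analytically known DF, used as ground truth by the test suite.

See `vignettes/distance-fluctuation-analysis.Rmd` for the statistical
conventions and design choices.

## Worked example

Compare a "locked" system (gate loop pinned closed, stationary open
probability 0.05) against a "free" system (loop toggling, 0.5), three
replicas of 500 frames each:

```r
library(distfluct)

locked <- ensemble_spec(p_open = 0.05, n_frames = 500, seed = 1)
free   <- ensemble_spec(p_open = 0.5,  n_frames = 500, seed = 2)
ref      <- build_toy_reference(locked)
e_locked <- generate_replicas(locked, 3, "locked")
e_free   <- generate_replicas(free,   3, "free")

ca <- select_atoms(ref, "name CA")
df_locked <- df_matrix(e_locked, ca)
df_free   <- df_matrix(e_free, ca)
df_free
#> df_matrix: 120 residues, 1500 frames, system free ; max DF 12.92 A^2

cmp  <- f_test_matrix(df_free, df_locked, dof_test = 1499, dof_ref = 1499)
mask <- significant_pairs(cmp, alpha = 0.05)
mask
#> significance_mask: alpha 0.05 correction none ; 4303 of 7140 pairs flagged
summarize_regions(mask)
#>   chain start_resid end_resid n_residues n_flagged_pairs direction
#> 1     A         590       610         21            2499    higher
#> 2     B         590       610         21            2499    higher

loop <- select_atoms(ref, "chain A and resid 590-610 and name CA")
fit  <- selection_from_indices(ref,
          setdiff(select_atoms(ref, "chain A and name CA")$atom_idx,
                  loop$atom_idx))
classify_states(rmsd_series(e_free, ref, fit, loop), threshold = 3.0)
#> state_series: threshold 3 A; closed 0.444 / open 0.556
```

The comparison recovers exactly the residues whose dynamics differ — the
gate loop 590–610 on both chains, with *higher* DF in the free system — and
the state classifier recovers the generator's open fraction (0.556 observed
vs 0.5 stationary over 1,500 correlated frames). `run_compare()` executes
the same chain end-to-end from a YAML config (DF, LF, RMSD/states, site
SASA, contacts, salt bridge, F-test, regions) and writes all tables with a
parameter-stamped header:

```r
res <- run_compare(default_run_config(output_dir = "out", seed = 1))
```

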