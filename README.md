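# footmorph

Ontogenetic allometry and convergence of salamander foot morphology.

European cave salamanders (*Hydromantes* / *Speleomantes*) climb cave walls
and rock faces, and adults of all eight European species have extensively
webbed feet. Does that adult morphology *develop* during growth (allometry:
webbing increases with size), or is it *retained* from the juvenile state
(isometry)? And do species with different developmental routes nevertheless
converge on a common adult foot? footmorph implements the complete analysis
chain for asking these questions from ontogenetic series of museum
specimens:

* **Geometric morphometrics** — webbing sinuosity (outline perimeter over
  foot width, `p/d`), generalized Procrustes superimposition with Kendall
  tangent-space shape coordinates and centroid size (`gpa()`), and
  thin-plate spline deformation grids (`tps_grid()`).
* **Allometry inference** — per-species regressions of sinuosity on size
  with allometric/isometric regime coding (`fit_species_regressions()`,
  `code_trajectories()`); sequential ANCOVA of webbing and MANCOVA
  (Pillai's trace) of shape on species × size (`ancova_webbing()`,
  `mancova_shape()`); shape regression scores (`regression_scores()`); and
  the biomechanical foot-growth power law `A = b W^α` fitted on the log-log
  scale (`fit_power_law()`, `compare_growth_parameters()`).
* **Ontogenetic convergence** — a permutation test of the statistic
  `ΣD_juv − ΣD_adult`: the summed pairwise Euclidean distance among
  species' predicted juvenile morphologies minus the same sum among
  predicted adult morphologies, with significance from randomising specimen
  morphologies against the (species, size) design and refitting
  (`convergence_permutation_test()`).
* **Character evolution** — two-state equal-rates Mk maximum-likelihood
  ancestral reconstruction of growth regime on a phylogeny, with marginal
  node probabilities and transition counting
  (`reconstruct_ancestral_states()`).
* **Synthetic data** — a calibrated generator (`generate_dataset()`,
  `hydromantes_params()`) emulating an eight-species, 330-specimen
  ontogenetic series, plus a synthetic fixture phylogeny
  (`hydromantes_tree()`), so the entire pipeline is testable end to end.
  `run_all()` chains every stage into one reproducible, manifest-stamped
  run.

File formats: TPS landmark files (`read_tps()` / `write_tps()`, including
`SCALE=` handling), specimen covariate CSVs, and newick trees via ape.

## Worked example

```r
library(footmorph)

ds     <- generate_dataset(hydromantes_params(), hydromantes_tree(), seed = 1)
shapes <- gpa(ds$landmarks)
regs   <- fit_species_regressions(ds$specimens)

ct <- convergence_permutation_test(ds$specimens$sinuosity,
                                   ds$specimens$species_id,
                                   ds$specimens$foot_length,
                                   n_permutations = 9999, seed = 102)
pl <- fit_power_law(ds$specimens)
```

which prints (seed 1):

```
Synthetic ontogenetic dataset: 330 specimens, 8 species (24-54 each), seed 1

Generalized Procrustes superimposition
  configurations: 330  landmarks: 9
  iterations: 3  converged: TRUE

       species_id        beta1      se     t        p
1      H_ambrosii -0.005457698 0.00572 -0.95 0.346000
2        H_flavus -0.015329946 0.01260 -1.22 0.229000
3         H_genei  0.011271993 0.00956  1.18 0.246000
4    H_imperialis -0.007878052 0.00690 -1.14 0.260000
5      H_italicus  0.001295343 0.01080  0.12 0.905000
6 H_sarrabusensis -0.069113291 0.01740 -3.97 0.000653
7     H_strinatii -0.011297773 0.01020 -1.10 0.276000
8   H_supramontis -0.033595735 0.00965 -3.48 0.001020

Ontogenetic convergence test (sinuosity)
  sum D_juv = 8.9418, sum D_adult = 4.9039
  statistic (sum D_juv - sum D_adult) = 4.0379
  P_rand = 0.0002  (9999 permutations, raw morphologies shuffled)

Allometric foot-growth fit: A = b W^alpha, alpha = 0.7518, b = 0.1402 (R^2 = 0.976, n = 315)
```

Reading the output: the two species with clearly negative slopes
(*H. sarrabusensis*, *H. supramontis*) are coded **allometric** — webbing
increases as they grow — while the non-significant slopes code
**isometric**. The generator's third allometric species (*H. flavus*,
designed slope −0.0346 with standard error 0.0126, i.e. a true effect of
about 2.8 standard errors) is missed at this seed: at that evidence
strength the slope test has roughly 78% power, so single runs will
sometimes classify it isometric — a property of the design's evidence
strength, not of the estimator. The convergence statistic is strongly
positive with `P_rand = 0.0002`: species' predicted adult morphologies are
far more similar to one another than their predicted juvenile morphologies,
i.e. different developmental routes converge on a common webbed adult
foot. The foot-growth fit recovers the generating power law
(α = 0.75, b = 0.14), nearest to the climbing-adapted cave-dweller entry of
`growth_reference_table()`.

`run_all(run_config(out_dir, synthetic = list(params = hydromantes_params(),
tree = hydromantes_tree()), seed = 1))` writes all of the above plus the
ANCOVA/MANCOVA tables, regression scores, ancestral-state report, annotated
tree and a JSON manifest into `out_dir`, reproducibly for a given seed.

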