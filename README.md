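# voxnet

Voxel-based brain network analysis of multi-session fMRI.

`voxnet` is for researchers who want to treat every gray-matter voxel
as a network node and ask how the brain's functional network topology
differs between cognitive states and how stable it is across repeated
sessions of the same state. It implements the full chain from aligned
4D BOLD volumes to state-level inference:

1. **Preprocess** — extract gray-matter voxel time courses, band-pass
   0.009–0.08 Hz (zero-phase DFT mask), regress out intercept, 6
   motion parameters and mean global/white/CSF signals.
2. **Build networks** — all-pairs Pearson correlations, binarized at
   the correlation value that satisfies the density rule
   `N = K^S` (equivalently mean degree `K = N^(1/S)`; default
   `S = 3.0`), so connection density is comparable across sessions,
   subjects and node counts.
3. **Measure** — nodal and network degree `K`, global efficiency
   `E_glob(i) = (1/(N−1)) Σ_{j≠i} 1/d(i,j)` (BFS distances,
   unreachable pairs contribute 0) and local efficiency `E_loc(i)` =
   global efficiency of the subgraph induced on i's neighbors;
   optional clustering coefficient and path length.
4. **Map consistency** — per-subject maps of how often each voxel
   ranks in the top 20% of a metric across sessions, cross-subject
   meta maps, and group maps of voxels connected to the top 15% of
   regional nodes (majority rule across subjects).
5. **Test** — spherical-ROI means and fully within-subjects
   2 (condition) × S (session) repeated-measures ANOVAs with partial
   eta squared, `SS_effect / (SS_effect + SS_error)`.

Because voxel-level scanner data are rarely shareable, the package
includes a deterministic synthetic-study generator
(`generate_study()`) with planted condition-dependent connectivity: a
rest-dominant posterior-medial hub, independent small rest-coherent
modules, and a task-dominant fronto-lateral hub coupled to a distal
parietal region. Every stage of the pipeline is testable end-to-end
against this ground truth.

## Worked example

A full synthetic study — 5 subjects, 5 rest + 5 task alternating
sessions of 120 volumes at TR = 2 s, ~1300 gray voxels — runs in well
under a minute:

```r
library(voxnet)
res <- run_study(run_config(seed = 42))

aggregate(value ~ metric + condition, res$summary, mean)
#>   metric condition  value
#> 1  Eglob      rest  0.270
#> 2   Eloc      rest  0.222
#> 3      K      rest 10.856
#> 4  Eglob      task  0.290
#> 5   Eloc      task  0.182
#> 6      K      task 10.856
```

Mean degree is identical across conditions by construction (the
`N = K^S` rule fixes density), while whole-brain local efficiency is
higher at rest — the planted rest-state coherence is broader and more
locally clustered. The repeated-measures ANOVA quantifies that state
effect:

```r
res$anova[["wholebrain.Eloc"]]
#>              effect df_num df_den       SS SS_error       F        p partial_eta_sq
#> 1         condition      1      4 0.020400 8.52e-05 958.066 6.49e-06          0.996
#> 2           session      4     16 0.000162 6.42e-04   1.007 4.33e-01          0.201
#> 3 condition:session      4     16 0.000130 7.30e-04   0.713 5.95e-01          0.151
```

There is a large condition effect and no session effect: topology
differs between states but is stable across repeated sessions of the
same state. The regional picture shows the double dissociation of the
planted hubs (ROI-mean degree, 10 mm spheres at the hub coordinates):

```r
aggregate(value ~ scope + condition,
          res$roi_table[res$roi_table$metric == "K", ], mean)
#>      scope condition value
#> 1 rest_hub      rest 31.21
#> 2 task_hub      rest  8.41
#> 3 rest_hub      task 10.28
#> 4 task_hub      task 23.51
```

The rest hub is a degree hub only at rest; the task hub only during
task. `res$consistency` holds the session-consistency and
cross-subject meta maps, `res$roi_connectivity` the group maps of
nodes connected to top regional nodes, and `res$network_info` the
per-session threshold bookkeeping:

```r
res$network_info[1, ]
#>   subject condition session S n_nodes n_edges mean_degree r_threshold
#> 1  sub-01      rest       1 3    1280    6948       10.86      0.4904
```

(`1280^(1/3) = 10.858`; the realized mean degree matches the target to
within one edge.) Setting `output_dir` in `run_config()` additionally
writes summary TSVs, NIfTI metric/consistency volumes and a JSON
provenance manifest; `write_study()` + `run_study(mode = "files")`
round-trips the whole study through NIfTI and text files.

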