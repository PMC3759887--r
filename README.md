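# fociscan

Automated scoring of gamma-H2AX foci with cell-cycle sorting, for
radiation-biology workflows built on multichannel fluorescence z-stacks.

Radiation-induced DNA double-strand breaks recruit phosphorylated histone
H2AX (gamma-H2AX) into discrete nuclear foci; the mean number of foci per
nucleus tracks dose down to the mGy range. Automated counting, however,
must deal with the cell cycle: G2 nuclei carry roughly twice the focus
background of G1 (twice the genome), S-phase nuclei show a rough
pan-nuclear signal, M cells a bright uniform one, and touching nuclei
masquerade as single cells with doubled counts. fociscan reimplements a
scanning-platform workflow that solves this with two co-stains: nuclei are
segmented from DAPI, foci counted in the gamma-H2AX channel across focal
planes, and every nucleus is sorted by **nuclear area** (gates 50/130/250
"points" for debris / G1 / G2 / overlapped-or-polyploid, calibrated on a
CENP-F-labelled G2 population) and by its **pericentrin count** (1-2
signals expected; 0 or >= 3 invalidates the object, which also rejects
touching nuclei). Valid cells are classified into groups
(pericentrin count, 0-10 foci).

For a sample *s* the scorer reports the mean and SE of the capped focus
count over valid cells, the focus histogram, and the mean brightest-focus
intensity; dose contrasts use the two-sided Mann-Whitney U test (exact
permutation null for small groups, tie-corrected normal approximation
otherwise), and intensity-versus-dose and manual-versus-automatic
agreement are OLS fits.

Because no public image data exists for this assay, the package includes a
first-class synthetic sample generator with known ground truth: elliptical
nuclei with the bimodal G1/G2 area distribution, Poisson focus counts
whose means follow the measured dose response (1.12, 4.75, 5.23 foci/cell
at 0, 0.5, 1 Gy), focus diameter and brightness growing linearly with dose
(which reproduces overlap saturation), pericentrin intensity coupled to
nuclear area by a Gaussian copula (Spearman 0.4942), and pan-nuclear S/M
patterns.

## Worked example

Generate a 0.5 Gy sample of 1000 cells at the measured 0.5 Gy focus rate
(4.75 foci/cell), score it, and compare against an unirradiated control:

```r
library(fociscan)

cfg <- generator_config(
  doses_Gy = c(0, 0.5), cells_per_dose = 1000,
  control_mean_foci = 4.75, foci_per_Gy = 0, foci_rate_table = NULL,
  g2_background_multiplier = 1, s_fraction = 0, m_fraction = 0,
  allow_focus_overlap = FALSE, seed = 8102)

s   <- generate_sample(cfg, 0.5)          # 13 fields, 1000 nuclei
res <- score_sample(s$fields, capture_settings(),
                    sample_id = "d05", dose_Gy = 0.5)
res$summary
#> Sample d05 (0.5 Gy): 999 valid cells, 4.741 +/- 0.069 foci/cell

mean(s$truth$true_focus_count)            # generating truth for comparison
#> [1] 4.751
```

The pipeline recovered 4.741 detected foci/cell against a generated truth
of 4.751 — within one cell-level standard error — and 999 of the 1000
nuclei passed the validity gates (pericentrin 1-2, area class G1/G2,
interphase staining). `res$cells` holds the per-nucleus classification
(area points and class, pericentrin count, raw and capped focus count,
phase flag, class group, brightest-focus intensity), and
`compare_doses(control$cells, res$cells)` gives the Mann-Whitney contrast.

A command-line front end wraps the same functions:

```sh
Rscript inst/scripts/fociscan.R simulate --config cfg.yaml --out sim/
Rscript inst/scripts/fociscan.R score    --input sim/dose_0.5Gy --out scored/
Rscript inst/scripts/fociscan.R report   --out cmp.json scored_a/ scored_b/
Rscript inst/scripts/fociscan.R calibrate-gates --input labelled.csv
```

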