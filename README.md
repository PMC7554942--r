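# qfib — periportal collagen quantification for NASH fibrosis staging

`qfib` quantifies fibrillar collagen on dual-channel nonlinear microscopy
images of liver biopsies: second-harmonic generation (SHG, the collagen
channel) paired with two-photon excited fluorescence (TPEF, the tissue
channel). It is aimed at image-analysis and biostatistics teams working on
NASH clinical-trial screening, where the boundary between stage F1
(perisinusoidal fibrosis only) and stage F2 (perisinusoidal **plus**
periportal fibrosis) decides patient eligibility and is notoriously hard
to call on routine histology.

## The method

The core construction is geometric. Around every annotated portal tract
the package builds a **periportal region**: all tissue pixels whose
Euclidean distance *d* to the tract satisfies 0 < *d* ≤ 100 µm. The
remaining tissue (minus the tracts) is the **reduced perisinusoidal
(RPS)** region, so `portal ∪ periportal ∪ RPS = tissue` exactly,
pairwise-disjoint.

Collagen is segmented from the SHG channel, split into fiber strings
(8-connected components), and each fiber is measured — area *A*,
skeleton length *L*, mean width *W = A/L* — and classified by three
inclusive dichotomies: short/long (*L* ≥ 20 µm), thin/thick
(*W* ≥ 3 µm), distributed/aggregated (*A* ≥ 200 µm²). Per region and per
stratum (all / aggregated / distributed) the package computes collagen
area percentages, class-wise fiber counts, summed area/length/width, and
skeleton-branch-point (intersection) counts: 28 periportal + 28 RPS
parameters = the fixed 56-parameter vector per sample.

Cohorts of vectors are screened parameter-by-parameter with the
two-sided Wilcoxon rank-sum test at strict p < 0.05 (exact null for
small tie-free samples, tie- and continuity-corrected normal
approximation otherwise). A two-stage screen — discovery contrast, then
validation on true-F1 vs true-F2 cases — yields the discriminant panel:
applied to the reference validation table shipped with the package, the
rule retains 26 of 28 candidate parameters.

Because no clinical images ship with the method, the package includes a
calibrated synthetic-slide generator (`generate_slide()`,
`generate_cohort()`) with exact ground truth — stage-dependent fiber
patterns, portal tracts, noise — used by the entire test suite.

## Worked example

```r
library(qfib)

# one synthetic F2-like biopsy field (400 x 400 um) with ground truth
truth <- generate_slide(stage_profiles()$F2like, seed = 7)
q <- quantify_slide(truth$slide, truth$portal)
q$regions
#> <qfib_regions> 1024 x 1024 px, margin 100 um
#>   portal:        20297 px (3097 um^2)
#>   periportal:   281810 px (43001 um^2)
#>   rps:          360027 px (54936 um^2)
q$params
#> <qfib_params> sample 'F2like_7': 56 parameters
#>   %Periportal = 4.187, #StrPeriportal = 28, %RPS = 2.014, #StrRPS = 35
```

The printed region areas are the portal tracts, the 100 µm margin and
the perisinusoidal remainder; `%Periportal = 4.187` means collagen
covers 4.19% of the periportal region's area, and 28 fiber strings were
assigned to that region.

```r
# screen a synthetic cohort: 15 F1-like vs 15 F2-like samples
syn <- generate_cohort(15, stage_profiles()[c("F1like", "F2like")], seed = 7)
screen <- compare_groups(cohort_parameters(syn), "F1like", "F2like")
screen
#> <qfib_screen> 56 parameters tested, 26 significant at p < 0.05
#>                parameter      p_value
#>              %Periportal 3.225479e-06
#>           %PeriportalAgg 9.575620e-07
#>  ...
```

Every flagged parameter is from the periportal family — the two profiles
differ only in periportal fiber rate, and the screen localises the
effect accordingly.

```r
# the discriminant panel from the reference validation p-values
build_panel(reference_validation_pvalues(), alpha = 0.05)
#> <qfib_panel> 26 of 28 candidates retained at p < 0.05
#>   dropped: #ThinStrPeriportal (p = 0.054), #ThinStrPeriportalDis (p = 0.054)
```

File-based workflows (`qfib_simulate()`, `qfib_quantify()`,
`qfib_compare()`, `qfib_panel()`, `qfib_schema()`) mirror these calls on
TIFF/PNG/CSV/JSON inputs; `inst/exec/qfib` wraps them as a command-line
tool.

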