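# isletscape

Whole-slide morphometry, immune burden and spatial statistics of
pancreatic islets across stages of type 1 diabetes (T1D).

## The problem

Histopathology of the T1D pancreas is quantified islet by islet:
multiplexed brightfield staining of consecutive hormone markers (CHGA,
ProINS, INS, IAPP, ProGCG, GCG, SST, PPY) plus the pan-immune marker CD45
yields, per tissue section, one aligned image per stain. From these, a
reproducible analysis must (i) build islet objects — contiguous
endocrine-stain components ≥ 1000 µm² (equivalent diameter ≈ 36 µm),
hole-filled, excluding anything within 10 µm of the tissue border; (ii)
quantify per-islet hormone areas and deficiency phenotypes (a hormone is
deficient below 1% of islet area — the insulin-deficient islet, IDI, is
the histopathological hallmark of T1D); (iii) attribute CD45⁺ cells to
islet and 20 µm peri-islet compartments (non-overlapping, watershed-style)
and score insulitis (≥ 15 associated CD45⁺ cells; donor diagnosis at ≥ 3
such islets); (iv) phenotype single islets by UMAP + two-round DBSCAN on
a 13-feature vector (log stain areas, union endocrine area, islet area,
mean Delaunay area, CD45 count, circularity), with semantic cluster names
I–V-BC and a rule-based approximate key; and (v) measure spatial
organization with boundary-aware statistics:

- **modified Ripley's K**: for islet *i* and radius *r*,
  `K(r) = mean_i[ c_i(r) / w_i(r) ] / (λ π r²)`, where `c_i(r)` counts
  other islets within *r*, `w_i(r)` is the fraction of the disc inside
  the parenchyma, and λ is the overall islet density — 1 under complete
  spatial randomness, 2 at twofold density enrichment;
- **fractal dimension**: the log–log slope of the boundary-adjusted
  count over radii > 600 µm (2 for a uniform planar pattern);
- **Delaunay neighborhood metrics** (4 mm search radius; a neighbor-less
  islet falls back to distance 4 mm and area π·16 mm²), class-specific
  variants at 8 mm with "isolated islet" fractions, and back-projection
  maps.

Because the underlying whole-slide images are not freely
redistributable, the package includes a seeded synthetic cohort
generator (donor archetypes Ctrl / AAb / T1DS / T1DL × pancreas tail /
head) that plants islet geometry, composition, and CD45 point patterns
with exact ground truth, so the entire pipeline is testable end to end.
It is intended for quantitative pathology and islet-biology groups who
want the measurement chain without the interactive tooling.

## Worked example

```r
library(isletscape)

# a synthetic stage-1/2 (autoantibody-positive) pancreas-head section
sy  <- synth_section("AAb", "PH", seed = 7, width_mm = 6, height_mm = 6)
res <- analyze_section(sy$section, sy$stains, sy$points[, c("x", "y", "kind")])

length(res$islets$polygons)        # islets detected from the stain geometry
#> [1] 61
mean(res$profiles$idi)             # insulin-deficient islet fraction
#> [1] 0.04918033
sum(res$immune$insulitic)          # islets with >= 15 associated CD45+ cells
#> [1] 2
res$fractal                        # fractal dimension of the islet pattern
#> [1] 1.961915
head(res$delaunay$mean_delaunay_distance, 3)   # um, 4 mm search radius
#> [1] 1268.6770  537.7803 1616.6972
```

Detection recovers the planted geometry exactly — matching islets to the
generator truth gives intersection-over-union 1 and integer-exact CD45
counts:

```r
m <- match_islets_to_truth(res$islets, sy)
min(m$iou)
#> [1] 1
all(res$immune$intra_cd45 == sy$truth$cd45_intra[m$truth_id])
#> [1] TRUE
```

A full cohort runs from a single configuration:

```r
cfg <- pipeline_config(seed = 1, donors_per_group = 2)  # 8 donors, 4 groups
run <- run_pipeline(cfg, outdir = "run1")
rep <- cohort_report(run)
rep$group_means[, c("group", "idi_fraction", "frac_ge1_cd45")]
#>      group idi_fraction frac_ge1_cd45
#> AAb    AAb   0.10636501     0.4723486
#> Ctrl  Ctrl   0.02951389     0.2586806
#> T1DL  T1DL   0.99132948     0.2687861
#> T1DS  T1DS   0.72222222     0.5208333
```

The IDI gradient (Ctrl ≈ 2% → T1DL ≈ 99%) and the immune-burden contrast
(about a quarter of control islets versus about half of AAb/T1DS islets
carrying ≥ 1 associated CD45⁺ cell) are the planted stage structure
recovered through the full measurement chain. A thin command-line
front-end (`inst/cli/isletscape`) wraps `simulate`, `run` and `report`.

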