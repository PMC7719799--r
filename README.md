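# synovetc

Is rheumatoid-arthritis synovitis one disease per patient, or one per joint?
`synovetc` implements the analysis pipeline for paired synovial biopsies —
one small joint (hand/wrist) and one large joint (knee) sampled from the
same patient on the same day — combining TCRβ repertoire sequencing with
UMI-based molecule counting, microarray-style expression profiling against
an osteoarthritis (OA) reference, and semiquantitative histology. It is
aimed at translational rheumatology and immune-repertoire analysts who want
the complete chain, from UMI-tagged reads to within-patient concordance
statistics, as tested, scriptable R functions.

A built-in synthetic-data generator produces blood and paired-joint
repertoires, expression matrices and histology scores with planted ground
truth, so the whole pipeline can be exercised and validated without any
external download.

## The statistics at its core

**Enriched T cell clonotypes (ETC).** Clonotypes are unique productive TCRβ
rearrangements (V gene, J gene, CDR3 junction). UMIs give absolute molecule
counts per clonotype. Each synovial clonotype is compared against a random
subsample of n = 20,000 blood molecules; a clonotype absent from the
subsample has its blood frequency censored at the detection floor 1/20,000.
A clonotype is an ETC when

1. it is represented by at least 10 TCRβ molecules in the synovium,
2. its synovial frequency is ≥ 100-fold its estimated blood frequency, and
3. the one-sided exact binomial p-value
   P(X ≥ k), X ~ Bin(N_syn, f_blood), is below 10⁻⁶.

An ETC of one joint is *shared* when the same rearrangement is detected at
all in the patient's other joint; the headline fraction divides the shared
clonotypes by the union of distinct ETC across both joints.

**Pathway gene scores.** For a pathway G and RA sample s, the score is
median over probes g ∈ G of ( x_gs − mean over OA samples of x_g ), on the
log2 scale — the median fold change against the OA reference.

**Within-patient concordance.** Per probe, the one-way single-rater
intra-class correlation ICC(1,1) = (MSB − MSW) / (MSB + MSW) of the
small/large pairs; the median per-probe ICC under the real patient pairing
is compared against random derangement re-pairings (permutation p-value
with add-one correction). Paired ordinal histology scores are compared by
Spearman rank correlation per marker.

## Worked example

Simulate one patient of the default study design (20,000 UMI molecules per
sample, 5,000 background blood clonotypes, five planted expansions of 1%
tissue frequency per joint) and detect ETC:

```r
library(synovetc)

cfg <- simulation_config(seed = 42)
sim <- simulate_patient(cfg, 1)

sub <- subsample_blood(sim$blood, n = 20000, seed = 42)
etc_small <- detect_etc(sim$joint_small, sub)
head(as.data.frame(etc_small), 5)
#>   v_call  j_call synovial_count synovial_freq blood_est_frequency fold p_value
#> 1  TRBV4 TRBJ1-1            205       0.01025               5e-05  205       0
#> 2 TRBV11 TRBJ2-5            201       0.01005               5e-05  201       0
#> 3 TRBV17 TRBJ2-7            199       0.00995               5e-05  199       0
#> 4 TRBV22 TRBJ2-2            194       0.00970               5e-05  194       0
#> 5 TRBV24 TRBJ1-3            194       0.00970               5e-05  194       0

shared_etc(etc_small, detect_etc(sim$joint_large, sub),
           sim$joint_small, sim$joint_large)
#> Shared-ETC summary, patient P01
#>   ETC small joint: 5, large joint: 5 (union 5)
#>   shared: 5 (100% of union)
```

Each detected clonotype sits at ~1% of the joint repertoire (about 200
molecules), is absent from the blood subsample (blood frequency censored at
5 × 10⁻⁵, hence fold ≈ 200), and clears the binomial significance bar by a
wide margin; this patient's expansions happen to all be systemic, so every
ETC is found in both joints.

The full pipeline (`run_pipeline()`) chains UMI collapse, repertoire
construction, blood subsampling, ETC and shared-ETC detection, pathway gene
scores, T-cell-rich/poor stratification, real-vs-random ICC, histology
concordance and the pair-level correlations, and writes a JSON + TSV report
with a config-hash provenance block.

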