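# aicescan

Genome mining for integrative and conjugative elements (ICEs) in
high-G+C actinobacteria.

Actinomycete ICEs (AICEs) integrate into the 3' end of a tRNA gene
between two short direct repeats (*attL*/*attR*), excise as circles by
site-specific recombination (*attB* + *attP*), replicate autonomously
through a rolling-circle or primase-polymerase initiator, and — unlike
the T4SS-driven ICEs of Gram-negative bacteria and Firmicutes — conjugate
as double-stranded DNA through a single FtsK/SpoIIIE-family translocase.
`aicescan` turns that biology into an auditable pipeline for genome
collections:

* **profile search** — position-specific log-odds profiles (built from
  protein alignments, scored by semi-global affine-gap dynamic
  programming, thresholds calibrated from an embedded shuffled null)
  assign module roles to CDS: integrase (Int-Tyr / Int-Ser), replication
  initiator (RepSA, RepAM, Prim-Pol with its RepPP partner, plus optional
  further Rep families), transfer (FtsK/SpoIIIE), and the T4SS triplet
  (T4CP, VirB4-like, MOB_F relaxase). Externally computed hit tables
  (e.g. HMMER + Pfam) drop in via `read_hits_tsv()`;
* **element calling** — a region within a 60-kb window carrying all three
  core modules is an AICE candidate; candidates whose integrase lies
  between the rep and tra genes are rejected; two-of-three regions are
  remnants; Int + T4CP + VirB4 + MOB_F (replication optional) calls a
  T4SS-type ICE; a plasmid carrying Int + Tra + Rep is an element in its
  excised form;
* **att resolution** — seed-and-extend direct-repeat search delimits each
  element at tRNA-anchored attL/attR pairs, handles multi-attL and tandem
  arrangements, and reconstructs every excision circle in silico with an
  exact sequence-conservation guarantee;
* **subfamilies** — bootstrapped protein trees are cut into clades with
  ≥ 4 members, patristic diameter ≤ 1 (or 2 for transfer proteins) and
  support > 80, with a p-distance NJ + bootstrap fallback for desk-scale
  work and motif frequency matrices for the HUH/catalytic-tyrosine
  hallmarks of rolling-circle initiators;
* **summaries** — per-domain hit tables (complete vs draft genomes) and
  element distributions per host suborder, environmental niche or
  genome-size bin;
* **synthetic genomes** — `simulate_genome()` plants elements, remnants
  and decoys into high-G+C replicons with a machine-readable truth table,
  so every stage of the pipeline is testable end to end without
  downloads.

Results are tibbles throughout; scan results carry `tidy()`, `glance()`
and plotting helpers. A thin command-line front-end
(`exec/aicescan`: `simulate`, `scan`, `subfam`, `summarize`) wraps the
same functions for shell use.

## Worked example

```r
library(aicescan)

sim <- simulate_genome(seed = 1)   # 500-kb circular chromosome, G+C 0.70
sim$replicon
#> <Replicon syn0001: circular chromosome, 526,142 bp, 246 features (236 CDS, 10 tRNA)>

res <- scan_replicon(sim$replicon)
res$elements[, c("element_id", "status", "start", "end", "repeat_len", "trna_anchor", "gc")]
#> # A tibble: 3 × 7
#>   element_id         status    start    end repeat_len trna_anchor    gc
#>   <chr>              <chr>     <dbl>  <dbl>      <int> <chr>       <dbl>
#> 1 syn0001_elem_00107 AICE     107685 114422         50 trna_03     0.639
#> 2 syn0001_elem_00238 T4SS_ICE 238515 243399         50 trna_05     0.628
#> 3 syn0001_elem_00459 AICE     459303 466927         50 trna_09     0.623

res$products[, c("element_id", "circle_len", "composite")]
#> # A tibble: 3 × 3
#>   element_id         circle_len composite
#>   <chr>                   <int> <lgl>
#> 1 syn0001_elem_00107       6688 FALSE
#> 2 syn0001_elem_00238       4835 FALSE
#> 3 syn0001_elem_00459       7575 FALSE
```

The genome carried two planted AICEs, one T4SS-type ICE, one remnant and
three decoys. Both AICEs and the T4SS ICE are recovered with their
planted 50-bp att repeats and exact boundaries (each element spans
attL start to attR end; `trna_anchor` names the tRNA whose 3' end is
duplicated as the repeat; `gc` is the element's G+C fraction, depressed
relative to the 0.70 host by low-G+C cargo). Each element yields one
excision circle whose length obeys
`circle_len = (attR_end − attL_start + 1) − repeat_len`, and the
post-excision chromosome plus circle reconstitute the input sequence
exactly. The remnant (integrase + replication gene, no transfer gene) is
reported separately and never counted as an element:

```r
scan <- run_scan(list(sim$replicon), seed = 1)
scan
#> <aice_scan: 1 replicon(s); 2 AICE, 1 T4SS ICE, 1 remnant, 0 rejected; 3 excision product(s)>
glance(scan)
#> # A tibble: 1 × 8
#>   n_replicons n_aice n_t4ss_ice n_plasmid_ice n_remnant n_rejected n_products mean_element_gc
#> 1           1      2          1             0         1          0          3           0.630
```

`run_scan(..., out_dir = "out")` writes TSV/GFF3/JSON reports plus a run
log; `tidy(scan, "hits")`, `tidy(scan, "regions")` etc. expose every
intermediate table. See the methods vignette
(`vignettes/aicescan-methods.Rmd`) for the model, the parameter defaults
and the design decisions behind them.

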