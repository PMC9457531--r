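# bbrpath

Comparative-genomics inference of essential, taxon-restricted enzymes in
the bacterial biodegradation of berberine (BBR), a plant isoquinoline
alkaloid used as a botanical pesticide.

## The problem

BBR disappears from soil water while particular bacterial genera — above
all *Methylotenera* — bloom transiently, yet every strain that can be
cultured from the same water fails to degrade the compound, alone or in
consortium. The degradation step the culturable community cannot supply
must then sit in the uncultivable, enriched taxa. `bbrpath` implements the
pipeline that localises that step:

1. **Align** the numbered enzymes of the plant BBR biosynthesis pathway
   (protein queries) against bacterial genomes — six-frame translation plus
   Smith–Waterman local alignment with affine gaps (BLOSUM62, gap open 11,
   extend 1; `X`/`*` score −4).
2. **Call presence** of an ortholog when the best hit has per-column
   similarity > 30% and query coverage ≥ 50%, giving an enzyme × genome
   presence/absence matrix.
3. **Cross-classify** presence against genome roles: an enzyme present in
   an enriched-genus genome but in *no* cultivable non-degrader isolate is
   an `essential_candidate` — in the motivating system, enzyme 9,
   tetrahydroisoquinoline N-methyltransferase, restricted to
   *Methylotenera*.
4. **Community stage**: genus relative-abundance time series and
   degradation curves identify which genera are degradation-associated
   (enriched only where the compound decays) in the first place.
5. **Motif stage**: center-star MSA of methyltransferase homologs and a
   wildcard scan for the conserved glycine-rich `GCGxG` active-site motif.
6. **Hit-table summary**: genus-level distribution of the top-500 homology
   hits on the genus-resolved denominator.

A seeded synthetic-data generator produces genomes with planted orthologs,
abundance series and degradation curves with known ground truth, so the
entire pipeline is testable without any external database.

## Worked example

Generate the default planted-truth scenario (26 enzymes of 300 residues;
one enriched-genus genome carrying orthologs of enzymes 1, 2, 3, 9, 24 at
60% identity; eight isolate genomes carrying 1, 2, 3, 24; 50 kb genomes
with decoy ORFs), then run the mapping and the essentiality logic:

```r
library(bbrpath)
scn <- generate_scenario(scenario_config(seed = 42))
res <- scenario_essentiality(scn)   # presence matrix + classification
print(res$report)
```

```
Essentiality report (26 enzymes; enriched rule: any)
  essential_candidate  1
  shared               4
  isolate_only         0
  absent               21
  essential candidate(s): 9
```

Enzyme 9 — planted only in the enriched genome — is recovered as the
unique candidate. The similarity values behind the calls (per cent, best
hit per genome) show why:

```r
round(res$matrix$similarity[c("1","2","3","9","24"),
                            c("enriched_Methylotenera","isolate_J1")], 1)
```

```
   enriched_Methylotenera isolate_J1
1                    65.7       63.0
2                    64.0       63.0
3                    63.7       64.6
9                    65.0       48.1
24                   64.7       65.3
```

Row 9 in `isolate_J1` (48.1% similarity) is a short chance alignment; it
fails the 50% coverage floor and is correctly absent. The genus
distribution stage reproduces the headline worked number — with 219 of 500
hits resolved to a genus and 11 of them *Methylotenera*:

```r
gd <- genus_fraction(top_hits(hits, 500))
gd$rows[gd$rows$genus == "Methylotenera", ]
#>           genus count pct_of_resolved
#> 4 Methylotenera    11            5.02
```

A thin CLI over the same functions is installed at `exec/bbrpath`
(subcommands `simulate`, `map`, `essential`, `enrich`, `motif`,
`distribution`).

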