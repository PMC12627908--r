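# uceforge

Design target-capture probe sets for ultraconserved elements (UCEs), test them
by in-silico capture, and compute the downstream locus-matrix statistics — all
in R, validated end to end on synthetic clades with planted conserved
elements.

## Who this is for

Phylogenomics practitioners building UCE bait sets from soft-masked genome
assemblies (the workflow popularized for arthropod and vertebrate clades), and
method developers who need a desk-scale, fully inspectable re-implementation
of that workflow with ground-truth validation: every stage is a plain R
function over data frames, and a synthetic-clade generator plants conserved
cores along a phylogeny so recovery can be scored against a known answer key.

## The method in brief

A *base* genome supplies coordinates; *exemplar* genomes supply cross-taxon
evidence. Error-free 100-bp paired reads simulated from each exemplar are
mapped to the base tolerating mismatch fraction ≤ 0.05; surviving placements
are merged (gap < 100 bp) and stripped (> 25 % soft-masked, any ambiguous
base, or < 80 bp ⇒ removed). Loci detected in ≥ k exemplars ("+k") are carried
forward: 160-bp centered windows are extracted, 120-bp probes are tiled at 3×
density (40-bp step plus an anchored final probe), screened for GC outside
[30 %, 70 %] and > 25 % masking, purged of cross-matching loci, aligned back
to every genome at ≥ 50 % identity (multi-hit loci removed), and 180-bp
buffered slices from every genome yield the final multi-taxon probe set.
Capture aligns probes to an assembly, slices matches + 400-bp flanks, and
enforces a one-to-one probe↔locus screen (80 % identity / 80 % coverage
in-silico; 60/60 preset for assembled contigs). Downstream, completeness-
filtered matrices give supermatrices with partition files,
parsimony-informative site counts, uncorrected *p* and Kimura-1980 distances
under pairwise deletion

    p = mismatches / valid sites
    d_K80 = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)

(P, Q = transition and transversion fractions), binary SNP matrices
(biallelic, < 25 % missing), and PCA scores.

## Worked example

```r
library(uceforge)

# a 4-taxon clade, 100-kb genomes, 20 planted conserved cores
cl <- generate_clade(n_taxa = 4, genome_len = 1e5, n_loci = 20, seed = 7)

disc <- uce_discover(cl$genomes, base_taxon = "t1", seed = 7)
disc$table
#> <locus_presence_table> 20 loci, 3 exemplars (t2, t3, t4)
#>  locus_id scaffold start   end  support
#>     uce-1    scaf1  1050  1274 t2,t3,t4
#>     uce-2    scaf1  6915  7119 t2,t3,t4
#>     uce-3    scaf1  9205  9402 t2,t3,t4
#>     uce-4    scaf1 11241 11417 t2,t3,t4
#>     uce-5    scaf1 13849 14056 t2,t3,t4
#>     uce-6    scaf1 18862 19076 t2,t3,t4
#> ... and 14 more

des <- uce_design(disc$table, cl$genomes, "t1", min_exemplars = 3)
des$report
#>     table_loci  selected_loci design_regions    temp_probes      temp_loci
#>             20             20             20             40             20
#>   final_probes     final_loci
#>            218             20

score_recovery(cl$truth, disc$table)[c("sensitivity", "false_loci")]
#> $sensitivity
#> [1] 1
#>
#> $false_loci
#> [1] 0

caps <- capture_all(des$probes, cl$genomes)   # self-capture, 80/80 screen
caps$counts
#>   taxon loci_extracted loci_removed loci_retained
#> 1    t1             20            0            20
#> 2    t2             20            0            20
#> 3    t3             20            0            20
#> 4    t4             20            0            20
```

Every planted core is recovered (`sensitivity = 1`) with no false loci; the
design report gives the per-stage accounting (shared-locus table → temporary
probes → final probes/loci), and self-capture retains all 20 loci in
each taxon through the duplicate screen. On the full-scale validation clade
(6 taxa, 1-Mb genomes, 300 cores) the same pipeline recovers ~84 % of planted
loci at "+5" with zero false loci — the vignette explains which filter absorbs
the remainder and why that is a property of the method, not a bug.

A thin CLI wraps the same functions for shell use:

```sh
Rscript inst/cli/forge.R synth --taxa 6 --loci 300 --seed 7 --out clade/
Rscript inst/cli/forge.R design --genomes clade/ --base t1 \
    --min-exemplars 5 --out design/
```

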