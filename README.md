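# vsdscout

Voltage-sensing domains (VSDs) are compact four-transmembrane-helix
modules (S1–S4) that move in response to membrane potential; they power
voltage-gated ion channels (Kv, Nav, Cav, the proton channel Hv),
voltage-sensing phosphatases (VSP), and — fused to a fluorescent
protein — genetically encoded voltage indicators (GEVIs). `vsdscout` is
an R toolkit for finding candidate VSDs in protein sequences and
turning them into chimeric GEVI designs. It is aimed at protein
engineers who want to mine newly sequenced genomes for voltage-sensor
donors without depending on web servers or external databases.

## What it computes

The search exploits a conserved charge architecture in the **S2**
helix: a bulky hydrophobic anchor, an acidic residue three positions
downstream and a basic residue seven positions downstream,

```
Fxx[E,D]xxx[R,K]        (strict)
[F,Y,W]xx[E,D]xxx[R,K]  (relaxed)
```

where `x` is any residue. Around each motif hit the pipeline:

1. predicts transmembrane helices from windowed **Kyte–Doolittle
   hydropathy** (window 19, threshold 1.6 by default);
2. assembles an **S1–S4 architecture call** — the motif must sit inside
   a helix (S2) with one helix before (S1) and two after (S3, S4),
   within loop/span bounds befitting a compact sensor;
3. fingerprints the extracted **S4** helix by the periodicity of its
   basic residues and classifies it against family templates,
   `R-x-x-R-x-x-R` for Hv and `R-x-x-R-x-x-I-x-x-R-x-x-(R/H)` for VSP
   (user templates can be added);
4. optionally clusters candidate VSDs with pairwise Needleman–Wunsch
   alignment (BLOSUM62), p-distances and a **neighbor-joining tree**
   written as Newick;
5. builds **chimeric GEVIs** by swapping a donor's S1–S4 span into a
   scaffold sensor (N-terminus ++ donor VSD ++ linker+FP), with a part
   map and a protein-level note marking the BamHI/EcoRV cloning
   cassette.

A deterministic generator of synthetic proteins with planted VSD
architectures (`generate_planted_proteome()`) makes the whole pipeline
testable offline.

## Worked example

```r
library(vsdscout)

px  <- generate_planted_proteome(4, family = c("Hv", "VSP"), seed = 20)
res <- run_pipeline(px$records, default_run_config())
#> [vsdscout] records=4 hits=4 candidates=4 classified=4

res$candidates[, c("record_id", "s1_start", "s2_start", "s3_start",
                   "s4_start", "s4_end", "anchor_pos")]
#>   record_id s1_start s2_start s3_start s4_start s4_end anchor_pos
#> 1 synth0001       26       64      104      154    178         73
#> 2 synth0002       29       71      111      161    180         80
#> 3 synth0003       32       75      119      162    188         84
#> 4 synth0004       30       73      128      173    191         83

res$classifications[, c("record_id", "label", "basic_count",
                        "spacing_vector")]
#>   record_id label basic_count spacing_vector
#> 1 synth0001    Hv           3            3,3
#> 2 synth0002   VSP           4          3,6,3
#> 3 synth0003    Hv           3            3,3
#> 4 synth0004   VSP           4          3,6,3
```

Each row is one architecture call: the four helix starts, the S4 end,
and the position of the S2 anchor. The classification table shows the
family label, how many R/K residues the S4 helix carries and their
spacings — `3,3` is the Hv signature (three arginines every third
residue), `3,6,3` the R/K spacing left by the VSP pattern's central
isoleucine. Real proteomes go in the same way via
`read_fasta("proteome.fasta")`, or from a shell:

```sh
exec/vsdscout scan proteome.fasta --mode relaxed --out hits.tsv
exec/vsdscout run  proteome.fasta --tree --out-dir results/
```

Chimera design takes a scaffold definition (sequence plus
N-terminus/VSD/linker+FP spans, see `scaffold_sensor()` or a JSON file
for `read_scaffold()`) and any candidate row:

```r
design <- build_chimera(scaffold, res$candidates[1, ], px$records[1, ])
flank_for_cloning(design)
#> Swapped VSD cassette (donor synth0001) occupies product residues 31-183;
#> at the DNA level this segment is the BamHI/EcoRV cassette of the
#> cloning scheme.
```

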