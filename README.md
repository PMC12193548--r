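# rnaformats

Parse, validate, translate, abstract and summarize RNA secondary
structures from R or from the shell.

RNA molecules fold into structures that determine their function, and the
standard computational abstraction of that fold — the *secondary
structure* — is a nucleotide sequence annotated with base pairs, drawn as
an arc diagram: nucleotides `1..n` on a backbone, each pair `(i, j)` an
arc. The field encodes this one object in many incompatible files: BPSEQ
and CT pairing tables, extended dot-bracket strings, arc-annotated
sequence (AAS) pair lists, FASTA (sequence only), and the XML-based RNAML
emitted by structure-extraction tools such as RNAView. Comparison and
classification pipelines routinely need all of them, plus reduced
"skeleton" views of each structure for motif censuses. This package is
for people building such pipelines: it provides

- **readers and writers** for the six formats (eight variants: dot-bracket
  and AAS each exist with and without a sequence line), with strict and
  lenient parsing, verbatim retention of headers and `#` comments, and
  auto-detection;
- **translation** between formats under the compatibility matrix
  (sequence-carrying formats convert to anything; structure-only variants
  only to each other; FASTA to nothing), in single-file and batch mode,
  with non-canonical pairs from RNAML diverted to a CSV side file;
- **extended dot-bracket rendering of pseudoknots** by first-come-first-served
  page assignment: arcs are visited in 5' order and each takes the lowest
  bracket family (`()`, `[]`, `{}`, `<>`, then `Aa`..`Zz`) on which it
  crosses nothing already placed;
- **three arc-diagram abstractions** — *core* (remove unpaired
  nucleotides, then collapse parallel arcs), *core plus* (collapse first,
  then remove; bulges block collapsing, so more arcs survive) and *shape*
  (keep only mutually crossing arcs; pseudoknot-free molecules reduce to
  the empty "Null Shape", an H-type pseudoknot to `([)]`);
- **statistics**: per-molecule length, A/C/G/U counts, bonds and G-C/A-U/G-U
  pair-class counts, with mean and sample standard deviation over a
  collection;
- a **synthetic structure generator** (hairpins, bulged helices, H-type
  and nested pseudoknots, canonical sequences) so everything is testable
  without downloads, and a **command-line interface** for batch runs.

## Worked example

```r
library(rnaformats)

hp <- rna_structure("GGGAAACCC", list(c(1, 9), c(2, 8), c(3, 7)))
hp
#> RNA secondary structure: 9 nt, 3 base pairs
#>   GGGAAACCC
#>   (((...)))
#>   pseudoknotted: FALSE

pk <- h_pseudoknot(3, 3, c(3, 3, 3), seed = 42)
pk
#> RNA secondary structure: 21 nt, 6 base pairs
#>   CGUACUCGGUGUGUGACUCCG
#>   (((...[[[...)))...]]]
#>   pseudoknotted: TRUE
```

The two stems of `pk` cross, so the second needs a new bracket family
(`[[[`). Its shape keeps only the crossing skeleton — the canonical
H-type pattern — while the hairpin `hp`, having no crossing, has the null
shape:

```r
abstraction_label(pk, "shape")
#> [1] "([)]"
abstraction_label(hp, "shape")
#> [1] "Null Shape"
```

Core versus core plus is observable on a bulged helix: the bulge at
position 3 blocks one collapse before unpaired removal, but not after.

```r
bulged <- rna_structure(pairs = list(c(1, 10), c(2, 9), c(4, 8)), length = 10)
abstraction_string(bulged, "core")
#> [1] "()"
abstraction_string(bulged, "coreplus")
#> [1] "(())"
```

Statistics count nucleotides, bonds and unordered pair classes:

```r
cat(stats_csv(structure_stats(pk, "pk.example"), NULL))
#> file,length,bonds,A,C,G,U,GC,AU,GU
#> pk.example,21,6,2,6,7,6,4,0,2
```

Here `pk.example` has 6 base pairs: 4 G-C, 0 A-U and 2 G-U wobble pairs.
Translation round-trips through any sequence-carrying format:

```r
ct <- render_rna(hp, "CT")       # connect table text
parse_rna(ct, "CT")$pairs        # identical pair set back
can_translate("FASTA", "CT")     # FALSE: no structure to convert
```

From the shell:

```sh
rnaformats translate --to CT --out-dir out/ structures/
rnaformats abstract --kind shape structures/   # file,kind,abstraction_string CSV
rnaformats stats structures/                   # per-file rows + Mean/St.Dev
rnaformats detect structures/*.txt
```

Exit codes: 0 success, 1 any per-file failure (the batch continues), 2
usage error.

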