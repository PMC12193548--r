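---
title: "RNA secondary structure formats, pseudoknot pages, and arc-diagram abstractions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RNA secondary structure formats, pseudoknot pages, and arc-diagram abstractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaformats)
```

## The model

An RNA secondary structure is the abstraction of a folded single-stranded
molecule as its nucleotide sequence plus a set of base pairs. We represent
it as an arc diagram: nucleotides `1..n` on a straight backbone, each base
pair an arc `(i, j)` with `i < j` in the upper half-plane. Two arcs
`(i1, j1)` and `(i2, j2)` *cross* when they interleave
(`i1 < i2 < j1 < j2`); a structure with at least one crossing is
*pseudoknotted*, otherwise it is pseudoknot-free (fully nested). Each
nucleotide participates in at most one pair — tertiary contacts,
base triples and multi-strand complexes are out of scope.

Coordinates are 1-based and inclusive throughout, matching the BPSEQ and
CT conventions; renumbering happens only inside the abstraction operators.
Sequences are upper-cased on ingest; `T` is accepted, preserved verbatim,
and treated as `U` for pair classification, since DNA-alphabet files occur
in the wild. The empty structure (length 0, no pairs) is legal and
round-trips through every structure format.

```{r}
hp <- rna_structure("GGGAAACCC", list(c(1, 9), c(2, 8), c(3, 7)))
hp
is_pseudoknotted(rna_structure(pairs = list(c(1, 5), c(3, 7)), length = 8))
```

## Formats and dialect rules

Eight format variants are supported: BPSEQ, CT, extended dot-bracket with
and without a sequence line, arc-annotated sequence (AAS) with and without
a sequence line, FASTA, and RNAML. The readers tolerate blank lines and
CRLF endings everywhere; `#`-prefixed lines are captured verbatim as
comments, and each format's designated metadata slot (a `>` line, the CT
name field, the RNAML molecule name) is captured as the header, so the
keep/drop options of `render_rna()` are lossless. Writers emit `\n`
endings and never emit blank lines.

Dialect decisions worth knowing:

* **BPSEQ** rows are `position base mate` with `0` for unpaired. Strict
  mode requires contiguous positions `1..n` and symmetric pairing records
  (if line `i` claims `j`, line `j` must claim `i`); lenient mode fills
  missing positions as unpaired `N`, which accommodates
  structure-extraction output that omits unresolved residues.
* **CT** rows are `i base i-1 i+1 mate i`. The 5'/3'-connect and original
  index columns are written by that law and ignored on read, since only the
  mate column carries structure. The first line is `<length> <name>`;
  with headers dropped the name falls back to `molecule`.
* **Dot-bracket** uses `.` for unpaired only (`-` is accepted as `.` in
  lenient mode). Bracket matching is per symbol family; uppercase letters
  open and lowercase letters close.
* **AAS** is the pair list `(i1,j1);(i2,j2);...` with an optional leading
  sequence line. A structure-only pair list cannot encode trailing
  unpaired residues, so the writer records the total length in a
  `# length=n` comment, which the reader honours; without it the length is
  the largest paired index. The dialect has no header slot, so carried
  headers are dropped with a warning.
* **RNAML** is read in its interoperable core: one molecule, absolute
  1-based positions, pairs from `base-pair` elements and from `helix`
  elements expanded to their stacked pairs; only the first `model` is
  consulted. The writer emits `base-pair` elements only, which is the
  simplest invertible choice.

Format detection tries the grammars in the fixed precedence order RNAML,
CT, BPSEQ, dot-bracket, AAS, FASTA. CT precedes BPSEQ because a CT body
row is a superset pattern of a BPSEQ row; dot-bracket precedes AAS. A
FASTA record is distinguished from a pairless AAS file by its `>` header,
which the strict AAS grammar rejects.

## Translation and the compatibility matrix

Translation goes through the internal arc diagram: parse, optionally
partition, render. A format carrying sequence and structure (dot-bracket,
RNAML, CT, BPSEQ, AAS) converts into anything; the structure-only variants
convert only into each other because a sequence cannot be invented; FASTA
carries no structure and converts into nothing. `can_translate()` exposes
the full 8×8 matrix and is checked cell by cell in the tests.

RNAML produced by structure-extraction tools (e.g. RNAView run on PDB
entries) may contain non-canonical pairs such as C–C or G–G. The canonical
set is `{G–C, A–U, G–U}` — Watson-Crick-Franklin pairs plus the wobble
pair, classified by nucleotide identity only. Non-canonical pairs never
enter the plain-text formats; with `retain_noncanonical = TRUE` they are
exported to a CSV side file (`molecule,position_5p,base_5p,position_3p,base_3p`),
otherwise discarded. If the canonical partition leaves a nucleotide paired
twice, strict mode errors naming the positions; lenient mode keeps the
first-encountered pair.

`batch_translate()` processes inputs in lexicographic path order and
records per-file failures without aborting, so one corrupt file cannot
spoil a large conversion run.

## Pseudoknot pages: first-come-first-served

Extended dot-bracket needs one bracket family per "page" of mutually
non-crossing arcs. Pages are assigned greedily, first come first served:
pairs are visited in ascending 5' index (openings are unique, so no ties
arise) and each takes the lowest page on which it crosses no previously
placed pair. Pseudoknot-free input therefore renders with `()` and `.`
only. The family order is `()`, `[]`, `{}`, `<>`, then `Aa`..`Zz` — 30
pages in total; exceeding them is an explicit error rather than a silent
wrap-around. Greedy assignment is not guaranteed minimal; the tests assert
only that it never beats the exact chromatic number of the crossing graph
on small instances.

```{r}
render_brackets(list(c(1, 4), c(2, 5), c(3, 6)), 6) # three mutual crossings
parse_brackets("(.[.).].")
```

## The three abstractions

Two arcs are *parallel* when they are nested with adjacent endpoints on
both sides: `(i1, j1)` and `(i1+1, j1-1)` with no vertex between the 5'
endpoints nor between the 3' endpoints. Collapsing merges the inner arc
into the outer one, deletes its two positions, renumbers, and repeats to
fixpoint; the merge order does not change the result (checked against a
random-order oracle). Note that *vertices*, not just paired positions,
block the merge — an unpaired bulge nucleotide between two stacked pairs
prevents their collapse until it is removed.

* **core**: remove unpaired nucleotides, then collapse. Every stack
  collapses to one arc even across bulges and internal loops.
* **core plus**: collapse first, then remove unpaired nucleotides, with no
  second collapse pass. Bulges block the pre-removal collapse, so core
  plus retains one arc per uninterrupted stack.
* **shape**: delete every arc that crosses no other arc, remove the
  now-unpaired nucleotides, collapse. Only the crossing skeleton survives;
  a pseudoknot-free molecule reduces to the empty structure, reported in
  census output as `Null Shape`, and an H-type pseudoknot reduces to
  `([)]`.

The bulged helix `{(1,10), (2,9), (4,8)}` is the discriminating example
for the order of operations:

```{r}
bulged <- rna_structure(pairs = list(c(1, 10), c(2, 9), c(4, 8)), length = 10)
abstraction_string(bulged, "core")     # bulge removed before collapsing
abstraction_string(bulged, "coreplus") # bulge blocks one merge
```

The shape definition deserves a note: pure parallel-collapsing alone would
not send every pseudoknot-free structure to the empty string (a multiloop
of non-parallel nested arcs has no parallel pair to merge). Deleting
non-crossing arcs first is the unique simple reading under which
pseudoknot-free molecules give the null shape, an H-type pseudoknot gives
`([)]`, and an H-type nested inside a larger one gives `([)([)]]` — the
three motif classes a 5S rRNA census is built on. Deletion of non-crossing
arcs cannot create new crossings, so a single deletion pass suffices.
These algebraic facts are enforced by tests: `core` and `shape` are
idempotent, `shape(core(x)) = shape(x)`, `core(core_plus(x)) = core(x)`,
`shape(x)` is empty exactly when `x` is pseudoknot-free, and
`|pairs(core_plus)| >= |pairs(core)| >= |pairs(shape)|`.

## Statistics

`structure_stats()` counts sequence length, A/C/G/U occurrences, the
number of base pairs (*bonds*), and the unordered pair classes GC, AU and
GU. `T` counts as `U`; letters outside ACGU go into `other` and their
pairs count toward bonds only, so the class counts tile the bonds exactly
when all pairs are canonical. `aggregate_stats()` reports the arithmetic
mean and the *sample* standard deviation (n−1 denominator; reported only
for n ≥ 2) — the choice is documented here because population-style
deviation would shrink values by a factor of about `sqrt((n-1)/n)`, which
matters for small collections. The CSV column order is
`file,length,bonds,A,C,G,U,GC,AU,GU` with `Mean` and `St.Dev` footer rows
to two decimals.

## The synthetic generator

`random_structure()` assembles structures from motif modules: hairpins
(stems of 2–6 pairs around loops of 3–6 nt, optionally split by a
one-nucleotide bulge), H-type pseudoknots (two mutually crossing stems),
and a nested-pseudoknot module (a complete H-type inside the span of a
larger one), separated by short unpaired spacers and padded to the
requested length. Loops default to at least 3 unpaired nucleotides for
steric realism, but 0 is allowed in `h_pseudoknot()` for algebraic
edge-case testing. Stem pairs are drawn from G–C/A–U/G–U with fixed
weights (0.60/0.30/0.10 per unordered class) and unpaired positions
uniformly from ACGU, so every generated pair is canonical by
construction. Generation is deterministic given `seed`, and the RNG state
of the caller is left untouched.

The generator guarantees exactly the motif content it is asked for:
`pseudoknot_count = 0` gives pseudoknot-free structures,
`pseudoknot_count = 1` gives shape `([)]`, and `nested_pk = TRUE` gives
shape `([)([)]]`. What it does *not* emulate: thermodynamic plausibility,
naturally occurring length and composition biases, non-canonical pairs in
text formats, missing residues, or the irregular metadata of real
database files. Passing tests therefore demonstrate the correctness of
parsing, translation and abstraction on well-formed and mildly irregular
input, not robustness to every dialect found in public repositories.

## Numerical and testing choices

Degenerate inputs are first-class: empty structures round-trip through
every structure format, pairless molecules have well-defined statistics,
and a structure line of zero length renders as the empty string. The
property suite runs 1000 seeded fixtures per invariant with structure
lengths of 35–130 nucleotides — large enough to contain several
interacting motifs, small enough that the full suite runs in a few
minutes on one CPU. The acceptance script builds a 200-molecule corpus
(49% H-type, 46% pseudoknot-free, 3% nested, 2% double-pseudoknot,
mirroring the published composition of curated 5S rRNA collections),
writes it as RNAML, batch-translates it, and reports translation success,
round-trip identity, the shape census fractions, aggregate statistics,
the page-assignment inverse rate, and the number of permitted matrix
cells — every value computed at run time.

## Known limitations

Multi-record dot-bracket/AAS/FASTA files return the first molecule only
(CT and BPSEQ accept concatenated records the same way); Stockholm,
bpRNA `.st` and CTE dialects are not supported; RNAML numbering tables,
stacking and tertiary annotations are ignored; pseudoknot order/genus and
loop-element censuses are out of scope. Whether the original
first-come-first-served formulation assigns pages per pair or per band is
ambiguous in the literature; per-pair greedy is implemented, and minimal
page embeddings are deliberately not attempted.
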