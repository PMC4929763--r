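---
title: "crispex: methods, model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{crispex: methods, model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crispex)
```

## The model

A Cas9 target candidate is a 23-mer: a 20-nt protospacer (positions 1–20,
position 1 PAM-distal) followed by a 3-nt PAM (positions 21–23). The PAM
rule is NGG or NAG — exactly one per run — where the leading N is a
wildcard, so PAM validity is decided by positions 22–23 alone. Candidates
are enumerated at every offset on both strands of each query; coordinates
in reports are always 1-based inclusive on the query's forward strand, and
a minus-strand candidate's sequence is the reverse complement of the
forward slice. Windows containing N anywhere are excluded: an ambiguous
protospacer cannot be synthesised, and an unknown base should never create
spurious evidence in either direction (a residue N matches pattern letter
N only, and counts as a mismatch in base-to-base comparison).

### Specificity: the two checks

Off-target similarity is the plain Hamming distance over the 20
protospacer positions between the candidate and a genomic site that itself
carries a valid PAM under the run rule. The PAM is a gating condition and
is never counted as mismatches. Position-weighted penalty schemes
(CFD/MIT-style scores) and bulge/indel off-targets are deliberately out of
scope: the method is a pure count-based PASS/FAIL design.

A candidate is a **potential Cas9 target** iff both hold:

* **check 1** — at most one genomic site (its own locus) lies within the
  mismatch ceiling (default 2);
* **check 2** — at most one genomic site reproduces the 15-base seed (the
  12 PAM-proximal protospacer bases, positions 9–20, plus the PAM with its
  wildcard first position) with zero mismatches.

This is the *specificity reading* of the published filter description,
whose sentences taken literally would PASS a candidate **because** it has
a close off-target — the opposite of the stated purpose of showing "low/no
off-target activity". The literal reading is not offered, even as an
option; this interpretation is the central design decision of the package.
The "at most one" form (rather than "exactly one") means a query that is
not part of the genome at all — a plasmid insert, a transgene — yields
zero hits and passes on the same rule. Multi-copy genes legitimately fail
both checks; that is a finding about the gene, not an error.

### Restriction screening

Cas9 cuts both strands bluntly ~3–4 bases upstream of the PAM: between
protospacer positions 17|18, with the adjacent 16|17 boundary also
honoured. A recognition site *overlaps the cut* iff its match interval
covers both flanking bases of either boundary, i.e.
`(start <= 17 & end >= 18) | (start <= 16 & end >= 17)`. Matching is
IUPAC-degenerate, runs over both strands of the 23-mer (recognition sites
need not be palindromic; palindromic double matches collapse to one
record), and is confined to the 23-mer — amplicon-level uniqueness of the
digest band is a primer-design question outside the model. The shipped
enzyme table is an explicit stand-in: twelve common commercial 6-cutters,
user-replaceable via `load_enzymes()` / `--enzymes`, because the original
curated list is not available in the source text.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `pam` | `"NGG"` | PAM rule; `"NAG"` selects the weaker motif. One rule per run, and off-target sites are required to carry the *same* rule (an NGG run does not count NAG genomic sites — the conservative alternative would shrink the usable target set and the source method does not state it). |
| `start` | `"N"` | `"G"` restricts to G-starting protospacers (U6/T7 transcription convenience); always a subset of the `"N"` set. |
| `max_mismatch` | `2` | check-1 ceiling, in protospacer mismatches. Hit retrieval is additionally guaranteed for all seed-exact sites regardless of this ceiling, because check 2 needs them. |
| `seed_length` | `15` (fixed) | last 15 bases of the 23-mer = 12 protospacer nt + PAM. |

## The index and its completeness argument

`build_index()` catalogs every N-free PAM-valid 23-mer on both strands of
every contig (contigs are scanned independently, so sites spanning
assembly gaps do not exist — the documented limitation for unassembled
input). Each site is hashed under four keys: the seed (positions 9–20 +
PAM 22–23) and a 7/7/6 partition of the protospacer (positions 1–7, 8–14,
15–20). By pigeonhole, any site within 2 mismatches of a candidate agrees
exactly with it on at least one partition, so the union of the four bucket
lookups contains every hit the contract requires; exact mismatch counts
are then computed on the retrieved sites only. The scheme is an
implementation choice — the *contract* is equivalence with
`brute_force_hits()`, an independently coded exhaustive both-strand scan,
and that equivalence is property-tested on random (genome, candidate)
pairs and enforced end-to-end (`run_pipeline(..., search = "brute")` must
produce byte-identical CSVs).

## What the synthetic generator emulates — and does not

`make_genome()` draws uniform A/C/G/T background and plants 23-mers with
known off-target structure: genome-unique targets, exact duplicates,
near-miss neighbours with chosen mismatch positions, seed-exact decoys
(3+ PAM-distal mismatches), and targets carrying a restriction site over
the cut. Because a random 5-kb background can collide with a 15-mer seed,
every plant's expected classification is **verified against the
brute-force oracle at generation time** and the whole genome is redrawn
(bounded retries) on any violation — expectations are guaranteed, not
probable. Identical seed and arguments give identical bytes; seeds 7, 11,
13, 42 and 99 name the standard suites.

Uniform background has no GC skew, repeat families, or gene structure. A
green fixture suite therefore establishes *algorithmic correctness*
(enumeration, search completeness, filter logic, report determinism), not
the published organism-level statistics: the fraction of real genes with a
potential target depends on real genome redundancy and cannot be
reproduced from synthetic data. Reproducing those numbers requires the
actual *P. tricornutum*/*T. pseudonana* annotations (hours of compute,
network downloads) and is intentionally outside the default surface.

## Numerical and formatting choices

* Coordinates 1-based inclusive everywhere; report order is fixed (query
  input order, then start, then '+' before '−'), making CSVs byte-stable.
* CSV output is RFC 4180 (quoting only when needed) with LF endings,
  written through a binary connection so the platform cannot inject CRLF.
* Percent efficiency of a gene with zero candidates is defined as 0;
  corpus percentages use **all** supplied query genes in the denominator,
  including candidate-free ones.
* `target_label` is `<query_id>_<start>_<stop>`; FASTA ids are truncated
  at the first whitespace.
* Soft-masked (lowercase) input is uppercased and treated normally.

## Known limitations

* No on-target activity scoring (Doench-type) and no weighted off-target
  scores — PASS/FAIL only, faithful to the method.
* Off-targets with bulges/indels are invisible to a Hamming model.
* The default enzyme table is a convenience stand-in; real screening
  designs should load the lab's own table.
* Sites spanning contig boundaries are not modelled.

```{r example}
cfg <- crispex_config(pam = "NGG", start = "N")
fx  <- make_genome(standard_plants(), rng_seed = 7, config = cfg)
res <- run_pipeline(fx$queries, fx$genome, cfg)
res$report[res$report$query_id == "g_rflp",
           c("target_label", "check1", "check2", "potential",
             "cleavage_site_enzymes")]
res$aggregates
```
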