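# crispex

CRISPR/Cas9 target design for any genome: candidate enumeration,
genome-wide specificity filtering, and restriction-site screening for
PCR–digest mutant detection.

## The problem

Designing an sgRNA reduces to choosing a 20-nt protospacer immediately 5′
of a PAM (NGG for SpCas9, optionally the weaker NAG). A usable guide must
be *specific*: no second site in the genome being edited should be similar
enough to attract the Cas9/sgRNA complex. Tools that only ship pre-indexed
model-organism databases are useless for non-model organisms such as
phytoplankton; `crispex` works against **any user-supplied genome or
transcriptome FASTA, assembled or not** (contigs/scaffolds/reads are
scanned independently).

For every query gene the pipeline:

1. **Enumerates** every 23-nt window `[5′-G/N(19 bp)PAM-3′]` on both
   strands whose last 3 bases satisfy the PAM rule (and, optionally, whose
   first base is G). Windows containing N are skipped.
2. **Searches the genome** for occurrences of each candidate using a
   PAM-anchored index. Mismatches are Hamming distances over the 20-nt
   protospacer; PAM validity is a gating condition, never counted.
3. **Filters at two levels.** A candidate is a *potential Cas9 target*
   iff it is genome-unique in both senses:
   - *check 1*: no second genomic site within ≤ 2 protospacer mismatches
     (ceiling configurable);
   - *check 2*: no second genomic site reproducing the 15-base **seed**
     (the 12 PAM-proximal protospacer bases + PAM) exactly.
   The candidate's own locus is the one permitted hit; a query absent
   from the genome (e.g. a plasmid insert) simply has zero hits.
4. **Annotates restriction sites.** Cas9 cuts bluntly ~3–4 bp upstream of
   the PAM (between protospacer positions 17|18, with the adjacent 16|17
   boundary honoured). A recognition site spanning the cut is destroyed by
   an induced indel, so wild-type amplicons digest where mutants do not —
   cheap RFLP screening. Sites overlapping the cut are flagged separately.
5. **Reports** a per-target CSV (`target_label, sequence, strand, check1,
   check2, potential, restriction_sites, cleavage_site_enzymes`) plus
   per-gene summaries (percent efficiency = 100 × potential/total) and
   corpus aggregates (% genes with ≥ 1 potential target, % genes with a
   potential target carrying a cleavage-site enzyme).

Every indexed search has a brute-force oracle twin
(`brute_force_hits()`, `search = "brute"`), and a synthetic-genome
generator (`make_genome()`) plants targets with known off-target structure
and *verifies* the expectations at generation time, so the whole pipeline
is testable offline.

## Worked example

```r
library(crispex)
cfg <- crispex_config(pam = "NGG", start = "N", max_mismatch = 2)
fx  <- make_genome(standard_plants(), rng_seed = 7, config = cfg)  # 3 x 5 kb
res <- run_pipeline(fx$queries, fx$genome, cfg)
head(res$report[, c("target_label", "check1", "check2", "potential",
                    "cleavage_site_enzymes")])
```

prints (abridged; full run has 22 rows over 6 genes):

```
   target_label check1 check2 potential cleavage_site_enzymes
  g_unique_8_30   PASS   PASS       YES                    NA
    g_dup_11_33   FAIL   FAIL        NO                    NA
  g_near1_10_32   FAIL   PASS        NO                    NA
  g_decoy_11_33   PASS   FAIL        NO                    NA
   g_rflp_11_33   PASS   PASS       YES        EcoRI@14-19(+)
```

- `g_unique_8_30` is genome-unique: both checks PASS, a potential target.
- `g_dup_11_33` sits in a duplicated locus: a second 0-mismatch site fails
  both checks.
- `g_near1_10_32` has a 1-mismatch neighbour: inside the mismatch ceiling
  (check 1 FAIL) but the neighbour's seed differs (check 2 PASS).
- `g_decoy_11_33` has a neighbour with 3 PAM-distal mismatches: outside
  the ceiling (check 1 PASS) but seed-identical (check 2 FAIL).
- `g_rflp_11_33` is unique *and* carries an EcoRI site over the cut
  (positions 14–19 span both cut boundaries) — ideal for mutant screening.

```r
res$summary[res$summary$query_id == "g_rflp", ]
#>  query_id total_candidates potential_targets efficiency_pct has_potential has_potential_with_cleavage_site
#>    g_rflp                5                 5            100          TRUE                             TRUE
res$aggregates
#> $pct_genes_with_potential               83.33333
#> $pct_genes_with_cleavage_site_potential 16.66667
```

## Command line

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "crispex.R", package = "crispex"))')" \
  --query genes.fa --genome genome.fa --pam NGG --start N --max-mm 2 \
  [--enzymes enzymes.csv] [--out report.csv] [--summary summary.csv] \
  [--potential-only]
```

Exit status 0 on success; validation errors print one diagnostic line on
stderr and exit nonzero. The enzyme table is a user-replaceable CSV
(`name,site`, `#` comments); the shipped default
(`inst/extdata/restriction_enzymes.csv`) lists 12 common commercial
6-cutters.

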