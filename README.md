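# ydelscan

Desk-scale, fully synthetic re-implementation of the comparative-genomic
pipeline that isolates a gene from the Y-specific region of a dioecious
plant by **k-mer subtraction between a male, a female, and
hermaphroditic Y-deletion mutants**, then screens, confirms and dates
it.

## Who this is for

Anyone who wants the *inference chain* of Y-deletion gene mapping as
runnable, tested code: methods developers probing where subtraction
screens break, teachers demonstrating sex-chromosome genomics at
laptop scale, and analysts who want each stage (trimming, k-mer
subtraction, mini-assembly, ratio filtering, expression screening,
segregation testing, molecular dating) as an individually callable,
individually tested function. Every stage runs in seconds to minutes on
synthetic genomes with known truth — no downloads, no external
aligners.

## The method

Given genomic reads from a male, a female and deletion mutants of one
inbred line:

1. **Trim** (leading/trailing Q20, sliding window 4:28, MINLEN 40).
2. **Count** 35-bp k-mers starting with `A` on both strands of every
   read.
3. **Subtract**: male-specific k-mers are those absent from the female
   and from every mutant, with total count in [10, 1000].
4. **Retain** pairs carrying any such k-mer; **assemble** them into
   unitigs (de Bruijn, k = 31, edge support ≥ 2).
5. **Select** Ydel contigs by normalized mapped-count ratios:
   female/male < 20% **or** mutant/male < 40%.
6. **Screen**: transcript fragments hitting the Ydel assembly at
   E < 1e-7 (ungapped Karlin–Altschul statistics), quantified per RNA
   sample (TPM), TE-homologous fragments removed, candidates = expressed
   in male (≥ 1 TPM) and silent elsewhere (< 0.1 TPM).
7. **X-linkage** of the X gametolog by segregation: in a sexed family,
   sons must always inherit the maternal allele.
8. **Dating**: Nei–Gojobori (1986) dS/dN with Jukes–Cantor correction
   (d = −3/4 log(1 − 4p/3)), Tajima's relative-rate test
   (χ² = (m1−m2)²/(m1+m2), 1 df), and T = dS / (2µ) with
   µ = 7.31×10⁻⁹ per site per generation, 1.5 yr/generation.

A synthetic-data module (`sim_config()`, `simulate_system()`,
`simulate_reads()`, `simulate_expression_reads()`, `simulate_cross()`)
generates the whole study system — X/Y gametologs at target synonymous
divergence 0.18 with X-lineage dN/dS 0.38 vs 0.08, two deletion mutants
covering the focal gene, five bud RNA samples, a 4-son/6-daughter
cross — so the pipeline can be validated end to end against planted
truth. See `vignettes/ydelscan-methods.Rmd` for assumptions and design
rationale.

## Worked example

```r
library(ydelscan)
cfg <- make_fixture("gsf-mini", seed = 7, out_dir = tempfile())
rep <- run_all(cfg)
print(rep)
```

```
# ydelscan run report

- preset: gsf-mini, seed: 7
- retained pairs: 584 of 12600
- contigs: 3 (4139 bases)
- Ydel contigs selected: 2 of 3
- candidates: focal_y
- X-linkage verdict: X-linked
- dS(x:y) = 0.192; omega X/outgroup = 0.36, Y/outgroup = 0.08; RRT m1=15 m2=1 P=0.000465; T ~ 1.3e+07 generations (19.7 My)
```

Reading it: of 12,600 trimmed male read pairs, 584 carry a
male-specific k-mer; they assemble into 3 contigs of which 2 pass the
coverage-ratio filter — together they tile the interval deleted in
*both* mutants. Exactly one transcript fragment (`focal_y`, the planted
gene) is expressed in the male and silent everywhere else after TE
exclusion. The X gametolog segregates as X-linked (sons never carry the
paternal allele). The 96-codon gametolog pair gives dS ≈ 0.19 — single
genes are noisy; the 3,000-codon acceptance simulations recover the
0.18 target to ±0.02 — and an excess of X-lineage amino-acid
replacements.

The headline estimators on the published counts:

```r
tajima_rrt(12, 3)
#> Tajima relative-rate test: m1 = 12, m2 = 3, chi^2 = 5.400, P = 0.02014
divergence_time(0.18)
#> dS = 0.18, mu = 7.31e-09/site/generation -> 1.23e+07 generations (~18.5 My at 1.5 yr/gen)
```

## Layout

- `R/` — synthetic data (`synthdata`), trimming (`readkit`), k-mer
  subtraction + assembly (`kmer`), pseudo-mapping + ratio filter
  (`contigselect`), homology/expression screen (`exprscreen`),
  segregation test (`xlinkage`), molecular evolution (`molevo`),
  orchestration (`pipeline`), plain-text I/O (`io`).
- `tests/testthat/` — unit and property tests per module, independent
  brute-force oracles in `helper-oracles.R`, acceptance criteria in
  `test-acceptance.R`.
- `inst/scripts/ydelscan-cli.R` — `simulate` / `run-all` command-line
  wrapper.
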