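---
title: "Finding and dating a Y-linked gene by k-mer subtraction: methods and design"
author: "ydelscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding and dating a Y-linked gene by k-mer subtraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In a dioecious plant with heteromorphic XY chromosomes, a Y-linked
*gynoecium suppression function* (GSF) blocks carpel development in
males. Hermaphroditic mutants that lost a small interval of the
Y-specific region ("Ydel") point at that interval as the place where the
suppressor lives. With a 3-Gb genome and a 570-Mb Y, the practical route
to the gene is comparative: sequence a male, a female, and the deletion
mutants from one inbred line, find the sequence present in the male but
absent from everyone else, assemble it, and ask which of its fragments
is expressed only where the suppressor must act — early male flower
buds. `ydelscan` implements that inference chain as a tested, desk-scale
pipeline, together with a synthetic-data generator so every stage can be
validated against known truth without any external data.

The stages mirror the original analysis:

1. **Trim** reads (leading/trailing Q20, sliding window 4:28, min length 40).
2. **Count** 35-bp k-mers that start with `A`, on both strands.
3. **Subtract**: keep k-mers present in the male, absent from the female
   and from every mutant, with a total count in [10, 1000].
4. **Retain** read pairs carrying at least one such k-mer; **assemble**
   them (de Bruijn unitigs, k = 31, edge support >= 2).
5. **Select** contigs by mapped-coverage ratios: female/male < 20% *or*
   mutant/male < 40%.
6. **Screen** transcript fragments against the selected contigs
   (ungapped seed-and-extend, E < 1e-7), quantify expression per sample,
   drop TE-homologous fragments, and keep fragments expressed in the
   male but silent in female and mutants.
7. **Confirm X-linkage** of the X gametolog by segregation in a sexed
   two-parent family (sons must always inherit the maternal allele).
8. **Date** the X/Y divergence: NG86 synonymous divergence with
   Jukes–Cantor correction, Tajima's relative-rate test on amino acids,
   and T = dS / (2 mu) with mu = 7.31e-9 per site per generation and
   1.5 years per generation.

## The synthetic world

`sim_config()` encodes the stated study design; its defaults are fixed
and are not tuning knobs:

* A fully homozygous inbred background (a `heterozygosity` knob exists
  for robustness experiments only). The male carries an autosome pair,
  one X and one Y; the female two X; each mutant is the male genome with
  one interval excised from the Y-specific region. Two mutants are
  simulated and both deletions must cover the focal gene, as in the
  mapping panel that defined the Ydel region.
* A 200-kb haploid genome (120-kb autosome, 50-kb X, 10-kb X/Y-shared
  head, 20-kb Y-specific region) at 30-fold coverage **per haplotype
  copy** — so the diploid autosome sees 60x and the male X and Y 30x
  each. This per-copy convention is what makes X-origin contigs show a
  female/male mapped ratio near 2 and Y-origin contigs near 0.
* A 96-codon focal CDS (288 nt, the cDNA length of the real candidate),
  evolved as an X/Y gametolog pair plus outgroup under the `gsf` preset
  (below).
* Paired-end 100-bp reads, insert 300 ± 30 (the study does not state
  insert sizes; this default is documented, not calibrated), per-base
  error 0.002, constant Phred 35 with 3-base Phred-15 tails so the
  trimmer has work to do.
* Five early-bud RNA samples (male, female, three mutants). Only the
  male expresses the focal Y gene. The X gametolog is **silent in buds
  of both sexes**, matching the expression assays of the real system
  (the X copy is on in the apical meristem, not in early buds). A
  TE-derived fragment and an autosome-duplicate fragment are planted
  inside the deleted interval so the TE filter and the ratio filter are
  both exercised; a housekeeping gene checks that unrelated transcripts
  fall out at the homology stage.
* A cross of two parents with 4 sons and 6 daughters, the family size
  of the original segregation test.

What the generator does *not* emulate: realistic TE landscapes,
recombination within the cross, indel sequencing errors, GC or coverage
biases. A green end-to-end test therefore establishes the *logic* of the
inference chain — deletion-aware subtraction, ratio selection,
expression filtering, segregation, dating — not robustness to every
artefact of real short-read data.

## The gsf divergence preset

The preset stores per-branch (dS, dN/dS) targets chosen once, in closed
form, so that the *pairwise* estimates match the documented values:
X:Y synonymous divergence 0.18, X-vs-outgroup dN/dS 0.38, Y-vs-outgroup
dN/dS 0.08, and ~93% nucleotide identity between the Y copy and the
outgroup. With additive branch divergences,

* dS is split 0.09/0.09 between the X and Y branches;
* the outgroup branch receives dS_o = 0.136 at omega_o = 0.09 (the
  outgroup lineage's own ratio), which lands the Y-to-outgroup
  nucleotide path near 7% divergence, i.e. ~93% identity;
* omega_x solves (0.09 omega_x + 0.136 x 0.09) / 0.226 = 0.38, giving
  0.8182, and omega_y solves the same equation for 0.08, giving 0.0649.

On each branch the generator converts the dS/dN targets into *observed*
difference counts through the inverse Jukes–Cantor map
p = 3/4 (1 − exp(−4d/3)) times the ancestral NG86 site counts, then
places exactly that many synonymous and nonsynonymous single-base
changes at distinct codons, rejecting stop codons. Multiple hits across
branches (different branches striking the same codon) remain possible,
which is precisely what the Jukes–Cantor correction absorbs; with a
3,000-codon ancestor the recovered mean dS sits within ±0.005 of target
in practice. Codon changes are uniform with no transition/transversion
bias, matching the assumptions of the estimators being validated (NG86
with equal-weight pathways, Jukes–Cantor with equal exchange rates).

## Numerical and algorithmic choices

* **NG86 conventions.** Site counts are fractional; changes producing a
  stop codon count as nonsynonymous, so S + N = 3 x codons exactly (an
  invariant the tests assert). Observed differences are averaged with
  equal weight over all minimal substitution pathways, excluding
  pathways through stop codons; if every pathway is blocked (never seen
  with sense endpoints) all pathways are used. pS or pN at or above 3/4
  raises an error rather than returning an undefined distance.
* **Codon alignment** translates, aligns the proteins (BLOSUM62, gap
  open 11 / extend 1) and threads codons back, so gaps are codon-sized
  by construction. Three sequences are merged on the first sequence's
  coordinates. Gapped columns are dropped pairwise for divergence and
  triple-wise for the relative-rate count.
* **Trimmer semantics** follow the canonical tool: leading, trailing,
  then a 5'→3' sliding window that cuts at the start of the first
  window whose mean falls below the threshold, followed by a trailing
  re-trim, then the length filter. A pair survives only if both mates
  survive; orphan mates are discarded (the original study does not say
  whether orphans were kept; dropping them keeps the downstream
  retention logic pair-based).
* **k-mer counting** scans both strands but keeps only `A`-anchored
  k-mers — the ~1/4 subsampling convention of the k-mer subtraction
  method the study reused. Windows containing non-ACGT characters are
  skipped rather than raising errors. Whether the original counting was
  strand-canonical is not stated; the both-strands-A-prefix convention
  is this package's documented choice.
* **Pseudo-mapper**: exact 21-mer seeds at the read's start, middle and
  end, ungapped extension, >= 90% identity over >= 90% of the read;
  pairs count once toward the contig of their best mate hit and exact
  ties split fractionally. Contigs shorter than ~90% of the read length
  can never accept a read and surface as `no_male_coverage`.
* **Homology search** is ungapped seed-and-extend (word 11, +1/−2,
  X-drop 20) with E = K m n exp(−lambda S). lambda is solved from the
  Karlin–Altschul identity for the scoring scheme (1.33); K uses the
  standard precomputed value for +1/−2 (0.621), as the classic aligner
  itself ships precomputed tables. At the near-identity, sub-kb scales
  of this screen, gapping changes nothing at E < 1e-7.
* **Quantification** assigns reads with the pseudo-mapper and splits
  multi-mapping ties equally; TPM = (count / length in kb) rescaled to
  1e6 per sample. One optional abundance-weighted reassignment
  iteration (`reassign = TRUE`, on by default in the pipeline) is the
  deliberate, minimal stand-in for the EM of full quantifiers: without
  it, a silent homolog 87% identical to a highly expressed gene
  accrues tie counts above any sensible expression threshold. Full EM
  is a non-goal.
* **"Expressed" vs "silent"** are operationalized as >= 1 TPM and
  < 0.1 TPM; the original description gives only the qualitative rule,
  so both thresholds are exposed as parameters.
* **Ratio filter** normalizes each library to the male's total and
  applies the disjunction female/male < 0.20 OR mutant/male < 0.40,
  with one designated mutant (mirroring the published filter, which
  used one of the two sequenced mutants); contigs with zero male
  coverage are rejected and flagged. The asymmetry — the second mutant
  is sequenced and subtracted but not ratio-filtered — is reproduced,
  not rationalized.
* **X-linkage**: a site is informative iff the father carries an allele
  absent from the mother; sons' homozygous-looking calls are treated as
  hemizygous-compatible (that is how diploid callers report hemizygous
  X sites), missing calls are skipped, and a locus is accepted only
  with >= 1 informative site and zero violations. The father's X allele
  is the paternal-specific allele daughters must carry; Y-linked
  paternal alleles are outside the model. For an autosomal site with an
  informative configuration the chance of mimicking X-linkage in a
  4-son/6-daughter family is (1/2)^10 ≈ 0.001, which the Monte-Carlo
  power estimator reproduces.
* **Determinism**: every generator is a pure function of (config,
  seed); the pipeline derives one sub-seed per stage from the master
  seed, and RNG state is saved and restored so library calls do not
  perturb user sessions.

## Known limitations

* The assembler is a unitig builder: it stops at every repeat branch
  and performs no scaffolding or error correction; at default error
  rates it relies on the edge-support filter to remove error k-mers.
* The homology search reports at most one (best) HSP per
  query/subject/strand pair and ignores edge-effect corrections in the
  E-value; fine at screen scale, not a general aligner.
* Divergence dating propagates no uncertainty: no bootstrap on dS and
  no confidence interval on T (hooks exist, deliberately unfilled).
* The expression model draws reads i.i.d. from abundance x length with
  uniform starts; no fragment-length or positional bias.
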