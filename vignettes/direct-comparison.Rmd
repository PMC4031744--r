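---
title: "Direct k-mer comparison for de novo mutation discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct k-mer comparison for de novo mutation discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denovok)
```

## The problem

When an affected child and two unaffected parents (or diseased and
matched normal tissue from one individual) are exome-sequenced, the
standard analysis aligns every sample to the reference genome and then
tries to subtract the tens of thousands of inherited variants each
comparison produces. `denovok` takes the opposite route: it compares the
samples' sequences *directly to one another* through their k-mer
content, and only touches the reference at the very end, to place and
annotate the handful of candidates that survive. A true de novo mutation
creates k-mers that exist in the affected sample and in no unaffected
relative; everything the family shares cancels out before any alignment
happens.

## The pipeline

Writing $P$ for the affected (proband/diseased) read set and $U_1,
U_2$ for the unaffected sets (one $U$ in pair mode), the pipeline is:

1. **Count** canonical k-mers (default $k = 27$) in every sample. A
   k-mer and its reverse complement are one key, because reads arrive
   from both strands; splitting them would halve every locus's signal.
2. **Error-filter the affected sample only**: discard k-mers with count
   $<$ `min_count` (default 10). Each sequencing error spawns up to $k$
   novel k-mers, so the raw spectrum is dominated by error singletons;
   at 80--100$\times$ coverage a heterozygous variant carries
   40--50$\times$ coverage and clears the threshold comfortably. The
   unaffected spectra are *not* filtered: even a single parental read
   is allowed to veto a candidate, which maximizes specificity.
3. **Screen** the surviving spectrum against (a) the canonical k-mers
   of a vector database and (b) the k-mers of the capture targets of
   the reference, each target padded by $k-1$ bases so edge-spanning
   windows are represented. Anything present in the reference cannot be
   the mutation sought. Additional "harmless variant" FASTAs can be
   supplied as further screens.
4. **Subtract** each unaffected sample's spectrum (presence-based).
   What remains are the candidate k-mers.
5. **Harvest** the affected reads containing a candidate k-mer, via an
   in-memory presence index (the counter does not retain read
   provenance).
6. **Screen reads for vector**: a harvested read is dropped if it
   shares an exact $\ge$ 18-bp substring with any vector on either
   strand, or a local alignment of $\ge$ 25 columns at $\ge$ 90%
   identity.
7. **Micro-assemble** the survivors with a greedy
   overlap-layout-consensus assembler (minimum overlap 31 bp, at most
   2% mismatches inside an overlap, both orientations). Because every
   read in a contig must contain the mutation, two reads of length $L$
   sharing a column can span at most $2L-1$ columns; merges that would
   exceed that bound are refused, so 100-bp reads can never yield a
   contig longer than 199 bp.
8. **Place, merge, filter**: contigs are placed on the reference by
   seed-and-extend alignment; contigs whose placements overlap are
   collapsed (supporting reads pooled and re-assembled); contigs with
   fewer than four supporting reads after merging are dropped.
9. **Parental evidence**: each placed contig is widened by one read
   length on each side, all unaffected reads are re-aligned to the
   window, reads that align better somewhere else in the genome are
   discarded (ties keep the read), and the contig survives only if
   *every* putative mutation column is covered by at least
   `min_parent_depth` reads from *each* unaffected sample. This is what
   defeats capture dropout: an inherited heterozygote in a region the
   transmitting parent's capture missed looks exactly like a de novo
   mutation until this step, at which point that parent's zero depth
   gives it away. A placed contig with no mutation column is a vacuous
   candidate and is removed; unplaced contigs are never filtered here
   but reported separately as potential novel sequence.
10. **Call and annotate**: affected reads are piled up per reference
    column over each surviving window; a variant is emitted where a
    non-reference allele has $\ge 2$ supporting reads at a mutation
    column, with indels anchored and left-normalized. Variants whose
    supporting fraction is not strictly $> 5\%$ are dropped — the
    strict inequality and the low default keep mosaic variants carried
    by a minority of cells. Coding consequence (synonymous / missense /
    nonsense / frameshift / splice-proximal) is classified from the
    gene models; synonymous and noncoding calls are flagged rather than
    silently dropped, with `coding_only` and `drop_synonymous` switches
    for stricter reporting.

Every stage logs its input/output count; the run object's `funnel` is
that table, and `funnel_is_monotone()` checks its shape: counts must
fall monotonically within the k-mer stages and from the read-harvest
stage onward. The harvest count may legitimately *exceed* the candidate
k-mer count (one k-mer occurs in many reads), so monotonicity is not
asserted across that one boundary.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | 27 | k-mer length; odd, $\le 31$ so a k-mer packs into one 64-bit word |
| `min_count` | 10 | error filter on the affected spectrum only |
| `min_reads_per_contig` | 4 | support filter after contig merging |
| `min_variant_fraction` | 0.05 | strict lower bound on supporting-read fraction |
| `min_parent_depth` | 1 | per-sample depth demanded at each mutation column |
| `min_overlap`, `max_mismatch_frac` | 31, 0.02 | assembler admissibility |
| `vector_seed_len` | 18 | exact-match trigger of the read-level vector screen |
| `vector_min_aln_len`, `vector_min_identity` | 25, 0.90 | alignment trigger of the vector screen |
| match/mismatch/gap open/gap extend | +1/−2/−4/−1 | all alignment scoring |
| `min_place_identity`, `min_place_qcov` | 0.80, 0.50 | contig placement acceptance |
| `min_realign_identity` | 0.90 | read-to-window alignment acceptance |

The alignment scores, placement thresholds, consensus tie-breaks
(majority, then the deepest-coverage read's base, then the
lexicographically smallest base) and the merge rule ("same location" =
any 1-bp placement overlap) are this package's own numerical choices —
the method constrains their role, not their values — and all live in
`pipeline_config()` so they can be varied.

## The synthetic trio generator

`simulation_spec()` / `simulate_trio()` generate the study conditions
the package is tested under: a uniform-random 100-kb reference carrying
eight valid protein-coding genes (1--3 exons, half on the minus
strand), capture targets covering ~20% of the reference, inherited
SNVs at $10^{-3}$ per bp per parent (70% heterozygous), Mendelian
transmission of one intact haplotype per parent (no recombination),
five de novo SNVs and one 3-bp de novo indel planted inside targets at
VAF 0.5, 80$\times$ target coverage with 100-bp reads, 0.5% uniform
per-base substitution error, and optional vector chimerism and
region-level capture dropout. A read covering a de novo locus carries
the alternate allele with probability equal to the variant's VAF, so
alt counts are Binomial(depth, VAF) by construction; mosaic fractions
are just smaller VAFs.

Reads start uniformly over the targets extended by one read length, and
the read count is sized so the *interior* target depth equals the
stated coverage (sizing by target length alone would dilute interior
depth by the extension overhang).

Design choices worth knowing:

* **Inherited variants are substitution-only**, so haplotype
  coordinates stay aligned with the reference and read construction
  needs no coordinate lifting; de novo variants include indels and
  exercise the full indel path. De novo loci are resampled until they
  are $> k$ bases from any inherited site (so one variant's k-mer
  context is not entangled with another's) and well separated from one
  another.
* **The truth set's `expected_detectable` flag is the method's
  information-theoretic limit**, and recall is measured against it. A
  planted variant is flagged detectable when (a) it lies inside a
  target, (b) its expected per-k-mer alternate support
  $\text{depth} \times \text{VAF} \times \frac{L-k+1}{L} \times
  (1-e)^k$ reaches `min_count`, and (c) at least one of its alternate
  k-mers is absent from every unaffected sample's reads. Condition (c)
  matters: with 0.5% uniform error at 80$\times$, each parent carries
  ~0.13 expected reads with the *same* substitution at any given site,
  and a single such read with the error near its middle reproduces all
  27 alternate k-mers — the subtraction then hides the variant from
  *any* implementation of this algorithm. Roughly half of random seeds
  lose one of six planted variants this way; the flag records it so
  that recall measures the pipeline, not the dice.
* **What the generator does not emulate**: recombination, GC and
  capture bias, indel sequencing errors (substitution-only error
  model), quality-score profiles (qualities are constant and unused by
  the filters), duplicate reads, and real repeat structure — a uniform
  random reference keeps k-mer uniqueness high, with an optional
  duplicated segment at configurable identity to reintroduce controlled
  paralogy for the better-placement test. Passing tests therefore
  demonstrate the pipeline's logic under clean, deep, targeted data,
  not its behavior on repeat-rich real genomes.

## Numerical and degenerate-input choices

* Alignment is affine-gap local (Gotoh) with greedy traceback;
  seed-and-extend against the reference uses exact 27-mer seed hits
  clustered by diagonal (band 24) and extended over a padded window.
  K-mers occurring at $> 200$ reference positions are skipped as seeds
  (repeat guard).
* Assembler determinism: merge order is longest-overlap first, ties
  broken by the lexicographically smaller merged consensus, then the
  smallest read id; all string ordering is C-locale radix order.
* An empty candidate set short-circuits the run with a header-only VCF
  and a complete zero-padded funnel; a contig that perfectly matches
  the reference is removed as vacuous and logged.
* Windows containing `N` contribute no k-mers (no substitution of N);
  reads shorter than $k$ contribute no windows.
* Indel alleles are anchored on the preceding reference base and
  left-aligned by the usual trim-and-extend normalization before being
  written; positions are 0-based half-open internally and 1-based only
  in the VCF.
* In pair mode the identical machinery runs with a single unaffected
  sample; `run_pair(normal, normal, ...)` on identical inputs returns
  an empty call set.

## Problem sizes used by the tests

The bundled tests run the full pipeline on 100-kb references at
80$\times$ coverage (~20,000 reads per sample) for the headline
checks, and on 30-kb / 40$\times$ fixtures for structural and
determinism checks; the oracle suites use hundreds of random instances
of up to a few thousand k-mers. These sizes were chosen so that every
scientific claim is exercised end-to-end at desk scale: the per-locus
depth, error load, and filter thresholds are exactly those of the full
setting, only the genome length is reduced.

## Known limitations

* Only de novo (sample-unique) variation is discoverable; compound
  heterozygotes and inherited causal variants are out of scope by
  design.
* The assembler assumes gapless read layouts within a contig, which is
  sound under a substitution-only error model and variant-consistent
  harvested reads, but would fray under frequent indel sequencing
  errors.
* Adjacent inherited heterozygotes inside a candidate contig's window
  can be reported alongside the de novo call (they sit on mutation
  columns and are covered by both parents); at most a couple of such
  records appear per run and they are trivially recognized by their
  ~50% fraction in both samples' pileups.
* The genome-wide better-placement re-alignment is exact enough on
  desk-scale references; genome-scale use would want a proper read
  mapper behind the same contract.
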