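---
title: "Methods: comparative mobility metrics and headful-packaging geometry"
author: "ltmob"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative mobility metrics and headful-packaging geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltmob)
```

# The problem

Horizontal gene transfer in bacteria is mediated by mechanisms with wildly
different unit conventions: conjugation frequencies are reported per donor,
transduction and lysogenisation as titres (transductant units per ml of
lysate), and the elements involved differ by orders of magnitude in how much
host-usable cargo they carry. `ltmob` puts them on one scale and models the
geometry of the strongest chromosomal-transfer mechanism, lateral
transduction (LT), in which a still-integrated, replicated prophage packages
successive headfuls of downstream chromosome in situ.

# The comparative statistics

**Normalisation.** A titre becomes a per-donor frequency by dividing by the
donor density at prophage induction:
\[ \mathrm{TE/donor} = \frac{\mathrm{TrU\,ml^{-1}}}{\mathrm{donor\ CFU\,ml^{-1}}}. \]
Two packaged calibrations map optical-density landmarks to donor densities:
OD~540~ 0.15 → 6.5 × 10⁷ CFU/ml (*S. aureus*) and OD~600~ 0.20 → 1.0 × 10⁸
CFU/ml (*Salmonella*). Normalisation is linear and performed at full floating
precision.

**Cargo capacity rate.** The fraction of a mobilised sequence the recipient
can actually use: accessory ORFs (virulence, resistance, colonisation
factors) over total ORFs. Counts carry 0.5 granularity because an ORF
truncated at a headful boundary counts half; values such as 17.5/51 and
41.5/41.5 are therefore legal inputs. The exact fraction is kept; tables
render it to two decimals.

**Relative frequency of genetic mobility.** The product of the two,
endpoint-wise over frequency ranges (a closed interval scaled by a positive
scalar maps endpoints). The multiplication always uses the exact ORF
fraction: 6.0 × 10⁻⁵ × 28/55 = 3.05 × 10⁻⁵, which is *not* recoverable from
the rounded rate 0.51. A not-determined ("ND") cargo propagates ND, never 0.

**Ledger assembly.** `build_mobility_ledger()` resolves each record's
frequency (given directly or normalised from a titre via its organism's
calibration), derives the two rates, and assigns dense ranks on the upper
endpoint, descending; ties share a rank and rows are ordered by descending
frequency then element id, so the ledger is invariant under permutation of
its input. ND mobilities rank last. Ranking convention is a package choice —
the source material orders elements only visually.

## Rendering and the packaged tables

Derived cells render to three significant figures (frequencies, mobilities)
and two decimals (cargo rates). Rounding uses the C library's decimal
formatting of the underlying double (`sprintf("%.2e", x)`) rather than
`signif()`: the two disagree on decimal half-way cases such as
7.69 × 10⁻³ × 3/60 = 3.845 × 10⁻⁴, which must round up to 3.85 × 10⁻⁴ to
match the published rendering.

The package ships curated record tables for the two study organisms, with
raw inputs (frequencies or ranges as reported, accessory/total ORF counts)
alongside the published derived cells. Printed range endpoints are paired
positionally with `freq_lo`/`freq_hi`. Three cells do not reproduce from
their own raw inputs and carry explicit `discrepancy` flags instead of
silent correction:

* the Tn916 relative-mobility endpoint paired with its upper conjugation
  frequency (3.4 × 10⁻⁸ × 2/24 ≈ 2.8 × 10⁻⁹, printed as 6.25 × 10⁻¹¹);
* the SaPI2 cargo-rate and relative-mobility cells (2/24 renders 0.08 and
  2.20 × 10⁻¹ × 2/24 ≈ 1.83 × 10⁻², printed as 0.04 and 2.20 × 10⁻²);
* the P22 lysogenisation TE/donor in the replicate table (printed 1.567;
  the packaged mean titre 1.57 × 10⁸ over 1.0 × 10⁸ CFU/ml renders 1.57,
  the printed value evidently deriving from unrounded replicate means that
  are not available).

The acceptance checks assert every *unflagged* cell at printed precision and
assert that the flagged cells disagree — a regression guard in both
directions.

# Headful geometry on circular chromosomes

All coordinates are 0-based, half-open, modulo the genome length L;
packaging direction is encoded ±1. The directed distance from the *attB* to
a locus is the number of bases walked in the packaging direction, and the
headful index is \( n = \lfloor d/H \rfloor + 1 \), out of reach when
\( n > n_\mathrm{max} \). Window *k* spans directed offsets
\([(k-1)H, kH)\); for direction −1 this makes window 1 cover the H bases
*strictly upstream* of the origin (the origin base itself is the last base
of the reach's mirror image, an unavoidable half-open edge under
mirroring — the property tests pin this convention exactly). Distances are
measured from the *attB* because published headful indices are
attachment-site-relative, even though packaging physically initiates at the
embedded *pac* site; a `pac_offset` field (default 0) shifts the origin for
users who want pac-relative geometry.

Built-in models: 80α/φ11 with H = 45 kb and n~max~ = 7 (demonstrated
processivity), P22 with H = 43 kb and n~max~ = 12 — giving single-prophage
reaches of 315 kb and 516 kb. A reach exceeding the full circle is truncated
at L with a warning (relevant only for toy genomes). Poly-lysogen coverage
is the union of per-site reach intervals, computed by splitting wrapped
intervals into linear pieces and merging with `IRanges::reduce()`; the
locus × site compatibility table reports the min–max headful range over the
windows a locus intersects, using both edges of its span (a midpoint rule
would miss boundary-straddling loci). Coverage of the real ten-site
poly-lysogen maps requires a user-supplied *attB* coordinate registry; no
coordinates are bundled, so those published percentages are exercised only
as properties on synthetic layouts.

The HF1 particle of an LT series carries `hf1_phage_carryover` bp of phage
DNA before chromosomal content begins. The default is 0 (pure geometry);
the quantity is known only through ORF accounting (the 17.5/51 HF1 cargo),
so it is exposed as a parameter rather than defaulted to a guess.

# The packaging simulator

The simulator is a mechanism model, not a fitted model. Per induced donor,
`particles_per_donor` packaging series start; each is an LT series (in-situ,
from the prophage *pac*) with probability `p_in_situ`, otherwise lytic phage
production. Pseudo-*pac* sites independently initiate generalised
transduction series at their `relative_efficiency`. Series lengths follow
1 + Geometric(q) truncated at n~max~ — the simplest one-parameter decaying
law consistent with per-headful frequency declines; under it
\(P(\text{length} \ge k) = q^{k-1}\), so the expected per-headful profile
decays geometrically. A marker transfers when a particle's chromosomal
interval contains its span and a Bernoulli(`recombination_prob`) succeeds;
phage particles lysogenise with `lysogenisation_prob`. All draws derive from
a single integer seed (recipient-side draws use seed + 1), so a fixed seed
fixes the entire experiment bit-for-bit.

Default parameters (units, value, rationale):

| parameter | default | rationale |
|---|---|---|
| `induction_fraction` | 1 | mitomycin C induction is near-complete |
| `particles_per_donor` | 50 | abstracts in-situ replication of packaging substrate |
| `p_in_situ` | 0.2 | a minority of activated prophages remain integrated |
| `series_continuation` (q) | 0.55 | matches the observed ~35-fold decline of LT frequencies from HF1 to HF7 (q⁶ ≈ 0.028) |
| `ppac relative_efficiency` | 10⁻⁴ | chromosomal *pac* mimics are recognised orders of magnitude less efficiently |
| `recombination_prob` | 0.005 | sets LT HF1 frequencies near 5 × 10⁻² TE/donor under the defaults |
| `lysogenisation_prob` | 0.02 | order of magnitude of observed lysogenisation per particle |

These defaults are modelling choices fixed once; the validation suite runs
with explicit parameters. `recover_continuation_probability()` estimates q
from a per-headful event profile by maximising the conditional multinomial
likelihood \( \ell(q) = \sum_k n_k (k-1)\ln q - N \ln \sum_j q^{j-1} \)
(the per-fragment detection probability cancels), solved by a 1-D root of
the score with the standard error from the observed information. Boundary
handling: all events in HF1 → q̂ = 0; a profile at least as flat as uniform →
q̂ = 1 (SE undefined at the boundary).

# Synthetic data

`generate_toy_genome()` emulates the structures the analysis assumes: a
circular 10⁴–5 × 10⁶ bp chromosome with random A/C/G/T sequence,
non-overlapping ORFs with ground-truth accessory/core labels whose product
strings deliberately match (accessory) or avoid (core) the default keyword
rules, *attB* sites at fractional positions with directions, and markers
placed strictly inside a requested headful window so `headful_index()`
recovers the requested index by construction. Generation is deterministic
per seed down to byte-identical GenBank/GFF3/FASTA output. What it does
*not* emulate: real gene density and operon structure, sequence motifs
(no *pac*-like sequence model), overlapping genes, or plasmids — so passing
tests demonstrate correctness of the arithmetic and the mechanism model,
not biological realism of any particular genome.

GenBank output uses the standard minimal flat-file dialect (LOCUS with
topology, CDS features with `complement()`/origin-crossing `join()`,
`/locus_tag`, `/product`, a `/note="class:..."` carrying the ground-truth
label, ORIGIN). GFF3+FASTA is written and read through
rtracklayer/Biostrings, with origin-crossing ORFs split into two parts
sharing an ID; the reader for the GenBank dialect is implemented in-package
because no offline flat-file feature-table parser is available in the
dependency stack. Cross-format equality is asserted in the suite.

# Problem sizes and tolerances used in validation

Table reproduction is exact at printed precision (3 significant figures /
2 decimals). Geometry is checked against brute-force per-base walking
oracles on 100 random multi-site layouts of ≤ 100 kb circles, plus property
sweeps (window partition, distance complementarity, direction mirroring,
coverage monotonicity and additivity). Simulator checks use 10⁵ packaging
series: the empirical per-headful profile must sit within 3 binomial
standard errors of q^(k−1) at every headful, q must be recovered within 3
standard errors, and with pseudo-*pac* efficiency 10⁻⁴ against in-situ
probability 0.2 the HF1 marker's LT frequency must exceed its GT frequency
at least 100-fold — the same direction, and a comparable magnitude, as the
observed LT-vs-GT contrast for first-headful markers. These sizes keep the
whole suite under a minute of simulator time while leaving the binomial
bands tight (≈ ±0.4% at HF1).

# Known limitations

* Accessory/core classification is rule-based (id lists + keywords); it
  reproduces curated counts but does not infer function.
* The simulator has no burst-size kinetics, MOI dynamics, superinfection
  immunity, host range, or homology-length model of recombination; the
  truncated-geometric series law is a convenience, not a measured law.
* Frequencies in the ledger are taken as published — no meta-analytic
  weighting, and no significance testing between element classes.
* Poly-lysogen coverage of real chromosomes is only as good as the
  user-supplied *attB* registry; none is bundled.
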