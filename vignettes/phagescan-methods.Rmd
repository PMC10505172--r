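---
title: "Methods: from tiled phage-display libraries to a chemokine-binding pharmacophore"
author: "phagescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from tiled phage-display libraries to a chemokine-binding pharmacophore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

phagescan implements the computational route from evasin-derived peptide
phage-display screens to a chemokine-binding pharmacophore: library design,
amplicon counting, enrichment scoring and residue mapping, saturation
mutagenesis statistics, and docking-pose proximity aggregation. This
vignette is the package's own account of the underlying models, the
parameters that matter, and the design choices made where the procedure was
genuinely open.

## The screen and its model

Tick evasins bind many CC- and CXC-class chemokines. To locate which parts
of an evasin do the binding, the mature proteins are tiled into
hexadecapeptides (16-mers) overlapping by a single residue, so a protein of
length $L$ yields $L-15$ tiles; because evasin binding sites often involve
disulfide-bonded Cys residues, every Cys-containing tile is additionally
synthesised with all of its Cys jointly mutated to Ala, and jointly to Ser.
Each peptide is encoded as a 48-nt insert inside an 81-mer oligonucleotide
flanked by fixed 18-nt and 15-nt cloning arms. The phage pool displaying
these peptides is panned against an immobilised chemokine for three rounds,
and the input and selected populations are sequenced as paired-end
amplicons.

Enrichment of peptide $p$ against chemokine $c$ is
$$E_{pc} = \frac{f^{\mathrm{out}}_{pc}}{f^{\mathrm{in}}_{p}},$$
reported as $\log_2 E$, where $f$ are within-sample peptide frequencies
over counted reads. Under proportional selection, $\log_2 E$ grows with the
(log) binding affinity of the displayed peptide, which is what the
synthetic-data generator plants and what the recovery tests measure.

### Zero counts

A peptide recovered after selection but unseen in the input would give
$E = \infty$; its input proportion is therefore replaced by the smallest
non-zero input proportion in the experiment. Symmetrically, in mutagenesis
campaigns (where the interest is in *loss* of binding) a peptide unseen in
the output takes the smallest non-zero output proportion. In selection mode
peptides absent from an output sample receive no entry at all — they were
not recovered, and assigning them a floored score would manufacture
negative enrichment out of sampling noise. With these rules every reported
$\log_2 E$ is finite, which the package asserts.

## Read filtering

Joined read pairs pass a fixed cascade; each pair receives exactly one
status, assigned in this order: missing demultiplexing motif, missing
constant region, mate-insert mismatch, ambiguous base, wrong insert size
(anything other than 48 nt), peptide not in the designed library, OK. Demux
and constant motifs are matched as exact substrings — the strictest reading
of "containing" — and mate 2 is assumed reverse-complemented (standard
Illumina orientation; reads are assumed long enough to span the full
insert, as in amplicon protocols with 2 x 250 chemistry). Matching to the
library is at the translated-protein level, so synonymous codon variants
pool into one peptide. Counting only library members makes the pipeline
robust to chimeric or frame-shifted artefacts at the cost of discarding
novel sequences, which the screen by construction cannot contain.

## Residue mapping and regions of interest

Entries with $\log_2 E > 0$ (strict) are mapped back to the wild-type
parent; mutant tiles map to their originating start. Residue-level
enrichment is
$$\mathrm{rlog_2E}(i) = \sum_{(p,c)\,:\, i \in [s_p, s_p+15]} \log_2 E_{pc},$$
smoothed with a centred rolling median of window $k = 7$ (ends absent:
exactly three residues on each side). The protein-wide median of
$\mathrm{rlog_2E}$ gets a 95% distribution-free confidence interval from
binomial order statistics — the exact conservative interval, requiring
$n \ge 6$; interpolated variants of this interval differ by at most the gap
between adjacent order statistics. Regions of interest (ROI) are maximal
runs of residues whose **smoothed** profile strictly exceeds the CI's upper
bound. Comparing the smoothed rather than raw profile is a recorded choice:
smoothing precedes ROI calling in the procedure this package follows, and
it suppresses single-tile spikes; `detect_roi(use_smoothed = FALSE)`
provides the raw alternative. No minimum ROI length is imposed.

## Saturation mutagenesis and its statistics

The NNK scan replaces each of the 16 positions of a parental peptide with
an NNK degenerate codon (32 codons; all 20 amino acids; the only reachable
stop, TAG, is dropped), deduplicated at the protein level. Effects are
summarised as $\Delta\log_2 E = \log_2 E_{\mathrm{mut}} -
\log_2 E_{\mathrm{WT}}$ per chemokine (positive = better binding).

Substitutions are classed independently as alanine, anionic \{E, D\},
cationic \{K, R\}, hydrophobic \{L, I, M, V\}, and conservative. The
conservative class is defined as PAM250(wt, mut) $> 0$ with wt $\ne$ mut;
the matrix is named by the procedure but no cut-off is, and a strictly
positive Dayhoff log-odds score is the conventional reading. Note Cys has
no PAM250-positive partner, so a parental Cys position has an empty
conservative class. Group sizes follow (class members excluding the
parental identity) x (number of chemokines): with a 16-mer and 24
chemokines this gives 48 for anionic/cationic, 96 for hydrophobic (72 where
the parent residue is itself hydrophobic), and 24 for wild-type and alanine
groups. A `top_conservative = 1` mode keeps only the best-scoring
conservative residue per position, reproducing a conservative group size
equal to the chemokine count.

Each group is compared with the parental control by a two-sided Dunnett
many-to-one test under the homoscedastic one-way model. The family-wise
adjustment integrates the equicorrelated multivariate $t$ by seeded Monte
Carlo (default 200,000 draws), making the procedure self-contained and
deterministic given a seed; Monte-Carlo error at 200,000 draws is about
0.001 on a p-value near 0.05, and the suite cross-checks the k = 1 case
against the closed-form t-test and a 3-group case against an independent
reference implementation. One-way ANOVA (for wild-type versus Cys-mutant
comparisons of total $\log_2 E$) and Spearman correlation (for relating
$\Delta$migrated cell counts to $\Delta\log_2 E$; average ranks, two-sided
t approximation) use the classical forms. Migrated cell counts are
normalised so the chemokine-alone median is 10,000 cells per experiment.

## Pose-ensemble proximity

Docked peptide:chemokine (or receptor:chemokine) models arrive as
ensembles: five AlphaFold-Multimer models ranked by confidence, ten ADCP
poses ranked by free energy, or four NMR-driven HADDOCK poses. A residue is
an interface residue of a pose when any of its atoms (side chains and, if
present, hydrogens included) lies within 5 Å of the other chain. Each
target residue accumulates the weight of every pose in which it is an
interface residue, and the profile is rescaled to a maximum of 100. Weights
follow the source: AlphaFold confidence as-is; ADCP free energies negated
and floored at zero, so the lowest energy ranks highest (the sign handling
is a recorded choice — energies are negative for bound poses, and only
their relative magnitudes matter after the max-100 normalisation, which
also absorbs any uniform rescaling of weights); NMR poses weigh 1 each.
Per-pose weights are not re-normalised before summation — only the final
max-100 step is applied. Contact profiles count cross-chain atom pairs
within 5 Å per binder residue, averaged over poses; atom pairs (not residue
pairs) mirror "interactions per residue", with a residue-pair mode left to
the caller by thresholding the returned counts.

## The synthetic generator: what it emulates and what it does not

No raw sequencing data accompany the screen this package models, so a
seeded generator stands in for it and doubles as the test bed:

* **Parents** — random mature sequences of 70–90 residues (evasin-like)
  with 4–8 Cys, one planted 16-residue binding interval per parent, shared
  by all chemokines of the panel (binding regions are treated as a property
  of the protein, mirroring how promiscuous peptides cluster in sequence).
* **Affinities** — $\log a(p,c) = \alpha\,\mathrm{overlap}(p) +
  \beta\,\mathrm{cys\_intact}(p) + \varepsilon$, with defaults
  $\alpha = 6\ln 2$ (a fully overlapping tile is $2^6$-fold favoured),
  $\beta = 2\ln 2$ (intact parental Cys rewarded), and
  $\varepsilon \sim N(0, 0.5)$.
* **Panning** — deterministic proportional enrichment
  $p_{r+1} \propto p_r\,a$ over three rounds, with multinomial observation
  noise only at sequencing (default depth 200,000 reads per sample). This
  is the simplest model consistent with enrichment tracking affinity;
  between-round amplification noise is deliberately omitted.
* **Reads** — each counted molecule becomes one 2 x 250 read pair around
  the full amplicon (demux motifs, both constant regions, 48-nt insert),
  with independent per-base substitution errors (default $10^{-3}$,
  typical of Illumina after filtering).
* **Poses** — idealised straight-backbone coordinates with the binder laid
  over a designated epitope at contact range, rigid-body jitter per pose,
  and scores that improve as jitter shrinks.

Passing recovery tests on these data shows the pipeline's inference is
sound when its assumptions hold; it does **not** show robustness to
amplification bias, PCR chimeras, quality-dependent errors, peptides whose
display is biased by folding or toxicity, or docking ensembles that
disagree with each other — none of which the generator produces.

## Problem sizes and numerical choices

The shipped analyses and checks use one to three parents (roughly 150–500
distinct peptides), panels of one to eight chemokines, depths of
$10^5$–$2\times10^5$ reads per sample, ten replicate seeds for recovery
rates, 200,000 Monte-Carlo draws where a single Dunnett p-value is compared
against a closed form and 10,000–50,000 where many are computed, and 1,000
simulated datasets for the null family-wise error rate. These sizes give
the recovery and calibration statistics comfortable margins (e.g.
multinomial noise on $\log_2 E$ at depth $2\times10^5$ is small against
planted effects of 3–18 log2 units) while keeping any single analysis in
the minutes range. Ties in the scrambled-control search are broken by
generation order under the given seed; all stage seeds derive from one
master seed through named substreams, so stages are independently
reproducible.

## Known limitations

* Enrichment is a rank proxy for affinity; no $K_D$ or dose-response
  quantities are estimated.
* The exact conservative median CI can be wider than interpolated
  variants, making ROI calling conservative near the threshold.
* Exact-substring landmark matching discards reads with any error inside a
  motif; at realistic error rates this is a few percent attrition, counted
  and reported but not recovered.
* Structural inputs are taken as pre-aligned on a shared target numbering;
  superposition is out of scope.
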