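---
title: "Designing and quantifying miRNA mimics with mimircraft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and quantifying miRNA mimics with mimircraft}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimircraft)
```

## Background

Plant microRNAs recognise their targets through nearly full complementarity
and cut them between the bases facing guide positions 10 and 11; bilaterian
animal miRNAs instead rely on a short 5' "seed" (guide positions 2–8),
sometimes helped by supplementary pairing of positions 13–16, and mismatches
at the central positions are the norm rather than the exception. Cnidarians —
sea anemones, corals, hydroids — sit at an informative evolutionary position:
their miRNAs behave like plant miRNAs, and probing which complementarity
modes do or do not silence a target there requires a panel of miRNA mimics
(mimiRs) that differ from a target-complementary guide only at controlled
positions.

mimircraft implements the sequence layer of that experimental design as a
reusable toolkit: it designs mimics on an endogenous precursor scaffold,
classifies guide–target complementarity modes, scans transcripts for binding
sites, engineers reporter 3' UTRs with uniformly spaced seed sites, and
quantifies guide/star loading from AGO immunoprecipitation (AGO-IP)
small-RNA reads at desk scale.

## The pairing model

All classification rests on an ungapped antiparallel register: a guide of
length $L$ (positions numbered 1..$L$ from its 5' end) faces a same-length
site window given in transcript sense orientation, guide position $i$
pairing site position $L+1-i$. Pair states are Watson–Crick (A:U, U:A, G:C,
C:G), wobble (G:U, U:G) or mismatch. Wobbles count as mismatches by default
— whether near-full complementarity tolerates wobbles is biologically
unsettled, so the conservative choice is the default and a `wobbleIsMatch`
flag exposes the alternative. Bulged (gapped) duplexes are out of scope: the
designs this toolkit produces and decodes are all ungapped.

A `PatternSpec` carries the positional rules, all 1-based on the guide:

| parameter | default | meaning |
|---|---|---|
| `seedInterval` | [2, 8] | classification seed (7 nt) |
| `requirePos1` | `TRUE` | position 1 must also pair for a "seed match" |
| `designSeedInterval` | [1, 8] | seed used when *scanning* in seed mode |
| `suppInterval` | [13, 16] | 3' supplementary pairing |
| `centralPositions` | {10, 11} | cleavage-site positions |
| `fixedBases` | 19 → C | never disqualify a near-full call |
| `nearFullMaxMismatches` | 2 | mismatch budget for NEAR_FULL |

The two seed intervals deserve a note. The classical seed definition is
positions 2–8; the guides this package is calibrated against were however
*designed* with positions 1–8 pairing (their position 1 is a U facing an A).
Classification therefore uses the 2–8 interval plus a default requirement
that position 1 also pairs, while seed-mode scanning anchors on positions
1–8; both are configurable independently.

Classification is total and deterministic, with a fixed precedence:
`NEAR_FULL` (mismatch count within budget, none of them in seed or central
positions apart from fixed bases), then the central-mismatch categories
(`CENTRAL_MM_10`, `CENTRAL_MM_11`, `CENTRAL_MM_10_11`: the only non-fixed
deviations from near-full lie at central positions), then
`SEED_SUPPLEMENTARY` (seed and supplementary fully matched, at least one
central mismatch), then `SEED_ONLY` (seed matched, supplementary broken),
else `NONE`. The near-full budget of 2 accommodates the designed fixed-base
mismatch at position 19 plus one incidental mismatch; it is a toolkit
convention, not a measured biochemical threshold.

## The scaffold and the duplex register

Mimics are grafted onto an endogenous miR-2022-derived hairpin: a 21-nt star
arm, a 7-nt loop (`GUUGUCA`) and a 21-nt guide arm, with the mature guide on
the 3' arm. The scaffold is data (`mir2022Scaffold()`, or a YAML file via
`readScaffold()`), not a constant baked into the code; the generic shRNA
hairpin used as a negative control, which carries a different loop, decodes
through a fold mode that takes the outermost guide-length stretches as arms.

The guide/star duplex register was calibrated once against the decoded
packaged templates and stored in the scaffold: guide position $g$ pairs star
position $L-1-g$ mapped to the star's own 5'→3' numbering (star position
$j$ pairs guide $20-j$ for the default $L=21$), leaving 2-nt 3' overhangs on
both strands — the classical siRNA/miRNA duplex geometry. The star's own
overhang sequence (`UG`) is scaffold data decoded from the templates, where
it is constant across all rows.

Two design rules come from transcription chemistry rather than target
biology. Standard T7 polymerase wants a G at the transcript +1, which is the
star's 5' base; under the register that base faces guide position 19, so
every guide carries a fixed C there, making position 19 the one guide
position that may mismatch the target by design. Designed star mismatches
sit at star positions 1, 8, 9 and 17. Empirically, those four positions are
where the decoded stars deviate from the *image of the target site* (the
exactly target-complementary duplex partner); relative to the final,
position-19-fixed guide, star position 1 actually pairs (G:C), and only 8, 9
and 17 mismatch. mimircraft therefore interprets `starMismatchPositions`
relative to the target-complementary reference — pass the site to
`deriveStar()` — which reproduces the printed geometry; the tests assert
both views.

When a position must be made non-pairing (central mismatches, the
non-conserved stretch of a seed-only guide, star mismatches), the
substitution rule is "use the base identical to the opposing base": an
identical ribonucleotide can neither Watson–Crick pair nor wobble with
itself, so the rule is always valid, needs no case analysis, and reproduces
the packaged central-mismatch guides (C facing C). The packaged seed-only
and seed+supplementary rows used heterogeneous substitutions at some
positions; those exact rows are reproduced by decoding the packaged
templates, not re-derived from the rule — `deriveGuide()` guarantees the
*category*, not byte-identity with any particular historical choice.

## Ordered templates and promoters

Hairpin templates for in vitro transcription are handled in the
ordered-oligo convention: the single-stranded DNA is the reverse complement
of promoter + transcript. `transcribeTemplate()` decodes such a template by
reverse-complementing, locating exactly one promoter motif, and reading the
transcript from the following base; `makeTemplate()` is its exact inverse.
Four promoter variants are packaged, distinguished by motif and by the +1
requirement at the transcript start:

* `T7_STD` — `TAATACGACTCACTATA`, transcripts start G;
* `T7_PHI25` (class II phi2.5) — `TAATACGACTCACTATT`, transcripts start A;
* `T7_CLEANCAP_AG` — standard motif, transcripts start AG (CleanCap-AG
  co-transcriptional capping);
* `SP6` — `ATTTAGGTGACACTATA`, transcripts start G.

The +1 offsets are calibrated conventions chosen so that every packaged
template and reporter row decodes; in particular the phi2.5 +1 position is
not something the source material states explicitly, and the packaged
choice (transcription starting at the A immediately after the motif) is the
one consistent with the printed primer and reporter sequences. When a
template satisfies several candidates, the most specific one wins (longest
+1 requirement, then longest motif): a transcript starting `AG...` decodes
as CleanCap-AG, one starting `G...` as standard T7.

## Reporter constructs

`parseReporter()`/`assembleMrna()` split and reassemble reporter mRNAs
(promoter, leader, EF1α kozak `TGTTAAACCAACCAACCACC`, CDS, 3' UTR, encoded
polyA run) such that the round trip is the identity on all five packaged
reporter rows. Enzymatic polyadenylation is metadata only — it changes no
sequence — while `ENCODED(n)` appends `n` adenines.

`buildUtr()` engineers a UTR carrying `n` seed sites with exactly `gap`
intervening bases between consecutive sites. "21 bases apart" is interpreted
as the count of bases strictly between the end of one 8-nt seed region (the
stretch pairing guide positions 1–8) and the start of the next — the
interpretation under which both inter-site gaps of the packaged reporter
measure exactly 21. New copies are inserted upstream of the original site,
reusing the `gap` bases that precede it as spacer so every site sits in an
identical local context; where the historical construct actually placed its
two added sites is not recorded in the source material, so only the printed
end product (which `validateConstruct()` measures) is treated as ground
truth. The builder re-validates its own output and refuses edits that
create, destroy or de-space occurrences — including collisions with an
optional full-match site.

`validateConstruct()` reports architecture as measured: kozak position, CDS
bounds, per-guide seed-mode and near-full-mode site lists with UTR5/CDS/UTR3
annotation, seed-site count, inter-site gaps and full-match-site count. On
the packaged mCherry reporter with the decoded seed-match guide it reports
3 seed sites, both gaps 21, all sites in the 3' UTR, and one full-match site
for the second positive-control mimic.

## Scanning and cleavage coordinates

`scanTranscript()` slides a guide-length window over a transcript. In seed
mode a hit requires a full Watson–Crick match across the design seed
interval; in near-full mode, a NEAR_FULL classification; in all mode, any
category other than NONE. Overlapping qualifying windows are resolved
greedily left to right — deterministic, and consistent with the
non-overlapping sites of the packaged construct. The predicted cleavage
coordinate of a hit is the bond between the transcript bases facing guide
positions 10 and 11 (`start + L - 11` on its 5' side), reported only when
both central positions are Watson–Crick paired.

## Loading quantification and the read simulator

The AGO-IP quantification is deliberately desk-scale. Reads shorter than
18 nt are discarded (the boundary is kept); reads are assigned to annotated
precursors by exact ungapped substring match (a `maxMismatches` option
exists; the exact-match default is a documented simplification of the
external aligner-based pipeline this mirrors); the strand label is the
annotated interval — guide, star or loop — with maximal overlap, ties going
to guide; guide reads touching the loop are flagged loop-spanning.
Normalization is reads per million of *genome-unmapped* reads — the correct
library size for exogenous mimics, which by construction do not map to the
host genome — with `unmappedTotal` supplied by the caller, since genome
mapping itself is out of scope; replicate values are combined by arithmetic
mean. Processing homogeneity is the fraction of guide reads whose 5' end
sits exactly at the annotated guide start, alongside the loop-spanning
fraction and the full 5'-offset histogram.

The synthetic-read generator exists so the quantifier can be tested against
known truth. It draws clean guide reads (5' end at the guide start, plus a
configurable jitter distribution), loop-spanning guide reads (5' end 1–3 nt
inside the loop) and star reads, with lengths uniform on 18–30 nt — the gel
size-selection window of a typical small-RNA library — and is byte-identical
under a fixed seed. It emulates the *structure* of AGO-IP read sets (strand
asymmetry, 5'-end heterogeneity, loop read-through), not their biology: no
sequencing error, no adapter artefacts, no ligation bias, no AGO-specific
loading preferences. Tests that pass on simulated reads therefore validate
the bookkeeping — counting, labelling, normalization, fraction recovery —
and say nothing about how real Dicer processes a given hairpin.

## Numerical and testing choices

Problem sizes in the test suite are chosen to exercise the properties
comfortably: the reverse-complement involution runs over 10,000 random
sequences, scanner/oracle equivalence over at least 1,000 windows of random
transcripts with planted sites, guide derivation over all six categories on
dozens of random sites, and simulator parameter recovery at 10,000 reads per
configuration with assertions at three binomial standard deviations under
fixed seeds. All randomness in the package proper flows through explicit
seeds (`synthReadConfig(seed=)`); the simulator saves and restores the
global RNG state.

Degenerate inputs are rejected loudly rather than repaired: templates with
zero or multiple promoter hits, precursors too short to fold, sites that
violate the 5'-U rule, a zero genome-unmapped denominator, UTR edits that
break their own invariant. `N` bases are accepted in sequences but always
count as mismatches.

## Known limitations

No thermodynamics (no ΔG, no seed-pairing-stability scoring), no bulged
sites, no transcriptome-wide statistics, no genome mapping, no prediction of
Dicer cut-site accuracy or AGO sorting. The site-location step used when
decoding a template against a target prefers seed-anchored windows and
otherwise takes the minimal-mismatch window, refusing anything worse than
half-mismatched — adequate for reporter-scale targets, not a general-purpose
aligner.
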