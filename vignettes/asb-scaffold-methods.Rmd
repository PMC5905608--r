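---
title: "Analog series-based scaffolds: models, parameters and design choices"
author: "asbscaffolds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analog series-based scaffolds: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asbscaffolds)
```

## The model

A scaffold in this package is a property of an *analog series*, not of a
single compound. The pipeline has two stages.

**Stage one — series extraction.** A matched molecular pair (MMP) is a pair
of compounds distinguished only by a chemical modification at a single site.
We generate MMPs by fragmentation at retrosynthetic bonds: an acyclic bond
matching one of eleven RECAP-type environments is cut, splitting the
molecule into a candidate core and a candidate substituent. Two compounds
that share a core and differ by the exchanged substituents form a RECAP-MMP
(RMMP). Analog series are the connected components of the graph whose
vertices are compounds and whose edges are RMMPs; compounds in no RMMP are
singletons.

**Stage two — scaffold derivation.** For each series, all single-cut RMMP
cores of the members are collected with their coverage (which members admit
a fragmentation with that core). A core covering *all* members captures
every pairwise RMMP relationship of the series and becomes the single-site
ASB scaffold. When no such core exists, the series varies at more than one
position and a multi-site scaffold is sought: candidates are the members'
own multi-cut cores (2 up to `maxSubstitutionSites` simultaneous cuts,
never abstract graph merges, so every candidate is chemically realizable
from the series); a candidate covers a member when the member admits a
fragmentation whose core equals the candidate after site renumbering, with
hydrogen permitted at unmatched sites. The maximal covering candidate is
the scaffold. Each series yields at most one scaffold.

A series that cannot be resolved fails with a defined reason:

* `ambiguous_sub_series` — the series holds sub-series supporting
  structurally different maximal candidate cores (different invariant
  parts), none covering all members. This mirrors the known failure mode of
  series-based scaffold assignment on complex series.
* `no_common_core` — no candidate covers the series and there is no
  evidence of distinct sub-series.
* `site_limit_exceeded` — a candidate probed with one cut beyond
  `maxSubstitutionSites` covers the series, i.e. resolution would require
  more sites than allowed.

## Retrosynthetic bond classes

The eleven bond classes are matched on the package's own molecular graph
(element, formal charge, aromaticity, bond order, ring membership) with
operational environment definitions: amide `C(=O)–N` (carbonyl carbon with
exactly one nitrogen neighbour; two nitrogens classify as urea), ester
`C(=O)–O`, amine `C–N` (aliphatic, single-bonded nitrogen of degree ≥ 2 not
adjacent to a carbonyl or sulfonyl group), urea `N–C(=O)N`, ether `C–O`
(divalent non-ester oxygen), olefin `C=C` (acyclic, both carbons further
substituted), quaternary nitrogen `C–N⁺` (tetracoordinate), aromatic
N–aliphatic C, lactam N–aliphatic C (exocyclic bond of a cyclic amide
nitrogen), aromatic C–aromatic C (biphenyl-type single bond), and
sulfonamide `S(=O)(=O)–N`. Ring bonds are never cut (acyclic = bridge in the
bond graph). A bond matching several environments takes the first matching
class in the order above; the precedence is fixed purely for determinism.
All classes are enabled by default and individually switchable
(`enabledRules`).

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `maxSubstituentHeavyAtoms` | 13 | heavy atoms | cap on the exchanged substituent; keeps modifications at the size of typical medicinal-chemistry R-groups |
| `coreToSubstituentMinRatio` | 2.0 | – | the conserved core must dominate the decomposition; prevents "cores" that are smaller than what they carry |
| `maxExchangeSizeDifference` | 8 | heavy atoms | cap on the size difference of the two exchanged substituents of a pair; applied at pair level because the modification only exists pairwise |
| `maxSubstitutionSites` | 4 | sites | bound on scaffold sites; keeps multi-cut enumeration tractable and scaffolds interpretable |
| `minSeriesSize` | 2 | compounds | smallest analog series |
| `keepStereo` | TRUE | – | keep stereo descriptors in stored compound SMILES |
| `randomSeed` | 1 | – | seed for the synthetic generators |

The three size thresholds are design defaults of this package: the
size-restriction concept is inherent to the method, but no universal
numeric values exist, so the defaults were fixed once for reproducibility
and are fully configurable.

## Structures, canonical forms and standardization

Compounds are parsed with OpenBabel and held as constitution-level graphs
(atoms with element/charge/aromaticity, bonds with kekulized orders;
hydrogens implicit). Standardization keeps the largest covalent fragment,
neutralizes charges where a neutral form exists, and perceives aromaticity
under OpenBabel's single model; it is idempotent. Identity everywhere is
string equality of OpenBabel canonical SMILES, which is invariant to atom
input order (property-tested over random permutations).

Attachment points are dummy atoms whose isotope field stores the site
number. Site numbering is itself canonicalized: sites are renumbered
1..n in the atom order of the unnumbered canonical SMILES, so two scaffolds
identical up to a site permutation have the same canonical form. Cores are
indexed by their *unnumbered* canonical string.

Stereochemistry is the one deliberate simplification: `keepStereo` controls
whether stored compound SMILES retain stereo descriptors (affecting
structure-level deduplication), but fragmentation and scaffold comparison
operate on constitution only. Enantiomers therefore never form an RMMP
(their exchanged substituents would be identical strings) and a scaffold
never carries stereo marks. Tautomer canonicalization is not attempted.

## Determinism and tie-breaks

Given identical inputs and configuration, every output is byte-identical
across runs: there is no randomness outside the seeded generators, string
ordering uses C-locale radix sort everywhere, and all selection rules are
total orders —

* qualifying single-site cores: most heavy atoms, then canonical string
  (the largest conserved structure is the series' scaffold);
* multi-site candidates: most heavy atoms, then fewest sites, then
  canonical string;
* ranking: decreasing analog count, then canonical string; ranks 1..n
  without gaps;
* series numbering: decreasing size, then smallest member id.

Degenerate inputs are defined cases: an empty input yields an empty
collection and a header-only table; unparsable records are logged and
skipped, never silently dropped; structure duplicates keep the first-seen
identifier and merge annotations as a union.

## Nonredundant cores and the hydrogen-at-site policy

Two operational choices close gaps the method description leaves open:

* *Nonredundancy.* A core is redundant when another core has an identical
  invariant part (the structure left after deleting the attachment branch)
  and a coverage superset. This collapses positional variants of one
  substitution site and is the basis for diagnosing ambiguous sub-series.
* *Hydrogen at a site.* An analog lacking a substituent at a designated
  site is accepted: during coverage checking, any subset of a candidate's
  sites may be hydrogenated before comparison with the member's own cores.
  The switch matters for coverage, not for series membership — an
  unsubstituted analog can only join a series through exchanges at bonds
  that exist in its own structure.

## The synthetic generators

`generateLibrary()` emulates exactly the situation the method is built for:
a combinatorial series over a template scaffold whose attachment bonds all
belong to retrosynthetic classes (amide, ether, sulfonamide in the built-in
templates), with substituent pools that satisfy the size rules by
construction. Analogs are built as a seeded random walk that changes one
site at a time, which guarantees (i) a connected RMMP network and (ii) that
every site varies — both necessary for the template to be the unique
recoverable scaffold. Decoys are drawn from a vocabulary of molecules with
no retrosynthetic bonds, so they can never join a series.
`generateAmbiguousSeries()` builds the negative control: two sub-series
with structurally different invariant parts joined by one bridging
compound, where the two-site decomposition of the underlying template is
blocked by the size rules.

What the generators do *not* emulate: ChEMBL-scale structural diversity,
stereochemistry, tautomerism, activity-data curation, measured potencies,
or series whose analogs arise from ring replacements rather than
substituent exchanges. Passing the recovery benchmark therefore shows the
machinery is correct on its own preconditions, not that any particular
coverage percentage would be obtained on a real repository.

## Validation problem sizes

The shipped tests and the acceptance script use 50 seeded libraries
spanning 1–3 substitution sites and 3–12 analogs each (plus decoys and the
ambiguous control), brute-force cross-checks on sets of ≤ 20 compounds, and
a two-source benchmark of ten template variants for the merge and
determinism checks. These sizes were chosen as the smallest that exercise
every code path — single- and multi-site derivation, all failure reasons,
cross-source sharing — while keeping a full validation run in minutes on
one CPU.

## Known limitations

* Series are connected components of the RMMP graph; finer decomposition of
  mixed components into unique sub-series before derivation (as in the
  original series-assignment tooling) is not reproduced — mixed components
  are handed to derivation intact and resolved or rejected there.
* Constitution-only scaffold comparison, as discussed above.
* The nonredundancy and site-limit diagnostics are this package's
  documented operational definitions; other implementations of the method
  may classify rare failure cases differently.
* Compound-based (ring-system) scaffolds are intentionally out of scope.
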