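# asbscaffolds

Extraction of **analog series-based (ASB) scaffolds** from compound
collections.

In medicinal chemistry, a *scaffold* is the core structure of a compound or
compound series. Classical scaffold definitions operate on single compounds
(e.g. ring-system frameworks) and can assign several different scaffolds to
one series of closely related analogs. The analog-series-based alternative
derives the scaffold from the *series*: compounds are first grouped into
analog series (ASs) through matched molecular pair (MMP) relationships whose
core/substituent decompositions arise from cutting retrosynthetic
(RECAP-type) bonds — RECAP-MMPs, or RMMPs — and each series is then reduced
to the one core structure, with numbered substitution sites, that represents
all of its analogs. A series yields one and only one ASB scaffold; the
scaffold records synthetically meaningful attachment chemistry and carries
the series' target annotations.

This package is for cheminformaticians and computational medicinal chemists
who want to organize SAR data, build scaffold collections from screening
libraries or public repositories, or generate series-aware templates for
compound design.

## Method

Two stages:

1. **Analog series extraction.** Every compound is fragmented at acyclic
   bonds matching one of eleven retrosynthetic bond classes (amide, ester,
   amine, urea, ether, olefin, quaternary N, aromatic N–aliphatic C, lactam
   N–aliphatic C, aromatic C–aromatic C, sulfonamide). A decomposition into a
   core and a substituent is kept when the substituent has ≤ 13 heavy atoms
   and the core has ≥ 2× as many heavy atoms as the substituent. Two
   compounds sharing a core with distinct exchanged substituents (heavy-atom
   difference ≤ 8) form an RMMP; analog series are the connected components
   of the compound–RMMP graph.

2. **Scaffold derivation.** All RMMP cores of a series are searched for one
   shared by *all* analogs: that core, with its substitution site labelled
   `R1`, is the (first-generation, single-site) ASB scaffold. If no single
   core qualifies, multi-cut cores of the members are searched for a
   candidate with 2–4 sites that covers every member, with hydrogen
   permitted at unmatched sites (second-generation, multi-site scaffolds).
   Series containing sub-series with structurally different invariant parts
   that cannot be mapped to one scaffold are reported as failures with a
   defined reason (`ambiguous_sub_series`, `no_common_core`,
   `site_limit_exceeded`).

Scaffolds are annotated with the union of their analogs' target identifiers
and compound-class labels, merged across sources on their site-normalized
canonical SMILES (shared scaffolds are labelled `both`), ranked by the
number of analogs they represent, and written as a deposition-style
tab-separated table.

Molecule parsing, canonical SMILES and charge neutralization are delegated
to OpenBabel (via ChemmineOB); the fragmentation rules, MMP indexing and
scaffold search are implemented in the package.

## Worked example

Three N-acyl-2-naphthylamines (an analog series varying the acyl group) and
one unrelated decoy:

```r
library(asbscaffolds)

smi <- c(cpd1 = "CC(=O)Nc1ccc2ccccc2c1",    # acetyl
         cpd2 = "CCC(=O)Nc1ccc2ccccc2c1",   # propanoyl
         cpd3 = "CCCC(=O)Nc1ccc2ccccc2c1",  # butanoyl
         cpd4 = "CCCCCCCC")                 # octane: no retrosynthetic bond

input <- tempfile(fileext = ".smi")      # tab-separated: id <TAB> smiles
writeLines(sprintf("%s\t%s", names(smi), smi), input)

config <- pipelineConfig()
cs     <- readCompounds(input, "smiles", "DEMO")
index  <- buildCoreIndex(cs, config)
rmmps  <- generateRmmps(index, config)
rmmps
#>   compound_a compound_b               core    sub_a     sub_b size_diff
#> 1       cpd1       cpd2 *Nc1ccc2c(c1)cccc2  *C(=O)C  *C(=O)CC         1
#> 2       cpd1       cpd3 *Nc1ccc2c(c1)cccc2  *C(=O)C *C(=O)CCC         2
#> 3       cpd2       cpd3 *Nc1ccc2c(c1)cccc2 *C(=O)CC *C(=O)CCC         1

series <- extractAnalogSeries(cs, rmmps, config)
series
#> AnalogSeriesSet: 1 series, 1 singleton(s), 0 in undersized component(s)

result <- deriveAsbScaffold(analogSeries(series)[[1]], cs, config)
scaffold(result)
#> ASBScaffold (1 site(s), 3 analog(s), source DEMO)
#>   [1*]Nc1ccc2c(c1)cccc2
```

The three analogs pairwise exchange acyl substituents over the conserved
2-aminonaphthalene core; that core, with its single substitution site
`[1*]`, is the series' ASB scaffold and represents 3 analogs. The octane
decoy participates in no RMMP and is counted as a singleton.

`runExtraction()` (or the `inst/scripts/asb.R` command line) performs the
same steps for whole collections, merges sources, and writes
`scaffolds.tsv`, `stats.json`, `failures.tsv` and `manifest.json`.

## Synthetic validation libraries

`generateLibrary()` builds combinatorial analog libraries from templates
with 1–3 substitution sites and known ground truth (`builtinTemplates()`),
plus structurally unrelated decoys; `generateAmbiguousSeries()` constructs a
negative control whose two sub-series cannot be mapped to one scaffold.
These generators drive the test suite — no external downloads are needed.

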