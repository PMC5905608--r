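#' @import methods
NULL

#' Molecular graph
#'
#' Lightweight constitution-level molecular graph used throughout the package:
#' a table of heavy atoms (element symbol, formal charge, isotope label,
#' aromaticity flag) and a table of bonds (atom index pair with `a1 < a2` and
#' integer bond order). Hydrogens are implicit. Attachment points (substitution
#' sites) are dummy atoms with element `"*"`; their `iso` field carries the
#' site number (0 = unnumbered).
#'
#' Objects are normally created by [parseSmiles()] or by the fragmentation
#' machinery, not by hand.
#'
#' @slot atoms data.frame with columns `elem` (character), `chg` (integer),
#'   `iso` (integer), `arom` (logical).
#' @slot bonds data.frame with columns `a1`, `a2`, `order` (integers).
#' @aliases MolGraph
#' @exportClass MolGraph
setClass("MolGraph",
  representation(atoms = "data.frame", bonds = "data.frame"))

setValidity("MolGraph", function(object) {
  a <- object@atoms; b <- object@bonds
  if (!all(c("elem", "chg", "iso", "arom") %in% names(a)))
    return("atoms must have columns elem, chg, iso, arom")
  if (!all(c("a1", "a2", "order") %in% names(b)))
    return("bonds must have columns a1, a2, order")
  if (nrow(b) > 0) {
    if (any(b$a1 < 1L) || any(b$a2 > nrow(a)))
      return("bond atom indices out of range")
    if (any(b$a1 >= b$a2)) return("bonds must satisfy a1 < a2")
  }
  TRUE
})

#' Pipeline configuration
#'
#' Holds the tunable parameters of the extraction pipeline: the substituent
#' size cap and core/substituent ratio that restrict matched-molecular-pair
#' modifications to medicinal-chemistry-sized exchanges, the pairwise
#' exchange-size-difference cap, the maximum number of substitution sites a
#' scaffold may carry, the minimum analog-series size, stereo handling, the
#' random seed, and the set of enabled retrosynthetic bond rules.
#'
#' @slot maxSubstituentHeavyAtoms integer, substituent heavy-atom cap (13).
#' @slot coreToSubstituentMinRatio numeric, minimum core/substituent heavy-atom
#'   ratio (2.0).
#' @slot maxExchangeSizeDifference integer, maximum heavy-atom difference of the
#'   two exchanged substituents of a pair (8).
#' @slot maxSubstitutionSites integer, maximum scaffold sites (4).
#' @slot minSeriesSize integer >= 2, minimum members per analog series (2).
#' @slot keepStereo logical, keep stereo descriptors in stored compound SMILES.
#' @slot randomSeed integer seed for seeded operations.
#' @slot enabledRules character, subset of [retrosyntheticRuleIds()].
#' @aliases PipelineConfig
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(
    maxSubstituentHeavyAtoms = "integer",
    coreToSubstituentMinRatio = "numeric",
    maxExchangeSizeDifference = "integer",
    maxSubstitutionSites = "integer",
    minSeriesSize = "integer",
    keepStereo = "logical",
    randomSeed = "integer",
    enabledRules = "character"))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (object@maxSubstituentHeavyAtoms < 1L)
    msg <- c(msg, "maxSubstituentHeavyAtoms must be positive")
  if (object@coreToSubstituentMinRatio <= 0)
    msg <- c(msg, "coreToSubstituentMinRatio must be positive")
  if (object@maxExchangeSizeDifference < 0L)
    msg <- c(msg, "maxExchangeSizeDifference must be non-negative")
  if (object@maxSubstitutionSites < 1L)
    msg <- c(msg, "maxSubstitutionSites must be positive")
  if (object@minSeriesSize < 2L)
    msg <- c(msg, "minSeriesSize must be >= 2")
  if (!all(object@enabledRules %in% retrosyntheticRuleIds()))
    msg <- c(msg, "unknown rule id in enabledRules")
  if (length(msg)) msg else TRUE
})

#' Compound collection
#'
#' A standardized, structure-deduplicated set of compounds from one source.
#' Stored columnar: parallel vectors/lists indexed by compound. `smiles` is the
#' stored canonical SMILES (stereo kept or stripped per configuration),
#' `constitution` the stereo-free graph-level canonical form used by the
#' fragmentation and scaffold machinery, `mols` the parsed [MolGraph-class]
#' objects. Parse failures and structure-level duplicates are logged, never
#' silently dropped.
#'
#' @slot ids character, unique compound identifiers (input order preserved).
#' @slot smiles character, stored canonical SMILES (unique within the set).
#' @slot constitution character, constitution-level canonical SMILES.
#' @slot mols list of [MolGraph-class].
#' @slot sourceLabel character scalar.
#' @slot targets list of character vectors (UniProt-style accessions).
#' @slot classes list of character vectors (subset of drug/probe/alert/other).
#' @slot parseFailures data.frame with columns `id`, `reason`.
#' @slot duplicates data.frame with columns `kept_id`, `dropped_id`.
#' @aliases CompoundSet
#' @exportClass CompoundSet
setClass("CompoundSet",
  representation(
    ids = "character",
    smiles = "character",
    constitution = "character",
    mols = "list",
    sourceLabel = "character",
    targets = "list",
    classes = "list",
    parseFailures = "data.frame",
    duplicates = "data.frame"))

setValidity("CompoundSet", function(object) {
  msg <- character()
  n <- length(object@ids)
  if (anyDuplicated(object@ids)) msg <- c(msg, "compound ids must be unique")
  if (anyDuplicated(object@smiles))
    msg <- c(msg, "canonical structures must be unique (dedup contract)")
  if (length(object@smiles) != n || length(object@constitution) != n ||
      length(object@mols) != n || length(object@targets) != n ||
      length(object@classes) != n)
    msg <- c(msg, "slot lengths inconsistent")
  if (length(object@sourceLabel) != 1L)
    msg <- c(msg, "sourceLabel must be a scalar")
  if (length(msg)) msg else TRUE
})

#' Core index
#'
#' Index of all size-rule-passing single-cut fragmentations of a compound set,
#' keyed by the (unnumbered) canonical core SMILES. One row per
#' (core, compound, substituent) triple.
#'
#' @slot entries data.frame with columns `core`, `compound_id`, `sub`,
#'   `sub_heavy`, `core_heavy`.
#' @aliases CoreIndex
#' @exportClass CoreIndex
setClass("CoreIndex", representation(entries = "data.frame"))

setValidity("CoreIndex", function(object) {
  need <- c("core", "compound_id", "sub", "sub_heavy", "core_heavy")
  if (!all(need %in% names(object@entries)))
    return(paste("entries must have columns", paste(need, collapse = ", ")))
  TRUE
})

#' Analog series
#'
#' A connected component of the compound-RMMP relationship graph with at least
#' `minSeriesSize` members: a set of closely related compounds sharing core
#' structures and differing by exchanged substituents.
#'
#' @slot seriesId integer.
#' @slot memberIds character, compound ids.
#' @slot edges data.frame of the RMMP records restricted to members
#'   (columns `compound_a`, `compound_b`, `core`, `sub_a`, `sub_b`).
#' @aliases AnalogSeries
#' @exportClass AnalogSeries
setClass("AnalogSeries",
  representation(seriesId = "integer", memberIds = "character",
                 edges = "data.frame"))

#' Set of analog series
#'
#' Result of series extraction: the analog series (connected components of the
#' RMMP graph meeting the size threshold), the singleton compounds that
#' participate in no RMMP, and members of components smaller than the
#' configured minimum series size.
#'
#' @slot series list of [AnalogSeries-class], ordered by decreasing size.
#' @slot singletonIds character, compounds in no RMMP.
#' @slot smallComponentIds character, compounds in components below
#'   `minSeriesSize` (empty with the default minimum of 2).
#' @aliases AnalogSeriesSet
#' @exportClass AnalogSeriesSet
setClass("AnalogSeriesSet",
  representation(series = "list", singletonIds = "character",
                 smallComponentIds = "character"))

#' Analog series-based scaffold
#'
#' The unique core structure representing an entire analog series, with
#' numbered substitution sites (`[1*]`, `[2*]`, ...) at the positions where
#' analogs vary. Every analog of the series decomposes as this structure plus
#' substituents placed only at designated sites (hydrogen permitted at a site).
#'
#' @slot smiles character, site-normalized canonical SMILES.
#' @slot structure [MolGraph-class] with `nSites` numbered attachment points.
#' @slot nSites integer >= 1.
#' @slot seriesId integer.
#' @slot analogIds character (may be empty for scaffolds read back from file).
#' @slot analogCount integer, number of analogs represented.
#' @slot source character, source label (or `"both"` after a merge).
#' @slot perSourceCounts named integer, analog count per source.
#' @slot targetIds character, union of member target annotations.
#' @slot classLabels character, union of member class annotations.
#' @aliases ASBScaffold
#' @exportClass ASBScaffold
setClass("ASBScaffold",
  representation(
    smiles = "character",
    structure = "MolGraph",
    nSites = "integer",
    seriesId = "integer",
    analogIds = "character",
    analogCount = "integer",
    source = "character",
    perSourceCounts = "integer",
    targetIds = "character",
    classLabels = "character"))

setValidity("ASBScaffold", function(object) {
  msg <- character()
  if (object@nSites < 1L) msg <- c(msg, "nSites must be >= 1")
  if (object@analogCount < 0L) msg <- c(msg, "analogCount must be >= 0")
  if (length(object@analogIds) && object@analogCount != length(object@analogIds))
    msg <- c(msg, "analogCount must equal length(analogIds) when ids are present")
  if (length(msg)) msg else TRUE
})

#' Scaffold derivation result
#'
#' Outcome of deriving the scaffold of one analog series: `single_site`
#' (a single-cut core shared by all analogs), `multi_site` (a multi-cut core
#' covering all analogs with hydrogen permitted at unmatched sites), or
#' `failed` with a defined reason: `ambiguous_sub_series` (the series contains
#' sub-series with structurally different invariant parts that cannot be
#' mapped to one scaffold), `no_common_core`, or `site_limit_exceeded`.
#'
#' @slot outcome character, one of `single_site`, `multi_site`, `failed`.
#' @slot scaffold [ASBScaffold-class] or NULL when failed.
#' @slot failureReason character, NA unless failed.
#' @slot seriesId integer.
#' @aliases DerivationResult
#' @exportClass DerivationResult
setClass("DerivationResult",
  representation(outcome = "character", scaffold = "ANY",
                 failureReason = "character", seriesId = "integer"))

setValidity("DerivationResult", function(object) {
  ok_out <- c("single_site", "multi_site", "failed")
  ok_fail <- c("ambiguous_sub_series", "no_common_core", "site_limit_exceeded")
  if (!object@outcome %in% ok_out) return("invalid outcome")
  if (object@outcome == "failed") {
    if (!is.null(object@scaffold)) return("failed result must not carry a scaffold")
    if (!object@failureReason %in% ok_fail) return("invalid failureReason")
  } else {
    if (!is(object@scaffold, "ASBScaffold"))
      return("non-failed result must carry an ASBScaffold")
    if (!is.na(object@failureReason))
      return("failureReason must be NA unless failed")
  }
  TRUE
})

#' Scaffold collection
#'
#' A (possibly merged and ranked) collection of ASB scaffolds. Canonical forms
#' are unique within a collection; ranking orders scaffolds by decreasing
#' analog count with canonical-SMILES tie-break.
#'
#' @slot scaffolds list of [ASBScaffold-class].
#' @slot sourceLabels character.
#' @slot ranked logical.
#' @slot ranks integer, 1..n without gaps when ranked.
#' @aliases ScaffoldCollection
#' @exportClass ScaffoldCollection
setClass("ScaffoldCollection",
  representation(scaffolds = "list", sourceLabels = "character",
                 ranked = "logical", ranks = "integer"))

setValidity("ScaffoldCollection", function(object) {
  smi <- vapply(object@scaffolds, function(s) s@smiles, character(1))
  if (anyDuplicated(smi))
    return("scaffold canonical forms must be unique within a collection")
  if (object@ranked && length(object@ranks) != length(object@scaffolds))
    return("ranked collection must carry one rank per scaffold")
  TRUE
})

#' Collection summary statistics
#'
#' Summary of a scaffold extraction run: analog-series coverage, the
#' single-/multi-site split, target-annotation counts, per-source breakdown
#' with the number of scaffolds shared between sources, and compound-class
#' based counts (drug-associated, drug-exclusive, alert-associated).
#' Percentages are reported rounded to one decimal (half-up); full precision
#' is retained in the `full` slot.
#'
#' @slot nSeries integer.
#' @slot nScaffolds integer.
#' @slot asCoveragePct numeric, scaffolds/series x 100.
#' @slot pctSingleSite numeric.
#' @slot pctMultiSite numeric.
#' @slot nScaffoldsSingleTarget integer.
#' @slot nScaffoldsMultiTarget integer.
#' @slot pctMultiTarget numeric, multi-target scaffolds / all scaffolds x 100.
#' @slot nUniqueTargets integer.
#' @slot perSource data.frame with columns `source`, `n_scaffolds`.
#' @slot nShared integer, scaffolds present in more than one source.
#' @slot nDrugAssociated integer.
#' @slot nDrugExclusive integer.
#' @slot nAlertAssociated integer.
#' @slot full list, unrounded values.
#' @aliases SummaryStats
#' @exportClass SummaryStats
setClass("SummaryStats",
  representation(
    nSeries = "integer", nScaffolds = "integer", asCoveragePct = "numeric",
    pctSingleSite = "numeric", pctMultiSite = "numeric",
    nScaffoldsSingleTarget = "integer", nScaffoldsMultiTarget = "integer",
    pctMultiTarget = "numeric", nUniqueTargets = "integer",
    perSource = "data.frame", nShared = "integer",
    nDrugAssociated = "integer", nDrugExclusive = "integer",
    nAlertAssociated = "integer", full = "list"))

#' Synthetic library specification
#'
#' Recipe for a combinatorial analog library with known ground truth: a
#' template scaffold with numbered attachment points, one substituent pool per
#' site (every pool member size-rule-compliant against the template), the
#' number of analogs to build, the number of structurally unrelated decoys to
#' add, and a seed.
#'
#' @slot templateSmiles character, scaffold SMILES with `[1*]..[k*]` sites.
#' @slot pools list of character vectors, substituent SMILES with one `[*]`.
#' @slot nAnalogs integer.
#' @slot nDecoys integer.
#' @slot seed integer.
#' @slot label character, id prefix/source label.
#' @aliases LibrarySpec
#' @exportClass LibrarySpec
setClass("LibrarySpec",
  representation(templateSmiles = "character", pools = "list",
                 nAnalogs = "integer", nDecoys = "integer",
                 seed = "integer", label = "character"))

setValidity("LibrarySpec", function(object) {
  msg <- character()
  k <- length(object@pools)
  if (k < 1L) msg <- c(msg, "at least one substituent pool required")
  if (!any(vapply(object@pools, function(p) length(unique(p)) >= 2L, logical(1))))
    msg <- c(msg, "at least one pool must contain >= 2 distinct substituents")
  if (object@nAnalogs < 2L) msg <- c(msg, "nAnalogs must be >= 2")
  if (object@nDecoys < 0L) msg <- c(msg, "nDecoys must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic library
#'
#' What the pipeline is expected to recover from a generated library: the
#' site-normalized canonical SMILES of the template, its site count, the
#' analog member ids, and the expected derivation outcome.
#'
#' @slot expectedScaffold character (NA for negative controls).
#' @slot expectedNSites integer.
#' @slot expectedMemberIds character.
#' @slot expectedOutcome character, a [DerivationResult-class] outcome.
#' @slot bridgeId character, id of the bridging compound of an ambiguous
#'   series (NA otherwise).
#' @aliases GroundTruth
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(expectedScaffold = "character", expectedNSites = "integer",
                 expectedMemberIds = "character", expectedOutcome = "character",
                 bridgeId = "character"))
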