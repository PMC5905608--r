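# Synthetic combinatorial analog libraries with known ground truth: positive
# controls (1-3 substitution sites), structurally unrelated decoys, and an
# ambiguous negative control.

#' Create a synthetic library specification
#'
#' @param templateSmiles scaffold SMILES with numbered attachment points
#'   `[1*]..[k*]`; every attachment bond of an assembled analog must belong to
#'   a retrosynthetic bond class, otherwise recovery is impossible by
#'   construction.
#' @param pools list (one per site) of substituent SMILES, each with a single
#'   `[*]` attachment point and size-rule-compliant against the template.
#' @param nAnalogs number of distinct analogs to build (>= number of sites
#'   + 1, so every site can vary).
#' @param nDecoys number of structurally unrelated decoys to add.
#' @param seed integer seed.
#' @param label id prefix / source label for generated compounds.
#' @return A [LibrarySpec-class].
#' @export
librarySpec <- function(templateSmiles, pools, nAnalogs, nDecoys = 2L,
                        seed = 1L, label = "LIB") {
  methods::new("LibrarySpec", templateSmiles = templateSmiles,
               pools = pools, nAnalogs = as.integer(nAnalogs),
               nDecoys = as.integer(nDecoys), seed = as.integer(seed),
               label = label)
}

#' Built-in library templates
#'
#' Three templates spanning one to three substitution sites, each attached
#' through retrosynthetic bond classes (amide, ether, sulfonamide) with
#' substituent pools that satisfy the size rules by construction:
#' an N-acyl-2-naphthylamine series (1 site), an N-acyl-4-alkoxyaniline
#' series (2 sites), and an N-acyl-alkoxy-benzenesulfonamide series (3
#' sites).
#'
#' @return named list of template definitions (`template`, `pools`,
#'   `max_analogs`).
#' @export
builtinTemplates <- function() list(
  naphthylamide_1site = list(
    template = "[1*]Nc1ccc2ccccc2c1",     # 11 heavy atoms
    pools = list(
      c("[*]C=O", "[*]C(=O)C", "[*]C(=O)CC", "[*]C(=O)CCC",
        "[*]C(=O)C(C)C", "[*]C(=O)C1CC1")),
    max_analogs = 6L),
  alkoxyanilide_2site = list(
    template = "[1*]Nc1ccc(O[2*])cc1",    # 8 heavy atoms
    pools = list(
      c("[*]C=O", "[*]C(=O)C", "[*]C(=O)CC"),
      c("[*]C", "[*]CC", "[*]CCC", "[*]C(C)C", "[*]CCCC")),
    max_analogs = 15L),
  sulfonamide_3site = list(
    template = "[1*]Nc1cc(O[2*])cc(S(=O)(=O)[3*])c1",  # 11 heavy atoms
    pools = list(
      c("[*]C(=O)C", "[*]C(=O)CC"),
      c("[*]C", "[*]CC"),
      c("[*]NC", "[*]NCC", "[*]N(C)C")),
    max_analogs = 12L))

# molecules with no retrosynthetic bond at all: can never join a series
.decoyVocabulary <- function() c(
  "CCCCCCCC", "Cc1ccc2ccccc2c1", "CC(C)Cc1ccccc1", "CCCCc1ccccc1",
  "CC1CCCCC1C", "c1ccc2c(c1)CCCC2", "Cc1cccc(C)c1", "CCC(C)(C)CC",
  "CC(C)(C)c1ccccc1", "C1CCC(CC1)C1CCCCC1")

.assembleAnalog <- function(template_mol, sub_smiles) {
  subs <- lapply(sub_smiles, function(s) {
    m <- parseSmiles(s)
    stopifnot(!is.null(m), .nSitesOf(m) == 1L)
    m
  })
  .attachSubstituents(template_mol, subs)
}

#' Generate a combinatorial analog library
#'
#' Builds `nAnalogs` distinct analogs by attaching pool substituents at the
#' template sites. The first analog uses the first pool entry at every site;
#' each further analog differs from a previously built one at exactly one
#' site, which guarantees that the RMMP network of the library is connected
#' and (for the first `k` steps, which change sites 1..k in turn) that every
#' site varies. Decoys are drawn from a vocabulary of molecules with no
#' retrosynthetic bonds. Reproducible under the spec's seed.
#'
#' @param spec a [LibrarySpec-class].
#' @param config a [PipelineConfig-class].
#' @return list with `compounds` (a [CompoundSet-class]) and `truth`
#'   (a [GroundTruth-class]).
#' @examples
#' tpl <- builtinTemplates()$naphthylamide_1site
#' lib <- generateLibrary(librarySpec(tpl$template, tpl$pools, 3))
#' lib$compounds
#' @export
generateLibrary <- function(spec, config = pipelineConfig()) {
  template <- parseSmiles(spec@templateSmiles)
  if (is.null(template)) stop("invalid template SMILES")
  k <- .nSitesOf(template)
  stopifnot(k >= 1L, k == length(spec@pools))
  pool_sizes <- vapply(spec@pools, length, integer(1))
  if (spec@nAnalogs > prod(pool_sizes))
    stop("substituent pools cannot yield ", spec@nAnalogs,
         " distinct analogs (max ", prod(pool_sizes), ")")
  if (spec@nAnalogs < k + 1L)
    stop("need at least nSites + 1 analogs so every site can vary")

  combos <- withr::with_seed(spec@seed, {
    cmb <- matrix(1L, nrow = spec@nAnalogs, ncol = k)
    for (i in seq_len(spec@nAnalogs)[-1]) {
      repeat {
        base <- cmb[sample.int(i - 1L, 1L), ]
        site <- if (i - 1L <= k) i - 1L else sample.int(k, 1L)
        choices <- setdiff(seq_len(pool_sizes[site]), base[site])
        cand <- base
        cand[site] <- if (length(choices) == 1L) choices else
          sample(choices, 1L)
        if (!any(apply(cmb[seq_len(i - 1L), , drop = FALSE], 1L,
                       identical, y = cand))) {
          cmb[i, ] <- cand
          break
        }
      }
    }
    cmb
  })
  analog_mols <- lapply(seq_len(nrow(combos)), function(i)
    .assembleAnalog(template, mapply(function(p, j) p[[j]], spec@pools,
                                     combos[i, ], SIMPLIFY = TRUE)))
  analog_smiles <- .canonMols(analog_mols)
  stopifnot(!anyDuplicated(analog_smiles))
  ids <- sprintf("%s_A%03d", spec@label, seq_along(analog_smiles))

  decoys <- withr::with_seed(spec@seed + 1L, {
    v <- .decoyVocabulary()
    v[sample.int(length(v), min(spec@nDecoys, length(v)))]
  })
  all_ids <- c(ids, sprintf("%s_D%03d", spec@label, seq_along(decoys)))
  all_smiles <- c(analog_smiles, decoys)

  compounds <- .newCompoundSet(all_ids, all_smiles, spec@label,
                               config = config)
  truth <- methods::new("GroundTruth",
    expectedScaffold = normalizeSiteNumbering(spec@templateSmiles),
    expectedNSites = k, expectedMemberIds = ids,
    expectedOutcome = if (k == 1L) "single_site" else "multi_site",
    bridgeId = NA_character_)
  list(compounds = compounds, truth = truth)
}

#' Generate an ambiguous analog series (negative control)
#'
#' Builds one connected RMMP component containing two sub-series with
#' structurally different invariant parts, joined by a bridging compound:
#' three N-acyl-4-hexyloxyanilines varying the acyl group (the hexyl ether is
#' too large relative to the bare template for a two-site decomposition) and
#' three N-propanoyl-4-alkoxyanilines varying the alkoxy chain. No single- or
#' multi-cut core covers all five compounds, so derivation fails with
#' `ambiguous_sub_series`; with the bridging compound removed, both
#' sub-series resolve as single-site series.
#'
#' @param seed integer; permutes record order only (the construction is
#'   fixed).
#' @param config a [PipelineConfig-class].
#' @return list with `compounds` and `truth` (expected outcome `failed`,
#'   `bridgeId` naming the bridging compound).
#' @export
generateAmbiguousSeries <- function(seed = 1L, config = pipelineConfig()) {
  smi <- c(
    AMB_A1 = "CC(=O)Nc1ccc(OCCCCCC)cc1",     # acetyl,    hexyloxy
    AMB_A2 = "CCCC(=O)Nc1ccc(OCCCCCC)cc1",   # butanoyl,  hexyloxy
    AMB_BR = "CCC(=O)Nc1ccc(OCCCCCC)cc1",    # propanoyl, hexyloxy (bridge)
    AMB_B1 = "CCC(=O)Nc1ccc(OCCCCC)cc1",     # propanoyl, pentyloxy
    AMB_B2 = "CCC(=O)Nc1ccc(OCCCC)cc1")      # propanoyl, butoxy
  ord <- withr::with_seed(seed, sample.int(length(smi)))
  smi <- smi[ord]
  compounds <- .newCompoundSet(names(smi), unname(smi), "AMBIG",
                               config = config)
  truth <- methods::new("GroundTruth",
    expectedScaffold = NA_character_, expectedNSites = 0L,
    expectedMemberIds = sort(names(smi)), expectedOutcome = "failed",
    bridgeId = "AMB_BR")
  list(compounds = compounds, truth = truth)
}
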