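# Derivation of the analog series-based scaffold of a series: single-site
# (a single-cut core shared by all analogs) first, multi-site (a multi-cut
# core covering all analogs, hydrogen permitted at unmatched sites) second,
# with defined failure reasons otherwise.

# ---------------------------------------------------------------------------
# site numbering

# replace the i-th attachment point of a SMILES string (in string order)
# by its numbered form [i*]
.labelSitesInSmiles <- function(smiles) {
  out <- character(); i <- 0L; pos <- 1L
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  while (pos <= n) {
    if (chars[pos] == "*") {
      i <- i + 1L
      bracketed <- pos > 1L && chars[pos - 1L] == "["
      if (bracketed) {
        out[length(out)] <- sprintf("[%d", i)  # rewrite the opening "["
        out <- c(out, "*")
      } else {
        out <- c(out, sprintf("[%d*]", i))
      }
    } else {
      out <- c(out, chars[pos])
    }
    pos <- pos + 1L
  }
  paste(out, collapse = "")
}

#' Canonicalize substitution-site numbering
#'
#' Renumbers the attachment points of a structure 1..n in the atom order of
#' its canonical SMILES, so that two scaffolds identical up to a site
#' permutation map to the same canonical form. Idempotent.
#'
#' @param structure a [MolGraph-class] with attachment points, or its SMILES.
#' @return Same type as the input: the renumbered `MolGraph`, or the
#'   site-normalized canonical SMILES for character input.
#' @examples
#' normalizeSiteNumbering("[2*]c1ccccc1N[1*]") ==
#'   normalizeSiteNumbering("[1*]c1ccccc1N[2*]")
#' @rdname normalizeSiteNumbering
#' @export
setMethod("normalizeSiteNumbering", "MolGraph", function(structure) {
  if (.nSitesOf(structure) == 0L) return(structure)
  s0 <- .canonMol(.stripSiteLabels(structure))
  mol <- parseSmiles(.labelSitesInSmiles(s0))
  stopifnot(!is.null(mol))
  mol
})

#' @rdname normalizeSiteNumbering
#' @export
setMethod("normalizeSiteNumbering", "character", function(structure) {
  mol <- parseSmiles(structure)
  if (is.null(mol)) stop("invalid SMILES: ", structure)
  .canonMol(normalizeSiteNumbering(mol))
})

# ---------------------------------------------------------------------------
# candidate cores

#' Collect the candidate single-cut cores of a series
#'
#' Unions all size-rule-passing single-cut cores over the members of the
#' series with their coverage sets (which members admit a fragmentation with
#' that core), deduplicated on the canonical core string and ordered by
#' decreasing coverage, then decreasing heavy atoms, then canonical string.
#'
#' @param series an [AnalogSeries-class].
#' @param compounds the [CompoundSet-class] the series was extracted from.
#' @param config a [PipelineConfig-class].
#' @return list of core records: `core` ([MolGraph-class] with one attachment
#'   point), `core_can`, `heavy`, `covered_ids`.
#' @export
collectCandidateCores <- function(series, compounds,
                                  config = pipelineConfig()) {
  recs <- new.env(parent = emptyenv())
  order_seen <- character()
  for (id in series@memberIds) {
    mol <- compounds@mols[[match(id, compounds@ids)]]
    if (is.na(match(id, compounds@ids)))
      stop("series member not in compound set: ", id)
    for (f in enumerateSingleCut(mol, config, compound_id = id)) {
      key <- f$core_can
      r <- recs[[key]]
      if (is.null(r)) {
        recs[[key]] <- list(core = f$core, core_can = key,
                            heavy = f$core_heavy, covered_ids = id)
        order_seen <- c(order_seen, key)
      } else {
        r$covered_ids <- union(r$covered_ids, id)
        recs[[key]] <- r
      }
    }
  }
  cores <- lapply(order_seen, function(k) recs[[k]])
  if (length(cores)) {
    ncov <- vapply(cores, function(r) length(r$covered_ids), integer(1))
    hv <- vapply(cores, function(r) r$heavy, integer(1))
    cc <- vapply(cores, function(r) r$core_can, character(1))
    cores <- cores[.corder(-ncov, -hv, cc)]
  }
  cores
}

#' First-generation (single-site) scaffold of a series
#'
#' Searches the candidate cores for one whose coverage equals the full member
#' set, i.e. an RMMP core capturing all pairwise RMMP relationships of the
#' series. When several qualify the largest (most heavy atoms, then canonical
#' string) is chosen. Returns `NULL` when no core covers all members.
#'
#' @param series an [AnalogSeries-class].
#' @param cores output of [collectCandidateCores()].
#' @return An [ASBScaffold-class] with one site, or `NULL`.
#' @export
findSingleSiteScaffold <- function(series, cores) {
  full <- Filter(function(r)
    setequal(r$covered_ids, series@memberIds), cores)
  if (length(full) == 0L) return(NULL)
  hv <- vapply(full, function(r) r$heavy, integer(1))
  cc <- vapply(full, function(r) r$core_can, character(1))
  best <- full[[.corder(-hv, cc)[1]]]
  .mkScaffold(best$core, series)
}

.mkScaffold <- function(core_mol, series, source = NA_character_) {
  structure <- normalizeSiteNumbering(core_mol)
  methods::new("ASBScaffold",
    smiles = .canonMol(structure), structure = structure,
    nSites = .nSitesOf(structure), seriesId = series@seriesId,
    analogIds = series@memberIds,
    analogCount = length(series@memberIds),
    source = source,
    perSourceCounts = stats::setNames(integer(), character()),
    targetIds = character(), classLabels = character())
}

# ---------------------------------------------------------------------------
# multi-site search

# canonical core strings of a member, by number of cuts j = 0..kmax
.memberCoreStrings <- function(mol, config, kmax) {
  out <- vector("list", kmax + 1L)
  out[[1]] <- .canonMol(mol)  # j = 0: the member itself
  out[[2]] <- unique(vapply(enumerateSingleCut(mol, config), `[[`,
                            character(1), "core_can"))
  if (kmax >= 2L) for (j in 2:kmax)
    out[[j + 1L]] <- unique(vapply(enumerateMultiCut(mol, j, config), `[[`,
                                   character(1), "core_can"))
  out
}

# hydrogenated variants of a k-site candidate, grouped by remaining sites j;
# variants[[j+1]] = canonical strings of the candidate with k-j sites deleted
.candidateVariants <- function(core_mol) {
  k <- .nSitesOf(core_mol)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  mols <- apply(subsets, 1L, function(del)
    .hydrogenateSites(core_mol, which(del)))
  cans <- .canonMols(lapply(mols, .stripSiteLabels))
  nleft <- k - rowSums(subsets)
  split(cans, nleft)
}

# does the candidate cover the member (hydrogen allowed at unmatched sites)?
.coversMember <- function(variants, member_strings) {
  for (j in names(variants)) {
    jj <- as.integer(j)
    if (jj + 1L > length(member_strings)) next
    if (any(variants[[j]] %in% member_strings[[jj + 1L]])) return(TRUE)
  }
  FALSE
}

# reduce cores to nonredundant ones: a core is redundant when another core has
# an identical invariant part (structure with the attachment branch deleted)
# and a coverage superset
.nonredundantCores <- function(cores) {
  if (length(cores) <= 1L) return(cores)
  inv <- .canonMols(lapply(cores, function(r)
    .hydrogenateSites(r$core, seq_len(.nSitesOf(r$core)))))
  keep <- rep(TRUE, length(cores))
  for (i in seq_along(cores)) {
    for (j in seq_along(cores)) {
      if (i == j || !keep[j]) next
      if (inv[i] != inv[j]) next
      ci <- cores[[i]]$covered_ids; cj <- cores[[j]]$covered_ids
      if (all(ci %in% cj) && (length(cj) > length(ci) || j < i)) {
        keep[i] <- FALSE; break
      }
    }
  }
  cores[keep]
}

#' Second-generation (multi-site) scaffold of a series
#'
#' Attempted when no single core covers the series. Candidate scaffolds are
#' generated from the members' own multi-cut cores (2..`maxSubstitutionSites`
#' cuts, never by abstract graph merging); a candidate covers a member when
#' the member admits a fragmentation whose core equals the candidate after
#' site renumbering, with hydrogen permitted at unmatched sites. The maximal
#' covering candidate (most heavy atoms, then fewest sites, then canonical
#' string) becomes the scaffold. When none covers all members the failure is
#' diagnosed: coverage achievable with one extra cut means the site limit was
#' exceeded; several coverage-maximal candidates with structurally different
#' invariant parts mean the series splits into sub-series that cannot be
#' unambiguously mapped; otherwise there is no common core.
#'
#' @param series an [AnalogSeries-class].
#' @param compounds the [CompoundSet-class] the series was extracted from.
#' @param cores output of [collectCandidateCores()].
#' @param config a [PipelineConfig-class].
#' @return A [DerivationResult-class].
#' @export
findMultisiteScaffold <- function(series, compounds, cores,
                                  config = pipelineConfig()) {
  kmax <- config@maxSubstitutionSites
  kprobe <- kmax + 1L  # one extra depth, to diagnose site_limit_exceeded
  members <- series@memberIds
  mols <- lapply(members, function(id)
    compounds@mols[[match(id, compounds@ids)]])
  names(mols) <- members
  member_strings <- lapply(mols, .memberCoreStrings, config = config,
                           kmax = kprobe)

  # candidate scaffolds: the members' own multi-cut cores, deduplicated
  cand <- new.env(parent = emptyenv()); cand_keys <- character()
  for (id in members) {
    for (k in 2:kprobe) {
      for (f in enumerateMultiCut(mols[[id]], k, config, compound_id = id)) {
        if (is.null(cand[[f$core_can]])) {
          cand[[f$core_can]] <- list(core = f$core, core_can = f$core_can,
                                     heavy = f$core_heavy, k = f$k)
          cand_keys <- c(cand_keys, f$core_can)
        }
      }
    }
  }
  candidates <- lapply(cand_keys, function(k) cand[[k]])

  coverage <- lapply(candidates, function(cd) {
    v <- .candidateVariants(cd$core)
    members[vapply(member_strings, .coversMember, logical(1), variants = v)]
  })
  is_full <- vapply(coverage, function(cv) setequal(cv, members), logical(1))
  k_of <- vapply(candidates, function(cd) cd$k, integer(1))

  full_ok <- which(is_full & k_of <= kmax)
  if (length(full_ok)) {
    hv <- vapply(candidates[full_ok], function(cd) cd$heavy, integer(1))
    cc <- vapply(candidates[full_ok], function(cd) cd$core_can, character(1))
    best <- candidates[full_ok][[.corder(-hv, k_of[full_ok], cc)[1]]]
    return(methods::new("DerivationResult", outcome = "multi_site",
                        scaffold = .mkScaffold(best$core, series,
                                               compounds@sourceLabel),
                        failureReason = NA_character_,
                        seriesId = series@seriesId))
  }
  fail <- function(reason) methods::new("DerivationResult",
    outcome = "failed", scaffold = NULL, failureReason = reason,
    seriesId = series@seriesId)

  if (any(is_full))            # coverable, but only beyond the site limit
    return(fail("site_limit_exceeded"))

  # partial candidates: nonredundant single-cut cores plus multi-cut
  # candidates; maximal = coverage not strictly contained in another's
  nr <- .nonredundantCores(cores)
  part_mols <- c(lapply(nr, function(r) r$core),
                 lapply(candidates, function(cd) cd$core))
  part_cov <- c(lapply(nr, function(r) r$covered_ids), coverage)
  keep <- vapply(seq_along(part_cov), function(i) {
    length(part_cov[[i]]) >= 2L &&
      !any(vapply(seq_along(part_cov), function(j) {
        j != i && all(part_cov[[i]] %in% part_cov[[j]]) &&
          length(part_cov[[j]]) > length(part_cov[[i]])
      }, logical(1)))
  }, logical(1))
  if (!any(keep)) return(fail("no_common_core"))
  inv <- unique(.canonMols(lapply(part_mols[keep], function(m)
    .hydrogenateSites(m, seq_len(.nSitesOf(m))))))
  if (length(inv) >= 2L) fail("ambiguous_sub_series") else
    fail("no_common_core")
}

#' Derive the scaffold of an analog series
#'
#' Two-stage orchestration: the single-site search is attempted first; the
#' multi-site search only on its failure. A series yields at most one
#' scaffold.
#'
#' @param series an [AnalogSeries-class].
#' @param compounds the [CompoundSet-class] the series was extracted from.
#' @param config a [PipelineConfig-class].
#' @return A [DerivationResult-class].
#' @examples
#' \dontrun{
#' res <- deriveAsbScaffold(series, compounds)
#' outcome(res)
#' }
#' @export
deriveAsbScaffold <- function(series, compounds, config = pipelineConfig()) {
  cores <- collectCandidateCores(series, compounds, config)
  single <- findSingleSiteScaffold(series, cores)
  if (!is.null(single)) {
    single@source <- compounds@sourceLabel
    return(methods::new("DerivationResult", outcome = "single_site",
                        scaffold = single, failureReason = NA_character_,
                        seriesId = series@seriesId))
  }
  findMultisiteScaffold(series, compounds, cores, config)
}

#' Does a scaffold cover a compound?
#'
#' Checks the defining substructure property of a scaffold: the compound
#' decomposes as the scaffold structure plus substituents placed only at
#' designated sites, with hydrogen permitted at a site.
#'
#' @param scaffold an [ASBScaffold-class] or a [MolGraph-class] with numbered
#'   attachment points.
#' @param compound a [MolGraph-class] or SMILES string.
#' @param config a [PipelineConfig-class].
#' @return logical scalar.
#' @export
scaffoldCoversCompound <- function(scaffold, compound,
                                   config = pipelineConfig()) {
  smol <- if (is(scaffold, "ASBScaffold")) scaffold@structure else scaffold
  cmol <- if (is.character(compound)) parseSmiles(compound) else compound
  stopifnot(is(smol, "MolGraph"), is(cmol, "MolGraph"))
  k <- .nSitesOf(smol)
  strings <- .memberCoreStrings(cmol, config, kmax = k)
  .coversMember(.candidateVariants(smol), strings)
}

# ---------------------------------------------------------------------------
# accessors / show

#' Accessors for scaffolds
#'
#' @param x an [ASBScaffold-class].
#' @name ASBScaffold-accessors
NULL

#' @rdname ASBScaffold-accessors
#' @export
setMethod("scaffoldSmiles", "ASBScaffold", function(x) x@smiles)
#' @rdname ASBScaffold-accessors
#' @export
setMethod("nSites", "ASBScaffold", function(x) x@nSites)
#' @rdname ASBScaffold-accessors
#' @export
setMethod("analogCount", "ASBScaffold", function(x) x@analogCount)
#' @rdname ASBScaffold-accessors
#' @export
setMethod("analogIds", "ASBScaffold", function(x) x@analogIds)
#' @rdname ASBScaffold-accessors
#' @export
setMethod("scaffoldSource", "ASBScaffold", function(x) x@source)
#' @rdname ASBScaffold-accessors
#' @export
setMethod("targetIds", "ASBScaffold", function(x) x@targetIds)
#' @rdname ASBScaffold-accessors
#' @export
setMethod("classLabels", "ASBScaffold", function(x) x@classLabels)

#' @describeIn ASBScaffold-class compact display
#' @param object an `ASBScaffold`
#' @export
setMethod("show", "ASBScaffold", function(object) {
  cat(sprintf("ASBScaffold (%d site(s), %d analog(s), source %s)\n  %s\n",
              object@nSites, object@analogCount, object@source,
              object@smiles))
})

#' Accessors for derivation results
#'
#' @param x a [DerivationResult-class].
#' @name DerivationResult-accessors
NULL

#' @rdname DerivationResult-accessors
#' @export
setMethod("outcome", "DerivationResult", function(x) x@outcome)
#' @rdname DerivationResult-accessors
#' @export
setMethod("scaffold", "DerivationResult", function(x) x@scaffold)
#' @rdname DerivationResult-accessors
#' @export
setMethod("failureReason", "DerivationResult", function(x) x@failureReason)

#' @describeIn DerivationResult-class compact display
#' @param object a `DerivationResult`
#' @export
setMethod("show", "DerivationResult", function(object) {
  if (object@outcome == "failed")
    cat(sprintf("DerivationResult: failed (%s), series %d\n",
                object@failureReason, object@seriesId))
  else
    cat(sprintf("DerivationResult: %s, series %d, scaffold %s\n",
                object@outcome, object@seriesId, object@scaffold@smiles))
})
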