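# Scaffold annotation, cross-source merging, ranking, and collection
# statistics.

# one-decimal half-up rounding used for reported percentages
.round1 <- function(x) floor(x * 10 + 0.5) / 10

#' Annotate a scaffold with its analogs' targets and classes
#'
#' Sets the scaffold's target ids and class labels to the union of its
#' members' annotations.
#'
#' @param scaffold an [ASBScaffold-class].
#' @param compounds the [CompoundSet-class] containing the analogs.
#' @return The annotated [ASBScaffold-class].
#' @export
annotateScaffold <- function(scaffold, compounds) {
  idx <- match(scaffold@analogIds, compounds@ids)
  if (anyNA(idx))
    stop("scaffold references unknown analog id(s): ",
         paste(scaffold@analogIds[is.na(idx)], collapse = ", "))
  scaffold@targetIds <- sort(unique(unlist(compounds@targets[idx])))
  scaffold@classLabels <- sort(unique(unlist(compounds@classes[idx])))
  scaffold
}

#' Build a scaffold collection from derivation results
#'
#' Collects the scaffolds of the non-failed results into an unranked
#' [ScaffoldCollection-class], annotating each from the compound set. Within
#' one source, distinct series can yield the same canonical scaffold; such
#' scaffolds are merged (annotation union, analog ids union).
#'
#' @param results list of [DerivationResult-class].
#' @param compounds the [CompoundSet-class].
#' @return A [ScaffoldCollection-class].
#' @export
collectScaffolds <- function(results, compounds) {
  scs <- list()
  for (r in results) {
    if (r@outcome == "failed") next
    s <- annotateScaffold(r@scaffold, compounds)
    s@source <- compounds@sourceLabel
    s@perSourceCounts <- stats::setNames(s@analogCount, compounds@sourceLabel)
    key <- match(s@smiles, vapply(scs, function(x) x@smiles, character(1)))
    if (length(scs) && !is.na(key)) {
      old <- scs[[key]]
      old@analogIds <- sort(union(old@analogIds, s@analogIds))
      old@analogCount <- length(old@analogIds)
      old@perSourceCounts <- stats::setNames(old@analogCount,
                                             compounds@sourceLabel)
      old@targetIds <- sort(union(old@targetIds, s@targetIds))
      old@classLabels <- sort(union(old@classLabels, s@classLabels))
      scs[[key]] <- old
    } else {
      scs <- c(scs, s)
    }
  }
  methods::new("ScaffoldCollection", scaffolds = scs,
               sourceLabels = compounds@sourceLabel,
               ranked = FALSE, ranks = integer())
}

#' Merge two scaffold collections
#'
#' Union on the site-normalized canonical form. A scaffold present in both
#' collections keeps both source labels (reported as `"both"`), the union of
#' its annotations, and its analog count per source (the displayed count is
#' the per-source maximum). `|result| = |a| + |b| - |shared|`.
#'
#' @param a,b internally deduplicated [ScaffoldCollection-class] objects.
#' @return An unranked merged [ScaffoldCollection-class]; the number of shared
#'   scaffolds is available as `attr(x, "nShared")` on the returned object's
#'   scaffold list or via [summarizeCollection()].
#' @export
mergeCollections <- function(a, b) {
  smi_a <- vapply(a@scaffolds, function(s) s@smiles, character(1))
  smi_b <- vapply(b@scaffolds, function(s) s@smiles, character(1))
  out <- a@scaffolds
  for (i in seq_along(b@scaffolds)) {
    s <- b@scaffolds[[i]]
    j <- match(smi_b[i], smi_a)
    if (is.na(j)) {
      out <- c(out, s)
    } else {
      m <- out[[j]]
      m@perSourceCounts <- c(m@perSourceCounts, s@perSourceCounts)
      m@analogCount <- max(m@perSourceCounts)
      m@analogIds <- sort(union(m@analogIds, s@analogIds))
      m@targetIds <- sort(union(m@targetIds, s@targetIds))
      m@classLabels <- sort(union(m@classLabels, s@classLabels))
      m@source <- "both"
      out[[j]] <- m
    }
  }
  methods::new("ScaffoldCollection", scaffolds = out,
               sourceLabels = unique(c(a@sourceLabels, b@sourceLabels)),
               ranked = FALSE, ranks = integer())
}

#' Rank a scaffold collection
#'
#' Orders scaffolds by decreasing analog count, ties broken by canonical
#' SMILES (ascending, C locale); ranks are 1..n without gaps. Idempotent.
#'
#' @param collection a [ScaffoldCollection-class].
#' @return The ranked collection.
#' @export
rankScaffolds <- function(collection) {
  sc <- collection@scaffolds
  if (length(sc) == 0L)
    return(methods::new("ScaffoldCollection", scaffolds = sc,
                        sourceLabels = collection@sourceLabels,
                        ranked = TRUE, ranks = integer()))
  cnt <- vapply(sc, function(s) s@analogCount, integer(1))
  smi <- vapply(sc, function(s) s@smiles, character(1))
  ord <- .corder(-cnt, smi)
  methods::new("ScaffoldCollection", scaffolds = sc[ord],
               sourceLabels = collection@sourceLabels,
               ranked = TRUE, ranks = seq_along(ord))
}

#' Summarize an extraction
#'
#' Computes the collection statistics: series and scaffold counts, analog
#' series coverage (scaffolds/series x 100), single-/multi-site percentages,
#' target-annotation counts (single = exactly one target, multi = two or
#' more), number of unique targets, per-source scaffold counts with the
#' number shared between sources (inclusion-exclusion:
#' `|union| = sum(per source) - shared` for two sources), and class-based
#' counts (scaffolds representing at least one drug, exclusively drugs, or at
#' least one alert compound). Reported percentages are rounded to one decimal
#' (half-up); unrounded values are kept in the `full` slot.
#'
#' @param seriesSets list of [AnalogSeriesSet-class] (one per source).
#' @param results list of [DerivationResult-class] (all sources).
#' @param merged the merged [ScaffoldCollection-class].
#' @return A [SummaryStats-class].
#' @export
summarizeCollection <- function(seriesSets, results, merged) {
  if (is(seriesSets, "AnalogSeriesSet")) seriesSets <- list(seriesSets)
  n_series <- sum(vapply(seriesSets, function(s) length(s@series), integer(1)))
  outc <- vapply(results, function(r) r@outcome, character(1))
  n_scaf <- sum(outc != "failed")
  sc <- merged@scaffolds
  nsites <- vapply(sc, function(s) s@nSites, integer(1))
  ntarg <- vapply(sc, function(s) length(s@targetIds), integer(1))
  cls <- lapply(sc, function(s) s@classLabels)
  srcs <- vapply(sc, function(s) s@source, character(1))
  n_uniq <- length(sc)

  per_source <- do.call(rbind, lapply(merged@sourceLabels, function(lb)
    data.frame(source = lb, n_scaffolds = sum(vapply(sc, function(s)
      lb %in% names(s@perSourceCounts) || identical(s@source, lb),
      logical(1))))))
  if (is.null(per_source))
    per_source <- data.frame(source = character(), n_scaffolds = integer())
  n_shared <- sum(srcs == "both")

  pct <- function(x, denom) if (denom > 0) 100 * x / denom else 0
  full <- list(
    as_coverage_pct = pct(n_scaf, n_series),
    pct_single_site = pct(sum(nsites == 1L), n_uniq),
    pct_multi_site = pct(sum(nsites > 1L), n_uniq),
    pct_multi_target = pct(sum(ntarg >= 2L), n_uniq))

  methods::new("SummaryStats",
    nSeries = n_series, nScaffolds = as.integer(n_scaf),
    asCoveragePct = .round1(full$as_coverage_pct),
    pctSingleSite = .round1(full$pct_single_site),
    pctMultiSite = .round1(full$pct_multi_site),
    nScaffoldsSingleTarget = sum(ntarg == 1L),
    nScaffoldsMultiTarget = sum(ntarg >= 2L),
    pctMultiTarget = .round1(full$pct_multi_target),
    nUniqueTargets = length(unique(unlist(lapply(sc, function(s)
      s@targetIds)))),
    perSource = per_source, nShared = as.integer(n_shared),
    nDrugAssociated = sum(vapply(cls, function(x) "drug" %in% x, logical(1))),
    nDrugExclusive = sum(vapply(cls, function(x)
      length(x) > 0L && all(x == "drug"), logical(1))),
    nAlertAssociated = sum(vapply(cls, function(x) "alert" %in% x,
                                  logical(1))),
    full = full)
}

#' Write summary statistics
#'
#' @param stats a [SummaryStats-class].
#' @param path output file.
#' @param format `"json"` or `"yaml"`.
#' @return `path`, invisibly.
#' @export
writeSummaryStats <- function(stats, path, format = c("json", "yaml")) {
  format <- match.arg(format)
  x <- list(
    n_series = stats@nSeries, n_scaffolds = stats@nScaffolds,
    as_coverage_pct = stats@asCoveragePct,
    pct_single_site = stats@pctSingleSite,
    pct_multi_site = stats@pctMultiSite,
    n_scaffolds_single_target = stats@nScaffoldsSingleTarget,
    n_scaffolds_multi_target = stats@nScaffoldsMultiTarget,
    pct_multi_target = stats@pctMultiTarget,
    n_unique_targets = stats@nUniqueTargets,
    per_source = stats@perSource, n_shared = stats@nShared,
    n_drug_associated = stats@nDrugAssociated,
    n_drug_exclusive = stats@nDrugExclusive,
    n_alert_associated = stats@nAlertAssociated)
  if (format == "json")
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  else
    yaml::write_yaml(x, path)
  invisible(path)
}

#' Accessors for scaffold collections
#'
#' @param x a [ScaffoldCollection-class].
#' @name ScaffoldCollection-accessors
NULL

#' @rdname ScaffoldCollection-accessors
#' @export
setMethod("scaffolds", "ScaffoldCollection", function(x) x@scaffolds)
#' @rdname ScaffoldCollection-accessors
#' @export
setMethod("isRanked", "ScaffoldCollection", function(x) x@ranked)
#' @rdname ScaffoldCollection-accessors
#' @export
setMethod("scaffoldRanks", "ScaffoldCollection", function(x) x@ranks)

#' @describeIn ScaffoldCollection-class number of scaffolds
#' @param x,object a `ScaffoldCollection`
#' @export
setMethod("length", "ScaffoldCollection", function(x) length(x@scaffolds))

#' @describeIn ScaffoldCollection-class compact display
#' @export
setMethod("show", "ScaffoldCollection", function(object) {
  cat(sprintf("ScaffoldCollection: %d scaffold(s) from %s%s\n",
              length(object@scaffolds),
              paste(object@sourceLabels, collapse = "+"),
              if (object@ranked) " (ranked)" else ""))
})

#' @describeIn SummaryStats-class display
#' @param object a `SummaryStats`
#' @export
setMethod("show", "SummaryStats", function(object) {
  cat("Extraction summary\n")
  cat(sprintf("  analog series:      %d\n", object@nSeries))
  cat(sprintf("  scaffolds derived:  %d (AS coverage %.1f%%)\n",
              object@nScaffolds, object@asCoveragePct))
  cat(sprintf("  unique scaffolds:   %d (%d shared across sources)\n",
              sum(object@perSource$n_scaffolds) - object@nShared,
              object@nShared))
  cat(sprintf("  single/multi site:  %.1f%% / %.1f%%\n",
              object@pctSingleSite, object@pctMultiSite))
  cat(sprintf("  target annotations: %d single, %d multi (%.1f%% MT), %d unique targets\n",
              object@nScaffoldsSingleTarget, object@nScaffoldsMultiTarget,
              object@pctMultiTarget, object@nUniqueTargets))
  cat(sprintf("  classes:            %d drug-associated, %d drug-exclusive, %d alert-associated\n",
              object@nDrugAssociated, object@nDrugExclusive,
              object@nAlertAssociated))
})
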