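# End-to-end orchestration: read, fragment, pair, extract series, derive
# scaffolds, annotate, merge, rank, write.

#' Run a full scaffold extraction
#'
#' For each input collection: read and standardize compounds, build the
#' single-cut core index, generate RECAP matched molecular pairs, extract
#' analog series, derive one scaffold per series, and annotate. Collections
#' are then merged across sources (union on canonical form, shared scaffolds
#' labelled `"both"`), ranked by analog count, and written to `out_dir`:
#'
#' * `scaffolds.tsv` - the ranked deposition-style scaffold table
#' * `stats.json` - summary statistics ([summarizeCollection()])
#' * `failures.tsv` - series that yielded no scaffold, with reasons
#' * `manifest.json` - configuration snapshot, input digests, stage counts
#'
#' All outputs are deterministic given inputs and configuration.
#'
#' @param inputs list of input descriptors, each a list/vector with elements
#'   `path`, `format` (`"smiles"` or `"sdf"`) and `source` (label).
#' @param config a [PipelineConfig-class].
#' @param out_dir output directory (created if needed).
#' @return The run manifest, invisibly (a list; also written as JSON).
#' @export
runExtraction <- function(inputs, config = pipelineConfig(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "read"
  manifest <- list(
    tool = "asbscaffolds",
    version = as.character(utils::packageVersion("asbscaffolds")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = list(
      max_substituent_heavy_atoms = config@maxSubstituentHeavyAtoms,
      core_to_substituent_min_ratio = config@coreToSubstituentMinRatio,
      max_exchange_size_difference = config@maxExchangeSizeDifference,
      max_substitution_sites = config@maxSubstitutionSites,
      min_series_size = config@minSeriesSize,
      keep_stereo = config@keepStereo,
      random_seed = config@randomSeed,
      enabled_rules = config@enabledRules),
    inputs = lapply(inputs, function(inp) list(
      path = inp[["path"]], format = inp[["format"]],
      source = inp[["source"]],
      md5 = unname(tools::md5sum(inp[["path"]])))),
    stages = list())

  collections <- list(); seriesSets <- list(); all_results <- list()
  failures <- data.frame(series_id = integer(), source = character(),
                         failure_reason = character(), n_members = integer())
  res <- tryCatch({
    for (inp in inputs) {
      src <- inp[["source"]]
      stage <- paste0("read:", src)
      cs <- readCompounds(inp[["path"]], inp[["format"]], src, config)
      stage <- paste0("fragment:", src)
      idx <- buildCoreIndex(cs, config)
      stage <- paste0("pairs:", src)
      rmmps <- generateRmmps(idx, config)
      stage <- paste0("series:", src)
      ss <- extractAnalogSeries(cs, rmmps, config)
      stage <- paste0("scaffolds:", src)
      results <- lapply(ss@series, deriveAsbScaffold, compounds = cs,
                        config = config)
      coll <- collectScaffolds(results, cs)
      for (r in results) if (r@outcome == "failed")
        failures <- rbind(failures, data.frame(
          series_id = r@seriesId, source = src,
          failure_reason = r@failureReason,
          n_members = length(ss@series[[r@seriesId]]@memberIds)))
      outc <- vapply(results, function(r) r@outcome, character(1))
      manifest$stages[[src]] <- list(
        compounds_read = length(cs) + nrow(cs@parseFailures) +
          nrow(cs@duplicates),
        compounds_kept = length(cs),
        parse_failures = nrow(cs@parseFailures),
        duplicates_merged = nrow(cs@duplicates),
        fragmentations = nrow(idx@entries),
        rmmps = nrow(rmmps),
        series = length(ss@series),
        singletons = length(ss@singletonIds),
        small_components = length(ss@smallComponentIds),
        scaffolds_single_site = sum(outc == "single_site"),
        scaffolds_multi_site = sum(outc == "multi_site"),
        failed = sum(outc == "failed"),
        failed_by_reason = as.list(table(vapply(
          results[outc == "failed"], function(r) r@failureReason,
          character(1)))))
      # stage-count consistency: series members + singletons + undersized
      # components partition the compound set
      n_in_series <- sum(vapply(ss@series, function(s)
        length(s@memberIds), integer(1)))
      stopifnot(n_in_series + length(ss@singletonIds) +
                  length(ss@smallComponentIds) == length(cs))
      collections[[src]] <- coll
      seriesSets[[src]] <- ss
      all_results <- c(all_results, results)
    }
    stage <- "merge"
    merged <- Reduce(mergeCollections, collections)
    stage <- "rank"
    ranked <- rankScaffolds(merged)
    stage <- "write"
    writeScaffoldTable(ranked, file.path(out_dir, "scaffolds.tsv"))
    stats <- summarizeCollection(seriesSets, all_results, ranked)
    writeSummaryStats(stats, file.path(out_dir, "stats.json"))
    writeLines(c("series_id\tsource\tfailure_reason\tn_members",
                 if (nrow(failures)) sprintf("%d\t%s\t%s\t%d",
                   failures$series_id, failures$source,
                   failures$failure_reason, failures$n_members)),
               file.path(out_dir, "failures.tsv"))
    manifest$n_unique_scaffolds <- length(ranked)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest
  }, error = function(e) {
    stop(sprintf("extraction failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}
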