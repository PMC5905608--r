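# Reading and standardizing compound collections; configuration; scaffold
# table serialization.

#' Create a pipeline configuration
#'
#' @param maxSubstituentHeavyAtoms substituent heavy-atom cap (default 13).
#' @param coreToSubstituentMinRatio minimum core/substituent heavy-atom ratio
#'   (default 2.0).
#' @param maxExchangeSizeDifference maximum heavy-atom difference between the
#'   two exchanged substituents of a matched pair (default 8).
#' @param maxSubstitutionSites maximum number of scaffold substitution sites
#'   (default 4).
#' @param minSeriesSize minimum analog-series size (default 2).
#' @param keepStereo keep stereo descriptors in stored compound SMILES
#'   (default TRUE).
#' @param randomSeed integer seed for seeded operations (default 1).
#' @param enabledRules retrosynthetic bond classes to perceive; defaults to
#'   all of [retrosyntheticRuleIds()].
#' @return A [PipelineConfig-class].
#' @examples
#' pipelineConfig(maxSubstituentHeavyAtoms = 10)
#' @export
pipelineConfig <- function(maxSubstituentHeavyAtoms = 13L,
                           coreToSubstituentMinRatio = 2.0,
                           maxExchangeSizeDifference = 8L,
                           maxSubstitutionSites = 4L,
                           minSeriesSize = 2L,
                           keepStereo = TRUE,
                           randomSeed = 1L,
                           enabledRules = retrosyntheticRuleIds()) {
  methods::new("PipelineConfig",
    maxSubstituentHeavyAtoms = as.integer(maxSubstituentHeavyAtoms),
    coreToSubstituentMinRatio = as.numeric(coreToSubstituentMinRatio),
    maxExchangeSizeDifference = as.integer(maxExchangeSizeDifference),
    maxSubstitutionSites = as.integer(maxSubstitutionSites),
    minSeriesSize = as.integer(minSeriesSize),
    keepStereo = isTRUE(keepStereo),
    randomSeed = as.integer(randomSeed),
    enabledRules = enabledRules)
}

#' Read or write a pipeline configuration as YAML
#'
#' The YAML file mirrors the configuration fields in snake_case
#' (`max_substituent_heavy_atoms`, `core_to_substituent_min_ratio`,
#' `max_exchange_size_difference`, `max_substitution_sites`,
#' `min_series_size`, `keep_stereo`, `random_seed`, `enabled_rules`).
#'
#' @param path file path.
#' @return `readPipelineConfig` returns a [PipelineConfig-class];
#'   `writePipelineConfig` returns `path` invisibly.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- pipelineConfig()
  get <- function(key, dflt) if (!is.null(y[[key]])) y[[key]] else dflt
  pipelineConfig(
    maxSubstituentHeavyAtoms = get("max_substituent_heavy_atoms",
                                   defaults@maxSubstituentHeavyAtoms),
    coreToSubstituentMinRatio = get("core_to_substituent_min_ratio",
                                    defaults@coreToSubstituentMinRatio),
    maxExchangeSizeDifference = get("max_exchange_size_difference",
                                    defaults@maxExchangeSizeDifference),
    maxSubstitutionSites = get("max_substitution_sites",
                               defaults@maxSubstitutionSites),
    minSeriesSize = get("min_series_size", defaults@minSeriesSize),
    keepStereo = get("keep_stereo", defaults@keepStereo),
    randomSeed = get("random_seed", defaults@randomSeed),
    enabledRules = unlist(get("enabled_rules", defaults@enabledRules)))
}

#' @param config a [PipelineConfig-class].
#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(list(
    max_substituent_heavy_atoms = config@maxSubstituentHeavyAtoms,
    core_to_substituent_min_ratio = config@coreToSubstituentMinRatio,
    max_exchange_size_difference = config@maxExchangeSizeDifference,
    max_substitution_sites = config@maxSubstitutionSites,
    min_series_size = config@minSeriesSize,
    keep_stereo = config@keepStereo,
    random_seed = config@randomSeed,
    enabled_rules = config@enabledRules), path)
  invisible(path)
}

# locale-independent string ordering used everywhere strings break ties
.corder <- function(...) order(..., method = "radix")

# ---------------------------------------------------------------------------
# standardization

# SMILES -> list(smiles, constitution, mol) or character scalar (reason)
.standardizeSmiles <- function(smiles, config) {
  can0 <- .obCanonicalSmiles(smiles)
  if (is.na(can0)) return("unparsable SMILES")
  # largest covalent fragment: canonical SMILES writes components dot-separated
  parts <- strsplit(can0, ".", fixed = TRUE)[[1]]
  if (length(parts) > 1L) {
    hv <- vapply(parts, function(p) {
      m <- parseSmiles(p)
      if (is.null(m)) -1L else .heavyCount(m)
    }, integer(1))
    if (all(hv < 0L)) return("unparsable fragment")
    parts <- parts[.corder(-hv, parts)]
    can0 <- parts[[1]]
  }
  neutral <- .obCanonicalSmiles(can0, op = "neutralize")
  if (is.na(neutral)) neutral <- can0
  mol <- parseSmiles(neutral)
  if (is.null(mol) || .heavyCount(mol) == 0L)
    return("empty structure after standardization")
  if (any(mol@atoms$elem == "*"))
    return("compound contains attachment points")
  constitution <- .canonMol(mol)
  stored <- if (config@keepStereo) neutral else constitution
  list(smiles = stored, constitution = constitution, mol = mol)
}

#' Standardize a structure
#'
#' Applies the package's standardization protocol: keep the largest covalent
#' fragment (salt/solvent stripping), neutralize charges where a neutral form
#' exists, perceive aromaticity under OpenBabel's model, and keep or strip
#' stereo descriptors per `config@keepStereo`. Standardization is idempotent.
#'
#' @param raw a SMILES string or a [MolGraph-class].
#' @param config a [PipelineConfig-class].
#' @return For a character input, the standardized canonical SMILES; for a
#'   `MolGraph`, the standardized `MolGraph`. Errors if standardization
#'   rejects the structure.
#' @examples
#' standardizeStructure("CC(=O)[O-].[Na+]")  # -> acetic acid
#' @rdname standardizeStructure
#' @export
setMethod("standardizeStructure", "character", function(raw, config) {
  res <- .standardizeSmiles(raw, config)
  if (is.character(res)) stop("standardization failed: ", res)
  res$smiles
})

#' @rdname standardizeStructure
#' @export
setMethod("standardizeStructure", "MolGraph", function(raw, config) {
  res <- .standardizeSmiles(.canonMol(raw), config)
  if (is.character(res)) stop("standardization failed: ", res)
  res$mol
})

# ---------------------------------------------------------------------------
# CompoundSet construction

.splitAnno <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(x)) character() else
    strsplit(x, ";", fixed = TRUE)[[1]]
}

# build a standardized, deduplicated CompoundSet from raw records
.newCompoundSet <- function(ids, smiles, sourceLabel,
                            targets = NULL, classes = NULL,
                            config = pipelineConfig()) {
  n <- length(ids)
  stopifnot(length(smiles) == n)
  if (is.null(targets)) targets <- rep(list(character()), n)
  if (is.null(classes)) classes <- rep(list(character()), n)
  if (anyDuplicated(ids))
    stop("duplicate compound ids in input: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  keep_ids <- character(); keep_smiles <- character()
  keep_const <- character(); keep_mols <- list()
  keep_targets <- list(); keep_classes <- list()
  fail <- data.frame(id = character(), reason = character())
  dup <- data.frame(kept_id = character(), dropped_id = character())
  seen <- new.env(parent = emptyenv())

  for (i in seq_len(n)) {
    res <- .standardizeSmiles(smiles[i], config)
    if (is.character(res)) {
      fail <- rbind(fail, data.frame(id = ids[i], reason = res))
      next
    }
    key <- res$smiles
    j <- seen[[key]]
    if (!is.null(j)) {
      # structure-level duplicate: first-seen id kept, annotations merged
      keep_targets[[j]] <- sort(union(keep_targets[[j]], targets[[i]]))
      keep_classes[[j]] <- sort(union(keep_classes[[j]], classes[[i]]))
      dup <- rbind(dup, data.frame(kept_id = keep_ids[j], dropped_id = ids[i]))
      next
    }
    keep_ids <- c(keep_ids, ids[i])
    keep_smiles <- c(keep_smiles, res$smiles)
    keep_const <- c(keep_const, res$constitution)
    keep_mols <- c(keep_mols, list(res$mol))
    keep_targets <- c(keep_targets, list(sort(unique(targets[[i]]))))
    keep_classes <- c(keep_classes, list(sort(unique(classes[[i]]))))
    seen[[key]] <- length(keep_ids)
  }
  if (nrow(fail))
    message(sprintf("readCompounds [%s]: %d record(s) failed to parse: %s",
                    sourceLabel, nrow(fail), paste(fail$id, collapse = ", ")))
  if (nrow(dup))
    message(sprintf("readCompounds [%s]: %d structure duplicate(s) merged: %s",
                    sourceLabel,
                    nrow(dup),
                    paste(sprintf("%s<-%s", dup$kept_id, dup$dropped_id),
                          collapse = ", ")))
  methods::new("CompoundSet",
    ids = keep_ids, smiles = keep_smiles, constitution = keep_const,
    mols = keep_mols, sourceLabel = sourceLabel,
    targets = keep_targets, classes = keep_classes,
    parseFailures = fail, duplicates = dup)
}

#' Read a compound collection
#'
#' Reads a SMILES table or an SDF file, standardizes every record
#' ([standardizeStructure()]), deduplicates at structure level (first-seen id
#' kept, annotations merged as the union), and logs parse failures and
#' duplicates on the returned object.
#'
#' The SMILES-table dialect is tab-separated with columns `id`, `smiles` and
#' optional `targets` and `classes` columns (semicolon-joined lists); lines
#' starting with `#` are ignored. SDF records take the identifier from the
#' molecule title line and annotations from the SD tags `TARGETS` and
#' `CLASSES`.
#'
#' @param path input file.
#' @param format `"smiles"` (table dialect above) or `"sdf"`.
#' @param sourceLabel label attached to the collection (e.g. `"CHEMBL"`).
#' @param config a [PipelineConfig-class].
#' @return A [CompoundSet-class]; record order is preserved.
#' @export
readCompounds <- function(path, format = c("smiles", "sdf"), sourceLabel,
                          config = pipelineConfig()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "smiles") {
    ln <- readLines(path, warn = FALSE)
    ln <- ln[nzchar(trimws(ln)) & !grepl("^\\s*#", ln)]
    if (length(ln) == 0L)
      return(.newCompoundSet(character(), character(), sourceLabel,
                             config = config))
    f <- strsplit(ln, "\t", fixed = TRUE)
    if (any(vapply(f, length, integer(1)) < 2L))
      stop("malformed smiles table: every row needs id<TAB>smiles")
    ids <- vapply(f, `[`, character(1), 1L)
    smi <- vapply(f, `[`, character(1), 2L)
    targets <- lapply(f, function(x) .splitAnno(x[3]))
    classes <- lapply(f, function(x) .splitAnno(x[4]))
  } else {
    sdfset <- ChemmineR::read.SDFset(path)
    ids <- character(); smi <- character()
    targets <- list(); classes <- list()
    for (i in seq_along(sdfset@SDF)) {
      sdf <- sdfset@SDF[[i]]
      hdr <- ChemmineR::header(sdf)
      id <- trimws(hdr[["Molecule_Name"]])
      if (!nzchar(id)) id <- sprintf("record_%d", i)
      block <- paste(c(ChemmineR::sdfstr2list(
        methods::as(sdfset[i], "SDFstr"))[[1]]), collapse = "\n")
      s <- .obConvert("SDF", "CAN", paste0(block, "\n"))
      s <- sub("[ \t].*$", "", sub("\n.*$", "", s))
      db <- ChemmineR::datablock(sdf)
      ids <- c(ids, id)
      smi <- c(smi, if (nzchar(s)) s else NA_character_)
      targets <- c(targets, list(.splitAnno(db["TARGETS"][[1]])))
      classes <- c(classes, list(.splitAnno(db["CLASSES"][[1]])))
    }
  }
  .newCompoundSet(ids, smi, sourceLabel, targets, classes, config)
}

#' Write compounds as a SMILES table
#'
#' Writes the tab-separated dialect read by [readCompounds()]: columns `id`,
#' `smiles`, `targets`, `classes` (semicolon-joined).
#'
#' @param compounds a [CompoundSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCompoundTable <- function(compounds, path) {
  join <- function(l) vapply(l, paste, character(1), collapse = ";")
  ln <- sprintf("%s\t%s\t%s\t%s", compounds@ids, compounds@smiles,
                join(compounds@targets), join(compounds@classes))
  writeLines(ln, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# scaffold tables

.scaffoldTableHeader <- c("rank", "scaffold_smiles", "n_sites", "n_analogs",
                          "source", "target_ids", "class_labels")

#' Write a ranked scaffold collection as the deposition-style table
#'
#' Tab-separated, one row per scaffold, columns `rank`, `scaffold_smiles`
#' (site-normalized canonical SMILES), `n_sites`, `n_analogs`, `source`
#' (`"both"` for scaffolds shared between two sources), `target_ids` and
#' `class_labels` (semicolon-joined, empty allowed). Rows are written in rank
#' order.
#'
#' @param collection a ranked [ScaffoldCollection-class] (see
#'   [rankScaffolds()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeScaffoldTable <- function(collection, path) {
  if (!collection@ranked)
    stop("collection is not ranked; call rankScaffolds() first")
  sc <- collection@scaffolds
  ord <- order(collection@ranks)
  rows <- vapply(ord, function(i) {
    s <- sc[[i]]
    paste(c(collection@ranks[i], s@smiles, s@nSites, s@analogCount, s@source,
            paste(s@targetIds, collapse = ";"),
            paste(s@classLabels, collapse = ";")), collapse = "\t")
  }, character(1))
  writeLines(c(paste(.scaffoldTableHeader, collapse = "\t"), rows), path)
  invisible(path)
}

#' Read a scaffold table back into a collection
#'
#' Inverse of [writeScaffoldTable()]. Analog membership is not stored in the
#' table, so the returned scaffolds carry counts but empty `analogIds`.
#'
#' @param path scaffold table written by [writeScaffoldTable()].
#' @return A ranked [ScaffoldCollection-class].
#' @export
readScaffoldTable <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (length(ln) == 0L || !identical(ln[1], paste(.scaffoldTableHeader,
                                                  collapse = "\t")))
    stop("not a scaffold table: ", path)
  ln <- ln[-1]
  scaffolds <- list(); ranks <- integer()
  for (row in ln) {
    f <- strsplit(row, "\t", fixed = TRUE)[[1]]
    length(f) <- 7L
    mol <- parseSmiles(f[2])
    if (is.null(mol)) stop("invalid scaffold SMILES in table: ", f[2])
    scaffolds <- c(scaffolds, methods::new("ASBScaffold",
      smiles = f[2], structure = mol, nSites = as.integer(f[3]),
      seriesId = NA_integer_, analogIds = character(),
      analogCount = as.integer(f[4]), source = f[5],
      perSourceCounts = stats::setNames(integer(), character()),
      targetIds = .splitAnno(f[6]), classLabels = .splitAnno(f[7])))
    ranks <- c(ranks, as.integer(f[1]))
  }
  srcs <- unique(vapply(scaffolds, function(s) s@source, character(1)))
  methods::new("ScaffoldCollection", scaffolds = scaffolds,
               sourceLabels = setdiff(srcs, "both"),
               ranked = TRUE, ranks = ranks)
}

# ---------------------------------------------------------------------------
# CompoundSet methods

#' Accessors for CompoundSet
#'
#' @param x a [CompoundSet-class].
#' @param id a compound identifier.
#' @return vectors/lists parallel to the compounds; `getCompound` returns one
#'   compound as a list (`id`, `smiles`, `mol`, `source`, `targets`,
#'   `classes`).
#' @name CompoundSet-accessors
NULL

#' @rdname CompoundSet-accessors
#' @export
setMethod("compoundIds", "CompoundSet", function(x) x@ids)
#' @rdname CompoundSet-accessors
#' @export
setMethod("compoundSmiles", "CompoundSet", function(x)
  stats::setNames(x@smiles, x@ids))
#' @rdname CompoundSet-accessors
#' @export
setMethod("sourceLabel", "CompoundSet", function(x) x@sourceLabel)
#' @rdname CompoundSet-accessors
#' @export
setMethod("parseFailures", "CompoundSet", function(x) x@parseFailures)
#' @rdname CompoundSet-accessors
#' @export
setMethod("duplicateLog", "CompoundSet", function(x) x@duplicates)
#' @rdname CompoundSet-accessors
#' @export
setMethod("targetAnnotations", "CompoundSet", function(x)
  stats::setNames(x@targets, x@ids))
#' @rdname CompoundSet-accessors
#' @export
setMethod("classAnnotations", "CompoundSet", function(x)
  stats::setNames(x@classes, x@ids))
#' @rdname CompoundSet-accessors
#' @export
setMethod("getCompound", "CompoundSet", function(x, id) {
  i <- match(id, x@ids)
  if (is.na(i)) stop("unknown compound id: ", id)
  list(id = x@ids[i], smiles = x@smiles[i], mol = x@mols[[i]],
       source = x@sourceLabel, targets = x@targets[[i]],
       classes = x@classes[[i]])
})

#' @describeIn CompoundSet-class number of compounds
#' @param x,object a `CompoundSet`
#' @export
setMethod("length", "CompoundSet", function(x) length(x@ids))

#' @describeIn CompoundSet-class compact display
#' @export
setMethod("show", "CompoundSet", function(object) {
  cat(sprintf("CompoundSet '%s': %d compound(s), %d parse failure(s), %d duplicate(s) merged\n",
              object@sourceLabel, length(object@ids),
              nrow(object@parseFailures), nrow(object@duplicates)))
})
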