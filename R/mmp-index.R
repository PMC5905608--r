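# Exhaustive RECAP-MMP generation by indexing single-cut cores.

#' Build the single-cut core index of a compound set
#'
#' Indexes every size-rule-passing single-cut fragmentation of every compound:
#' one row per (core, compound, substituent) with the unnumbered canonical
#' core and substituent SMILES and their heavy-atom counts. Compound pairs
#' sharing a row key are matched-pair candidates.
#'
#' @param compounds a [CompoundSet-class].
#' @param config a [PipelineConfig-class].
#' @return A [CoreIndex-class].
#' @export
buildCoreIndex <- function(compounds, config = pipelineConfig()) {
  rows <- vector("list", length(compounds@ids))
  for (i in seq_along(compounds@ids)) {
    frags <- enumerateSingleCut(compounds@mols[[i]], config,
                                compound_id = compounds@ids[i])
    if (length(frags) == 0L) next
    rows[[i]] <- data.frame(
      core = vapply(frags, `[[`, character(1), "core_can"),
      compound_id = compounds@ids[i],
      sub = vapply(frags, function(f) f$sub_can[[1]], character(1)),
      sub_heavy = vapply(frags, function(f) f$sub_heavy[[1]], integer(1)),
      core_heavy = vapply(frags, `[[`, integer(1), "core_heavy"),
      stringsAsFactors = FALSE)
  }
  entries <- do.call(rbind, rows)
  if (is.null(entries))
    entries <- data.frame(core = character(), compound_id = character(),
                          sub = character(), sub_heavy = integer(),
                          core_heavy = integer())
  entries <- unique(entries)
  entries <- entries[.corder(entries$core, entries$compound_id, entries$sub), ,
                     drop = FALSE]
  rownames(entries) <- NULL
  methods::new("CoreIndex", entries = entries)
}

#' Generate RECAP matched molecular pairs from a core index
#'
#' Emits one RMMP per unordered compound pair per shared core with distinct
#' exchanged substituents whose heavy-atom difference is at most
#' `maxExchangeSizeDifference`. Records are deduplicated on (pair, core) and
#' stored with `compound_a < compound_b` under a fixed (C-locale) order.
#'
#' @param index a [CoreIndex-class].
#' @param config a [PipelineConfig-class].
#' @return data.frame with columns `compound_a`, `compound_b`, `core`,
#'   `sub_a`, `sub_b`, `size_diff`.
#' @export
generateRmmps <- function(index, config = pipelineConfig()) {
  e <- index@entries
  empty <- data.frame(compound_a = character(), compound_b = character(),
                      core = character(), sub_a = character(),
                      sub_b = character(), size_diff = integer())
  if (nrow(e) == 0L) return(empty)
  out <- list()
  for (core in unique(e$core)) {
    g <- e[e$core == core, , drop = FALSE]
    if (nrow(g) < 2L) next
    cmb <- utils::combn(nrow(g), 2L)
    for (j in seq_len(ncol(cmb))) {
      i1 <- cmb[1, j]; i2 <- cmb[2, j]
      if (g$compound_id[i1] == g$compound_id[i2]) next
      if (g$sub[i1] == g$sub[i2]) next
      d <- abs(g$sub_heavy[i1] - g$sub_heavy[i2])
      if (d > config@maxExchangeSizeDifference) next
      swap <- .corder(c(g$compound_id[i1], g$compound_id[i2]))[1] == 2L
      a <- if (swap) i2 else i1
      b <- if (swap) i1 else i2
      out <- c(out, list(data.frame(
        compound_a = g$compound_id[a], compound_b = g$compound_id[b],
        core = core, sub_a = g$sub[a], sub_b = g$sub[b],
        size_diff = d, stringsAsFactors = FALSE)))
    }
  }
  if (length(out) == 0L) return(empty)
  r <- do.call(rbind, out)
  # a pair can share one core through several cut placements: keep one record
  r <- r[!duplicated(r[, c("compound_a", "compound_b", "core")]), ,
         drop = FALSE]
  r <- r[.corder(r$compound_a, r$compound_b, r$core), , drop = FALSE]
  rownames(r) <- NULL
  r
}

#' Export an RMMP table
#'
#' Writes the matched-pair records as a tab-separated file with columns
#' `compound_a`, `compound_b`, `core_smiles`, `sub_a`, `sub_b`.
#'
#' @param rmmps data.frame from [generateRmmps()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRmmpTable <- function(rmmps, path) {
  hdr <- "compound_a\tcompound_b\tcore_smiles\tsub_a\tsub_b"
  rows <- sprintf("%s\t%s\t%s\t%s\t%s", rmmps$compound_a, rmmps$compound_b,
                  rmmps$core, rmmps$sub_a, rmmps$sub_b)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @describeIn CoreIndex-class the entries table
#' @param x,object a `CoreIndex`
#' @export
setMethod("coreEntries", "CoreIndex", function(x) x@entries)

#' @describeIn CoreIndex-class compact display
#' @export
setMethod("show", "CoreIndex", function(object) {
  cat(sprintf("CoreIndex: %d entrie(s) over %d distinct core(s)\n",
              nrow(object@entries), length(unique(object@entries$core))))
})
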