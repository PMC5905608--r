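# Shared helpers: compound sets built in code, a pipeline driver, and
# independent brute-force oracles.

# CompoundSet from a named character vector of SMILES (names = ids)
make_compound_set <- function(smiles, source = "TEST",
                              config = pipelineConfig()) {
  suppressMessages(asbscaffolds:::.newCompoundSet(
    names(smiles), unname(smiles), source, config = config))
}

# full pipeline on one CompoundSet; returns series set and derivation results
run_pipeline <- function(cs, config = pipelineConfig()) {
  idx <- buildCoreIndex(cs, config)
  rmmps <- generateRmmps(idx, config)
  ss <- extractAnalogSeries(cs, rmmps, config)
  res <- lapply(analogSeries(ss), deriveAsbScaffold, compounds = cs,
                config = config)
  list(index = idx, rmmps = rmmps, seriesSet = ss, results = res)
}

# --- independent single-cut oracle -----------------------------------------
# Tries every acyclic bond (igraph bridges, recomputed here), splits the graph
# with its own BFS-free component logic, builds both role assignments with the
# low-level graph utilities, and post-filters by rule environment membership
# and the size rules. Independent of the .cutBonds()/enumerateSingleCut path.
brute_force_single_cut <- function(mol, config = pipelineConfig()) {
  bonds <- mol@bonds
  if (nrow(bonds) == 0L) return(character())
  g <- igraph::graph_from_data_frame(bonds[, c("a1", "a2")],
    directed = FALSE, vertices = data.frame(name = seq_len(length(mol))))
  rule_bonds <- findRetrosyntheticBonds(mol, config)
  rule_key <- paste(rule_bonds$a1, rule_bonds$a2)
  out <- character()
  for (bi in seq_len(nrow(bonds))) {
    g2 <- igraph::delete_edges(g, bi)
    comp <- igraph::components(g2)$membership
    if (max(comp) != 2L) next                      # ring bond: no split
    if (!(paste(bonds$a1[bi], bonds$a2[bi]) %in% rule_key)) next
    for (core_side in 1:2) {
      core_idx <- which(comp == core_side)
      sub_idx <- which(comp != core_side)
      core <- asbscaffolds:::.molSubgraph(mol, core_idx)
      sub <- asbscaffolds:::.molSubgraph(mol, sub_idx)
      anchor_c <- match(intersect(core_idx, c(bonds$a1[bi], bonds$a2[bi])),
                        sort(core_idx))
      anchor_s <- match(intersect(sub_idx, c(bonds$a1[bi], bonds$a2[bi])),
                        sort(sub_idx))
      core <- asbscaffolds:::.addAtom(core, "*")
      core <- asbscaffolds:::.addBond(core, anchor_c, length(core),
                                      bonds$order[bi])
      sub <- asbscaffolds:::.addAtom(sub, "*")
      sub <- asbscaffolds:::.addBond(sub, anchor_s, length(sub),
                                     bonds$order[bi])
      if (passesSizeRules(asbscaffolds:::.heavyCount(core),
                          asbscaffolds:::.heavyCount(sub), config))
        out <- c(out, paste(asbscaffolds:::.canonMol(core),
                            asbscaffolds:::.canonMol(sub), sep = " | "))
    }
  }
  sort(out)
}

# --- independent pairwise RMMP oracle --------------------------------------
# Fragments both molecules of every pair and intersects the cores directly,
# without the shared-core index.
brute_force_rmmps <- function(cs, config = pipelineConfig()) {
  ids <- compoundIds(cs)
  frags <- lapply(seq_along(ids), function(i)
    enumerateSingleCut(cs@mols[[i]], config, compound_id = ids[i]))
  out <- character()
  n <- length(ids)
  if (n < 2L) return(out)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    fi <- frags[[i]]; fj <- frags[[j]]
    if (!length(fi) || !length(fj)) next
    ci <- vapply(fi, `[[`, character(1), "core_can")
    cj <- vapply(fj, `[[`, character(1), "core_can")
    for (core in intersect(ci, cj)) {
      si <- unique(vapply(fi[ci == core], function(f) f$sub_can[[1]],
                          character(1)))
      sj <- unique(vapply(fj[cj == core], function(f) f$sub_can[[1]],
                          character(1)))
      hi <- vapply(fi[ci == core], function(f) f$sub_heavy[[1]], integer(1))
      hj <- vapply(fj[cj == core], function(f) f$sub_heavy[[1]], integer(1))
      names(hi) <- vapply(fi[ci == core], function(f) f$sub_can[[1]],
                          character(1))
      names(hj) <- vapply(fj[cj == core], function(f) f$sub_can[[1]],
                          character(1))
      hit <- FALSE
      for (sa in si) for (sb in sj) {
        if (sa == sb) next
        if (abs(hi[[sa]] - hj[[sb]]) > config@maxExchangeSizeDifference) next
        hit <- TRUE
      }
      if (hit) {
        pair <- sort(c(ids[i], ids[j]), method = "radix")
        out <- c(out, paste(pair[1], pair[2], core, sep = " | "))
      }
    }
  }
  sort(unique(out))
}

rmmp_keys <- function(rmmps) {
  sort(unique(paste(rmmps$compound_a, rmmps$compound_b, rmmps$core,
                    sep = " | ")))
}

# a small two-source benchmark written to disk; returns paths and truths
write_benchmark <- function(dir, seeds = 1:4) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tpls <- builtinTemplates()
  truths <- list(); paths <- character()
  for (i in seq_along(seeds)) {
    tpl <- tpls[[(i - 1L) %% length(tpls) + 1L]]
    lib <- generateLibrary(librarySpec(tpl$template, tpl$pools,
      nAnalogs = min(tpl$max_analogs, 4L + i %% 3L), nDecoys = 1L,
      seed = seeds[i], label = sprintf("B%02d", i)))
    p <- file.path(dir, sprintf("lib%02d.smi", i))
    writeCompoundTable(lib$compounds, p)
    truths[[i]] <- lib$truth
    paths <- c(paths, p)
  }
  list(paths = paths, truths = truths)
}

# unlabeled canonical form used for core/substituent identity in the index
unlabeled_can <- function(smi) {
  asbscaffolds:::.canonMol(asbscaffolds:::.stripSiteLabels(parseSmiles(smi)))
}
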