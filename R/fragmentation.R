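# Perception of retrosynthetic (RECAP-type) bonds and enumeration of
# size-restricted single- and multi-cut core/substituent decompositions.

#' Retrosynthetic bond classes
#'
#' The eleven RECAP-type bond environments perceived by
#' [findRetrosyntheticBonds()], in precedence order: a bond matching two
#' environments is assigned the first matching class. Only acyclic bonds
#' qualify; ring bonds are never cut.
#'
#' @return character vector of rule identifiers.
#' @export
retrosyntheticRuleIds <- function() c(
  "amide", "ester", "amine", "urea", "ether", "olefin", "quaternary_N",
  "aromatic_N_aliphatic_C", "lactam_N_aliphatic_C",
  "aromatic_C_aromatic_C", "sulfonamide")

# per-molecule atom environment used by the rule predicates
.atomEnv <- function(mol) {
  a <- mol@atoms; b <- mol@bonds
  n <- nrow(a)
  deg <- integer(n); maxord <- integer(n)
  nbr <- vector("list", n)
  for (i in seq_len(nrow(b))) {
    deg[b$a1[i]] <- deg[b$a1[i]] + 1L
    deg[b$a2[i]] <- deg[b$a2[i]] + 1L
    maxord[b$a1[i]] <- max(maxord[b$a1[i]], b$order[i])
    maxord[b$a2[i]] <- max(maxord[b$a2[i]], b$order[i])
    nbr[[b$a1[i]]] <- c(nbr[[b$a1[i]]], i)
    nbr[[b$a2[i]]] <- c(nbr[[b$a2[i]]], i)
  }
  other <- function(bi, at) if (b$a1[bi] == at) b$a2[bi] else b$a1[bi]
  # carbonyl carbon: C with a double bond to O
  carbonyl <- vapply(seq_len(n), function(i) {
    a$elem[i] == "C" && any(vapply(nbr[[i]], function(bi)
      b$order[bi] == 2L && a$elem[other(bi, i)] == "O", logical(1)))
  }, logical(1))
  # sulfonyl sulfur: S with >= 2 double bonds to O
  sulfonyl <- vapply(seq_len(n), function(i) {
    a$elem[i] == "S" && sum(vapply(nbr[[i]], function(bi)
      b$order[bi] == 2L && a$elem[other(bi, i)] == "O", logical(1))) >= 2L
  }, logical(1))
  ring_atom <- logical(n)
  acyc <- .acyclicBondIdx(mol)
  ring_bonds <- setdiff(seq_len(nrow(b)), acyc)
  ring_atom[unlist(b[ring_bonds, c("a1", "a2")])] <- TRUE
  list(a = a, b = b, deg = deg, maxord = maxord, nbr = nbr, other = other,
       carbonyl = carbonyl, sulfonyl = sulfonyl, ring_atom = ring_atom,
       ring_bond = ring_bonds, acyclic = acyc)
}

# rule predicates; x,y are the bond's atoms (tried in both orientations)
.rulePredicates <- list(
  amide = function(e, x, y, ord) {
    ord == 1L && e$a$elem[y] == "N" && !e$a$arom[y] && e$carbonyl[x] &&
      sum(e$a$elem[vapply(e$nbr[[x]], e$other, integer(1), at = x)] == "N") == 1L
  },
  ester = function(e, x, y, ord) {
    ord == 1L && e$a$elem[y] == "O" && !e$a$arom[y] && e$deg[y] == 2L &&
      e$carbonyl[x]
  },
  amine = function(e, x, y, ord) {
    if (ord != 1L || e$a$elem[y] != "N" || e$a$arom[y] || e$a$chg[y] != 0L ||
        e$maxord[y] > 1L || e$deg[y] < 2L)
      return(FALSE)
    if (e$a$elem[x] != "C" || e$a$arom[x] || e$carbonyl[x]) return(FALSE)
    # not an amide/sulfonamide/urea nitrogen
    ynb <- vapply(e$nbr[[y]], e$other, integer(1), at = y)
    !any(e$carbonyl[ynb] | e$sulfonyl[ynb])
  },
  urea = function(e, x, y, ord) {
    ord == 1L && e$a$elem[y] == "N" && !e$a$arom[y] && e$carbonyl[x] &&
      sum(e$a$elem[vapply(e$nbr[[x]], e$other, integer(1), at = x)] == "N") >= 2L
  },
  ether = function(e, x, y, ord) {
    if (ord != 1L || e$a$elem[y] != "O" || e$a$arom[y] || e$a$chg[y] != 0L ||
        e$deg[y] != 2L)
      return(FALSE)
    if (e$a$elem[x] != "C" || e$carbonyl[x]) return(FALSE)
    ynb <- vapply(e$nbr[[y]], e$other, integer(1), at = y)
    !any(e$carbonyl[ynb])  # exclude ester oxygens
  },
  olefin = function(e, x, y, ord) {
    ord == 2L && e$a$elem[x] == "C" && e$a$elem[y] == "C" &&
      !e$a$arom[x] && !e$a$arom[y] && e$deg[x] >= 2L && e$deg[y] >= 2L
  },
  quaternary_N = function(e, x, y, ord) {
    ord == 1L && e$a$elem[y] == "N" && e$a$chg[y] == 1L && e$deg[y] == 4L &&
      e$maxord[y] == 1L && e$a$elem[x] == "C"
  },
  aromatic_N_aliphatic_C = function(e, x, y, ord) {
    ord == 1L && e$a$elem[y] == "N" && e$a$arom[y] &&
      e$a$elem[x] == "C" && !e$a$arom[x] && !e$carbonyl[x]
  },
  lactam_N_aliphatic_C = function(e, x, y, ord) {
    if (ord != 1L || e$a$elem[y] != "N" || e$a$arom[y] || !e$ring_atom[y])
      return(FALSE)
    if (e$a$elem[x] != "C" || e$a$arom[x] || e$carbonyl[x]) return(FALSE)
    # ring neighbor of the N is a carbonyl carbon (cyclic amide)
    ynb_b <- e$nbr[[y]]
    ring_nb <- vapply(ynb_b, function(bi) bi %in% e$ring_bond, logical(1))
    any(vapply(ynb_b[ring_nb], function(bi)
      e$carbonyl[e$other(bi, y)], logical(1)))
  },
  aromatic_C_aromatic_C = function(e, x, y, ord) {
    ord == 1L && e$a$elem[x] == "C" && e$a$elem[y] == "C" &&
      e$a$arom[x] && e$a$arom[y]
  },
  sulfonamide = function(e, x, y, ord) {
    ord == 1L && e$sulfonyl[x] && e$a$elem[y] == "N" && !e$a$arom[y]
  })

#' Find retrosynthetic bonds
#'
#' Perceives all acyclic bonds of a standardized structure matching one of the
#' enabled retrosynthetic bond classes ([retrosyntheticRuleIds()]). A bond
#' matching several environments is assigned the first matching class in the
#' fixed precedence order; the result is ordered by atom indices.
#'
#' @param compound a [MolGraph-class] or SMILES string.
#' @param config a [PipelineConfig-class] (its `enabledRules` are applied).
#' @return data.frame with columns `a1`, `a2` (atom indices), `order`
#'   (bond order) and `rule` (class id); zero rows when no bond qualifies.
#' @examples
#' findRetrosyntheticBonds("CC(=O)Nc1ccccc1")  # one amide bond
#' findRetrosyntheticBonds("CCc1ccccc1")       # none
#' @export
findRetrosyntheticBonds <- function(compound, config = pipelineConfig()) {
  mol <- if (is.character(compound)) parseSmiles(compound) else compound
  stopifnot(is(mol, "MolGraph"))
  e <- .atomEnv(mol)
  rules <- retrosyntheticRuleIds()
  rules <- rules[rules %in% config@enabledRules]
  res <- data.frame(a1 = integer(), a2 = integer(), order = integer(),
                    rule = character())
  for (bi in e$acyclic) {
    x <- e$b$a1[bi]; y <- e$b$a2[bi]; ord <- e$b$order[bi]
    if (e$a$elem[x] == "*" || e$a$elem[y] == "*") next
    for (r in rules) {
      p <- .rulePredicates[[r]]
      if (p(e, x, y, ord) || p(e, y, x, ord)) {
        res <- rbind(res, data.frame(a1 = x, a2 = y, order = ord, rule = r))
        break
      }
    }
  }
  res[order(res$a1, res$a2), , drop = FALSE]
}

#' Size restriction for core/substituent decompositions
#'
#' A decomposition passes when the substituent has at most
#' `maxSubstituentHeavyAtoms` heavy atoms and the core has at least
#' `coreToSubstituentMinRatio` times as many heavy atoms as the substituent.
#' Attachment points do not count as heavy atoms.
#'
#' @param coreHeavy,substituentHeavy heavy-atom counts (vectorized).
#' @param config a [PipelineConfig-class].
#' @return logical vector.
#' @examples
#' passesSizeRules(11, 4)   # TRUE
#' passesSizeRules(7, 4)    # FALSE: core below 2x substituent
#' passesSizeRules(20, 14)  # FALSE: substituent above the 13-atom cap
#' @export
passesSizeRules <- function(coreHeavy, substituentHeavy,
                            config = pipelineConfig()) {
  substituentHeavy <= config@maxSubstituentHeavyAtoms &
    coreHeavy >= config@coreToSubstituentMinRatio * substituentHeavy
}

# assemble a fragmentation record from a .cutBonds() result
.mkFragmentation <- function(compound_id, core, subs, cut_sites) {
  core_can <- .canonMol(.stripSiteLabels(core))
  sub_can <- .canonMols(lapply(subs, .stripSiteLabels))
  list(compound_id = compound_id,
       k = length(subs),
       core = core, core_can = core_can, core_heavy = .heavyCount(core),
       subs = subs, sub_can = sub_can,
       sub_heavy = vapply(subs, .heavyCount, integer(1)),
       cut_sites = cut_sites)
}

#' Enumerate single-cut fragmentations
#'
#' Cuts each retrosynthetic bond of the compound in turn, considers both
#' core/substituent role assignments, and returns every decomposition passing
#' [passesSizeRules()]. Each fragmentation is a list with the core and
#' substituent [MolGraph-class]s, their unnumbered canonical SMILES
#' (`core_can`, `sub_can`), heavy-atom counts and the cut-site table.
#'
#' @param compound a [MolGraph-class] or SMILES string.
#' @param config a [PipelineConfig-class].
#' @param compound_id identifier stored on the records.
#' @return list of fragmentation records (deterministic order).
#' @examples
#' length(enumerateSingleCut("CC(=O)Nc1ccccc1"))  # 1: anilide core + acetyl
#' @export
enumerateSingleCut <- function(compound, config = pipelineConfig(),
                               compound_id = NA_character_) {
  mol <- if (is.character(compound)) parseSmiles(compound) else compound
  stopifnot(is(mol, "MolGraph"))
  sites <- findRetrosyntheticBonds(mol, config)
  out <- list()
  if (nrow(sites) == 0L) return(out)
  bond_key <- paste(mol@bonds$a1, mol@bonds$a2)
  for (i in seq_len(nrow(sites))) {
    bi <- match(paste(sites$a1[i], sites$a2[i]), bond_key)
    cut <- .cutBonds(mol, bi)
    if (is.null(cut)) next
    frags <- cut$components
    for (role in 1:2) {
      core <- frags[[role]]; sub <- frags[[3L - role]]
      if (passesSizeRules(.heavyCount(core), .heavyCount(sub), config))
        out <- c(out, list(.mkFragmentation(compound_id, core, list(sub),
                                            sites[i, , drop = FALSE])))
    }
  }
  out
}

#' Enumerate multi-cut fragmentations
#'
#' Cuts every subset of `k` retrosynthetic bonds for which the remaining graph
#' decomposes into one connected core carrying all `k` attachment points and
#' `k` pairwise non-overlapping single-attachment substituents, each passing
#' [passesSizeRules()] against the core.
#'
#' @param compound a [MolGraph-class] or SMILES string.
#' @param k number of simultaneous cuts (2..`maxSubstitutionSites`).
#' @param config a [PipelineConfig-class].
#' @param compound_id identifier stored on the records.
#' @return list of fragmentation records (deterministic order).
#' @export
enumerateMultiCut <- function(compound, k, config = pipelineConfig(),
                              compound_id = NA_character_) {
  stopifnot(k >= 2L)
  mol <- if (is.character(compound)) parseSmiles(compound) else compound
  stopifnot(is(mol, "MolGraph"))
  sites <- findRetrosyntheticBonds(mol, config)
  out <- list()
  if (nrow(sites) < k) return(out)
  bond_key <- paste(mol@bonds$a1, mol@bonds$a2)
  bidx <- match(paste(sites$a1, sites$a2), bond_key)
  combos <- utils::combn(seq_len(nrow(sites)), k, simplify = FALSE)
  for (cmb in combos) {
    cut <- .cutBonds(mol, bidx[cmb])
    if (is.null(cut) || is.na(cut$core_comp)) next
    core_pos <- match(cut$core_comp, cut$comp_ids)
    core <- cut$components[[core_pos]]
    subs <- cut$components[-core_pos]
    ch <- .heavyCount(core)
    if (!all(passesSizeRules(ch, vapply(subs, .heavyCount, integer(1)),
                             config)))
      next
    # order substituents by the site number they occupy on the core
    site_of <- vapply(subs, function(s) {
      # a substituent carries exactly the site number of its single cut
      cut_site <- s@atoms$iso[s@atoms$elem == "*"]
      as.integer(cut_site[cut_site > 0L][1])
    }, integer(1))
    subs <- lapply(order(site_of), function(j) .stripSiteLabels(subs[[j]]))
    # renumber the core's sites 1..k in cut order (already 1..k by .cutBonds)
    out <- c(out, list(.mkFragmentation(compound_id, core, subs,
                                        sites[cmb, , drop = FALSE])))
  }
  out
}

#' Reassemble a fragmentation
#'
#' Rebuilds the parent structure from a fragmentation record by attaching each
#' substituent at its numbered core site. For every fragmentation emitted by
#' [enumerateSingleCut()]/[enumerateMultiCut()], the reassembled canonical
#' form equals the parent's constitution-level canonical form.
#'
#' @param fragmentation a fragmentation record.
#' @return A [MolGraph-class].
#' @export
reassembleFragmentation <- function(fragmentation) {
  core <- fragmentation$core
  subs <- fragmentation$subs
  # core sites are numbered 1..k; substituents are ordered accordingly
  .attachSubstituents(core, subs)
}
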