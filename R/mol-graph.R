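# Graph surgery on MolGraph objects: subgraphs, atom deletion, bond cutting
# with numbered attachment points, reattachment, site handling.

.emptyBonds <- function()
  data.frame(a1 = integer(), a2 = integer(), order = integer())

.molIgraph <- function(mol) {
  igraph::graph_from_data_frame(
    d = if (nrow(mol@bonds)) mol@bonds[, c("a1", "a2")] else
      data.frame(a1 = integer(), a2 = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(mol@atoms))))
}

# heavy atoms, attachment points excluded
.heavyCount <- function(mol) sum(mol@atoms$elem != "*")

.nSitesOf <- function(mol) sum(mol@atoms$elem == "*")

# indices (into mol@bonds) of acyclic bonds = bridges of the bond graph
.acyclicBondIdx <- function(mol) {
  if (nrow(mol@bonds) == 0L) return(integer())
  g <- .molIgraph(mol)
  br <- igraph::bridges(g)
  # edge order in g follows the row order of mol@bonds
  sort(as.integer(br))
}

# connected-component membership vector (length = n atoms)
.molComponents <- function(mol) {
  igraph::components(.molIgraph(mol))$membership
}

.molSubgraph <- function(mol, atom_idx) {
  atom_idx <- sort(atom_idx)
  map <- integer(nrow(mol@atoms)); map[atom_idx] <- seq_along(atom_idx)
  b <- mol@bonds
  keep <- b$a1 %in% atom_idx & b$a2 %in% atom_idx
  b <- b[keep, , drop = FALSE]
  if (nrow(b)) {
    b$a1 <- map[b$a1]; b$a2 <- map[b$a2]
    swp <- b$a1 > b$a2
    if (any(swp)) { tmp <- b$a1[swp]; b$a1[swp] <- b$a2[swp]; b$a2[swp] <- tmp }
  }
  rownames(b) <- NULL
  a <- mol@atoms[atom_idx, , drop = FALSE]; rownames(a) <- NULL
  methods::new("MolGraph", atoms = a, bonds = b)
}

.deleteAtoms <- function(mol, idx) {
  .molSubgraph(mol, setdiff(seq_len(nrow(mol@atoms)), idx))
}

.addAtom <- function(mol, elem, chg = 0L, iso = 0L, arom = FALSE) {
  mol@atoms <- rbind(mol@atoms,
    data.frame(elem = elem, chg = as.integer(chg), iso = as.integer(iso),
               arom = arom, stringsAsFactors = FALSE))
  mol
}

.addBond <- function(mol, a1, a2, order) {
  mol@bonds <- rbind(mol@bonds,
    data.frame(a1 = min(a1, a2), a2 = max(a1, a2),
               order = as.integer(order)))
  mol
}

# set site numbers of all attachment points to 0 (identity up to numbering)
.stripSiteLabels <- function(mol) {
  mol@atoms$iso[mol@atoms$elem == "*"] <- 0L
  mol
}

# delete the attachment points whose site numbers are in `sites`
# (hydrogen-at-site: the anchor atom regains an implicit hydrogen)
.hydrogenateSites <- function(mol, sites) {
  idx <- which(mol@atoms$elem == "*" & mol@atoms$iso %in% sites)
  if (length(idx) == 0L) return(mol)
  .deleteAtoms(mol, idx)
}

# Cut the given bond rows out of `mol`. Returns NULL unless the cuts induce a
# valid core/substituent decomposition: exactly one component (the core) is
# incident to every cut bond and each remaining component is incident to
# exactly one. Core attachment points are numbered by cut order (1..k);
# substituent attachment points are unnumbered.
.cutBonds <- function(mol, bond_rows) {
  k <- length(bond_rows)
  b <- mol@bonds[bond_rows, , drop = FALSE]
  rest <- mol@bonds[-bond_rows, , drop = FALSE]
  cutmol <- methods::new("MolGraph", atoms = mol@atoms, bonds = rest)
  memb <- .molComponents(cutmol)
  m1 <- memb[b$a1]; m2 <- memb[b$a2]
  if (any(m1 == m2)) return(NULL)     # cut did not separate (shouldn't happen)
  counts <- table(c(m1, m2))
  core_comp <- as.integer(names(counts)[counts == k])
  if (length(core_comp) != 1L && k > 1L) return(NULL)
  if (k == 1L) core_comp <- NA        # both roles considered by the caller
  comps <- sort(unique(memb))
  if (length(comps) != k + 1L) return(NULL)
  if (k > 1L) {
    inc_core <- (m1 == core_comp) | (m2 == core_comp)
    if (!all(inc_core)) return(NULL)  # a cut bond not touching the core
  }
  # build each component with its attachment dummies
  build <- function(comp, site_for_cut) {
    idx <- which(memb == comp)
    sub <- .molSubgraph(mol = cutmol, atom_idx = idx)
    map <- integer(nrow(mol@atoms)); map[idx] <- seq_along(sort(idx))
    for (i in seq_len(k)) {
      anchor <- if (m1[i] == comp) b$a1[i] else if (m2[i] == comp) b$a2[i] else 0L
      if (anchor == 0L) next
      sub <- .addAtom(sub, "*", iso = site_for_cut[i])
      sub <- .addBond(sub, map[anchor], nrow(sub@atoms), b$order[i])
    }
    sub
  }
  list(
    components = lapply(comps, function(cp) build(cp, seq_len(k))),
    comp_ids = comps,
    core_comp = core_comp,
    cut_bonds = b)
}

# Replace each numbered attachment point of `core` by the corresponding
# substituent (a MolGraph with exactly one attachment point). Used for the
# reassembly identity and by the library generator.
.attachSubstituents <- function(core, subs) {
  stopifnot(length(subs) == .nSitesOf(core))
  mol <- core
  for (site in seq_along(subs)) {
    sub <- subs[[site]]
    d_core <- which(mol@atoms$elem == "*" & mol@atoms$iso == site)
    stopifnot(length(d_core) == 1L)
    cb <- mol@bonds$a1 == d_core | mol@bonds$a2 == d_core
    stopifnot(sum(cb) == 1L)
    anchor_core <- setdiff(unlist(mol@bonds[cb, c("a1", "a2")]), d_core)
    order_core <- mol@bonds$order[cb]

    d_sub <- which(sub@atoms$elem == "*")
    stopifnot(length(d_sub) == 1L)
    sb <- sub@bonds$a1 == d_sub | sub@bonds$a2 == d_sub
    anchor_sub <- setdiff(unlist(sub@bonds[sb, c("a1", "a2")]), d_sub)

    off <- nrow(mol@atoms)
    joined_atoms <- rbind(mol@atoms, sub@atoms)
    sb2 <- sub@bonds; sb2$a1 <- sb2$a1 + off; sb2$a2 <- sb2$a2 + off
    joined_bonds <- rbind(mol@bonds, sb2)
    mol <- methods::new("MolGraph", atoms = joined_atoms, bonds = joined_bonds)
    mol <- .addBond(mol, anchor_core, anchor_sub + off, order_core)
    mol <- .deleteAtoms(mol, c(d_core, d_sub + off))
  }
  mol
}

# random atom permutation (property tests)
.permuteAtoms <- function(mol, perm) {
  stopifnot(length(perm) == nrow(mol@atoms))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  a <- mol@atoms[perm, , drop = FALSE]; rownames(a) <- NULL
  b <- mol@bonds
  if (nrow(b)) {
    b$a1 <- inv[b$a1]; b$a2 <- inv[b$a2]
    swp <- b$a1 > b$a2
    if (any(swp)) { tmp <- b$a1[swp]; b$a1[swp] <- b$a2[swp]; b$a2[swp] <- tmp }
  }
  methods::new("MolGraph", atoms = a, bonds = b)
}

#' @describeIn MolGraph-class number of atoms (attachment points included)
#' @param x,object a `MolGraph`
#' @export
setMethod("length", "MolGraph", function(x) nrow(x@atoms))

#' @describeIn MolGraph-class compact display
#' @export
setMethod("show", "MolGraph", function(object) {
  cat(sprintf("MolGraph: %d heavy atoms, %d bonds, %d attachment point(s)\n",
              .heavyCount(object), nrow(object@bonds), .nSitesOf(object)))
  cat(" ", .canonMol(object), "\n")
})
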