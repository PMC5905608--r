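# Bridge to OpenBabel (via ChemmineOB). All SMILES parsing, canonicalization
# and charge neutralization are delegated here; the rest of the package works
# on MolGraph objects.

.ob_noopt <- data.frame(names = character(), args = character(),
                        stringsAsFactors = FALSE)

# One conversion call. `op` adds a transformation op (e.g. "neutralize").
# Returns "" when OpenBabel could not parse/convert the input.
.obConvert <- function(from, to, src, op = NULL) {
  opts <- if (is.null(op)) .ob_noopt else
    data.frame(names = op, args = "", stringsAsFactors = FALSE)
  out <- tryCatch(ChemmineOB::convertFormat(from, to, source = src,
                                            options = opts),
                  error = function(e) "")
  if (length(out) != 1L || is.na(out)) "" else out
}

# SMILES string(s) -> canonical SMILES vector (NA where parsing failed).
# One record per call keeps id alignment robust to parse failures.
.obCanonicalSmiles <- function(smiles, op = NULL) {
  vapply(smiles, function(s) {
    out <- .obConvert("SMI", "CAN", paste0(s, " m"), op = op)
    out <- sub("[ \t].*$", "", sub("\n.*$", "", out))
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

#' Parse a SMILES string into a molecular graph
#'
#' Parses one SMILES string with OpenBabel and returns the constitution-level
#' [MolGraph-class]: heavy atoms with formal charges, isotope labels and
#' aromaticity flags, and bonds with integer (kekulized) orders. Stereo
#' descriptors are not represented at graph level. Attachment points written
#' as `[*]`/`[n*]` become dummy atoms with element `"*"` and site number `n`.
#'
#' @param smiles character scalar.
#' @return A [MolGraph-class], or `NULL` if the SMILES cannot be parsed.
#' @examples
#' m <- parseSmiles("CC(=O)Nc1ccccc1")
#' m
#' @export
parseSmiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (is.na(smiles) || !nzchar(smiles)) return(NULL)
  cml <- .obConvert("SMI", "CML", paste0(smiles, " m"))
  if (!nzchar(cml)) return(NULL)
  doc <- tryCatch(xml2::read_xml(cml), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  xml2::xml_ns_strip(doc)
  anodes <- xml2::xml_find_all(doc, ".//atom")
  if (length(anodes) == 0L) return(NULL)
  aid <- xml2::xml_attr(anodes, "id")
  elem <- xml2::xml_attr(anodes, "elementType")
  chg <- xml2::xml_attr(anodes, "formalCharge")
  iso <- xml2::xml_attr(anodes, "isotope")
  atoms <- data.frame(
    elem = elem,
    chg = ifelse(is.na(chg), 0L, as.integer(chg)),
    iso = ifelse(is.na(iso), 0L, as.integer(iso)),
    arom = FALSE,
    stringsAsFactors = FALSE)
  idx <- seq_len(nrow(atoms)); names(idx) <- aid

  bnodes <- xml2::xml_find_all(doc, ".//bond")
  if (length(bnodes)) {
    refs <- strsplit(xml2::xml_attr(bnodes, "atomRefs2"), " ", fixed = TRUE)
    a1 <- idx[vapply(refs, `[`, character(1), 1L)]
    a2 <- idx[vapply(refs, `[`, character(1), 2L)]
    ord <- xml2::xml_attr(bnodes, "order")
    ord <- ifelse(ord %in% c("A", "a"), 1L, as.integer(ord))
    bonds <- data.frame(a1 = pmin(a1, a2), a2 = pmax(a1, a2), order = ord)
  } else {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  }

  # aromaticity flags from the MOL2 rendering of the same parse (same atom
  # order); atoms incident to an "ar" bond are aromatic
  mol2 <- .obConvert("SMI", "MOL2", paste0(smiles, " m"))
  if (nzchar(mol2)) {
    ln <- strsplit(mol2, "\n", fixed = TRUE)[[1]]
    bstart <- grep("^@<TRIPOS>BOND", ln)
    if (length(bstart) == 1L) {
      bl <- ln[seq.int(bstart + 1L, length(ln))]
      bl <- bl[!grepl("^@", bl) & nzchar(trimws(bl))]
      if (length(bl)) {
        fields <- strsplit(trimws(bl), "[[:space:]]+")
        ar <- vapply(fields, function(f) identical(f[4], "ar"), logical(1))
        arats <- unique(unlist(lapply(fields[ar], function(f)
          as.integer(f[2:3]))))
        if (length(arats) && max(arats) <= nrow(atoms))
          atoms$arom[arats] <- TRUE
      }
    }
  }

  # fold explicit hydrogens into implicit ones
  h <- which(atoms$elem %in% c("H", "D", "T") & atoms$chg == 0L)
  mol <- methods::new("MolGraph", atoms = atoms, bonds = bonds)
  if (length(h)) mol <- .deleteAtoms(mol, h)
  mol
}

# MolGraph -> V2000 molblock (SDF record). Feeds OpenBabel only.
.molToMolblock <- function(mol, title = "m") {
  a <- mol@atoms; b <- mol@bonds
  n <- nrow(a); nb <- nrow(b)
  stopifnot(n >= 1L, n <= 999L, nb <= 999L)
  out <- c(
    title, " asbscaffolds", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
    sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            a$elem),
    if (nb) sprintf("%3d%3d%3d  0  0  0  0", b$a1, b$a2, b$order))
  chg <- which(a$chg != 0L)
  if (length(chg))
    out <- c(out, sprintf("M  CHG%3d%s", length(chg),
      paste0(sprintf(" %3d %3d", chg, a$chg[chg]), collapse = "")))
  iso <- which(a$iso != 0L)
  if (length(iso))
    out <- c(out, sprintf("M  ISO%3d%s", length(iso),
      paste0(sprintf(" %3d %3d", iso, a$iso[iso]), collapse = "")))
  paste(c(out, "M  END", "$$$$"), collapse = "\n")
}

# Batched canonicalization of MolGraph objects -> canonical SMILES vector.
.canonMols <- function(mols) {
  if (length(mols) == 0L) return(character())
  titles <- sprintf("t%06d", seq_along(mols))
  sdf <- paste(mapply(.molToMolblock, mols, titles), collapse = "\n")
  out <- .obConvert("SDF", "CAN", paste0(sdf, "\n"))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smi <- vapply(parts, `[`, character(1), 1L)
  got <- vapply(parts, function(p) if (length(p) >= 2L) p[2] else "",
                character(1))
  if (length(smi) != length(mols) || !identical(got, titles)) {
    # fall back to one-at-a-time to preserve alignment
    smi <- vapply(mols, function(m) {
      o <- .obConvert("SDF", "CAN", paste0(.molToMolblock(m), "\n"))
      sub("[ \t].*$", "", sub("\n.*$", "", o))
    }, character(1))
  }
  unname(smi)
}

.canonMol <- function(mol) .canonMols(list(mol))[[1]]

#' Canonical SMILES of a structure
#'
#' Deterministic canonical SMILES: two structures are equal if and only if
#' their canonical forms are string-equal. For structures carrying attachment
#' points the site numbering is canonicalized first (see
#' [normalizeSiteNumbering()]), so scaffolds identical up to a site
#' permutation map to the same string. The character method parses, then
#' canonicalizes at graph (constitution) level.
#'
#' @param structure a [MolGraph-class] or a SMILES string.
#' @return character scalar.
#' @examples
#' canonicalForm("C1=CC=CC=C1") == canonicalForm("c1ccccc1")
#' @rdname canonicalForm
#' @export
setMethod("canonicalForm", "MolGraph", function(structure) {
  if (any(structure@atoms$elem == "*"))
    structure <- normalizeSiteNumbering(structure)
  .canonMol(structure)
})

#' @rdname canonicalForm
#' @export
setMethod("canonicalForm", "character", function(structure) {
  stopifnot(length(structure) == 1L)
  mol <- parseSmiles(structure)
  if (is.null(mol)) stop("invalid SMILES: ", structure)
  canonicalForm(mol)
})
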