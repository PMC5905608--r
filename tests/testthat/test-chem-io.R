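test_that("smiles tables are read, standardized, deduplicated, and failures logged", {
  # empty file
  p <- withr::local_tempfile(fileext = ".smi")
  writeLines(character(), p)
  cs <- readCompounds(p, "smiles", "S")
  expect_s4_class(cs, "CompoundSet")
  expect_length(cs, 0)
  expect_identical(nrow(parseFailures(cs)), 0L)

  # three records, one invalid SMILES
  writeLines(c("# comment line",
               "c1\tCC(=O)Nc1ccccc1",
               "c2\tnot_a_smiles",
               "c3\tCCOC(=O)c1ccccc1"), p)
  cs <- suppressMessages(readCompounds(p, "smiles", "S"))
  expect_length(cs, 2)
  expect_identical(parseFailures(cs)$id, "c2")

  # identical canonical structure under different ids: one kept, logged
  writeLines(c("x1\tC1=CC=CC=C1O\tP1\tdrug",
               "x2\tOc1ccccc1\tP2\t"), p)
  cs <- suppressMessages(readCompounds(p, "smiles", "S"))
  expect_length(cs, 1)
  expect_identical(compoundIds(cs), "x1")
  expect_identical(duplicateLog(cs),
                   data.frame(kept_id = "x1", dropped_id = "x2"))
  # annotations merged as union
  expect_identical(targetAnnotations(cs)[["x1"]], c("P1", "P2"))
  expect_identical(classAnnotations(cs)[["x1"]], "drug")
})

test_that("standardization strips salts, neutralizes, and is idempotent", {
  expect_identical(standardizeStructure("CC(=O)[O-].[Na+]"),
                   canonicalForm("CC(=O)O"))
  # benzene is a fixed point
  bz <- standardizeStructure("c1ccccc1")
  expect_identical(bz, canonicalForm("c1ccccc1"))
  # idempotence over a mixed bag
  for (smi in c("CC(=O)[O-].[Na+]", "C[NH3+].[Cl-]", "c1ccccc1",
                "CC(=O)Nc1ccc(OC)cc1", "O=S(=O)(c1ccccc1)NCC")) {
    once <- standardizeStructure(smi)
    expect_identical(standardizeStructure(once), once, label = smi)
  }
  # stereo flag contract: keep_stereo=FALSE drops descriptors
  chiral <- "C[C@H](N)C(=O)O"
  with_st <- standardizeStructure(chiral, pipelineConfig(keepStereo = TRUE))
  without <- standardizeStructure(chiral, pipelineConfig(keepStereo = FALSE))
  expect_true(grepl("@", with_st, fixed = TRUE))
  expect_false(grepl("@", without, fixed = TRUE))
})

test_that("canonicalization identifies equal structures and is permutation-invariant", {
  expect_identical(canonicalForm("c1ccccc1"), canonicalForm("C1=CC=CC=C1"))
  # site-label invariance
  expect_identical(canonicalForm("[1*]Oc1ccc(N[2*])cc1"),
                   canonicalForm("[2*]Oc1ccc(N[1*])cc1"))
  # 100 random atom-order permutations collapse to one canonical string
  mol <- parseSmiles("CC(=O)Nc1ccc2ccccc2c1OCC(C)C")
  set.seed(11)
  cans <- replicate(100, asbscaffolds:::.canonMol(
    asbscaffolds:::.permuteAtoms(mol, sample(length(mol)))))
  expect_length(unique(cans), 1)
  expect_identical(unique(cans), asbscaffolds:::.canonMol(mol))
})

test_that("scaffold tables are rank-ordered and round-trip exactly", {
  p <- withr::local_tempfile(fileext = ".tsv")
  # empty collection: header-only file
  empty <- rankScaffolds(methods::new("ScaffoldCollection",
    scaffolds = list(), sourceLabels = "S", ranked = FALSE,
    ranks = integer()))
  writeScaffoldTable(empty, p)
  expect_length(readLines(p), 1)

  mk <- function(smi, n, targets = character()) {
    st <- parseSmiles(smi)
    methods::new("ASBScaffold", smiles = canonicalForm(st), structure = st,
                 nSites = asbscaffolds:::.nSitesOf(st),
                 seriesId = 1L, analogIds = character(),
                 analogCount = as.integer(n), source = "S",
                 perSourceCounts = c(S = as.integer(n)),
                 targetIds = targets, classLabels = character())
  }
  coll <- methods::new("ScaffoldCollection",
    scaffolds = list(mk("[1*]Nc1ccc2ccccc2c1", 3, c("P1", "P2")),
                     mk("[1*]Nc1ccc(O[2*])cc1", 7),
                     mk("[1*]C(=O)Nc1ccccc1", 2)),
    sourceLabels = "S", ranked = FALSE, ranks = integer())
  expect_error(writeScaffoldTable(coll, p), "rank")
  ranked <- rankScaffolds(coll)
  writeScaffoldTable(ranked, p)
  rows <- read.delim(p, check.names = FALSE)
  expect_identical(rows$rank, 1:3)
  expect_identical(rows$n_analogs, c(7L, 3L, 2L))
  expect_identical(rows$target_ids, c("", "P1;P2", ""))

  back <- readScaffoldTable(p)
  expect_true(isRanked(back))
  expect_identical(
    lapply(scaffolds(back), function(s)
      list(s@smiles, s@nSites, s@analogCount, s@source, s@targetIds)),
    lapply(scaffolds(ranked), function(s)
      list(s@smiles, s@nSites, s@analogCount, s@source, s@targetIds)))
})

test_that("configuration round-trips through YAML", {
  p <- withr::local_tempfile(fileext = ".yaml")
  cfg <- pipelineConfig(maxSubstituentHeavyAtoms = 9,
                        coreToSubstituentMinRatio = 1.5,
                        maxSubstitutionSites = 3, keepStereo = FALSE)
  writePipelineConfig(cfg, p)
  back <- readPipelineConfig(p)
  expect_equal(back, cfg)
  expect_error(pipelineConfig(minSeriesSize = 1), "minSeriesSize")
  expect_error(pipelineConfig(maxSubstituentHeavyAtoms = 0), "positive")
})

test_that("sdf input carries ids and annotations through standardization", {
  p <- withr::local_tempfile(fileext = ".sdf")
  mb <- asbscaffolds:::.obConvert("SMI", "SDF", "CC(=O)Nc1ccccc1 cpd1")
  sdf <- sub("[$][$][$][$]",
             "> <TARGETS>\nP12345;P67890\n\n> <CLASSES>\ndrug\n\n$$$$", mb)
  writeLines(sdf, p)
  cs <- readCompounds(p, "sdf", "SDFSRC")
  expect_length(cs, 1)
  expect_identical(compoundIds(cs), "cpd1")
  expect_identical(unname(compoundSmiles(cs)), canonicalForm("CC(=O)Nc1ccccc1"))
  expect_identical(targetAnnotations(cs)[["cpd1"]], c("P12345", "P67890"))
  expect_identical(classAnnotations(cs)[["cpd1"]], "drug")
})
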