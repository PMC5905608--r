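mk_scaffold <- function(smi, n, source = "S", targets = character(),
                        classes = character()) {
  st <- parseSmiles(smi)
  methods::new("ASBScaffold", smiles = canonicalForm(st), structure = st,
               nSites = asbscaffolds:::.nSitesOf(st), seriesId = 1L,
               analogIds = character(), analogCount = as.integer(n),
               source = source,
               perSourceCounts = stats::setNames(as.integer(n), source),
               targetIds = targets, classLabels = classes)
}

mk_collection <- function(scaffolds, source = "S") {
  methods::new("ScaffoldCollection", scaffolds = scaffolds,
               sourceLabels = source, ranked = FALSE, ranks = integer())
}

# a pool of structurally distinct single-site scaffolds for merge tests
scaffold_pool <- function() {
  acyl <- c("", "C", "CC", "CCC", "C(C)C", "CC(C)C", "CCCC", "C1CC1")
  c("[1*]NC(=O)c1ccc2ccccc2c1",
    "[1*]Nc1ccc2ccccc2c1",
    "[1*]Oc1ccc2ccccc2c1",
    sprintf("[1*]Nc1ccc(C%s)cc1", acyl))
}

test_that("annotation is the union of member annotations", {
  cs <- suppressMessages(asbscaffolds:::.newCompoundSet(
    c("m1", "m2", "m3"),
    c("CC(=O)Nc1ccc2ccccc2c1", "CCC(=O)Nc1ccc2ccccc2c1",
      "CCCC(=O)Nc1ccc2ccccc2c1"),
    "S",
    targets = list("P1", c("P1", "P2"), character()),
    classes = list("drug", "drug", character())))
  out <- run_pipeline(cs)
  sc <- annotateScaffold(scaffold(out$results[[1]]), cs)
  expect_identical(targetIds(sc), c("P1", "P2"))
  expect_identical(classLabels(sc), "drug")
  # unknown analog id is a consistency error
  bad <- sc; bad@analogIds <- c(bad@analogIds, "ghost")
  expect_error(annotateScaffold(bad, cs), "unknown analog")
  # unannotated members leave the sets empty
  cs0 <- make_compound_set(c(m1 = "CC(=O)Nc1ccc2ccccc2c1",
                             m2 = "CCC(=O)Nc1ccc2ccccc2c1"))
  sc0 <- annotateScaffold(scaffold(run_pipeline(cs0)$results[[1]]), cs0)
  expect_length(targetIds(sc0), 0)
})

test_that("merging collections follows inclusion-exclusion exactly", {
  pool <- scaffold_pool()
  # disjoint 3 + 2
  a <- mk_collection(lapply(pool[1:3], mk_scaffold, n = 2), "A")
  b <- mk_collection(lapply(pool[4:5], mk_scaffold, n = 3, source = "B"), "B")
  m <- mergeCollections(a, b)
  expect_length(m, 5)
  # overlapping 4 + 3 sharing 2
  a <- mk_collection(lapply(pool[1:4], mk_scaffold, n = 2, source = "A"), "A")
  b <- mk_collection(lapply(pool[3:5], mk_scaffold, n = 5, source = "B"), "B")
  m <- mergeCollections(a, b)
  expect_length(m, 5)
  shared <- Filter(function(s) s@source == "both", scaffolds(m))
  expect_length(shared, 2)
  # shared scaffolds keep per-source analog counts; displayed count is max
  expect_identical(shared[[1]]@perSourceCounts, c(A = 2L, B = 5L))
  expect_identical(analogCount(shared[[1]]), 5L)
  # merge with an empty collection is the identity
  e <- mk_collection(list(), "B")
  expect_length(mergeCollections(a, e), length(a))

  # randomized property: |A union B| = |A| + |B| - |A intersect B|
  set.seed(99)
  for (rep in 1:10) {
    ia <- sample(length(pool), sample(2:length(pool), 1))
    ib <- sample(length(pool), sample(2:length(pool), 1))
    a <- mk_collection(lapply(pool[ia], mk_scaffold, n = 2), "A")
    b <- mk_collection(lapply(pool[ib], mk_scaffold, n = 3, source = "B"),
                       "B")
    m <- mergeCollections(a, b)
    expect_identical(length(m),
                     length(ia) + length(ib) - length(intersect(ia, ib)))
    expect_identical(sum(vapply(scaffolds(m), function(s)
      s@source == "both", logical(1))), length(intersect(ia, ib)))
  }
})

test_that("ranking is stable, gap-free and idempotent", {
  pool <- scaffold_pool()
  counts <- c(7L, 3L, 3L, 2L)
  coll <- mk_collection(mapply(mk_scaffold, pool[1:4], counts,
                               SIMPLIFY = FALSE))
  r <- rankScaffolds(coll)
  expect_true(isRanked(r))
  expect_identical(scaffoldRanks(r), 1:4)
  got <- unname(vapply(scaffolds(r), analogCount, integer(1)))
  expect_identical(got, c(7L, 3L, 3L, 2L))
  # the two count-3 scaffolds are ordered by canonical string
  ties <- vapply(scaffolds(r)[2:3], scaffoldSmiles, character(1))
  expect_identical(ties, sort(ties, method = "radix"))
  # idempotent
  r2 <- rankScaffolds(r)
  expect_identical(vapply(scaffolds(r2), scaffoldSmiles, character(1)),
                   vapply(scaffolds(r), scaffoldSmiles, character(1)))
  # empty collection ranks to empty
  expect_true(isRanked(rankScaffolds(mk_collection(list()))))
})

test_that("summary statistics compute the reported quantities", {
  pool <- scaffold_pool()
  # 10 series, 9 scaffolds -> coverage 90.0; 5 scaffolds incl. 1 multi-site
  mk_res <- function(i, out) {
    if (out == "failed")
      methods::new("DerivationResult", outcome = "failed", scaffold = NULL,
                   failureReason = "no_common_core", seriesId = i)
    else
      methods::new("DerivationResult", outcome = out,
                   scaffold = mk_scaffold(pool[i], 2),
                   failureReason = NA_character_, seriesId = i)
  }
  series <- methods::new("AnalogSeriesSet",
    series = rep(list(mk_series <- methods::new("AnalogSeries",
      seriesId = 1L, memberIds = c("a", "b"),
      edges = data.frame())), 10),
    singletonIds = character(), smallComponentIds = character())
  results <- c(lapply(1:9, mk_res, out = "single_site"),
               list(mk_res(10L, "failed")))
  sc <- list(
    mk_scaffold(pool[1], 4, targets = c("P1", "P2"), classes = "drug"),
    mk_scaffold(pool[2], 3, targets = "P1", classes = c("drug", "alert")),
    mk_scaffold(pool[3], 2, targets = c("P2", "P3")),
    mk_scaffold("[1*]Nc1ccc(O[2*])cc1", 2),
    mk_scaffold(pool[5], 2))
  st <- summarizeCollection(series, results, mk_collection(sc))
  expect_identical(st@nSeries, 10L)
  expect_identical(st@nScaffolds, 9L)
  expect_equal(st@asCoveragePct, 90.0)
  expect_equal(st@pctSingleSite, 80.0)
  expect_equal(st@pctMultiSite, 20.0)
  expect_equal(st@pctSingleSite + st@pctMultiSite, 100, tolerance = 0.051)
  # single- plus multi-target counts equal scaffolds with >= 1 target
  expect_identical(st@nScaffoldsSingleTarget + st@nScaffoldsMultiTarget, 3L)
  expect_identical(st@nUniqueTargets, 3L)
  expect_identical(st@nDrugAssociated, 2L)
  expect_identical(st@nDrugExclusive, 1L)
  expect_identical(st@nAlertAssociated, 1L)
  # reported percentages are rounded half-up to one decimal
  expect_identical(asbscaffolds:::.round1(0.05), 0.1)
  expect_identical(asbscaffolds:::.round1(56.65), 56.7)
})

test_that("summary internal consistency holds on a two-source run", {
  tpl <- builtinTemplates()$naphthylamide_1site
  libA <- generateLibrary(librarySpec(tpl$template, tpl$pools, 4L,
                                      seed = 1L, label = "A"))
  tplB <- builtinTemplates()$alkoxyanilide_2site
  libB <- generateLibrary(librarySpec(tplB$template, tplB$pools, 5L,
                                      seed = 2L, label = "B"))
  outA <- run_pipeline(libA$compounds)
  outB <- run_pipeline(libB$compounds)
  collA <- collectScaffolds(outA$results, libA$compounds)
  collB <- collectScaffolds(outB$results, libB$compounds)
  merged <- rankScaffolds(mergeCollections(collA, collB))
  st <- summarizeCollection(list(outA$seriesSet, outB$seriesSet),
                            c(outA$results, outB$results), merged)
  # inclusion-exclusion across the per-source breakdown
  expect_identical(length(merged),
                   sum(st@perSource$n_scaffolds) - st@nShared)
  expect_equal(st@full$pct_single_site + st@full$pct_multi_site, 100)
})
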