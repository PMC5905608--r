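mk_series <- function(members, id = 1L) {
  methods::new("AnalogSeries", seriesId = id, memberIds = members,
               edges = data.frame(compound_a = character(),
                                  compound_b = character(),
                                  core = character(), sub_a = character(),
                                  sub_b = character()))
}

mk_core_record <- function(smiles, covered) {
  mol <- parseSmiles(smiles)
  list(core = mol,
       core_can = asbscaffolds:::.canonMol(
         asbscaffolds:::.stripSiteLabels(mol)),
       heavy = asbscaffolds:::.heavyCount(mol), covered_ids = covered)
}

test_that("candidate cores carry coverage and deterministic order", {
  cs <- make_compound_set(c(n1 = "CC(=O)Nc1ccc2ccccc2c1",
                            n2 = "CCC(=O)Nc1ccc2ccccc2c1"))
  ss <- extractAnalogSeries(cs, generateRmmps(buildCoreIndex(cs)))
  cores <- collectCandidateCores(analogSeries(ss)[[1]], cs)
  expect_length(cores, 1)
  expect_identical(cores[[1]]$core_can,
                   unlabeled_can("[*]Nc1ccc2ccccc2c1"))
  expect_setequal(cores[[1]]$covered_ids, c("n1", "n2"))

  # partial coverage is retained, ordered by coverage then size
  amb <- generateAmbiguousSeries(1)
  ss <- extractAnalogSeries(amb$compounds,
                            generateRmmps(buildCoreIndex(amb$compounds)))
  cores <- collectCandidateCores(analogSeries(ss)[[1]], amb$compounds)
  ncov <- vapply(cores, function(r) length(r$covered_ids), integer(1))
  expect_identical(ncov, sort(ncov, decreasing = TRUE))
  expect_true(all(ncov < 5))  # no core covers the whole ambiguous series
})

test_that("single-site derivation finds the shared core with the documented tie-break", {
  # 3-member naphthamide series: 2-aminonaphthalene core, one site
  cs <- make_compound_set(c(n1 = "CC(=O)Nc1ccc2ccccc2c1",
                            n2 = "CCC(=O)Nc1ccc2ccccc2c1",
                            n3 = "CCCC(=O)Nc1ccc2ccccc2c1"))
  out <- run_pipeline(cs)
  expect_length(out$results, 1)
  res <- out$results[[1]]
  expect_identical(outcome(res), "single_site")
  sc <- scaffold(res)
  expect_identical(scaffoldSmiles(sc),
                   normalizeSiteNumbering("[1*]Nc1ccc2ccccc2c1"))
  expect_identical(nSites(sc), 1L)
  expect_identical(analogCount(sc), 3L)

  # tie-break contract: among qualifying cores of 11 and 9 heavy atoms the
  # 11-atom core is chosen
  series <- mk_series(c("x1", "x2"))
  cores <- list(
    mk_core_record("[*]Nc1ccccc1C", covered = c("x1", "x2")),      # 8 heavy
    mk_core_record("[*]Nc1ccc2ccccc2c1", covered = c("x1", "x2")), # 11 heavy
    mk_core_record("[*]Nc1ccccc1", covered = "x1"))                # partial
  sc <- findSingleSiteScaffold(series, cores)
  expect_identical(scaffoldSmiles(sc),
                   normalizeSiteNumbering("[1*]Nc1ccc2ccccc2c1"))

  # no full-coverage core -> NULL
  expect_null(findSingleSiteScaffold(series,
    list(mk_core_record("[*]Nc1ccccc1", covered = "x1"))))
})

test_that("multi-site derivation recovers templates and reports analog counts", {
  tpl <- builtinTemplates()$alkoxyanilide_2site
  # full 3x3 sub-grid: 9 analogs, scaffold = template, count 9
  pools <- list(tpl$pools[[1]], tpl$pools[[2]][1:3])
  combos <- expand.grid(1:3, 1:3)
  mols <- lapply(seq_len(nrow(combos)), function(i)
    asbscaffolds:::.attachSubstituents(parseSmiles(tpl$template),
      list(parseSmiles(pools[[1]][combos[i, 1]]),
           parseSmiles(pools[[2]][combos[i, 2]]))))
  smi <- asbscaffolds:::.canonMols(mols)
  names(smi) <- sprintf("g%02d", seq_along(smi))
  cs <- make_compound_set(smi)
  out <- run_pipeline(cs)
  expect_length(out$results, 1)
  res <- out$results[[1]]
  expect_identical(outcome(res), "multi_site")
  expect_identical(scaffoldSmiles(scaffold(res)),
                   normalizeSiteNumbering(tpl$template))
  expect_identical(nSites(scaffold(res)), 2L)
  expect_identical(analogCount(scaffold(res)), 9L)

  # three-site series shaped like one scaffold with three cores
  tpl3 <- builtinTemplates()$sulfonamide_3site
  lib <- generateLibrary(librarySpec(tpl3$template, tpl3$pools, 6L,
                                     nDecoys = 0L, seed = 8L, label = "T3"))
  out <- run_pipeline(lib$compounds)
  res <- out$results[[1]]
  expect_identical(outcome(res), "multi_site")
  expect_identical(nSites(scaffold(res)), 3L)
  expect_identical(scaffoldSmiles(scaffold(res)),
                   lib$truth@expectedScaffold)
})

test_that("hydrogen is permitted at a designated site of a scaffold", {
  # series varying at both sites; the derived two-site scaffold must also
  # cover a compound carrying hydrogen at the alkoxy site
  tpl <- "[1*]Nc1ccc(O[2*])cc1"
  mk <- function(acyl, alk) asbscaffolds:::.canonMol(
    asbscaffolds:::.attachSubstituents(parseSmiles(tpl),
      list(parseSmiles(acyl), parseSmiles(alk))))
  smi <- c(h1 = mk("[*]C(=O)C", "[*]C"),
           h2 = mk("[*]C(=O)CC", "[*]C"),
           h3 = mk("[*]C(=O)C", "[*]CC"))
  cs <- make_compound_set(smi)
  out <- run_pipeline(cs)
  expect_length(out$results, 1)
  res <- out$results[[1]]
  expect_identical(outcome(res), "multi_site")
  sc <- scaffold(res)
  expect_identical(scaffoldSmiles(sc), normalizeSiteNumbering(tpl))
  # hydrogen at the second site: still covered by the scaffold
  expect_true(scaffoldCoversCompound(sc, "CC(=O)Nc1ccc(O)cc1"))
  # substituent at an undesignated ring position: not covered
  expect_false(scaffoldCoversCompound(sc, "CC(=O)Nc1ccc(OC)cc1C"))
})

test_that("single-site resolution takes precedence over multi-site", {
  tpl <- builtinTemplates()$naphthylamide_1site
  lib <- generateLibrary(librarySpec(tpl$template, tpl$pools, 5L,
                                     seed = 13L, label = "P"))
  out <- run_pipeline(lib$compounds)
  expect_identical(outcome(out$results[[1]]), "single_site")
  # a multi-site attempt on the same series would be rejected by precedence:
  # derive again with the single-site stage's answer removed is not possible,
  # so assert the orchestration result only reports one scaffold per series
  expect_length(out$results, length(analogSeries(out$seriesSet)))
})

test_that("ambiguous series fail with ambiguous_sub_series; separated sub-series resolve", {
  for (seed in c(1L, 7L)) {
    amb <- generateAmbiguousSeries(seed)
    out <- run_pipeline(amb$compounds)
    expect_length(out$results, 1)
    res <- out$results[[1]]
    expect_identical(outcome(res), "failed")
    expect_identical(failureReason(res), "ambiguous_sub_series")
    expect_null(scaffold(res))

    # control of the control: removing the bridge yields two single-site series
    keep <- setdiff(compoundIds(amb$compounds), amb$truth@bridgeId)
    cs2 <- make_compound_set(compoundSmiles(amb$compounds)[keep],
                             source = "AMBIG")
    out2 <- run_pipeline(cs2)
    expect_length(out2$results, 2)
    expect_identical(vapply(out2$results, outcome, character(1)),
                     c("single_site", "single_site"))
  }
})

test_that("coverage requiring more sites than allowed is diagnosed", {
  # two-site grid derived under a one-site limit
  tpl <- builtinTemplates()$alkoxyanilide_2site
  lib <- generateLibrary(librarySpec(tpl$template, tpl$pools, 6L,
                                     nDecoys = 0L, seed = 21L, label = "SL"))
  cfg <- pipelineConfig(maxSubstitutionSites = 1L)
  out <- run_pipeline(lib$compounds, cfg)
  expect_length(out$results, 1)
  res <- out$results[[1]]
  expect_identical(outcome(res), "failed")
  expect_identical(failureReason(res), "site_limit_exceeded")
})

test_that("site numbering normalization is canonical, idempotent and permutation-invariant", {
  a <- normalizeSiteNumbering("[2*]Oc1ccc(N[1*])cc1")
  b <- normalizeSiteNumbering("[1*]Oc1ccc(N[2*])cc1")
  expect_identical(a, b)
  expect_identical(normalizeSiteNumbering(a), a)
  # single-site scaffolds keep their one numbered site
  one <- normalizeSiteNumbering("[1*]Nc1ccccc1")
  expect_identical(normalizeSiteNumbering(one), one)
  expect_true(grepl("[1*]", one, fixed = TRUE))
  # graph method agrees with the character method
  m <- normalizeSiteNumbering(parseSmiles("[2*]Oc1ccc(N[1*])cc1"))
  expect_identical(asbscaffolds:::.canonMol(m), a)
})

test_that("every derived scaffold covers all its analogs (substructure property)", {
  tpls <- builtinTemplates()
  for (i in seq_along(tpls)) {
    tpl <- tpls[[i]]
    lib <- generateLibrary(librarySpec(tpl$template, tpl$pools,
      nAnalogs = min(tpl$max_analogs, 5L), seed = 30L + i, label = "C"))
    out <- run_pipeline(lib$compounds)
    # uniqueness: at most one scaffold per series
    expect_lte(sum(vapply(out$results, function(r)
      outcome(r) != "failed", logical(1))), length(out$results))
    for (res in out$results) {
      if (outcome(res) == "failed") next
      sc <- scaffold(res)
      for (id in analogIds(sc)) {
        mol <- lib$compounds@mols[[match(id, compoundIds(lib$compounds))]]
        expect_true(scaffoldCoversCompound(sc, mol),
                    label = sprintf("template %d, analog %s", i, id))
      }
    }
  }
})
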