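test_that("retrosynthetic bond perception matches the rule environments", {
  # acetanilide: exactly one amide bond
  b <- findRetrosyntheticBonds("CC(=O)Nc1ccccc1")
  expect_identical(nrow(b), 1L)
  expect_identical(b$rule, "amide")
  # ethylbenzene: no rule environment present
  expect_identical(nrow(findRetrosyntheticBonds("CCc1ccccc1")), 0L)
  # delta-valerolactam: the ring amide bond is never cut
  expect_identical(nrow(findRetrosyntheticBonds("O=C1CCCCN1")), 0L)
  # one representative per remaining class
  cases <- list(
    ester = "CCOC(=O)c1ccccc1",
    ether = "COc1ccccc1",
    amine = "c1ccccc1CN(C)CC",          # aliphatic tertiary amine
    urea = "CNC(=O)Nc1ccccc1",
    olefin = "CC/C=C/c1ccccc1OC(=O)C",  # acyclic C=C, both sides substituted
    quaternary_N = "C[N+](C)(C)Cc1ccccc1",
    aromatic_N_aliphatic_C = "CCn1cccc1",
    lactam_N_aliphatic_C = "O=C1CCCCN1CCc1ccccc1",
    aromatic_C_aromatic_C = "c1ccc(cc1)-c1ccncc1",
    sulfonamide = "CC(C)NS(=O)(=O)c1ccccc1")
  for (rule in names(cases)) {
    b <- findRetrosyntheticBonds(cases[[rule]])
    expect_true(rule %in% b$rule, label = sprintf("%s in %s", rule,
                                                  cases[[rule]]))
  }
  # urea bonds are classified urea, not amide
  b <- findRetrosyntheticBonds("CNC(=O)Nc1ccccc1")
  expect_setequal(unique(b$rule), "urea")
  # rules can be disabled individually
  cfg <- pipelineConfig(enabledRules = setdiff(retrosyntheticRuleIds(),
                                               "amide"))
  expect_identical(nrow(findRetrosyntheticBonds("CC(=O)Nc1ccccc1", cfg)), 0L)
})

test_that("size rules gate decompositions as specified", {
  expect_false(passesSizeRules(20, 14))  # substituent above the 13-atom cap
  expect_false(passesSizeRules(7, 4))    # core below 2x substituent
  expect_true(passesSizeRules(11, 4))
  expect_true(all(passesSizeRules(c(26, 13), c(13, 1))))
  # configurable thresholds
  cfg <- pipelineConfig(maxSubstituentHeavyAtoms = 3,
                        coreToSubstituentMinRatio = 1)
  expect_true(passesSizeRules(4, 3, cfg))
  expect_false(passesSizeRules(4, 4, cfg))
})

test_that("single-cut enumeration applies roles and size rules", {
  # acetanilide: only the anilide core / acetyl substituent split passes
  f <- enumerateSingleCut("CC(=O)Nc1ccccc1")
  expect_length(f, 1)
  expect_identical(f[[1]]$core_can, unlabeled_can("[*]Nc1ccccc1"))
  expect_identical(f[[1]]$core_heavy, 7L)
  expect_identical(f[[1]]$sub_can, unlabeled_can("[*]C(=O)C"))
  expect_identical(f[[1]]$sub_heavy, 3L)
  # no cut sites -> no fragmentations
  expect_length(enumerateSingleCut("CCc1ccccc1"), 0)
  # N-(2-naphthyl)acetamide: one fragmentation, 2-aminonaphthalene core
  f <- enumerateSingleCut("CC(=O)Nc1ccc2ccccc2c1")
  expect_length(f, 1)
  expect_identical(f[[1]]$core_can,
                   unlabeled_can("[*]Nc1ccc2ccccc2c1"))
})

test_that("single-cut enumeration equals the brute-force oracle", {
  mols <- c(
    "CC(=O)Nc1ccc2ccccc2c1", "CCOC(=O)c1ccc(OC)cc1",
    "CC(C)NS(=O)(=O)c1ccc(NC(=O)CC)cc1", "c1ccc(cc1)-c1ccc(NC(=O)C)cc1",
    "COc1ccc(CN(C)CC)cc1", "CCc1ccccc1", "O=C1CCCCN1CCc1ccccc1",
    "CNC(=O)Nc1ccc2ccccc2c1", "CC(=O)Nc1ccc(OCCCCCC)cc1")
  for (smi in mols) {
    mol <- parseSmiles(smi)
    got <- sort(vapply(enumerateSingleCut(mol),
                       function(f) paste(f$core_can, f$sub_can, sep = " | "),
                       character(1)))
    expect_identical(got, brute_force_single_cut(mol), label = smi)
  }
})

test_that("every emitted fragmentation reassembles to its parent", {
  mols <- c("CC(=O)Nc1ccc2ccccc2c1", "CC(=O)Nc1cc(OC)cc(S(=O)(=O)NC)c1",
            "CCOC(=O)c1ccc(OC)cc1", "CC(=O)Nc1ccc(OCC)cc1")
  for (smi in mols) {
    mol <- parseSmiles(smi)
    parent <- asbscaffolds:::.canonMol(mol)
    frags <- c(enumerateSingleCut(mol),
               enumerateMultiCut(mol, 2L),
               enumerateMultiCut(mol, 3L))
    expect_gt(length(frags), 0)
    for (f in frags)
      expect_identical(
        asbscaffolds:::.canonMol(reassembleFragmentation(f)), parent,
        label = sprintf("%s (k=%d)", smi, f$k))
  }
})

test_that("multi-cut enumeration needs enough sites and respects connectivity", {
  # one cut site only: no k=2 decomposition
  expect_length(enumerateMultiCut("CC(=O)Nc1ccccc1", 2L), 0)
  # two-site fixture: the k=2 core equals the generating template
  tpl <- builtinTemplates()$alkoxyanilide_2site
  analog <- asbscaffolds:::.attachSubstituents(
    parseSmiles(tpl$template),
    list(parseSmiles("[*]C(=O)C"), parseSmiles("[*]CC")))
  f2 <- enumerateMultiCut(analog, 2L)
  expect_gt(length(f2), 0)
  cores <- vapply(f2, `[[`, character(1), "core_can")
  tpl_can <- asbscaffolds:::.canonMol(
    asbscaffolds:::.stripSiteLabels(parseSmiles(tpl$template)))
  expect_true(tpl_can %in% cores)
})

test_that("tightening the substituent cap never adds fragmentations", {
  mols <- c("CC(=O)Nc1ccc2ccccc2c1", "CCOC(=O)c1ccc(OC)cc1",
            "CC(C)NS(=O)(=O)c1ccc(NC(=O)CC)cc1",
            "CC(=O)Nc1ccc(OCCCCCC)cc1")
  caps <- c(13L, 8L, 5L, 3L, 1L)
  for (smi in mols) {
    mol <- parseSmiles(smi)
    counts <- vapply(caps, function(cap)
      length(enumerateSingleCut(mol,
        pipelineConfig(maxSubstituentHeavyAtoms = cap))), integer(1))
    expect_true(all(diff(counts) <= 0), label = smi)
  }
})
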