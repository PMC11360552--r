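test_that("plain definitions parse into single-KO steps", {
  m <- parseModuleDefinition("M1", "K1 K2 K3 K4")
  expect_equal(nSteps(m), 4)
  expect_true(all(vapply(moduleSteps(m), function(s) s$op == "KO",
                         logical(1))))
})

test_that("branch and complex steps evaluate over the full truth table", {
  m <- parseModuleDefinition("M1", "(K1,K2) K3+K4")
  expect_equal(nSteps(m), 2)
  kos <- c("K1", "K2", "K3", "K4")
  for (mask in 0:15) {
    present <- kos[bitwAnd(mask, 2^(0:3)) > 0]
    want <- sum(("K1" %in% present) || ("K2" %in% present),
                ("K3" %in% present) && ("K4" %in% present))
    got <- stepwiseCompleteness(m, present)$n_satisfied
    expect_equal(got, want, label = paste(present, collapse = ","))
  }
})

test_that("optional components drop out of the step count and satisfaction", {
  m <- parseModuleDefinition("M1", "K1 -K2 K3")
  expect_equal(nSteps(m), 2)
  expect_equal(stepwiseCompleteness(m, c("K1", "K3"))$completeness, 1)
  expect_equal(stepwiseCompleteness(m, c("K1", "K2"))$completeness, 0.5)
  # optional inside a complex: "K1-K2" needs only K1
  m2 <- parseModuleDefinition("M2", "K1-K2")
  expect_equal(stepwiseCompleteness(m2, "K1")$completeness, 1)
})

test_that("gap steps count in the denominator and never satisfy", {
  m <- parseModuleDefinition("M1", "K1 K2 -- K3")
  expect_equal(nSteps(m), 4)
  r <- stepwiseCompleteness(m, c("K1", "K2", "K3"))
  expect_equal(r$n_satisfied, 3)
  expect_equal(r$completeness, 0.75)
  expect_true(r$complete)
})

test_that("unbalanced parentheses raise a positioned parse error", {
  expect_error(parseModuleDefinition("M1", "K1 (K2,K3"), "unbalanced")
  expect_error(parseModuleDefinition("M1", "K1 K2)K3"), "position")
  expect_error(parseModuleDefinition("M1", "  "), "empty")
})

test_that("an empty KO set gives zero completeness", {
  m <- parseModuleDefinition("M1", "K1 K2 K3 K4")
  expect_equal(stepwiseCompleteness(m, character(0))$completeness, 0)
})

test_that("the evaluator equals the truth-table oracle on every toy module", {
  mods <- toyModuleSet()
  for (i in seq_len(nrow(mods))) {
    id <- mods$module_id[i]
    m <- parseModuleDefinition(id, mods$definition[i])
    kos <- toyModuleKos[[id]]
    oracle <- toyModuleOracle[[id]]
    for (mask in 0:(2^length(kos) - 1)) {
      present <- kos[bitwAnd(mask, 2^(seq_along(kos) - 1)) > 0]
      want <- sum(oracle(present))
      got <- stepwiseCompleteness(m, present)$n_satisfied
      expect_equal(got, want,
                   label = sprintf("%s with {%s}", id,
                                   paste(present, collapse = ",")))
    }
  }
})

test_that("parse -> unparse round-trips to an equivalent expression", {
  mods <- toyModuleSet()
  set.seed(3)
  for (i in seq_len(nrow(mods))) {
    m1 <- parseModuleDefinition(mods$module_id[i], mods$definition[i])
    m2 <- parseModuleDefinition(mods$module_id[i],
                                unparseModuleDefinition(m1))
    expect_equal(nSteps(m2), nSteps(m1))
    kos <- toyModuleKos[[mods$module_id[i]]]
    for (r in 1:8) {
      present <- kos[runif(length(kos)) < 0.5]
      expect_equal(stepwiseCompleteness(m2, present)$n_satisfied,
                   stepwiseCompleteness(m1, present)$n_satisfied)
    }
  }
})

test_that("adding KOs never decreases completeness", {
  mods <- toyModuleSet()
  set.seed(14)
  all_kos <- unique(unlist(toyModuleKos))
  for (r in 1:20) {
    base <- all_kos[runif(length(all_kos)) < 0.4]
    extra <- unique(c(base, all_kos[runif(length(all_kos)) < 0.3]))
    for (i in seq_len(nrow(mods))) {
      m <- parseModuleDefinition(mods$module_id[i], mods$definition[i])
      expect_gte(stepwiseCompleteness(m, extra)$completeness,
                 stepwiseCompleteness(m, base)$completeness)
    }
  }
})

test_that("pathway classification matches hand enumeration and nests", {
  mods <- toyModuleSet()
  set.seed(27)
  all_kos <- unique(unlist(toyModuleKos))
  for (r in 1:5) {
    micro <- all_kos[runif(length(all_kos)) < 0.7]
    viral <- all_kos[runif(length(all_kos)) < 0.35]
    got <- classifyPathways(mods, micro, viral)
    for (i in seq_len(nrow(mods))) {
      id <- mods$module_id[i]
      msat <- toyModuleOracle[[id]](micro)
      vsat <- toyModuleOracle[[id]](viral)
      present <- sum(msat) >= 1
      expect_equal(got$microbial_present[got$module_id == id], present)
      expect_equal(got$microbial_complete[got$module_id == id],
                   present && mean(msat) >= 0.75)
      expect_equal(got$amg_targeted[got$module_id == id],
                   present && sum(vsat) >= 1)
      expect_equal(got$amg_hotspot[got$module_id == id],
                   present && sum(vsat) >= 1 && mean(vsat) >= 0.75)
    }
    expect_true(all(got$amg_hotspot <= got$amg_targeted))
    expect_true(all(got$amg_targeted <= got$microbial_present))
  }
})

test_that("ko targeting mode counts definition membership", {
  mods <- data.frame(module_id = "M1", definition = "K1+K2 K3")
  got <- classifyPathways(mods, microbial_kos = c("K1", "K3"),
                          viral_amg_kos = "K2", targeted_mode = "ko")
  expect_true(got$amg_targeted)
  got2 <- classifyPathways(mods, microbial_kos = c("K1", "K3"),
                           viral_amg_kos = "K2", targeted_mode = "step")
  expect_false(got2$amg_targeted)   # K2 alone satisfies no step
})
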