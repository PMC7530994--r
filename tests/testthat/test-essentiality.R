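test_that("single-gene deletion recovers the constructed essential sets", {
  toy <- toy_fixture()
  ess <- single_gene_deletion(toy$model, toy$media$minimal_glucose)
  expect_setequal(ess$gene[ess$essential], toy$truth$essential_minimal_glucose)
  # a gene absent from every GPR leaves growth untouched
  expect_true(all(ess$growth_ratio[ess$n_disabled == 0] == 1))
  # deletions never increase growth
  expect_true(all(ess$growth_ratio <= 1 + 1e-6))
  # screen is order-independent
  ess_rev <- single_gene_deletion(toy$model, toy$media$minimal_glucose,
                                  genes = rev(toy$model$genes))
  ord <- match(ess$gene, ess_rev$gene)
  expect_equal(ess_rev$growth_ratio[ord], ess$growth_ratio)
  # carbon-source dependence: ethanol needs gluconeogenesis + decarboxylase
  ess_e <- single_gene_deletion(toy$model, toy$media$minimal_ethanol)
  expect_setequal(ess_e$gene[ess_e$essential],
                  toy$truth$essential_minimal_ethanol)
})

test_that("isozyme pairs buffer deletions; single-gene steps are lethal", {
  toy <- toy_fixture()
  med <- toy$media$minimal_glucose
  ess <- single_gene_deletion(toy$model, med,
                              genes = c("adh1", "adh2", "etc1", "etc2",
                                        "glk1", "pfk1"))
  by_gene <- stats::setNames(ess$essential, ess$gene)
  expect_false(any(by_gene[c("adh1", "adh2", "etc1", "etc2")]))
  expect_true(all(by_gene[c("glk1", "pfk1")]))   # AND complex: each subunit lethal
  # with no isozyme pair configured, the respiratory chain gene set shrinks
  solo <- make_toy_model(toy_model_config(n_isozyme_pairs = 0))
  expect_false(all(c("adh2", "etc2") %in% solo$model$genes))
})

test_that("rich media relax essentiality relative to minimal media", {
  toy <- toy_fixture()
  n_rich <- sum(single_gene_deletion(toy$model, toy$media$rich)$essential)
  n_min <- sum(single_gene_deletion(toy$model,
                                    toy$media$minimal_glucose)$essential)
  expect_lte(n_rich, n_min)
  expect_identical(n_rich, 0L)    # every route is buffered on the full platter
})

test_that("non-viable wild type aborts the screen with a diagnostic", {
  toy <- toy_fixture()
  no_n <- medium("no_n", c(EX_h2o = 1000, EX_h = 1000, EX_co2 = 1000,
                           EX_glc = 10, EX_o2 = 1000))
  expect_error(single_gene_deletion(toy$model, no_n), "non-viable")
  expect_warning(
    single_gene_deletion(toy$model, toy$media$minimal_glucose,
                         genes = c("glk1", "not_a_gene")), "unknown genes")
})

test_that("confusion statistics match direct formula evaluation on random matrices", {
  set.seed(505)
  for (i in 1:1000) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1)
    tn <- sample(0:50, 1); fn <- sample(0:50, 1)
    if (tp + fn == 0 || tn + fp == 0 || tp + fp + tn + fn == 0) next
    genes <- paste0("g", seq_len(tp + fp + tn + fn))
    pred <- c(rep(TRUE, tp), rep(TRUE, fp), rep(FALSE, tn), rep(FALSE, fn))
    tru <- c(rep(TRUE, tp), rep(FALSE, fp), rep(FALSE, tn), rep(TRUE, fn))
    cs <- confusion_statistics(data.frame(gene = genes, essential = pred),
                               stats::setNames(tru, genes))
    expect_identical(c(cs$tp, cs$fp, cs$tn, cs$fn), c(tp, fp, tn, fn))
    expect_equal(cs$sensitivity, tp / (tp + fn))
    expect_equal(cs$specificity, tn / (tn + fp))
    expect_equal(cs$accuracy, (tp + tn) / (tp + fp + tn + fn))
    expect_equal(cs$f1, 2 * tp / (2 * tp + fp + fn))
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    expect_equal(cs$mcc, if (den > 0) (tp * tn - fp * fn) / den else 0,
                 tolerance = 1e-12)
  }
})

test_that("confusion statistics: worked example, perfect prediction, ortholog rules", {
  # TP=7 FP=3 TN=80 FN=10
  genes <- paste0("g", 1:100)
  pred <- c(rep(TRUE, 10), rep(FALSE, 90))
  tru <- c(rep(TRUE, 7), rep(FALSE, 3), rep(FALSE, 80), rep(TRUE, 10))
  cs <- confusion_statistics(data.frame(gene = genes, essential = pred),
                             stats::setNames(tru, genes))
  expect_equal(cs$sensitivity, 7 / 17)
  expect_equal(cs$specificity, 80 / 83)
  # perfect prediction scores 1 everywhere
  cp <- confusion_statistics(data.frame(gene = genes, essential = tru),
                             stats::setNames(tru, genes))
  expect_equal(c(cp$sensitivity, cp$specificity, cp$mcc, cp$f1),
               c(1, 1, 1, 1))
  # multi-ortholog genes count as essential only if all references are
  om <- data.frame(gene = c("a", "a", "b"), reference = c("r1", "r2", "r3"))
  truth <- c(r1 = TRUE, r2 = FALSE, r3 = TRUE)
  cs2 <- confusion_statistics(
    data.frame(gene = c("a", "b", "c"), essential = c(FALSE, TRUE, TRUE)),
    truth, om)
  expect_identical(c(cs2$tp, cs2$fp, cs2$tn, cs2$fn), c(1L, 0L, 1L, 0L))
  expect_identical(cs2$n_unmapped, 1L)   # gene c has no ortholog
  expect_error(confusion_statistics(
    data.frame(gene = "z", essential = TRUE), c(r1 = TRUE),
    data.frame(gene = character(), reference = character())),
    "no genes")
})

test_that("media presets open the declared component classes", {
  toy <- toy_fixture()
  pres <- media_presets(toy$model,
                        carbon = c(EX_glc = 10, EX_gal = 10, EX_etoh = 20),
                        nitrogen = "EX_nh4",
                        trace = c("EX_h2o", "EX_h", "EX_co2", "EX_o2"))
  expect_named(pres, c("ypd_rich", "minimal_glc", "minimal_gal",
                       "minimal_etoh"), ignore.order = TRUE)
  # minimal glucose opens exactly carbon + nitrogen + trace
  expect_setequal(names(pres$minimal_glc$uptake),
                  c("EX_glc", "EX_nh4", "EX_h2o", "EX_h", "EX_co2", "EX_o2"))
  # all presets aerobic: O2 uptake unconstrained
  expect_true(all(vapply(pres, function(m) m$uptake[["EX_o2"]] == 1000,
                         logical(1))))
  # rich opens every carbon source
  expect_true(all(c("EX_glc", "EX_gal", "EX_etoh") %in%
                  names(pres$ypd_rich$uptake)))
  # absent component is skipped with a warning
  expect_warning(media_presets(toy$model, carbon = c(EX_glc = 10),
                               nitrogen = "EX_nh4",
                               trace = c("EX_h2o", "EX_absent")),
                 "absent")
})
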