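test_that("regulatory decision table is total over all evidence patterns", {
  pats <- expand.grid(p = c(TRUE, FALSE), h = c(TRUE, FALSE),
                      t = c(TRUE, FALSE), lh = c(-1, 0, 1),
                      lt = c(-1, 0, 1))
  out <- classify_regulatory(pats$p, pats$h, pats$t, pats$lh, pats$lt)
  vocab <- c("conserved", "cis", "trans", "cis_plus_trans",
             "cis_x_trans", "compensatory", "ambiguous")
  expect_true(all(out %in% vocab))
  expect_length(out, nrow(pats))

  # the named geometries of the framework
  expect_equal(classify_regulatory(FALSE, FALSE, FALSE, 0, 0),
               "conserved")
  expect_equal(classify_regulatory(TRUE, TRUE, FALSE, 1, 0), "cis")
  expect_equal(classify_regulatory(TRUE, FALSE, TRUE, 0, 1), "trans")
  expect_equal(classify_regulatory(TRUE, TRUE, TRUE, 1, 1),
               "cis_plus_trans")
  expect_equal(classify_regulatory(TRUE, TRUE, TRUE, 1, -1),
               "cis_x_trans")
  expect_equal(classify_regulatory(FALSE, TRUE, TRUE, 1, -1),
               "compensatory")
  # a zero sign with all three significant cannot be oriented
  expect_equal(classify_regulatory(TRUE, TRUE, TRUE, 0, 1), "ambiguous")

  # without the parental requirement, the H/T pattern alone decides
  expect_equal(classify_regulatory(FALSE, TRUE, FALSE, 1, 0,
                                   require_parental_sig = FALSE), "cis")
  expect_equal(classify_regulatory(FALSE, FALSE, TRUE, 0, 1,
                                   require_parental_sig = FALSE),
               "trans")
})

test_that("inheritance decision table is total and orders the means", {
  pats <- expand.grid(p = c(TRUE, FALSE), m = c(TRUE, FALSE),
                      f = c(TRUE, FALSE), hyb = c(40, 100, 150, 200, 260))
  out <- classify_inheritance(pats$p, pats$m, pats$f,
                              mean_maternal = rep(200, nrow(pats)),
                              mean_paternal = rep(100, nrow(pats)),
                              mean_hybrid = pats$hyb)
  expect_true(all(out %in% c("conserved", "additive", "maternal_dominant",
                             "paternal_dominant", "overdominant",
                             "underdominant", "ambiguous")))

  expect_equal(classify_inheritance(FALSE, FALSE, FALSE, 200, 100, 150),
               "conserved")
  expect_equal(classify_inheritance(TRUE, FALSE, TRUE, 200, 100, 195),
               "maternal_dominant")
  expect_equal(classify_inheritance(TRUE, TRUE, FALSE, 200, 100, 105),
               "paternal_dominant")
  expect_equal(classify_inheritance(TRUE, TRUE, TRUE, 200, 100, 150),
               "additive")
  expect_equal(classify_inheritance(TRUE, TRUE, TRUE, 200, 100, 260),
               "overdominant")
  expect_equal(classify_inheritance(FALSE, TRUE, TRUE, 200, 100, 40),
               "underdominant")
  # exact tie of hybrid and a parental mean falls to ambiguous
  expect_equal(classify_inheritance(TRUE, TRUE, TRUE, 200, 100, 200),
               "ambiguous")
})

test_that("effect size is the pseudocounted parental log2 ratio", {
  expect_equal(effect_size(10, 10), 0)
  expect_equal(effect_size(4, 1, pseudocount = 1e-9), 2,
               tolerance = 1e-6)
  expect_equal(effect_size(0, 0, pseudocount = 0.5), 0)
  expect_error(effect_size(-1, 2), "nonnegative")
})

test_that("simulated compensatory geometry earns the compensatory call", {
  ds <- quick_dataset(300, c(compensatory = 1), seed = 21)
  res <- classify_all(ds$counts, ds$samples)
  tab <- table(res$calls$regulatory_mode)
  expect_equal(names(which.max(tab)), "compensatory")
})

test_that("conserved regulatory calls never sit in the DA set", {
  ds <- quick_dataset(400, equal_six, seed = 22)
  res <- classify_all(ds$counts, ds$samples, alpha = 0.05)
  cons <- res$calls[res$calls$regulatory_mode == "conserved", ]
  expect_true(all(cons$padj_P > 0.05))
})

test_that("swapping maternal and paternal labels mirrors the calls", {
  ds <- quick_dataset(300, equal_six, seed = 23)
  res <- classify_all(ds$counts, ds$samples)

  sw <- ds$samples
  sw$cross <- c(maternal_species = "paternal_species",
                paternal_species = "maternal_species",
                hybrid = "hybrid")[sw$cross]
  sw$allele <- c(total = "total", maternal = "paternal",
                 paternal = "maternal")[sw$allele]
  res2 <- classify_all(ds$counts, sw)

  map <- c(conserved = "conserved", additive = "additive",
           maternal_dominant = "paternal_dominant",
           paternal_dominant = "maternal_dominant",
           overdominant = "overdominant",
           underdominant = "underdominant", ambiguous = "ambiguous")
  expect_identical(unname(map[res$calls$inheritance_mode]),
                   res2$calls$inheritance_mode)
  expect_identical(res$calls$regulatory_mode, res2$calls$regulatory_mode)
  expect_equal(res2$calls$effect_size, -res$calls$effect_size)
})

test_that("mode switches are counted exactly across consecutive stages", {
  calls <- data.frame(
    peak_id = rep(c("p1", "p2"), 3),
    stage = rep(c("s1", "s2", "s3"), each = 2),
    regulatory_mode = c("cis", "trans", "cis", "trans", "trans", "trans"),
    inheritance_mode = "conserved", effect_size = 0)
  sw <- count_mode_switches(calls, "regulatory",
                            stages = c("s1", "s2", "s3"))
  expect_equal(sw$per_peak$n_switches[sw$per_peak$peak_id == "p1"], 1)
  expect_equal(sw$per_peak$n_switches[sw$per_peak$peak_id == "p2"], 0)
  expect_equal(sw$n_switch_total, 1)
  expect_equal(sum(sw$transitions), 4)  # 2 peaks x 2 stage pairs
  expect_error(count_mode_switches(calls[calls$stage == "s1", ],
                                   "regulatory"), "2 stages")

  # brute-force recount on random call tables
  set.seed(7)
  for (i in 1:20) {
    n <- 30
    stages <- c("a", "b", "c")
    rcalls <- expand.grid(peak_id = paste0("p", 1:n), stage = stages,
                          stringsAsFactors = FALSE)
    rcalls$regulatory_mode <- sample(c("cis", "trans", "conserved"),
                                     nrow(rcalls), replace = TRUE)
    rcalls$inheritance_mode <- "conserved"
    sw <- count_mode_switches(rcalls, "regulatory", stages)
    manual <- vapply(paste0("p", 1:n), function(pk) {
      v <- vapply(stages, function(st)
        rcalls$regulatory_mode[rcalls$peak_id == pk &
                                 rcalls$stage == st], "")
      sum(v[-1] != v[-length(v)])
    }, 0L)
    expect_equal(sw$per_peak$n_switches[match(names(manual),
                                              sw$per_peak$peak_id)],
                 unname(manual))
    expect_true(all(sw$per_peak$n_switches %in% 0:2))
    expect_equal(sum(sw$transitions), 2 * n)
  }
})

test_that("effect-size ranking orders by |ES| with stable ties", {
  calls <- data.frame(peak_id = c("pB", "pA", "pC"), stage = "s1",
                      regulatory_mode = c("cis", "trans", "cis"),
                      inheritance_mode = "conserved",
                      effect_size = c(-3, 1, 3))
  top <- rank_by_effect(calls, 1)
  expect_equal(top$top$peak_id, "pB")  # |ES| tie 3 vs 3 -> smaller id
  top <- rank_by_effect(calls, 3)
  expect_equal(unname(top$mode_fractions[c("cis", "trans")]),
               unname(top$overall_fractions[c("cis", "trans")]))
  expect_error(rank_by_effect(calls, 0), "positive")
  expect_error(rank_by_effect(calls, 9), "exceeds")
})

test_that("cis calls carry larger effect sizes when |c| dominates |t|", {
  law <- list(cis = effect_law("uniform", min = 1.0, max = 2.5),
              trans = effect_law("uniform", min = 0.5, max = 1.5))
  ds <- quick_dataset(500, c(cis = 0.5, trans = 0.5), seed = 24,
                      effect_size_law = law)
  res <- classify_all(ds$counts, ds$samples)
  calls <- res$calls
  es_cis <- abs(calls$effect_size[calls$regulatory_mode == "cis"])
  es_trans <- abs(calls$effect_size[calls$regulatory_mode == "trans"])
  cmp <- group_compare(c(es_cis, es_trans),
                       rep(c("cis", "trans"),
                           c(length(es_cis), length(es_trans))),
                       method = "welch_t", alternative = "greater")
  expect_lt(cmp$p.value, 0.05)
})
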