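make_ct <- function(ct_target, ct_ref, groups, e_t = 2, e_r = 2) {
  n <- length(ct_target)
  rbind(
    data.frame(sample_id = paste0("s", 1:n), group = groups, gene = "tg",
               replicate = 1, ct = ct_target),
    data.frame(sample_id = paste0("s", 1:n), group = groups, gene = "ref",
               replicate = 1, ct = ct_ref))
}

test_that("efficiency-corrected ratios follow the Pfaffl formula", {
  # one cycle below calibrator in the target, reference unchanged -> ratio 2
  ct <- make_ct(c(20, 20, 19), c(22, 22, 22), c("ctl", "ctl", "trt"))
  rel <- relative_expression(ct, "tg", "ref", "ctl",
                             efficiencies = c(tg = 2, ref = 2))
  expect_equal(rel$ratio[rel$group == "trt"], 2)
  # a sample sitting at the calibrator mean has ratio 1
  expect_equal(rel$ratio[rel$sample_id == "s1"], 1)
  # mixed efficiencies: 1.8^2 / 2^0.5
  ct <- make_ct(c(20, 18), c(22, 21.5), c("ctl", "trt"))
  rel <- relative_expression(ct, "tg", "ref", "ctl",
                             efficiencies = c(tg = 1.8, ref = 2))
  expect_equal(rel$ratio[rel$group == "trt"], 1.8^2 / 2^0.5)
  # ddct mode forces E = 2 regardless of the efficiency table
  rel2 <- relative_expression(ct, "tg", "ref", "ctl",
                              efficiencies = c(tg = 1.8, ref = 2),
                              method = "ddct")
  expect_equal(rel2$ratio[rel2$group == "trt"], 2^2 / 2^0.5)
})

test_that("ratio preconditions are enforced", {
  ct <- make_ct(c(20, 19), c(22, 22), c("ctl", "trt"))
  expect_error(relative_expression(ct, "tg", "ref", "ctl",
                                   efficiencies = c(tg = 1.0, ref = 2)),
               "in \\(1, 3\\)")
  expect_error(relative_expression(ct[ct$gene == "tg", ], "tg", "ref", "ctl"),
               "absent")
  expect_error(relative_expression(ct, "tg", "ref", "nope"), "calibrator")
  drop_ref <- ct[!(ct$gene == "ref" & ct$sample_id == "s2"), ]
  expect_error(relative_expression(drop_ref, "tg", "ref", "ctl"),
               "missing reference-gene rows.*s2")
})

test_that("technical replicates average at the Ct level and calibrator geometric mean is 1", {
  a <- simulate_assay(seed = 19)
  rel <- relative_expression(a$ct, "cyp2k5", "ef1a", "saline", a$efficiencies)
  expect_equal(exp(mean(log(rel$ratio[rel$group == "saline"]))), 1)
  # collapsing duplicates by hand first gives identical ratios
  avg <- stats::aggregate(ct ~ sample_id + group + gene, data = a$ct, FUN = mean)
  avg$replicate <- 1
  rel2 <- relative_expression(avg, "cyp2k5", "ef1a", "saline", a$efficiencies)
  expect_equal(rel2$ratio[match(rel$sample_id, rel2$sample_id)], rel$ratio)
})

test_that("assumption checks flag the planted violations", {
  set.seed(5)
  g <- rep(c("a", "b", "c"), each = 6)
  ok <- assumption_checks(rnorm(18), g)
  expect_gte(ok$shapiro_p, 0.05)
  expect_gte(ok$levene_p, 0.05)
  expect_true(ok$pass)
  expect_false(ok$transform_recommended)
  # one group scaled x10: heteroscedastic
  set.seed(8)
  v <- rnorm(18); v[13:18] <- v[13:18] * 10
  het <- assumption_checks(v, g)
  expect_lt(het$levene_p, 0.05)
  expect_true(het$transform_recommended)
  # lognormal: fails raw, passes after the recommended log transform
  set.seed(12)
  ln <- exp(rnorm(18, sd = 1.5) + rep(c(0, 1, 2), each = 6))
  raw <- assumption_checks(ln, g)
  expect_false(raw$pass)
  expect_true(raw$after_log$pass)
  # constant group is flagged, not fatal
  cg <- assumption_checks(c(rep(1, 6), rnorm(12)), g)
  expect_true(any(grepl("constant group", cg$flagged)))
  expect_error(assumption_checks(rnorm(4), c("a", "a", "b", "b")), ">= 3")
})

test_that("one-way ANOVA reproduces hand-computed decompositions", {
  r <- one_way_anova(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(r$F, 0)
  expect_equal(c(r$df_between, r$df_within), c(2, 6))
  # {1,2},{2,3},{4,5}: SSB = 9.3333, SSW = 1.5, F = 9.3333
  r <- one_way_anova(c(1, 2, 2, 3, 4, 5), rep(c("a", "b", "c"), each = 2))
  expect_equal(r$ss_between, 28 / 3)
  expect_equal(r$ss_within, 1.5)
  expect_equal(r$F, (28 / 3 / 2) / (1.5 / 3))
  # three groups of n = 6: df = (2, 15)
  set.seed(3)
  r <- one_way_anova(rnorm(18), rep(c("a", "b", "c"), each = 6))
  expect_equal(c(r$df_between, r$df_within), c(2, 15))
  expect_error(one_way_anova(rep(2, 9), rep(c("a", "b", "c"), each = 3)),
               "degenerate")
  expect_error(one_way_anova(rnorm(6), rep("a", 6)), ">= 2 groups")
})

test_that("ANOVA invariants: SS additivity and F = t^2 for two groups", {
  set.seed(77)
  for (i in 1:15) {
    k <- sample(2:5, 1)
    n <- sample(3:8, 1)
    v <- rnorm(k * n, mean = rep(runif(k, 0, 2), each = n))
    g <- rep(letters[1:k], each = n)
    r <- one_way_anova(v, g)
    ss_total <- sum((v - mean(v))^2)
    expect_lt(abs(ss_total - (r$ss_between + r$ss_within)) / ss_total, 1e-10)
    if (k == 2) {
      t2 <- t.test(v[g == "a"], v[g == "b"], var.equal = TRUE)$statistic^2
      expect_equal(r$F, unname(t2))
    }
  }
})

test_that("SNK separates well-separated groups and reduces to t for k = 2", {
  v <- c(1, 2, 3, 11, 12, 13)
  g <- rep(c("lo", "hi"), each = 3)
  s <- snk_posthoc(v, g)
  expect_equal(sort(s$groups$letters), c("a", "b"))
  expect_equal(s$groups$group[1], "hi")  # descending means, 'a' on top
  # for two groups q = t * sqrt(2) against the same critical point family
  t_stat <- abs(t.test(v[g == "lo"], v[g == "hi"], var.equal = TRUE)$statistic)
  msw <- s$anova$ms_within
  q_obs <- (12 - 2) / sqrt(msw / 3)
  expect_equal(q_obs, unname(t_stat) * sqrt(2))
  # identically distributed groups share a letter
  set.seed(9)
  v <- rnorm(18)
  s <- snk_posthoc(v, rep(c("a", "b", "c"), each = 6))
  expect_equal(length(unique(s$groups$letters)), 1L)
  expect_error(snk_posthoc(rnorm(6), rep("a", 6)), ">= 2 groups")
})

test_that("SNK letters mirror the pairwise separation relation", {
  set.seed(1234)
  for (i in 1:10) {
    k <- sample(3:5, 1)
    v <- rnorm(k * 6, mean = rep(runif(k, 0, 3), each = 6))
    g <- rep(letters[1:k], each = 6)
    s <- snk_posthoc(v, g)
    lt <- strsplit(s$groups$letters, "")
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      share <- length(intersect(lt[[a]], lt[[b]])) > 0
      expect_equal(!share, unname(s$different[a, b]))
    }
  }
})

test_that("SNK rejects at least every pair Tukey HSD rejects", {
  set.seed(555)
  for (i in 1:10) {
    k <- sample(3:4, 1)
    v <- rnorm(k * 6, mean = rep(runif(k, 0, 2.5), each = 6))
    g <- factor(rep(letters[1:k], each = 6))
    s <- snk_posthoc(v, g)
    tk <- TukeyHSD(aov(v ~ g))$g
    for (rn in rownames(tk)) {
      if (tk[rn, "p adj"] < 0.05) {
        pair <- strsplit(rn, "-")[[1]]
        expect_true(s$different[pair[1], pair[2]])
      }
    }
  }
})

test_that("the control-vs-equal-treatments design yields the a,b,b letter pattern", {
  a <- simulate_assay(seed = 42)
  glu <- a$metabolites[a$metabolites$analyte == "glucose", ]
  s <- snk_posthoc(glu$value, glu$group)
  lt <- stats::setNames(s$groups$letters, s$groups$group)
  expect_false(grepl(lt[["saline"]], lt[["low_dose"]], fixed = TRUE))
  expect_false(grepl(lt[["saline"]], lt[["high_dose"]], fixed = TRUE))
  expect_equal(lt[["low_dose"]], lt[["high_dose"]])
})
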