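# Statistical kernels against brute-force oracles, call gates at their
# boundaries, partition summaries and enrichment.

test_that("CPM normalisation satisfies its defining identities", {
  m <- matrix(c(10, 990, 0, 20, 1980, 0), 3,
              dimnames = list(c("g1", "g2", "g3"), c("l1", "l2")))
  cpm <- cpm_normalize(m)
  expect_equal(colSums(cpm), c(l1 = 1e6, l2 = 1e6))
  expect_equal(cpm_normalize(m * 2), cpm)          # scale invariance
  expect_equal(cpm["g1", "l1"], 10 / 1000 * 1e6)
  expect_equal(cpm_normalize(matrix(10, 1, 1, dimnames = list("g", "l")),
                             totals = 1e6)[1, 1], 10)
  expect_error(cpm_normalize(matrix(0, 2, 1)), "positive")
})

test_that("fisher_de matches hypergeometric enumeration and null tables", {
  null <- fisher_de(25, 1000, 25, 1000)
  expect_equal(null$p, 1.0)
  expect_equal(null$fold, 1.0)
  expect_equal(fisher_de(0, 1000, 0, 1000)$p, 1.0)

  ft <- fisher_de(40, 1e5, 10, 1e5)
  expect_equal(ft$p, oracle_fisher2(40, 1e5 - 40, 10, 1e5 - 10),
               tolerance = 1e-10)
  expect_equal(ft$fold, (400 + 0.5) / (100 + 0.5))

  set.seed(7)
  for (i in 1:25) {
    a <- sample(0:30, 1); b <- sample(0:30, 1)
    c_ <- sample(0:30, 1); d <- sample(0:30, 1)
    if (a + b == 0 || c_ + d == 0) next
    expect_equal(fisher_de(a, a + b, c_, c_ + d)$p,
                 oracle_fisher2(a, b, c_, d), tolerance = 1e-9)
  }
  expect_error(fisher_de(10, 5, 1, 10), "exceed")
})

test_that("bh_adjust reproduces the step-up rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(42)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # order preserving
  }
})

test_that("DE calls apply the fold and FDR gates inclusively", {
  expect_identical(call_de(2.0, 0.009), "up")
  expect_identical(call_de(1.99, 1e-4), "none")
  expect_identical(call_de(4.0, 0.011), "none")
  expect_identical(call_de(0.5, 0.0005), "down")
  expect_identical(call_de(c(3, 0.2, 1), c(0.001, 0.001, 0.001)),
                   c("up", "down", "none"))
})

test_that("chi-square bias statistic and p match the df = 2 closed form", {
  perfect <- chisq_bias(100, 100, 100)
  expect_equal(perfect$statistic, 0)
  expect_equal(perfect$p, 1.0)
  skew <- chisq_bias(150, 75, 75)
  expect_equal(skew$statistic, 37.5)
  expect_equal(skew$p, exp(-37.5 / 2), tolerance = 1e-12)
  # closed-form agreement across magnitudes
  set.seed(3)
  o <- matrix(rpois(300, 60), 100, 3)
  res <- chisq_bias(o[, 1], o[, 2], o[, 3])
  expect_equal(res$p, exp(-res$statistic / 2), tolerance = 1e-12)
  expect_true(all(res$statistic >= 0))
  expect_true(is.na(chisq_bias(0, 0, 0)$p))
})

test_that("bias flag combines the p gate and the Expmax/Expmin gate", {
  cb <- chisq_bias(150, 100, 100)
  # E = 350/3; sum((O-E)^2)/E = ((100/3)^2 + 2*(50/3)^2) * 3/350 = 100/7
  expect_equal(cb$statistic, 100 / 7)
  expect_equal(cb$p, exp(-cb$statistic / 2), tolerance = 1e-12)
  flag <- call_bias(cb$p, 150, 100, 100)
  expect_equal(flag$ratio, 1.5)
  expect_true(flag$biased)          # p ~ 7.9e-4 < 0.01 and ratio at 1.5

  # ratio below 1.5 is never biased, however significant
  expect_false(call_bias(1e-10, 140, 100, 100)$biased)
  # zero minimum counts as infinite ratio
  z <- call_bias(chisq_bias(100, 100, 0)$p, 100, 100, 0)
  expect_identical(z$ratio, Inf)
  expect_true(z$biased)
  expect_true(is.na(call_bias(0.5, 0, 0, 0)$biased))
})

test_that("per-contrast DE recovers planted fold changes", {
  set.seed(11)
  n_null <- 300; n_de <- 40
  mu <- exp(runif(n_null + n_de, log(50), log(400)))
  fold <- c(rep(1, n_null), rep(4, n_de))
  libs <- c("g_control_06h", "g_stress_06h")
  counts <- cbind(rpois(n_null + n_de, mu), rpois(n_null + n_de, mu * fold))
  dimnames(counts) <- list(sprintf("gene%03d", seq_len(n_null + n_de)), libs)
  samples <- data.frame(library = libs, genotype = "g",
                        condition = c("control", "stress"),
                        timepoint = 6)
  # the tested features are a subset of the transcriptome: library totals
  # are fixed externally so null genes are null under the exact test
  de <- run_de(counts, samples, totals = c(g_control_06h = 5e5,
                                           g_stress_06h = 5e5))
  truth <- fold[match(de$feature, rownames(counts))]
  sens <- mean(de$call[truth == 4] == "up")
  fdp_denom <- sum(de$call != "none")
  expect_gt(sens, 0.85)
  expect_lt(sum(de$call != "none" & truth == 1) / max(fdp_denom, 1), 0.05)
})

test_that("partition summary flags match a brute-force recount", {
  # ten hand-written triplets over two conditions of one genotype
  calls <- expand.grid(triplet_id = sprintf("t%02d", 1:10),
                       homeolog = c("A", "B", "D"),
                       genotype = "g", timepoint = c(6, 12),
                       stringsAsFactors = FALSE)
  calls$call <- "none"
  set_call <- function(df, t, h, tp, val) {
    df$call[df$triplet_id == t & df$homeolog == h & df$timepoint == tp] <- val
    df
  }
  calls <- set_call(calls, "t01", "A", 6, "up")  # unequal at 6 h
  for (h in c("A", "B", "D")) calls <- set_call(calls, "t02", h, 6, "up")
  calls <- set_call(calls, "t03", "A", 12, "up") # unequal at 12 h
  calls <- set_call(calls, "t03", "B", 12, "down")
  for (h in c("A", "B")) calls <- set_call(calls, "t04", h, 12, "down")
  ps <- summarize_partitioning(calls)
  tr <- ps$triplets[order(ps$triplets$triplet_id), ]
  expect_identical(tr$responsive[tr$triplet_id %in%
                                   c("t01", "t02", "t03", "t04")],
                   rep(TRUE, 4))
  expect_identical(sum(tr$responsive), 4L)
  # all-identical calls => responsive but equal contribution
  expect_false(tr$unequal[tr$triplet_id == "t02"])
  expect_identical(tr$unequal[tr$triplet_id %in% c("t01", "t03", "t04")],
                   rep(TRUE, 3))
  # aggregate recount oracle
  expect_identical(ps$totals$n_triplets, 10L)
  expect_identical(ps$totals$n_responsive, 4L)
  expect_identical(ps$totals$n_unequal, 3L)
  expect_equal(ps$totals$pct_responsive, 40.0)
  ph <- ps$per_homeolog
  expect_identical(ph$n_up[ph$timepoint == 6 & ph$homeolog == "A"], 2L)
  expect_identical(ph$n_down[ph$timepoint == 12 & ph$homeolog == "B"], 2L)
})

test_that("bias summary reports percentages through the reporting path", {
  bias <- data.frame(library = rep(c("x", "y"), c(4, 4)),
                     biased = c(TRUE, TRUE, FALSE, NA,
                                FALSE, FALSE, TRUE, FALSE))
  s <- summarize_bias(bias)
  expect_identical(s$n_tested, c(3L, 4L))
  expect_equal(s$pct_biased, c(66.7, 25.0))
})

test_that("term enrichment equals the hypergeometric tail oracle", {
  pop <- sprintf("g%03d", 1:100)
  tm <- rbind(data.frame(gene = pop, term = "universe"),
              data.frame(gene = pop[1:10], term = "rare"))
  study <- pop[c(1:5, 60:64)]
  res <- enrich_terms(study, pop, tm)
  expect_equal(res$p[res$term == "universe"], 1.0)
  expect_equal(res$p[res$term == "rare"],
               oracle_hyper_ge(5, 10, 100, 10), tolerance = 1e-12)
  # study identical to a rare term's gene set is strongly enriched
  res2 <- enrich_terms(pop[1:10], pop, tm)
  expect_lt(res2$p[res2$term == "rare"], 0.01)
  expect_true(res2$significant[res2$term == "rare"])
  expect_error(enrich_terms("g", character(0), tm), "non-empty")
  expect_error(enrich_terms("zz", pop, tm), "subset")
})
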