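# Synthetic allopolyploid data generator: determinism, calibration of the
# substitution process, conservation, and ground-truth structure.

test_that("triplet simulation is deterministic and counts are conserved", {
  s1 <- simulate_triplets(5, 300, 0.02, seed = 11)
  s2 <- simulate_triplets(5, 300, 0.02, seed = 11)
  expect_identical(s1, s2)
  for (sg in c("A", "B", "D")) expect_length(s1$sequences[[sg]], 5)
  # byte-identical FASTA under the same seed
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta(s1$sequences$A, f1)
  write_fasta(s2$sequences$A, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(simulate_triplets(5, 300, 0), "divergence")
})

test_that("pairwise divergence matches the substitution model expectation", {
  d <- 0.02; len <- 1000L; n <- 40L
  s <- simulate_triplets(n, len, d, seed = 3)
  diffs <- function(a, b)
    mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b)
  total_cols <- n * len
  for (pr in list(c("A", "B"), c("A", "D"), c("B", "D"))) {
    observed <- sum(diffs(s$sequences[[pr[1]]], s$sequences[[pr[2]]]))
    expected <- total_cols * d
    tol <- 3 * sqrt(total_cols * d * (1 - d))
    expect_lt(abs(observed - expected), tol)
  }
})

test_that("SNP truth records exactly the divergent columns", {
  s <- simulate_triplets(3, 250, 0.05, seed = 5)
  for (tid in names(s$sequences$A)) {
    a <- strsplit(s$sequences$A[[tid]], "")[[1]]
    b <- strsplit(s$sequences$B[[tid]], "")[[1]]
    d <- strsplit(s$sequences$D[[tid]], "")[[1]]
    expect_identical(s$snps$pos[s$snps$triplet_id == tid],
                     which(!(a == b & b == d)))
  }
  # each recorded site has at least two distinct alleles
  alleles <- s$snps[, c("allele_A", "allele_B", "allele_D")]
  expect_true(all(apply(alleles, 1, function(z) length(unique(z)) >= 2)))
})

test_that("expression truths honour degenerate bias and DE specs", {
  s <- simulate_triplets(10, 250, 0.02, seed = 2)
  des <- sim_design(depth = 100)
  even <- simulate_expression(s, des, bias_spec = list(pi = c(1, 1, 1) / 3),
                              seed = 2)
  expect_true(all(abs(even$proportions$pi_A - 1 / 3) < 1e-12))
  expect_true(all(abs(even$proportions$pi_B - even$proportions$pi_D) < 1e-12))

  null_de <- simulate_expression(s, des, de_spec = list(fraction = 0),
                                 seed = 2)
  ab <- null_de$abundance
  ctl <- ab[ab$library == "tolerant_control_06h", "abundance"]
  str <- ab[ab$library == "tolerant_stress_06h", "abundance"]
  expect_equal(str, ctl)
  expect_true(all(null_de$response$fold == 1))

  forced <- simulate_expression(
    s, des, de_spec = list(fraction = 1, fold_range = c(4, 4), p_down = 0),
    seed = 2)
  ab <- forced$abundance
  ctl <- ab[ab$library == "sensitive_control_24h", "abundance"]
  str <- ab[ab$library == "sensitive_stress_24h", "abundance"]
  expect_equal(str / ctl, rep(4, length(ctl)))
  # proportions always sum to 1
  pr <- true_proportions(forced)
  expect_true(all(abs(pr$pi_A + pr$pi_B + pr$pi_D - 1) < 1e-12))
})

test_that("read simulation respects origins, depth model and error rate", {
  s <- simulate_triplets(4, 300, 0.02, seed = 9)
  des <- sim_design(depth = 500, error_rate = 0, read_length = 50)
  s <- simulate_expression(s, des, seed = 9)
  rd <- simulate_reads(s, des, seed = 9,
                       libraries = "tolerant_control_06h")
  reads <- rd$reads[[1]]
  expect_length(reads, 500)  # fixed-count mode is exact
  expect_identical(nrow(rd$origin), 500L)
  # error-free reads are exact substrings of their origin homeolog
  ok <- mapply(function(rid, tr, h, st) {
    substr(s$sequences[[h]][[tr]], st + 1, st + 50) == reads[[rid]]
  }, rd$origin$read_id, rd$origin$triplet_id, rd$origin$homeolog,
     rd$origin$start)
  expect_true(all(ok))
  # degenerate proportions: all reads from homeolog A
  sA <- simulate_expression(s, des, bias_spec = list(pi = c(1, 0, 0)),
                            seed = 9)
  rdA <- simulate_reads(sA, des, seed = 9,
                        libraries = "tolerant_control_06h")
  expect_true(all(rdA$origin$homeolog == "A"))
  # per-library sub-seeding: an earlier library is unchanged when more
  # libraries are simulated
  rd2 <- simulate_reads(s, des, seed = 9,
                        libraries = c("tolerant_control_06h",
                                      "tolerant_stress_06h"))
  expect_identical(rd2$reads[["tolerant_control_06h"]], reads)
  expect_error(
    simulate_reads(s, sim_design(read_length = 400, depth = 10), seed = 1),
    "read_length")
})

test_that("empirical origin fractions converge to true proportions", {
  s <- simulate_triplets(1, 400, 0.02, seed = 21)
  des <- sim_design(depth = 20000, error_rate = 0)
  s <- simulate_expression(s, des, bias_spec = list(pi = c(0.5, 0.3, 0.2)),
                           de_spec = list(fraction = 0), seed = 21)
  rd <- simulate_reads(s, des, seed = 21,
                       libraries = "tolerant_control_06h")
  frac <- table(rd$origin$homeolog) / nrow(rd$origin)
  se <- sqrt(c(0.5, 0.3, 0.2) * c(0.5, 0.7, 0.8) / 20000)
  expect_true(all(abs(frac[c("A", "B", "D")] - c(0.5, 0.3, 0.2)) < 3 * se))
})

test_that("layout simulation plants exactly the requested hotspot runs", {
  spec <- data.frame(chrom = c(1, 1, 2), start = c(10, 40, 100),
                     length = c(5, 3, 4),
                     family = c("HSP20-like", "NAC", "WRKY"))
  lay <- simulate_layout(2, 200, spec, background_responsive_rate = 0,
                         seed = 4)
  expect_identical(nrow(lay$layout), 400L)
  expect_identical(nrow(lay$hotspots), 3L)
  expect_identical(lay$hotspots$start, c(10L, 40L, 100L))
  expect_identical(lay$hotspots$end, c(15L, 43L, 104L))
  expect_identical(sum(lay$layout$responsive), 12L)
  # null layout
  lay0 <- simulate_layout(1, 50, NULL, 0, seed = 1)
  expect_false(any(lay0$layout$responsive))
  expect_identical(nrow(lay0$hotspots), 0L)
  # with background noise, planted runs remain the unique runs >= 3
  layb <- simulate_layout(2, 200, spec, background_responsive_rate = 0.08,
                          seed = 13)
  for (ch in unique(layb$layout$chrom)) {
    runs <- oracle_runs(layb$layout$responsive[layb$layout$chrom == ch], 3)
    truth <- layb$hotspots[layb$hotspots$chrom == ch, ]
    expect_equal(runs$start, truth$start)
    expect_equal(runs$end, truth$end)
  }
  expect_error(
    simulate_layout(1, 50, data.frame(chrom = 1, start = 48, length = 3,
                                      family = "x"), 0, seed = 1),
    "exceeds")
  expect_error(
    simulate_layout(1, 50, data.frame(chrom = 1, start = 1, length = 2,
                                      family = "x"), 0, seed = 1),
    "length >= 3")
})
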