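# Read assignment classes, proportional allocation arithmetic,
# conservation, label symmetry and recovery against simulator truth.

make_homeologs <- function(len = 200, seed = 5) {
  set.seed(seed)
  anc <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  hom <- lapply(1:3, function(i) {
    ch <- anc
    idx <- sample(len, 6)
    for (j in idx) ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
    ch
  })
  setNames(vapply(hom, paste, "", collapse = ""), c("A", "B", "D"))
}

test_that("read classes follow the two-mismatch compatibility gate", {
  set.seed(2)
  base <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  subst <- function(s, i, ch) { substr(s, i, i) <- ch; s }
  hom <- c(A = subst(base, 100, "A"), B = subst(base, 100, "T"),
           D = subst(base, 100, "T"))
  # error-free read overlapping the A|BD site with the A allele
  readA <- substr(hom[["A"]], 81, 130)
  expect_identical(assign_read(readA, hom)$class, "A")
  # read from a region with no diagnostic site
  read_shared <- substr(hom[["A"]], 1, 50)
  expect_identical(assign_read(read_shared, hom)$class, "ABD")
  # B-allele read is compatible with B and D but not A
  readBD <- substr(hom[["B"]], 81, 130)
  expect_identical(assign_read(readBD, hom)$class, "BD")
  # three errors against every homeolog: unassigned
  set.seed(1)
  bad <- readA
  for (i in c(5, 17, 33)) bad <- subst(bad, i, c(A = "C", C = "G", G = "T",
                                                 T = "A")[[substr(bad, i, i)]])
  res <- assign_read(bad, hom)
  expect_identical(res$class, "UNASSIGNED")
  expect_true(all(res$mismatches >= 3))
  # mismatch counts at the chosen placement are reported per homeolog
  expect_identical(unname(assign_read(readA, hom)$mismatches),
                   c(0L, 1L, 1L))
})

test_that("proportional allocation matches forced arithmetic", {
  # AB splits 15/5 by the 30:10 specific ratio; ABD splits 30/10/10
  got <- allocate_counts(30, 10, 10, n_AB = 20, n_ABD = 50)
  expect_equal(got$c_A, 75)
  expect_equal(got$c_B, 25)
  expect_equal(got$c_D, 20)
  # equal-split fallback at 0/0
  expect_equal(as.numeric(allocate_counts(0, 0, 0, n_ABD = 9)), c(3, 3, 3))
  expect_equal(allocate_counts(0, 0, 0, n_AB = 7)$c_A, 3.5)
  # identity when nothing is shared
  expect_equal(as.numeric(allocate_counts(4, 5, 6)), c(4, 5, 6))
  expect_error(allocate_counts(-1, 0, 0), "non-negative")
})

test_that("allocation conserves totals exactly across random inputs", {
  set.seed(99)
  n <- 200
  x <- matrix(rpois(7 * n, 20), n, 7)
  out <- allocate_counts(x[, 1], x[, 2], x[, 3], x[, 4], x[, 5], x[, 6],
                         x[, 7])
  expect_equal(rowSums(out), rowSums(x), tolerance = 1e-12)
})

test_that("allocation is equivariant under subgenome relabelling", {
  # swapping B and D in the inputs swaps the outputs
  out <- allocate_counts(12, 30, 7, n_AB = 9, n_AD = 4, n_BD = 11,
                         n_ABD = 20)
  swp <- allocate_counts(12, 7, 30, n_AB = 4, n_AD = 9, n_BD = 11,
                         n_ABD = 20)
  expect_equal(out$c_A, swp$c_A)
  expect_equal(out$c_B, swp$c_D)
  expect_equal(out$c_D, swp$c_B)
})

test_that("quantify recovers proportions and conserves assigned reads", {
  s <- simulate_triplets(3, 600, 0.03, seed = 41)
  des <- sim_design(depth = 20000, error_rate = 0)
  s <- simulate_expression(s, des, bias_spec = list(pi = c(0.5, 0.3, 0.2)),
                           de_spec = list(fraction = 0), seed = 41)
  rd <- simulate_reads(s, des, seed = 41,
                       libraries = "tolerant_control_06h")
  q <- quantify(rd$reads, s$sequences)
  # conservation: allocated totals equal assigned class totals per row
  class_tot <- rowSums(q[, c("n_A", "n_B", "n_D", "n_AB", "n_AD", "n_BD",
                             "n_ABD")])
  expect_equal(rowSums(q[, c("c_A", "c_B", "c_D")]), class_tot,
               tolerance = 1e-9)
  # all error-free reads are assigned somewhere
  expect_equal(sum(class_tot) + sum(q$n_unassigned) +
                 sum(attr(q, "ambiguous_reads")) +
                 sum(attr(q, "unseeded_reads")),
               20000)
  # per-triplet proportions within +/-0.02 of the latent truth at this depth
  prop <- q[, c("c_A", "c_B", "c_D")] / class_tot
  expect_true(all(abs(prop$c_A - 0.5) < 0.02))
  expect_true(all(abs(prop$c_B - 0.3) < 0.02))
  expect_true(all(abs(prop$c_D - 0.2) < 0.02))
})

test_that("quantify handles empty libraries and permuted labels", {
  hom <- make_homeologs()
  seqs <- list(A = c(T1 = hom[["A"]]), B = c(T1 = hom[["B"]]),
               D = c(T1 = hom[["D"]]))
  q0 <- quantify(list(empty = character(0)), seqs)
  expect_true(all(q0[, c("n_A", "n_B", "n_D", "c_A", "c_B", "c_D")] == 0))

  reads <- c(r1 = substr(hom[["A"]], 1, 60), r2 = substr(hom[["B"]], 100, 170),
             r3 = substr(hom[["D"]], 41, 120), r4 = substr(hom[["A"]], 81, 160))
  q1 <- quantify(list(lib = reads), seqs)
  # permuting subgenome labels permutes outputs identically
  seqs_p <- list(A = seqs$D, B = seqs$A, D = seqs$B)
  q2 <- quantify(list(lib = reads), seqs_p)
  expect_equal(q2$c_A, q1$c_D)
  expect_equal(q2$c_B, q1$c_A)
  expect_equal(q2$c_D, q1$c_B)
})

test_that("SAM import reproduces the k-mer quantifier's classes", {
  hom <- make_homeologs(seed = 12)
  seqs <- list(A = c(T1 = hom[["A"]]), B = c(T1 = hom[["B"]]),
               D = c(T1 = hom[["D"]]))
  reads <- c(r1 = substr(hom[["A"]], 1, 80),
             r2 = substr(hom[["B"]], 60, 140),
             r3 = substr(hom[["D"]], 121, 200))
  q <- quantify(list(lib = reads), seqs)

  # write the equivalent SAM: one alignment per read per homeolog with
  # the true end-to-end mismatch count in NM
  mm <- function(rd, ref, off) sum(charToRaw(rd) !=
                                     charToRaw(substr(ref, off, off +
                                                        nchar(rd) - 1)))
  offs <- c(r1 = 1, r2 = 60, r3 = 121)
  recs <- c("@HD\tVN:1.6", "@SQ\tSN:T1_A\tLN:200", "@SQ\tSN:T1_B\tLN:200",
            "@SQ\tSN:T1_D\tLN:200")
  for (r in names(reads)) for (h in c("A", "B", "D")) {
    recs <- c(recs, paste(r, 0, paste0("T1_", h), offs[[r]], 42,
                          paste0(nchar(reads[[r]]), "M"), "*", 0, 0,
                          reads[[r]], strrep("I", nchar(reads[[r]])),
                          sprintf("NM:i:%d", mm(reads[[r]], hom[[h]],
                                                offs[[r]])),
                          sep = "\t"))
  }
  sam <- tempfile(fileext = ".sam")
  writeLines(recs, sam)
  qs <- quantify_sam(sam, library = "lib")
  cls <- c("n_A", "n_B", "n_D", "n_AB", "n_AD", "n_BD", "n_ABD")
  expect_identical(unlist(qs[, cls]), unlist(q[, cls]))
  expect_equal(qs$c_A, q$c_A)
  expect_error(suppressWarnings(quantify_sam(tempfile())),
               "cannot open|No such")
})
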