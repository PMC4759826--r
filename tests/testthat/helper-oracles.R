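# Independent brute-force oracles used across test files. These stay
# deliberately naive and separate from the package implementation.

# Benjamini-Hochberg step-up, straight from the definition:
# q_(i) = min_{j >= i} m * p_(j) / j, clipped at 1, mapped back.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * ps[i] / i)
    q[i] <- running
  }
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Two-sided Fisher exact p by direct hypergeometric enumeration of all
# tables with the observed margins; tables as likely or less likely
# than the observed one (with the conventional 1e-7 relative slack).
oracle_fisher2 <- function(a, b, c, d) {
  m <- a + b      # row 1 total
  n <- c + d      # row 2 total
  k <- a + c      # column 1 total
  xs <- max(0, k - n):min(k, m)
  dens <- dhyper(xs, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# One-sided hypergeometric enrichment tail: P(X >= k) by summation.
oracle_hyper_ge <- function(k, K, N, n) {
  xs <- k:min(K, n)
  sum(dhyper(xs, K, N - K, n))
}

# Exhaustive maximal-run scan over a logical vector (0-based half-open).
oracle_runs <- function(flags, min_run) {
  out <- list()
  i <- 1
  n <- length(flags)
  while (i <= n) {
    if (flags[i]) {
      j <- i
      while (j < n && flags[j + 1]) j <- j + 1
      if (j - i + 1 >= min_run)
        out[[length(out) + 1]] <- c(start = i - 1, end = j)  # half-open
      i <- j + 1
    } else i <- i + 1
  }
  if (length(out) == 0)
    return(data.frame(start = integer(), end = integer()))
  df <- as.data.frame(do.call(rbind, out))
  data.frame(start = df$start, end = df$end)
}

# Brute-force window percentages.
oracle_windows <- function(flags, window, step) {
  n <- length(flags)
  if (n < window) return(data.frame(start = integer(), pct = numeric()))
  starts <- seq(0, n - window, by = step)
  data.frame(start = starts,
             pct = vapply(starts, function(s)
               100 * sum(flags[(s + 1):(s + window)]) / window, 0))
}

# All-vs-all triplet finder oracle: aligns every cross-subgenome pair
# with the package's pair scorer (the scorer itself is unit-tested
# against arithmetic cases), applies the gates, single-linkage clusters
# by repeated set expansion, and keeps 1:1:1 clusters whose three hits
# all pass. Independent of the k-mer prescreen and union-find code.
oracle_triplets <- function(ga, gb, gd, min_identity = 0.90,
                            min_coverage = 0.75) {
  ids <- c(names(ga), names(gb), names(gd))
  subg <- rep(c("A", "B", "D"), c(length(ga), length(gb), length(gd)))
  seqs <- c(ga, gb, gd)
  n <- length(ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  # align every cross-subgenome pair (no prescreen); identity/coverage
  # per the definitions: matches over aligned columns, aligned columns
  # over the shorter length
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  for (j in seq_len(n)) {
    others <- which(subg != subg[j] & seq_len(n) < j)
    if (length(others) == 0) next
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(unlist(seqs[others], use.names = FALSE)),
      seqs[[j]], type = "global", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2)
    nm <- Biostrings::nmatch(aln)
    cols <- nm + Biostrings::nmismatch(aln)
    ident <- ifelse(cols > 0, nm / cols, 0)
    cov <- cols / pmin(nchar(seqs[others]), nchar(seqs[[j]]))
    hit <- ident >= min_identity & cov >= min_coverage
    adj[others, j] <- hit
    adj[j, others] <- hit
  }
  seen <- rep(FALSE, n)
  out <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    comp <- i
    repeat {
      grow <- unique(c(comp, which(rowSums(adj[, comp, drop = FALSE]) > 0)))
      if (length(grow) == length(comp)) break
      comp <- grow
    }
    seen[comp] <- TRUE
    if (length(comp) != 3) next
    sg <- subg[comp]
    if (!setequal(sg, c("A", "B", "D"))) next
    a <- comp[sg == "A"]; b <- comp[sg == "B"]; d <- comp[sg == "D"]
    if (adj[a, b] && adj[a, d] && adj[b, d])
      out[[length(out) + 1]] <- c(A = ids[a], B = ids[b], D = ids[d])
  }
  if (length(out) == 0)
    return(data.frame(gene_A = character(), gene_B = character(),
                      gene_D = character()))
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  names(df) <- c("gene_A", "gene_B", "gene_D")
  df <- df[order(df$gene_A), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Small deterministic random-sequence helper for fixtures.
random_dna <- function(n, len, seed = 1, prefix = "g") {
  set.seed(seed)
  setNames(vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), ""),
    sprintf("%s%03d", prefix, seq_len(n)))
}

# Mutate a sequence at `k` random positions (distinct), returning the
# mutated sequence; deterministic under the caller's RNG state.
mutate_seq <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  idx <- sample(seq_along(ch), k)
  bases <- c("A", "C", "G", "T")
  for (i in idx) ch[i] <- sample(setdiff(bases, ch[i]), 1)
  paste(ch, collapse = "")
}

# Three subgenome gene sets: n_true homeologous triplets derived from a
# shared ancestor by `mut` substitutions per homeolog, plus unrelated
# decoy genes split across the subgenomes.
make_triplet_sets <- function(n_true, n_decoy, len = 300, seed = 42,
                              mut = round(len * 0.01)) {
  set.seed(seed)
  ga <- gb <- gd <- character(0)
  for (i in seq_len(n_true)) {
    anc <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
    ga[sprintf("a%03d", i)] <- mutate_seq(anc, mut)
    gb[sprintf("b%03d", i)] <- mutate_seq(anc, mut)
    gd[sprintf("d%03d", i)] <- mutate_seq(anc, mut)
  }
  decoy <- function(prefix, n) {
    out <- character(0)
    for (i in seq_len(n))
      out[sprintf("%s%03d", prefix, i)] <-
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = "")
    out
  }
  list(A = c(ga, decoy("xa", ceiling(n_decoy / 3))),
       B = c(gb, decoy("xb", ceiling(n_decoy / 3))),
       D = c(gd, decoy("xd", n_decoy - 2 * ceiling(n_decoy / 3))))
}
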