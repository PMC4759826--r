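#' Describe a simulated sequencing design
#'
#' Captures the experimental layout emulated by the read simulator: two
#' genotypes (a salt-tolerant and a salt-sensitive cultivar), paired
#' control/stress sampling at four timepoints, and the sequencing
#' parameters. The default design therefore has 2 x 2 x 4 = 16 libraries.
#'
#' @param genotypes Character vector of genotype labels.
#' @param timepoints_h Integer vector of sampling timepoints in hours.
#' @param conditions Character vector of conditions; must contain
#'   `"control"` and `"stress"`.
#' @param read_length Read length in bases (>= 20).
#' @param error_rate Per-base substitution error probability, in `[0, 0.1]`.
#' @param depth Expected number of reads per library (> 0).
#' @param depth_model `"fixed"` emits exactly `depth` reads per library;
#'   `"poisson"` draws the library size from Poisson(`depth`).
#' @param paired If `TRUE`, draw read pairs from both ends of a fragment.
#' @param fragment_length Fragment length for paired-end mode.
#'
#' @return A list of class `sim_design`.
#' @export
sim_design <- function(genotypes = c("tolerant", "sensitive"),
                       timepoints_h = c(6L, 12L, 24L, 48L),
                       conditions = c("control", "stress"),
                       read_length = 125L,
                       error_rate = 0.001,
                       depth = 20000L,
                       depth_model = c("fixed", "poisson"),
                       paired = FALSE,
                       fragment_length = 300L) {
  depth_model <- match.arg(depth_model)
  stopifnot(length(genotypes) >= 1, length(timepoints_h) >= 1)
  if (!all(c("control", "stress") %in% conditions))
    stop("conditions must include 'control' and 'stress'")
  if (read_length < 20) stop("read_length must be >= 20")
  if (error_rate < 0 || error_rate > 0.1)
    stop("error_rate must lie in [0, 0.1]")
  if (depth <= 0) stop("depth must be positive")
  structure(list(
    genotypes = genotypes, timepoints_h = as.integer(timepoints_h),
    conditions = conditions, read_length = as.integer(read_length),
    error_rate = error_rate, depth = depth, depth_model = depth_model,
    paired = paired, fragment_length = as.integer(fragment_length)
  ), class = "sim_design")
}

#' Sample sheet for a simulated design
#'
#' @param design A [sim_design()] object.
#' @return A data.frame with columns `library`, `genotype`, `condition`,
#'   `timepoint` (one row per library, in a fixed deterministic order).
#' @export
design_samples <- function(design) {
  grid <- expand.grid(
    timepoint = design$timepoints_h,
    condition = design$conditions,
    genotype = design$genotypes,
    stringsAsFactors = FALSE
  )
  grid <- grid[, c("genotype", "condition", "timepoint")]
  grid$library <- sprintf("%s_%s_%02dh", grid$genotype, grid$condition,
                          grid$timepoint)
  grid[, c("library", "genotype", "condition", "timepoint")]
}

# Per-homeolog mutation probability m such that the expected pairwise
# difference between two homeologs, each mutated independently from a
# common ancestor (substitution to a uniformly chosen different base),
# equals `divergence`: P(differ) = 2m(1-m) + (2/3)m^2.
.mutation_prob <- function(divergence) {
  (3 - sqrt(9 - 12 * divergence)) / 4
}

.BASES <- c("A", "C", "G", "T")

# substitute positions `idx` of character vector `x` (one base per element)
.substitute_bases <- function(x, idx) {
  if (length(idx) == 0) return(x)
  old <- x[idx]
  shift <- sample.int(3L, length(idx), replace = TRUE)
  x[idx] <- .BASES[(match(old, .BASES) - 1L + shift) %% 4L + 1L]
  x
}

#' Simulate homeologous triplets with known diagnostic SNPs
#'
#' Generates `n_triplets` ancestral coding sequences and derives one
#' homeolog per subgenome (A, B, D) by independent substitution, so the
#' three homeologs of a triplet share coordinates (no indels) and every
#' divergent alignment column is a known diagnostic SNP site. The
#' per-homeolog substitution rate is calibrated so that the expected
#' pairwise difference between homeologs equals `divergence`.
#'
#' @param n_triplets Number of triplets (>= 1).
#' @param gene_length Gene length in bases (>= 200).
#' @param divergence Expected per-base substitution fraction between any
#'   two homeologs of a triplet, in `(0, 0.10]`.
#' @param seed Integer seed; identical seeds give identical output.
#'
#' @return A list of class `triplet_sim` with elements:
#'   \describe{
#'     \item{sequences}{list of three named character vectors (`A`, `B`,
#'       `D`), names are triplet ids (`T000001`, ...).}
#'     \item{snps}{data.frame of true SNP columns: `triplet_id`, `pos`
#'       (1-based), `allele_A`, `allele_B`, `allele_D`.}
#'     \item{gene_length}{generation parameter.}
#'     \item{divergence}{generation parameter.}
#'   }
#' @export
simulate_triplets <- function(n_triplets, gene_length = 1000L,
                              divergence = 0.02, seed = 1L) {
  stopifnot(n_triplets >= 1, gene_length >= 200)
  if (divergence <= 0)
    stop("divergence must be > 0 (no diagnostic SNP sites are possible at 0)")
  if (divergence > 0.10) stop("divergence must be <= 0.10")
  set.seed(seed)
  m <- .mutation_prob(divergence)
  ids <- sprintf("T%06d", seq_len(n_triplets))
  seqs <- list(A = character(n_triplets), B = character(n_triplets),
               D = character(n_triplets))
  snp_list <- vector("list", n_triplets)
  for (i in seq_len(n_triplets)) {
    anc <- sample(.BASES, gene_length, replace = TRUE)
    hom <- lapply(c("A", "B", "D"), function(s) {
      idx <- which(runif(gene_length) < m)
      .substitute_bases(anc, idx)
    })
    names(hom) <- c("A", "B", "D")
    poly <- which(hom$A != hom$B | hom$B != hom$D)
    if (length(poly))
      snp_list[[i]] <- data.frame(
        triplet_id = ids[i], pos = poly,
        allele_A = hom$A[poly], allele_B = hom$B[poly],
        allele_D = hom$D[poly], stringsAsFactors = FALSE)
    for (s in c("A", "B", "D")) seqs[[s]][i] <- paste(hom[[s]], collapse = "")
  }
  for (s in c("A", "B", "D")) names(seqs[[s]]) <- ids
  structure(list(
    sequences = seqs,
    snps = if (length(snp_list)) do.call(rbind, snp_list) else
      data.frame(triplet_id = character(), pos = integer(),
                 allele_A = character(), allele_B = character(),
                 allele_D = character(), stringsAsFactors = FALSE),
    gene_length = as.integer(gene_length), divergence = divergence
  ), class = "triplet_sim")
}

#' Simulate homeolog expression truths over a stress time-course
#'
#' Fills a [simulate_triplets()] object with ground-truth expression:
#' per-triplet homeolog proportions drawn from a Dirichlet distribution
#' (or fixed), a baseline total abundance per triplet, and per-homeolog
#' stress fold-changes applied between control and stress libraries.
#' Non-responsive homeologs have fold exactly 1.
#'
#' @param sim A `triplet_sim` object.
#' @param design A [sim_design()].
#' @param bias_spec Either `list(alpha = c(aA, aB, aD))` for Dirichlet
#'   proportions or `list(pi = c(pA, pB, pD))` for fixed proportions.
#' @param de_spec List with `fraction` (probability that a homeolog is
#'   stress-responsive), `fold_range` (2-vector within `[1/16, 16]`;
#'   folds are drawn log-uniformly), and `p_down` (probability that a
#'   responsive homeolog's fold is inverted, i.e. down-regulated).
#' @param abundance_spec List with `meanlog` and `sdlog` of the
#'   lognormal baseline total abundance per triplet.
#' @param seed Integer seed.
#'
#' @return The input object with added elements `samples` (sample sheet),
#'   `proportions` (per-triplet `pi_A`, `pi_B`, `pi_D`), `response`
#'   (per triplet x homeolog: `responsive`, `fold`), `base_abundance`
#'   (per-triplet baseline), and `abundance` (long data.frame: `library`,
#'   `triplet_id`, `homeolog`, `abundance`).
#' @export
simulate_expression <- function(sim, design = sim_design(),
                                bias_spec = list(alpha = c(2, 2, 2)),
                                de_spec = list(fraction = 0.25,
                                               fold_range = c(2, 8),
                                               p_down = 0.4),
                                abundance_spec = list(meanlog = log(100),
                                                      sdlog = 1),
                                seed = 1L) {
  stopifnot(inherits(sim, "triplet_sim"))
  fr <- de_spec$fold_range
  if (is.null(fr)) fr <- c(2, 8)
  if (any(fr < 1 / 16) || any(fr > 16))
    stop("fold_range must lie within [1/16, 16]")
  frac <- de_spec$fraction
  if (is.null(frac)) frac <- 0.25
  if (frac < 0 || frac > 1) stop("de fraction must lie in [0, 1]")
  p_down <- if (is.null(de_spec$p_down)) 0.4 else de_spec$p_down
  set.seed(seed)
  ids <- names(sim$sequences$A)
  n <- length(ids)

  if (!is.null(bias_spec$pi)) {
    pi <- matrix(rep(bias_spec$pi / sum(bias_spec$pi), each = n), nrow = n)
  } else {
    alpha <- bias_spec$alpha
    g <- cbind(rgamma(n, alpha[1]), rgamma(n, alpha[2]), rgamma(n, alpha[3]))
    pi <- g / rowSums(g)
  }
  colnames(pi) <- c("pi_A", "pi_B", "pi_D")
  proportions <- data.frame(triplet_id = ids, pi, stringsAsFactors = FALSE)

  base <- rlnorm(n, meanlog = abundance_spec$meanlog,
                 sdlog = abundance_spec$sdlog)
  hom <- rep(c("A", "B", "D"), each = n)
  responsive <- runif(3 * n) < frac
  fold <- rep(1, 3 * n)
  k <- sum(responsive)
  if (k > 0) {
    f <- exp(runif(k, log(fr[1]), log(fr[2])))
    down <- runif(k) < p_down
    f[down] <- 1 / f[down]
    fold[responsive] <- f
  }
  response <- data.frame(
    triplet_id = rep(ids, 3), homeolog = hom,
    responsive = responsive, fold = fold, stringsAsFactors = FALSE)

  samples <- design_samples(design)
  ab_list <- vector("list", nrow(samples))
  ctl <- rep(base, 3) * as.vector(pi)   # triplet-major, homeolog blocks
  for (j in seq_len(nrow(samples))) {
    a <- ctl
    if (samples$condition[j] == "stress") a <- a * fold
    ab_list[[j]] <- data.frame(
      library = samples$library[j], triplet_id = rep(ids, 3),
      homeolog = hom, abundance = a, stringsAsFactors = FALSE)
  }
  sim$samples <- samples
  sim$proportions <- proportions
  sim$response <- response
  sim$base_abundance <- data.frame(triplet_id = ids, base = base,
                                   stringsAsFactors = FALSE)
  sim$abundance <- do.call(rbind, ab_list)
  sim$design <- design
  sim
}

#' True per-library homeolog proportions
#'
#' @param sim A `triplet_sim` with expression filled in.
#' @return data.frame `library`, `triplet_id`, `pi_A`, `pi_B`, `pi_D`
#'   (abundance-derived proportions; in stress libraries these reflect
#'   the applied fold-changes).
#' @export
true_proportions <- function(sim) {
  ab <- sim$abundance
  wide <- reshape_counts(ab, "abundance")
  tot <- wide$A + wide$B + wide$D
  data.frame(library = wide$library, triplet_id = wide$triplet_id,
             pi_A = wide$A / tot, pi_B = wide$B / tot, pi_D = wide$D / tot,
             stringsAsFactors = FALSE)
}

# long (library, triplet_id, homeolog, <value>) -> wide A/B/D columns
reshape_counts <- function(long, value) {
  dt <- data.table::as.data.table(long)
  wide <- data.table::dcast(dt, library + triplet_id ~ homeolog,
                            value.var = value, fill = 0)
  as.data.frame(wide)
}

#' Simulate short reads from expression truth
#'
#' Draws reads from homeologs with probability proportional to their true
#' abundance, uniform start positions, and uniform substitution errors.
#' Library sizes follow the design's depth model. Each library uses the
#' sub-seed `seed + library index` so adding a library never perturbs
#' earlier ones.
#'
#' @param sim A `triplet_sim` with expression filled
#'   ([simulate_expression()]).
#' @param design A [sim_design()]; defaults to the one stored in `sim`.
#' @param seed Integer seed.
#' @param libraries Optional character vector restricting which libraries
#'   to simulate (default: all in the sample sheet).
#'
#' @return List with `reads` (named list per library of named character
#'   vectors, names are read ids) and `origin` (data.frame: `read_id`,
#'   `library`, `triplet_id`, `homeolog`, `start` 0-based).
#' @export
simulate_reads <- function(sim, design = sim$design, seed = 1L,
                           libraries = NULL) {
  stopifnot(inherits(sim, "triplet_sim"), !is.null(sim$abundance))
  rl <- design$read_length
  L <- sim$gene_length
  if (rl > L) stop("read_length exceeds gene_length")
  samples <- sim$samples
  if (!is.null(libraries)) {
    stopifnot(all(libraries %in% samples$library))
  } else libraries <- samples$library
  seq_by <- sim$sequences
  reads_out <- list()
  origin_out <- list()
  for (lib in libraries) {
    j <- match(lib, samples$library)
    set.seed((seed + j) %% .Machine$integer.max)
    ab <- sim$abundance[sim$abundance$library == lib, ]
    n <- if (design$depth_model == "poisson") rpois(1, design$depth) else
      as.integer(design$depth)
    if (n == 0) {
      reads_out[[lib]] <- setNames(character(0), character(0))
      next
    }
    pick <- sample.int(nrow(ab), n, replace = TRUE, prob = ab$abundance)
    trip <- ab$triplet_id[pick]
    homeo <- ab$homeolog[pick]
    if (design$paired) {
      fl <- min(design$fragment_length, L)
      fstart <- floor(runif(n, 0, L - fl + 1))
      start <- c(fstart, fstart + fl - rl)  # mate1 fwd, mate2 position
      trip <- rep(trip, 2); homeo <- rep(homeo, 2)
      mate <- rep(1:2, each = n)
      n_reads <- 2L * n
    } else {
      start <- floor(runif(n, 0, L - rl + 1))
      mate <- rep(1L, n)
      n_reads <- n
    }
    src <- mapply(function(t, h) seq_by[[h]][[t]], trip, homeo,
                  USE.NAMES = FALSE)
    reads <- substring(src, start + 1, start + rl)
    if (design$paired) {
      i2 <- which(mate == 2L)
      reads[i2] <- .revcomp(reads[i2])
    }
    if (design$error_rate > 0) {
      nerr <- rbinom(n_reads, rl, design$error_rate)
      for (i in which(nerr > 0)) {
        ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
        idx <- sample.int(rl, nerr[i])
        reads[i] <- paste(.substitute_bases(ch, idx), collapse = "")
      }
    }
    ids <- if (design$paired)
      sprintf("%s:r%06d/%d", lib, rep(seq_len(n), 2), mate) else
      sprintf("%s:r%06d", lib, seq_len(n_reads))
    names(reads) <- ids
    reads_out[[lib]] <- reads
    origin_out[[lib]] <- data.frame(
      read_id = ids, library = lib, triplet_id = trip, homeolog = homeo,
      start = as.integer(start), stringsAsFactors = FALSE)
  }
  list(reads = reads_out,
       origin = if (length(origin_out)) do.call(rbind, origin_out) else
         data.frame(read_id = character(), library = character(),
                    triplet_id = character(), homeolog = character(),
                    start = integer(), stringsAsFactors = FALSE))
}

.revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""), ""))
}

# maximal runs of TRUE in a logical vector; data.frame(start0, end0) half-open
.runs <- function(flags, min_run = 3L) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  data.frame(start = starts[keep] - 1L, end = ends[keep],
             stringsAsFactors = FALSE)
}

#' Simulate chromosome gene layouts with planted responsive hotspots
#'
#' Builds ordered gene maps for synthetic chromosomes, plants runs of >= 3
#' consecutive stress-responsive genes of a shared family (tandem arrays),
#' and flags background genes responsive independently at
#' `background_responsive_rate`. Background draws that would create or
#' extend a run of >= 3 outside the planted intervals are re-rolled, so
#' the planted intervals are exactly the maximal responsive runs of
#' length >= 3.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param genes_per_chromosome Genes per chromosome.
#' @param hotspot_spec data.frame with columns `chrom` (1-based index),
#'   `start` (0-based gene index), `length` (>= 3) and `family`.
#' @param background_responsive_rate Per-gene background responsive
#'   probability in `[0, 1)`.
#' @param seed Integer seed.
#'
#' @return List with `layout` (data.frame: `chrom`, `index`, `gene_id`,
#'   `family`, `responsive`, `start`, `end`, `strand`) and `hotspots`
#'   (planted truth: `chrom`, `start`, `end` half-open gene indices,
#'   `family`).
#' @export
simulate_layout <- function(n_chromosomes = 3L, genes_per_chromosome = 200L,
                            hotspot_spec = NULL,
                            background_responsive_rate = 0.05, seed = 1L) {
  stopifnot(n_chromosomes >= 1, genes_per_chromosome >= 1)
  if (background_responsive_rate < 0 || background_responsive_rate >= 1)
    stop("background_responsive_rate must lie in [0, 1)")
  if (is.null(hotspot_spec))
    hotspot_spec <- data.frame(chrom = integer(), start = integer(),
                               length = integer(), family = character(),
                               stringsAsFactors = FALSE)
  if (nrow(hotspot_spec)) {
    if (any(hotspot_spec$length < 3))
      stop("planted hotspot runs must have length >= 3")
    if (any(hotspot_spec$chrom < 1 | hotspot_spec$chrom > n_chromosomes))
      stop("hotspot chromosome index out of range")
    if (any(hotspot_spec$start < 0 |
            hotspot_spec$start + hotspot_spec$length > genes_per_chromosome))
      stop("hotspot placement exceeds chromosome length")
    for (ch in unique(hotspot_spec$chrom)) {
      hs <- hotspot_spec[hotspot_spec$chrom == ch, ]
      hs <- hs[order(hs$start), ]
      if (nrow(hs) > 1 &&
          any(hs$start[-1] < (hs$start + hs$length)[-nrow(hs)] + 1))
        stop("planted hotspots overlap or touch on chromosome ", ch)
    }
  }
  set.seed(seed)
  layouts <- vector("list", n_chromosomes)
  truth <- vector("list", n_chromosomes)
  fam_counter <- 0L
  for (ch in seq_len(n_chromosomes)) {
    n <- genes_per_chromosome
    chrom <- sprintf("chr%d", ch)
    planted <- logical(n)
    family <- sprintf("FAM_%s_%04d", chrom, seq_len(n) + fam_counter)
    hs <- hotspot_spec[hotspot_spec$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(hs))) {
      idx <- hs$start[i] + seq_len(hs$length[i])  # 1-based indices
      planted[idx] <- TRUE
      family[idx] <- hs$family[i]
    }
    fam_counter <- fam_counter + n
    flags <- planted | (runif(n) < background_responsive_rate)
    planted_runs <- .runs(planted, 3L)
    tries <- 0L
    repeat {
      runs <- .runs(flags, 3L)
      if (identical(runs, planted_runs)) break
      tries <- tries + 1L
      if (tries > 1000L)
        stop("could not place background responsive genes without ",
             "creating accidental runs; lower background_responsive_rate")
      # re-roll background genes inside offending runs
      bad <- rep(FALSE, n)
      for (r in seq_len(nrow(runs))) {
        span <- (runs$start[r] + 1L):runs$end[r]
        if (!any(planted_runs$start == runs$start[r] &
                 planted_runs$end == runs$end[r]))
          bad[span] <- TRUE
      }
      redo <- which(bad & !planted)
      flags[redo] <- runif(length(redo)) < background_responsive_rate
    }
    layouts[[ch]] <- data.frame(
      chrom = chrom, index = seq_len(n) - 1L,
      gene_id = sprintf("G%s_%04d", chrom, seq_len(n)),
      family = family, responsive = flags,
      start = (seq_len(n) - 1L) * 1000L,
      end = (seq_len(n) - 1L) * 1000L + 600L,
      strand = "+", stringsAsFactors = FALSE)
    if (nrow(planted_runs))
      truth[[ch]] <- data.frame(chrom = chrom, start = planted_runs$start,
                                end = planted_runs$end,
                                family = hs$family[order(hs$start)],
                                stringsAsFactors = FALSE)
  }
  truth <- truth[!vapply(truth, is.null, TRUE)]
  list(layout = do.call(rbind, layouts),
       hotspots = if (length(truth)) do.call(rbind, truth) else
         data.frame(chrom = character(), start = integer(), end = integer(),
                    family = character(), stringsAsFactors = FALSE))
}
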