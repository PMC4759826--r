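#' @title Differential expression, homeolog bias and enrichment statistics
#' @description Unreplicated per-library contrasts are tested with
#'   Fisher's exact test on raw counts against library totals, corrected
#'   by Benjamini-Hochberg within each contrast; homeolog bias is tested
#'   by a chi-square goodness-of-fit against the balanced 1A:1B:1D
#'   expectation with an expression-ratio gate; term enrichment uses the
#'   one-sided hypergeometric (Fisher exact) test.
#' @name response_stats
NULL

#' Counts-per-million normalisation
#'
#' @param counts Numeric matrix (features x libraries) with non-negative
#'   entries; column names are library ids.
#' @param totals Optional library totals to normalise against (default:
#'   column sums). Use this to normalise a feature subset against full
#'   library sizes.
#' @return Matrix of CPM values, same shape as `counts`.
#' @export
cpm_normalize <- function(counts, totals = NULL) {
  counts <- as.matrix(counts)
  if (is.null(totals)) totals <- colSums(counts)
  if (any(totals <= 0)) stop("every library total must be positive")
  t(t(counts) / totals) * 1e6
}

#' Report a count as the percentage its denominator implies
#'
#' The package's single percentage-reporting path: all summary tables
#' print `round(100 * numerator / denominator, digits)`.
#'
#' @param numerator,denominator Non-negative numbers.
#' @param digits Decimal places (default 1, as printed in summaries).
#' @return Numeric percentage.
#' @export
fraction_pct <- function(numerator, denominator, digits = 1) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  round(100 * numerator / denominator, digits)
}

#' Fisher's exact test for an unreplicated two-library contrast
#'
#' Tests each feature's stress count against its control count given the
#' two library totals (two-sided Fisher exact probability of the 2x2
#' table), and reports the CPM fold change with a 0.5-CPM pseudocount.
#' Vectorised over features.
#'
#' @param count_stress,count_control Feature counts in the two libraries.
#' @param total_stress,total_control Library totals (scalars or vectors).
#' @param pseudo_cpm Pseudocount added to both CPM values (default 0.5).
#' @return data.frame with `p` and `fold` (stress over control).
#' @export
fisher_de <- function(count_stress, total_stress, count_control,
                      total_control, pseudo_cpm = 0.5) {
  n <- max(length(count_stress), length(count_control))
  cs <- rep_len(count_stress, n); cc <- rep_len(count_control, n)
  ts <- rep_len(total_stress, n); tc <- rep_len(total_control, n)
  if (any(cs > ts) || any(cc > tc)) stop("counts cannot exceed totals")
  if (any(ts <= 0) || any(tc <= 0)) stop("totals must be positive")
  p <- vapply(seq_len(n), function(i) {
    stats::fisher.test(matrix(c(cs[i], ts[i] - cs[i],
                                cc[i], tc[i] - cc[i]), 2, byrow = TRUE))$p.value
  }, 0)
  cpm_s <- cs / ts * 1e6
  cpm_c <- cc / tc * 1e6
  data.frame(p = pmin(p, 1), fold = (cpm_s + pseudo_cpm) / (cpm_c + pseudo_cpm))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of BH-adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differential expression from fold change and FDR
#'
#' `up` requires fold >= `fold_threshold` and q < `q_threshold`; `down`
#' requires fold <= 1/`fold_threshold` and q < `q_threshold`; anything
#' else is `none`. Both gates are exactly as stated, inclusive at the
#' fold boundary.
#'
#' @param fold Fold changes (> 0).
#' @param q BH-adjusted p-values.
#' @param fold_threshold Fold gate (default 2).
#' @param q_threshold FDR gate (default 0.01).
#' @return Character vector in `{"up", "down", "none"}`.
#' @export
call_de <- function(fold, q, fold_threshold = 2, q_threshold = 0.01) {
  stopifnot(all(fold > 0), all(q >= 0 & q <= 1))
  ifelse(q < q_threshold & fold >= fold_threshold, "up",
  ifelse(q < q_threshold & fold <= 1 / fold_threshold, "down", "none"))
}

#' Chi-square goodness-of-fit test of homeolog balance
#'
#' Tests observed homeolog counts against the balanced 1A:1B:1D
#' expectation (each expected count = total/3), with 2 degrees of
#' freedom. Allocated fractional counts are rounded to the nearest
#' integer first (rounding error is bounded by 1 per homeolog because
#' allocation conserves totals). Zero-total triplets are not testable
#' and return `NA`. Vectorised.
#'
#' @param c_A,c_B,c_D Homeolog counts (allocated counts accepted).
#' @param round_counts Round inputs to integers first (default `TRUE`).
#' @return data.frame with `statistic` and `p` (`NA` where total is 0).
#' @export
chisq_bias <- function(c_A, c_B, c_D, round_counts = TRUE) {
  n <- max(length(c_A), length(c_B), length(c_D))
  o <- cbind(rep_len(c_A, n), rep_len(c_B, n), rep_len(c_D, n))
  if (any(o < 0)) stop("counts must be non-negative")
  if (round_counts) o <- round(o)
  total <- rowSums(o)
  e <- total / 3
  stat <- ifelse(total > 0, rowSums((o - e)^2) / e, NA_real_)
  data.frame(statistic = stat,
             p = ifelse(is.na(stat), NA_real_,
                        stats::pchisq(stat, df = 2, lower.tail = FALSE)))
}

#' Flag biased homeolog expression
#'
#' A triplet is biased when the goodness-of-fit p-value is below
#' `p_threshold` and the maximum homeolog expression is at least
#' `ratio_threshold` times the minimum (Expmax/Expmin gate). A zero
#' minimum with a positive maximum counts as an infinite ratio and
#' satisfies the gate.
#'
#' @param p Chi-square p-values ([chisq_bias()]).
#' @param e_A,e_B,e_D Homeolog expression values (>= 0).
#' @param p_threshold Significance gate (default 0.01).
#' @param ratio_threshold Expression-ratio gate (default 1.5).
#' @return data.frame with `ratio` and logical `biased` (`NA` where `p`
#'   is `NA` or all expressions are zero).
#' @export
call_bias <- function(p, e_A, e_B, e_D, p_threshold = 0.01,
                      ratio_threshold = 1.5) {
  n <- max(length(p), length(e_A))
  e <- cbind(rep_len(e_A, n), rep_len(e_B, n), rep_len(e_D, n))
  if (any(e < 0)) stop("expressions must be non-negative")
  p <- rep_len(p, n)
  mx <- apply(e, 1, max); mn <- apply(e, 1, min)
  ratio <- ifelse(mx == 0, NA_real_, ifelse(mn == 0, Inf, mx / mn))
  data.frame(ratio = ratio,
             biased = ifelse(is.na(p) | is.na(ratio), NA,
                             p < p_threshold & ratio >= ratio_threshold))
}

#' Per-contrast differential expression over a stress time-course
#'
#' For every (genotype, timepoint) the stress library is contrasted
#' against the same genotype and timepoint's control library with
#' [fisher_de()]. Only expressed features (raw count >= 1 in at least
#' one library) are tested; BH adjustment is applied within each
#' contrast over its expressed features.
#'
#' @param counts Integer matrix (features x libraries).
#' @param samples Sample sheet data.frame: `library`, `genotype`,
#'   `condition`, `timepoint` ([design_samples()] layout).
#' @param fold_threshold,q_threshold Call gates ([call_de()]).
#' @param totals Optional named library totals (default: column sums of
#'   `counts`).
#' @return data.frame: `feature`, `genotype`, `timepoint`, `fold`, `p`,
#'   `q`, `call`.
#' @export
run_de <- function(counts, samples, fold_threshold = 2, q_threshold = 0.01,
                   totals = NULL) {
  counts <- as.matrix(counts)
  stopifnot(all(samples$library %in% colnames(counts)))
  if (is.null(totals)) totals <- colSums(counts)
  expressed <- rownames(counts)[rowSums(counts >= 1) > 0]
  grid <- unique(samples[samples$condition == "stress",
                         c("genotype", "timepoint")])
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid$genotype[i]; tp <- grid$timepoint[i]
    lib_s <- samples$library[samples$genotype == g &
                             samples$timepoint == tp &
                             samples$condition == "stress"]
    lib_c <- samples$library[samples$genotype == g &
                             samples$timepoint == tp &
                             samples$condition == "control"]
    if (length(lib_s) != 1 || length(lib_c) != 1)
      stop("expected exactly one stress and one control library for ",
           g, " at ", tp, " h")
    ft <- fisher_de(counts[expressed, lib_s], totals[[lib_s]],
                    counts[expressed, lib_c], totals[[lib_c]])
    q <- bh_adjust(ft$p)
    out[[i]] <- data.frame(
      feature = expressed, genotype = g, timepoint = tp,
      fold = ft$fold, p = ft$p, q = q,
      call = call_de(ft$fold, q, fold_threshold, q_threshold),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarise homeolog response partitioning
#'
#' Collapses per-homeolog differential-expression calls into per-triplet
#' flags: `responsive` (at least one homeolog called up or down in at
#' least one stress condition) and `unequal` (responsive, and in at
#' least one condition the three homeolog calls are not all identical —
#' an unequal contribution of the homeologs to the stress response).
#' Triplets missing any homeolog call in a condition are excluded with a
#' warning.
#'
#' @param calls data.frame: `triplet_id`, `homeolog` (`A`/`B`/`D`),
#'   `genotype`, `timepoint`, `call` (`up`/`down`/`none`).
#' @return List: `triplets` (per triplet x genotype: `responsive`,
#'   `unequal`), `per_homeolog` (per genotype x timepoint x homeolog:
#'   `n_up`, `n_down`), `totals` (per genotype: `n_triplets`,
#'   `n_responsive`, `pct_responsive`, `n_unequal`, `pct_unequal`).
#' @export
summarize_partitioning <- function(calls) {
  req <- c("triplet_id", "homeolog", "genotype", "timepoint", "call")
  stopifnot(all(req %in% names(calls)))
  key <- interaction(calls$triplet_id, calls$genotype, calls$timepoint,
                     drop = TRUE)
  n_hom <- tapply(calls$homeolog, key, function(h)
    length(unique(intersect(h, c("A", "B", "D")))))
  bad <- names(n_hom)[n_hom < 3]
  if (length(bad)) {
    bad_trip <- unique(sub("\\..*$", "", bad))
    warning(length(bad_trip), " triplet(s) excluded: missing homeolog ",
            "calls", call. = FALSE)
    calls <- calls[!calls$triplet_id %in% bad_trip, , drop = FALSE]
  }
  dt <- data.table::as.data.table(calls)
  cond <- dt[, .(any_de = any(call != "none"),
                 identical_calls = length(unique(call)) == 1L),
             by = .(triplet_id, genotype, timepoint)]
  trip <- cond[, .(responsive = any(any_de),
                   unequal = any(any_de) & any(any_de & !identical_calls)),
               by = .(triplet_id, genotype)]
  per_hom <- dt[, .(n_up = sum(call == "up"), n_down = sum(call == "down")),
                by = .(genotype, timepoint, homeolog)]
  totals <- trip[, .(n_triplets = .N, n_responsive = sum(responsive),
                     n_unequal = sum(unequal)), by = genotype]
  totals[, `:=`(pct_responsive = fraction_pct(n_responsive, n_triplets),
                pct_unequal = fraction_pct(n_unequal, n_triplets))]
  list(triplets = as.data.frame(trip),
       per_homeolog = as.data.frame(
         per_hom[order(genotype, timepoint, homeolog)]),
       totals = as.data.frame(totals))
}

#' Summarise homeolog bias calls per library
#'
#' @param bias data.frame with `library` and logical `biased` columns
#'   (one row per tested triplet; `NA` rows are not testable and are
#'   excluded from the denominator).
#' @return data.frame per library: `n_tested`, `n_biased`, `pct_biased`
#'   (via the package's percentage-reporting path, [fraction_pct()]).
#' @export
summarize_bias <- function(bias) {
  stopifnot(all(c("library", "biased") %in% names(bias)))
  dt <- data.table::as.data.table(bias)
  res <- dt[!is.na(biased),
            .(n_tested = .N, n_biased = sum(biased)), by = library]
  res[, pct_biased := fraction_pct(n_biased, n_tested)]
  as.data.frame(res)
}

#' Fisher-exact term enrichment
#'
#' One-sided hypergeometric enrichment of each term's genes in the study
#' set relative to the population. Terms with `p <= p_threshold` are
#' flagged significant. No multiple-testing correction is applied (raw
#' p-values are reported, with the threshold applied to them).
#'
#' @param study Character vector of study gene ids (must be a subset of
#'   `population`).
#' @param population Character vector of population gene ids.
#' @param term_map data.frame with columns `gene` and `term`.
#' @param p_threshold Significance flag threshold (default 0.01).
#' @return data.frame per term: `term`, `study_hits`, `study_size`,
#'   `pop_hits`, `pop_size`, `p`, `significant`.
#' @export
enrich_terms <- function(study, population, term_map, p_threshold = 0.01) {
  population <- unique(population)
  study <- unique(study)
  if (length(population) == 0) stop("population must be non-empty")
  if (!all(study %in% population))
    stop("study set must be a subset of the population")
  tm <- term_map[term_map$gene %in% population, , drop = FALSE]
  terms <- unique(tm$term)
  n <- length(study); N <- length(population)
  res <- lapply(terms, function(tt) {
    genes <- unique(tm$gene[tm$term == tt])
    K <- length(genes)
    k <- sum(study %in% genes)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tt, study_hits = k, study_size = n, pop_hits = K,
               pop_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out$significant <- out$p <= p_threshold
  out
}
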