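#' @title Sliding-window scan and hotspot detection
#' @description Ordered chromosome gene maps are scanned with a fixed
#'   window and step to profile the local density of stress-responsive
#'   genes; hotspots are maximal runs of at least `min_run` consecutive
#'   responsive genes, annotated for tandem duplication when at least two
#'   members share a gene family.
#' @name hotspot_scan
NULL

.check_layout <- function(layout) {
  stopifnot(all(c("chrom", "gene_id", "responsive") %in% names(layout)))
  layout
}

#' Sliding-window responsive-gene percentages
#'
#' Windows of `window` genes advance by `step` genes along each
#' chromosome's gene order; a trailing window shorter than `window` is
#' dropped so percentages stay comparable. Genes flagged unexpressed
#' (optional `expressed` column) are removed from the map first by
#' default, so "consecutive" means adjacent among expressed genes.
#'
#' @param layout data.frame with `chrom`, `gene_id`, `responsive`
#'   (logical), optional `expressed` (logical), ordered by map position
#'   within each chromosome.
#' @param window Window size in genes (default 10).
#' @param step Window shift in genes (default 5).
#' @param drop_unexpressed Remove genes with `expressed == FALSE` before
#'   scanning (default `TRUE`; ignored without an `expressed` column).
#' @return data.frame: `chrom`, `start` (0-based gene index of the
#'   window), `window`, `pct_responsive`.
#' @export
window_scan <- function(layout, window = 10L, step = 5L,
                        drop_unexpressed = TRUE) {
  stopifnot(window >= 1, step >= 1)
  layout <- .check_layout(layout)
  if (drop_unexpressed && "expressed" %in% names(layout))
    layout <- layout[layout$expressed, , drop = FALSE]
  if (nrow(layout) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      window = integer(), pct_responsive = numeric(),
                      stringsAsFactors = FALSE))
  out <- lapply(split(layout$responsive, layout$chrom), function(flags) {
    n <- length(flags)
    if (n < window) return(NULL)
    starts <- seq(0L, n - window, by = step)
    data.frame(start = starts, window = as.integer(window),
               pct_responsive = vapply(starts, function(s)
                 100 * sum(flags[(s + 1):(s + window)]) / window, 0))
  })
  chroms <- names(out)[!vapply(out, is.null, TRUE)]
  out <- out[chroms]
  res <- do.call(rbind, Map(function(ch, df) cbind(chrom = ch, df),
                            chroms, out))
  rownames(res) <- NULL
  res
}

#' Find hotspots of consecutive responsive genes
#'
#' Returns the maximal runs of consecutive responsive genes of length at
#' least `min_run` on each chromosome (runs never span chromosomes).
#' Flanking genes of every returned run are non-responsive or chromosome
#' ends.
#'
#' @inheritParams window_scan
#' @param min_run Minimum run length (default 3).
#' @return data.frame: `chrom`, `start`, `end` (0-based half-open gene
#'   indices in the scanned order), `n_genes`, `genes` (comma-separated
#'   member ids).
#' @export
find_hotspots <- function(layout, min_run = 3L, drop_unexpressed = TRUE) {
  stopifnot(min_run >= 1)
  layout <- .check_layout(layout)
  if (drop_unexpressed && "expressed" %in% names(layout))
    layout <- layout[layout$expressed, , drop = FALSE]
  out <- lapply(split(layout, layout$chrom), function(df) {
    runs <- .runs(df$responsive, min_run)
    if (nrow(runs) == 0) return(NULL)
    runs$n_genes <- runs$end - runs$start
    runs$genes <- vapply(seq_len(nrow(runs)), function(i)
      paste(df$gene_id[(runs$start[i] + 1):runs$end[i]], collapse = ","),
      "")
    runs
  })
  chroms <- names(out)[!vapply(out, is.null, TRUE)]
  if (length(chroms) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_genes = integer(),
                      genes = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, Map(function(ch, df) cbind(chrom = ch, df),
                            chroms, out[chroms]))
  rownames(res) <- NULL
  res
}

# single-linkage clusters of sequences at >= min identity
.family_clusters <- function(seqs, min_identity = 0.60) {
  n <- length(seqs)
  labels <- names(seqs)
  edges_from <- character(0); edges_to <- character(0)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      sp <- score_pairwise(seqs[[i]], seqs[[j]])
      if (sp$identity >= min_identity) {
        edges_from <- c(edges_from, labels[i])
        edges_to <- c(edges_to, labels[j])
      }
    }
  }
  comp <- .components(labels, edges_from, edges_to)
  fam <- stats::setNames(rep(NA_character_, n), labels)
  for (ci in seq_along(comp))
    fam[comp[[ci]]] <- sprintf("CLUST%03d", ci)
  fam
}

#' Annotate hotspots for tandem duplication
#'
#' A hotspot is a tandem array when at least two of its member genes
#' belong to the same family. Families come from a `gene_id`-to-family
#' table when provided; otherwise member sequences are clustered by
#' single linkage at >= `min_identity` identity. With neither source the
#' tandem flag is `NA` and a warning is raised.
#'
#' @param hotspots Output of [find_hotspots()].
#' @param families Optional data.frame `gene_id`, `family`.
#' @param sequences Optional named character vector of member gene
#'   sequences.
#' @param min_identity Identity threshold for sequence-based family
#'   clustering (default 0.60).
#' @return `hotspots` with added columns `tandem` (logical) and
#'   `dominant_family` (most frequent repeated family, `NA` if none).
#' @export
annotate_tandem <- function(hotspots, families = NULL, sequences = NULL,
                            min_identity = 0.60) {
  if (nrow(hotspots) == 0) {
    hotspots$tandem <- logical(0)
    hotspots$dominant_family <- character(0)
    return(hotspots)
  }
  if (is.null(families) && is.null(sequences)) {
    warning("neither family labels nor sequences supplied; tandem flag ",
            "undetermined", call. = FALSE)
    hotspots$tandem <- NA
    hotspots$dominant_family <- NA_character_
    return(hotspots)
  }
  fam_of <- if (!is.null(families))
    stats::setNames(families$family, families$gene_id) else NULL
  res <- lapply(seq_len(nrow(hotspots)), function(i) {
    members <- strsplit(hotspots$genes[i], ",", fixed = TRUE)[[1]]
    fams <- if (!is.null(fam_of)) unname(fam_of[members]) else {
      miss <- setdiff(members, names(sequences))
      if (length(miss))
        stop("sequences missing for hotspot members: ",
             paste(head(miss, 3), collapse = ", "))
      unname(.family_clusters(sequences[members], min_identity)[members])
    }
    tab <- table(fams[!is.na(fams)])
    rep_fams <- tab[tab >= 2]
    data.frame(
      tandem = length(rep_fams) > 0,
      dominant_family = if (length(rep_fams))
        names(rep_fams)[which.max(rep_fams)] else NA_character_,
      stringsAsFactors = FALSE)
  })
  cbind(hotspots, do.call(rbind, res))
}
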