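#' @title Homeologous triplet identification
#' @description Functions to score candidate homeolog pairs, cluster them
#'   into triplets (exactly one gene per subgenome) under identity and
#'   coverage gates, and extract subgenome-diagnostic SNP sites.
#' @name triplet_finder
NULL

.IUPAC <- "ACGTRYSWKMBDHVN"

.check_dna <- function(x, what = "sequence") {
  x <- toupper(as.character(x))
  if (any(!nzchar(x))) stop(what, " must be non-empty")
  bad <- grepl(sprintf("[^%s]", .IUPAC), x)
  if (any(bad))
    stop(what, " contains non-IUPAC characters: ",
         paste(head(names(x)[bad], 3), collapse = ", "))
  x
}

# global alignment scoring used throughout: match +1, mismatch -1,
# gap open -5, gap extend -2
.align_pair <- function(pattern, subject) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  Biostrings::pairwiseAlignment(pattern, subject, type = "global",
                                substitutionMatrix = mat,
                                gapOpening = 5, gapExtension = 2)
}

#' Score a pair of genes for homeology
#'
#' Globally aligns two sequences and reports identity and coverage.
#' Identity is matches over aligned (non-gap) columns; coverage is
#' aligned columns over the length of the shorter sequence.
#'
#' @param a,b DNA sequences (character scalars or `DNAString`s).
#' @return A list with `identity`, `coverage` and `score` (alignment
#'   score under match +1 / mismatch -1 / gap open 5 / gap extend 2).
#' @export
score_pairwise <- function(a, b) {
  a <- .check_dna(as.character(a)); b <- .check_dna(as.character(b))
  aln <- .align_pair(a, b)
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  cols <- nm + nmm
  list(identity = if (cols > 0) nm / cols else 0,
       coverage = cols / min(nchar(a), nchar(b)),
       score = Biostrings::score(aln))
}

# unique k-mers of each sequence -> data.table(gene, kmer)
.kmer_table <- function(seqs, k) {
  res <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    n <- nchar(s) - k + 1L
    if (n < 1) return(NULL)
    data.table::data.table(gene = id,
                           kmer = unique(substring(s, 1:n, k:(n + k - 1L))))
  })
  data.table::rbindlist(res)
}

# candidate cross-set pairs sharing at least one k-mer
.candidate_pairs <- function(seqs_x, seqs_y, k = 16L) {
  tx <- .kmer_table(seqs_x, k); ty <- .kmer_table(seqs_y, k)
  if (nrow(tx) == 0 || nrow(ty) == 0)
    return(data.frame(x = character(), y = character()))
  m <- merge(tx, ty, by = "kmer", allow.cartesian = TRUE)
  unique(as.data.frame(m[, c("gene.x", "gene.y")])) |>
    stats::setNames(c("x", "y"))
}

# align candidate pairs, return passing hits
.passing_hits <- function(seqs_x, seqs_y, pairs, min_identity, min_coverage) {
  if (nrow(pairs) == 0)
    return(data.frame(x = character(), y = character(),
                      identity = numeric(), coverage = numeric()))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  out <- vector("list", length(unique(pairs$y)))
  i <- 0L
  for (y in unique(pairs$y)) {
    xs <- pairs$x[pairs$y == y]
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(unlist(seqs_x[xs], use.names = FALSE)),
      seqs_y[[y]], type = "global", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2)
    nm <- Biostrings::nmatch(aln); nmm <- Biostrings::nmismatch(aln)
    cols <- nm + nmm
    ident <- ifelse(cols > 0, nm / cols, 0)
    cov <- cols / pmin(nchar(seqs_x[xs]), nchar(seqs_y[[y]]))
    keep <- ident >= min_identity & cov >= min_coverage
    i <- i + 1L
    out[[i]] <- data.frame(x = xs[keep], y = rep(y, sum(keep)),
                           identity = ident[keep], coverage = cov[keep],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

.homeo_group <- function(chrom) {
  g <- sub("^[^0-9]*([0-9]+).*$", "\\1", chrom)
  g[!grepl("[0-9]", chrom)] <- NA_character_
  g
}

# union-find over gene labels
.components <- function(nodes, edges_from, edges_to) {
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(edges_from)) {
    ri <- find(match(edges_from[e], nodes))
    rj <- find(match(edges_to[e], nodes))
    if (ri != rj) parent[rj] <- ri
  }
  roots <- vapply(seq_along(nodes), find, 0L)
  split(nodes, roots)
}

.as_named_seqs <- function(x, what) {
  if (inherits(x, "DNAStringSet")) x <- as.character(x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop(what, " sequences must be named by gene id")
  if (anyDuplicated(names(x)))
    stop("duplicate gene ids within ", what)
  stats::setNames(.check_dna(x, what), names(x))
}

#' Identify homeologous triplets from three subgenome gene sets
#'
#' Scores cross-subgenome gene pairs (k-mer prescreen followed by global
#' alignment), keeps hits meeting the identity and coverage gates,
#' single-linkage clusters genes over passing hits, and retains only
#' clusters with exactly one gene per subgenome whose three pairwise hits
#' all pass. When gene positions with parseable chromosome names are
#' supplied (e.g. `2A`/`2B`/`2D`), pairs from different homeologous
#' groups are discarded before clustering; without positions the check is
#' skipped with a warning.
#'
#' @param genes_A,genes_B,genes_D Named character vectors or
#'   `DNAStringSet`s of gene sequences, one per subgenome.
#' @param positions Optional data.frame (`gene_id`, `chrom`) used for the
#'   homeologous-group consistency check.
#' @param min_identity Minimum identity fraction (default 0.90).
#' @param min_coverage Minimum coverage fraction (default 0.75).
#' @param prescreen_k Word size for the shared k-mer prescreen; pairs
#'   sharing no `prescreen_k`-mer are never aligned.
#'
#' @return data.frame with one row per triplet: `triplet_id`, `gene_A`,
#'   `gene_B`, `gene_D`, pairwise `identity_AB/AD/BD` and
#'   `coverage_AB/AD/BD`.
#' @export
build_triplets <- function(genes_A, genes_B, genes_D, positions = NULL,
                           min_identity = 0.90, min_coverage = 0.75,
                           prescreen_k = 16L) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1)
  sets <- list(A = .as_named_seqs(genes_A, "subgenome A"),
               B = .as_named_seqs(genes_B, "subgenome B"),
               D = .as_named_seqs(genes_D, "subgenome D"))
  if (length(sets$A) == 0 || length(sets$B) == 0 || length(sets$D) == 0)
    stop("gene lists must be non-empty")
  all_ids <- unlist(lapply(sets, names), use.names = FALSE)
  if (anyDuplicated(all_ids)) stop("gene ids must be unique across subgenomes")
  subg_of <- stats::setNames(rep(c("A", "B", "D"), vapply(sets, length, 0L)),
                             all_ids)
  grp <- NULL
  if (!is.null(positions)) {
    grp <- stats::setNames(.homeo_group(positions$chrom), positions$gene_id)
  } else {
    warning("no gene positions supplied; homeologous-group consistency ",
            "check skipped", call. = FALSE)
  }
  hit_list <- list()
  for (pr in list(c("A", "B"), c("A", "D"), c("B", "D"))) {
    cand <- .candidate_pairs(sets[[pr[1]]], sets[[pr[2]]], prescreen_k)
    if (!is.null(grp) && nrow(cand)) {
      gx <- grp[cand$x]; gy <- grp[cand$y]
      cand <- cand[is.na(gx) | is.na(gy) | gx == gy, , drop = FALSE]
    }
    h <- .passing_hits(sets[[pr[1]]], sets[[pr[2]]], cand,
                       min_identity, min_coverage)
    if (!is.null(h) && nrow(h)) {
      h$pair <- paste0(pr[1], pr[2])
      hit_list[[length(hit_list) + 1L]] <- h
    }
  }
  empty <- data.frame(
    triplet_id = character(), gene_A = character(), gene_B = character(),
    gene_D = character(), identity_AB = numeric(), identity_AD = numeric(),
    identity_BD = numeric(), coverage_AB = numeric(),
    coverage_AD = numeric(), coverage_BD = numeric(),
    stringsAsFactors = FALSE)
  if (length(hit_list) == 0) return(empty)
  hits <- do.call(rbind, hit_list)
  comp <- .components(all_ids, hits$x, hits$y)
  comp <- comp[vapply(comp, length, 0L) == 3L]
  rows <- list()
  for (members in comp) {
    sg <- subg_of[members]
    if (!setequal(sg, c("A", "B", "D"))) next
    gm <- stats::setNames(members, sg)
    h <- function(p) {
      i <- which(hits$pair == p &
                 hits$x == gm[substr(p, 1, 1)] &
                 hits$y == gm[substr(p, 2, 2)])
      if (length(i)) hits[i[1], c("identity", "coverage")] else NULL
    }
    ab <- h("AB"); ad <- h("AD"); bd <- h("BD")
    if (is.null(ab) || is.null(ad) || is.null(bd)) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene_A = gm[["A"]], gene_B = gm[["B"]], gene_D = gm[["D"]],
      identity_AB = ab$identity, identity_AD = ad$identity,
      identity_BD = bd$identity, coverage_AB = ab$coverage,
      coverage_AD = ad$coverage, coverage_BD = bd$coverage,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_A), , drop = FALSE]
  rownames(out) <- NULL
  cbind(data.frame(triplet_id = sprintf("TRP%05d", seq_len(nrow(out))),
                   stringsAsFactors = FALSE), out)
}

# project b onto a's coordinates via global alignment; returns character
# vector of length nchar(a) with "-" where b is gapped
.project_onto <- function(a, b) {
  aln <- .align_pair(a, b)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sb[pa != "-"]
}

#' Call diagnostic SNP sites of a triplet
#'
#' Reports every alignment column where the three homeolog alleles are not
#' all identical, with its discrimination class: `A|BD` (A differs from
#' the shared B=D allele), `B|AD`, `D|AB`, or `all-distinct`. Columns
#' containing ambiguity codes or alignment gaps are skipped. Equal-length
#' sequences are compared column-wise directly; otherwise B and D are
#' projected onto A's coordinates by global alignment.
#'
#' @param a,b,d Homeolog sequences for subgenomes A, B and D.
#' @return data.frame: `pos` (1-based column in A's coordinates),
#'   `allele_A`, `allele_B`, `allele_D`, `class`.
#' @export
call_diagnostic_sites <- function(a, b, d) {
  a <- .check_dna(as.character(a)); b <- .check_dna(as.character(b))
  d <- .check_dna(as.character(d))
  ca <- strsplit(a, "")[[1]]
  cb <- if (nchar(b) == nchar(a)) strsplit(b, "")[[1]] else .project_onto(a, b)
  cd <- if (nchar(d) == nchar(a)) strsplit(d, "")[[1]] else .project_onto(a, d)
  ok <- ca %in% .BASES & cb %in% .BASES & cd %in% .BASES
  div <- ok & !(ca == cb & cb == cd)
  pos <- which(div)
  if (length(pos) == 0)
    return(data.frame(pos = integer(), allele_A = character(),
                      allele_B = character(), allele_D = character(),
                      class = character(), stringsAsFactors = FALSE))
  A <- ca[pos]; B <- cb[pos]; D <- cd[pos]
  cls <- ifelse(B == D, "A|BD",
         ifelse(A == D, "B|AD",
         ifelse(A == B, "D|AB", "all-distinct")))
  data.frame(pos = pos, allele_A = A, allele_B = B, allele_D = D,
             class = cls, stringsAsFactors = FALSE)
}
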