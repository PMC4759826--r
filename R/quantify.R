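#' @title SNP-based homeolog read quantification
#' @description Reads are matched to their triplet by exact k-mer seeding
#'   and classified into homeolog compatibility classes by end-to-end
#'   mismatch counting: homeologs within the two-mismatch mapping gate
#'   are candidates, and the class is the set of candidates at the
#'   minimum mismatch count (the homeologs the read's diagnostic-site
#'   alleles support). Shared classes are then allocated proportionally
#'   to the subgenome-specific read counts.
#' @name homeolog_quant
NULL

.CLASSES <- c("A", "B", "D", "AB", "AD", "BD", "ABD")

# mismatch count between two equal-length strings
.mm_count <- function(a, b) sum(charToRaw(a) != charToRaw(b))

#' Classify a read against the three homeologs of a triplet
#'
#' Computes, for every end-to-end placement of the read on the shared
#' homeolog coordinates, the mismatch count against each homeolog. At the
#' best common placement (the offset minimising the smallest per-homeolog
#' mismatch count), homeologs within the `max_mismatches` mapping gate
#' are candidates, and the compatible set is the candidates achieving
#' the minimum mismatch count — the homeologs whose alleles at the
#' diagnostic SNP sites covered by the read match it best. The read's
#' class is the label of that set (`A`, `B`, `D`, `AB`, `AD`, `BD`,
#' `ABD`) or `UNASSIGNED` when no homeolog passes the gate. With
#' `offsets` supplied only those placements are examined (used by the
#' seeded quantifier); otherwise all placements are.
#'
#' @param read Read sequence (character scalar).
#' @param homeologs Named character vector of the three homeolog
#'   sequences (`A`, `B`, `D`), equal length.
#' @param max_mismatches Mismatch gate per homeolog (default 2).
#' @param offsets Optional integer vector of 0-based candidate offsets.
#' @return List: `class`, `mismatches` (named A/B/D at the chosen
#'   placement), `offset` (0-based).
#' @export
assign_read <- function(read, homeologs, max_mismatches = 2L,
                        offsets = NULL) {
  read <- toupper(as.character(read))
  stopifnot(length(homeologs) == 3L,
            all(c("A", "B", "D") %in% names(homeologs)))
  homeologs <- toupper(as.character(homeologs[c("A", "B", "D")]))
  names(homeologs) <- c("A", "B", "D")
  L <- unique(nchar(homeologs))
  if (length(L) != 1L)
    stop("homeolog sequences must be equal length (substitution-only mode)")
  rl <- nchar(read)
  if (rl > L) stop("read is longer than the homeolog sequences")
  if (is.null(offsets)) offsets <- 0:(L - rl)
  offsets <- offsets[offsets >= 0 & offsets <= L - rl]
  mm <- vapply(offsets, function(o) {
    vapply(homeologs, function(s)
      .mm_count(read, substr(s, o + 1L, o + rl)), 0L)
  }, integer(3))
  mm <- matrix(mm, nrow = 3L,
               dimnames = list(c("A", "B", "D"), NULL))
  best_o <- which.min(apply(mm, 2, min))
  v <- mm[, best_o]
  compat <- names(v)[v <= max_mismatches & v == min(v)]
  list(class = if (length(compat)) paste(compat, collapse = "") else
         "UNASSIGNED",
       mismatches = v, offset = offsets[best_o])
}

#' Allocate shared read counts proportionally to specific counts
#'
#' Subgenome-specific counts are kept; each shared class (`AB`, `AD`,
#' `BD`, `ABD`) is divided among its member homeologs in proportion to
#' those members' specific counts, falling back to an equal split when
#' the relevant specific counts are all zero. Totals are conserved
#' exactly. All arguments are vectorised.
#'
#' @param n_A,n_B,n_D Subgenome-specific read counts.
#' @param n_AB,n_AD,n_BD,n_ABD Shared read counts.
#' @return data.frame with allocated fractional counts `c_A`, `c_B`,
#'   `c_D`.
#' @export
allocate_counts <- function(n_A, n_B, n_D, n_AB = 0, n_AD = 0, n_BD = 0,
                            n_ABD = 0) {
  args <- list(n_A, n_B, n_D, n_AB, n_AD, n_BD, n_ABD)
  n <- max(lengths(args))
  args <- lapply(args, rep_len, n)
  names(args) <- c("n_A", "n_B", "n_D", "n_AB", "n_AD", "n_BD", "n_ABD")
  if (any(unlist(args) < 0)) stop("counts must be non-negative")
  with(args, {
    share2 <- function(shared, x, y) {
      s <- x + y
      w <- ifelse(s > 0, x / s, 0.5)
      shared * w
    }
    tot3 <- n_A + n_B + n_D
    w3 <- function(x) ifelse(tot3 > 0, x / tot3, 1 / 3)
    data.frame(
      c_A = n_A + share2(n_AB, n_A, n_B) + share2(n_AD, n_A, n_D) +
        n_ABD * w3(n_A),
      c_B = n_B + share2(n_AB, n_B, n_A) + share2(n_BD, n_B, n_D) +
        n_ABD * w3(n_B),
      c_D = n_D + share2(n_AD, n_D, n_A) + share2(n_BD, n_D, n_B) +
        n_ABD * w3(n_D))
  })
}

# k-mer index over all homeolog sequences:
# data.table(kmer, t_idx, h, pos) with pos 1-based
.build_kmer_index <- function(seqs, k) {
  ids <- names(seqs$A)
  res <- vector("list", 3L * length(ids))
  i <- 0L
  for (h in c("A", "B", "D")) {
    s <- seqs[[h]]
    for (tix in seq_along(ids)) {
      n <- nchar(s[[tix]]) - k + 1L
      if (n < 1L) next
      i <- i + 1L
      res[[i]] <- data.table::data.table(
        kmer = substring(s[[tix]], 1:n, k:(n + k - 1L)),
        t_idx = tix, h = h, pos = 1:n)
    }
  }
  idx <- data.table::rbindlist(res)
  unique(idx[, c("kmer", "t_idx", "pos")])
}

.normalize_seq_set <- function(sequences) {
  seqs <- lapply(sequences[c("A", "B", "D")], function(s) {
    if (inherits(s, "DNAStringSet")) s <- as.character(s)
    toupper(s)
  })
  ids <- names(seqs$A)
  stopifnot(!is.null(ids), identical(ids, names(seqs$B)),
            identical(ids, names(seqs$D)))
  seqs
}

# classify one library's reads; returns list(assign = data.frame,
# n_ambiguous, n_unseeded)
.classify_reads <- function(reads, seqs, index, k, max_mismatches) {
  ids <- names(seqs$A)
  n_reads <- length(reads)
  empty <- data.frame(read_i = integer(), t_idx = integer(),
                      off = integer(), mm_A = integer(), mm_B = integer(),
                      mm_D = integer(), class = character(),
                      stringsAsFactors = FALSE)
  if (n_reads == 0)
    return(list(assign = empty, n_ambiguous = 0L, n_unseeded = 0L))
  rl <- nchar(reads)
  collect_cand <- function(rd, which_reads) {
    rlx <- nchar(rd)
    starts <- lapply(seq_along(rd), function(i) {
      s <- unique(c(seq(1L, max(1L, rlx[i] - k + 1L), by = k),
                    max(1L, rlx[i] - k + 1L)))
      s[s + k - 1L <= rlx[i]]
    })
    ns <- lengths(starts)
    if (sum(ns) == 0) return(NULL)
    seeds <- data.table::data.table(
      read_i = rep(which_reads, ns),
      s = unlist(starts),
      kmer = substring(rep(rd, ns), unlist(starts),
                       unlist(starts) + k - 1L))
    hits <- index[seeds, on = "kmer", nomatch = 0L, allow.cartesian = TRUE]
    if (nrow(hits) == 0) return(NULL)
    hits[, off := pos - s]
    unique(hits[, c("read_i", "t_idx", "off")])
  }
  cand <- collect_cand(reads, seq_len(n_reads))
  # reverse-complement fallback for reads (e.g. second mates) that did
  # not seed in forward orientation
  seeded <- if (is.null(cand)) integer(0) else unique(cand$read_i)
  misses <- setdiff(seq_len(n_reads), seeded)
  rc_set <- integer(0)
  if (length(misses)) {
    rc <- .revcomp(reads[misses])
    cand_rc <- collect_cand(rc, misses)
    if (!is.null(cand_rc)) {
      rc_set <- unique(cand_rc$read_i)
      reads[rc_set] <- rc[match(rc_set, misses)]
      cand <- if (is.null(cand)) cand_rc else rbind(cand, cand_rc)
    }
  }
  if (is.null(cand) || nrow(cand) == 0)
    return(list(assign = empty, n_ambiguous = 0L, n_unseeded = n_reads))
  n_unseeded <- n_reads - length(unique(cand$read_i))
  gl <- nchar(seqs$A[cand$t_idx])
  keep <- cand$off >= 0L & cand$off + rl[cand$read_i] <= gl
  cand <- cand[keep]
  if (nrow(cand) == 0)
    return(list(assign = empty, n_ambiguous = 0L, n_unseeded = n_reads))
  mm <- matrix(NA_integer_, nrow(cand), 3L)
  for (hj in 1:3) {
    h <- c("A", "B", "D")[hj]
    refs <- substring(seqs[[h]][cand$t_idx], cand$off + 1L,
                      cand$off + rl[cand$read_i])
    rds <- reads[cand$read_i]
    mm[, hj] <- mapply(function(a, b) sum(charToRaw(a) != charToRaw(b)),
                       rds, refs, USE.NAMES = FALSE)
  }
  cand[, `:=`(mm_A = mm[, 1], mm_B = mm[, 2], mm_D = mm[, 3],
              best = pmin(mm[, 1], mm[, 2], mm[, 3]))]
  data.table::setorder(cand, read_i, best, t_idx, off)
  first <- cand[!duplicated(cand$read_i)]
  # a read whose best mismatch count is achieved in two distinct triplets
  # is counted for neither
  amb_tab <- cand[, .(n_t = data.table::uniqueN(t_idx[best == min(best)])),
                  by = read_i]
  amb <- amb_tab$read_i[amb_tab$n_t > 1L]
  first <- first[!first$read_i %in% amb]
  compat <- cbind(first$mm_A <= max_mismatches & first$mm_A == first$best,
                  first$mm_B <= max_mismatches & first$mm_B == first$best,
                  first$mm_D <= max_mismatches & first$mm_D == first$best)
  cls <- apply(compat, 1, function(z)
    if (any(z)) paste(c("A", "B", "D")[z], collapse = "") else "UNASSIGNED")
  assign <- data.frame(read_i = first$read_i, t_idx = first$t_idx,
                       off = first$off, mm_A = first$mm_A,
                       mm_B = first$mm_B, mm_D = first$mm_D,
                       class = cls, stringsAsFactors = FALSE)
  list(assign = assign, n_ambiguous = length(amb), n_unseeded = n_unseeded)
}

#' Quantify homeolog expression from reads
#'
#' Associates each read with a candidate triplet by exact k-mer seeding
#' against all homeolog sequences, classifies it by end-to-end mismatch
#' counting ([assign_read()] semantics), tallies the seven compatibility
#' classes per triplet and library, and allocates shared classes with
#' [allocate_counts()]. Reads seeding equally well to two triplets are
#' dropped (counted in the `ambiguous_reads` attribute); reads with no
#' compatible homeolog are tallied as `n_unassigned` and excluded from
#' allocation.
#'
#' @param reads A named character vector of read sequences (one library)
#'   or a named list of such vectors (one element per library).
#' @param sequences List with elements `A`, `B`, `D`: named character
#'   vectors (or `DNAStringSet`s) of homeolog sequences, identically
#'   named by triplet id.
#' @param k Seed word size (default 31).
#' @param max_mismatches Per-homeolog mismatch gate (default 2).
#'
#' @return data.frame with one row per (library, triplet): class counts
#'   `n_A` ... `n_ABD`, `n_unassigned`, and allocated counts `c_A`,
#'   `c_B`, `c_D`. Attributes `ambiguous_reads` and `unseeded_reads`
#'   give per-library drop counts.
#' @export
quantify <- function(reads, sequences, k = 31L, max_mismatches = 2L) {
  if (!is.list(reads) || inherits(reads, "DNAStringSet"))
    reads <- list(library1 = reads)
  seqs <- .normalize_seq_set(sequences)
  ids <- names(seqs$A)
  index <- .build_kmer_index(seqs, k)
  data.table::setkey(index, kmer)
  out <- vector("list", length(reads))
  amb <- unseed <- stats::setNames(integer(length(reads)), names(reads))
  for (li in seq_along(reads)) {
    lib <- names(reads)[li]
    res <- .classify_reads(as.character(reads[[li]]), seqs, index, k,
                           max_mismatches)
    amb[li] <- res$n_ambiguous
    unseed[li] <- res$n_unseeded
    a <- res$assign
    counts <- matrix(0L, length(ids), length(.CLASSES) + 1L,
                     dimnames = list(ids, c(.CLASSES, "UNASSIGNED")))
    if (nrow(a)) {
      tab <- table(factor(a$t_idx, levels = seq_along(ids)),
                   factor(a$class, levels = c(.CLASSES, "UNASSIGNED")))
      counts <- counts + unclass(tab)
    }
    alloc <- allocate_counts(counts[, "A"], counts[, "B"], counts[, "D"],
                             counts[, "AB"], counts[, "AD"], counts[, "BD"],
                             counts[, "ABD"])
    out[[li]] <- data.frame(
      library = lib, triplet_id = ids,
      n_A = counts[, "A"], n_B = counts[, "B"], n_D = counts[, "D"],
      n_AB = counts[, "AB"], n_AD = counts[, "AD"], n_BD = counts[, "BD"],
      n_ABD = counts[, "ABD"], n_unassigned = counts[, "UNASSIGNED"],
      alloc, row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "ambiguous_reads") <- amb
  attr(res, "unseeded_reads") <- unseed
  res
}

#' Quantify homeolog expression from a SAM file
#'
#' Import path for externally aligned reads: alignments of each read to
#' the homeolog genes of a triplet are grouped by read, the `NM` tag is
#' taken as the end-to-end mismatch count per homeolog, and the same
#' two-mismatch compatibility gate and proportional allocation as
#' [quantify()] are applied. Reference names must be `<triplet>_<A|B|D>`
#' unless a `triplet_map` is given.
#'
#' @param sam_path Path to a SAM file (text; `@` headers ignored). All
#'   alignments of a read should be reported (e.g. `bowtie2 -a`).
#' @param library Library label for the output (default: file base name).
#' @param triplet_map Optional data.frame (`reference`, `triplet_id`,
#'   `homeolog`) mapping reference names.
#' @param max_mismatches Per-homeolog mismatch gate (default 2).
#'
#' @return Same shape as [quantify()].
#' @export
quantify_sam <- function(sam_path, library = NULL, triplet_map = NULL,
                         max_mismatches = 2L) {
  if (is.null(library))
    library <- sub("\\.sam$", "", basename(sam_path))
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(library = character(), triplet_id = character()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  qname <- vapply(f, `[[`, "", 1L)
  flagv <- as.integer(vapply(f, `[[`, "", 2L))
  rname <- vapply(f, `[[`, "", 3L)
  nm <- vapply(f, function(x) {
    tag <- grep("^NM:i:", x[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[1])) else NA_integer_
  }, 0L)
  keep <- rname != "*" & !bitwAnd(flagv, 4L)
  if (any(is.na(nm[keep])))
    stop("SAM alignments lack the required NM tag")
  qname <- qname[keep]; rname <- rname[keep]; nm <- nm[keep]
  if (is.null(triplet_map)) {
    ok <- grepl("_[ABD]$", rname)
    if (!all(ok))
      stop("reference names must end in _A/_B/_D or a triplet_map ",
           "must be supplied")
    trip <- sub("_[ABD]$", "", rname)
    hom <- sub("^.*_", "", rname)
  } else {
    m <- match(rname, triplet_map$reference)
    if (anyNA(m)) stop("reference names missing from triplet_map")
    trip <- triplet_map$triplet_id[m]
    hom <- triplet_map$homeolog[m]
  }
  dt <- data.table::data.table(qname = qname, trip = trip, hom = hom,
                               nm = nm)
  dt <- dt[, .(nm = min(nm)), by = .(qname, trip, hom)]
  per_read <- split(dt, dt$qname)
  ids <- sort(unique(trip))
  counts <- matrix(0L, length(ids), length(.CLASSES) + 1L,
                   dimnames = list(ids, c(.CLASSES, "UNASSIGNED")))
  n_amb <- 0L
  for (g in per_read) {
    best_by_t <- tapply(g$nm, g$trip, min)
    tbest <- names(best_by_t)[best_by_t == min(best_by_t)]
    if (length(tbest) > 1L) { n_amb <- n_amb + 1L; next }
    gg <- g[g$trip == tbest]
    compat <- sort(gg$hom[gg$nm <= max_mismatches & gg$nm == min(gg$nm)])
    cls <- if (length(compat)) paste(compat, collapse = "") else "UNASSIGNED"
    counts[tbest, cls] <- counts[tbest, cls] + 1L
  }
  alloc <- allocate_counts(counts[, "A"], counts[, "B"], counts[, "D"],
                           counts[, "AB"], counts[, "AD"], counts[, "BD"],
                           counts[, "ABD"])
  res <- data.frame(
    library = library, triplet_id = ids,
    n_A = counts[, "A"], n_B = counts[, "B"], n_D = counts[, "D"],
    n_AB = counts[, "AB"], n_AD = counts[, "AD"], n_BD = counts[, "BD"],
    n_ABD = counts[, "ABD"], n_unassigned = counts[, "UNASSIGNED"],
    alloc, row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "ambiguous_reads") <- stats::setNames(n_amb, library)
  res
}
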