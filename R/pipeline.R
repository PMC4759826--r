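#' Pipeline configuration
#'
#' All stage thresholds in one object. The defaults are the thresholds
#' the analysis is defined by: identity 0.90 and coverage 0.75 for
#' triplet identification, a two-mismatch gate for read assignment,
#' two-fold change with BH-adjusted p < 0.01 for differential
#' expression, chi-square p < 0.01 with Expmax/Expmin >= 1.5 for
#' homeolog bias, and a 10-gene window with 5-gene step and 3-gene
#' minimum run for the hotspot scan.
#'
#' @param simulate Run the synthetic-data stage (`TRUE`) or consume
#'   user-supplied inputs from `paths`.
#' @param paths Named list of input paths when `simulate = FALSE`:
#'   `fasta_A`, `fasta_B`, `fasta_D`, `fastq` (named character vector of
#'   library FASTQ paths), optional `positions`, `layout`, `families`.
#' @param min_identity,min_coverage Triplet gates.
#' @param max_mismatches Read-assignment mismatch gate.
#' @param seed_k Seed word size for read-triplet lookup.
#' @param fold,q DE gates.
#' @param bias_p,bias_ratio Bias gates.
#' @param window,step,min_run Hotspot-scan parameters.
#' @param n_triplets,gene_length,divergence Simulation parameters.
#' @param background_responsive_rate,hotspot_spec Layout simulation
#'   parameters (see [simulate_layout()]).
#' @param design A [sim_design()].
#' @param bias_spec,de_spec Expression simulation parameters
#'   (see [simulate_expression()]).
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = TRUE, paths = list(),
                            min_identity = 0.90, min_coverage = 0.75,
                            max_mismatches = 2L, seed_k = 31L,
                            fold = 2.0, q = 0.01,
                            bias_p = 0.01, bias_ratio = 1.5,
                            window = 10L, step = 5L, min_run = 3L,
                            n_triplets = 50L, gene_length = 1000L,
                            divergence = 0.02,
                            background_responsive_rate = 0.05,
                            hotspot_spec = NULL,
                            design = sim_design(),
                            bias_spec = list(alpha = c(2, 2, 2)),
                            de_spec = list(fraction = 0.25,
                                           fold_range = c(2, 8),
                                           p_down = 0.4),
                            seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg A `pipeline_config`.
#' @return `cfg` invisibly; signals an error (class
#'   `homeoscan_validation_error`) naming the offending field otherwise.
#' @export
validate_config <- function(cfg) {
  fail <- function(field, msg)
    stop(structure(class = c("homeoscan_validation_error", "error",
                             "condition"),
                   list(message = sprintf("config field '%s': %s", field,
                                          msg),
                        call = NULL)))
  chk <- function(field, ok, msg) if (!ok) fail(field, msg)
  chk("min_identity", cfg$min_identity > 0 && cfg$min_identity <= 1,
      "must lie in (0, 1]")
  chk("min_coverage", cfg$min_coverage > 0 && cfg$min_coverage <= 1,
      "must lie in (0, 1]")
  chk("max_mismatches", cfg$max_mismatches >= 0, "must be >= 0")
  chk("fold", cfg$fold >= 1, "must be >= 1")
  chk("q", cfg$q > 0 && cfg$q <= 1, "must lie in (0, 1]")
  chk("bias_p", cfg$bias_p > 0 && cfg$bias_p <= 1, "must lie in (0, 1]")
  chk("bias_ratio", cfg$bias_ratio >= 1, "must be >= 1")
  chk("window", cfg$window >= 1, "must be >= 1")
  chk("step", cfg$step >= 1, "must be >= 1")
  chk("min_run", cfg$min_run >= 1, "must be >= 1")
  if (!cfg$simulate) {
    for (p in c("fasta_A", "fasta_B", "fasta_D")) {
      chk(p, !is.null(cfg$paths[[p]]), "required when simulate = FALSE")
      chk(p, file.exists(cfg$paths[[p]]), "file does not exist")
    }
    chk("fastq", !is.null(cfg$paths$fastq),
        "required when simulate = FALSE")
  }
  invisible(cfg)
}

.write_stage <- function(files, stage, manifest) {
  rbind(manifest, data.frame(stage = stage, file = basename(files),
                             md5 = unname(tools::md5sum(files)),
                             stringsAsFactors = FALSE))
}

#' Run the full homeolog-partitioning pipeline
#'
#' Stages run in dependency order: simulate (optional), triplet
#' identification, homeolog quantification, differential-expression /
#' bias / partitioning statistics, and the hotspot scan. All stage
#' outputs are written as TSV/FASTA/FASTQ/BED under `out_dir` together
#' with the resolved configuration (`config.yaml`) and a run manifest of
#' md5 checksums (`manifest.tsv`). Fixed seeds give byte-identical
#' reruns.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results
#'   (`triplets`, `counts`, `de`, `bias`, `partition`, `windows`,
#'   `hotspots`, and for simulated runs `sim`, `reads`, `layout`) plus
#'   the `manifest` data.frame.
#' @export
run_pipeline <- function(cfg, out_dir) {
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(stage = character(), file = character(),
                         md5 = character(), stringsAsFactors = FALSE)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(.config_as_yaml(cfg), cfg_path)

  positions <- NULL
  layout <- NULL
  families <- NULL
  sim <- NULL
  origin <- NULL
  if (cfg$simulate) {
    message("stage simulate: ", cfg$n_triplets, " triplets")
    sim <- simulate_triplets(cfg$n_triplets, cfg$gene_length,
                             cfg$divergence, seed = cfg$seed)
    sim <- simulate_expression(sim, cfg$design, cfg$bias_spec,
                               cfg$de_spec, seed = cfg$seed)
    rd <- simulate_reads(sim, cfg$design, seed = cfg$seed)
    origin <- rd$origin
    lay <- simulate_layout(hotspot_spec = cfg$hotspot_spec,
                           background_responsive_rate =
                             cfg$background_responsive_rate,
                           seed = cfg$seed)
    layout <- lay$layout
    families <- layout[, c("gene_id", "family")]
    fasta_files <- character(3)
    for (s in c("A", "B", "D")) {
      f <- file.path(out_dir, sprintf("genes_%s.fasta", s))
      write_fasta(stats::setNames(sim$sequences[[s]],
                                  paste0(names(sim$sequences[[s]]), "_", s)),
                  f)
      fasta_files[match(s, c("A", "B", "D"))] <- f
    }
    fq_files <- vapply(names(rd$reads), function(lib) {
      f <- file.path(out_dir, paste0(lib, ".fastq"))
      write_fastq(rd$reads[[lib]], f)
      f
    }, "")
    bed <- file.path(out_dir, "layout.bed")
    write_bed(layout, bed)
    truth_files <- c(file.path(out_dir, "truth_snps.tsv"),
                     file.path(out_dir, "truth_origin.tsv"),
                     file.path(out_dir, "truth_hotspots.tsv"))
    write_tsv(sim$snps, truth_files[1])
    write_tsv(origin, truth_files[2])
    write_tsv(lay$hotspots, truth_files[3])
    manifest <- .write_stage(c(fasta_files, fq_files, bed, truth_files),
                             "simulate", manifest)
    genes <- lapply(stats::setNames(c("A", "B", "D"), c("A", "B", "D")),
                    function(s) stats::setNames(
                      sim$sequences[[s]],
                      paste0(names(sim$sequences[[s]]), "_", s)))
    reads <- rd$reads
  } else {
    genes <- list(A = read_fasta(cfg$paths$fasta_A),
                  B = read_fasta(cfg$paths$fasta_B),
                  D = read_fasta(cfg$paths$fasta_D))
    reads <- lapply(cfg$paths$fastq, read_fastq)
    if (!is.null(cfg$paths$positions))
      positions <- read_gene_positions(cfg$paths$positions)
    if (!is.null(cfg$paths$layout)) {
      layout <- read_tsv(cfg$paths$layout)
      layout$responsive <- as.logical(layout$responsive)
    }
    if (!is.null(cfg$paths$families))
      families <- read_tsv(cfg$paths$families)
  }

  message("stage triplets")
  triplets <- suppressWarnings(build_triplets(
    genes$A, genes$B, genes$D, positions = positions,
    min_identity = cfg$min_identity, min_coverage = cfg$min_coverage))
  sites <- do.call(rbind, lapply(seq_len(nrow(triplets)), function(i) {
    s <- call_diagnostic_sites(genes$A[[triplets$gene_A[i]]],
                               genes$B[[triplets$gene_B[i]]],
                               genes$D[[triplets$gene_D[i]]])
    if (nrow(s)) cbind(triplet_id = triplets$triplet_id[i], s)
  }))
  f_trip <- file.path(out_dir, "triplets.tsv")
  f_sites <- file.path(out_dir, "diagnostic_sites.tsv")
  write_tsv(triplets, f_trip)
  write_tsv(sites, f_sites)
  manifest <- .write_stage(c(f_trip, f_sites), "triplets", manifest)

  message("stage quantify: ", sum(lengths(reads)), " reads")
  seqset <- list(
    A = stats::setNames(as.character(genes$A[triplets$gene_A]),
                        triplets$triplet_id),
    B = stats::setNames(as.character(genes$B[triplets$gene_B]),
                        triplets$triplet_id),
    D = stats::setNames(as.character(genes$D[triplets$gene_D]),
                        triplets$triplet_id))
  counts <- quantify(reads, seqset, k = cfg$seed_k,
                     max_mismatches = cfg$max_mismatches)
  f_counts <- file.path(out_dir, "homeolog_counts.tsv")
  write_tsv(counts, f_counts)
  manifest <- .write_stage(f_counts, "quantify", manifest)

  message("stage stats")
  samples <- if (!is.null(sim)) sim$samples else {
    sheet <- cfg$paths$samples
    if (is.null(sheet))
      stop("a sample sheet path is required when simulate = FALSE")
    read_tsv(sheet)
  }
  mat <- .counts_matrix(counts)
  de <- run_de(mat, samples, fold_threshold = cfg$fold,
               q_threshold = cfg$q)
  de_h <- .split_feature(de)
  part <- summarize_partitioning(de_h)
  cb <- chisq_bias(counts$c_A, counts$c_B, counts$c_D)
  bc <- call_bias(cb$p, counts$c_A, counts$c_B, counts$c_D,
                  p_threshold = cfg$bias_p,
                  ratio_threshold = cfg$bias_ratio)
  bias <- cbind(counts[, c("library", "triplet_id")], cb, bc)
  f_stats <- file.path(out_dir, c("de_calls.tsv", "bias_calls.tsv",
                                  "bias_summary.tsv",
                                  "partition_triplets.tsv",
                                  "partition_totals.tsv"))
  write_tsv(de_h, f_stats[1])
  write_tsv(bias, f_stats[2])
  write_tsv(summarize_bias(bias), f_stats[3])
  write_tsv(part$triplets, f_stats[4])
  write_tsv(part$totals, f_stats[5])
  manifest <- .write_stage(f_stats, "stats", manifest)

  windows <- NULL
  hotspots <- NULL
  if (!is.null(layout)) {
    message("stage hotspots")
    windows <- window_scan(layout, cfg$window, cfg$step)
    hotspots <- find_hotspots(layout, cfg$min_run)
    hotspots <- annotate_tandem(hotspots, families = families)
    f_hot <- file.path(out_dir, c("windows.tsv", "hotspots.tsv"))
    write_tsv(windows, f_hot[1])
    write_tsv(hotspots, f_hot[2])
    manifest <- .write_stage(f_hot, "hotspots", manifest)
  }

  f_man <- file.path(out_dir, "manifest.tsv")
  write_tsv(manifest, f_man)
  invisible(list(triplets = triplets, sites = sites, counts = counts,
                 de = de_h, bias = bias, partition = part,
                 windows = windows, hotspots = hotspots, sim = sim,
                 origin = origin, layout = layout, manifest = manifest))
}

# homeolog counts table -> feature x library matrix of rounded allocated
# counts, features named <triplet>_<homeolog>
.counts_matrix <- function(counts) {
  long <- do.call(rbind, lapply(c("A", "B", "D"), function(h)
    data.frame(feature = paste0(counts$triplet_id, "_", h),
               library = counts$library,
               count = round(counts[[paste0("c_", h)]]),
               stringsAsFactors = FALSE)))
  dt <- data.table::dcast(data.table::as.data.table(long),
                          feature ~ library, value.var = "count",
                          fill = 0)
  mat <- as.matrix(dt[, -1])
  rownames(mat) <- dt$feature
  mat
}

# split "<triplet>_<homeolog>" features back into columns
.split_feature <- function(de) {
  de$triplet_id <- sub("_[ABD]$", "", de$feature)
  de$homeolog <- sub("^.*_", "", de$feature)
  de
}

.config_as_yaml <- function(cfg) {
  out <- unclass(cfg)
  out$design <- unclass(out$design)
  out$hotspot_spec <- if (!is.null(out$hotspot_spec))
    as.list(as.data.frame(out$hotspot_spec)) else NULL
  out
}
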