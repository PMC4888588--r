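#' Pipeline run configuration
#'
#' Holds every tunable of the end-to-end pipeline with valid defaults.
#' Configurations round-trip losslessly through the flat key-value file
#' form ([write_run_config()] / [read_run_config()]).
#'
#' @param alignments_dir directory of per-cell BAM/SAM files (one library
#'   per cell); alternatively `counts_tsv` may point at a counts table
#'   written by [write_counts_tsv()].
#' @param chrom_sizes 2-column chromosome-sizes file (required with
#'   `alignments_dir` unless `mappability` is an interval track carrying
#'   its own extent).
#' @param mappability mappability source path (bedGraph/BigWig/BAM/SAM) or
#'   empty for uniform fixed-width bins.
#' @param blacklist optional BED of artefact-prone regions to exclude.
#' @param counts_tsv optional pre-binned counts TSV (skips binning and
#'   counting; `bin_width` and GC must be encoded in the grid used to
#'   produce it).
#' @param output_dir where all artefacts are written.
#' @param target_width target mean bin width (bp).
#' @param c_max,most_frequent_state,tol,max_iter,n_restarts,seed HMM
#'   settings, see [karyo_hmm()].
#' @param min_mapq,discard_duplicates read-counting filters.
#' @param k_max maximum QC clusters, see [cluster_and_select()].
#' @param ploidy baseline copy number for every chromosome.
#' @param gc_correction apply [gc_correct()] when GC fractions are known.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(alignments_dir = "", chrom_sizes = "",
                       mappability = "", blacklist = "", counts_tsv = "",
                       output_dir = "karyoHMM_out", target_width = 1e6,
                       c_max = 10L, most_frequent_state = 2L, tol = 1e-4,
                       max_iter = 200L, n_restarts = 3L, seed = 1L,
                       min_mapq = 10L, discard_duplicates = TRUE,
                       k_max = 3L, ploidy = 2L, gc_correction = TRUE) {
  cfg <- list(alignments_dir = alignments_dir, chrom_sizes = chrom_sizes,
              mappability = mappability, blacklist = blacklist,
              counts_tsv = counts_tsv, output_dir = output_dir,
              target_width = as.numeric(target_width),
              c_max = as.integer(c_max),
              most_frequent_state = as.integer(most_frequent_state),
              tol = as.numeric(tol), max_iter = as.integer(max_iter),
              n_restarts = as.integer(n_restarts), seed = as.integer(seed),
              min_mapq = as.integer(min_mapq),
              discard_duplicates = as.logical(discard_duplicates),
              k_max = as.integer(k_max), ploidy = as.integer(ploidy),
              gc_correction = as.logical(gc_correction))
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration as a flat key=value file
#' @param cfg a [run_config()].
#' @param path output file.
#' @export
write_run_config <- function(cfg, path) {
  vals <- vapply(cfg, function(v) format(v, digits = 15, scientific = FALSE),
                 character(1))
  writeLines(paste0(names(cfg), "=", vals), path)
  invisible(path)
}

#' Read a run configuration written by [write_run_config()]
#' @param path config file; keys missing from the file keep their
#'   defaults.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  cfg <- run_config()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (!k %in% names(cfg)) stop("unknown configuration key: ", k)
    proto <- cfg[[k]]
    cfg[[k]] <- if (is.logical(proto)) as.logical(vals[i])
      else if (is.integer(proto)) as.integer(vals[i])
      else if (is.numeric(proto)) as.numeric(vals[i])
      else vals[i]
  }
  cfg
}

#' Run the full single-cell copy-number pipeline
#'
#' Binning, read counting (or counts ingestion), GC correction, per-cell
#' HMM fitting and decoding, library QC with cluster selection, karyotype
#' scoring of the selected cells, profile clustering and the genome-wide
#' heatmap. Every artefact is written under `cfg$output_dir`; the run is
#' deterministic given the configuration (all randomness flows from
#' `cfg$seed`).
#'
#' @param cfg a [run_config()]. Provide either `alignments_dir` (with
#'   `chrom_sizes`) or `counts_tsv` (with `chrom_sizes` and, optionally,
#'   `mappability`).
#' @param population label used in the scores table.
#' @return Invisibly, a list with the fitted objects: `grid`, `cells`,
#'   `fits`, `qc`, `measures`, `output_dir`.
#' @export
run_pipeline <- function(cfg, population = "population") {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$output_dir, "run.log")
  log_line <- function(...) cat(sprintf("[%s] ", format(Sys.time())),
                                sprintf(...), "\n", sep = "", file = logf,
                                append = TRUE)
  cat("", file = logf)
  log_line("karyoHMM %s; seed %d", as.character(utils::packageVersion("karyoHMM")),
           cfg$seed)
  write_run_config(cfg, file.path(cfg$output_dir, "config.txt"))

  stage <- "binning"
  result <- tryCatch({
    if (nzchar(cfg$chrom_sizes)) {
      layout <- read_chrom_sizes(cfg$chrom_sizes, ploidy = cfg$ploidy)
    } else stop("chrom_sizes is required")
    grid <- if (nzchar(cfg$mappability)) {
      build_variable_bins(cfg$mappability, layout, cfg$target_width)
    } else uniform_bins(layout, cfg$target_width)
    if (nzchar(cfg$blacklist)) grid <- apply_blacklist(grid, cfg$blacklist)
    write_bins_bed(grid, file.path(cfg$output_dir, "bins.bed"))
    log_line("binning: %d bins (mean width %.2f Mb)", n_bins(grid),
             mean(grid$bins$width) / 1e6)

    stage <- "counting"
    cells <- if (nzchar(cfg$counts_tsv)) {
      read_counts_tsv(cfg$counts_tsv, grid)
    } else {
      files <- list.files(cfg$alignments_dir, pattern = "\\.(bam|sam)$",
                          ignore.case = TRUE, full.names = TRUE)
      if (length(files) == 0) stop("no alignment files in ", cfg$alignments_dir)
      lapply(files, count_reads, grid = grid, min_mapq = cfg$min_mapq,
             discard_duplicates = cfg$discard_duplicates)
    }
    log_line("counting: %d cells", length(cells))

    stage <- "gc_correction"
    if (cfg$gc_correction && !anyNA(grid$bins$gc))
      cells <- lapply(cells, gc_correct)
    write_counts_tsv(cells, file.path(cfg$output_dir, "counts.tsv"))

    stage <- "hmm_fit"
    fits <- lapply(cells, function(cc) {
      karyo_hmm(cc, c_max = cfg$c_max,
                most_frequent_state = cfg$most_frequent_state,
                tol = cfg$tol, max_iter = cfg$max_iter,
                n_restarts = cfg$n_restarts, seed = cfg$seed)
    })
    prof_dir <- file.path(cfg$output_dir, "profiles")
    dir.create(prof_dir, showWarnings = FALSE)
    for (f in fits) {
      write_profile_bed(f$profile,
                        file.path(prof_dir, paste0(f$cell$cell_id, ".bed")))
      write_model_params(f, file.path(prof_dir,
                                      paste0(f$cell$cell_id, ".params.txt")))
    }
    log_line("hmm_fit: %d cells fitted", length(fits))

    stage <- "qc"
    qc <- cluster_and_select(quality_metrics(fits), k_max = cfg$k_max)
    write_qc_tsv(qc, file.path(cfg$output_dir, "qc.tsv"))
    log_line("qc: %d/%d libraries selected (k = %d)", sum(qc$selected),
             nrow(qc), attr(qc, "k"))

    stage <- "scoring"
    sel <- fits[qc$selected]
    profiles <- lapply(sel, function(f) f$profile)
    measures <- karyotype_measures(profiles, layout, population)
    write_scores_tsv(measures, file.path(cfg$output_dir, "scores.tsv"))

    stage <- "heatmap"
    ord <- if (length(profiles) >= 2) cluster_cells(profiles)$order
           else seq_along(profiles)
    writeLines(vapply(profiles[ord], function(p) p$cell_id, character(1)),
               file.path(cfg$output_dir, "cell_order.txt"))
    genomewide_heatmap(profiles, ord,
                       file = file.path(cfg$output_dir, "heatmap.png"),
                       c_max = cfg$c_max)
    log_line("done")
    list(grid = grid, cells = cells, fits = fits, qc = qc,
         measures = measures, output_dir = cfg$output_dir)
  }, error = function(e) {
    log_line("ERROR in stage %s: %s", stage, conditionMessage(e))
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

#' Write a simulated cohort to disk as pipeline input
#'
#' Materialises a simulated cohort as a chromosome-sizes file, a counts
#' TSV, the truth table and (optionally) per-cell SAM files, so the full
#' pipeline can be exercised from files alone.
#'
#' @param dir output directory.
#' @param write_sam also write one minimal SAM per cell.
#' @param ... passed to [simulate_cohort()].
#' @return Invisibly, list(truth, cells, manifest).
#' @export
simulate_cohort_files <- function(dir, write_sam = FALSE, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(...)
  layout <- sim$truth$layout
  sizes <- file.path(dir, "chrom.sizes")
  writeLines(sprintf("%s\t%d", layout$chrom, as.integer(layout$length)),
             sizes)
  counts <- file.path(dir, "counts.tsv")
  write_counts_tsv(sim$cells, counts)
  truth <- file.path(dir, "truth.tsv")
  write_truth_tsv(sim$truth, truth)
  manifest <- c(chrom_sizes = sizes, counts_tsv = counts, truth_tsv = truth)
  if (write_sam) {
    sam_dir <- file.path(dir, "alignments")
    dir.create(sam_dir, showWarnings = FALSE)
    for (cc in sim$cells)
      write_cell_sam(cc, file.path(sam_dir, paste0(cc$cell_id, ".sam")))
    manifest <- c(manifest, alignments_dir = sam_dir)
  }
  invisible(list(truth = sim$truth, cells = sim$cells, manifest = manifest))
}
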