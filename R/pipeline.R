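#' Default pipeline configuration
#'
#' Returns the full parameter tree of [run_pipeline()] with the standard
#' defaults: SNP filters MAF > 0.05 and integrity > 0.8; het/hom region
#' partition at 25-kb/5-kb windows, rate threshold 0.002 and 50-kb minimum
#' region length; 20-kb non-overlapping block windows with a top-5 percent
#' frequency cutoff; 50-kb/10-kb ratio-scan windows with a top-1 percent
#' threshold and at least 5 SNPs per window. Any subset of these can be
#' overridden by the `config` argument of [run_pipeline()].
#'
#' @return A nested list of parameters.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    stages = list(simulate = TRUE, filter = TRUE, stats = TRUE,
                  regions = TRUE, blocks = TRUE, sweeps = TRUE, assoc = TRUE),
    paths = list(vcf = NULL, samples = NULL, traits = NULL,
                 annotation = NULL, chrom_lengths = NULL),
    simulate = list(),
    filter = list(maf_min = 0.05, integrity_min = 0.8),
    stats = list(size = 50e3, step = 10e3, min_segsites = 3),
    region = list(window_bp = 25e3, step_bp = 5e3, rate_threshold = 0.002,
                  min_len_bp = 50e3, reference_sample = NULL),
    block = list(window_bp = 20e3, quantile = 0.95),
    sweep = list(size = 50e3, step = 10e3, top_q = 0.01, min_sites = 5),
    assoc = list(snps = NULL, min_group_size = 5)
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' Reads a plain YAML file and overlays it on [default_pipeline_config()].
#'
#' @param path Path to a YAML file.
#' @return A full configuration list.
#' @export
read_pipeline_config <- function(path) {
  merge_config(default_pipeline_config(), yaml::read_yaml(path))
}

#' Run the heterozygosity-variation analysis pipeline end to end
#'
#' Orchestrates the stages with one configuration: simulate (or read)
#' genotypes -> SNP filtering -> window statistics -> het/hom region
#' partition and diversity comparison -> heterozygous blocks, highly
#' heterozygous blocks and trait segregation -> He and pi ratio sweep scans,
#' intersection and gene overlap -> candidate-SNP trait associations. Each
#' stage writes its outputs as TSV/BED under `out_dir`; a deterministic run
#' manifest (`manifest.yaml`) records parameters, the seed, input checksums
#' and per-stage row counts, so rerunning an identical configuration
#' reproduces byte-identical outputs.
#'
#' @param config Configuration list (defaults from
#'   [default_pipeline_config()]; any subset may be supplied).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the stage results (`matrix`, `filtered`,
#'   `win_stats`, `regions`, `region_diversity`, `blocks`, `sweeps`,
#'   `assoc`, `manifest`).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- merge_config(default_pipeline_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, parameters = cfg[setdiff(names(cfg), "stages")],
                   stage_rows = list(), inputs = list())
  res <- list()

  # --- inputs: simulate or read ------------------------------------------
  if (isTRUE(cfg$stages$simulate)) {
    sim <- simulate_genotypes(do.call(sim_config,
                                      c(cfg$simulate, list(seed = cfg$seed))))
    traits <- simulate_traits(sim)
    gm <- sim$matrix
    chrom_lengths <- sim$chrom_lengths
    write_vcf(gm, file.path(out_dir, "genotypes.vcf"))
    readr::write_tsv(gm$samples, file.path(out_dir, "samples.tsv"))
    readr::write_tsv(traits, file.path(out_dir, "traits.tsv"))
    readr::write_tsv(chrom_lengths, file.path(out_dir, "chrom_lengths.tsv"))
    write_truth(sim$truth, out_dir)
    res$truth <- sim$truth
    annotation <- NULL
  } else {
    p <- cfg$paths
    if (is.null(p$vcf) || is.null(p$samples) || is.null(p$chrom_lengths)) {
      abort("config$paths must provide vcf, samples and chrom_lengths when not simulating.")
    }
    for (f in c("vcf", "samples", "chrom_lengths")) {
      manifest$inputs[[f]] <- unname(tools::md5sum(p[[f]]))
    }
    meta <- read_sample_metadata(p$samples)
    gm <- read_vcf(p$vcf, meta)
    chrom_lengths <- read_chrom_lengths(p$chrom_lengths)
    traits <- if (!is.null(p$traits)) read_trait_table(p$traits) else NULL
    annotation <- if (!is.null(p$annotation)) read_gene_annotation(p$annotation) else NULL
  }
  res$matrix <- gm
  manifest$stage_rows$input_sites <- n_sites(gm)
  manifest$stage_rows$input_samples <- n_samples(gm)
  wild <- wild_ids(gm)
  cultivars <- cultivar_ids(gm)

  # --- filter ------------------------------------------------------------
  if (isTRUE(cfg$stages$filter)) {
    gm <- filter_sites(gm, cfg$filter$maf_min, cfg$filter$integrity_min)
    manifest$stage_rows$filtered_sites <- n_sites(gm)
  }
  res$filtered <- gm

  # --- window statistics -------------------------------------------------
  if (isTRUE(cfg$stages$stats)) {
    wins <- make_windows(chrom_lengths, cfg$stats$size, cfg$stats$step)
    ws <- window_stats(gm, wins, samples = if (length(cultivars)) cultivars else NULL,
                       tajima = TRUE, min_segsites = cfg$stats$min_segsites)
    if (length(wild) && length(cultivars)) {
      wf <- window_fst(gm, wins, wild, cultivars)
      ws$fst <- wf$fst
    }
    write_stats_tsv(ws, file.path(out_dir, "window_stats.tsv"))
    res$win_stats <- ws
    manifest$stage_rows$stat_windows <- nrow(ws)
  }

  # --- het/hom region partition ------------------------------------------
  if (isTRUE(cfg$stages$regions)) {
    ref <- cfg$region$reference_sample %||%
      (if (length(cultivars)) cultivars[1] else gm$samples$sample_id[1])
    regions <- classify_het_hom_regions(
      gm, ref, chrom_lengths,
      window = cfg$region$window_bp, step = cfg$region$step_bp,
      rate_threshold = cfg$region$rate_threshold,
      min_len = cfg$region$min_len_bp
    )
    write_regions_bed(regions, file.path(out_dir, "het_hom_regions.bed"))
    res$regions <- regions
    manifest$stage_rows$het_hom_regions <- nrow(regions)
    if (!is.null(res$win_stats) && nrow(regions)) {
      stats_cols <- intersect(c("pi", "tajimas_d", "fst"), names(res$win_stats))
      cmp <- compare_region_diversity(regions, res$win_stats, stats = stats_cols)
      write_stats_tsv(cmp, file.path(out_dir, "region_diversity.tsv"))
      res$region_diversity <- cmp
    }
  }

  # --- heterozygous blocks -----------------------------------------------
  if (isTRUE(cfg$stages$blocks) && length(cultivars)) {
    calls <- per_accession_het_blocks(gm, cultivars, chrom_lengths,
                                      window = cfg$block$window_bp)
    hb <- highly_het_blocks(calls, quantile = cfg$block$quantile)
    write_stats_tsv(hb$table, file.path(out_dir, "block_frequency.tsv"))
    write_regions_bed(hb$regions, file.path(out_dir, "highly_het_blocks.bed"))
    res$blocks <- hb
    manifest$stage_rows$highly_het_blocks <- nrow(hb$regions)
    manifest$stage_rows$block_cutoff <- round(attr(calls, "cutoff"), 6)
    if (!is.null(traits) && nrow(hb$regions)) {
      quant <- names(traits)[vapply(traits, is.numeric, logical(1))]
      quant <- setdiff(quant, "sample_id")
      if (length(quant)) {
        seg <- trait_segregation_scan(hb$regions, calls, traits, quant)
        write_stats_tsv(seg, file.path(out_dir, "trait_segregation.tsv"))
        res$segregation <- seg
      }
    }
  }

  # --- sweep scans -------------------------------------------------------
  if (isTRUE(cfg$stages$sweeps) && length(wild) && length(cultivars)) {
    scans <- lapply(c(he = "he", pi = "pi"), function(st) {
      ratio_scan(gm, wild, cultivars, chrom_lengths, statistic = st,
                 size = cfg$sweep$size, step = cfg$sweep$step,
                 top_q = cfg$sweep$top_q, min_sites = cfg$sweep$min_sites)
    })
    sw_he <- call_sweeps(scans$he)
    sw_pi <- call_sweeps(scans$pi)
    sw_both <- intersect_sweeps(sw_he, sw_pi)
    write_stats_tsv(scans$he$windows, file.path(out_dir, "scan_he.tsv"))
    write_stats_tsv(scans$pi$windows, file.path(out_dir, "scan_pi.tsv"))
    write_regions_bed(sw_he, file.path(out_dir, "sweeps_he.bed"))
    write_regions_bed(sw_pi, file.path(out_dir, "sweeps_pi.bed"))
    write_regions_bed(sw_both[c("chrom", "start0", "end0", "label", "score")],
                      file.path(out_dir, "sweeps_both.bed"))
    summ <- sweep_summary(sw_both, chrom_lengths, annotation)
    writeLines(jsonlite::toJSON(summ[c("n_regions", "total_span_bp",
                                       "genome_fraction", "n_genes")],
                                auto_unbox = TRUE, pretty = TRUE, digits = NA),
               file.path(out_dir, "sweep_summary.json"))
    res$sweeps <- list(he = sw_he, pi = sw_pi, both = sw_both,
                       scans = scans, summary = summ)
    manifest$stage_rows$sweeps_he <- nrow(sw_he)
    manifest$stage_rows$sweeps_pi <- nrow(sw_pi)
    manifest$stage_rows$sweeps_both <- nrow(sw_both)
  }

  # --- candidate-SNP associations ----------------------------------------
  if (isTRUE(cfg$stages$assoc) && !is.null(traits)) {
    cand <- cfg$assoc$snps
    if (is.null(cand) && !is.null(res$truth)) {
      cand <- res$truth$causal[c("chrom", "pos", "trait_name", "type")]
    }
    if (!is.null(cand) && nrow(cand)) {
      # candidate positions refer to the full site set, not the filtered one
      assoc <- purrr::map_dfr(seq_len(nrow(cand)), function(i) {
        gg <- genotype_groups(res$matrix, cand[i, c("chrom", "pos")],
                              samples = if (length(cultivars)) cultivars else NULL,
                              min_group_size = cfg$assoc$min_group_size)
        tn <- cand$trait_name[i]
        is_quant <- is.numeric(traits[[tn]])
        if (is_quant) {
          open <- names(gg$sizes)[!gg$flagged]
          if (length(open) < 2) return(NULL)
          pr <- utils::combn(open, 2, simplify = FALSE)
          purrr::map_dfr(pr, function(p2) {
            quantitative_assoc(gg, traits, tn, pair = p2)
          })
        } else {
          categorical_assoc(gg, traits, tn)
        }
      })
      write_stats_tsv(assoc, file.path(out_dir, "candidate_assoc.tsv"))
      res$assoc <- assoc
      manifest$stage_rows$assoc_tests <- nrow(assoc)
    }
  }

  manifest$stage_rows <- manifest$stage_rows[order(names(manifest$stage_rows))]
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  res$manifest <- manifest
  invisible(res)
}
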