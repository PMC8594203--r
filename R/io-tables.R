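#' Read sample metadata, chromosome lengths and trait tables
#'
#' Plain TSV readers for the package's tabular inputs. Sample metadata has
#' columns `sample_id`, `pop_class` (`wild`/`landrace`/`breeding`) and
#' optionally `country`; chromosome lengths have `chrom` and `length_bp`;
#' the trait table has `sample_id` plus one column per trait (quantitative
#' traits numeric, categorical traits character/factor).
#'
#' @param path Path to a tab-separated file with a header line.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path) {
  md <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"sample_id" %in% names(md)) abort("metadata TSV needs a `sample_id` column.")
  if ("pop_class" %in% names(md)) {
    bad <- setdiff(stats::na.omit(unique(md$pop_class)),
                   c("wild", "landrace", "breeding"))
    if (length(bad)) {
      abort(paste0("unknown pop_class value(s): ", paste(bad, collapse = ", "), "."))
    }
  }
  md
}

#' @rdname read_sample_metadata
#' @export
read_chrom_lengths <- function(path) {
  cl <- readr::read_tsv(path, show_col_types = FALSE)
  as_chrom_lengths(cl)
}

#' @rdname read_sample_metadata
#' @export
read_trait_table <- function(path) {
  tt <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"sample_id" %in% names(tt)) abort("trait TSV needs a `sample_id` column.")
  tt
}

#' Read gene annotation from GFF3 or BED
#'
#' GFF3 files are filtered to `gene` features; 4+ column BED files are taken
#' as-is (`chrom`, `start0`, `end0`, `gene_id`). Output intervals are 0-based
#' half-open.
#'
#' @param path Path to a `.gff3`/`.gff` or `.bed` file.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @return Tibble with `gene_id`, `chrom`, `start0`, `end0`, `strand`.
#' @export
read_gene_annotation <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  if (format == "bed") {
    bed <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                           show_col_types = FALSE)
    if (ncol(bed) < 4) abort("BED annotation needs at least 4 columns.")
    out <- tibble(
      gene_id = as.character(bed[[4]]),
      chrom = as.character(bed[[1]]),
      start0 = as.integer(bed[[2]]),
      end0 = as.integer(bed[[3]]),
      strand = if (ncol(bed) >= 6) as.character(bed[[6]]) else "*"
    )
  } else {
    gff <- readr::read_tsv(
      path, col_names = c("seqid", "source", "type", "start", "end",
                          "score", "strand", "phase", "attributes"),
      comment = "#", show_col_types = FALSE
    )
    gff <- gff[gff$type == "gene", , drop = FALSE]
    id <- sub(".*ID=([^;]+).*", "\\1", gff$attributes)
    noid <- !grepl("ID=", gff$attributes)
    id[noid] <- paste0("gene_", seq_len(nrow(gff)))[noid]
    out <- tibble(
      gene_id = id,
      chrom = as.character(gff$seqid),
      start0 = as.integer(gff$start) - 1L,   # GFF is 1-based closed
      end0 = as.integer(gff$end),
      strand = gff$strand
    )
  }
  if (anyDuplicated(out$gene_id)) abort("gene ids must be unique.")
  if (any(out$start0 >= out$end0)) abort("gene intervals must satisfy start0 < end0.")
  dplyr::arrange(out, .data$chrom, .data$start0)
}

#' Write regions as BED
#'
#' Regions are emitted natively 0-based half-open with `label` as the BED
#' name column and `score` as the score column.
#'
#' @param regions Tibble with `chrom`, `start0`, `end0` and optionally
#'   `label`, `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  regions <- as_tibble(regions)
  df <- tibble(
    chrom = regions$chrom,
    start0 = regions$start0,
    end0 = regions$end0,
    name = if ("label" %in% names(regions)) regions$label else ".",
    score = if ("score" %in% names(regions)) {
      formatC(regions$score, format = "g", digits = 6)
    } else "0"
  )
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Write a statistics table as TSV
#'
#' Thin wrapper around [readr::write_tsv()] kept for a uniform output
#' surface across pipeline stages.
#'
#' @param df A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stats_tsv <- function(df, path) {
  readr::write_tsv(as_tibble(df), path)
  invisible(path)
}
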