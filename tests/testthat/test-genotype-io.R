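test_that("geno_matrix enforces its invariants", {
  expect_error(toy_matrix(rbind(c(0L, 3L))), "genotype codes")
  expect_error(
    geno_matrix(rbind(c(0L, 1L)),
                sites = data.frame(chrom = "chr1", pos = c(200, 100),
                                   ref = "A", alt = "T"),
                samples = data.frame(sample_id = "a")),
    "sorted"
  )
  expect_error(
    geno_matrix(rbind(c(0L, 1L)),
                sites = data.frame(chrom = "chr1", pos = c(100, 200),
                                   ref = "A", alt = "A"),
                samples = data.frame(sample_id = "a")),
    "differ"
  )
  expect_error(
    geno_matrix(rbind(a = 0L, b = 1L),
                sites = data.frame(chrom = "chr1", pos = 1, ref = "A", alt = "T"),
                samples = data.frame(sample_id = c("a", "a"))),
    "unique"
  )
})

test_that("VCF GT codes map to dosages and multiallelic records are dropped", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "a", "b", "c"), collapse = "\t"),
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\t.\tG\tA,T\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t300\t.\tG\tGA\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t400\t.\tC\tG\t.\tPASS\t.\tGT\t1|0\t./.\t0|0"
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  md <- data.frame(sample_id = c("a", "b", "c"), pop_class = "breeding")
  gm <- read_vcf(path, md)
  expect_equal(n_sites(gm), 2L)           # multiallelic + indel dropped
  expect_equal(attr(gm, "n_excluded"), 2L)
  expect_equal(unname(gm$geno[, 1]), c(0L, 1L, 2L))
  # phased het and missing handled
  expect_equal(unname(gm$geno[, 2]), c(1L, NA_integer_, 0L))
  # unknown samples rejected with offender named
  expect_error(read_vcf(path, md[1:2, ]), "c")
})

test_that("write_vcf/read_vcf round trip is the identity on codes and sites", {
  withr::local_seed(11)
  gm <- random_matrix(8, 60)
  gm$samples$pop_class <- rep(c("wild", "breeding"), each = 4)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  back <- read_vcf(path, gm$samples)
  expect_identical(unname(back$geno), unname(gm$geno))
  expect_equal(back$sites$pos, gm$sites$pos)
  expect_equal(back$sites$ref, gm$sites$ref)
  expect_equal(back$sites$alt, gm$sites$alt)
  # deterministic output: writing twice gives identical bytes
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, path2)
  expect_identical(unname(tools::md5sum(path)), unname(tools::md5sum(path2)))
})

test_that("an empty matrix writes a header-only VCF", {
  gm <- geno_matrix(matrix(integer(), 2, 0),
                    sites = data.frame(chrom = character(), pos = integer(),
                                       ref = character(), alt = character()),
                    samples = data.frame(sample_id = c("a", "b")))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  lines <- readLines(path)
  expect_length(lines, 4)
  expect_match(lines[length(lines)], "^#CHROM")
})

test_that("filter_sites applies strict MAF and integrity rules and is idempotent", {
  # monomorphic site removed; 7/10 integrity removed at 0.8
  geno <- cbind(
    rep(0L, 10),                                   # MAF 0
    c(rep(1L, 7), rep(NA_integer_, 3)),            # integrity 0.7
    c(rep(0L, 5), rep(1L, 5))                      # keeper
  )
  gm <- toy_matrix(geno)
  kept <- filter_sites(gm, maf_min = 0.05, integrity_min = 0.8)
  expect_equal(n_sites(kept), 1L)
  expect_equal(attr(kept, "n_removed"), 2L)
  expect_equal(kept$sites$pos, gm$sites$pos[3])

  # brute-force per-site oracle on a random matrix
  withr::local_seed(42)
  gm <- random_matrix(50, 200, missing_rate = 0.25)
  kept <- filter_sites(gm, 0.1, 0.7)
  manual <- vapply(seq_len(200), function(s) {
    g <- gm$geno[, s]
    n <- sum(!is.na(g))
    p <- sum(g, na.rm = TRUE) / (2 * n)
    min(p, 1 - p) > 0.1 && n / 50 > 0.7
  }, logical(1))
  expect_equal(kept$sites$pos, gm$sites$pos[manual])
  twice <- filter_sites(kept, 0.1, 0.7)
  expect_identical(unname(twice$geno), unname(kept$geno))
  # zero samples is an error
  gm0 <- geno_matrix(matrix(integer(), 0, 0),
                     sites = data.frame(chrom = character(), pos = integer(),
                                        ref = character(), alt = character()),
                     samples = data.frame(sample_id = character()))
  expect_error(filter_sites(gm0), "zero samples")
})

test_that("make_windows matches the brute-force enumeration and covers the genome", {
  w <- make_windows(c(chr1 = 100e3), size = 50e3, step = 10e3)
  expect_equal(w$start0[1], 0)
  expect_equal(w$end0[1], 50e3)
  expect_equal(w$end0[6], 100e3)            # sixth window [50k, 100k)
  expect_equal(w$start0[nrow(w)], 90e3)     # terminal partial, span 10k
  expect_equal(w$end0[nrow(w)] - w$start0[nrow(w)], 10e3)

  w1 <- make_windows(c(chrA = 20e3), size = 20e3)
  expect_equal(nrow(w1), 1L)

  ob <- oracle_windows(123456, 25e3, 5e3)
  w2 <- make_windows(c(chr1 = 123456), size = 25e3, step = 5e3)
  expect_equal(unname(as.matrix(w2[, c("start0", "end0")])), unname(ob))
  # full coverage when step <= size
  covered <- merge_intervals(w2)
  expect_equal(covered$start0, 0L)
  expect_equal(covered$end0, 123456L)
  expect_error(make_windows(c(chr1 = 1e5), size = 1e3, step = 2e3), "step")
})

test_that("region-gene intersection honours half-open bounds and matches the quadratic oracle", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                          start0 = c(100L, 99L), end0 = c(200L, 200L),
                          strand = "+")
  region <- tibble::tibble(chrom = "chr1", start0 = 0L, end0 = 100L)
  expect_equal(intersect_regions(region, genes["g1" == genes$gene_id, ])$gene_id,
               character(0))
  expect_equal(intersect_regions(region, genes)$gene_id, "g2")

  withr::local_seed(7)
  rnd_iv <- function(n) {
    s <- sample.int(5e4, n)
    tibble::tibble(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                   start0 = s, end0 = s + sample.int(2e3, n))
  }
  regions <- rnd_iv(40)
  genes <- dplyr::mutate(rnd_iv(25), gene_id = sprintf("g%02d", 1:25),
                         strand = "*")
  got <- intersect_regions(regions, genes)
  exp_hits <- oracle_overlaps(regions, genes)
  expect_equal(nrow(got), NROW(exp_hits))
  got_keys <- sort(paste(got$start0, got$gene_id))
  exp_keys <- sort(paste(regions$start0[exp_hits[, 1]],
                         genes$gene_id[exp_hits[, 2]]))
  expect_equal(got_keys, exp_keys)
})

test_that("table readers validate their inputs", {
  md_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample_id\tpop_class\na\twild\nb\tcultivarish", md_path)
  expect_error(read_sample_metadata(md_path), "pop_class")
  writeLines("sample_id\tpop_class\na\twild\nb\tbreeding", md_path)
  expect_equal(nrow(read_sample_metadata(md_path)), 2)

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=geneA;Name=foo",
    "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=t1;Parent=geneA",
    "chr2\tsrc\tgene\t501\t900\t.\t-\t.\tID=geneB"
  ), gff)
  ann <- read_gene_annotation(gff)
  expect_equal(ann$gene_id, c("geneA", "geneB"))
  expect_equal(ann$start0, c(100L, 500L))   # 1-based closed -> 0-based half-open
  expect_equal(ann$end0, c(200L, 900L))
})
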