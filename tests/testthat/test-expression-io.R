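abundance_df <- function(n = 3) {
  m <- max(n, 1L)
  df <- data.frame(target_id = paste0("T", seq_len(m)),
                   length = 1000L + seq_len(m),
                   eff_length = 800 + seq_len(m),
                   est_counts = as.numeric(seq_len(m) * 10),
                   tpm = as.numeric(seq_len(m)),
                   stringsAsFactors = FALSE)
  df[seq_len(n), ]
}

test_that("read_abundance is strict about the dialect", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(abundance_df(2), path)
  rec <- read_abundance(path)
  expect_equal(nrow(rec), 2L)
  expect_type(rec$est_counts, "double")

  # missing eff_length column
  write_tsv(abundance_df(2)[, -3], path)
  expect_error(read_abundance(path), "malformed abundance header")

  # non-numeric field cites the line (header is line 1, so bad row 2 -> line 3)
  df <- abundance_df(3)
  df$est_counts[2] <- "NA"
  write_tsv(df, path)
  expect_error(read_abundance(path), "line 3")

  # empty file
  write_tsv(abundance_df(0), path)
  expect_error(read_abundance(path), "no data rows")
})

test_that("abundance files round-trip numerically to 6 significant digits", {
  set.seed(7)
  df <- abundance_df(50)
  df$est_counts <- stats::rexp(50) * 1000
  df$tpm <- stats::rexp(50) * 100
  path <- withr::local_tempfile(fileext = ".tsv")
  write_abundance(df, path)
  back <- read_abundance(path)
  expect_equal(signif(back$est_counts, 6), signif(df$est_counts, 6))
  expect_equal(signif(back$tpm, 6), signif(df$tpm, 6))
  expect_identical(back$target_id, df$target_id)
})

test_that("compute_tpm matches hand-derived values and always sums to 1e6", {
  # counts/eff_length rates (0.1, 0.05) scale to 1e6 * (2/3, 1/3)
  expect_equal(compute_tpm(c(10, 10), c(100, 200)),
               c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  expect_equal(compute_tpm(5, 123), 1e6)
  expect_identical(compute_tpm(c(0, 5), c(100, 100))[1], 0)

  set.seed(1)
  for (i in 1:20) {
    n <- sample(1:200, 1)
    counts <- stats::rpois(n, 50) + (if (i == 1) 1 else 0)
    if (all(counts == 0)) counts[1] <- 1
    eff <- stats::runif(n, 50, 5000)
    expect_lt(abs(sum(compute_tpm(counts, eff)) - 1e6) / 1e6, 1e-6)
  }

  expect_error(compute_tpm(c(0, 0), c(10, 10)), "all estimated counts")
  expect_error(compute_tpm(c(1, 1), c(10, 0)), "positive")
  expect_error(compute_tpm(c(1, 1), c(10)), "length")
})

test_that("compute_fpkm matches the hand-derived case and the TPM identity", {
  # 10 fragments over 1 kb in a 10-fragment library of 1e-5 millions
  expect_equal(compute_fpkm(10, 1000), 1e6)
  expect_identical(compute_fpkm(c(0, 8), c(100, 700))[1], 0)
  expect_error(compute_fpkm(c(0, 0), c(1, 1)), "zero total")

  set.seed(2)
  counts <- stats::rpois(100, 30)
  counts[counts == 0] <- 1
  eff <- stats::runif(100, 100, 3000)
  fpkm <- compute_fpkm(counts, eff)
  expect_equal(compute_tpm(counts, eff), fpkm / sum(fpkm) * 1e6,
               tolerance = 1e-12)
})

test_that("aggregate_to_genes sums member transcripts and drops unmapped ones", {
  t2g <- data.frame(transcript_id = c("t1", "t2", "t3"),
                    gene_id = c("g", "g", "h"), stringsAsFactors = FALSE)
  expect_equal(aggregate_to_genes(c(t1 = 5, t2 = 7, t3 = 2), t2g),
               c(g = 12, h = 2))
  # 1:1 mapping is the identity
  one <- data.frame(transcript_id = c("a", "b"), gene_id = c("ga", "gb"))
  expect_equal(aggregate_to_genes(c(a = 1.5, b = 2.5), one),
               c(ga = 1.5, gb = 2.5))
  # unmapped transcripts dropped with a logged count; mass conserved
  expect_message(out <- aggregate_to_genes(c(t1 = 1, zz = 9, t3 = 2), t2g),
                 "1 unmapped")
  expect_equal(sum(out), 3)
  expect_error(aggregate_to_genes(c(t1 = 1), t2g[0, ]), "empty")
})

test_that("aggregation agrees with an independent group-by oracle", {
  set.seed(3)
  tx <- paste0("t", 1:100)
  genes <- paste0("g", sample.int(10, 100, replace = TRUE))
  t2g <- data.frame(transcript_id = tx, gene_id = genes,
                    stringsAsFactors = FALSE)
  tpm <- stats::setNames(stats::rexp(100) * 10, tx)
  out <- aggregate_to_genes(tpm, t2g)
  oracle <- c(tapply(tpm, genes, sum))   # strip the 1-d array shape
  expect_equal(out[sort(names(out))], oracle[sort(names(oracle))],
               tolerance = 1e-12, ignore_attr = FALSE)
})

test_that("assemble_matrix outer-joins genes, zero-fills and rejects duplicates", {
  meta <- make_meta(1L)[1:2, ]
  gene_tpm <- list(c(A = 1, B = 2), c(A = 3, C = 4))
  names(gene_tpm) <- meta$sample_id
  expect_warning(mat <- assemble_matrix(gene_tpm, meta), "zero-filled")
  expect_equal(dim(mat$values), c(3L, 2L))
  expect_equal(mat$values["B", 2], 0)
  expect_equal(mat$values["C", 1], 0)
  expect_identical(colnames(mat$values), meta$sample_id)

  # identical gene lists: clean 2-column matrix, no warning
  gene_tpm2 <- list(c(A = 1, B = 2), c(A = 3, B = 4))
  names(gene_tpm2) <- meta$sample_id
  expect_silent(mat2 <- assemble_matrix(gene_tpm2, meta))
  expect_equal(mat2$values["B", ], c(2, 4), ignore_attr = TRUE)

  meta_dup <- rbind(meta, meta[1, ])
  expect_error(assemble_matrix(gene_tpm, meta_dup), "duplicate sample_id")
})

test_that("group_mean averages the matching replicates only", {
  meta <- make_meta(2L)
  values <- base::matrix(0, 1, 16, dimnames = list("G1", meta$sample_id))
  values[1, meta$genotype == "transgenic" & meta$stage == "DN2"] <- c(2, 4)
  mat <- expression_matrix(values, meta)
  expect_equal(unname(group_mean(mat, "transgenic", "DN2")), 3)
  expect_equal(unname(group_mean(mat, "wildtype", "DN2")), 0)
  expect_error(group_mean(mat, "transgenic", "DN5"), "no samples")

  set.seed(4)
  values3 <- base::matrix(stats::rexp(5 * 24), 5,
                          dimnames = list(paste0("G", 1:5), NULL))
  mat3 <- make_matrix(values3, make_meta(3L))
  sel <- mat3$samples$genotype == "wildtype" & mat3$samples$stage == "DN3"
  oracle <- apply(values3[, sel], 1, function(v) sum(v) / 3)
  expect_equal(group_mean(mat3, "wildtype", "DN3"), oracle)
})

test_that("expression matrices round-trip through TSV + sidecar", {
  set.seed(5)
  mat <- make_matrix(base::matrix(stats::rexp(6 * 8), 6,
                                  dimnames = list(paste0("G", 1:6), NULL)),
                     unit = "FPKM", species = "human")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(mat, path)
  back <- read_expression_matrix(path)
  expect_equal(back$values, mat$values, tolerance = 1e-12)
  expect_identical(back$unit, "FPKM")
  expect_identical(back$species, "human")
  expect_identical(back$samples, mat$samples)
})
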