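test_that("classify_expression implements the documented bins and boundaries", {
  expect_identical(as.character(classify_expression(0.05)), "ZERO")
  expect_identical(as.character(classify_expression(15)), "HIGH")
  # decided boundary convention: [0,0.1) / [0.1,1) / [1,10] / (10,Inf)
  expect_identical(as.character(classify_expression(c(0, 0.1, 1, 10, 10.0001))),
                   c("ZERO", "LOW", "MED", "MED", "HIGH"))
  expect_error(classify_expression(-1), "non-negative")
  expect_error(classify_expression(Inf), "finite")
})

test_that("classify_expression is total and monotone over random TPM values", {
  set.seed(10)
  tpm <- sort(c(0, stats::rexp(500) * 30, 0.1, 1, 10))
  cls <- classify_expression(tpm)
  expect_false(anyNA(cls))
  expect_true(all(diff(as.integer(cls)) >= 0))
})

test_that("tile_matrix counts class transitions and conserves genes", {
  tg <- base::matrix(c(15, 2, 0.5), 3, 4,
                     dimnames = list(NULL, c("DN1", "DN2", "DN3", "DN4")))
  wt <- base::matrix(c(0.05, 2, 0.5), 3, 4, dimnames = dimnames(tg))
  mat <- make_matrix_from_means(tg, wt)
  tile <- tile_matrix(mat, "DN1")
  expect_equal(tile$counts["ZERO", "HIGH"], 1L)
  expect_equal(tile$counts["MED", "MED"], 1L)
  expect_equal(tile$counts["LOW", "LOW"], 1L)
  expect_equal(sum(tile$counts), 3L)
  expect_equal(tile$n_genes, 3L)

  # empty matrix: all-zero tiles
  empty <- subset_genes(mat, character())
  tile0 <- tile_matrix(empty, "DN2")
  expect_equal(sum(tile0$counts), 0L)
  expect_equal(tile0$n_genes, 0L)
})

test_that("tile conservation holds on random matrices with marginal histograms", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(20:400, 1)
    tg <- base::matrix(stats::rexp(n * 4) * 20, n,
                       dimnames = list(NULL, c("DN1", "DN2", "DN3", "DN4")))
    wt <- base::matrix(stats::rexp(n * 4) * 20, n, dimnames = dimnames(tg))
    mat <- make_matrix_from_means(tg, wt)
    for (st in c("DN1", "DN3")) {
      tile <- tile_matrix(mat, st)
      expect_equal(sum(tile$counts), n)
      wt_hist <- table(classify_expression(wt[, st]))
      tg_hist <- table(classify_expression(tg[, st]))
      expect_equal(unname(rowSums(tile$counts)), as.vector(wt_hist))
      expect_equal(unname(colSums(tile$counts)), as.vector(tg_hist))
    }
  }
})

test_that("call_differential applies the strict gates", {
  expect_identical(call_differential(25, 2), "up")
  expect_identical(call_differential(5, 0), "up")    # no division by zero
  expect_identical(call_differential(15, 1.5), "none")  # 15 not > 10*1.5
  expect_identical(call_differential(0.5, 0.01), "none")  # fails mean gate
  expect_identical(call_differential(2, 25), "down")
  expect_identical(call_differential(1, 0), "none")  # 1 not > 1
  expect_error(call_differential(-1, 0), "non-negative")
})

test_that("call_differential is antisymmetric under genotype swap", {
  set.seed(12)
  a <- stats::rexp(10000) * 20
  b <- stats::rexp(10000) * 20
  a[sample.int(10000, 500)] <- 0
  b[sample.int(10000, 500)] <- 0
  ab <- call_differential(a, b)
  ba <- call_differential(b, a)
  expect_identical(ab == "up", ba == "down")
  expect_identical(ab == "down", ba == "up")
  expect_false(any(ab == "up" & ab == "down"))
})

test_that("differential_by_stage screens each stage with the group means", {
  # one gene constitutively up, one flat, one down at DN2 only
  genes <- c("UP", "FLAT", "DOWN2")
  tg <- base::matrix(c(25, 5, 5), 3, 4,
                     dimnames = list(genes, c("DN1", "DN2", "DN3", "DN4")))
  wt <- base::matrix(c(2, 5, 5), 3, 4, dimnames = dimnames(tg))
  wt["DOWN2", "DN2"] <- 80
  tg["DOWN2", "DN2"] <- 5
  mat <- make_matrix_from_means(tg, wt, gene_ids = genes)
  res <- differential_by_stage(mat)
  for (st in c("DN1", "DN2", "DN3", "DN4")) {
    expect_identical(res$stages[[st]]$up, "UP")
  }
  expect_identical(res$stages$DN2$down, "DOWN2")
  expect_identical(res$stages$DN1$down, character(0))
  expect_equal(sum(res$calls$direction == "up"), 4L)

  # identical genotypes: all sets empty
  same <- make_matrix_from_means(tg, tg, gene_ids = genes)
  res0 <- differential_by_stage(same)
  expect_true(all(vapply(res0$stages, function(s)
    length(s$up) + length(s$down), integer(1)) == 0L))
})

test_that("venn_partition matches the exhaustive signature oracle", {
  stages <- c("DN1", "DN2", "DN3", "DN4")
  oracle <- function(sets) {
    genes <- unique(unlist(sets))
    out <- list()
    for (g in genes) {
      sig <- paste(stages[vapply(sets, function(s) g %in% s, logical(1))],
                   collapse = "&")
      out[[sig]] <- c(out[[sig]], g)
    }
    lapply(out, sort)
  }
  set.seed(13)
  for (rep in 1:200) {
    universe <- paste0("g", seq_len(sample.int(20, 1)))
    sets <- lapply(stages, function(s)
      sample(universe, sample.int(length(universe) + 1, 1) - 1))
    names(sets) <- stages
    vp <- venn_partition(sets)
    exp <- oracle(sets)
    nonempty <- vp$regions[vapply(vp$regions, length, integer(1)) > 0]
    expect_identical(lapply(nonempty, sort), exp[names(nonempty)])
    # disjoint and exhaustive
    all_genes <- unlist(vp$regions, use.names = FALSE)
    expect_false(anyDuplicated(all_genes) > 0)
    expect_setequal(all_genes, unique(unlist(sets)))
    expect_length(vp$regions, 15L)
  }
})

test_that("venn_partition degenerate shapes behave as stated", {
  stages <- c("DN1", "DN2", "DN3", "DN4")
  same <- stats::setNames(rep(list(c("a", "b")), 4), stages)
  vp <- venn_partition(same)
  expect_equal(vp$all_four, 2L)
  expect_equal(sum(vp$counts), 2L)

  disjoint <- stats::setNames(list("a", "b", "c", "d"), stages)
  vp2 <- venn_partition(disjoint)
  expect_equal(unname(vp2$counts[stages]), rep(1L, 4))
  expect_equal(sum(vp2$counts), 4L)
  expect_equal(vp2$all_four, 0L)
})

test_that("select_candidates gates on best stage mean and any-stage fold", {
  genes <- c("HIT", "LOWEXP", "NOFOLD")
  tg <- base::matrix(c(30, 15, 30), 3, 4,
                     dimnames = list(genes, c("DN1", "DN2", "DN3", "DN4")))
  tg["HIT", ] <- c(30, 40, 35, 25)
  wt <- base::matrix(c(2, 1, 30), 3, 4, dimnames = dimnames(tg))
  wt["HIT", ] <- c(2, 3, 4, 5)
  mat <- make_matrix_from_means(tg, wt, gene_ids = genes)
  out <- select_candidates(mat)
  expect_identical(out$gene_id[out$selected], "HIT")
  expect_equal(out$max_mean_tg[out$gene_id == "HIT"], 40)
  # LOWEXP fails the TPM gate despite infinite fold at wt ~ small
  expect_false(out$selected[out$gene_id == "LOWEXP"])
  expect_false(out$selected[out$gene_id == "NOFOLD"])
  expect_error(select_candidates(mat, min_mean_tpm = -1), "positive")
})

test_that("expression_call is strictly greater-than", {
  expect_false(expression_call(4.0))
  expect_true(expression_call(4.1))
  expect_false(expression_call(0))
  expect_identical(expression_call(c(3, 5), threshold = 4), c(FALSE, TRUE))
  expect_error(expression_call(-0.1), "non-negative")
})

test_that("marker_summary produces a tidy table and cohort expressed fraction", {
  meta <- make_meta(1L)[c(1, 5), ]   # 2 samples
  values <- base::matrix(c(5, 7), 1, 2, dimnames = list("G1", NULL))
  mat <- make_matrix(values, meta)
  ms <- marker_summary(mat, "G1")
  expect_equal(nrow(ms$values), 2L)
  expect_identical(names(ms$values),
                   c("gene_id", "sample_id", "genotype", "stage",
                     "replicate", "value"))

  # cohort [5, 3, 4.5, 1] at threshold 4 -> 2 of 4 expressed
  meta4 <- make_meta(1L)[c(1, 2, 5, 6), ]
  mat4 <- make_matrix(base::matrix(c(5, 3, 4.5, 1), 1, 4,
                                   dimnames = list("G1", NULL)), meta4)
  ms4 <- marker_summary(mat4, "G1")
  expect_equal(unname(ms4$expressed_fraction["G1"]), 0.5)

  # absent gene: warning, empty rows for it
  expect_warning(none <- marker_summary(mat4, c("G1", "GX")), "GX")
  expect_false("GX" %in% none$values$gene_id)
})
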