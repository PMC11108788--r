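# Fixtures are built in code, deterministically where no seed is given.

make_sce <- function(counts, modality = "cell", doublet = NULL, extra = list()) {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%04d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("c%04d", seq_len(ncol(counts)))
  }
  cd <- S4Vectors::DataFrame(
    barcode = colnames(counts),
    modality = rep_len(modality, ncol(counts)),
    row.names = colnames(counts))
  if (!is.null(doublet)) cd$doublet_score <- doublet
  for (nm in names(extra)) cd[[nm]] <- extra[[nm]]
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = cd)
}

# 1,000-cell QC fixture with one planted violation class per block of
# cells, plus boundary cells sitting exactly on each threshold. Returns
# the matrix and the analytically expected outcome per cell.
planted_qc_fixture <- function() {
  n_genes <- 6000
  mito_idx <- c(5999L, 6000L)
  cells <- list()
  expect_kept <- logical(0)
  fail_rule <- character(0)
  doublet <- numeric(0)

  add <- function(n, n_expr, count_per_gene, mito_counts, dbl, kept, rule) {
    for (i in seq_len(n)) {
      cells[[length(cells) + 1]] <<- list(n_expr = n_expr,
                                          cpg = count_per_gene,
                                          mito = mito_counts)
      expect_kept <<- c(expect_kept, kept)
      fail_rule <<- c(fail_rule, rule)
      doublet <<- c(doublet, dbl)
    }
  }

  # clean cells: 600 genes x 2 counts, no mito, low doublet
  add(880, 600, 2, 0, 0.1, TRUE, "none")
  # doublet violations (also fail nothing else)
  add(20, 600, 2, 0, 0.401, FALSE, "doublet")
  # boundary doublet exactly 0.4 -> kept
  add(10, 600, 2, 0, 0.4, TRUE, "none")
  # low genes: 499 expressed (counts 998 >= 700 so only the gene rule fails)
  add(20, 499, 2, 0, 0.1, FALSE, "genes")
  # boundary: exactly 500 genes, 2 each -> kept
  add(10, 500, 2, 0, 0.1, TRUE, "none")
  # high genes: 5001 expressed at 1 count
  add(10, 5001, 1, 0, 0.1, FALSE, "genes")
  # low counts: 500 genes x 1 = 500 < 700
  add(20, 500, 1, 0, 0.1, FALSE, "counts")
  # boundary: 700 counts exactly (500 genes, 350 at 1 and 150 at... use 1.4?)
  # use 700 genes x 1 count = 700 counts exactly -> kept
  add(10, 700, 1, 0, 0.1, TRUE, "none")
  # mito violation for cells: fraction 1200*0.  -> mito 160 of 1360 ~ 0.1176
  add(10, 600, 2, 160, 0.1, FALSE, "mito")
  # boundary mito exactly 10%: 1200 non-mito (598 genes x 2 + 2 mito genes
  # counted among expressed) -> use 600 genes x 2 = 1200 plus mito 133.33 no;
  # 1206 total with mito 120 -> 120/1320 = 0.0909 kept; make exact: non-mito
  # 1080 (540 genes x 2), mito 120 -> fraction 0.1 exactly -> kept
  add(5, 540, 2, 120, 0.1, TRUE, "none")
  # attribution: doublet AND low genes -> attributed to doublet
  add(5, 499, 2, 0, 0.5, FALSE, "doublet")

  n_cells <- length(cells)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_len(n_cells)) {
    cl <- cells[[j]]
    genes <- seq_len(cl$n_expr)
    ii <- c(ii, genes); jj <- c(jj, rep(j, length(genes)))
    xx <- c(xx, rep(cl$cpg, length(genes)))
    if (cl$mito > 0) {
      ii <- c(ii, mito_idx[1]); jj <- c(jj, j); xx <- c(xx, cl$mito)
    }
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(n_genes, n_cells))
  rownames(m) <- c(sprintf("g%04d", seq_len(n_genes - 2)), "MT-A", "MT-B")
  colnames(m) <- sprintf("c%04d", seq_len(n_cells))
  sce <- make_sce(m, modality = "cell", doublet = doublet)
  list(sce = sce, kept = expect_kept, rule = fail_rule,
       mito_genes = c("MT-A", "MT-B"))
}

# small expression dataset shared by deg tests (built once per test run)
deg_test_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      des <- simulate_composition(composition_truth(n_donors = 8), 11)$samples
      truth <- expression_truth(n_genes = 60, deg_indices = 1:5,
                                deg_log2fc = 1.5, n_cells_per_sample = 120)
      sce <- simulate_expression(truth, des, 12)
      cache <<- list(sce = sce, truth = truth, design = des)
    }
    cache
  }
})
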