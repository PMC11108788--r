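test_that("composition generator is deterministic in (truth, seed)", {
  tr <- composition_truth(age_logfc = c(0.5, rep(0, 7)))
  a <- simulate_composition(tr, 42)
  b <- simulate_composition(tr, 42)
  expect_identical(a, b)
  c <- simulate_composition(tr, 43)
  expect_false(identical(a$composition$count, c$composition$count))
})

test_that("null composition model gives equal means across age groups", {
  tr <- composition_truth(cell_types = paste0("CT", 1:4),
                          n_donors = 25, libraries_per_donor = 2,
                          age_logfc = 0,
                          re_sd = c(sample = 0, chemistry = 0, modality = 0,
                                    chemistry_celltype = 0,
                                    modality_celltype = 0,
                                    sample_celltype = 0))
  sim <- simulate_composition(tr, 7)
  df <- merge(sim$composition, sim$samples, by = "sample")
  for (ct in unique(df$cell_type)) {
    young <- df$count[df$cell_type == ct & df$age_group == "young"]
    aged <- df$count[df$cell_type == ct & df$age_group == "aged"]
    se <- sqrt(var(young) / length(young) + var(aged) / length(aged))
    expect_lt(abs(mean(young) - mean(aged)), 3 * se + 1e-9)
  }
})

test_that("planted age effect of 1.0 gives ~e^2 mean ratio across +/-1 SD", {
  # two donor ages exactly +/- 1 SD apart after standardization
  tr <- composition_truth(cell_types = c("A", "B"),
                          n_donors = 60, libraries_per_donor = 1,
                          age_logfc = c(1, 0),
                          re_sd = c(sample = 0),
                          ages = rep(c(30, 70), each = 30))
  sim <- simulate_composition(tr, 3)
  df <- merge(sim$composition, sim$samples, by = "sample")
  stopifnot(all(abs(abs(scale(sim$samples$age_years)) - 1) < 0.05))

  # independent Monte-Carlo oracle of the log-rate formula
  set.seed(99)
  ages_s <- (df$age_years - mean(tr$ages)) / sd(tr$ages)
  oracle <- replicate(200, {
    y <- rpois(nrow(df), exp(log(150) + 1 * ages_s * (df$cell_type == "A")))
    mean(y[df$cell_type == "A" & df$age_group == "aged"]) /
      mean(y[df$cell_type == "A" & df$age_group == "young"])
  })
  expect_lt(abs(mean(oracle) - exp(2 * sd(scale(tr$ages)))), 0.2)

  a_aged <- df$count[df$cell_type == "A" & df$age_group == "aged"]
  a_young <- df$count[df$cell_type == "A" & df$age_group == "young"]
  ratio <- mean(a_aged) / mean(a_young)
  expect_lt(abs(ratio - mean(oracle)), 3 * sd(oracle) + 3 * sd(oracle) / sqrt(200))
  expect_gt(ratio, exp(2) * 0.8)
  expect_lt(ratio, exp(2) * 1.2)
})

test_that("non-finite log-rate is rejected with a clear message", {
  # the constructor already refuses non-finite baselines ...
  expect_error(composition_truth(baseline_log_abundance = c(Inf, log(100))),
               "finite")
  expect_error(composition_truth(age_logfc = NaN), "finite")
  # ... and the generator guards against corrupted truth objects
  tr <- composition_truth()
  tr$baseline_log_abundance[1] <- NaN
  expect_error(simulate_composition(tr, 1), "non-finite log-rate")
})

test_that("expression generator is deterministic and emits ground truth", {
  des <- simulate_composition(composition_truth(n_donors = 4), 5)$samples
  tr <- expression_truth(n_genes = 30, n_cells_per_sample = 20,
                         deg_indices = 1:3, deg_log2fc = 1)
  a <- simulate_expression(tr, des, 9)
  b <- simulate_expression(tr, des, 9)
  expect_identical(SummarizedExperiment::assay(a, "counts"),
                   SummarizedExperiment::assay(b, "counts"))
  rd <- SummarizedExperiment::rowData(a)
  expect_identical(which(rd$is_deg), 1:3)
  expect_true(all(rd$deg_log2fc[1:3] == 1))
  expect_true(any(rd$is_mito))
  expect_setequal(c("MYH7", "MYH2", "MYH1"),
                  intersect(rownames(a), c("MYH7", "MYH2", "MYH1")))
})

test_that("null expression truth centers empirical log fold changes at 0", {
  des <- simulate_composition(composition_truth(n_donors = 8), 21)$samples
  tr <- expression_truth(n_genes = 100, n_cells_per_sample = 60,
                         donor_re_sd = 0, lib_factor_sd = 0)
  sce <- simulate_expression(tr, des, 22)
  m <- SummarizedExperiment::assay(sce, "counts")[1:100, ]
  aged <- SummarizedExperiment::colData(sce)$age_group == "aged"
  lfc <- log2((Matrix::rowMeans(m[, aged]) + 0.1) /
              (Matrix::rowMeans(m[, !aged]) + 0.1))
  expect_lt(abs(mean(lfc)), 0.05)
})

test_that("dispersion -> Inf approaches the Poisson variance/mean ratio", {
  des <- simulate_composition(composition_truth(n_donors = 4), 31)$samples
  tr <- expression_truth(n_genes = 50, n_cells_per_sample = 400,
                         dispersion = 1e8, donor_re_sd = 0, lib_factor_sd = 0)
  sce <- simulate_expression(tr, des, 32)
  m <- as.matrix(SummarizedExperiment::assay(sce, "counts")[1:50, ])
  vm <- apply(m, 1, var) / pmax(rowMeans(m), 1e-9)
  # var/mean of Poisson samples: ratio ~ 1 +/- sqrt(2/(n-1)) roughly
  expect_lt(abs(median(vm) - 1), 0.1)

  tr2 <- expression_truth(n_genes = 50, n_cells_per_sample = 400,
                          dispersion = 0.5, donor_re_sd = 0, lib_factor_sd = 0)
  m2 <- as.matrix(SummarizedExperiment::assay(
    simulate_expression(tr2, des, 32), "counts")[1:50, ])
  vm2 <- apply(m2, 1, var) / pmax(rowMeans(m2), 1e-9)
  expect_gt(median(vm2), median(vm))  # overdispersed case clearly above
})

test_that("spiked gene recovers 2^1.5 empirical mean ratio", {
  des <- simulate_composition(composition_truth(n_donors = 8), 41)$samples
  tr <- expression_truth(n_genes = 40, n_cells_per_sample = 250,
                         deg_indices = 1L, deg_log2fc = 1.5,
                         donor_re_sd = 0, lib_factor_sd = 0)
  sce <- simulate_expression(tr, des, 42)
  y <- as.numeric(SummarizedExperiment::assay(sce, "counts")[1, ])
  aged <- SummarizedExperiment::colData(sce)$age_group == "aged"
  ratio <- mean(y[aged]) / mean(y[!aged])
  se_ratio <- ratio * sqrt(var(y[aged]) / (sum(aged) * mean(y[aged])^2) +
                           var(y[!aged]) / (sum(!aged) * mean(y[!aged])^2))
  expect_lt(abs(ratio - 2^1.5), 3 * se_ratio)
})

test_that("invalid expression truths and designs are rejected", {
  expect_error(expression_truth(deg_log2fc = 1), "deg_indices")
  expect_error(expression_truth(deg_indices = 300, n_genes = 200), "subset")
  expect_error(expression_truth(dispersion = 0), "> 0")
  des <- simulate_composition(composition_truth(n_donors = 4), 5)$samples
  young_only <- des[des$age_group == "young", ]
  expect_error(simulate_expression(expression_truth(), young_only, 1),
               "age groups")
})

test_that("fixture tables are internally consistent and round-trip", {
  fx <- make_fixture_tables(77)
  universe <- sprintf("gene%04d", 1:200)
  expect_true(all(fx$homologs$human_gene %in% universe))
  expect_true(all(vapply(fx$gene_sets, function(s) all(s %in% universe), TRUE)))
  expect_true(all(lengths(fx$gene_sets) >= 5 & lengths(fx$gene_sets) <= 50))
  expect_gte(nrow(fx$lr_pairs), 10)
  expect_identical(fx, make_fixture_tables(77))

  path <- tempfile(fileext = ".gmt")
  write_gmt(fx$gene_sets, path)
  expect_identical(read_gmt(path), fx$gene_sets)
  # independent reader cross-check
  skip_if_not_installed("fgsea")
  expect_identical(lapply(fgsea::gmtPathways(path), unname), fx$gene_sets)
})

test_that("duplicated ligand-receptor pairs are deduplicated with warning", {
  lr <- data.frame(interaction_id = c("a", "b", "c"),
                   ligand = c("L1", "L1", "L2"),
                   receptor_subunits = c("R1", "R1", "R2;R3"))
  expect_warning(out <- validate_lr_pairs(lr), "duplicated")
  expect_equal(nrow(out), 2)
  expect_silent(validate_lr_pairs(out))
})

test_that("MTX round-trip preserves counts and metadata", {
  des <- simulate_composition(composition_truth(n_donors = 4), 5)$samples
  sce <- simulate_expression(expression_truth(n_genes = 20,
                                              n_cells_per_sample = 10),
                             des, 6)
  d <- tempfile()
  write_mtx_dir(sce, d)
  back <- read_mtx_dir(d)
  expect_equal(as.matrix(SummarizedExperiment::assay(back, "counts")),
               as.matrix(SummarizedExperiment::assay(sce, "counts")))
  expect_identical(back$donor, sce$donor)
  unlink(d, recursive = TRUE)
})
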