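#' @importFrom stats rpois rnbinom rnorm runif rbeta setNames
NULL

#' Run code under a fixed RNG seed without disturbing the session RNG
#'
#' @param seed non-negative integer seed
#' @param code expression to evaluate
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0, seed == floor(seed))
  withr::with_seed(as.integer(seed %% .Machine$integer.max), code)
}

#' Derive a named sub-seed from a global seed
#'
#' Each pipeline stage draws from its own substream so toggling one stage
#' does not perturb another's randomness.
#'
#' @param seed global integer seed
#' @param stream stage name
#' @return integer seed below 2^31
#' @export
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

#' Ground truth for the composition generator
#'
#' Defines the generative counterpart of the hierarchical Poisson model of
#' cell-type abundance: per-cell-type baseline log-abundance, a per-cell-type
#' age effect (natural-log scale per 1 SD of age), and Gaussian random
#' effects on the log scale for library, chemistry, modality and their
#' cell-type interactions.
#'
#' Defaults describe the study conditions the generator emulates: a
#' multi-donor two-age-group cohort, two 10x libraries per donor (technical
#' replicates), mixed cell/nucleus modalities and v2/v3 chemistries. Donor
#' ages are part of the truth (deterministic, evenly spaced within the young
#' 20-45 and aged 60-85 ranges) so the planted effect size has a fixed
#' meaning in years.
#'
#' @param cell_types character vector of cell-type labels
#' @param n_donors number of donors (half young, half aged)
#' @param libraries_per_donor 10x libraries per donor
#' @param baseline_log_abundance per-cell-type log expected count per library
#'   (recycled)
#' @param age_logfc per-cell-type age effect, natural log per 1 SD of age
#'   (recycled)
#' @param re_sd named numeric vector of random-effect standard deviations;
#'   recognized names: sample, chemistry, modality, chemistry_celltype,
#'   modality_celltype, sample_celltype
#' @param ages per-donor ages in years; default evenly spaced in the two
#'   age-group ranges
#' @return object of class `composition_truth`
#' @export
composition_truth <- function(cell_types = paste0("CT", 1:8),
                              n_donors = 20,
                              libraries_per_donor = 2,
                              baseline_log_abundance = log(150),
                              age_logfc = 0,
                              re_sd = c(sample = 0.2, chemistry = 0.05,
                                        modality = 0.05,
                                        chemistry_celltype = 0.05,
                                        modality_celltype = 0.05,
                                        sample_celltype = 0.1),
                              ages = NULL) {
  k <- length(cell_types)
  stopifnot(k >= 1, n_donors >= 2, libraries_per_donor >= 1)
  baseline <- rep_len(baseline_log_abundance, k)
  logfc <- rep_len(age_logfc, k)
  if (!all(is.finite(logfc))) stop("age_logfc must be finite")
  if (!all(is.finite(baseline))) stop("every cell type needs a finite baseline")
  if (any(re_sd < 0)) stop("re_sd values must be >= 0")
  if (is.null(ages)) {
    n_young <- ceiling(n_donors / 2)
    n_aged <- n_donors - n_young
    ages <- c(seq(20, 45, length.out = n_young),
              seq(60, 85, length.out = max(n_aged, 1))[seq_len(n_aged)])
  }
  stopifnot(length(ages) == n_donors, all(is.finite(ages)))
  structure(list(cell_types = cell_types,
                 n_donors = n_donors,
                 libraries_per_donor = libraries_per_donor,
                 baseline_log_abundance = setNames(baseline, cell_types),
                 age_logfc = setNames(logfc, cell_types),
                 re_sd = re_sd,
                 ages = ages),
            class = "composition_truth")
}

re_sd_value <- function(truth, name) {
  if (name %in% names(truth$re_sd)) unname(truth$re_sd[[name]]) else 0
}

#' Build the library-level design implied by a composition truth
#'
#' Modality alternates within a donor's libraries and chemistry alternates
#' across donors, keeping the technical design balanced with respect to age.
#' @noRd
composition_design <- function(truth) {
  n_lib <- truth$n_donors * truth$libraries_per_donor
  donor_idx <- rep(seq_len(truth$n_donors), each = truth$libraries_per_donor)
  lib_within <- rep(seq_len(truth$libraries_per_donor), times = truth$n_donors)
  data.frame(
    sample = sprintf("lib%03d", seq_len(n_lib)),
    donor = sprintf("donor%02d", donor_idx),
    age_years = truth$ages[donor_idx],
    age_group = ifelse(truth$ages[donor_idx] >= 55, "aged", "young"),
    modality = c("cell", "nucleus")[1 + (lib_within - 1 + donor_idx - 1) %% 2],
    chemistry = c("v2", "v3")[1 + (donor_idx - 1) %% 2],
    sex = c("M", "F")[1 + donor_idx %% 2],
    stringsAsFactors = FALSE
  )
}

#' Simulate a cell-type composition table
#'
#' Draws Poisson counts for every (cell type x library) pair with
#' log-rate = baseline + age_logfc * scaled_age + random effects for
#' library, chemistry, modality and their cell-type interactions — the
#' generative mirror of the Poisson mixed model fitted by
#' [fit_composition_glmm()]. Age is standardized across libraries, the same
#' convention the fitter uses.
#'
#' @param truth a [composition_truth()] object
#' @param seed integer seed; identical (truth, seed) gives identical output
#' @return list with `composition` (cell_type, sample, count; all pairs
#'   materialized) and `samples` (library-level covariates)
#' @export
simulate_composition <- function(truth, seed) {
  stopifnot(inherits(truth, "composition_truth"))
  design <- composition_design(truth)
  k <- length(truth$cell_types)
  n_lib <- nrow(design)
  age_scaled <- as.numeric(scale(design$age_years))

  with_seed(seed, {
    u_sample <- rnorm(n_lib, 0, re_sd_value(truth, "sample"))
    u_chem <- setNames(rnorm(2, 0, re_sd_value(truth, "chemistry")), c("v2", "v3"))
    u_mod <- setNames(rnorm(2, 0, re_sd_value(truth, "modality")), c("cell", "nucleus"))
    u_cc <- matrix(rnorm(2 * k, 0, re_sd_value(truth, "chemistry_celltype")),
                   nrow = 2, dimnames = list(c("v2", "v3"), truth$cell_types))
    u_mc <- matrix(rnorm(2 * k, 0, re_sd_value(truth, "modality_celltype")),
                   nrow = 2, dimnames = list(c("cell", "nucleus"), truth$cell_types))
    u_sc <- matrix(rnorm(n_lib * k, 0, re_sd_value(truth, "sample_celltype")),
                   nrow = n_lib, dimnames = list(design$sample, truth$cell_types))

    grid <- expand.grid(cell_type = truth$cell_types, lib = seq_len(n_lib),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    ct <- grid$cell_type
    li <- grid$lib
    log_rate <- truth$baseline_log_abundance[ct] +
      truth$age_logfc[ct] * age_scaled[li] +
      u_sample[li] +
      u_chem[design$chemistry[li]] +
      u_mod[design$modality[li]] +
      u_cc[cbind(design$chemistry[li], ct)] +
      u_mc[cbind(design$modality[li], ct)] +
      u_sc[cbind(li, match(ct, truth$cell_types))]
    if (!all(is.finite(log_rate))) {
      stop("non-finite log-rate in composition generator; check baselines and effects")
    }
    counts <- rpois(length(log_rate), exp(log_rate))
    composition <- data.frame(cell_type = ct,
                              sample = design$sample[li],
                              count = counts,
                              stringsAsFactors = FALSE)
    list(composition = composition, samples = design)
  })
}

#' Ground truth for the expression generator
#'
#' Describes a cell-by-gene negative binomial count matrix with planted
#' aging differential expression: spiked genes have their mean multiplied by
#' `2^deg_log2fc` in aged cells; per-gene dispersion follows the
#' (mean, dispersion) NB parameterization with variance mu + mu^2/dispersion;
#' donors get per-gene Gaussian log-scale intercepts; each cell gets a
#' lognormal(0, 0.3^2) library-depth factor.
#'
#' Gene universe: `n_genes` generic genes plus designated MYH marker genes
#' (MYH7/MYH2/MYH1, whose means follow `myh_profile` per cluster),
#' mitochondrial genes (MT-*) whose per-cell share targets a fraction drawn
#' from `mito_fraction_range`, and `n_background_genes` stable background
#' genes (BG-*) carrying `background_mass` expected counts per cell in
#' total. The background emulates the bulk of a real transcriptome that a
#' small analysis panel sits inside: it gives cells realistic library sizes
#' and keeps the log library-size offset insensitive to the planted spikes
#' (without it, up-spiking 5% of a small panel deflates every null gene
#' through the offset — a compositional artifact real data of ~20k genes
#' do not show at this magnitude).
#'
#' @param n_genes number of generic (non-marker, non-mito) genes
#' @param n_cells_per_sample cells drawn per library
#' @param deg_indices integer indices (into the generic genes) of spiked genes
#' @param deg_log2fc log2 fold change per spiked gene (recycled)
#' @param dispersion per-gene NB dispersion (> 0, recycled)
#' @param donor_re_sd SD of per-donor per-gene log-scale intercepts
#' @param lib_factor_sd SD of the per-cell lognormal depth factor
#' @param myh_profile 3 x n_cluster matrix of expected MYH7/MYH2/MYH1 counts
#' @param clusters cluster labels cells are assigned to
#' @param cluster_prob cluster assignment probabilities
#' @param mito_fraction_range range of per-cell target mitochondrial fraction
#' @param n_mito_genes number of MT- genes carrying the mitochondrial mass
#' @param background_mass total expected background counts per cell
#' @param n_background_genes number of BG- genes sharing that mass equally
#' @return object of class `expression_truth`
#' @export
expression_truth <- function(n_genes = 200,
                             n_cells_per_sample = 250,
                             deg_indices = integer(),
                             deg_log2fc = numeric(),
                             dispersion = 2,
                             donor_re_sd = 0.1,
                             lib_factor_sd = 0.3,
                             myh_profile = default_myh_profile(),
                             clusters = colnames(default_myh_profile()),
                             cluster_prob = NULL,
                             mito_fraction_range = c(0.005, 0.05),
                             n_mito_genes = 5,
                             background_mass = 3000,
                             n_background_genes = 30) {
  stopifnot(n_genes >= 1, n_cells_per_sample >= 1, donor_re_sd >= 0,
            lib_factor_sd >= 0, n_mito_genes >= 1,
            background_mass >= 0, n_background_genes >= 1)
  deg_indices <- as.integer(deg_indices)
  if (length(deg_indices) && (min(deg_indices) < 1 || max(deg_indices) > n_genes)) {
    stop("deg_indices must be a subset of the generic gene indices")
  }
  if (length(deg_log2fc) && !length(deg_indices)) {
    stop("deg_log2fc given for genes not in deg_indices")
  }
  deg_log2fc <- rep_len(if (length(deg_log2fc)) deg_log2fc else 0, length(deg_indices))
  dispersion <- rep_len(dispersion, n_genes)
  if (any(dispersion <= 0)) stop("dispersion must be > 0")
  stopifnot(nrow(myh_profile) == 3, length(clusters) == ncol(myh_profile))
  if (is.null(cluster_prob)) cluster_prob <- rep(1 / length(clusters), length(clusters))
  stopifnot(length(mito_fraction_range) == 2,
            all(mito_fraction_range >= 0), all(mito_fraction_range <= 1))
  structure(list(n_genes = n_genes,
                 n_cells_per_sample = n_cells_per_sample,
                 deg_indices = deg_indices,
                 deg_log2fc = deg_log2fc,
                 dispersion = dispersion,
                 donor_re_sd = donor_re_sd,
                 lib_factor_sd = lib_factor_sd,
                 myh_profile = myh_profile,
                 clusters = clusters,
                 cluster_prob = cluster_prob,
                 mito_fraction_range = mito_fraction_range,
                 n_mito_genes = n_mito_genes,
                 background_mass = background_mass,
                 n_background_genes = n_background_genes),
            class = "expression_truth")
}

#' Default per-cluster expected expression of the three MYH marker genes
#'
#' Rows MYH7/MYH2/MYH1 (slow type I, fast IIA, fast IIX); columns are
#' myonucleus clusters: pure type I, pure type II, and a IIA/IIX hybrid.
#' @return 3 x 3 numeric matrix of expected raw counts
#' @export
default_myh_profile <- function() {
  m <- cbind("MF-I" = c(25, 0.1, 0.05),
             "MF-II" = c(0.1, 25, 8),
             "MF-Hyb" = c(8, 8, 8))
  rownames(m) <- c("MYH7", "MYH2", "MYH1")
  m
}

#' Simulate a cell-by-gene count matrix with planted aging effects
#'
#' Negative binomial counts per the generative model described in
#' [expression_truth()]. Cells are drawn per library of `design` (one row
#' per library with donor, age_group, modality, chemistry — the shape
#' produced by [simulate_composition()]`$samples`).
#'
#' @param truth an [expression_truth()] object
#' @param design library-level metadata table; needs >= 2 age groups and
#'   >= 2 donors per group
#' @param seed integer seed
#' @return a [SingleCellExperiment::SingleCellExperiment] with sparse integer
#'   `counts`, per-cell metadata (donor, sample, age, cluster, doublet_score,
#'   target mito fraction) in `colData` and generator ground truth
#'   (base mean, spike flag, log2FC, dispersion) in `rowData`
#' @export
simulate_expression <- function(truth, design, seed) {
  stopifnot(inherits(truth, "expression_truth"))
  req <- c("sample", "donor", "age_years", "age_group", "modality", "chemistry")
  if (!all(req %in% names(design))) {
    stop("design must carry columns: ", paste(req, collapse = ", "))
  }
  grp <- split(design$donor, design$age_group)
  if (length(grp) < 2 || any(vapply(grp, function(d) length(unique(d)), 1L) < 2)) {
    stop("design needs >= 2 age groups with >= 2 donors each")
  }

  gene_names <- c(sprintf("gene%04d", seq_len(truth$n_genes)),
                  rownames(truth$myh_profile),
                  sprintf("MT-G%d", seq_len(truth$n_mito_genes)),
                  sprintf("BG-G%d", seq_len(truth$n_background_genes)))
  n_gene_tot <- length(gene_names)
  n_lib <- nrow(design)
  n_cells <- n_lib * truth$n_cells_per_sample
  donors <- unique(design$donor)

  with_seed(seed, {
    # per-gene base mean: lognormal spread around ~0.5 counts/cell
    base_mean <- exp(rnorm(truth$n_genes, log(0.5), 1))
    lib_of_cell <- rep(seq_len(n_lib), each = truth$n_cells_per_sample)
    cluster <- sample(truth$clusters, n_cells, replace = TRUE,
                      prob = truth$cluster_prob)
    aged <- design$age_group[lib_of_cell] == "aged"
    donor_of_cell <- design$donor[lib_of_cell]
    lib_factor <- exp(rnorm(n_cells, 0, truth$lib_factor_sd))
    donor_re <- matrix(rnorm(truth$n_genes * length(donors), 0, truth$donor_re_sd),
                       nrow = truth$n_genes, dimnames = list(NULL, donors))

    # generic genes: mean = base * 2^log2fc[aged] * donor RE * depth factor
    log2fc <- numeric(truth$n_genes)
    log2fc[truth$deg_indices] <- truth$deg_log2fc
    mu <- outer(base_mean, lib_factor) *
      exp(donor_re[, donor_of_cell, drop = FALSE])
    mu <- mu * 2^(log2fc %o% as.numeric(aged))
    counts_generic <- matrix(
      rnbinom(length(mu), size = rep(truth$dispersion, times = n_cells), mu = mu),
      nrow = truth$n_genes)

    # MYH marker genes follow the per-cluster profile (Poisson-like, disp 10)
    myh_mu <- truth$myh_profile[, cluster, drop = FALSE] *
      rep(lib_factor, each = 3)
    counts_myh <- matrix(rnbinom(length(myh_mu), size = 10, mu = myh_mu), nrow = 3)

    # stable background transcriptome: equal-mass genes, depth-scaled only
    bg_mean <- truth$background_mass / truth$n_background_genes
    bg_mu <- matrix(rep(bg_mean * lib_factor, each = truth$n_background_genes),
                    nrow = truth$n_background_genes)
    counts_bg <- matrix(rnbinom(length(bg_mu), size = 2, mu = bg_mu),
                        nrow = truth$n_background_genes)

    # mito genes: per-cell target fraction f -> mito mass = f/(1-f) * nuclear mass
    target_mito <- runif(n_cells, truth$mito_fraction_range[1],
                         truth$mito_fraction_range[2])
    nuclear_mass <- colSums(mu) + colSums(myh_mu) + colSums(bg_mu)
    mito_total <- target_mito / (1 - target_mito) * nuclear_mass
    mito_mu <- matrix(rep(mito_total / truth$n_mito_genes,
                          each = truth$n_mito_genes),
                      nrow = truth$n_mito_genes)
    counts_mito <- matrix(rnbinom(length(mito_mu), size = 5, mu = mito_mu),
                          nrow = truth$n_mito_genes)

    counts <- rbind(counts_generic, counts_myh, counts_mito, counts_bg)
    rownames(counts) <- gene_names
    barcodes <- sprintf("cell%05d", seq_len(n_cells))
    colnames(counts) <- barcodes

    doublet_score <- rbeta(n_cells, 1, 12)

    cd <- S4Vectors::DataFrame(
      barcode = barcodes,
      sample = design$sample[lib_of_cell],
      donor = donor_of_cell,
      age_years = design$age_years[lib_of_cell],
      age_group = design$age_group[lib_of_cell],
      modality = design$modality[lib_of_cell],
      chemistry = design$chemistry[lib_of_cell],
      cluster = cluster,
      doublet_score = doublet_score,
      target_mito_fraction = target_mito,
      row.names = barcodes)
    n_extra <- 3 + truth$n_mito_genes + truth$n_background_genes
    rd <- S4Vectors::DataFrame(
      gene = gene_names,
      base_mean = c(base_mean, rowMeans(truth$myh_profile),
                    rep(NA_real_, truth$n_mito_genes),
                    rep(bg_mean, truth$n_background_genes)),
      is_deg = c(seq_len(truth$n_genes) %in% truth$deg_indices,
                 rep(FALSE, n_extra)),
      deg_log2fc = c(log2fc, rep(0, n_extra)),
      dispersion = c(truth$dispersion, rep(10, 3), rep(5, truth$n_mito_genes),
                     rep(2, truth$n_background_genes)),
      is_mito = grepl("^MT-", gene_names),
      row.names = gene_names)
    SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                         "CsparseMatrix")),
      colData = cd, rowData = rd)
  })
}

#' Generate small internally consistent fixture tables
#'
#' Produces a homolog-mapping table (mostly 1:1 with a few 1:2 expansions),
#' GMT-style gene sets drawn from the synthetic gene universe, and a
#' ligand-receptor pair table (including multi-subunit receptors).
#'
#' @param seed integer seed
#' @param genes gene universe (character); defaults to the generator's
#'   generic gene names
#' @return list with `homologs` (data.frame human_gene, mouse_gene),
#'   `gene_sets` (named list), `lr_pairs` (data.frame interaction_id,
#'   ligand, receptor_subunits)
#' @export
make_fixture_tables <- function(seed, genes = sprintf("gene%04d", 1:200)) {
  stopifnot(length(genes) >= 30)
  max_set <- min(50, length(genes) - 10)
  with_seed(seed, {
    mouse <- paste0("m", genes)
    homologs <- data.frame(human_gene = genes, mouse_gene = mouse,
                           stringsAsFactors = FALSE)
    # a few 1:2 expansions
    dup <- sample(genes, 5)
    homologs <- rbind(homologs,
                      data.frame(human_gene = dup,
                                 mouse_gene = paste0("m", dup, "-b"),
                                 stringsAsFactors = FALSE))
    homologs <- homologs[order(homologs$human_gene, homologs$mouse_gene), ]
    rownames(homologs) <- NULL

    sizes <- sample(5:max_set, 6, replace = TRUE)
    gene_sets <- lapply(sizes, function(s) sort(sample(genes, s)))
    names(gene_sets) <- sprintf("SET_%02d", seq_along(gene_sets))

    lig <- sample(genes, 12)
    rec <- lapply(1:12, function(i) {
      n_sub <- if (i <= 3) 2 else 1
      sample(setdiff(genes, lig), n_sub)
    })
    lr_pairs <- data.frame(
      interaction_id = sprintf("LR_%02d", 1:12),
      ligand = lig,
      receptor_subunits = vapply(rec, paste, "", collapse = ";"),
      stringsAsFactors = FALSE)
    list(homologs = homologs, gene_sets = gene_sets, lr_pairs = lr_pairs)
  })
}

#' Deduplicate a ligand-receptor table
#'
#' Duplicate (ligand, receptor) pairs are collapsed with a warning.
#' @param lr_pairs data.frame with columns ligand, receptor_subunits
#' @return deduplicated data.frame
#' @export
validate_lr_pairs <- function(lr_pairs) {
  stopifnot(all(c("ligand", "receptor_subunits") %in% names(lr_pairs)))
  if (any(!nzchar(lr_pairs$ligand)) || any(!nzchar(lr_pairs$receptor_subunits))) {
    stop("ligand-receptor table has empty gene fields")
  }
  key <- paste(lr_pairs$ligand, lr_pairs$receptor_subunits, sep = "|")
  if (anyDuplicated(key)) {
    warning("duplicated ligand-receptor pairs removed")
    lr_pairs <- lr_pairs[!duplicated(key), , drop = FALSE]
    rownames(lr_pairs) <- NULL
  }
  lr_pairs
}
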