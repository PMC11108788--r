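#' Library-size normalization with log transform
#'
#' value = log1p(count / library_size * scale). All-zero cells stay
#' all-zero; a zero library size among non-empty cells is an error.
#'
#' @param x counts: a genes x cells matrix (sparse or dense) or a
#'   SingleCellExperiment (returns the SCE with a `lognorm` assay added)
#' @param scale target library size (default counts per 10,000)
#' @return same shape as the input, normalized
#' @export
normalize_log <- function(x, scale = 1e4) {
  stopifnot(scale > 0)
  if (methods::is(x, "SingleCellExperiment")) {
    m <- SummarizedExperiment::assay(x, "counts")
    SummarizedExperiment::assay(x, "lognorm") <- normalize_log(m, scale)
    return(x)
  }
  libsize <- Matrix::colSums(x)
  nonzero_cells <- libsize > 0
  if (!all(nonzero_cells)) {
    if (any(Matrix::colSums(x != 0)[!nonzero_cells] > 0)) {
      stop("zero library size")
    }
  }
  denom <- ifelse(libsize > 0, libsize, 1)
  out <- x %*% Matrix::Diagonal(ncol(x), scale / denom)
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(x)
  out
}

#' Per-gene Bayesian negative binomial mixed model for age
#'
#' The aging differential-expression model: NB log-link regression of a
#' gene's counts on standardized age with a random donor intercept and a
#' log library-size offset; technical/biological covariates enter as fixed
#' terms. The Gaussian (Laplace) posterior of the age coefficient yields
#' the sign probability; the Bayes factor for the age term uses a
#' N(0, prior_sd^2) prior on the coefficient and is computed either from
#' the posterior summary (Savage-Dickey form, default) or as the explicit
#' ratio of Laplace-approximated marginal likelihoods of the fits with and
#' without the age term (`refit = TRUE`). The two coincide when the age
#' evidence is weak; for strong effects the two-fit version is the more
#' conservative, because the reduced model's free donor intercepts can
#' absorb donor-level age structure that the posterior-summary route
#' attributes to age.
#'
#' The reported LTSR is the posterior probability that the age effect has
#' the estimated sign under a spike-and-slab view of the age term: with
#' posterior inclusion probability p1 = BF / (1 + BF) (even prior odds),
#' LTSR = p1 * Phi(|m|/s) + (1 - p1) / 2. A gene with no evidence for any
#' age effect thus sits near 0.5 regardless of how sharp its (spurious)
#' sign estimate is, which is what makes LTSR > 0.9 a usable genome-wide
#' significance rule without further multiplicity correction.
#'
#' The reported log2 fold change is scaled to the aged-vs-young contrast:
#' coefficient x (difference in mean standardized age between groups),
#' divided by log 2, so it is comparable to a group-level fold change.
#'
#' @param y integer counts for one gene across cells
#' @param cells per-cell metadata with donor, age_years, age_group and any
#'   covariate columns
#' @param covariates names of `cells` columns to adjust for (fixed terms)
#' @param offset log library size per cell
#' @param age_mode "scaled" (continuous standardized years, default) or
#'   "group" (binary aged indicator)
#' @param prior_sd prior SD of the age coefficient for the Bayes factor
#' @param refit compute the Bayes factor by refitting without the age term
#' @param sigma_prior,fix_log_disp,fix_log_sd passed to [nbglmm_laplace()]
#' @return object of class `gene_fit`: coefficient posteriors, dispersion,
#'   donor sd, log marginal likelihoods with/without age, bayes_factor,
#'   ltsr, logfc_age (log2, group contrast), degenerate flag
#' @export
fit_gene_lmm <- function(y, cells, covariates = character(),
                         offset = NULL,
                         age_mode = c("scaled", "group"),
                         prior_sd = 1,
                         refit = FALSE,
                         sigma_prior = c(shape = 2, rate = 5),
                         fix_log_disp = NULL, fix_log_sd = NULL) {
  age_mode <- match.arg(age_mode)
  stopifnot(length(y) == nrow(cells))
  if (is.null(offset)) offset <- rep(0, length(y))

  if (sum(y > 0) == 0) {
    out <- list(degenerate = TRUE, logfc_age = NA_real_, sd = NA_real_,
                ltsr = NA_real_, bayes_factor = NA_real_,
                coef = NULL, theta = NA_real_, sigma = NA_real_,
                logml_with = NA_real_, logml_without = NA_real_)
    return(structure(out, class = "gene_fit"))
  }

  grp_means <- tapply(cells$age_years, cells$age_group, mean)
  if (age_mode == "scaled") {
    age <- as.numeric(scale(cells$age_years))
    mu <- mean(cells$age_years); sdv <- stats::sd(cells$age_years)
    contrast <- (grp_means[["aged"]] - grp_means[["young"]]) / sdv
  } else {
    age <- as.numeric(cells$age_group == "aged")
    contrast <- 1
  }

  X <- cbind(`(Intercept)` = 1, age = age)
  for (v in covariates) {
    f <- factor(cells[[v]])
    if (nlevels(f) > 1) {
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(v, levels(f)[-1])
      X <- cbind(X, mm)
    }
  }

  fit <- nbglmm_laplace(y, X, offset = offset, group = cells$donor,
                        sigma_prior = sigma_prior,
                        fix_log_disp = fix_log_disp, fix_log_sd = fix_log_sd)
  m <- unname(fit$beta["age"])
  s <- unname(fit$se["age"])
  if (!is.finite(s) || s <= 0) s <- NA_real_

  sign_prob <- if (is.na(s)) NA_real_ else compute_ltsr(m, s)

  # Laplace marginal likelihood of the model with the age term integrated
  # over its N(0, prior_sd^2) prior; without-age marginal from a refit or
  # via the Savage-Dickey identity on the Gaussian posterior.
  logml_with <- fit$loglik + stats::dnorm(m, 0, prior_sd, log = TRUE) +
    0.5 * log(2 * pi) + log(s)
  if (refit) {
    fit0 <- nbglmm_laplace(y, X[, colnames(X) != "age", drop = FALSE],
                           offset = offset, group = cells$donor,
                           sigma_prior = sigma_prior,
                           fix_log_disp = fix_log_disp,
                           fix_log_sd = fix_log_sd)
    logml_without <- fit0$loglik
    log_bf <- logml_with - logml_without
  } else {
    log_bf <- stats::dnorm(m, 0, sqrt(s^2 + prior_sd^2), log = TRUE) -
      stats::dnorm(m, 0, s, log = TRUE)
    logml_without <- logml_with - log_bf
  }

  bf <- exp(log_bf)
  p1 <- bf / (1 + bf)
  ltsr <- if (is.na(sign_prob)) NA_real_ else p1 * sign_prob + (1 - p1) * 0.5

  out <- list(degenerate = FALSE,
              coef = data.frame(term = names(fit$beta),
                                mean = unname(fit$beta),
                                sd = unname(fit$se)),
              theta = fit$theta, sigma = fit$sigma,
              age_coef = m, age_sd = s,
              logfc_age = m * contrast / log(2),
              sd = abs(s * contrast / log(2)),
              sign_prob = sign_prob,
              ltsr = ltsr,
              bayes_factor = bf,
              logml_with = logml_with,
              logml_without = logml_without,
              converged = fit$converged)
  structure(out, class = "gene_fit")
}

#' Fraction of cells expressing each gene
#'
#' @param sce SingleCellExperiment
#' @param group "aged", "young" or "all": which cells to count over
#'   (dot-plot convention keys size to the aged group)
#' @return named numeric vector, per gene
#' @export
prop_expressed <- function(sce, group = c("aged", "young", "all")) {
  group <- match.arg(group)
  m <- SummarizedExperiment::assay(sce, "counts")
  if (group != "all") {
    keep <- SummarizedExperiment::colData(sce)$age_group == group
    m <- m[, keep, drop = FALSE]
  }
  Matrix::rowSums(m > 0) / ncol(m)
}

#' Fit the aging DE model for every gene of a cell subset
#'
#' @param sce SingleCellExperiment (one cell type / cluster subset)
#' @param covariates fixed-term covariate columns of `colData`
#' @param genes genes to fit (default all)
#' @param cell_type label recorded in the result
#' @param ... passed to [fit_gene_lmm()]
#' @return data.frame of per-gene results (gene, cell_type, logfc_age,
#'   sd, ltsr, bayes_factor, prop_expressed)
#' @export
fit_aging_degs <- function(sce, covariates = c("chemistry", "modality"),
                           genes = rownames(sce), cell_type = "all", ...) {
  m <- SummarizedExperiment::assay(sce, "counts")
  cells <- as.data.frame(SummarizedExperiment::colData(sce))
  off <- log(pmax(Matrix::colSums(m), 1))
  props <- prop_expressed(sce, "aged")
  rows <- lapply(genes, function(g) {
    f <- fit_gene_lmm(as.numeric(m[g, ]), cells, covariates = covariates,
                      offset = off, ...)
    data.frame(gene = g, cell_type = cell_type,
               logfc_age = if (f$degenerate) NA_real_ else f$logfc_age,
               sd = if (f$degenerate) NA_real_ else f$sd,
               ltsr = if (f$degenerate) NA_real_ else f$ltsr,
               bayes_factor = if (f$degenerate) NA_real_ else f$bayes_factor,
               prop_expressed = unname(props[g]),
               degenerate = f$degenerate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Apply the aging DEG significance rule
#'
#' A gene is a significant aging DEG when LTSR > 0.9 and it is expressed
#' in more than 5% of cells of the relevant group; direction follows the
#' sign of the age effect. Degenerate fits are never significant.
#'
#' @param fits data.frame from [fit_aging_degs()] (needs logfc_age, ltsr,
#'   prop_expressed)
#' @param ltsr_cutoff LTSR significance cutoff (default 0.9)
#' @param prop_cutoff expressed-proportion cutoff (default 0.05)
#' @return the input with `significant` and `direction` columns added
#' @export
call_aging_degs <- function(fits, ltsr_cutoff = 0.9, prop_cutoff = 0.05) {
  stopifnot(all(c("logfc_age", "ltsr", "prop_expressed") %in% names(fits)))
  ok <- !is.na(fits$ltsr)
  fits$significant <- ok & fits$ltsr > ltsr_cutoff &
    fits$prop_expressed > prop_cutoff
  fits$direction <- ifelse(!ok, NA_character_,
                           ifelse(fits$logfc_age >= 0, "up", "down"))
  fits
}

#' Gene-set module score with expression-bin-matched controls
#'
#' For every set gene, `n_ctrl` control genes are sampled from its
#' mean-expression bin (`n_bins` bins over all genes); a cell's score is
#' the mean normalized expression of the set genes minus the mean over the
#' sampled control pool. A set spanning the whole universe therefore
#' scores ~0 everywhere.
#'
#' @param normmat normalized genes x cells matrix (see [normalize_log()])
#' @param gene_set character vector of set genes
#' @param n_bins number of expression bins (default 25)
#' @param n_ctrl control genes sampled per set gene (default 50)
#' @param seed integer seed for control sampling
#' @return numeric per-cell score
#' @export
score_gene_set <- function(normmat, gene_set, n_bins = 25, n_ctrl = 50, seed = 0) {
  gene_set <- intersect(gene_set, rownames(normmat))
  if (!length(gene_set)) stop("gene set has empty intersection with the matrix")
  gmeans <- Matrix::rowMeans(normmat)
  bins <- cut(rank(gmeans, ties.method = "first"),
              breaks = min(n_bins, length(gmeans)), labels = FALSE)
  names(bins) <- rownames(normmat)
  ctrl <- with_seed(seed, {
    unlist(lapply(gene_set, function(g) {
      pool <- names(bins)[bins == bins[[g]]]
      sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
    }))
  })
  set_mean <- Matrix::colMeans(normmat[gene_set, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(normmat[ctrl, , drop = FALSE])
  as.numeric(set_mean - ctrl_mean)
}
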