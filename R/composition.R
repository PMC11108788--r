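#' Model specification for the composition GLMM
#'
#' The default reproduces the eight-term hierarchical Poisson model of
#' cell-type abundance: a fixed standardized-age effect plus random
#' intercepts for cell type, library, chemistry and modality, a random age
#' slope per cell type, and cell-type interactions of chemistry, modality
#' and library. All covariates other than age enter as random terms, which
#' keeps the model estimable despite collinear technical covariates.
#'
#' @param fixed fixed-effect terms (besides the intercept)
#' @param random random-effect terms in lme4 notation
#' @return object of class `composition_model_spec`
#' @export
composition_model_spec <- function(fixed = "age_scaled",
                                   random = c("(1 | cell_type)",
                                              "(1 | sample)",
                                              "(1 | chemistry)",
                                              "(1 | modality)",
                                              "(0 + age_scaled | cell_type)",
                                              "(1 | chemistry:cell_type)",
                                              "(1 | modality:cell_type)",
                                              "(1 | sample:cell_type)")) {
  structure(list(fixed = fixed, random = random),
            class = "composition_model_spec")
}

composition_formula <- function(spec) {
  rhs <- paste(c(spec$fixed, spec$random), collapse = " + ")
  stats::as.formula(paste("count ~", rhs))
}

#' Assemble the model frame for the composition GLMM
#'
#' Joins the composition table with library covariates and standardizes age
#' across libraries (each library counted once).
#' @noRd
composition_model_frame <- function(table, samples) {
  stopifnot(all(c("cell_type", "sample", "count") %in% names(table)))
  if (anyDuplicated(paste(table$cell_type, table$sample))) {
    stop("duplicate (cell_type, sample) rows in composition table")
  }
  if (any(table$count < 0)) stop("negative counts")
  df <- merge(table, samples, by = "sample", sort = FALSE)
  lib_age <- samples$age_years[match(unique(samples$sample), samples$sample)]
  mu <- mean(lib_age)
  sdv <- stats::sd(lib_age)
  if (!is.finite(sdv) || sdv == 0) stop("age has zero variance across libraries")
  df$age_scaled <- (df$age_years - mu) / sdv
  for (v in c("cell_type", "sample", "chemistry", "modality")) {
    if (v %in% names(df)) df[[v]] <- factor(df[[v]])
  }
  df
}

#' Fit the hierarchical Poisson mixed model of cell-type abundance
#'
#' Counts per (cell type x library) are modeled with a Poisson log-link
#' GLMM whose variance components maximize the Laplace-approximated
#' marginal likelihood (lme4::glmer). Random-coefficient posteriors are the
#' Gaussian (mode, curvature) summaries at the optimum, which downstream
#' feeds the grand-mean-adjusted log fold changes and LTSR.
#'
#' With `pin_variances = TRUE` every variance component is held at zero and
#' only the fixed effects are optimized (over the same Laplace deviance
#' function); in that limit the model collapses to an ordinary Poisson GLM.
#'
#' @param table composition table (cell_type, sample, count; zero pairs
#'   materialized)
#' @param samples library-level covariates (sample, donor, age_years,
#'   modality, chemistry, ...)
#' @param spec a [composition_model_spec()]
#' @param pin_variances logical; fix all random-effect variances at 0
#' @return object of class `composition_fit`
#' @export
fit_composition_glmm <- function(table, samples,
                                 spec = composition_model_spec(),
                                 pin_variances = FALSE) {
  df <- composition_model_frame(table, samples)
  if (nlevels(df$cell_type) < 2) stop("need >= 2 cell types")
  if (nlevels(df$sample) < 4) stop("need >= 4 libraries")
  zero_ct <- tapply(df$count, df$cell_type, sum) == 0
  if (any(zero_ct)) {
    warning("all-zero cell type(s) kept (shrinkage handles them): ",
            paste(names(zero_ct)[zero_ct], collapse = ", "))
  }
  form <- composition_formula(spec)

  if (pin_variances) {
    gf <- lme4::glFormula(form, data = df, family = stats::poisson())
    devfun <- do.call(lme4::mkGlmerDevfun, gf)
    devfun <- lme4::updateGlmerDevfun(devfun, gf$reTrms)
    nth <- length(gf$reTrms$theta)
    nbeta <- ncol(gf$X)
    obj <- function(beta) devfun(c(rep(0, nth), beta))
    opt <- stats::nlminb(rep(0, nbeta), obj,
                         control = list(rel.tol = 1e-12, iter.max = 500))
    beta <- stats::setNames(opt$par, colnames(gf$X))
    H <- stats::optimHess(opt$par, obj)
    vc <- tryCatch(solve(H / 2), error = function(e) matrix(NA, nbeta, nbeta))
    fit <- list(engine = NULL, beta = beta,
                se = sqrt(pmax(diag(vc), 0)),
                cell_types = levels(df$cell_type),
                slopes = stats::setNames(rep(0, nlevels(df$cell_type)),
                                         levels(df$cell_type)),
                slope_var = stats::setNames(rep(0, nlevels(df$cell_type)),
                                            levels(df$cell_type)),
                varcorr = stats::setNames(rep(0, nth), seq_len(nth)),
                logLik = -opt$objective / 2,
                converged = opt$convergence == 0,
                pinned = TRUE, spec = spec, data = df)
    return(structure(fit, class = "composition_fit"))
  }

  converged <- TRUE
  msgs <- character()
  m <- withCallingHandlers(
    lme4::glmer(form, data = df, family = stats::poisson(),
                control = lme4::glmerControl(calc.derivs = FALSE)),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (any(grepl("failed to converge|convergence", msgs))) converged <- FALSE

  beta <- lme4::fixef(m)
  se <- sqrt(diag(as.matrix(stats::vcov(m))))
  re <- lme4::ranef(m, condVar = TRUE)
  ct_levels <- levels(df$cell_type)
  slopes <- stats::setNames(rep(0, length(ct_levels)), ct_levels)
  slope_var <- stats::setNames(rep(0, length(ct_levels)), ct_levels)
  # the (0 + age_scaled | cell_type) term: lme4 stores repeated grouping
  # factors as separate list entries with the same name
  ct_blocks <- which(names(re) == "cell_type")
  for (b in ct_blocks) {
    blk <- re[[b]]
    if ("age_scaled" %in% colnames(blk)) {
      pv <- attr(blk, "postVar")
      slopes[rownames(blk)] <- blk[["age_scaled"]]
      slope_var[rownames(blk)] <- if (is.list(pv)) {
        as.numeric(pv[["age_scaled"]][1, 1, ])
      } else {
        j <- match("age_scaled", colnames(blk))
        pv[j, j, ]
      }
    }
  }
  vcsd <- unlist(lapply(lme4::VarCorr(m), function(v) attr(v, "stddev")))
  fit <- list(engine = m, beta = beta, se = stats::setNames(se, names(beta)),
              cell_types = ct_levels,
              slopes = slopes, slope_var = slope_var,
              varcorr = vcsd,
              logLik = as.numeric(stats::logLik(m)),
              converged = converged, pinned = FALSE, spec = spec, data = df)
  structure(fit, class = "composition_fit")
}

#' @export
print.composition_fit <- function(x, ...) {
  cat("Poisson mixed-model composition fit:",
      length(x$cell_types), "cell types,",
      nlevels(x$data$sample), "libraries;",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' Local true sign rate of a Gaussian posterior
#'
#' Probability that the estimated sign of an effect is correct:
#' `max(P(b > 0), P(b < 0)) = pnorm(|mean| / sd)` under N(mean, sd^2).
#' Always in [0.5, 1]; 0.5 means the direction is a coin flip.
#'
#' @param mean posterior mean(s)
#' @param sd posterior standard deviation(s), > 0
#' @return LTSR value(s) in [0.5, 1]
#' @export
compute_ltsr <- function(mean, sd) {
  if (any(sd <= 0)) stop("sd must be > 0")
  stats::pnorm(abs(mean) / sd)
}

#' Per-cell-type age effects with LTSR
#'
#' The age effect of cell type c is the shared fixed age coefficient plus
#' that cell type's random age slope, centered so the grand mean over cell
#' types equals the shared term (and hence 0 when there is no effect).
#' Posterior sd combines the fixed-coefficient uncertainty with the
#' conditional variance of the slope.
#'
#' @param fit a [fit_composition_glmm()] result
#' @param ltsr_cutoff significance cutoff on LTSR (default 0.9)
#' @return data.frame with cell_type, covariate, logfc (natural log),
#'   log2fc, sd, ltsr, significant
#' @export
celltype_age_effects <- function(fit, ltsr_cutoff = 0.9) {
  stopifnot(inherits(fit, "composition_fit"))
  age_name <- fit$spec$fixed[1]
  beta_age <- unname(fit$beta[age_name])
  se_age <- unname(fit$se[age_name])
  b <- fit$slopes[fit$cell_types]
  logfc <- beta_age + (b - mean(b))
  sd <- sqrt(se_age^2 + pmax(fit$slope_var[fit$cell_types], 0))
  sd[sd <= 0] <- .Machine$double.eps
  ltsr <- compute_ltsr(logfc, sd)
  data.frame(cell_type = fit$cell_types,
             covariate = "age",
             logfc = unname(logfc),
             log2fc = unname(logfc) / log(2),
             sd = unname(sd),
             ltsr = unname(ltsr),
             significant = unname(ltsr) > ltsr_cutoff,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Label differential-abundance neighborhoods
#'
#' A neighborhood is labeled by its most abundant cell type when that type
#' contributes at least 70% of its cells; otherwise it is "mixed" and
#' dropped. A neighborhood with more than 90% of cells from a single donor
#' is "Donor-specific" and dropped (checked after the mixed rule).
#'
#' @param ct_counts neighborhoods x cell types count matrix
#' @param donor_counts neighborhoods x donors count matrix (same rows)
#' @param majority_cutoff minimum share of the top cell type (default 0.70)
#' @param donor_cutoff maximum share of any one donor (default 0.90)
#' @return data.frame with neighborhood, label, keep
#' @export
label_neighborhoods <- function(ct_counts, donor_counts,
                                majority_cutoff = 0.70,
                                donor_cutoff = 0.90) {
  ct_counts <- as.matrix(ct_counts)
  donor_counts <- as.matrix(donor_counts)
  if (nrow(ct_counts) != nrow(donor_counts) ||
      (!is.null(rownames(ct_counts)) && !is.null(rownames(donor_counts)) &&
       !identical(rownames(ct_counts), rownames(donor_counts)))) {
    stop("neighborhood rows are misaligned between the two matrices")
  }
  rs <- rowSums(ct_counts)
  if (any(rs <= 0)) stop("neighborhood with zero cells")
  top_share <- apply(ct_counts, 1, max) / rs
  top_ct <- colnames(ct_counts)[max.col(ct_counts, ties.method = "first")]
  donor_share <- apply(donor_counts, 1, max) / rowSums(donor_counts)

  label <- top_ct
  label[top_share < majority_cutoff] <- "mixed"
  donor_specific <- label != "mixed" & donor_share > donor_cutoff
  label[donor_specific] <- "Donor-specific"
  keep <- !(label %in% c("mixed", "Donor-specific"))
  data.frame(neighborhood = if (!is.null(rownames(ct_counts)))
               rownames(ct_counts) else seq_len(nrow(ct_counts)),
             label = label, keep = keep,
             row.names = NULL, stringsAsFactors = FALSE)
}
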