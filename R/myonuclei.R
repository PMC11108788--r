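MYH_CLASSES <- c("MYH7+", "MYH2+", "MYH1+",
                 "MYH7+MYH2+", "MYH7+MYH1+", "MYH2+MYH1+",
                 "MYH7+MYH2+MYH1+", "unclassified")

#' Classify myonuclei by MYH marker expression
#'
#' A nucleus is called as expressing a marker when its normalized
#' (library-size-scaled, log-transformed) expression strictly exceeds the
#' threshold; its class is the combination of expressed markers among
#' MYH7 (slow type I), MYH2 (fast IIA) and MYH1 (fast IIX). Nuclei with
#' all three markers at or below the threshold — or carrying an exclusion
#' flag (fragment or rare hybrid subtypes) — are "unclassified".
#'
#' @param expr matrix or data.frame with columns MYH7, MYH2, MYH1 of
#'   normalized expression (>= 0)
#' @param threshold expression threshold (default 0.5, strict)
#' @param excluded logical vector flagging nuclei to force to unclassified
#' @return data.frame with nucleus, MYH7, MYH2, MYH1, class,
#'   excluded_by_flag
#' @export
classify_myonuclei <- function(expr, threshold = 0.5, excluded = NULL) {
  expr <- as.data.frame(expr)
  stopifnot(all(c("MYH7", "MYH2", "MYH1") %in% names(expr)))
  vals <- as.matrix(expr[, c("MYH7", "MYH2", "MYH1")])
  if (any(vals < 0)) stop("negative normalized expression values")
  if (is.null(excluded)) excluded <- rep(FALSE, nrow(vals))
  stopifnot(length(excluded) == nrow(vals))
  member <- vals > threshold
  cls <- apply(member, 1, function(m) {
    if (!any(m)) return("unclassified")
    paste0(paste0(c("MYH7", "MYH2", "MYH1")[m], "+"), collapse = "")
  })
  cls[excluded] <- "unclassified"
  data.frame(nucleus = if (!is.null(rownames(expr))) rownames(expr)
             else seq_len(nrow(expr)),
             MYH7 = vals[, "MYH7"], MYH2 = vals[, "MYH2"], MYH1 = vals[, "MYH1"],
             class = factor(cls, levels = MYH_CLASSES),
             excluded_by_flag = excluded,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-donor myonucleus class proportions with the exclusion rule
#'
#' Proportions are computed over all of a donor's nuclei (classified plus
#' unclassified); donors whose unclassified fraction exceeds 75% are
#' flagged `excluded` and should be discarded from group comparisons.
#'
#' @param calls output of [classify_myonuclei()]
#' @param donor per-nucleus donor id
#' @param age_group optional per-nucleus age group label
#' @param unclassified_cutoff exclusion cutoff on the unclassified
#'   fraction (default 0.75, strict)
#' @return data.frame: donor, age_group, one proportion column per class,
#'   unclassified_fraction, excluded
#' @export
donor_proportions <- function(calls, donor, age_group = NULL,
                              unclassified_cutoff = 0.75) {
  stopifnot(length(donor) == nrow(calls))
  donor <- as.character(donor)
  if (any(!nzchar(donor)) || anyNA(donor)) stop("every nucleus needs a donor")
  tab <- table(donor, factor(calls$class, levels = MYH_CLASSES))
  if (any(rowSums(tab) == 0)) stop("donor with zero nuclei")
  props <- sweep(tab, 1, rowSums(tab), "/")
  out <- data.frame(donor = rownames(props), stringsAsFactors = FALSE)
  if (!is.null(age_group)) {
    out$age_group <- as.character(age_group)[match(out$donor, donor)]
  }
  out <- cbind(out, as.data.frame.matrix(props))
  out$unclassified_fraction <- props[, "unclassified"]
  out$excluded <- out$unclassified_fraction > unclassified_cutoff
  rownames(out) <- NULL
  out
}

#' Two-group comparison of donor-level values
#'
#' Unpaired two-tailed Student t-test (Welch by option) or exact
#' Mann-Whitney-Wilcoxon (exact for small samples without ties, normal
#' approximation with tie correction otherwise). When both groups have
#' zero variance the t statistic is undefined; the comparison is reported
#' as degenerate with p = 1 (statistic 0 if the means are equal).
#'
#' @param x,y numeric donor-level values for the two groups
#' @param test "t" or "mannwhitney"
#' @param var_equal use the pooled-variance Student t-test (default TRUE)
#' @return list with statistic, p_value, test, degenerate
#' @export
compare_age_groups <- function(x, y, test = c("t", "mannwhitney"),
                               var_equal = TRUE) {
  test <- match.arg(test)
  if (test == "t") {
    if (length(x) < 2 || length(y) < 2) stop("t-test needs >= 2 donors per group")
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      return(list(statistic = 0, p_value = 1, test = "t", degenerate = TRUE))
    }
    r <- stats::t.test(x, y, var.equal = var_equal)
    list(statistic = unname(r$statistic), p_value = r$p.value,
         test = "t", degenerate = FALSE)
  } else {
    exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
    r <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                             correct = !exact))
    list(statistic = unname(r$statistic), p_value = r$p.value,
         test = "mannwhitney", degenerate = FALSE)
  }
}
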