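#' ROUT outlier identification (location-only model)
#'
#' Robust-regression-and-outlier-removal for a univariate sample, the form
#' used for boxplot data: a robust center is fitted by iteratively
#' reweighted averaging under a Lorentzian loss, the robust standard
#' deviation of the residuals (RSDR) is the 68.27th percentile of the
#' absolute residuals with an n/(n-1) correction, and points are flagged
#' from the most extreme inward while their two-tailed t-tail probability
#' stays below the step-down FDR ladder `alpha_i = (Q/100) * i / n`.
#'
#' @param values numeric sample, n >= 3.
#' @param q false discovery rate Q in percent (default 1).
#' @return list of class `rout_result`: `robust_center`, `rsdr`,
#'   `outlier_flags` (logical per observation), `q`.
#' @export
rout_outliers <- function(values, q = 1) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 3L) stop("ROUT needs at least 3 observations", call. = FALSE)
  if (any(!is.finite(x))) stop("values must be finite", call. = FALSE)
  center <- median(x)
  rsdr <- .rsdr(x - center, n)
  if (rsdr > 0) {
    for (it in seq_len(100L)) {
      r <- x - center
      w <- 1 / (1 + (r / rsdr)^2)
      new_center <- sum(w * x) / sum(w)
      new_rsdr <- .rsdr(x - new_center, n)
      done <- abs(new_center - center) < 1e-10 * (1 + abs(center))
      center <- new_center
      if (new_rsdr > 0) rsdr <- new_rsdr
      if (done) break
    }
  }
  flags <- rep(FALSE, n)
  if (rsdr > 0) {
    tt <- abs(x - center) / rsdr
    ord <- order(tt, decreasing = TRUE)
    df <- n - 1L
    for (i in seq_len(n)) {
      p <- 2 * pt(-tt[ord[i]], df)
      # step-down FDR ladder: the i-th most extreme point is the i-th
      # smallest p, so its Benjamini-Hochberg threshold is Q * i / n
      alpha_i <- (q / 100) * i / n
      if (p < alpha_i) flags[ord[i]] <- TRUE else break
    }
  }
  structure(list(robust_center = center, rsdr = rsdr, outlier_flags = flags,
                 q = q), class = "rout_result")
}

# robust SD of residuals: 68.27th percentile of |r| with small-n correction
.rsdr <- function(r, n) {
  as.numeric(quantile(abs(r), 0.6827, names = FALSE)) * n / (n - 1)
}

#' @export
print.rout_result <- function(x, ...) {
  cat(sprintf("ROUT (Q = %g%%): center %.4g, RSDR %.4g, %d outlier(s) of %d\n",
              x$q, x$robust_center, x$rsdr, sum(x$outlier_flags),
              length(x$outlier_flags)))
  invisible(x)
}

#' Two-tailed unpaired Student t test
#'
#' Pooled-variance two-sample t test (the conventional "unpaired
#' parametric t test"); Welch's correction is available via `welch = TRUE`.
#' Degenerate zero-variance inputs are resolved deterministically: equal
#' means give p = 1, unequal means give p = 0 with a warning.
#'
#' @param a,b numeric groups, each n >= 2.
#' @param welch use the Welch (unequal-variance) statistic.
#' @return list: `t`, `df`, `p`.
#' @export
unpaired_t_test <- function(a, b, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations", call. = FALSE)
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2L, p = 1))
    warning("zero variance with unequal means: p = 0")
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2L, p = 0))
  }
  ht <- t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Pearson correlation with R-squared and 95% CI
#'
#' Standard product-moment correlation; p from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))`, confidence interval via the Fisher
#' z transform.
#'
#' @param x,y numeric vectors (n >= 3, finite, non-constant).
#' @return list: `r`, `r_squared`, `p`, `conf_int` (95% CI of r).
#' @export
pearson_r2 <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must share a length of at least 3", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("values must be finite", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in x or y: correlation undefined", call. = FALSE)
  ht <- cor.test(x, y, method = "pearson", conf.level = 0.95)
  r <- unname(ht$estimate)
  list(r = r, r_squared = r^2, p = unname(ht$p.value),
       conf_int = as.numeric(ht$conf.int))
}

#' Compare two groups with per-group outlier removal
#'
#' The comparison used throughout the downstream analyses: ROUT (Q = 1)
#' is applied to each group separately, flagged observations are dropped,
#' and the remaining values are compared by the unpaired t test. Set
#' `rout_q = NULL` to skip outlier removal.
#'
#' @param a,b numeric groups.
#' @param rout_q ROUT Q in percent, or `NULL` for no outlier removal.
#' @param welch use the Welch statistic.
#' @return list: `t`, `df`, `p`, `n_removed` (per group).
#' @export
compare_groups <- function(a, b, rout_q = 1, welch = FALSE) {
  removed <- c(0L, 0L)
  if (!is.null(rout_q)) {
    fa <- rout_outliers(a, rout_q)$outlier_flags
    fb <- rout_outliers(b, rout_q)$outlier_flags
    removed <- c(sum(fa), sum(fb))
    a <- a[!fa]; b <- b[!fb]
  }
  out <- unpaired_t_test(a, b, welch = welch)
  out$n_removed <- removed
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, each gene's Ct is normalized to the housekeeping gene
#' (dCt = Ct_gene - Ct_housekeeping); the group contrast
#' ddCt = mean dCt(treated) - mean dCt(control) gives the fold change
#' `2^-ddCt`. A gene is called significant when |log2 fold change|
#' strictly exceeds `cutoff`.
#'
#' @param ct_table data frame with columns `sample`, `group`, `gene`, `ct`
#'   (e.g. from [generate_ct_table()]).
#' @param housekeeping housekeeping gene name present for every sample.
#' @param control name of the control group.
#' @param cutoff log2 fold-change significance cutoff (default 0.5,
#'   exclusive).
#' @return data frame, one row per gene: `gene`, `delta_delta_ct`,
#'   `fold_change`, `log2_fc`, `significant`.
#' @export
ddct <- function(ct_table, housekeeping = "HPRT", control = "control",
                 cutoff = 0.5) {
  stopifnot(all(c("sample", "group", "gene", "ct") %in% names(ct_table)))
  hk <- ct_table[ct_table$gene == housekeeping, ]
  missing_hk <- setdiff(unique(ct_table$sample), hk$sample)
  if (length(missing_hk))
    stop("missing housekeeping Ct for sample(s): ",
         paste(missing_hk, collapse = ", "), call. = FALSE)
  hk_ct <- stats::setNames(hk$ct, hk$sample)
  tab <- ct_table[ct_table$gene != housekeeping, ]
  tab$dct <- tab$ct - hk_ct[tab$sample]
  genes <- unique(tab$gene)
  out <- lapply(genes, function(g) {
    gt <- tab[tab$gene == g, ]
    ddc <- mean(gt$dct[gt$group != control]) - mean(gt$dct[gt$group == control])
    data.frame(gene = g, delta_delta_ct = ddc, fold_change = 2^(-ddc),
               log2_fc = -ddc, significant = abs(ddc) > cutoff)
  })
  do.call(rbind, out)
}
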