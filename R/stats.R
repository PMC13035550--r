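#' Group comparisons between conditions
#'
#' Two-sample unpaired t-tests (normoxia vs hyperoxia) for each numeric
#' metric; sex-stratified comparisons are run where both cells hold at
#' least two animals, otherwise skipped with a note.
#'
#' @param metrics Tibble with `condition` (`"Nx"`/`"Hx"`), optionally
#'   `sex`, and numeric metric columns.
#' @param by_sex Also run sex-stratified comparisons.
#' @return Tibble: metric, stratum, group means, t-statistic, p-value,
#'   note.
#' @export
group_comparisons <- function(metrics, by_sex = FALSE) {
  num_cols <- names(metrics)[vapply(metrics, is.numeric, TRUE)]
  strata <- list(list(label = "all", data = metrics))
  if (by_sex && "sex" %in% names(metrics))
    for (s in unique(metrics$sex))
      strata <- c(strata, list(list(label = paste0("sex=", s),
                                    data = metrics[metrics$sex == s, ])))
  purrr::map_dfr(strata, function(st) {
    d <- st$data
    purrr::map_dfr(num_cols, function(m) {
      x <- d[[m]][d$condition == "Nx"]
      y <- d[[m]][d$condition == "Hx"]
      if (length(x) < 2 || length(y) < 2)
        return(tibble(metric = m, stratum = st$label,
                      mean_Nx = mean(x), mean_Hx = mean(y),
                      t = NA_real_, p = NA_real_,
                      note = "skipped: fewer than 2 animals in a group"))
      if (stats::sd(c(x, y)) == 0)
        return(tibble(metric = m, stratum = st$label,
                      mean_Nx = mean(x), mean_Hx = mean(y),
                      t = 0, p = 1, note = "degenerate: constant metric"))
      tt <- t.test(x, y, var.equal = FALSE)
      tibble(metric = m, stratum = st$label,
             mean_Nx = mean(x), mean_Hx = mean(y),
             t = unname(tt$statistic), p = tt$p.value, note = "")
    })
  })
}

#' Correlation tests between metric pairs
#'
#' Pearson (linear) or Spearman (monotone) correlation tests for the
#' requested variable pairs, pooled across conditions.
#'
#' @param metrics Tibble of per-animal metrics/parameters.
#' @param pairs List of length-2 character vectors naming the columns.
#' @param method `"pearson"` or `"spearman"`.
#' @return Tibble: input1, input2, rho, p.
#' @export
correlation_table <- function(metrics,
                              pairs = list(
                                c("delta_Cm_SEP", "SW_RV"),
                                c("delta_Cm_SEP", "mPAP"),
                                c("delta_Cm_SEP", "Am_ref_RV")),
                              method = "pearson") {
  purrr::map_dfr(pairs, function(pr) {
    ok <- pr %in% names(metrics)
    if (!all(ok))
      return(tibble(input1 = pr[1], input2 = pr[2],
                    rho = NA_real_, p = NA_real_))
    ct <- suppressWarnings(
      cor.test(metrics[[pr[1]]], metrics[[pr[2]]], method = method))
    tibble(input1 = pr[1], input2 = pr[2],
           rho = unname(ct$estimate), p = ct$p.value)
  })
}

#' Linear-discriminant separability of the two conditions
#'
#' Fisher discriminant projection for one or more feature sets. Features
#' are standardized to zero mean and unit variance; the pooled within-class
#' scatter is shrunk toward its diagonal mean (`(1-lambda) S + lambda
#' mean(diag(S)) I`), which keeps the direction well-defined when features
#' outnumber animals. The separation index is the between-class over
#' within-class scatter of the 1-D projections.
#'
#' @param feature_sets Named list of feature matrices/data frames (rows =
#'   animals, aligned with `labels`).
#' @param labels Condition labels (two classes).
#' @param lambda Shrinkage intensity in `[0, 1]`.
#' @return An `rh_lda` tibble: feature_set, sample, label, projection;
#'   attribute `separation` (named vector of separation indices) and
#'   `shrinkage`.
#' @export
lda_separability <- function(feature_sets, labels, lambda = 0.25) {
  labels <- as.factor(labels)
  stopifnot(nlevels(labels) == 2)
  sep <- setNames(numeric(length(feature_sets)), names(feature_sets))
  out <- purrr::map_dfr(names(feature_sets), function(nm) {
    X <- as.matrix(as.data.frame(feature_sets[[nm]]))
    keep <- apply(X, 2, function(cl) stats::sd(cl) > 0)
    X <- scale(X[, keep, drop = FALSE])
    g1 <- labels == levels(labels)[1]
    Sw <- (crossprod(scale(X[g1, , drop = FALSE], scale = FALSE)) +
             crossprod(scale(X[!g1, , drop = FALSE], scale = FALSE))) /
      (nrow(X) - 2)
    Sw_reg <- (1 - lambda) * Sw +
      lambda * mean(diag(Sw)) * diag(ncol(X))
    dmu <- colMeans(X[!g1, , drop = FALSE]) -
      colMeans(X[g1, , drop = FALSE])
    w <- solve(Sw_reg, dmu)
    z <- drop(X %*% w)
    within <- (stats::var(z[g1]) * (sum(g1) - 1) +
                 stats::var(z[!g1]) * (sum(!g1) - 1)) / (length(z) - 2)
    sep[nm] <<- (mean(z[!g1]) - mean(z[g1]))^2 / max(within, 1e-12)
    tibble(feature_set = nm, sample = seq_along(z),
           label = as.character(labels), projection = z)
  })
  structure(out, class = c("rh_lda", class(out)),
            separation = sep, shrinkage = lambda)
}
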