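filter_report <- function(stage, bundle_in, keep, parameters,
                          skipped = FALSE, reasons = NULL) {
  removed <- bundle_in$probe_ids[!keep]
  structure(
    list(stage = stage,
         n_in = n_probes(bundle_in),
         n_kept = sum(keep),
         n_removed = sum(!keep),
         removed_ids = removed,
         parameters = parameters,
         skipped = skipped,
         reasons = reasons),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report:%s> %d -> %d probes (%d removed)%s\n",
              x$stage, x$n_in, x$n_kept, x$n_removed,
              if (isTRUE(x$skipped)) " [skipped]" else ""))
  invisible(x)
}

#' Presence filter: keep probes expressed above a floor in every sample
#'
#' A probe survives only when its presence-scale (linear) value is at or
#' above `floor` in *all* samples; the boundary is inclusive (a probe sitting
#' exactly at the floor everywhere is kept).
#'
#' @param bundle An [expression_bundle()].
#' @param floor Minimum presence-scale value (default 50).
#' @return A list `(bundle, report)` with the filtered bundle and a
#'   `filter_report`.
#' @export
presence_filter <- function(bundle, floor = 50) {
  keep <- rowSums(bundle$presence < floor) == 0L
  if (!any(keep)) {
    warning("presence filter removed every probe", call. = FALSE)
  }
  list(bundle = subset_probes(bundle, keep),
       report = filter_report("presence", bundle, keep,
                              list(floor = floor)))
}

#' Coefficient-of-variation filter: drop invariant probes
#'
#' The CV of each probe is computed across samples on the variance-scale
#' matrix with the sample standard deviation (n - 1). Under the standard
#' `sd_over_mean` convention (default) probes with CV >= `min_cv` are kept;
#' `mean_over_sd` applies the same keep rule to the inverted ratio for
#' compatibility with sources that define CV that way. Probes whose ratio is
#' undefined (zero mean, resp. zero sd) are removed with a dedicated reason
#' code.
#'
#' @param bundle An [expression_bundle()] with a variance-scale matrix.
#' @param min_cv Minimum CV to keep a probe (default 0.10 = 10%).
#' @param convention `"sd_over_mean"` (standard) or `"mean_over_sd"`.
#' @param ann Optional [sample_annotations()], required for
#'   `scope = "per_group"`.
#' @param scope `"all"` computes CV across all samples; `"per_group"` keeps
#'   a probe when its CV clears `min_cv` in at least one group.
#' @return A list `(bundle, report)`.
#' @export
cv_filter <- function(bundle, min_cv = 0.10,
                      convention = c("sd_over_mean", "mean_over_sd"),
                      ann = NULL, scope = c("all", "per_group")) {
  convention <- match.arg(convention)
  scope <- match.arg(scope)
  m <- bundle$variance
  if (is.null(m)) stop("cv_filter needs a variance-scale matrix", call. = FALSE)

  cv_keep <- function(cols) {
    mu <- rowMeans(m[, cols, drop = FALSE])
    s <- row_sd(m[, cols, drop = FALSE])
    if (convention == "sd_over_mean") {
      ratio <- ifelse(mu == 0, NA_real_, s / mu)
    } else {
      ratio <- ifelse(s == 0, NA_real_, mu / s)
    }
    list(keep = !is.na(ratio) & ratio >= min_cv, undefined = is.na(ratio))
  }

  if (scope == "all") {
    r <- cv_keep(seq_len(n_samples(bundle)))
    keep <- r$keep
    undefined <- r$undefined
  } else {
    if (is.null(ann)) stop("per_group CV needs sample annotations", call. = FALSE)
    groups <- unique(ann$group)
    parts <- lapply(groups, function(g) {
      cv_keep(which(bundle$sample_ids %in% ann$sample_id[ann$group == g]))
    })
    keep <- Reduce(`|`, lapply(parts, `[[`, "keep"))
    undefined <- Reduce(`&`, lapply(parts, `[[`, "undefined"))
  }
  reasons <- rep("below_min_cv", sum(!keep))
  names(reasons) <- bundle$probe_ids[!keep]
  reasons[bundle$probe_ids[undefined & !keep]] <-
    if (convention == "sd_over_mean") "zero_mean" else "zero_sd"
  list(bundle = subset_probes(bundle, keep),
       report = filter_report("cv", bundle, keep,
                              list(min_cv = min_cv, convention = convention,
                                   scope = scope),
                              reasons = reasons))
}

#' Sex filter: drop probes differing between male and female samples
#'
#' A two-sided Welch t-test compares male vs female values on the
#' variance-scale matrix, pooled over all samples regardless of group;
#' probes with p < `alpha` are removed. With fewer than two annotated
#' samples per sex the filter is skipped with an explicit warning and the
#' report flags `skipped = TRUE`.
#'
#' @param bundle An [expression_bundle()].
#' @param ann A [sample_annotations()] data frame carrying `sex`.
#' @param alpha Removal threshold on the Welch p-value (default 0.05).
#' @param test Currently only `"welch_t"`.
#' @return A list `(bundle, report)`.
#' @export
sex_filter <- function(bundle, ann, alpha = 0.05, test = "welch_t") {
  test <- match.arg(test, "welch_t")
  sex <- ann$sex[match(bundle$sample_ids, ann$sample_id)]
  males <- which(sex == "male")
  females <- which(sex == "female")
  if (length(males) < 2L || length(females) < 2L) {
    warning("sex filter skipped: fewer than 2 annotated samples per sex",
            call. = FALSE)
    keep <- rep(TRUE, n_probes(bundle))
    return(list(bundle = bundle,
                report = filter_report("sex", bundle, keep,
                                       list(alpha = alpha, test = test),
                                       skipped = TRUE)))
  }
  m <- analysis_matrix(bundle)
  p <- row_welch_p(m[, males, drop = FALSE], m[, females, drop = FALSE])
  keep <- !(p < alpha)
  list(bundle = subset_probes(bundle, keep),
       report = filter_report("sex", bundle, keep,
                              list(alpha = alpha, test = test)))
}

## Vectorised two-sided Welch t-test p-values per row. Rows with zero
## variance in both groups get p = 1 when the means agree (no evidence of a
## difference) and p = 0 when they differ exactly.
row_welch_p <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- row_sd(a)^2; v2 <- row_sd(b)^2
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- se2 == 0
  p[degenerate & m1 == m2] <- 1
  p[degenerate & m1 != m2] <- 0
  p
}

#' Run the three-stage filtering cascade
#'
#' Applies the presence floor, then the CV filter, then the sex filter, in
#' that fixed order. Because each stage is an independent per-probe
#' predicate, the surviving set equals the intersection of the three
#' stand-alone filters' keep-sets; the reports' counts telescope.
#'
#' @param bundle An [expression_bundle()].
#' @param ann A [sample_annotations()] data frame.
#' @param presence_floor,min_cv,cv_convention,cv_scope,sex_alpha Stage
#'   parameters; see [presence_filter()], [cv_filter()], [sex_filter()].
#' @return A list `(bundle, reports)`; `reports` is a list of three
#'   `filter_report`s in cascade order.
#' @export
run_cascade <- function(bundle, ann, presence_floor = 50, min_cv = 0.10,
                        cv_convention = "sd_over_mean", cv_scope = "all",
                        sex_alpha = 0.05) {
  s1 <- presence_filter(bundle, floor = presence_floor)
  s2 <- cv_filter(s1$bundle, min_cv = min_cv, convention = cv_convention,
                  ann = ann, scope = cv_scope)
  s3 <- sex_filter(s2$bundle, ann, alpha = sex_alpha)
  list(bundle = s3$bundle,
       reports = list(s1$report, s2$report, s3$report))
}
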