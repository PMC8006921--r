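#' Delta-delta-Ct relative quantification of a qPCR array
#'
#' Per sample, each target gene's Ct is normalized by the mean housekeeping
#' Ct of that sample (`dCt = Ct_gene - mean(Ct_HK)`); the group contrast is
#' `ddCt = mean(dCt | case) - mean(dCt | control)` (mean of per-sample dCts,
#' not dCt of means), and the relative quantity is `2^(-ddCt)` with
#' `log2fc = -ddCt`. Undetermined target Cts (`NA`) are imputed to a
#' documented floor (35 cycles, the profiler-array convention) and flagged;
#' samples with an undetermined housekeeping Ct are excluded with a warning.
#'
#' @param table A long-format Ct table: columns `sample_id`, `group`,
#'   `gene`, `ct`, `is_housekeeping` (see [simulate_ct_table()]).
#' @param case_group,control_group Group labels to contrast.
#' @param hk_mean `"arithmetic"` (default) or `"geometric"` mean of the
#'   housekeeping Cts.
#' @param undetermined_floor Ct imputed for undetermined target wells.
#' @return A data frame of class `rq_table`: `gene`, `rq`, `log2fc`,
#'   `n_case`, `n_control`, `imputed` (any undetermined well involved),
#'   sorted by gene. Genes absent from either group are skipped; their
#'   names are attached as attribute `skipped`.
#' @export
ddct <- function(table, case_group, control_group,
                 hk_mean = c("arithmetic", "geometric"),
                 undetermined_floor = 35) {
  hk_mean <- match.arg(hk_mean)
  need <- c("sample_id", "group", "gene", "ct", "is_housekeeping")
  if (!all(need %in% names(table))) {
    stop("Ct table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab <- table[table$group %in% c(case_group, control_group), , drop = FALSE]
  if (!all(c(case_group, control_group) %in% tab$group)) {
    stop("both groups must be present in the Ct table", call. = FALSE)
  }
  ok_ct <- is.na(tab$ct) | (tab$ct > 0 & tab$ct <= 45)
  if (!all(ok_ct)) {
    stop("Ct values must lie in (0, 45] or be NA (undetermined)",
         call. = FALSE)
  }

  ## per-sample housekeeping reference
  hk <- tab[tab$is_housekeeping, , drop = FALSE]
  if (!nrow(hk)) stop("no housekeeping genes in the table", call. = FALSE)
  bad_samples <- unique(hk$sample_id[is.na(hk$ct)])
  if (length(bad_samples)) {
    warning("excluding sample(s) with undetermined housekeeping Ct: ",
            paste(bad_samples, collapse = ", "), call. = FALSE)
    tab <- tab[!tab$sample_id %in% bad_samples, , drop = FALSE]
    hk <- hk[!hk$sample_id %in% bad_samples, , drop = FALSE]
  }
  hk_ref <- tapply(hk$ct, hk$sample_id, function(x) {
    if (hk_mean == "arithmetic") mean(x) else exp(mean(log(x)))
  })

  tg <- tab[!tab$is_housekeeping, , drop = FALSE]
  imputed_well <- is.na(tg$ct)
  tg$ct[imputed_well] <- undetermined_floor
  tg$dct <- tg$ct - as.numeric(hk_ref[tg$sample_id])

  genes <- sort(unique(tg$gene))
  rows <- lapply(genes, function(g) {
    gi <- tg[tg$gene == g, , drop = FALSE]
    dc_case <- gi$dct[gi$group == case_group]
    dc_ctrl <- gi$dct[gi$group == control_group]
    if (!length(dc_case) || !length(dc_ctrl)) return(NULL)
    ddct_g <- mean(dc_case) - mean(dc_ctrl)
    data.frame(gene = g, rq = 2^(-ddct_g), log2fc = -ddct_g,
               n_case = length(dc_case), n_control = length(dc_ctrl),
               imputed = any(imputed_well[tg$gene == g]),
               stringsAsFactors = FALSE)
  })
  skipped <- genes[vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(gene = character(0), rq = numeric(0),
                      log2fc = numeric(0), n_case = integer(0),
                      n_control = integer(0), imputed = logical(0))
  }
  rownames(out) <- NULL
  class(out) <- c("rq_table", "data.frame")
  attr(out, "skipped") <- skipped
  out
}

#' Fura-2 F340/F380 ratio trace and summary
#'
#' Computes the per-timepoint bound/free ratio `f340 / f380` (points with
#' `f380 <= 0` are masked with a warning) plus summary statistics: mean
#' baseline ratio over the pre-stimulus window, peak ratio, and
#' peak-minus-baseline amplitude.
#'
#' @param time Numeric vector of timepoints (seconds).
#' @param f340,f380 Channel intensities, same length as `time`.
#' @param baseline_window `c(t0, t1)` time range defining the pre-stimulus
#'   baseline; default: the first 20% of the trace.
#' @return A list of class `fura_trace`: `trace` (data frame time, f340,
#'   f380, ratio), `baseline`, `peak`, `amplitude`.
#' @export
fura_ratio <- function(time, f340, f380, baseline_window = NULL) {
  if (length(unique(c(length(time), length(f340), length(f380)))) != 1L) {
    stop("time, f340 and f380 must have equal lengths", call. = FALSE)
  }
  ratio <- ifelse(f380 > 0, f340 / f380, NA_real_)
  if (anyNA(ratio)) {
    warning(sum(is.na(ratio)), " point(s) with f380 <= 0 masked",
            call. = FALSE)
  }
  if (is.null(baseline_window)) {
    t1 <- min(time) + 0.2 * diff(range(time))
    baseline_window <- c(min(time), t1)
  }
  in_base <- time >= baseline_window[1] & time <= baseline_window[2]
  baseline <- mean(ratio[in_base], na.rm = TRUE)
  peak <- max(ratio, na.rm = TRUE)
  structure(list(
    trace = data.frame(time = time, f340 = f340, f380 = f380, ratio = ratio),
    baseline = baseline, peak = peak, amplitude = peak - baseline),
    class = "fura_trace")
}

#' Corrected total cell fluorescence
#'
#' `CTCF = integrated_density - area * mean_background`, the standard
#' ImageJ-style correction. Negative values are allowed (reported as-is);
#' a `negative` attribute flags them.
#'
#' @param integrated_density Summed pixel intensity over the region.
#' @param area Region area (> 0).
#' @param mean_background Mean background intensity per unit area.
#' @return Numeric CTCF value(s) with attribute `negative`.
#' @export
ctcf <- function(integrated_density, area, mean_background) {
  if (any(!is.finite(integrated_density)) || any(!is.finite(area)) ||
      any(!is.finite(mean_background))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (any(area <= 0)) stop("area must be > 0", call. = FALSE)
  out <- integrated_density - area * mean_background
  attr(out, "negative") <- out < 0
  out
}
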