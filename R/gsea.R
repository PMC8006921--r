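#' Parameters of the enrichment pipeline
#'
#' Houses the two thresholds the signature derivation turns on: the
#' set-level nominal significance `alpha` (default 0.05) and the gene-level
#' signal-to-noise cutoffs (`+0.25` up, `-0.25` down).
#'
#' @param weight_p Running-sum exponent on the metric weights (default 1,
#'   the standard weighted statistic).
#' @param n_perm Number of phenotype permutations for nominal p-values.
#' @param alpha Set-level significance threshold.
#' @param up_cutoff,down_cutoff Signal-to-noise cutoffs for calling a gene
#'   up- or down-regulated (`up_cutoff > 0 > down_cutoff`).
#' @param sigma_floor `"none"` uses raw sample standard deviations in the
#'   signal-to-noise denominator; `"gsea_default"` floors each group sd at
#'   `0.2 * |mean|` (0.2 when the mean is 0), the desktop-tool heuristic for
#'   linear-scale data.
#' @param seed Seed for the permutation stream.
#' @return A validated list of class `pipeline_params`.
#' @export
pipeline_params <- function(weight_p = 1, n_perm = 1000, alpha = 0.05,
                            up_cutoff = 0.25, down_cutoff = -0.25,
                            sigma_floor = c("none", "gsea_default"),
                            seed = 1) {
  sigma_floor <- match.arg(sigma_floor)
  assert_that(n_perm >= 1, "n_perm must be >= 1")
  assert_that(up_cutoff > 0 && down_cutoff < 0,
              "need up_cutoff > 0 > down_cutoff")
  structure(list(weight_p = weight_p, n_perm = as.integer(n_perm),
                 alpha = alpha, up_cutoff = up_cutoff,
                 down_cutoff = down_cutoff, sigma_floor = sigma_floor,
                 seed = as.integer(seed)),
            class = "pipeline_params")
}

#' Collapse probes to one row per gene symbol (max-mean rule)
#'
#' Among the probes mapping to a symbol, the probe with the highest mean
#' presence-scale value is kept; symbols are grouped case-insensitively and
#' probes without a symbol are dropped (their count is attached as attribute
#' `n_unannotated`). Idempotent.
#'
#' @param bundle An [expression_bundle()].
#' @return A gene-level [expression_bundle()].
#' @export
collapse_probes <- function(bundle) {
  sym <- bundle$gene_symbols
  annotated <- !is.na(sym) & nzchar(sym)
  means <- rowMeans(bundle$presence)
  key <- toupper(sym)
  ## deterministic winner: highest mean, ties by original row order
  ord <- order(-means, seq_along(means))
  first_of_key <- ord[!duplicated(key[ord]) & annotated[ord]]
  keep <- sort(first_of_key)
  out <- subset_probes(bundle, keep)
  attr(out, "n_unannotated") <- sum(!annotated)
  out
}

## Signal-to-noise scores for many case/control label assignments at once.
## X: genes x samples; cm: samples x B matrix of 0/1 case indicators with a
## constant column sum n1. Returns a genes x B score matrix.
s2n_columns <- function(X, cm, sigma_floor = "none") {
  n <- ncol(X)
  n1 <- sum(cm[, 1L])
  n2 <- n - n1
  stopifnot(n1 >= 2, n2 >= 2)
  S1 <- X %*% cm
  Q1 <- (X * X) %*% cm
  tot <- rowSums(X)
  qtot <- rowSums(X * X)
  m1 <- S1 / n1
  m2 <- (tot - S1) / n2
  v1 <- pmax(Q1 - n1 * m1^2, 0) / (n1 - 1)
  v2 <- pmax((qtot - Q1) - n2 * m2^2, 0) / (n2 - 1)
  s1 <- sqrt(v1)
  s2 <- sqrt(v2)
  if (sigma_floor == "gsea_default") {
    s1 <- pmax(s1, ifelse(m1 == 0, 0.2, 0.2 * abs(m1)))
    s2 <- pmax(s2, ifelse(m2 == 0, 0.2, 0.2 * abs(m2)))
  }
  den <- s1 + s2
  out <- (m1 - m2) / den
  out[den == 0] <- 0
  out
}

#' Signal-to-noise ranking of a gene-level bundle
#'
#' Computes `(mean_case - mean_control) / (sd_case + sd_control)` per gene
#' on the variance-scale matrix (sample standard deviations), then sorts
#' descending; ties are broken lexicographically by symbol so the ranking is
#' reproducible. With `absolute = TRUE` the ranking uses the absolute score.
#'
#' @param bundle A gene-level [expression_bundle()] (see
#'   [collapse_probes()]); symbols must be unique and non-empty.
#' @param ann A [sample_annotations()] data frame.
#' @param params A [pipeline_params()].
#' @param case,control Group labels; default to the first two labels in
#'   order of appearance.
#' @param absolute Rank by `|score|` (the absolute-enrichment pre-screen
#'   metric) instead of the signed score.
#' @return A data frame of class `ranked_list` with columns `gene`, `score`,
#'   sorted by decreasing score; the metric name is attached as attribute
#'   `metric_name`.
#' @export
signal_to_noise <- function(bundle, ann, params = pipeline_params(),
                            case = NULL, control = NULL, absolute = FALSE) {
  sym <- bundle$gene_symbols
  if (any(!nzchar(sym)) || anyDuplicated(toupper(sym))) {
    stop("signal_to_noise needs unique, non-empty gene symbols; ",
         "run collapse_probes() first", call. = FALSE)
  }
  if (is.null(case) || is.null(control)) {
    g <- default_groups(ann)
    case <- case %||% g$case
    control <- control %||% g$control
  }
  check_two_groups(ann, case, control)
  idx <- match(bundle$sample_ids, ann$sample_id)
  if (anyNA(idx)) stop("samples missing from annotations", call. = FALSE)
  grp <- ann$group[idx]
  used <- grp %in% c(case, control)
  X <- analysis_matrix(bundle)[, used, drop = FALSE]
  cm <- matrix(as.numeric(grp[used] == case), ncol = 1)
  s <- drop(s2n_columns(X, cm, params$sigma_floor))
  if (params$sigma_floor == "none") {
    zero_den <- s == 0 &
      row_sd(X[, cm[, 1] == 1, drop = FALSE]) +
        row_sd(X[, cm[, 1] == 0, drop = FALSE]) == 0
    if (any(zero_den)) {
      warning(sum(zero_den),
              " gene(s) with zero pooled sd assigned score 0", call. = FALSE)
    }
  }
  if (absolute) s <- abs(s)
  ord <- order(-s, sym)
  out <- data.frame(gene = sym[ord], score = s[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  attr(out, "metric_name") <-
    if (absolute) "abs_signal_to_noise" else "signal_to_noise"
  out
}

#' Weighted running-sum enrichment score of one gene set
#'
#' Walking down the ranked list, positions holding set members ("hits") add
#' `|score|^weight_p / N_R` (with `N_R` the sum of those weights over all
#' hits) and other positions subtract `1 / (N - N_H)`. The enrichment score
#' is the running sum's value of maximal absolute deviation from zero,
#' signed. When every hit has score zero the hits add `1 / N_H` instead
#' (degenerate uniform weighting).
#'
#' @param ranked A `ranked_list` from [signal_to_noise()].
#' @param gene_set Character vector of gene symbols.
#' @param weight_p Exponent on the metric weights (default 1).
#' @return A list with `es`, `hit_positions`, `running_sum`, `leading_edge`
#'   and `n_hits`; if the set shares no gene with the list, `no_hits = TRUE`
#'   and `es` is `NA` (such sets are excluded from downstream counting).
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  genes <- ranked$gene
  N <- length(genes)
  hit <- symbols_in(genes, gene_set)
  NH <- sum(hit)
  if (NH == 0L) {
    return(list(es = NA_real_, hit_positions = integer(0),
                running_sum = NULL, leading_edge = character(0),
                n_hits = 0L, no_hits = TRUE))
  }
  w <- abs(ranked$score)^weight_p * hit
  NR <- sum(w)
  if (NR == 0) {
    w[hit] <- 1 / NH
    NR <- 1
  }
  incr <- w / NR
  if (NH < N) incr[!hit] <- -1 / (N - NH)
  running <- cumsum(incr)
  peak <- which.max(abs(running))
  es <- running[peak]
  hit_positions <- which(hit)
  leading_edge <- if (es >= 0) genes[hit & seq_len(N) <= peak]
                  else genes[hit & seq_len(N) >= peak]
  list(es = es, hit_positions = hit_positions, running_sum = running,
       leading_edge = leading_edge, n_hits = NH, no_hits = FALSE)
}

## Enrichment scores for one set across many rankings at once, from hit
## positions only. pos: k x B matrix of hit ranks; w: k x B non-negative hit
## weights (|score|^p); N: ranked-list length. The running sum is piecewise
## linear between hits, so its extrema lie just before or at hit positions;
## both candidates are evaluated per hit, in list order, and the first value
## of maximal absolute deviation is returned (matching enrichment_score()).
es_columns <- function(pos, w, N) {
  k <- nrow(pos)
  B <- ncol(pos)
  NR <- colSums(w)
  z <- NR == 0
  if (any(z)) {
    w[, z] <- 1 / k
    NR[z] <- 1
  }
  ord <- order(col(pos), pos)
  ps <- matrix(pos[ord], k, B)
  ws <- matrix(w[ord], k, B)
  cwn <- sweep(col_cumsum(ws), 2L, NR, "/")
  miss <- (ps - seq_len(k)) / max(N - k, 1)
  top <- cwn - miss
  bot <- rbind(0, cwn[-k, , drop = FALSE]) - miss
  cand <- matrix(0, 2L * k, B)
  cand[seq(1L, 2L * k, by = 2L), ] <- bot
  cand[seq(2L, 2L * k, by = 2L), ] <- top
  mi <- max.col(t(abs(cand)), ties.method = "first")
  cand[cbind(mi, seq_len(B))]
}

## Case-indicator matrix for the observed labels plus permutations.
## Column 1 is the observed assignment; when the number of distinct
## case/control relabellings is at most n_perm the permutations enumerate
## all of them (exhaustive = TRUE), otherwise n_perm are sampled.
prepare_perms <- function(case_ind, n_perm, seed) {
  n <- length(case_ind)
  n1 <- sum(case_ind)
  n_distinct <- choose(n, n1)
  exhaustive <- n_distinct <= n_perm
  cm <- withr::with_seed(seed, {
    if (exhaustive) {
      sel <- utils::combn(n, n1)
      m <- matrix(0, n, ncol(sel))
      m[cbind(as.vector(sel), rep(seq_len(ncol(sel)), each = n1))] <- 1
      m
    } else {
      m <- matrix(0, n, n_perm)
      for (b in seq_len(n_perm)) m[sample.int(n, n1), b] <- 1
      m
    }
  })
  list(cm = cbind(as.numeric(case_ind), cm), exhaustive = exhaustive)
}

## Per-column rank positions under descending score with lexicographic
## symbol tie-break.
rank_positions <- function(M, genes) {
  pos <- matrix(0L, nrow(M), ncol(M))
  ix <- seq_len(nrow(M))
  for (j in seq_len(ncol(M))) {
    o <- order(-M[, j], genes)
    pos[o, j] <- ix
  }
  pos
}

## Sign-stratified permutation p-value with add-one smoothing: the observed
## score is compared only against permuted scores of the same sign, ties
## count as extreme, and the +1 keeps p strictly positive.
perm_pvalue <- function(obs, perm) {
  s <- if (obs >= 0) 1 else -1
  same <- perm * s >= 0
  (1 + sum(same & abs(perm) >= abs(obs))) / (1 + sum(same))
}

## Shared screening core: per-set enrichment score and permutation p-value
## given the precomputed score matrix (observed + permutations).
screen_with_scores <- function(S_all, genes, library, params, mode) {
  M <- if (mode == "absolute") abs(S_all) else S_all
  pos <- rank_positions(M, genes)
  N <- length(genes)
  obs_ranked <- data.frame(gene = genes, score = M[, 1L],
                           stringsAsFactors = FALSE)
  obs_ranked <- obs_ranked[order(-obs_ranked$score, obs_ranked$gene), ]
  class(obs_ranked) <- c("ranked_list", "data.frame")

  nm <- names(library$sets)
  res <- lapply(nm, function(s) {
    members <- library$sets[[s]]
    idx <- which(symbols_in(genes, members))
    if (!length(idx)) {
      return(list(set = s, n_hits = 0L, es = NA_real_, p = NA_real_,
                  leading_edge = character(0), no_hits = TRUE))
    }
    es_vec <- es_columns(pos[idx, , drop = FALSE],
                         abs(M[idx, , drop = FALSE])^params$weight_p, N)
    obs <- enrichment_score(obs_ranked, members, params$weight_p)
    list(set = s, n_hits = length(idx), es = obs$es,
         p = perm_pvalue(es_vec[1L], es_vec[-1L]),
         leading_edge = obs$leading_edge, no_hits = FALSE)
  })
  out <- data.frame(
    set = vapply(res, `[[`, character(1), "set"),
    n_hits = vapply(res, `[[`, integer(1), "n_hits"),
    es = vapply(res, `[[`, numeric(1), "es"),
    p = vapply(res, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE
  )
  out$leading_edge <- lapply(res, `[[`, "leading_edge")
  out$no_hits <- vapply(res, `[[`, logical(1), "no_hits")
  out
}

## Resolve bundle + annotations into the score matrix over observed +
## permuted labels.
score_matrix <- function(bundle, ann, params, case, control) {
  bundle <- collapse_probes(bundle)
  if (is.null(case) || is.null(control)) {
    g <- default_groups(ann)
    case <- case %||% g$case
    control <- control %||% g$control
  }
  check_two_groups(ann, case, control)
  grp <- ann$group[match(bundle$sample_ids, ann$sample_id)]
  used <- grp %in% c(case, control)
  X <- analysis_matrix(bundle)[, used, drop = FALSE]
  perms <- prepare_perms(grp[used] == case, params$n_perm, params$seed)
  list(S_all = s2n_columns(X, perms$cm, params$sigma_floor),
       genes = bundle$gene_symbols, exhaustive = perms$exhaustive)
}

#' Permutation p-value for a single gene set
#'
#' Phenotype labels are permuted (seeded); the signal-to-noise ranking and
#' the enrichment score are recomputed per permutation, in the requested
#' mode (`"absolute"` ranks by `|score|`, the pre-screen; `"classical"` by
#' the signed score). The nominal p-value is sign-stratified with add-one
#' smoothing, so it is always strictly positive. For cohorts with fewer
#' distinct relabellings than `n_perm`, all are enumerated and the result is
#' flagged `exhaustive`.
#'
#' @param bundle An [expression_bundle()] (collapsed internally).
#' @param ann A [sample_annotations()] data frame.
#' @param gene_set Character vector of gene symbols.
#' @param params A [pipeline_params()].
#' @param mode `"classical"` or `"absolute"`.
#' @param case,control Group labels (defaults: first two in appearance order).
#' @return A one-row data frame with `set`, `n_hits`, `es`, `p`, plus
#'   attributes `leading_edge`, `mode` and `exhaustive`.
#' @export
permutation_p <- function(bundle, ann, gene_set,
                          params = pipeline_params(),
                          mode = c("classical", "absolute"),
                          case = NULL, control = NULL) {
  mode <- match.arg(mode)
  sm <- score_matrix(bundle, ann, params, case, control)
  lib <- gene_set_library(list(set = unique(as.character(gene_set))))
  out <- screen_with_scores(sm$S_all, sm$genes, lib, params, mode)
  attr(out, "leading_edge") <- out$leading_edge[[1L]]
  out$leading_edge <- NULL
  attr(out, "mode") <- mode
  attr(out, "exhaustive") <- sm$exhaustive
  out
}

#' Two-stage enrichment screen: absolute pre-screen, then classical run
#'
#' Stage 1 evaluates every set in absolute mode (ranking by `|S2N|`,
#' sensitive to sets changed in either direction); sets with a nominal
#' p-value below `alpha` proceed to stage 2, a classical signed-metric run.
#' A set is *significant* iff it clears `alpha` in both stages. Both stages
#' reuse the same seeded phenotype permutations.
#'
#' @inheritParams permutation_p
#' @param library A [gene_set_library()].
#' @return A data frame of class `gsea_screen`, one row per set, with
#'   columns `set`, `n_hits`, `es_abs`, `p_abs`, `stage2` (reached stage 2),
#'   `es`, `p` (classical; `NA` if screened out), `significant`, and a
#'   `leading_edge` list-column from the classical run.
#' @export
two_stage_screen <- function(bundle, ann, library,
                             params = pipeline_params(),
                             case = NULL, control = NULL) {
  sm <- score_matrix(bundle, ann, params, case, control)
  s1 <- screen_with_scores(sm$S_all, sm$genes, library, params, "absolute")
  pass <- !is.na(s1$p) & s1$p < params$alpha
  out <- data.frame(set = s1$set, n_hits = s1$n_hits,
                    es_abs = s1$es, p_abs = s1$p,
                    stage2 = pass, es = NA_real_, p = NA_real_,
                    significant = FALSE, stringsAsFactors = FALSE)
  out$leading_edge <- rep(list(character(0)), nrow(out))
  if (any(pass)) {
    lib2 <- gene_set_library(library$sets[pass],
                             library$descriptions[pass],
                             library$source_collection[pass])
    s2 <- screen_with_scores(sm$S_all, sm$genes, lib2, params, "classical")
    i <- match(s2$set, out$set)
    out$es[i] <- s2$es
    out$p[i] <- s2$p
    out$significant[i] <- !is.na(s2$p) & s2$p < params$alpha
    out$leading_edge[i] <- s2$leading_edge
  }
  class(out) <- c("gsea_screen", "data.frame")
  attr(out, "params") <- params
  attr(out, "exhaustive") <- sm$exhaustive
  out
}

#' Classify genes as up-, down-regulated or neutral at the score cutoff
#'
#' A gene is called *up* when its signed signal-to-noise score is at or
#' above `up_cutoff` (default +0.25, boundary inclusive), *down* at or below
#' `down_cutoff` (default -0.25), *neutral* otherwise.
#'
#' @param ranked A signed-metric `ranked_list` from [signal_to_noise()].
#' @param params A [pipeline_params()].
#' @return A data frame of class `gene_calls` with columns `gene`, `score`,
#'   `direction`.
#' @export
classify_genes <- function(ranked, params = pipeline_params()) {
  if (identical(attr(ranked, "metric_name"), "abs_signal_to_noise")) {
    stop("classify_genes needs the signed metric, not the absolute ranking",
         call. = FALSE)
  }
  direction <- ifelse(ranked$score >= params$up_cutoff, "up",
                      ifelse(ranked$score <= params$down_cutoff, "down",
                             "neutral"))
  out <- data.frame(gene = ranked$gene, score = ranked$score,
                    direction = direction, stringsAsFactors = FALSE)
  class(out) <- c("gene_calls", "data.frame")
  out
}
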