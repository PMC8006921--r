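#' Simulation configuration for the synthetic two-group study
#'
#' Defaults describe the study design the package is exercised on: a
#' 2,000-probe array over 15 cases and 15 controls with 30 up- and 30
#' down-regulated genes planted at a log2 effect of 2.0 over log2-normal
#' noise of sd 1.0, 20 sex-dimorphic nuisance genes, a 5% "absent" probe
#' fraction below the presence floor, and a 100-set library in which half
#' the sets are enriched for planted genes (60% of their members drawn from
#' the planted pool).
#'
#' @param n_probes Number of probes (one gene symbol per probe).
#' @param n_case,n_control Sample counts per group.
#' @param n_up,n_down Planted up-/down-regulated gene counts.
#' @param effect_size Mean log2 shift added to case samples of planted genes
#'   (positive for up, negative for down).
#' @param noise_sd Per-observation log2-scale noise standard deviation.
#' @param n_sex_genes Count of sex-dimorphic nuisance genes.
#' @param sex_effect Log2 shift added to male samples of sex genes.
#' @param baseline_mean,baseline_sd Log2 baseline distribution of expressed
#'   probes.
#' @param presence_floor_fraction Fraction of probes simulated as absent
#'   (all presence-scale values strictly below 50).
#' @param n_sets Gene-set count of the simulated library.
#' @param set_size_range Integer `c(min, max)` set size.
#' @param planted_set_fraction Fraction of sets enriched for planted genes.
#' @param planted_overlap Fraction of a planted set's members drawn from the
#'   planted (up or down) genes.
#' @param seed Master seed; each artifact (expression, gene sets, Ct table)
#'   draws from its own derived stream.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 2000, n_case = 15, n_control = 15,
                       n_up = 30, n_down = 30, effect_size = 2.0,
                       noise_sd = 1.0, n_sex_genes = 20, sex_effect = 2.0,
                       baseline_mean = 10.5, baseline_sd = 0.5,
                       presence_floor_fraction = 0.05,
                       n_sets = 100, set_size_range = c(25, 25),
                       planted_set_fraction = 0.5, planted_overlap = 0.6,
                       seed = 1) {
  cfg <- list(n_probes = as.integer(n_probes), n_case = as.integer(n_case),
              n_control = as.integer(n_control), n_up = as.integer(n_up),
              n_down = as.integer(n_down), effect_size = effect_size,
              noise_sd = noise_sd, n_sex_genes = as.integer(n_sex_genes),
              sex_effect = sex_effect, baseline_mean = baseline_mean,
              baseline_sd = baseline_sd,
              presence_floor_fraction = presence_floor_fraction,
              n_sets = as.integer(n_sets),
              set_size_range = as.integer(set_size_range),
              planted_set_fraction = planted_set_fraction,
              planted_overlap = planted_overlap, seed = as.integer(seed))
  counts <- c(cfg$n_probes, cfg$n_case, cfg$n_control, cfg$n_up, cfg$n_down,
              cfg$n_sex_genes, cfg$n_sets)
  assert_that(all(counts >= 0), "all counts must be >= 0")
  assert_that(cfg$n_up + cfg$n_down + cfg$n_sex_genes <= cfg$n_probes,
              "n_up + n_down + n_sex_genes must not exceed n_probes")
  fr <- c(cfg$presence_floor_fraction, cfg$planted_set_fraction,
          cfg$planted_overlap)
  assert_that(all(fr >= 0 & fr <= 1), "fractions must lie in [0, 1]")
  assert_that(length(cfg$set_size_range) == 2L &&
                cfg$set_size_range[1] >= 1 &&
                cfg$set_size_range[2] >= cfg$set_size_range[1] &&
                cfg$set_size_range[2] <= cfg$n_probes,
              "set_size_range must be within [1, n_probes]")
  assert_that(cfg$noise_sd >= 0 && cfg$baseline_sd >= 0,
              "standard deviations must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Simulate a two-group expression bundle with planted ground truth
#'
#' Expression follows a log2-normal model: the presence-scale value of gene
#' g in sample s is `2^(mu_g + delta_g * I[s in case] + s_g * I[male] + eps)`
#' with `eps ~ N(0, noise_sd)`; the variance-scale matrix is its log2
#' (emulating the paired linear/log normalization scales). Absent probes are
#' drawn around a low baseline and rescaled where needed so every value is
#' strictly below 50. Sex alternates male/female within each group.
#'
#' @param config A [sim_config()].
#' @return A list with elements `bundle` ([expression_bundle()]),
#'   `annotations` ([sample_annotations()]) and `truth` (lists of
#'   `up_genes`, `down_genes`, `sex_genes`, `absent_probes`, per-gene
#'   `effects`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seed <- derive_seeds(config$seed, 3L)[1L]
  np <- config$n_probes
  ns <- config$n_case + config$n_control
  assert_that(ns >= 2, "need at least two samples")

  withr::with_seed(seed, {
    symbols <- sprintf("GENE%04d", seq_len(np))
    probes <- sprintf("P%04d_at", seq_len(np))

    roles <- rep("background", np)
    special <- sample.int(np, config$n_up + config$n_down + config$n_sex_genes)
    up_idx <- special[seq_len(config$n_up)]
    down_idx <- special[config$n_up + seq_len(config$n_down)]
    sex_idx <- special[config$n_up + config$n_down +
                         seq_len(config$n_sex_genes)]
    roles[up_idx] <- "up"; roles[down_idx] <- "down"; roles[sex_idx] <- "sex"
    n_absent <- round(config$presence_floor_fraction * np)
    absent_idx <- if (n_absent > 0) {
      sample(which(roles == "background"), min(n_absent,
                                               sum(roles == "background")))
    } else integer(0)
    roles[absent_idx] <- "absent"

    mu <- stats::rnorm(np, config$baseline_mean, config$baseline_sd)
    mu[absent_idx] <- stats::rnorm(length(absent_idx), 4, 1)
    delta <- numeric(np)
    delta[up_idx] <- config$effect_size
    delta[down_idx] <- -config$effect_size
    sex_shift <- numeric(np)
    sex_shift[sex_idx] <- config$sex_effect

    group <- rep(c("case", "control"), c(config$n_case, config$n_control))
    sample_ids <- c(sprintf("case_%02d", seq_len(config$n_case)),
                    sprintf("ctrl_%02d", seq_len(config$n_control)))
    sex <- unlist(lapply(c(config$n_case, config$n_control), function(k) {
      rep_len(c("male", "female"), k)
    }))

    is_case <- as.numeric(group == "case")
    is_male <- as.numeric(sex == "male")
    logx <- matrix(mu, np, ns) +
      outer(delta, is_case) +
      outer(sex_shift, is_male) +
      matrix(stats::rnorm(np * ns, 0, config$noise_sd), np, ns)
    presence <- 2^logx
    ## enforce the absent-probe contract: all values strictly below the
    ## presence floor of 50
    if (length(absent_idx)) {
      mx <- apply(presence[absent_idx, , drop = FALSE], 1L, max)
      over <- which(mx >= 49.99)
      if (length(over)) {
        rows <- absent_idx[over]
        presence[rows, ] <- presence[rows, , drop = FALSE] * (49 / mx[over])
      }
    }
    variance <- log2(presence)
  })

  bundle <- expression_bundle(probes, symbols, presence, variance, sample_ids)
  ann <- sample_annotations(sample_ids, group, sex)
  truth <- list(
    up_genes = symbols[up_idx],
    down_genes = symbols[down_idx],
    sex_genes = symbols[sex_idx],
    absent_probes = probes[absent_idx],
    effects = setNames(delta, symbols)
  )
  list(bundle = bundle, annotations = ann, truth = truth)
}

#' Simulate a gene-set library with planted enriched sets
#'
#' Planted sets draw `ceiling(planted_overlap * size)` members from the
#' planted up/down genes and the remainder uniformly from non-planted genes;
#' background sets are drawn uniformly from the whole universe. Planted
#' members are dealt round-robin from shuffled passes over the planted pool,
#' so every planted gene lands in an (almost) equal number of planted sets.
#'
#' @param config A [sim_config()].
#' @param truth The `truth` element of [simulate_expression()] run on the
#'   same config.
#' @return A [gene_set_library()]; planted set names are attached as
#'   attribute `planted_sets`.
#' @export
simulate_genesets <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  seed <- derive_seeds(config$seed, 3L)[2L]
  planted_pool <- c(truth$up_genes, truth$down_genes)
  universe <- names(truth$effects)
  background_pool <- setdiff(universe, planted_pool)
  n_planted_sets <- round(config$planted_set_fraction * config$n_sets)

  withr::with_seed(seed, {
    sizes <- sample(seq(config$set_size_range[1], config$set_size_range[2]),
                    config$n_sets, replace = TRUE)
    k_planted <- ceiling(config$planted_overlap * sizes)
    if (n_planted_sets > 0) {
      if (length(planted_pool) == 0 && any(k_planted[seq_len(n_planted_sets)] > 0)) {
        stop("planted sets requested but no planted genes in the truth",
             call. = FALSE)
      }
      if (any(k_planted[seq_len(n_planted_sets)] > length(planted_pool))) {
        stop("requested planted_overlap impossible: a planted set needs more ",
             "planted members than planted genes exist", call. = FALSE)
      }
      if (any(sizes[seq_len(n_planted_sets)] - k_planted[seq_len(n_planted_sets)] >
                length(background_pool))) {
        stop("not enough non-planted genes to fill planted sets", call. = FALSE)
      }
    }

    queue <- character(0)
    draw_planted <- function(k) {
      out <- character(0)
      carry <- character(0)
      while (length(out) < k) {
        if (!length(queue)) queue <<- c(carry, sample(planted_pool))
        cand <- queue[1L]
        queue <<- queue[-1L]
        if (cand %in% out) carry <- c(carry, cand) else out <- c(out, cand)
      }
      queue <<- c(carry, queue)
      out
    }

    sets <- vector("list", config$n_sets)
    names(sets) <- sprintf("SET%03d", seq_len(config$n_sets))
    for (i in seq_len(config$n_sets)) {
      if (i <= n_planted_sets) {
        members <- draw_planted(k_planted[i])
        n_fill <- sizes[i] - length(members)
        if (n_fill > 0) {
          members <- c(members, sample(background_pool, n_fill))
        }
      } else {
        members <- sample(universe, sizes[i])
      }
      sets[[i]] <- members
    }
  })

  lib <- gene_set_library(
    sets,
    descriptions = setNames(rep("synthetic", length(sets)), names(sets)),
    source_collection = setNames(rep("synthetic", length(sets)), names(sets))
  )
  attr(lib, "planted_sets") <- names(sets)[seq_len(n_planted_sets)]
  lib
}

#' Simulate a long-format qPCR Ct table with planted fold changes
#'
#' Housekeeping genes sit at a fixed mean Ct across groups; each target
#' gene's case Ct is shifted by `-log2(fold)` relative to control, so the
#' planted relative quantity is exactly `fold` in the noiseless case.
#'
#' @param n_genes Number of target genes (the array's panel size).
#' @param n_hk Number of housekeeping genes (>= 1).
#' @param groups Named integer vector of per-group sample counts,
#'   e.g. `c(case = 3, control = 3)`.
#' @param fold_changes Optional named (by gene) or unnamed length-`n_genes`
#'   vector of planted fold changes (case vs the second group). Default:
#'   first 8 genes at fold 4, next 8 at fold 0.25, remainder at 1.
#' @param noise_sd Per-well Ct noise standard deviation (0 = noiseless).
#' @param seed Seed for baselines and noise.
#' @return A data frame of class `ct_table` with columns `sample_id`,
#'   `group`, `gene`, `ct`, `is_housekeeping`; planted fold changes are
#'   attached as attribute `truth`.
#' @export
simulate_ct_table <- function(n_genes = 84, n_hk = 5,
                              groups = c(case = 3, control = 3),
                              fold_changes = NULL, noise_sd = 0, seed = 1) {
  assert_that(n_hk >= 1, "need at least one housekeeping gene")
  assert_that(length(groups) == 2 && all(groups >= 1) &&
                !is.null(names(groups)), "groups must be a named pair of counts")
  genes <- sprintf("WNT%02d", seq_len(n_genes))
  hk <- sprintf("HK%d", seq_len(n_hk))
  if (is.null(fold_changes)) {
    fold_changes <- rep(1, n_genes)
    fold_changes[seq_len(min(8, n_genes))] <- 4
    if (n_genes > 8) {
      fold_changes[8 + seq_len(min(8, n_genes - 8))] <- 0.25
    }
    names(fold_changes) <- genes
  } else if (is.null(names(fold_changes))) {
    assert_that(length(fold_changes) == n_genes,
                "unnamed fold_changes must have one value per gene")
    names(fold_changes) <- genes
  } else {
    fc <- rep(1, n_genes); names(fc) <- genes
    fc[names(fold_changes)] <- fold_changes
    fold_changes <- fc
  }
  assert_that(all(fold_changes > 0), "fold changes must be positive")

  sub_seed <- derive_seeds(seed, 3L)[3L]
  withr::with_seed(sub_seed, {
    baseline <- stats::runif(n_genes, 22, 30)
    names(baseline) <- genes
    rows <- list()
    for (gi in seq_along(groups)) {
      gname <- names(groups)[gi]
      for (s in seq_len(groups[gi])) {
        sid <- sprintf("%s_%d", gname, s)
        shift <- if (gi == 1L) -log2(fold_changes) else rep(0, n_genes)
        ct_t <- baseline + shift +
          stats::rnorm(n_genes, 0, noise_sd)
        ct_h <- rep(18, n_hk) + stats::rnorm(n_hk, 0, noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, group = gname,
          gene = c(genes, hk), ct = c(ct_t, ct_h),
          is_housekeeping = c(rep(FALSE, n_genes), rep(TRUE, n_hk)),
          stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ct_table", "data.frame")
  attr(out, "truth") <- fold_changes
  out
}
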