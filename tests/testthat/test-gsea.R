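two_group_ann <- function(n1, n2) {
  sample_annotations(paste0("S", seq_len(n1 + n2)),
                     rep(c("case", "control"), c(n1, n2)),
                     rep(c("male", "female"), length.out = n1 + n2))
}

ranked_from <- function(genes, scores) {
  out <- data.frame(gene = genes, score = scores, stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  attr(out, "metric_name") <- "signal_to_noise"
  out
}

test_that("probe collapse keeps the max-mean probe per symbol", {
  m <- rbind(p_low = c(200, 200, 200, 200),
             p_high = c(800, 800, 800, 800),
             other = c(50, 60, 70, 80),
             unnamed = c(5, 5, 5, 5))
  colnames(m) <- paste0("S", 1:4)
  b <- expression_bundle(rownames(m), c("WNT5A", "wnt5a", "TP53", ""), m,
                         log2(m))
  cb <- collapse_probes(b)
  expect_setequal(cb$probe_ids, c("p_high", "other"))
  expect_identical(attr(cb, "n_unannotated"), 1L)
  ## idempotent, and identity when symbols are already unique
  expect_identical(collapse_probes(cb)$presence, cb$presence)
})

test_that("signal-to-noise matches direct arithmetic and is antisymmetric", {
  m <- matrix(c(2, 4, 1, 1), 1, 4,
              dimnames = list("G1", paste0("S", 1:4)))
  b <- expression_bundle("G1", "G1", 2^m, m)
  ann <- two_group_ann(2, 2)

  r_none <- signal_to_noise(b, ann, pipeline_params(sigma_floor = "none"),
                            case = "case", control = "control")
  expect_equal(r_none$score, 2 / sqrt(2), tolerance = 1e-12)

  r_floor <- signal_to_noise(b, ann,
                             pipeline_params(sigma_floor = "gsea_default"),
                             case = "case", control = "control")
  expect_equal(r_floor$score, 2 / (sqrt(2) + 0.2), tolerance = 1e-4)
  expect_equal(r_floor$score, 1.2389, tolerance = 1e-4)

  ## swapping the groups negates every score
  r_swap <- signal_to_noise(b, ann, pipeline_params(sigma_floor = "none"),
                            case = "control", control = "case")
  expect_equal(r_swap$score, -r_none$score)

  ## equal group means with nonzero spread score exactly 0
  m2 <- matrix(c(1, 3, 3, 1), 1, 4, dimnames = list("G1", paste0("S", 1:4)))
  b2 <- expression_bundle("G1", "G1", 2^m2, m2)
  expect_equal(signal_to_noise(b2, ann, case = "case",
                               control = "control")$score, 0)
})

test_that("ranking is deterministic with lexicographic tie-breaks", {
  m <- matrix(rep(c(5, 6, 3, 4), 3), 3, 4, byrow = TRUE,
              dimnames = list(c("B", "C", "A"), paste0("S", 1:4)))
  b <- expression_bundle(rownames(m), rownames(m), 2^m, m)
  r <- signal_to_noise(b, two_group_ann(2, 2), case = "case",
                       control = "control")
  expect_identical(r$gene, c("A", "B", "C"))
})

test_that("enrichment score hits the exact boundary cases", {
  rk <- ranked_from(paste0("G", 1:10), seq(5, -4, length.out = 10))
  top <- enrichment_score(rk, "G1")
  expect_equal(top$es, 1)
  bottom <- enrichment_score(rk, "G10")
  expect_equal(bottom$es, -1)
  none <- enrichment_score(rk, "ZZZ")
  expect_true(none$no_hits)
  expect_true(is.na(none$es))
})

test_that("engine ES equals the brute-force running-sum oracle", {
  set.seed(101)
  for (i in 1:200) {
    inst <- random_es_instance()
    got <- enrichment_score(inst$ranked, inst$set)
    want <- oracle_es(inst$ranked$gene, inst$ranked$score, inst$set)
    expect_equal(got$es, want, tolerance = 1e-12)
    expect_gte(got$es, -1)
    expect_lte(got$es, 1)
  }
})

test_that("ES structural invariants hold on random instances", {
  set.seed(202)
  for (i in 1:100) {
    inst <- random_es_instance()
    es <- enrichment_score(inst$ranked, inst$set)$es

    ## reversing the list negates the score
    rev_rk <- ranked_from(rev(inst$ranked$gene), rev(inst$ranked$score))
    expect_equal(enrichment_score(rev_rk, inst$set)$es, -es,
                 tolerance = 1e-12)

    ## uniform positive rescaling of the metric leaves ES unchanged
    sc_rk <- ranked_from(inst$ranked$gene, inst$ranked$score * 3.7)
    expect_equal(enrichment_score(sc_rk, inst$set)$es, es,
                 tolerance = 1e-12)
  }
})

test_that("all-zero hit scores fall back to uniform weights", {
  rk <- ranked_from(paste0("G", 1:6), c(2, 1, 0, 0, -1, -2))
  r <- enrichment_score(rk, c("G3", "G4"))
  want <- oracle_es(rk$gene, rk$score, c("G3", "G4"))
  expect_equal(r$es, want, tolerance = 1e-12)
})

test_that("leading edge is the hit prefix (suffix) up to the ES peak", {
  rk <- ranked_from(paste0("G", 1:8), c(4, 3, 2, 1, -1, -2, -3, -4))
  r <- enrichment_score(rk, c("G1", "G2", "G8"))
  peak <- which.max(abs(r$running_sum))
  expect_true(r$es >= 0)
  expect_setequal(r$leading_edge,
                  rk$gene[intersect(r$hit_positions, seq_len(peak))])
})

test_that("vectorised permutation ES path agrees with enrichment_score", {
  set.seed(303)
  for (i in 1:50) {
    inst <- random_es_instance()
    genes <- inst$ranked$gene
    N <- length(genes)
    idx <- which(genes %in% inst$set)
    pos <- matrix(seq_len(N)[idx], ncol = 1)
    w <- matrix(abs(inst$ranked$score[idx]), ncol = 1)
    es_fast <- coresig:::es_columns(pos, w, N)
    expect_equal(es_fast, enrichment_score(inst$ranked, inst$set)$es,
                 tolerance = 1e-12)
  }
})

test_that("absolute-mode ranking equals classical when scores are non-negative", {
  ## every gene upregulated in cases with a distinct effect and a fixed
  ## within-group spread, so all signed scores are positive and distinct
  base <- c(0, 0.1, 0, 0.1)
  delta <- c(G1 = 0.5, G2 = 1.5, G3 = 1.0, G4 = 2.0)
  m <- t(vapply(delta, function(d) base + c(d, d, 0, 0), numeric(4)))
  colnames(m) <- paste0("S", 1:4)
  b <- expression_bundle(names(delta), names(delta), 2^m, m)
  ann <- two_group_ann(2, 2)
  r_cls <- signal_to_noise(b, ann, case = "case", control = "control")
  r_abs <- signal_to_noise(b, ann, case = "case", control = "control",
                           absolute = TRUE)
  expect_true(all(r_cls$score > 0))
  expect_identical(r_abs$gene, r_cls$gene)
  expect_equal(r_abs$score, r_cls$score)
})

test_that("permutation p-values are deterministic and exhaust tiny cohorts", {
  sim <- simulate_expression(sim_config(n_probes = 50, n_case = 4,
                                        n_control = 4, n_up = 5, n_down = 0,
                                        n_sex_genes = 0, n_sets = 4,
                                        set_size_range = c(3, 5), seed = 12))
  set1 <- sim$truth$up_genes
  p1 <- permutation_p(sim$bundle, sim$annotations, set1,
                      pipeline_params(n_perm = 200, seed = 5),
                      case = "case", control = "control")
  p2 <- permutation_p(sim$bundle, sim$annotations, set1,
                      pipeline_params(n_perm = 200, seed = 5),
                      case = "case", control = "control")
  expect_identical(p1$p, p2$p)
  expect_gt(p1$p, 0)  # add-one smoothing
  ## choose(8, 4) = 70 <= 200 relabellings: enumerated exhaustively
  expect_true(attr(p1, "exhaustive"))
})

test_that("two-stage screen gates stage 2 on the absolute pre-screen", {
  cfg <- sim_config(n_probes = 300, n_case = 8, n_control = 8, n_up = 15,
                    n_down = 15, n_sex_genes = 0, n_sets = 20,
                    set_size_range = c(10, 15), planted_set_fraction = 0.5,
                    planted_overlap = 0.8, seed = 21)
  sim <- simulate_expression(cfg)
  lib <- simulate_genesets(cfg, sim$truth)
  params <- pipeline_params(n_perm = 200, seed = 21)
  scr <- two_stage_screen(sim$bundle, sim$annotations, lib, params,
                          case = "case", control = "control")
  expect_identical(scr$set, names(lib$sets))
  expect_true(all(is.na(scr$p[!scr$stage2])))
  expect_true(all(scr$significant[scr$significant] & scr$stage2[scr$significant]))
  ## planted sets pass at a higher rate than background sets
  planted <- scr$set %in% attr(lib, "planted_sets")
  expect_gt(mean(scr$significant[planted]), mean(scr$significant[!planted]))

  ## alpha = 1 waves every scored set through to stage 2
  scr_all <- two_stage_screen(sim$bundle, sim$annotations, lib,
                              pipeline_params(n_perm = 50, alpha = 1,
                                              seed = 21),
                              case = "case", control = "control")
  expect_true(all(scr_all$stage2[!scr_all$n_hits == 0]))

  ## ES bounds hold everywhere
  expect_true(all(abs(scr$es_abs) <= 1 + 1e-12, na.rm = TRUE))
  expect_true(all(abs(scr$es) <= 1 + 1e-12, na.rm = TRUE))
})

test_that("gene classification applies the inclusive +/-0.25 cutoffs", {
  rk <- ranked_from(c("A", "B", "C", "D", "E"),
                    c(1.0, 0.25, 0.0, -0.2499, -0.3))
  calls <- classify_genes(rk)
  expect_identical(calls$direction, c("up", "up", "neutral", "neutral",
                                      "down"))
  rk_abs <- rk
  attr(rk_abs, "metric_name") <- "abs_signal_to_noise"
  expect_error(classify_genes(rk_abs), "signed")
})
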