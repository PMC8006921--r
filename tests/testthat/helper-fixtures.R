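# Independent oracles and small fixture builders shared across tests.

## Brute-force running sum: walks the list position by position. Kept
## deliberately naive and separate from the package's implementation.
oracle_running <- function(genes, scores, set, weight_p = 1) {
  N <- length(genes)
  hit <- toupper(genes) %in% toupper(set)
  NH <- sum(hit)
  stopifnot(NH > 0)
  NR <- sum(abs(scores[hit])^weight_p)
  run <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- if (hit[i]) {
      cur + (if (NR > 0) abs(scores[i])^weight_p / NR else 1 / NH)
    } else {
      cur - 1 / (N - NH)
    }
    run[i] <- cur
  }
  run
}

oracle_es <- function(genes, scores, set, weight_p = 1) {
  run <- oracle_running(genes, scores, set, weight_p)
  run[which.max(abs(run))]
}

## Random ranked-list instance: continuous descending scores and a random
## set of >= 2 members. Instances whose running sum attains its extremum at
## exactly +x and -x are rejected: on such self-symmetric instances the
## extremum's sign is arbitrary under any deterministic tie rule, so
## sign-sensitive properties (reversal negation) are ill-posed. The check
## uses the independent brute-force running sum, not the engine.
random_es_instance <- function(n_max = 50, set_max = 10) {
  repeat {
    N <- sample(4:n_max, 1)
    genes <- sprintf("G%03d", seq_len(N))
    scores <- sort(stats::rnorm(N, 0, 2), decreasing = TRUE)
    k <- sample(2:min(set_max, N - 1), 1)
    set <- sample(genes, k)
    run <- oracle_running(genes, scores, set)
    at_max <- run[abs(abs(run) - max(abs(run))) < 1e-12]
    if (all(at_max > 0) || all(at_max < 0)) break
  }
  ranked <- data.frame(gene = genes, score = scores, stringsAsFactors = FALSE)
  class(ranked) <- c("ranked_list", "data.frame")
  list(ranked = ranked, set = set)
}

## Small bundle builder: variance matrix defaults to log2 of the presence
## matrix, mirroring the simulator's paired scales.
make_bundle <- function(m, symbols = rownames(m), probes = rownames(m),
                        variance = log2(m)) {
  expression_bundle(probes, symbols, m, variance)
}

## 10-probe cascade fixture: 7 clean keepers plus one probe failing exactly
## one stage each (presence floor, CV, sex association). Six samples,
## sex alternating male/female.
cascade_fixture <- function() {
  keep_row <- 2^c(6, 6, 8, 8, 7, 7)        # CV(log2) ~ 0.13, sex-balanced
  m <- matrix(rep(keep_row, 7), nrow = 7, byrow = TRUE)
  r_presence <- 2^c(7, 7, 7, 7, 7, 7); r_presence[2] <- 49
  r_cv <- rep(2^7, 6)                      # constant: CV = 0
  r_sex <- 2^c(10, 6, 10, 6, 10, 6)        # males high, females low
  m <- rbind(m, r_presence, r_cv, r_sex)
  rownames(m) <- c(paste0("K", 1:7), "R_PRES", "R_CV", "R_SEX")
  colnames(m) <- paste0("S", 1:6)
  bundle <- make_bundle(m)
  ann <- sample_annotations(colnames(m),
                            group = rep(c("case", "control"), 3),
                            sex = rep(c("male", "female"), 3))
  list(bundle = bundle, ann = ann)
}

## Random filter-test fixture: 8 samples (4 male / 4 female, 2 groups).
random_filter_fixture <- function(n_probes = 20) {
  m <- matrix(2^stats::rnorm(n_probes * 8, 7, 1.5), n_probes, 8)
  rownames(m) <- sprintf("P%02d", seq_len(n_probes))
  colnames(m) <- paste0("S", 1:8)
  bundle <- make_bundle(m)
  ann <- sample_annotations(colnames(m),
                            group = rep(c("case", "control"), each = 4),
                            sex = rep(c("male", "female"), 4))
  list(bundle = bundle, ann = ann)
}

## Exhaustive agglomerative clustering oracle for a distance matrix:
## repeatedly merges the closest pair under average linkage, recomputing
## cluster distances as unweighted pairwise means over members.
oracle_average_linkage <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        dij <- mean(d[clusters[[i]], clusters[[j]]])
        if (dij < best_d) { best_d <- dij; best <- c(i, j) }
      }
    }
    heights[step] <- best_d
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}
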