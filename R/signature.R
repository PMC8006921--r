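#' Count, per gene, the significant gene sets it is enriched in
#'
#' Candidate genes are those with a non-neutral direction call. In the
#' default `"leading_edge"` mode a gene is counted for a significant set
#' when it belongs to that set's core-enrichment (leading-edge) genes from
#' the classical run — the genes that actually drive the set's enrichment;
#' `"membership"` counts plain set membership instead. Candidates appearing
#' in no significant set get count 0.
#'
#' @param screen A `gsea_screen` from [two_stage_screen()], or (in
#'   membership mode) a [gene_set_library()] whose sets are all treated as
#'   significant.
#' @param gene_calls A `gene_calls` data frame from [classify_genes()].
#' @param mode `"leading_edge"` or `"membership"`.
#' @param library Required for membership mode when `screen` is a
#'   `gsea_screen`: the library the screen was run on.
#' @return A named integer vector: enrichment count per candidate gene.
#' @export
count_enrichments <- function(screen, gene_calls,
                              mode = c("leading_edge", "membership"),
                              library = NULL) {
  mode <- match.arg(mode)
  candidates <- gene_calls$gene[gene_calls$direction != "neutral"]
  counts <- setNames(integer(length(candidates)), candidates)
  if (inherits(screen, "gsea_screen")) {
    sig <- screen[screen$significant, , drop = FALSE]
    groups <- if (mode == "leading_edge") {
      sig$leading_edge
    } else {
      if (is.null(library)) {
        stop("membership counting needs the gene-set library", call. = FALSE)
      }
      library$sets[sig$set]
    }
  } else if (inherits(screen, "gene_set_library")) {
    groups <- screen$sets
  } else {
    stop("screen must be a gsea_screen or a gene_set_library", call. = FALSE)
  }
  up_cand <- toupper(candidates)
  for (g in groups) {
    hit <- up_cand %in% toupper(g)
    counts[hit] <- counts[hit] + 1L
  }
  counts
}

#' Median-threshold selection of the core signature
#'
#' The median is computed over the candidate genes' enrichment counts (an
#' even-length list takes the mean of the two middle values); a gene is
#' selected when its count *strictly exceeds* the median and its direction
#' is not neutral. With `median_universe = "all"` the median is taken over
#' every gene in `gene_calls` instead of the candidates only.
#'
#' @param counts Named counts from [count_enrichments()].
#' @param gene_calls A `gene_calls` data frame from [classify_genes()].
#' @param median_universe `"candidates"` (default) or `"all"`.
#' @return An object of class `core_signature`: a list with `table` (gene,
#'   score, count, direction, selected), `median_count`, `n_candidates`,
#'   `n_selected`, `empty`.
#' @export
median_select <- function(counts, gene_calls,
                          median_universe = c("candidates", "all")) {
  median_universe <- match.arg(median_universe)
  cand <- gene_calls[gene_calls$direction != "neutral", , drop = FALSE]
  if (nrow(cand) == 0L) {
    warning("no candidate genes: empty signature, median undefined",
            call. = FALSE)
    return(structure(list(
      table = data.frame(gene = character(0), score = numeric(0),
                         count = integer(0), direction = character(0),
                         selected = logical(0), stringsAsFactors = FALSE),
      median_count = NA_real_, n_candidates = 0L, n_selected = 0L,
      empty = TRUE), class = "core_signature"))
  }
  cand_counts <- counts[cand$gene]
  cand_counts[is.na(cand_counts)] <- 0L
  med <- if (median_universe == "candidates") {
    stats::median(as.numeric(cand_counts))
  } else {
    all_counts <- counts[gene_calls$gene]
    all_counts[is.na(all_counts)] <- 0L
    stats::median(as.numeric(all_counts))
  }
  selected <- as.numeric(cand_counts) > med
  tab <- data.frame(gene = cand$gene, score = cand$score,
                    count = as.integer(cand_counts),
                    direction = cand$direction, selected = selected,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$count, tab$gene), ]
  rownames(tab) <- NULL
  structure(list(table = tab, median_count = med,
                 n_candidates = nrow(cand), n_selected = sum(selected),
                 empty = FALSE),
            class = "core_signature")
}

#' @export
print.core_signature <- function(x, ...) {
  cat(sprintf(
    "<core_signature> %d selected of %d candidates (median count %s)\n",
    x$n_selected, x$n_candidates, format(x$median_count)))
  if (x$n_selected > 0) {
    print(utils::head(x$table[x$table$selected, ], 10))
  }
  invisible(x)
}

#' Selected genes of a core signature
#' @param signature A `core_signature`.
#' @return Character vector of selected gene symbols.
#' @export
selected_genes <- function(signature) {
  signature$table$gene[signature$table$selected]
}

#' Intersect differentially-expressed gene calls across datasets
#'
#' A gene is *shared* when it carries a non-neutral and consistent direction
#' in every collection; genes non-neutral everywhere but with conflicting
#' directions are reported separately.
#'
#' @param ... Two or more `gene_calls` data frames (or one list of them).
#' @return A list with `shared` (data frame gene, direction) and
#'   `conflicts` (character vector of gene symbols).
#' @export
intersect_deg <- function(...) {
  lists <- list(...)
  if (length(lists) == 1L && !inherits(lists[[1L]], "data.frame")) {
    lists <- lists[[1L]]
  }
  if (length(lists) < 2L) {
    stop("need at least two gene-call collections", call. = FALSE)
  }
  nonneutral <- lapply(lists, function(x) {
    x[x$direction != "neutral", c("gene", "direction")]
  })
  common <- Reduce(intersect, lapply(nonneutral, `[[`, "gene"))
  dirs <- vapply(common, function(g) {
    d <- unique(vapply(nonneutral,
                       function(x) x$direction[match(g, x$gene)],
                       character(1)))
    if (length(d) == 1L) d else "conflict"
  }, character(1))
  shared <- data.frame(gene = common[dirs != "conflict"],
                       direction = unname(dirs[dirs != "conflict"]),
                       stringsAsFactors = FALSE)
  shared <- shared[order(shared$gene), , drop = FALSE]
  rownames(shared) <- NULL
  list(shared = shared, conflicts = sort(common[dirs == "conflict"]))
}

#' Cosine hierarchical clustering
#'
#' Pairwise distance `1 - cos(x, y)` followed by agglomerative clustering
#' (average linkage by default; the linkage is configurable). Items are the
#' matrix columns for `axis = "samples"` (the heat-map sample ordering) or
#' rows for `axis = "genes"`. Leaf order is deterministic: `hclust`'s
#' ordering applied to a fixed input order.
#'
#' @param m Numeric matrix with dimnames on the clustered axis.
#' @param axis `"samples"` (columns) or `"genes"` (rows).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return An `hclust` object; the leaf labels in dendrogram order are
#'   attached as attribute `leaf_order`.
#' @export
cosine_hclust <- function(m, axis = c("samples", "genes"),
                          linkage = "average") {
  axis <- match.arg(axis)
  v <- if (axis == "samples") t(m) else m
  if (nrow(v) < 2L) stop("need at least two items to cluster", call. = FALSE)
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm == 0)) {
    bad <- rownames(v)[nrm == 0] %||% which(nrm == 0)
    stop("all-zero vector(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cs <- (v %*% t(v)) / outer(nrm, nrm)
  d <- 1 - pmin(pmax(cs, -1), 1)
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  attr(hc, "leaf_order") <- hc$labels[hc$order]
  hc
}

#' Export a dendrogram as a Newick string
#'
#' @param hc An `hclust` object (e.g. from [cosine_hclust()]).
#' @param path Optional path; when given the tree is written there.
#' @return The Newick string, invisibly when written to a file.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  tree <- ape::as.phylo(hc)
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
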