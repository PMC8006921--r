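#' Expression bundle: paired per-probe matrices plus identifiers
#'
#' The substrate of the filtering cascade and of the enrichment engine.
#' Two matrices travel together: a non-negative *presence-scale* matrix
#' (linear intensities, MAS5-like role, used by the presence floor) and an
#' optional *variance-scale* matrix (log-scale intensities, gcRMA-like role,
#' used by the CV and sex filters and by the signal-to-noise metric).
#'
#' @param probe_ids Character vector of unique probe identifiers.
#' @param gene_symbols Per-probe gene symbol; may repeat across probes and may
#'   be empty (`""`/`NA`) for unannotated probes.
#' @param presence Numeric probe x sample matrix, values >= 0.
#' @param variance Optional numeric matrix with identical dimensions and
#'   probe/sample ordering.
#' @param sample_ids Character vector of unique sample identifiers.
#' @return An object of class `expr_bundle`.
#' @export
expression_bundle <- function(probe_ids, gene_symbols, presence,
                              variance = NULL,
                              sample_ids = colnames(presence)) {
  probe_ids <- as.character(probe_ids)
  gene_symbols <- as.character(gene_symbols)
  gene_symbols[is.na(gene_symbols)] <- ""
  presence <- as.matrix(presence)
  storage.mode(presence) <- "double"
  if (is.null(sample_ids)) stop("sample_ids are required", call. = FALSE)
  sample_ids <- as.character(sample_ids)

  dup <- unique(probe_ids[duplicated(probe_ids)])
  if (length(dup)) {
    stop("duplicate probe id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup)) {
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (length(probe_ids) != nrow(presence) ||
      length(sample_ids) != ncol(presence)) {
    stop("presence matrix dimensions do not match probe/sample ids",
         call. = FALSE)
  }
  if (length(gene_symbols) != length(probe_ids)) {
    stop("gene_symbols must have one entry per probe", call. = FALSE)
  }
  if (any(presence < 0, na.rm = TRUE)) {
    stop("presence matrix must be non-negative", call. = FALSE)
  }
  dimnames(presence) <- list(probe_ids, sample_ids)
  if (!is.null(variance)) {
    variance <- as.matrix(variance)
    storage.mode(variance) <- "double"
    if (!all(dim(variance) == dim(presence))) {
      stop("variance matrix dimensions differ from presence matrix",
           call. = FALSE)
    }
    dimnames(variance) <- list(probe_ids, sample_ids)
  }
  structure(
    list(probe_ids = probe_ids, gene_symbols = gene_symbols,
         presence = presence, variance = variance, sample_ids = sample_ids),
    class = "expr_bundle"
  )
}

#' @export
print.expr_bundle <- function(x, ...) {
  cat(sprintf("<expr_bundle> %d probes x %d samples (%s variance matrix)\n",
              length(x$probe_ids), length(x$sample_ids),
              if (is.null(x$variance)) "no" else "with"))
  invisible(x)
}

#' Number of probes / samples in a bundle
#' @param bundle An `expr_bundle`.
#' @return Integer count.
#' @export
n_probes <- function(bundle) length(bundle$probe_ids)

#' @rdname n_probes
#' @export
n_samples <- function(bundle) length(bundle$sample_ids)

## Row-subset a bundle, keeping both matrices aligned.
subset_probes <- function(bundle, keep) {
  expression_bundle(
    probe_ids = bundle$probe_ids[keep],
    gene_symbols = bundle$gene_symbols[keep],
    presence = bundle$presence[keep, , drop = FALSE],
    variance = if (is.null(bundle$variance)) NULL
               else bundle$variance[keep, , drop = FALSE],
    sample_ids = bundle$sample_ids
  )
}

## The matrix the differential metric and the CV/sex filters operate on:
## variance-scale when available, presence-scale otherwise.
analysis_matrix <- function(bundle) {
  bundle$variance %||% bundle$presence
}

#' Sample annotations: group and sex per sample
#'
#' @param sample_id Unique sample identifiers.
#' @param group Categorical group label per sample (e.g. case/control).
#' @param sex Per-sample sex; accepted tokens (case-insensitive):
#'   `male`/`m`, `female`/`f`, `unknown`/`u`/`na`/`""`.
#' @return A `data.frame` of class `sample_annotations` with columns
#'   `sample_id`, `group`, `sex`.
#' @export
sample_annotations <- function(sample_id, group, sex = "unknown") {
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  sex <- rep_len(as.character(sex), length(sample_id))
  dup <- unique(sample_id[duplicated(sample_id)])
  if (length(dup)) {
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (length(group) != length(sample_id)) {
    stop("group must have one entry per sample", call. = FALSE)
  }
  sex <- normalize_sex(sex)
  structure(
    data.frame(sample_id = sample_id, group = group, sex = sex,
               stringsAsFactors = FALSE),
    class = c("sample_annotations", "data.frame")
  )
}

normalize_sex <- function(sex) {
  key <- tolower(trimws(sex))
  key[is.na(key) | key == ""] <- "unknown"
  map <- c(male = "male", m = "male",
           female = "female", f = "female",
           unknown = "unknown", u = "unknown", na = "unknown")
  out <- map[key]
  if (anyNA(out)) {
    bad <- unique(sex[is.na(out)])
    stop("unknown sex token(s): ", paste(bad, collapse = ", "),
         "; allowed: male/m, female/f, unknown/u/na", call. = FALSE)
  }
  unname(out)
}

## Check that a two-group comparison is well-posed.
check_two_groups <- function(ann, case, control, min_n = 2L) {
  tab <- table(ann$group)
  for (g in c(case, control)) {
    if (is.na(tab[g]) || tab[g] < min_n) {
      stop(sprintf("group '%s' needs >= %d samples", g, min_n), call. = FALSE)
    }
  }
  invisible(TRUE)
}

## Default case/control labels: order of first appearance in the annotations.
default_groups <- function(ann) {
  lv <- unique(ann$group)
  if (length(lv) < 2L) stop("need at least two group labels", call. = FALSE)
  list(case = lv[1L], control = lv[2L])
}

#' Gene-set library (GMT semantics)
#'
#' @param sets Named list; each element a character vector of unique gene
#'   symbols (at least one per set). Names are the set names (unique).
#' @param descriptions Optional named character vector of per-set descriptions.
#' @param source_collection Optional named character vector tagging the
#'   collection each set came from.
#' @return An object of class `gene_set_library`.
#' @export
gene_set_library <- function(sets, descriptions = NULL,
                             source_collection = NULL) {
  if (length(sets)) {
    nm <- names(sets)
    if (is.null(nm) || any(nm == "")) {
      stop("every gene set must be named", call. = FALSE)
    }
    dup <- unique(nm[duplicated(nm)])
    if (length(dup)) {
      stop("duplicate set name(s): ", paste(dup, collapse = ", "),
           call. = FALSE)
    }
    for (s in nm) {
      v <- sets[[s]]
      if (!length(v)) stop("set '", s, "' is empty", call. = FALSE)
      if (anyDuplicated(v)) {
        stop("set '", s, "' contains duplicate symbols", call. = FALSE)
      }
    }
    sets <- lapply(sets, as.character)
  }
  descriptions <- descriptions %||% setNames(rep("", length(sets)), names(sets))
  source_collection <- source_collection %||%
    setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets, descriptions = descriptions,
                 source_collection = source_collection),
            class = "gene_set_library")
}

#' @export
print.gene_set_library <- function(x, ...) {
  sz <- lengths(x$sets)
  cat(sprintf("<gene_set_library> %d sets (sizes %s)\n", length(x$sets),
              if (length(sz)) paste0(min(sz), "-", max(sz)) else "-"))
  invisible(x)
}

#' @export
length.gene_set_library <- function(x) length(x$sets)
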