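#' Read an expression matrix (GCT #1.2 or TSV) into an expression bundle
#'
#' When both a presence-scale and a variance-scale file are given, the two
#' must contain the same probe and sample sets; the variance file is
#' reconciled to the presence file's ordering *by identifier*, so permuting
#' its rows or columns never changes the result.
#'
#' @param path_presence Path to the presence-scale (linear, MAS5-role) file.
#' @param path_variance Optional path to the variance-scale (log, gcRMA-role)
#'   file.
#' @param format `"gct"` (version #1.2 only) or `"tsv"` (columns `probe_id`,
#'   `gene_symbol`, then one column per sample).
#' @return An [expression_bundle()].
#' @export
read_expression <- function(path_presence, path_variance = NULL,
                            format = c("gct", "tsv")) {
  format <- match.arg(format)
  pres <- read_expr_table(path_presence, format)
  bundle <- expression_bundle(pres$probe_ids, pres$gene_symbols, pres$values)
  if (!is.null(path_variance)) {
    varf <- read_expr_table(path_variance, format)
    ip <- match(pres$probe_ids, varf$probe_ids)
    is <- match(colnames(pres$values), colnames(varf$values))
    if (anyNA(ip) || !setequal(pres$probe_ids, varf$probe_ids)) {
      stop("probe sets differ between files; only in presence: ",
           paste(setdiff(pres$probe_ids, varf$probe_ids), collapse = ", "),
           "; only in variance: ",
           paste(setdiff(varf$probe_ids, pres$probe_ids), collapse = ", "),
           call. = FALSE)
    }
    if (anyNA(is) || !setequal(colnames(pres$values), colnames(varf$values))) {
      stop("sample sets differ between files; only in presence: ",
           paste(setdiff(colnames(pres$values), colnames(varf$values)),
                 collapse = ", "),
           "; only in variance: ",
           paste(setdiff(colnames(varf$values), colnames(pres$values)),
                 collapse = ", "),
           call. = FALSE)
    }
    bundle <- expression_bundle(pres$probe_ids, pres$gene_symbols,
                                pres$values, varf$values[ip, is, drop = FALSE])
  }
  bundle
}

read_expr_table <- function(path, format) {
  lines <- readLines(path)
  if (format == "gct") {
    if (length(lines) < 3L || trimws(lines[1L]) != "#1.2") {
      stop("unsupported GCT version in ", path,
           " (only #1.2 is supported; first line must be '#1.2')",
           call. = FALSE)
    }
    dims <- as.integer(strsplit(trimws(lines[2L]), "\t")[[1L]])
    body <- lines[-(1:2)]
    tab <- parse_delim_block(body, path)
    if (nrow(tab$values) != dims[1L] || ncol(tab$values) != dims[2L]) {
      stop(sprintf(
        "GCT header of %s declares %d x %d but file contains %d x %d",
        path, dims[1L], dims[2L], nrow(tab$values), ncol(tab$values)),
        call. = FALSE)
    }
    tab
  } else {
    parse_delim_block(lines, path)
  }
}

## Shared body parser: header (id, symbol, samples...) then data rows.
## Values read as character so a non-numeric cell can be reported by
## row/column before conversion.
parse_delim_block <- function(lines, path) {
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no data rows in ", path, call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  if (length(header) < 3L) {
    stop("expression header needs id, symbol and >=1 sample column in ",
         path, call. = FALSE)
  }
  samples <- header[-(1:2)]
  rows <- cells[-1L]
  nfield <- length(header)
  probe_ids <- character(length(rows))
  gene_symbols <- character(length(rows))
  values <- matrix(NA_real_, length(rows), length(samples),
                   dimnames = list(NULL, samples))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != nfield) {
      stop(sprintf("row %d of %s has %d fields, expected %d",
                   i + 1L, path, length(r), nfield), call. = FALSE)
    }
    probe_ids[i] <- r[1L]
    gene_symbols[i] <- r[2L]
    v <- suppressWarnings(as.numeric(r[-(1:2)]))
    bad <- which(is.na(v) & !(r[-(1:2)] %in% c("NA", "")))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at row %d (probe %s), column %s of %s",
                   r[-(1:2)][bad[1L]], i + 1L, r[1L], samples[bad[1L]], path),
           call. = FALSE)
    }
    values[i, ] <- v
  }
  dup <- unique(probe_ids[duplicated(probe_ids)])
  if (length(dup)) {
    stop("duplicate probe id(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  dup <- unique(samples[duplicated(samples)])
  if (length(dup)) {
    stop("duplicate sample id(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  rownames(values) <- probe_ids
  list(probe_ids = probe_ids, gene_symbols = gene_symbols, values = values)
}

#' Write an expression bundle to GCT (#1.2) or TSV
#'
#' @param bundle An [expression_bundle()].
#' @param path Output path.
#' @param matrix Which matrix to write: `"presence"` or `"variance"`.
#' @param format `"gct"` or `"tsv"`.
#' @return The path, invisibly.
#' @export
write_expression <- function(bundle, path, matrix = c("presence", "variance"),
                             format = c("gct", "tsv")) {
  matrix <- match.arg(matrix)
  format <- match.arg(format)
  m <- if (matrix == "presence") bundle$presence else bundle$variance
  if (is.null(m)) stop("bundle has no ", matrix, " matrix", call. = FALSE)
  body <- cbind(bundle$probe_ids, bundle$gene_symbols,
                format(m, digits = 15, trim = TRUE, scientific = FALSE))
  header <- c(if (format == "gct") "NAME" else "probe_id",
              if (format == "gct") "Description" else "gene_symbol",
              bundle$sample_ids)
  out <- c(
    if (format == "gct") c("#1.2", paste(nrow(m), ncol(m), sep = "\t")),
    paste(header, collapse = "\t"),
    apply(body, 1L, paste, collapse = "\t")
  )
  writeLines(out, path)
  invisible(path)
}

#' Read phenotype labels (CLS two-class dialect or TSV)
#'
#' CLS carries no sample identifiers or sex; identifiers default to
#' `S1..Sn` (override with `sample_ids`) and sex is `unknown`.
#'
#' @param path Input path.
#' @param format `"cls"` or `"tsv"` (columns `sample_id`, `group`, `sex`).
#' @param sample_ids Optional identifiers to attach to CLS labels, e.g. the
#'   sample ids of the matching expression file.
#' @return A [sample_annotations()] data frame.
#' @export
read_phenotypes <- function(path, format = c("cls", "tsv"),
                            sample_ids = NULL) {
  format <- match.arg(format)
  if (format == "cls") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 3L) stop("CLS file needs 3 lines: ", path, call. = FALSE)
    hdr <- strsplit(trimws(lines[1L]), "[ \t]+")[[1L]]
    n_declared <- as.integer(hdr[1L])
    n_classes <- as.integer(hdr[2L])
    cls_line <- strsplit(trimws(sub("^#", "", lines[2L])), "[ \t]+")[[1L]]
    cls_line <- cls_line[nzchar(cls_line)]
    if (length(cls_line) != n_classes) {
      stop(sprintf("CLS declares %d classes but names %d: %s",
                   n_classes, length(cls_line), path), call. = FALSE)
    }
    labels <- strsplit(trimws(lines[3L]), "[ \t]+")[[1L]]
    labels <- labels[nzchar(labels)]
    if (length(labels) != n_declared) {
      stop(sprintf("CLS declares %d samples but lists %d labels: %s",
                   n_declared, length(labels), path), call. = FALSE)
    }
    if (all(grepl("^[0-9]+$", labels))) {
      labels <- cls_line[as.integer(labels) + 1L]
    } else if (!all(labels %in% cls_line)) {
      stop("CLS label(s) not among declared class names: ",
           paste(setdiff(labels, cls_line), collapse = ", "), call. = FALSE)
    }
    ids <- sample_ids %||% paste0("S", seq_along(labels))
    if (length(ids) != length(labels)) {
      stop("sample_ids length does not match CLS label count", call. = FALSE)
    }
    sample_annotations(ids, labels, "unknown")
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    need <- c("sample_id", "group")
    if (!all(need %in% names(df))) {
      stop("phenotype TSV needs columns sample_id, group (sex optional): ",
           path, call. = FALSE)
    }
    sample_annotations(df$sample_id, df$group,
                       if ("sex" %in% names(df)) df$sex else "unknown")
  }
}

#' Write sample annotations as CLS or TSV
#'
#' @param ann A [sample_annotations()] data frame.
#' @param path Output path.
#' @param format `"cls"` or `"tsv"`.
#' @return The path, invisibly.
#' @export
write_phenotypes <- function(ann, path, format = c("cls", "tsv")) {
  format <- match.arg(format)
  if (format == "cls") {
    classes <- unique(ann$group)
    writeLines(c(
      paste(nrow(ann), length(classes), 1),
      paste("#", paste(classes, collapse = " ")),
      paste(ann$group, collapse = " ")
    ), path)
  } else {
    utils::write.table(ann, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a GMT gene-set library
#'
#' Tab-separated lines: set name, description, then gene symbols. Duplicate
#' symbols within a line are collapsed (first occurrence kept) and reported
#' through a single warning carrying the total duplicate count.
#'
#' @param path Input path.
#' @return A [gene_set_library()]; the number of collapsed duplicates is
#'   attached as attribute `n_duplicates`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path, call. = FALSE)
    lib <- gene_set_library(list())
    attr(lib, "n_duplicates") <- 0L
    return(lib)
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  n_dup <- 0L
  sets <- list()
  desc <- character(0)
  for (i in seq_along(cells)) {
    f <- cells[[i]]
    if (length(f) < 3L) {
      stop(sprintf("GMT line %d has %d fields (need name, description, >=1 symbol): %s",
                   i, length(f), path), call. = FALSE)
    }
    nm <- f[1L]
    if (nm %in% names(sets)) {
      stop("duplicate set name in ", path, ": ", nm, call. = FALSE)
    }
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    n_dup <- n_dup + sum(duplicated(genes))
    sets[[nm]] <- unique(genes)
    desc[nm] <- f[2L]
  }
  if (n_dup > 0L) {
    warning(sprintf("%d duplicate symbol(s) collapsed while reading %s",
                    n_dup, path), call. = FALSE)
  }
  lib <- gene_set_library(sets, desc)
  attr(lib, "n_duplicates") <- n_dup
  lib
}

#' Write a gene-set library as GMT
#'
#' @param library A [gene_set_library()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(library, path) {
  lines <- vapply(names(library$sets), function(nm) {
    paste(c(nm, library$descriptions[[nm]] %||% "", library$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write pipeline result objects with a deterministic layout
#'
#' Tables are emitted with a documented sort order so identical analyses give
#' byte-identical files: enrichment screens sort by classical p ascending then
#' set name; signatures, gene calls and relative quantities sort by gene;
#' filter reports keep cascade order.
#'
#' @param x A result object: the data frame returned by [two_stage_screen()],
#'   a [median_select()] signature, [classify_genes()] calls, a list of
#'   filter reports from [run_cascade()], or a [ddct()] table.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return The path, invisibly.
#' @export
write_results <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  tab <- as_result_table(x)
  if (format == "tsv") {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(tab, path, auto_unbox = FALSE, digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' Read back a TSV written by [write_results()]
#' @param path Input path.
#' @return A data frame.
#' @export
read_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

as_result_table <- function(x) UseMethod("as_result_table")

#' @export
as_result_table.data.frame <- function(x) {
  out <- x
  for (j in seq_along(out)) {
    if (is.list(out[[j]])) {
      out[[j]] <- vapply(out[[j]], function(v) paste(v, collapse = ","),
                         character(1))
    }
  }
  if (all(c("p", "set") %in% names(out))) {
    out <- out[order(out$p, out$set), , drop = FALSE]
  } else if ("gene" %in% names(out)) {
    out <- out[order(out$gene), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' @export
as_result_table.core_signature <- function(x) {
  out <- x$table[order(x$table$gene),
                 c("gene", "count", "direction", "selected")]
  rownames(out) <- NULL
  out
}

#' @export
as_result_table.filter_report <- function(x) {
  data.frame(stage = x$stage, n_in = x$n_in, n_kept = x$n_kept,
             n_removed = x$n_removed,
             removed_ids = paste(x$removed_ids, collapse = ","),
             parameters = paste(names(x$parameters), unlist(x$parameters),
                                sep = "=", collapse = ";"),
             stringsAsFactors = FALSE)
}

#' @export
as_result_table.list <- function(x) {
  if (all(vapply(x, inherits, logical(1), "filter_report"))) {
    do.call(rbind, lapply(x, as_result_table))
  } else {
    stop("cannot serialize this list as a result table", call. = FALSE)
  }
}
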