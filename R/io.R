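#' Read a gene- or exon-level count table
#'
#' Tab-separated, UTF-8, Unix newlines; a header row of sample ids. Gene
#' tables have gene ids in the first column; exon tables lead with
#' `gene_id` and `exon_id` columns. Cells must be non-negative integers
#' and ids must be unique.
#'
#' @param path File path.
#' @param kind `"gene"` or `"exon"`.
#' @param sheet Optional sample sheet for cross-validation of sample ids.
#' @return For `kind = "gene"` an integer matrix (genes x samples); for
#'   `kind = "exon"` a data frame with `gene_id`, `exon_id`, then sample
#'   columns.
#' @export
read_counts <- function(path, kind = c("gene", "exon"), sheet = NULL) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  id_cols <- if (kind == "gene") 1L else 2L
  if (kind == "exon" && !all(names(df)[1:2] == c("gene_id", "exon_id"))) {
    stop("exon table must start with gene_id and exon_id columns",
         call. = FALSE)
  }
  ids <- if (kind == "gene") df[[1L]] else paste(df[[1L]], df[[2L]], sep = ":")
  if (anyDuplicated(ids)) {
    stop("duplicate ", kind, " ids: ",
         paste(utils::head(unique(ids[duplicated(ids)]), 3), collapse = ", "),
         call. = FALSE)
  }
  samples <- names(df)[-seq_len(id_cols)]
  for (s in samples) {
    v <- suppressWarnings(as.numeric(df[[s]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad)) {
      stop(sprintf("non-integer count '%s' at (%s, %s)", df[[s]][bad[1]],
                   ids[bad[1]], s), call. = FALSE)
    }
    df[[s]] <- as.integer(v)
  }
  if (!is.null(sheet)) {
    miss <- setdiff(samples, sheet$sample_id)
    if (length(miss)) {
      stop("count samples absent from the sample sheet: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  if (kind == "gene") {
    m <- as.matrix(df[, samples, drop = FALSE])
    rownames(m) <- df[[1L]]
    m
  } else {
    df$exon_id <- as.integer(df$exon_id)
    df
  }
}

#' Write a count table
#'
#' @param counts Gene matrix or exon data frame (see [read_counts()]).
#' @param path Output path.
#' @param kind `"gene"` or `"exon"`.
#' @export
write_counts <- function(counts, path, kind = c("gene", "exon")) {
  kind <- match.arg(kind)
  if (kind == "gene") {
    df <- data.frame(gene_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    df <- counts
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' CSV with columns `sample_id`, `family`, `population`, `treatment`
#' (`control`/`ltherm`), `tissue` (`gonad`/`brain`), `stage_dpf`
#' (15/40). Sample ids must be unique and every
#' (family, tissue, stage) cell may hold at most one sample per arm.
#'
#' @param path File path.
#' @return Validated data frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet A sample-sheet data frame to validate in place.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "family", "population", "treatment", "tissue",
            "stage_dpf")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) {
    stop("sample sheet missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample ids in sample sheet", call. = FALSE)
  }
  bad <- which(!sheet$treatment %in% c("control", "ltherm"))
  if (length(bad)) {
    stop(sprintf("invalid treatment '%s' in sample sheet row %d",
                 sheet$treatment[bad[1]], bad[1]), call. = FALSE)
  }
  if (!all(sheet$tissue %in% c("gonad", "brain"))) {
    stop("tissue must be 'gonad' or 'brain'", call. = FALSE)
  }
  if (!all(sheet$stage_dpf %in% c(15L, 40L))) {
    stop("stage_dpf must be 15 or 40", call. = FALSE)
  }
  key <- paste(sheet$family, sheet$tissue, sheet$stage_dpf, sheet$treatment)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("more than one sample for (family, tissue, stage, treatment): ",
         dup, call. = FALSE)
  }
  sheet
}

#' Write a sample sheet
#' @param sheet Sample-sheet data frame.
#' @param path Output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a family-level phenotype table
#'
#' CSV with columns `population`, `family`, `treatment`, `n_stocked`,
#' `n_alive_31dpf`, `n_sexed`, `n_males`.
#'
#' @param path File path.
#' @return Validated batch data frame.
#' @export
read_phenotypes <- function(path) {
  validate_batches(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a family-level phenotype table
#' @param batches Batch data frame.
#' @param path Output path.
#' @export
write_phenotypes <- function(batches, path) {
  utils::write.csv(batches, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One term per line: term id, description, then tab-separated member
#' gene ids. Terms with an empty member list are dropped with a warning.
#'
#' @param path File path.
#' @return List with `gene_sets` (named list of member vectors) and
#'   `term_names` (named character vector of descriptions).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list(); names_v <- character()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      warning("dropping GMT term with empty member list: ", f[1],
              call. = FALSE)
      next
    }
    if (f[1] %in% names(sets)) {
      stop("duplicate GMT term id: ", f[1], call. = FALSE)
    }
    sets[[f[1]]] <- f[-(1:2)]
    names_v[f[1]] <- f[2]
  }
  list(gene_sets = sets, term_names = names_v)
}

#' Write a GMT gene-set file
#' @param gene_sets Named list of member gene-id vectors.
#' @param path Output path.
#' @param term_names Optional named descriptions (defaults to the term id).
#' @export
write_gmt <- function(gene_sets, path, term_names = NULL) {
  lines <- vapply(names(gene_sets), function(term) {
    desc <- if (!is.null(term_names) && term %in% names(term_names))
      term_names[[term]] else term
    paste(c(term, desc, gene_sets[[term]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Read an identifier mapping table
#'
#' TSV with columns `source`, `from_id`, `to_id`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_mapping <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("source", "from_id", "to_id")
  if (!all(need %in% names(df))) {
    stop("mapping table must have columns source, from_id, to_id",
         call. = FALSE)
  }
  df
}

#' @rdname read_mapping
#' @param mapping Mapping data frame.
#' @export
write_mapping <- function(mapping, path) {
  utils::write.table(mapping, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Export a seed network
#'
#' Writes a [seed_network()] graph as GraphML (node attributes
#' `deg_direction`, `corr_sign`, `is_seed`; edge attribute `weight`) or as
#' a tab-separated edge list (`from`, `to`, `weight`).
#'
#' @param graph An igraph object.
#' @param path Output path.
#' @param format `"graphml"` or `"edgelist"`.
#' @export
write_network <- function(graph, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(graph, what = "edges")
    utils::write.table(el, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
  }
  invisible(path)
}

#' Write a results table as TSV
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}
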