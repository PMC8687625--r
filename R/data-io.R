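#' Readers and writers for the pipeline's tabular formats
#'
#' All tables are tab-delimited UTF-8 with a header row.  Missing ADME
#' values may be encoded as the empty string, `NA`, or an em/en dash
#' (`—`, `–`, `-` alone), matching how chemical-analysis tables are
#' usually typeset.  Gene symbols are normalized with [normalize_gene()] at
#' the I/O boundary.
#'
#' @name data_io
NULL

MISSING_TOKENS <- c("", "NA", "—", "–", "-")

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) {
    stop_cfig("%s file not found: %s", what, path, class = "cfig_io_error")
  }
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = NULL, check.names = FALSE,
                    fileEncoding = "UTF-8")
  miss <- setdiff(required, names(tab))
  if (length(miss) > 0) {
    stop_cfig("%s file %s lacks required column(s): %s", what, path,
              paste(miss, collapse = ", "), class = "cfig_parse_error")
  }
  tab
}

parse_num <- function(x, path, col) {
  x <- trimws(x)
  x[x %in% MISSING_TOKENS] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    stop_cfig("parse error in %s, column %s, line %d: %s is not numeric",
              path, col, bad[1] + 1L, x[bad[1]], class = "cfig_parse_error")
  }
  out
}

parse_flag <- function(x) {
  tolower(trimws(x)) %in% c("true", "t", "1", "yes")
}

#' Read an ingredient table
#'
#' Expected columns: `ingredient_id`, `name`, `herbs` (herb codes joined by
#' `herb_sep`), `caco2`, `dl`, `literature_flag`; optional `concentration`
#' and `conc_unit`.  Literature-reported compounds (`literature_flag` true)
#' may lack ADME values.
#'
#' @param path TSV file path.
#' @param herb_sep delimiter between herb codes in the `herbs` column.
#' @return data.frame of ingredient records; `herbs` is a list-column of
#'   character vectors.
#' @export
read_ingredients <- function(path, herb_sep = ";") {
  tab <- read_tsv_checked(path, c("ingredient_id", "name", "herbs", "caco2",
                                  "dl", "literature_flag"), "ingredient")
  id <- trimws(tab$ingredient_id)
  if (any(id == "")) {
    stop_cfig("parse error in %s, line %d: empty ingredient_id",
              path, which(id == "")[1] + 1L, class = "cfig_parse_error")
  }
  if (anyDuplicated(id)) {
    stop_cfig("duplicate ingredient_id(s) in %s: %s", path,
              paste(unique(id[duplicated(id)]), collapse = ", "),
              class = "cfig_validation_error")
  }
  herbs <- lapply(strsplit(tab$herbs, herb_sep, fixed = TRUE), function(h) {
    h <- trimws(h)
    h[h != ""]
  })
  out <- data.frame(
    ingredient_id = id,
    name = trimws(tab$name),
    caco2 = parse_num(tab$caco2, path, "caco2"),
    dl = parse_num(tab$dl, path, "dl"),
    literature_flag = parse_flag(tab$literature_flag),
    stringsAsFactors = FALSE
  )
  out$herbs <- herbs
  if ("concentration" %in% names(tab)) {
    out$concentration <- parse_num(tab$concentration, path, "concentration")
    out$conc_unit <- if ("conc_unit" %in% names(tab)) {
      trimws(tab$conc_unit)
    } else {
      NA_character_
    }
  }
  out
}

#' Read a gene evidence table
#'
#' Expected columns: `gene`, `n_reports`, `relevance_score`; optional
#' `source`.  Each gene must carry at least one positive evidence channel.
#'
#' @param path TSV file path.
#' @return data.frame with normalized gene symbols.
#' @export
read_evidence <- function(path) {
  tab <- read_tsv_checked(path, c("gene", "n_reports", "relevance_score"),
                          "evidence")
  gene <- normalize_gene(trimws(tab$gene))
  if (anyDuplicated(gene)) {
    stop_cfig("duplicate gene(s) in %s after normalization: %s", path,
              paste(unique(gene[duplicated(gene)]), collapse = ", "),
              class = "cfig_validation_error")
  }
  out <- data.frame(
    gene = gene,
    n_reports = parse_num(tab$n_reports, path, "n_reports"),
    relevance_score = parse_num(tab$relevance_score, path, "relevance_score"),
    source = if ("source" %in% names(tab)) trimws(tab$source) else NA_character_,
    stringsAsFactors = FALSE
  )
  no_evidence <- (is.na(out$n_reports) | out$n_reports <= 0) &
    (is.na(out$relevance_score) | out$relevance_score <= 0)
  if (any(no_evidence)) {
    stop_cfig("evidence row(s) with neither reports nor relevance in %s: %s",
              path, paste(out$gene[no_evidence][1:min(5, sum(no_evidence))],
                          collapse = ", "),
              class = "cfig_validation_error")
  }
  out
}

#' Read an undirected edge list
#'
#' Two tab-separated columns (header `from`, `to`).  Self-loops are dropped
#' with a warning, duplicate undirected edges (either orientation)
#' deduplicated, and symbols normalized.
#'
#' @param path TSV file path.
#' @return data.frame edge list (`from`, `to`).
#' @export
read_network <- function(path) {
  tab <- read_tsv_checked(path, c("from", "to"), "network")
  if (ncol(tab) != 2) {
    stop_cfig("network file %s must have exactly 2 columns, found %d",
              path, ncol(tab), class = "cfig_parse_error")
  }
  canonical_edges(data.frame(from = normalize_gene(tab$from),
                             to = normalize_gene(tab$to)))
}

#' Read ingredient-target associations
#'
#' @param path TSV file path with columns `ingredient_id`, `target_gene`.
#' @return data.frame of unique associations, targets normalized.
#' @export
read_associations <- function(path) {
  tab <- read_tsv_checked(path, c("ingredient_id", "target_gene"),
                          "association")
  unique(data.frame(
    ingredient_id = trimws(tab$ingredient_id),
    target_gene = normalize_gene(tab$target_gene),
    stringsAsFactors = FALSE
  ))
}

#' Read a GMT annotation collection
#'
#' Standard GMT: one term per line, tab-separated `term id`, `description`,
#' then member genes.  Lines with fewer than three fields are a parse error.
#' A zero-line file is a valid empty collection.
#'
#' @param path GMT file path.
#' @return named list of character gene-set vectors, with a `description`
#'   attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    stop_cfig("GMT file not found: %s", path, class = "cfig_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  terms <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop_cfig("GMT parse error in %s, line %d: fewer than 3 fields",
                path, i, class = "cfig_parse_error")
    }
    id <- trimws(fields[1])
    if (id %in% names(terms)) {
      stop_cfig("duplicate term id in %s: %s", path, id,
                class = "cfig_validation_error")
    }
    terms[[id]] <- unique(normalize_gene(fields[-(1:2)]))
    desc[id] <- fields[2]
  }
  attr(terms, "description") <- desc
  terms
}

#' Write a GMT annotation collection
#'
#' @param annotations named list of gene sets (optionally with a
#'   `description` attribute).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotations, path) {
  desc <- attr(annotations, "description")
  lines <- vapply(names(annotations), function(id) {
    d <- if (!is.null(desc) && id %in% names(desc)) desc[[id]] else id
    paste(c(id, d, annotations[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

write_tsv <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Packaged reference fixtures
#'
#' Paths to the plain-text tables shipped with the package: the
#' literature-reported ingredient table (36 chemical-analysis compounds of
#' the five-herb injection), the per-herb ingredient count summary, and the
#' 60-ingredient critical functional ingredients group table with their
#' Caco-2 / DL values.
#'
#' @param name one of `"table1_ingredients"`, `"table2_counts"`,
#'   `"table3_cfig"`, `"greek_map"`.
#' @return file path.
#' @export
cfig_fixture <- function(name = c("table1_ingredients", "table2_counts",
                                  "table3_cfig", "greek_map")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, ".tsv"), package = "cfig",
              mustWork = TRUE)
}
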