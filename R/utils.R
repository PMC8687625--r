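#' @keywords internal
"_PACKAGE"

#' @importFrom stats median phyper p.adjust rlnorm rnbinom rpois runif setNames
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

greek_map_cache <- new.env(parent = emptyenv())

# Greek-letter transliteration used when normalizing gene symbols
# (e.g. "IL-1β" -> "IL1B").  Shipped as a plain mapping table so the
# convention is visible to users.
greek_map <- function() {
  if (is.null(greek_map_cache$map)) {
    path <- system.file("extdata", "greek_map.tsv", package = "cfig")
    tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    greek_map_cache$map <- setNames(tab$latin, tab$greek)
  }
  greek_map_cache$map
}

#' Normalize gene symbols
#'
#' Upper-cases symbols, transliterates Greek letters (beta -> B, alpha -> A,
#' ...) using the packaged mapping table, and strips hyphens, so that mixed
#' styles such as `IL-1β` and `IL1B` collapse to one identifier.  Applied at
#' every I/O boundary; purely syntactic (no alias resolution).
#'
#' @param x character vector of gene symbols.
#' @return character vector of normalized symbols.
#' @export
#' @examples
#' normalize_gene(c("IL-1β", "Tnf", "NF-κB"))
normalize_gene <- function(x) {
  x <- as.character(x)
  map <- greek_map()
  for (g in names(map)) {
    x <- gsub(g, map[[g]], x, fixed = TRUE)
  }
  x <- toupper(x)
  gsub("-", "", x, fixed = TRUE)
}

stop_cfig <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "cfig_error")))
}
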