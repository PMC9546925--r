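#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one term per line, tab-delimited as
#' \code{term<TAB>description<TAB>gene1<TAB>gene2...}. The description
#' field is ignored; duplicate genes within a term are deduplicated.
#'
#' @param path GMT file path.
#' @return A named list of character vectors (term -> gene symbols),
#'   class \code{gene_set_collection}.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L)
    stop("GMT line ", bad[1L], " has fewer than 3 tab-separated fields")
  terms <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(terms))
    stop("duplicate term names in GMT: ",
         paste(unique(terms[duplicated(terms)]), collapse = ", "))
  sets <- lapply(fields, function(x) unique(x[-(1:2)]))
  names(sets) <- terms
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#' @param collection named list of gene vectors.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, "na", collection[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d terms, %d distinct genes\n",
              length(x), length(unique(unlist(x)))))
  invisible(x)
}
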