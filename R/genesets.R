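#' Gene-set collections
#'
#' A `GeneSetCollection` is a named list of gene sets (protein complexes,
#' pathways) with an optional background universe. Gene symbols are
#' case-normalized to uppercase on construction; blank or missing symbols are
#' dropped with a message. Set names must be unique and no set may end up
#' empty.
#'
#' @param sets named list of character vectors of gene symbols.
#' @param descriptions optional character vector, one per set (recycled from
#'   `""` when absent).
#' @param universe optional character vector: the background gene universe.
#' @return an object of class `GeneSetCollection` with elements `sets`
#'   (named list of uppercase symbol vectors), `descriptions`, `universe`.
#' @examples
#' gsc <- gene_set_collection(list(C1 = c("kras", "BRCA1"), C2 = c("RPA1", "RPA2")))
#' lengths(gsc$sets)
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe = NULL) {
  if (!is.list(sets) || length(sets) == 0L)
    stop("'sets' must be a nonempty named list of character vectors")
  nm <- names(sets)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    stop("every gene set must be named")
  if (anyDuplicated(nm))
    stop("duplicate set names: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  n_dropped <- 0L
  sets <- lapply(sets, function(g) {
    g <- as.character(g)
    keep <- !is.na(g) & nzchar(trimws(g))
    n_dropped <<- n_dropped + sum(!keep)
    unique(toupper(trimws(g[keep])))
  })
  if (n_dropped > 0L)
    message("gene_set_collection: dropped ", n_dropped, " blank/NA gene symbols")
  if (any(lengths(sets) == 0L))
    stop("empty gene set(s): ",
         paste(nm[lengths(sets) == 0L], collapse = ", "))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  descriptions <- rep_len(as.character(descriptions), length(sets))
  names(descriptions) <- nm
  if (!is.null(universe)) universe <- unique(toupper(trimws(as.character(universe))))
  structure(list(sets = sets, descriptions = descriptions, universe = universe),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat("GeneSetCollection:", length(x$sets), "sets,",
      length(unique(unlist(x$sets))), "distinct genes")
  if (!is.null(x$universe)) cat(",", length(x$universe), "universe genes")
  cat("\n")
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' GMT is the tab-separated format used for complex and pathway catalogues:
#' one set per line, fields `name`, `description`, then gene symbols.
#'
#' @param path file path.
#' @param universe optional background universe passed through to the
#'   collection.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("GMT line(s) with fewer than 3 fields: ", paste(bad, collapse = ", "))
  nms <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nms
  gene_set_collection(sets, descriptions = desc, universe = universe)
}

#' Write a collection to GMT
#'
#' @param collection a `GeneSetCollection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
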