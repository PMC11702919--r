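# Gene set collections and GMT I/O.

#' Create a gene set collection
#'
#' A named collection of gene sets (e.g. pathways) with optional per-set
#' descriptions and an optional gene universe. This is the container consumed
#' by [gsea_es()], [ssgsea()], [ora()] and the propagation annotators.
#'
#' @param sets named list of character vectors of gene IDs. Each set must be
#'   non-empty; duplicate members within a set are an error.
#' @param descriptions optional character vector (recycled name-wise); default
#'   empty strings.
#' @param universe optional character vector of all gene IDs the sets live in.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe = NULL) {
  if (!is.list(sets))
    abort_invalid("'sets' must be a named list of character vectors")
  if (length(sets) > 0 && (is.null(names(sets)) || any(!nzchar(names(sets)))))
    abort_invalid("'sets' must be a named list of character vectors")
  if (anyDuplicated(names(sets)))
    abort_invalid("duplicate gene set names")
  for (nm in names(sets)) {
    members <- sets[[nm]]
    if (!is.character(members) || length(members) == 0)
      abort_invalid(sprintf("gene set '%s' is empty or not character", nm))
    if (anyDuplicated(members))
      abort_invalid(sprintf("gene set '%s' has duplicate members", nm))
  }
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("", length(sets)), names(sets))
  } else {
    descriptions <- setNames(rep_len(as.character(descriptions), length(sets)),
                             names(sets))
  }
  structure(list(sets = sets, descriptions = descriptions, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat(sprintf("gene_set_collection: %d sets (sizes %d-%d)%s\n",
              length(x$sets),
              if (length(sizes)) min(sizes) else 0L,
              if (length(sizes)) max(sizes) else 0L,
              if (is.null(x$universe)) "" else
                sprintf(", universe %d genes", length(x$universe))))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read a GMT file
#'
#' GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Empty member fields are
#' skipped with a warning; a line with fewer than three fields is an error
#' reporting the line number.
#'
#' @param path file path.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort_invalid(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descriptions <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("malformed GMT line %d: fewer than 3 fields", i))
    members <- fields[-(1:2)]
    if (any(!nzchar(members))) {
      warning(sprintf("GMT line %d: skipping empty member fields", i))
      members <- members[nzchar(members)]
    }
    if (length(members) == 0)
      stop(sprintf("malformed GMT line %d: no members", i))
    sets[[fields[[1]]]] <- members
    descriptions[[fields[[1]]]] <- fields[[2]]
  }
  gene_set_collection(sets, descriptions)
}

#' Write a GMT file
#'
#' @param collection a [gene_set_collection()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict a collection to a universe and size bounds
#'
#' Members are intersected with the universe; sets whose post-intersection
#' size falls outside `[min_size, max_size]` are dropped. The defaults (10 and
#' 500) are the conventional GSEA bounds.
#'
#' @param collection a [gene_set_collection()].
#' @param universe character vector of gene IDs.
#' @param min_size,max_size inclusive size bounds applied after intersection.
#' @return a filtered [gene_set_collection()] whose `universe` is set.
#' @export
filter_collection <- function(collection, universe, min_size = 10,
                              max_size = 500) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(universe) == 0) abort_invalid("universe is empty")
  kept <- list()
  for (nm in names(collection$sets)) {
    members <- intersect(collection$sets[[nm]], universe)
    if (length(members) >= min_size && length(members) <= max_size)
      kept[[nm]] <- members
  }
  gene_set_collection(
    kept,
    descriptions = collection$descriptions[names(kept)],
    universe = universe
  )
}
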