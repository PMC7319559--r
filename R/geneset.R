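#' Gene-set collections
#'
#' A `GeneSetCollection` holds named biological categories (gene sets) plus
#' the background universe against which every enrichment test in this
#' package is computed. Categories are stored as character vectors of gene
#' identifiers; identifiers are compared case-sensitively after whitespace
#' stripping.
#'
#' @param name collection name.
#' @param sets named list of character vectors (category id -> members).
#' @param set_names optional character vector of display names, parallel to
#'   `sets`; defaults to the category ids.
#' @param universe character vector of gene ids; defaults to the union of
#'   all members.
#' @return an object of class `GeneSetCollection` with fields `name`,
#'   `ids`, `set_names`, `sets` and `universe`.
#' @export
gene_set_collection <- function(name, sets, set_names = NULL, universe = NULL) {
  if (length(sets) == 0L) stop("no categories")
  ids <- names(sets)
  if (is.null(ids) || any(!nzchar(ids))) stop("every category needs an id")
  if (anyDuplicated(ids)) {
    stop("duplicate category id: ", ids[duplicated(ids)][1L])
  }
  sets <- lapply(sets, function(s) unique(trimws(as.character(s))))
  if (any(lengths(sets) == 0L)) stop("empty category not allowed")
  if (is.null(set_names)) set_names <- ids
  if (is.null(universe)) universe <- sort(unique(unlist(sets, use.names = FALSE)))
  structure(
    list(name = name, ids = ids,
         set_names = stats::setNames(as.character(set_names), ids),
         sets = sets,
         universe = unique(trimws(as.character(universe)))),
    class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  sz <- lengths(x$sets)
  cat(sprintf("GeneSetCollection '%s': %d categories, universe of %d genes\n",
              x$name, length(x$sets), length(x$universe)))
  if (length(sz)) {
    cat(sprintf("  category sizes: min %d, median %g, max %d\n",
                min(sz), stats::median(sz), max(sz)))
  }
  invisible(x)
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' Read a gene-set collection from a GMT file
#'
#' GMT is the de-facto exchange format for gene-set databases (GO, KEGG,
#' Reactome, MSigDB): one set per line, tab-separated, with the set id in
#' column 1, a free-text description in column 2 and the member gene ids in
#' the remaining columns.
#'
#' @param path path to a GMT file.
#' @param mapping optional two-column data.frame (or path to a header-less
#'   two-column TSV) mapping old gene ids to new ones; applied to members
#'   and, implicitly, to the universe.
#' @param name collection name, default the file name.
#' @return a [gene_set_collection()]; the universe is the union of all
#'   members (use [harmonize()] to override it).
#' @export
read_gmt <- function(path, mapping = NULL, name = basename(path)) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no categories in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop(sprintf("malformed GMT line %d in %s: need >= 3 tab-separated fields",
                 bad[1L], path))
  }
  ids <- trimws(vapply(fields, `[[`, "", 1L))
  if (anyDuplicated(ids)) {
    stop("duplicate category id in ", path, ": ", ids[duplicated(ids)][1L])
  }
  descs <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) {
    m <- trimws(f[-(1:2)])
    unique(m[nzchar(m)])
  })
  names(sets) <- ids
  if (!is.null(mapping)) {
    map <- .read_id_mapping(mapping)
    sets <- lapply(sets, function(s) {
      hit <- match(s, map$from)
      s[!is.na(hit)] <- map$to[hit[!is.na(hit)]]
      unique(s)
    })
  }
  gene_set_collection(name, sets, set_names = descs)
}

.read_id_mapping <- function(mapping) {
  if (is.character(mapping) && length(mapping) == 1L) {
    mapping <- utils::read.table(mapping, sep = "\t", header = FALSE,
                                 colClasses = "character", quote = "",
                                 comment.char = "")
  }
  if (ncol(mapping) < 2L) stop("id mapping needs two columns")
  data.frame(from = trimws(mapping[[1L]]), to = trimws(mapping[[2L]]),
             stringsAsFactors = FALSE)
}

#' Write a gene-set collection to a GMT file
#'
#' Emits the same dialect [read_gmt()] reads, so write/read round-trips
#' category membership exactly.
#'
#' @param coll a `GeneSetCollection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(coll, path) {
  stopifnot(inherits(coll, "GeneSetCollection"))
  lines <- vapply(coll$ids, function(id) {
    paste(c(id, coll$set_names[[id]], coll$sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Filter categories by size
#'
#' Retains categories whose intersection with the current universe has
#' between `min_size` and `max_size` members. ORA on singleton or huge
#' categories is uninformative, hence the default bounds of 2 and 1000.
#'
#' @param coll a `GeneSetCollection`.
#' @param min_size,max_size inclusive size bounds.
#' @return the filtered collection; the universe is unchanged. An empty
#'   result is returned (with a warning) rather than an error.
#' @export
filter_by_size <- function(coll, min_size = 2L, max_size = 1000L) {
  stopifnot(inherits(coll, "GeneSetCollection"))
  if (min_size < 1L || min_size > max_size) {
    stop("need 1 <= min_size <= max_size")
  }
  eff <- vapply(coll$sets, function(s) sum(s %in% coll$universe), 0L)
  keep <- eff >= min_size & eff <= max_size
  if (!any(keep)) warning("size filter removed every category")
  coll$ids <- coll$ids[keep]
  coll$set_names <- coll$set_names[keep]
  coll$sets <- coll$sets[keep]
  coll
}

#' Harmonize a collection against a gene universe
#'
#' Intersects every category with `universe` and replaces the collection's
#' universe, so that every enrichment test sees a consistent background.
#' Categories left empty by the intersection are dropped with a warning.
#'
#' @param coll a `GeneSetCollection`.
#' @param universe non-empty character vector of gene ids.
#' @return the harmonized collection; afterwards every category is a subset
#'   of the universe.
#' @export
harmonize <- function(coll, universe) {
  stopifnot(inherits(coll, "GeneSetCollection"))
  universe <- unique(trimws(as.character(universe)))
  if (length(universe) == 0L) stop("universe must be nonempty")
  sets <- lapply(coll$sets, function(s) s[s %in% universe])
  drop <- lengths(sets) == 0L
  if (any(drop)) {
    warning(sum(drop), " categories fell fully outside the universe and were dropped")
  }
  coll$ids <- coll$ids[!drop]
  coll$set_names <- coll$set_names[!drop]
  coll$sets <- sets[!drop]
  coll$universe <- universe
  coll
}
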