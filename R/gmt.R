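# GMT gene-set collection input/output (MSigDB dialect: one set per line,
# tab-separated: name, description, members...).

#' Read a gene-set collection from a GMT file
#'
#' Each well-formed line has at least three tab-separated fields: set name,
#' description, and one or more member gene ids. Duplicate members within a
#' set are removed with a warning.
#'
#' @param path path to a GMT file.
#' @return Named list of character vectors (the member ids); descriptions are
#'   kept in the `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  descs <- character(length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    f <- f[nzchar(f)]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, ": fewer than 3 fields")
    nms[i] <- f[1L]
    descs[i] <- f[2L]
    mem <- f[-(1:2)]
    if (anyDuplicated(mem)) {
      warning("duplicate members in set '", f[1L], "' deduplicated")
      mem <- unique(mem)
    }
    sets[[i]] <- mem
  }
  names(sets) <- nms
  names(descs) <- nms
  attr(sets, "descriptions") <- descs
  sets
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets named list of character vectors of member gene ids.
#' @param path output file path.
#' @param descriptions optional character vector of per-set descriptions
#'   (defaults to the `descriptions` attribute of `sets`, or `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  if (any(lengths(sets) == 0L)) stop("cannot write a set with no members")
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[[i]], sets[[i]]), collapse = "\t"),
    character(1L))
  writeLines(lines, path)
  invisible(path)
}
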