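#' Tie-aware ranked list of reference species
#'
#' A `ranked_list` is the central container of the package: an ordered
#' sequence of ranks (rank 1 first), where each rank is a non-empty set of
#' reference species labels that achieved exactly equal similarity scores.
#' Lists derived from different queries need not contain the same labels
#' (non-conjoint), may differ in length, and may be empty (a query with no
#' hits at all).
#'
#' Invariants enforced at construction:
#' * every rank is a non-empty set of unique, non-empty labels;
#' * no label appears in more than one rank;
#' * labels are used as given (surrounding whitespace trimmed, case kept).
#'
#' @param ranks list of character vectors, best rank first. Tied labels share
#'   one vector.
#' @param query_id optional label of the query the list was derived from.
#' @return An object of class `ranked_list` with elements `query_id` and
#'   `ranks`.
#' @examples
#' ranked_list(list("Yersinia enterocolitica",
#'                  c("Yersinia rohdei", "Yersinia ruckeri")))
#' @export
ranked_list <- function(ranks = list(), query_id = NA_character_) {
  if (!is.list(ranks))
    stop("'ranks' must be a list of character vectors", call. = FALSE)
  ranks <- lapply(ranks, function(r) trimws(as.character(r)))
  validate_ranked_list(ranks)
  structure(list(query_id = as.character(query_id)[1], ranks = ranks),
            class = "ranked_list")
}

validate_ranked_list <- function(ranks) {
  if (any(vapply(ranks, length, 0L) == 0L))
    stop("every rank must contain at least one label", call. = FALSE)
  labs <- unlist(ranks, use.names = FALSE)
  if (length(labs)) {
    if (any(!nzchar(labs)))
      stop("empty label in ranked list", call. = FALSE)
    dup <- labs[duplicated(labs)]
    if (length(dup))
      stop("label appears in more than one rank: ",
           paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  invisible(ranks)
}

#' @export
length.ranked_list <- function(x) length(x$ranks)

#' @export
print.ranked_list <- function(x, ...) {
  cat("ranked_list", if (!is.na(x$query_id)) paste0("<", x$query_id, ">"),
      "with", length(x$ranks), "ranks\n")
  n_show <- min(length(x$ranks), 10L)
  for (i in seq_len(n_show))
    cat(sprintf("  %3d. %s\n", i, paste(x$ranks[[i]], collapse = ", ")))
  if (length(x$ranks) > n_show)
    cat("  ... and", length(x$ranks) - n_show, "more ranks\n")
  invisible(x)
}

#' All labels of a ranked list, best rank first
#'
#' @param x a [ranked_list()].
#' @return Character vector of labels in rank order (ties in their stored
#'   order within a rank).
#' @export
ranklist_labels <- function(x) {
  stopifnot(inherits(x, "ranked_list"))
  unlist(x$ranks, use.names = FALSE) %||% character(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove labels from a ranked list
#'
#' Deletes the given labels from every rank; ranks emptied by the removal are
#' dropped and later ranks shift up. Used by the contig-robustness protocol,
#' where a subsampled contig's parent genome must be excluded from the
#' reference before re-scoring (see [exclude_parent()]).
#'
#' @param x a [ranked_list()].
#' @param labels character vector of labels to remove; labels absent from the
#'   list are ignored.
#' @return A `ranked_list` without the given labels.
#' @examples
#' rl <- ranked_list(list(c("spA", "parent"), "spB"))
#' drop_labels(rl, "parent")
#' @export
drop_labels <- function(x, labels) {
  stopifnot(inherits(x, "ranked_list"))
  kept <- lapply(x$ranks, setdiff, y = labels)
  ranked_list(kept[vapply(kept, length, 0L) > 0L], query_id = x$query_id)
}

# ---- plain-text ranked-list format ------------------------------------------
# One rank per line in rank order; tied labels comma-separated; UTF-8;
# no blank interior lines. One file per query, named <query_id>.txt.

#' Read / write ranked lists in the plain-text format
#'
#' The on-disk format is one rank per line (best first); labels tied for a
#' rank are comma-separated on one line. A file holds the list of a single
#' query; by convention a directory of such files is named `<query_id>.txt`.
#'
#' @param path file to read or write.
#' @param query_id query label; defaults to the file name without extension.
#' @return `read_ranklist()` returns a [ranked_list()]; `write_ranklist()`
#'   invisibly returns `path`.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' write_ranklist(ranked_list(list("spA", c("spB", "spC"))), f)
#' read_ranklist(f)
#' @export
read_ranklist <- function(path, query_id = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  # trailing blank lines are tolerated, interior ones are corrupt
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (any(!nzchar(trimws(lines))))
    stop("blank interior line in ranked-list file: ", path, call. = FALSE)
  ranks <- lapply(strsplit(lines, ",", fixed = TRUE), trimws)
  ranked_list(ranks, query_id = query_id)
}

#' @rdname read_ranklist
#' @param x a [ranked_list()] to write.
#' @export
write_ranklist <- function(x, path) {
  stopifnot(inherits(x, "ranked_list"))
  writeLines(vapply(x$ranks, paste, "", collapse = ","), path, useBytes = TRUE)
  invisible(path)
}

#' Read / write a directory of ranked-list files
#'
#' @param dir directory containing (or to receive) one `<query_id>.txt` file
#'   per query.
#' @return `read_ranklist_dir()` returns a named list of [ranked_list()]
#'   objects (names = query ids, sorted); `write_ranklist_dir()` invisibly
#'   returns `dir`.
#' @export
read_ranklist_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  lists <- lapply(files, read_ranklist)
  stats::setNames(lists, vapply(lists, function(x) x$query_id, ""))
}

#' @rdname read_ranklist_dir
#' @param lists named list of [ranked_list()] objects.
#' @export
write_ranklist_dir <- function(lists, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(lists) %||% vapply(lists, function(x) x$query_id, "")
  for (i in seq_along(lists))
    write_ranklist(lists[[i]], file.path(dir, paste0(ids[i], ".txt")))
  invisible(dir)
}
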