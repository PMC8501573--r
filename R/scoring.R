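#' All-vs-all virus x host interaction score matrix
#'
#' Scores every virus ranked list against every candidate-host ranked list
#' with [rbo()]. The expanded-reference ("+viruses") mode — where the
#' reference database also contains viral sequences, so a phage and a host
#' can be linked through shared similarity to other phages — needs no
#' special handling here: it is purely a property of the input lists, and
#' both modes run through this same function.
#'
#' @param virus_lists,host_lists named lists of [ranked_list()] objects;
#'   names (or the lists' `query_id`s) must be unique within each
#'   collection.
#' @param params an [rbo_params()] object.
#' @param workers number of worker processes; values > 1 split rows across
#'   forked workers via the parallel package (output is identical for any
#'   worker count).
#' @return A numeric matrix of class `score_matrix`, viruses as rows, hosts
#'   as columns, entries in \[0, 1\].
#' @export
score_all <- function(virus_lists, host_lists, params = rbo_params(),
                      workers = 1L) {
  vids <- collection_ids(virus_lists, "virus_lists")
  hids <- collection_ids(host_lists, "host_lists")

  row_fun <- function(v)
    vapply(host_lists, function(h) rbo(v, h, params), 0)
  rows <- if (workers > 1L &&
              requireNamespace("parallel", quietly = TRUE) &&
              .Platform$OS.type == "unix") {
    parallel::mclapply(virus_lists, row_fun, mc.cores = workers)
  } else {
    lapply(virus_lists, row_fun)
  }
  m <- do.call(rbind, rows)
  dimnames(m) <- list(vids, hids)
  structure(m, class = c("score_matrix", class(m)))
}

collection_ids <- function(lists, what) {
  ids <- names(lists) %||%
    vapply(lists, function(x) x$query_id, "")
  if (is.null(names(lists)))
    ids <- vapply(lists, function(x) x$query_id, "")
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("every element of ", what, " needs an id (name or query_id)",
         call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate id in ", what, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  ids
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("score_matrix:", nrow(x), "viruses x", ncol(x), "hosts\n")
  print(unclass(x)[seq_len(min(nrow(x), 6L)), seq_len(min(ncol(x), 6L)),
                   drop = FALSE])
  invisible(x)
}

#' Exclude a contig's parent genome from ranked lists
#'
#' In the contig-robustness protocol each subsampled viral contig must not
#' be matched to its own full-length parent sequence: the parent's label is
#' removed from every rank of the given lists before scoring (ranks emptied
#' by the removal are dropped, later ranks shift up).
#'
#' @param lists named list of [ranked_list()] objects, keyed by contig id.
#' @param parent_map named character vector mapping contig id to parent
#'   genome label; every list id must be present.
#' @return The lists with each contig's parent label removed.
#' @seealso [drop_labels()] for the single-list operation;
#'   [subsample_contigs()] for generating the contigs.
#' @export
exclude_parent <- function(lists, parent_map) {
  ids <- collection_ids(lists, "lists")
  missing <- setdiff(ids, names(parent_map))
  if (length(missing))
    stop("no parent genome recorded for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- lapply(seq_along(lists), function(i)
    drop_labels(lists[[i]], parent_map[[ids[i]]]))
  stats::setNames(out, ids)
}

#' Read / write a score matrix as TSV
#'
#' Viruses as rows, hosts as columns; header row of host ids, first column
#' of virus ids. Scores are written with full precision (17 significant
#' digits, shortest round-trip) so downstream evaluation is bit-stable.
#'
#' @param x a `score_matrix` (or plain numeric matrix with dimnames).
#' @param path TSV file.
#' @return `read_score_matrix()` returns a `score_matrix`;
#'   `write_score_matrix()` invisibly returns `path`.
#' @export
write_score_matrix <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  header <- paste(c("virus_id", colnames(x)), collapse = "\t")
  body <- vapply(seq_len(nrow(x)), function(i)
    paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])), collapse = "\t"), "")
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_score_matrix
#' @export
read_score_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, quote = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  structure(m, class = c("score_matrix", class(m)))
}
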