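#' Parse BLAST tabular output (outfmt 6/7)
#'
#' Reads the standard 12-column tabular dialect (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`). Comment lines
#' starting with `#` (outfmt 7) are skipped. For every query, each subject is
#' kept once at its highest bit-score, and subjects are returned in order of
#' decreasing bit-score; subjects with exactly equal bit-scores keep their
#' input order (first appearance) and become ties when collapsed to ranks.
#'
#' No e-value or score floor is applied: whatever hits the upstream search
#' emitted are consumed.
#'
#' @param path file of BLAST tabular lines, or a character vector of lines
#'   via `text`.
#' @param text optional character vector of lines (overrides `path`).
#' @return Named list (one element per query id, in order of first
#'   appearance) of data frames with columns `subject_id`, `score`
#'   (bit-score), sorted best-first.
#' @seealso [collapse_to_ranks()] to turn each table into a [ranked_list()].
#' @export
parse_blast_tab <- function(path = NULL, text = NULL) {
  lines <- text %||% readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(stats::setNames(list(), character(0)))

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 0L)
  if (any(nf != 12L))
    stop("malformed BLAST tabular line ", lineno[which(nf != 12L)[1]],
         ": expected 12 tab-separated columns, got ", nf[nf != 12L][1],
         call. = FALSE)
  qid <- trimws(vapply(fields, `[[`, "", 1L))
  sid <- trimws(vapply(fields, `[[`, "", 2L))
  bit <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 12L)))
  if (anyNA(bit))
    stop("malformed BLAST tabular line ", lineno[which(is.na(bit))[1]],
         ": bit-score not a number", call. = FALSE)
  if (any(!nzchar(qid)) || any(!nzchar(sid)))
    stop("malformed BLAST tabular line ",
         lineno[which(!nzchar(qid) | !nzchar(sid))[1]],
         ": empty query or subject id", call. = FALSE)
  if (any(bit < 0))
    stop("malformed BLAST tabular line ", lineno[which(bit < 0)[1]],
         ": negative bit-score", call. = FALSE)

  split_hits(qid, sid, bit, best = "max")
}

#' Parse Mash distance output
#'
#' Reads the 5-column `mash dist` dialect: `reference-ID query-ID distance
#' p-value shared-hashes`. For every query, each reference is kept once at
#' its smallest distance and references are returned in order of increasing
#' distance; equal distances keep input order and become ties downstream
#' (pass `ascending = TRUE` to [collapse_to_ranks()]).
#'
#' @inheritParams parse_blast_tab
#' @return Named list per query id of data frames with columns `subject_id`,
#'   `score` (the Mash distance), sorted ascending.
#' @export
parse_mash_dist <- function(path = NULL, text = NULL) {
  lines <- text %||% readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(stats::setNames(list(), character(0)))

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 0L)
  if (any(nf != 5L))
    stop("malformed Mash dist line ", lineno[which(nf != 5L)[1]],
         ": expected 5 tab-separated columns, got ", nf[nf != 5L][1],
         call. = FALSE)
  sid <- trimws(vapply(fields, `[[`, "", 1L))  # reference = ranked subject
  qid <- trimws(vapply(fields, `[[`, "", 2L))
  dst <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(dst))
    stop("malformed Mash dist line ", lineno[which(is.na(dst))[1]],
         ": distance not a number", call. = FALSE)
  split_hits(qid, sid, dst, best = "min")
}

# per query: one row per subject at its best score, ordered best-first,
# stable (first appearance) among exact ties
split_hits <- function(qid, sid, score, best = c("max", "min")) {
  best <- match.arg(best)
  out <- lapply(split(seq_along(qid), factor(qid, levels = unique(qid))),
                function(i) {
    s <- sid[i]; v <- score[i]
    first <- !duplicated(s)
    rep_score <- if (best == "max") tapply(v, factor(s, levels = s[first]), max)
                 else                tapply(v, factor(s, levels = s[first]), min)
    d <- data.frame(subject_id = s[first],
                    score = as.numeric(rep_score[s[first]]),
                    stringsAsFactors = FALSE)
    o <- if (best == "max") order(-d$score) else order(d$score)  # stable
    d <- d[o, , drop = FALSE]
    rownames(d) <- NULL
    d
  })
  out
}

#' Read a genome-to-species mapping
#'
#' Two-column TSV: `genome_id <TAB> species`. Used to collapse multiple
#' genomes of one prokaryotic species into a single ranked label, avoiding
#' the taxonomic bias of over-represented species.
#'
#' @param path TSV file.
#' @return Named character vector: `names` are genome ids, values species
#'   labels.
#' @export
read_species_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "#")
  if (ncol(df) != 2L)
    stop("species map must have exactly 2 tab-separated columns", call. = FALSE)
  stats::setNames(trimws(df[[2]]), trimws(df[[1]]))
}

#' Collapse an ordered hit table into a tie-aware ranked list of species
#'
#' Implements the list construction at the heart of the method: subjects are
#' mapped to species, each species is kept only at its first (best)
#' appearance, and species whose representative scores are exactly equal
#' share one rank. Deduplication by species happens *before* tie grouping,
#' so a species' lower-scored duplicate genomes never create spurious ties.
#'
#' Ties are defined by exact score equality (BLAST bit-scores are discrete;
#' Mash distances are compared as parsed), with no epsilon.
#'
#' @param hits data frame with columns `subject_id` and `score`, ordered
#'   best-first (decreasing bit-score, or increasing distance with
#'   `ascending = TRUE`), as produced by [parse_blast_tab()] /
#'   [parse_mash_dist()].
#' @param species_map named character vector mapping genome id to species
#'   (see [read_species_map()]), or `NULL` to rank subject ids directly.
#'   Subjects missing from the map fall back to their own id with a warning;
#'   this keeps the expanded-reference ("+viruses") mode uniform, since viral
#'   reference sequences carry no species.
#' @param ascending set `TRUE` when `score` is a distance (smaller is
#'   better).
#' @param query_id label for the resulting list.
#' @return A [ranked_list()].
#' @examples
#' hits <- data.frame(subject_id = c("gA1", "gA2", "gB1"),
#'                    score = c(90, 85, 85))
#' collapse_to_ranks(hits, c(gA1 = "spA", gA2 = "spA", gB1 = "spB"))
#' @export
collapse_to_ranks <- function(hits, species_map = NULL, ascending = FALSE,
                              query_id = NA_character_) {
  stopifnot(is.data.frame(hits),
            all(c("subject_id", "score") %in% names(hits)))
  if (nrow(hits) == 0L) return(ranked_list(query_id = query_id))
  sc <- if (ascending) -hits$score else hits$score
  if (is.unsorted(rev(sc)))  # sc must be non-increasing (best first)
    stop("'hits' must be ordered best-first", call. = FALSE)

  sp <- trimws(hits$subject_id)
  if (!is.null(species_map)) {
    m <- species_map[sp]
    unmapped <- is.na(m)
    if (any(unmapped))
      warning("no species mapping for ",
              paste(unique(sp[unmapped]), collapse = ", "),
              "; using the subject id itself", call. = FALSE)
    sp[!unmapped] <- m[!unmapped]
  }

  # first (best) appearance per species, then group exactly-equal scores
  first <- !duplicated(sp)
  sp <- sp[first]
  sc <- hits$score[first]
  grp <- cumsum(c(TRUE, sc[-1] != sc[-length(sc)]))
  ranked_list(unname(split(sp, grp)), query_id = query_id)
}
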