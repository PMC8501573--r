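# Synthetic desk-scale inputs. The planted-host universe stands in for the
# published virus-host benchmark collections: every virus gets exactly one
# true host, and its ranked list is a noise-corrupted copy of that host's
# list, so recovery of the planted host is a measurable property.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed, kind = "Mersenne-Twister")  # generator fixed by contract
  }
  force(code)
}

#' Random tie-structured ranked list
#'
#' Draws `list_len` distinct labels from `pool` in random order, then merges
#' each adjacent pair of ranks into a tie with probability `tie_prob`.
#' Uses the current RNG state (seed it with `set.seed()` for
#' reproducibility).
#'
#' @param pool character vector of available labels.
#' @param list_len number of labels to draw (<= `length(pool)`).
#' @param tie_prob per-boundary probability of merging adjacent ranks.
#' @param query_id label for the list.
#' @return A [ranked_list()].
#' @export
random_ranked_list <- function(pool, list_len, tie_prob = 0.15,
                               query_id = NA_character_) {
  if (list_len > length(pool))
    stop("'list_len' exceeds the label pool size", call. = FALSE)
  labs <- sample(pool, list_len)
  if (list_len == 0L) return(ranked_list(query_id = query_id))
  merge <- if (list_len > 1L) stats::runif(list_len - 1L) < tie_prob
           else logical(0)
  grp <- cumsum(c(TRUE, !merge))
  ranked_list(unname(split(labs, grp)), query_id = query_id)
}

mutate_list <- function(rl, pool, noise) {
  if (noise <= 0) return(rl)
  labs <- unlist(rl$ranks, use.names = FALSE)
  sizes <- vapply(rl$ranks, length, 0L)
  hit <- stats::runif(length(labs)) < noise
  # replacements draw from the whole pool (minus labels already placed), so
  # at noise = 1 the list is a uniform random sample unrelated to the host
  new_labs <- character(length(labs))
  for (i in seq_along(labs)) {
    placed <- new_labs[seq_len(i - 1L)]
    if (!hit[i] && !(labs[i] %in% placed)) {
      new_labs[i] <- labs[i]
    } else {
      cand <- setdiff(pool, placed)
      new_labs[i] <- if (length(cand) == 1L) cand else sample(cand, 1L)
    }
  }
  ranks <- unname(split(new_labs, rep(seq_along(sizes), sizes)))
  # noise also perturbs the tie structure: merge adjacent ranks
  if (length(ranks) > 1L) {
    merge <- stats::runif(length(ranks) - 1L) < noise / 2
    grp <- cumsum(c(TRUE, !merge))
    ranks <- lapply(unname(split(ranks, grp)), function(g)
      unlist(g, use.names = FALSE))
  }
  ranked_list(ranks, query_id = rl$query_id)
}

#' Generate a planted-host universe
#'
#' Builds a self-contained benchmark: `n_hosts` candidate hosts, each with a
#' random tie-structured ranked list over a shared reference label pool, and
#' `n_viruses` viruses, each assigned one true host whose list it copies and
#' then corrupts — every label is replaced by a random unused pool label
#' with probability `noise`, and adjacent ranks merge into ties with
#' probability `noise / 2`. At `noise = 0` each virus list is an exact copy
#' of its host's list; at `noise = 1` virus lists carry no host signal and
#' species-level recovery falls to the chance level `1 / n_hosts`.
#'
#' The taxonomy nests hosts dyadically (every 2 hosts share a genus, every
#' 4 a family, and so on), so accuracy is monotone non-increasing from
#' phylum down to species, and each host is its own species.
#'
#' All randomness flows from one Mersenne-Twister generator seeded once, so
#' a universe is fully reproducible from its seed on any platform.
#'
#' @param n_hosts,n_viruses counts of candidate hosts and query viruses.
#' @param pool_size size of the shared reference label pool.
#' @param list_len ranked-list length (labels per list).
#' @param noise corruption probability in \[0, 1\].
#' @param tie_prob tie density of the host lists.
#' @param seed integer seed.
#' @return A `planted_universe` list: `host_lists`, `virus_lists` (named
#'   lists of [ranked_list()]), `truth` (data frame `virus_id`, `host_id`),
#'   `taxonomy` (data frame, see [read_taxonomy()]), plus the generating
#'   parameters.
#' @export
make_planted_universe <- function(n_hosts, n_viruses, pool_size = 500L,
                                  list_len = 20L, noise = 0.1,
                                  tie_prob = 0.15, seed = 1L) {
  stopifnot(n_hosts >= 1L, n_viruses >= 1L, pool_size >= 1L, list_len >= 1L,
            noise >= 0, noise <= 1)
  if (list_len > pool_size)
    stop("'list_len' must not exceed 'pool_size'", call. = FALSE)
  with_seed(seed, {
    pool <- sprintf("sp%04d", seq_len(pool_size))
    hid <- sprintf("host%03d", seq_len(n_hosts))
    vid <- sprintf("virus%04d", seq_len(n_viruses))

    host_lists <- stats::setNames(lapply(hid, function(h)
      random_ranked_list(pool, list_len, tie_prob, query_id = h)), hid)

    true_host <- hid[sample.int(n_hosts, n_viruses, replace = TRUE)]
    virus_lists <- stats::setNames(lapply(seq_len(n_viruses), function(i) {
      rl <- host_lists[[true_host[i]]]
      rl$query_id <- vid[i]
      mutate_list(rl, pool, noise)
    }), vid)

    g <- function(width) sprintf("tax%s%03d", width,
                                 (seq_len(n_hosts) - 1L) %/% width + 1L)
    taxonomy <- data.frame(host_id = hid,
                           species = paste0(hid, "_sp"),
                           genus = g(2L), family = g(4L), order = g(8L),
                           class = g(16L), phylum = g(32L),
                           stringsAsFactors = FALSE)

    structure(list(host_lists = host_lists, virus_lists = virus_lists,
                   truth = data.frame(virus_id = vid, host_id = true_host,
                                      stringsAsFactors = FALSE),
                   taxonomy = taxonomy, pool = pool,
                   noise = noise, seed = seed),
              class = "planted_universe")
  })
}

#' @export
print.planted_universe <- function(x, ...) {
  cat("planted_universe:", length(x$virus_lists), "viruses,",
      length(x$host_lists), "hosts, pool", length(x$pool),
      ", noise", x$noise, ", seed", x$seed, "\n")
  invisible(x)
}

#' Serialize a planted universe to benchmark input files
#'
#' Writes the virus and host ranked lists as two directories of
#' `<query_id>.txt` files, the truth pairs and the taxonomy as TSVs —
#' exactly the inputs the scoring and evaluation steps consume.
#'
#' @param universe a `planted_universe`.
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_universe <- function(universe, dir) {
  stopifnot(inherits(universe, "planted_universe"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ranklist_dir(universe$virus_lists, file.path(dir, "virus_lists"))
  write_ranklist_dir(universe$host_lists, file.path(dir, "host_lists"))
  utils::write.table(universe$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(universe$taxonomy, file.path(dir, "taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(dir)
}

#' Emit a BLAST-like tabular hit table for ranked lists
#'
#' Synthesizes 12-column tabular rows whose bit-scores reproduce the given
#' lists' rank orders and ties (one subject row per label; labels tied for
#' a rank get exactly equal bit-scores), so the parsing and collapsing path
#' can be exercised end-to-end against known rankings.
#'
#' @param x a `planted_universe` (virus and host lists are both emitted) or
#'   a named list of [ranked_list()] objects.
#' @return Character vector of tabular lines (no trailing newline).
#' @export
emit_blast_like_table <- function(x) {
  lists <- if (inherits(x, "planted_universe"))
    c(x$virus_lists, x$host_lists) else x
  rows <- character(0)
  for (id in names(lists)) {
    rl <- lists[[id]]
    for (d in seq_along(rl$ranks)) {
      bit <- 5000 - 10 * (d - 1)       # distinct per rank, equal within
      for (lab in rl$ranks[[d]])
        rows <- c(rows, sprintf(
          "%s\t%s\t%.3f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.2e\t%.1f",
          id, lab, 98.5, 1000L, 12L, 3L, 1L, 1000L, 1L, 1000L, 1e-50, bit))
    }
  }
  rows
}

#' Randomly subsample fixed-length contigs from a genome
#'
#' Emulates incomplete viral sequences: for each requested length, draws
#' `replicates` substrings with start positions uniform over the genome
#' (0-based half-open coordinates; linear genome, no wraparound). A length
#' exceeding the genome is skipped with a warning. Contig names encode
#' parent, length, replicate and start as
#' `<parent>|len<L>|rep<i>|start<pos0>`.
#'
#' @param genome a single genome: a `Biostrings::DNAStringSet` of length 1,
#'   a `DNAString`, or a (optionally named) character string.
#' @param lengths contig lengths in bases; defaults to the 20/10/5/3/1 kb
#'   ladder.
#' @param replicates subsamples per length (replicates may overlap).
#' @param seed optional integer seed.
#' @return A `Biostrings::DNAStringSet` of contigs.
#' @export
subsample_contigs <- function(genome,
                              lengths = c(20000L, 10000L, 5000L, 3000L,
                                          1000L),
                              replicates = 10L, seed = NULL) {
  if (inherits(genome, "DNAString"))
    genome <- Biostrings::DNAStringSet(genome)
  if (is.character(genome)) {
    nm <- names(genome) %||% "genome"
    genome <- Biostrings::DNAStringSet(stats::setNames(genome, nm))
  }
  stopifnot(inherits(genome, "DNAStringSet"), length(genome) == 1L)
  if (is.null(names(genome))) names(genome) <- "genome"
  seqstr <- as.character(genome[[1]])
  if (grepl("[^ACGTacgt]", seqstr))
    warning("genome contains non-ACGT characters; subsampling anyway",
            call. = FALSE)
  L <- nchar(seqstr)
  parent <- names(genome)[1]

  with_seed(seed, {
    out <- character(0); ids <- character(0)
    for (len in as.integer(lengths)) {
      if (len > L) {
        warning("genome ", parent, " (", L, " bp) shorter than requested ",
                len, " bp; length skipped", call. = FALSE)
        next
      }
      for (r in seq_len(replicates)) {
        start0 <- sample.int(L - len + 1L, 1L) - 1L   # 0-based start
        out <- c(out, substr(seqstr, start0 + 1L, start0 + len))
        ids <- c(ids, sprintf("%s|len%d|rep%d|start%d", parent, len, r,
                              start0))
      }
    }
    Biostrings::DNAStringSet(stats::setNames(out, ids))
  })
}
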