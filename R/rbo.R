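#' Parameters of the rank-biased overlap score
#'
#' The persistence parameter `p` in (0, 1) sets how steeply rank weights
#' decay: the weight of depth d is proportional to p^(d-1), so small p
#' concentrates all weight at the top of the lists. The default p = 0.75
#' places about 98.6% of the total weight on the first 10 ranks (see
#' [weight_mass()]), matching the scale at which similarity searches carry
#' host signal.
#'
#' With `normalize = TRUE` (default) the finite-list score is divided by
#' 1 - p^n so that identical lists score exactly 1; `normalize = FALSE`
#' returns the raw truncated geometric sum.
#'
#' @param p persistence parameter, 0 < p < 1.
#' @param normalize divide by the maximum attainable mass `1 - p^n`?
#' @return An object of class `rbo_params`.
#' @export
rbo_params <- function(p = 0.75, normalize = TRUE) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1)
    stop("'p' must be a single number in (0, 1)", call. = FALSE)
  structure(list(p = as.numeric(p), normalize = isTRUE(normalize)),
            class = "rbo_params")
}

#' @export
print.rbo_params <- function(x, ...) {
  cat(sprintf("rbo_params: p = %g, %s\n", x$p,
              if (x$normalize) "normalized" else "raw"))
  invisible(x)
}

#' Jaccard agreement of two ranked lists at a given depth
#'
#' The agreement A(S, T, d) is the Jaccard index of the two depth-d prefix
#' sets: |S_:d intersect T_:d| / |S_:d union T_:d|, where a prefix is the
#' union of the first d rank sets. A whole tied rank enters the prefix at
#' its rank's depth (depth counts ranks, not items), and a depth beyond a
#' list's end saturates at the full list, so uneven lengths are handled
#' naturally.
#'
#' @param S,T [ranked_list()] objects.
#' @param d depth, a positive integer.
#' @return Agreement in \[0, 1\]; 0 when both prefixes are empty.
#' @examples
#' S <- ranked_list(list("a", "b", "c"))
#' T <- ranked_list(list("a", "c", "b"))
#' jaccard_at_depth(S, T, 2)  # |{a}| / |{a,b,c}| = 1/3
#' @export
jaccard_at_depth <- function(S, T, d) {
  stopifnot(inherits(S, "ranked_list"), inherits(T, "ranked_list"))
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 1)
    stop("'d' must be a positive integer", call. = FALSE)
  d <- as.integer(d)
  ps <- unique(unlist(S$ranks[seq_len(min(d, length(S$ranks)))],
                      use.names = FALSE))
  pt <- unique(unlist(T$ranks[seq_len(min(d, length(T$ranks)))],
                      use.names = FALSE))
  un <- length(union(ps, pt))
  if (un == 0L) return(0)
  length(intersect(ps, pt)) / un
}

#' Rank-biased overlap between two tie-aware ranked lists
#'
#' The interaction score between a virus and a candidate host is the
#' rank-biased overlap of their reference ranked lists:
#'
#'   RBO(S, T, p) = (1 - p) * sum over d = 1..n of p^(d-1) * A(S, T, d)
#'
#' where A(S, T, d) is the depth-d Jaccard agreement ([jaccard_at_depth()])
#' and n is the larger of the two lists' rank counts, so all content of both
#' lists can contribute. The geometric weights make agreement among
#' top-ranked species count most. The score is symmetric, lies in \[0, 1\],
#' is 0 exactly when the lists share no labels, and (in the default
#' normalized mode) is 1 exactly for identical lists. Two empty lists score
#' 0, so score matrices stay total for queries without hits.
#'
#' @param S,T [ranked_list()] objects (either may be empty).
#' @param params an [rbo_params()] object.
#' @return A single number in \[0, 1\].
#' @examples
#' S <- ranked_list(list("a", "b", "c"))
#' T <- ranked_list(list("a", "c", "b"))
#' rbo(S, T, rbo_params(p = 0.5))            # 0.8095238
#' rbo(S, T, rbo_params(p = 0.5, normalize = FALSE))  # 0.7083333
#' @export
rbo <- function(S, T, params = rbo_params()) {
  stopifnot(inherits(S, "ranked_list"), inherits(T, "ranked_list"),
            inherits(params, "rbo_params"))
  nS <- length(S$ranks); nT <- length(T$ranks)
  n <- max(nS, nT)
  if (n == 0L) return(0)

  labs <- unique(c(unlist(S$ranks, use.names = FALSE),
                   unlist(T$ranks, use.names = FALSE)))
  Sidx <- lapply(S$ranks, match, table = labs)
  Tidx <- lapply(T$ranks, match, table = labs)

  inS <- logical(length(labs)); inT <- logical(length(labs))
  szS <- 0L; szT <- 0L; inter <- 0L
  p <- params$p
  acc <- 0
  wsum <- 0                        # running total mass, equals 1 - p^n
  w <- 1 - p                       # (1 - p) * p^(d - 1)
  for (d in seq_len(n)) {
    if (d <= nS) {
      i <- Sidx[[d]]
      inter <- inter + sum(inT[i])
      inS[i] <- TRUE
      szS <- szS + length(i)
    }
    if (d <= nT) {
      j <- Tidx[[d]]
      inter <- inter + sum(inS[j] & !inT[j])
      inT[j] <- TRUE
      szT <- szT + length(j)
    }
    acc <- acc + w * inter / (szS + szT - inter)
    wsum <- wsum + w
    w <- w * p
  }
  # dividing by the identically-accumulated mass makes rbo(S, S) exactly 1
  val <- if (params$normalize) acc / wsum else acc
  min(max(val, 0), 1)
}

#' Cumulative weight of the top k ranks under RBO weighting
#'
#' The fraction of the total rank-biased-overlap weight carried by ranks
#' 1..k, from the closed-form RBO weight function (Webber et al. 2010):
#'
#'   W(p, k) = 1 - p^(k-1)
#'             + k (1 - p)/p * ( ln(1/(1 - p)) - sum i = 1..k-1 of p^i / i )
#'
#' Strictly increasing in k with limit 1. At the package default p = 0.75,
#' W = 0.9858 at k = 10: about 98.6% of the score is decided by the first
#' ten ranked species, which is why moderate list depths suffice.
#'
#' @param p persistence parameter in (0, 1).
#' @param k positive integer depth.
#' @return Weight mass in (0, 1).
#' @examples
#' weight_mass(0.75, 10)
#' @export
weight_mass <- function(p, k) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1)
    stop("'p' must be a single number in (0, 1)", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1)
    stop("'k' must be a positive integer", call. = FALSE)
  k <- as.integer(k)
  i <- seq_len(k - 1L)
  1 - p^(k - 1L) + ((1 - p) / p) * k * (log(1 / (1 - p)) - sum(p^i / i))
}
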