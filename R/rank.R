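#' Rank treatments by attraction
#'
#' Ranks treatments from most to least attractive: rank 1 goes to the
#' largest mean catch. Ties take average ranks by default (so the rank sum
#' is always k(k+1)/2), or first-occurrence order.
#'
#' @param mean_catches named numeric vector of per-treatment mean catches.
#' @param tie_method `"average"` or `"first"`.
#' @param source_year optional label carried on the ranking.
#' @return object of class `ranking`: named `ranks`, `tie_method`,
#'   `tied` flag, `source_year`.
#' @examples
#' rank_treatments(c(A = 10, B = 5, C = 1))
#' @export
rank_treatments <- function(mean_catches, tie_method = c("average", "first"),
                            source_year = NA) {
  tie_method <- match.arg(tie_method)
  if (length(mean_catches) < 2L) stop("need at least two treatments")
  if (is.null(names(mean_catches)) || anyDuplicated(names(mean_catches)))
    stop("mean catches must carry unique treatment names")
  if (any(!is.finite(mean_catches))) stop("means must be finite")
  r <- rank(-mean_catches,
            ties.method = if (tie_method == "average") "average" else "first")
  structure(list(ranks = r, tie_method = tie_method,
                 tied = anyDuplicated(mean_catches) > 0L,
                 source_year = source_year), class = "ranking")
}

#' @export
print.ranking <- function(x, ...) {
  cat("ranking", if (!is.na(x$source_year)) paste0("(", x$source_year, ")"),
      "\n")
  print(x$ranks)
  invisible(x)
}

as_rank_vector <- function(r) {
  if (inherits(r, "ranking")) r$ranks
  else if (is.numeric(r) && !is.null(names(r))) r
  else stop("expected a ranking or a named rank vector")
}

#' Squared-rank-difference concordance statistic
#'
#' \eqn{D = \sum_i (r_{1i} - r_{2i})^2} over the shared treatments. D = 0
#' for identical rankings; the maximum, k(k^2-1)/3, is attained by full
#' reversal. Small D indicates concordant rankings between years.
#'
#' @param r1,r2 [rank_treatments()] objects (or named rank vectors) over the
#'   same treatment set.
#' @return the statistic (non-negative scalar).
#' @export
rank_distance <- function(r1, r2) {
  a <- as_rank_vector(r1); b <- as_rank_vector(r2)
  if (!setequal(names(a), names(b)) || length(a) != length(b))
    stop("rankings must cover the same treatments")
  sum((a - b[names(a)])^2)
}

#' Monte Carlo permutation test of ranking concordance
#'
#' Tests whether two years' treatment rankings are more similar than chance.
#' Each replicate generates two independent uniform-random rankings of the k
#' treatments and computes D; the p-value is
#' \eqn{p = (1 + \#\{D_{rand} \le D_{obs}\}) / (n_{reps} + 1)}, counting the
#' observed statistic itself (guaranteeing p > 0) and using "<=" because
#' small D means similarity. Tied input rankings are allowed but flagged.
#'
#' @inheritParams rank_distance
#' @param n_reps number of random replicates (999 by default).
#' @param seed integer seed.
#' @return object of class `rank_test`: `d_obs`, `k_items`, `n_reps`,
#'   `p_value`, `method = "monte_carlo"`, `seed`, `tied`.
#' @export
permutation_pvalue <- function(r1, r2, n_reps = 999L, seed = 1L) {
  a <- as_rank_vector(r1); b <- as_rank_vector(r2)
  if (!setequal(names(a), names(b))) stop("treatment sets differ")
  k <- length(a)
  if (k < 2L) stop("need k >= 2 treatments")
  if (n_reps < 1L) stop("n_reps must be >= 1")
  d_obs <- rank_distance(r1, r2)
  tied <- anyDuplicated(a) > 0L || anyDuplicated(b) > 0L
  if (tied)
    warning("tied ranks present; the random-ranking null uses untied ranks")
  m <- with_seed(substream_seed(seed, "perm"), {
    cnt <- 0L
    for (i in seq_len(n_reps)) {
      d <- sum((sample.int(k) - sample.int(k))^2)
      if (d <= d_obs) cnt <- cnt + 1L
    }
    cnt
  })
  structure(list(d_obs = d_obs, k_items = k, n_reps = as.integer(n_reps),
                 p_value = (1 + m) / (n_reps + 1), method = "monte_carlo",
                 seed = seed, tied = tied), class = "rank_test")
}

# All k! permutations of 1..k as a matrix (k! rows); k <= 8 keeps this small.
all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  row <- 1L
  for (pos in seq_len(k)) {
    block <- matrix(0L, nrow(sub), k)
    block[, pos] <- k
    block[, -pos] <- sub
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Exact concordance p-value by enumeration
#'
#' Exact analogue of [permutation_pvalue()]: p = P(D <= D_obs) under the
#' uniform-random-rankings null. Because D depends only on the relative
#' permutation between the two rankings, one ranking is held fixed while the
#' other runs over all k! permutations — an equivalence that is itself
#' unit-tested. Refuses tied ranks (the enumeration assumes untied
#' permutations) and k > 8.
#'
#' @inheritParams rank_distance
#' @return a `rank_test` with `method = "exact"`.
#' @examples
#' r <- rank_treatments(c(A = 3, B = 2, C = 1))
#' exact_pvalue(r, r)  # p = 1/6
#' @export
exact_pvalue <- function(r1, r2) {
  a <- as_rank_vector(r1); b <- as_rank_vector(r2)
  if (!setequal(names(a), names(b))) stop("treatment sets differ")
  k <- length(a)
  if (k < 2L) stop("need k >= 2 treatments")
  if (k > 8L) stop("exact enumeration limited to k <= 8")
  if (anyDuplicated(a) || anyDuplicated(b))
    stop("exact enumeration requires untied ranks")
  d_obs <- rank_distance(r1, r2)
  perms <- all_permutations(k)
  ref <- seq_len(k)
  d_all <- rowSums((perms - matrix(ref, nrow(perms), k, byrow = TRUE))^2)
  structure(list(d_obs = d_obs, k_items = k, n_reps = nrow(perms),
                 p_value = mean(d_all <= d_obs), method = "exact",
                 seed = NA_integer_, tied = FALSE), class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("rank concordance: D = %g on k = %d items, p = %.5g (%s%s)\n",
              x$d_obs, x$k_items, x$p_value, x$method,
              if (x$method == "monte_carlo")
                sprintf(", %d reps, seed %d", x$n_reps, x$seed) else ""))
  invisible(x)
}
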