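#' Kullback-Leibler divergence between two topic distributions
#'
#' `KL(P || Q) = sum_i P(i) * ln(P(i) / Q(i))` (natural logarithm). Both
#' arguments must be strictly positive probability vectors of equal length;
#' smoothed topic distributions from [fit_lda()] satisfy this by construction,
#' and distributions containing zeros are rejected rather than patched.
#'
#' @param p,q Strictly positive numeric vectors summing to 1.
#' @return A non-negative scalar, zero iff `p == q`.
#' @export
#' @examples
#' kl_divergence(c(0.5, 0.5), c(0.25, 0.75))
kl_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("distributions must have equal length", call. = FALSE)
  if (any(p <= 0) || any(q <= 0)) {
    stop("distributions must be strictly positive", call. = FALSE)
  }
  sum(p * log(p / q))
}

#' Symmetrized Kullback-Leibler distance
#'
#' The pairwise drug distance `D(A, B) = (KL(A || B) + KL(B || A)) / 2`;
#' symmetric in its arguments and zero iff the distributions are equal.
#'
#' @inheritParams kl_divergence
#' @return A non-negative scalar.
#' @export
symmetrized_kl <- function(p, q) {
  (kl_divergence(p, q) + kl_divergence(q, p)) / 2
}

#' Pairwise symmetrized K-L distance matrix over drugs
#'
#' Fills every unordered pair of rows of the per-drug topic distribution
#' matrix with [symmetrized_kl()]; the diagonal is exactly zero and the result
#' is exactly symmetric.
#'
#' @param x An `lda_fit` (its `theta` is used) or a strictly positive matrix
#'   whose rows are topic distributions, with drug ids as rownames.
#' @return A D x D numeric matrix of class `kl_dist`, drug ids as dimnames.
#' @export
pairwise_distances <- function(x) {
  theta <- if (inherits(x, "lda_fit")) x$theta else x
  stopifnot(is.matrix(theta), !is.null(rownames(theta)))
  if (any(theta <= 0)) stop("topic distributions must be strictly positive", call. = FALSE)
  lt <- log(theta)
  # KL[i, j] = sum_k theta[i,k] (log theta[i,k] - log theta[j,k])
  self <- rowSums(theta * lt)
  cross <- theta %*% t(lt)
  kl <- self - cross
  d <- (kl + t(kl)) / 2
  d[d < 0] <- 0          # clip float noise on near-identical rows
  diag(d) <- 0
  dimnames(d) <- list(rownames(theta), rownames(theta))
  class(d) <- c("kl_dist", class(d))
  d
}

#' Nearest neighbor of each drug under the symmetrized K-L distance
#'
#' For every drug, the off-diagonal minimum of its distance-matrix row. The
#' relation is directional: A's nearest neighbor need not have A as its own.
#' Exact ties are broken toward the lexicographically smallest neighbor id.
#'
#' @param d A `kl_dist` (or any symmetric distance matrix with id dimnames)
#'   over at least 2 drugs.
#' @return A tibble with columns `drug_id`, `neighbor_id`, `distance`.
#' @export
nearest_neighbors <- function(d) {
  stopifnot(is.matrix(d), nrow(d) >= 2, !is.null(rownames(d)))
  ids <- rownames(d)
  rows <- purrr::map(seq_len(nrow(d)), function(i) {
    v <- d[i, ]
    v[i] <- Inf
    mn <- min(v)
    cand <- ids[v == mn]
    tibble::tibble(drug_id = ids[i],
                   neighbor_id = sort(cand)[1],
                   distance = mn)
  })
  dplyr::bind_rows(rows)
}
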