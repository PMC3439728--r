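#' PCA eigenvalue spectrum of a drug-term matrix
#'
#' Mean-centers the term columns and returns the eigenvalues of the sample
#' covariance matrix (divisor D - 1), i.e. the squared singular values of the
#' centered matrix divided by D - 1, sorted in non-increasing order. At most
#' `min(D - 1, V)` eigenvalues are non-trivially defined and retained.
#'
#' @param m A `drug_term_matrix` (or any numeric matrix) with at least 2 rows
#'   and 2 columns.
#' @param binarize If `TRUE`, reduce counts to presence/absence before PCA.
#' @return A list of class `eigen_spectrum` with elements `eigenvalues` and
#'   `n`.
#' @export
compute_spectrum <- function(m, binarize = FALSE) {
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("spectrum requires >= 2 drugs and >= 2 terms", call. = FALSE)
  }
  x <- unclass(m)
  storage.mode(x) <- "double"
  if (binarize) x[] <- as.numeric(x > 0)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  n <- min(nrow(x) - 1L, ncol(x))
  ev <- ev[seq_len(min(n, length(ev)))]
  if (length(ev) < n) ev <- c(ev, rep(0, n - length(ev)))
  eigen_spectrum(ev)
}

#' Construct an eigenvalue spectrum
#'
#' @param eigenvalues Numeric vector, sorted non-increasing. Values in
#'   `[-1e-8, 0)` are clipped to zero; more negative values are an error.
#' @return A list of class `eigen_spectrum`.
#' @export
eigen_spectrum <- function(eigenvalues) {
  ev <- as.numeric(eigenvalues)
  if (any(ev < -1e-8)) stop("eigenvalues must be non-negative", call. = FALSE)
  ev[ev < 0] <- 0
  if (is.unsorted(rev(ev))) stop("eigenvalues must be sorted non-increasing",
                                 call. = FALSE)
  structure(list(eigenvalues = ev, n = length(ev)), class = "eigen_spectrum")
}

#' Information loss of truncating an eigenvalue spectrum at k components
#'
#' The retained information is measured against the penalized discarded tail:
#' `|sum(e) - lambda * sum(e[(k+1):n])|`. With the default penalty
#' `lambda = 2` this is `|sum(e[1:k]) - sum(e[(k+1):n])|`, the imbalance
#' between the variance captured by the leading k components and the variance
#' left in the tail; it is minimized where the leading components carry about
#' half the total variance.
#'
#' @param spectrum An `eigen_spectrum`.
#' @param k Number of retained components, `1 <= k <= n - 1`.
#' @param lambda Positive penalty on the discarded tail (default 2).
#' @return A non-negative scalar.
#' @export
information_loss <- function(spectrum, k, lambda = 2) {
  stopifnot(inherits(spectrum, "eigen_spectrum"), lambda > 0)
  ev <- spectrum$eigenvalues
  n <- spectrum$n
  if (k < 1 || k > n - 1 || k != round(k)) {
    stop(sprintf("k must be an integer in [1, %d]", n - 1L), call. = FALSE)
  }
  abs(sum(ev) - lambda * sum(ev[(k + 1):n]))
}

#' Choose the number of topics by minimizing information loss
#'
#' Evaluates [information_loss()] for every admissible `k` in `[1, n - 1]` and
#' returns the minimizer; ties are broken toward the smallest `k`, so the
#' selection is deterministic. The choice is scale-invariant: multiplying all
#' eigenvalues by a positive constant does not change it.
#'
#' @param spectrum An `eigen_spectrum` with `n >= 2`.
#' @param lambda Positive penalty (default 2).
#' @return A list of class `k_selection` with elements `k_star`, `lambda` and
#'   `loss_curve` (a tibble with columns `k`, `loss`).
#' @export
#' @examples
#' choose_k(eigen_spectrum(c(5, 1, 1, 1, 1, 1)))$k_star
choose_k <- function(spectrum, lambda = 2) {
  stopifnot(inherits(spectrum, "eigen_spectrum"))
  if (spectrum$n < 2) stop("spectrum must contain >= 2 eigenvalues", call. = FALSE)
  ks <- seq_len(spectrum$n - 1L)
  loss <- vapply(ks, function(k) information_loss(spectrum, k, lambda), 0)
  structure(
    list(k_star = ks[which.min(loss)], lambda = lambda,
         loss_curve = tibble::tibble(k = ks, loss = loss)),
    class = "k_selection"
  )
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("<k_selection: k* = %d (lambda = %g) over k in [1, %d]>\n",
              x$k_star, x$lambda, max(x$loss_curve$k)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the topic-count loss curve
#'
#' @param x A `k_selection`.
#' @param ... Unused.
#' @return A tibble with columns `k`, `loss`, `selected`.
#' @export
tidy.k_selection <- function(x, ...) {
  dplyr::mutate(x$loss_curve, selected = .data$k == x$k_star)
}

#' Plot the information-loss curve of a topic-count selection
#'
#' @param object A `k_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.k_selection <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$loss)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(data = df[df$selected, ], color = "red", size = 2) +
    ggplot2::labs(x = "number of topics k", y = "information loss",
                  title = sprintf("Selected k = %d (lambda = %g)",
                                  object$k_star, object$lambda)) +
    ggplot2::theme_minimal()
}
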