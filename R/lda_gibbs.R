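#' Fit an LDA topic model by collapsed Gibbs sampling
#'
#' Each drug label is a bag of side-effect term tokens (counts expanded to
#' multiplicities). Topic labels are initialized uniformly at random and each
#' sweep resamples every token from its collapsed conditional
#' `p(z = k) ∝ (n_kw + beta) / (n_k + V*beta) * (n_dk + alpha)` with the
#' token's own assignment removed from the counts. The returned `theta`
#' (per-drug topic distributions, P(z|d)) and `phi` (per-topic term
#' distributions, P(w|z)) are posterior-mean estimates
#' `(n_dk + alpha) / (N_d + K*alpha)` and `(n_kw + beta) / (n_k + V*beta)`
#' averaged over samples taken every `sample_lag` sweeps after `burn_in`.
#' Identical seed, configuration and matrix give a bit-identical fit.
#'
#' @param m A `drug_term_matrix` with no all-zero rows.
#' @param k Number of topics K (>= 1).
#' @param alpha Symmetric Dirichlet prior on topic mixtures; default `50 / k`.
#' @param beta Symmetric Dirichlet prior on term distributions; default 0.1.
#' @param n_iter Total Gibbs sweeps (default 1000).
#' @param burn_in Sweeps discarded before averaging (default 500,
#'   `0 <= burn_in < n_iter`).
#' @param sample_lag Thinning interval between retained samples (default 10).
#' @param seed Integer seed for the sampler.
#' @param debug If `TRUE`, verify count-conservation invariants after every
#'   sweep (slower; aborts on any violation).
#' @return A list of class `lda_fit`: `theta` (D x K), `phi` (K x V),
#'   `log_likelihood` (per-sweep collapsed joint log-likelihood trace),
#'   `assignments` (final per-token topic labels and count tables `n_dk`,
#'   `n_kw`, `n_k`, `N_d`, plus token `doc`/`word` indices), and `config`.
#' @export
#' @examples
#' corp <- generate_corpus(n_drugs = 20, vocab_size = 30, n_topics = 2,
#'                         mean_doc_length = 20, seed = 1)
#' fit <- fit_lda(corp$matrix, k = 2, n_iter = 50, burn_in = 20,
#'                sample_lag = 5, seed = 1)
#' rowSums(fit$theta)[1:3]
fit_lda <- function(m, k, alpha = 50 / k, beta = 0.1, n_iter = 1000,
                    burn_in = 500, sample_lag = 10, seed = 1, debug = FALSE) {
  stopifnot(is.matrix(m), k >= 1, k == round(k), alpha > 0, beta > 0,
            n_iter >= 1, burn_in >= 0, sample_lag >= 1)
  if (burn_in >= n_iter) stop("burn_in must be < n_iter", call. = FALSE)
  if (any(rowSums(m) == 0)) stop("matrix must have no all-zero rows", call. = FALSE)
  if (burn_in + sample_lag > n_iter) {
    stop("no samples would be collected: need burn_in + sample_lag <= n_iter",
         call. = FALSE)
  }
  n_tokens <- sum(m)
  if (k > n_tokens) {
    warning(sprintf("k = %d exceeds the total token count (%d)", k, n_tokens),
            call. = FALSE)
  }

  # expand counts to token streams (0-based for the sampler)
  idx <- which(unclass(m) > 0, arr.ind = TRUE)
  reps <- m[idx]
  doc <- rep.int(idx[, 1] - 1L, reps)
  word <- rep.int(idx[, 2] - 1L, reps)
  ord <- order(doc, word)
  doc <- doc[ord]; word <- word[ord]

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)
  res <- lda_gibbs_cpp(doc, word, nrow(m), ncol(m), as.integer(k),
                       alpha, beta, as.integer(n_iter), as.integer(burn_in),
                       as.integer(sample_lag), debug)

  theta <- res$theta_sum / res$n_samples
  phi <- res$phi_sum / res$n_samples
  dimnames(theta) <- list(rownames(m), paste0("topic", seq_len(k)))
  dimnames(phi) <- list(paste0("topic", seq_len(k)), colnames(m))
  structure(
    list(
      theta = theta,
      phi = phi,
      log_likelihood = res$trace,
      assignments = list(z = res$z + 1L, doc = doc + 1L, word = word + 1L,
                         n_dk = res$n_dk, n_kw = res$n_kw,
                         n_k = res$n_k, N_d = res$N_d),
      config = list(k = as.integer(k), alpha = alpha, beta = beta,
                    n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                    sample_lag = as.integer(sample_lag), seed = seed,
                    n_samples = res$n_samples)
    ),
    class = "lda_fit"
  )
}

#' Collapsed joint log-likelihood of a topic assignment state
#'
#' Computes `log p(w, z | alpha, beta)` from the count tables via the standard
#' Dirichlet-multinomial closed form (ratios of log-gamma terms). The value is
#' invariant under any permutation relabeling of the topics.
#'
#' @param assignments The `assignments` element of an [fit_lda()] result (or a
#'   compatible list with `n_dk`, `n_kw`, `n_k`, `N_d`).
#' @param alpha,beta The Dirichlet hyperparameters used by the sampler.
#' @return A finite scalar.
#' @export
log_likelihood <- function(assignments, alpha, beta) {
  a <- assignments
  n_dk <- a$n_dk; n_kw <- a$n_kw; n_k <- a$n_k; N_d <- a$N_d
  if (length(N_d) == 0 || sum(N_d) == 0) stop("empty corpus", call. = FALSE)
  if (!isTRUE(all.equal(rowSums(n_dk), as.numeric(N_d))) ||
      !isTRUE(all.equal(rowSums(n_kw), as.numeric(n_k))) ||
      any(n_dk < 0) || any(n_kw < 0)) {
    stop("inconsistent count tables", call. = FALSE)
  }
  K <- ncol(n_dk); V <- ncol(n_kw); D <- nrow(n_dk)
  ll <- K * (lgamma(V * beta) - V * lgamma(beta)) +
    D * (lgamma(K * alpha) - K * lgamma(alpha)) +
    sum(lgamma(n_kw + beta)) - sum(lgamma(n_k + V * beta)) +
    sum(lgamma(n_dk + alpha)) - sum(lgamma(N_d + K * alpha))
  ll
}

#' Top terms of a topic
#'
#' @param fit An `lda_fit`.
#' @param topic Topic index in `1..K`.
#' @param n Number of terms to return (truncated at V).
#' @return A tibble with columns `term_id` and `probability`, sorted by
#'   probability descending, ties broken by term id ascending.
#' @export
top_terms <- function(fit, topic, n = 10) {
  stopifnot(inherits(fit, "lda_fit"))
  K <- nrow(fit$phi)
  if (topic < 1 || topic > K) stop("invalid topic index", call. = FALSE)
  p <- fit$phi[topic, ]
  ord <- order(-p, colnames(fit$phi))
  ord <- ord[seq_len(min(n, length(ord)))]
  tibble::tibble(term_id = colnames(fit$phi)[ord], probability = unname(p[ord]))
}

#' Match estimated topics to reference topics
#'
#' Greedy best match on total-variation distance between rows of the two
#' term-distribution matrices: the globally closest (reference, estimated)
#' pair is matched first, both are removed, and the process repeats. Each
#' reference topic is used exactly once and ties resolve toward the smallest
#' indices, so the matching is deterministic.
#'
#' @param phi_est Estimated K x V topic-term matrix.
#' @param phi_ref Reference K x V topic-term matrix.
#' @return An integer vector `perm` of length K with `perm[i]` the estimated
#'   topic matched to reference topic `i`.
#' @export
match_topics <- function(phi_est, phi_ref) {
  if (!all(dim(phi_est) == dim(phi_ref))) {
    stop("phi_est and phi_ref must have identical dimensions", call. = FALSE)
  }
  K <- nrow(phi_ref)
  tv <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      tv[i, j] <- 0.5 * sum(abs(phi_ref[i, ] - phi_est[j, ]))
    }
  }
  perm <- integer(K)
  used_ref <- rep(FALSE, K); used_est <- rep(FALSE, K)
  for (step in seq_len(K)) {
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in which(!used_ref)) {
      for (j in which(!used_est)) {
        if (tv[i, j] < best) { best <- tv[i, j]; bi <- i; bj <- j }
      }
    }
    perm[bi] <- bj
    used_ref[bi] <- TRUE; used_est[bj] <- TRUE
  }
  perm
}

#' @export
print.lda_fit <- function(x, ...) {
  cat(sprintf("<lda_fit: %d drugs, %d terms, K = %d; %d sweeps (%d samples)>\n",
              nrow(x$theta), ncol(x$phi), x$config$k, x$config$n_iter,
              x$config$n_samples))
  invisible(x)
}

#' Tidy an LDA fit
#'
#' Broom-style accessors in the convention used for topic models: `matrix =
#' "beta"` returns the per-topic term probabilities (one row per topic-term
#' pair), `matrix = "gamma"` the per-drug topic probabilities.
#'
#' @param x An `lda_fit`.
#' @param matrix `"beta"` (topic-term) or `"gamma"` (drug-topic).
#' @param ... Unused.
#' @return A tibble in long format.
#' @export
tidy.lda_fit <- function(x, matrix = c("beta", "gamma"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "beta") {
    tibble::tibble(
      topic = rep(seq_len(nrow(x$phi)), times = ncol(x$phi)),
      term_id = rep(colnames(x$phi), each = nrow(x$phi)),
      beta = as.vector(x$phi)
    )
  } else {
    tibble::tibble(
      drug_id = rep(rownames(x$theta), times = ncol(x$theta)),
      topic = rep(seq_len(ncol(x$theta)), each = nrow(x$theta)),
      gamma = as.vector(x$theta)
    )
  }
}

#' One-row summary of an LDA fit
#'
#' @param x An `lda_fit`.
#' @param ... Unused.
#' @return A tibble with the configuration and final log-likelihood.
#' @export
glance.lda_fit <- function(x, ...) {
  tibble::tibble(
    k = x$config$k, alpha = x$config$alpha, beta = x$config$beta,
    n_iter = x$config$n_iter, n_samples = x$config$n_samples,
    log_likelihood = x$log_likelihood[length(x$log_likelihood)]
  )
}

#' Plot the Gibbs log-likelihood trace
#'
#' @param object An `lda_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lda_fit <- function(object, ...) {
  df <- tibble::tibble(sweep = seq_along(object$log_likelihood),
                       log_likelihood = object$log_likelihood)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sweep, y = .data$log_likelihood)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_vline(xintercept = object$config$burn_in, linetype = "dashed") +
    ggplot2::labs(x = "Gibbs sweep", y = "collapsed joint log-likelihood") +
    ggplot2::theme_minimal()
}
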