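# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Full-enumeration two-sided Fisher p-value from log-gamma arithmetic.
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c_ + d; k <- a + c_
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  lchoose2 <- function(n, k) lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)
  denom <- lchoose2(m + n, k)
  support <- max(0, k - n):min(k, m)
  logp <- vapply(support, function(x) {
    lchoose2(m, x) + lchoose2(n, k - x) - denom
  }, 0)
  obs <- logp[support == a]
  sum(exp(logp[logp <= obs + log(1 + 1e-7)]))
}

# Brute-force scan of the information-loss objective over all admissible k.
brute_force_k <- function(ev, lambda = 2) {
  n <- length(ev)
  loss <- vapply(seq_len(n - 1), function(k) {
    abs(sum(ev) - lambda * sum(ev[(k + 1):n]))
  }, 0)
  list(k_star = which.min(loss), loss = loss)
}

# Sequential Polya-urn product for the collapsed joint p(w, z | alpha, beta):
# tokens are added one at a time with Dirichlet-multinomial predictive
# probabilities. By exchangeability the product equals the closed form.
polya_urn_log_lik <- function(doc, word, z, D, V, K, alpha, beta) {
  n_dk <- matrix(0, D, K); n_kw <- matrix(0, K, V)
  n_k <- rep(0, K); N_d <- rep(0, D)
  ll <- 0
  for (i in seq_along(doc)) {
    d <- doc[i]; w <- word[i]; k <- z[i]
    ll <- ll + log((n_dk[d, k] + alpha) / (N_d[d] + K * alpha)) +
      log((n_kw[k, w] + beta) / (n_k[k] + V * beta))
    n_dk[d, k] <- n_dk[d, k] + 1
    n_kw[k, w] <- n_kw[k, w] + 1
    n_k[k] <- n_k[k] + 1
    N_d[d] <- N_d[d] + 1
  }
  ll
}

# Count tables for a fixed token/topic configuration, shaped like the
# `assignments` element of an lda_fit.
make_assignments <- function(doc, word, z, D, V, K) {
  n_dk <- matrix(0L, D, K); n_kw <- matrix(0L, K, V)
  for (i in seq_along(doc)) {
    n_dk[doc[i], z[i]] <- n_dk[doc[i], z[i]] + 1L
    n_kw[z[i], word[i]] <- n_kw[z[i], word[i]] + 1L
  }
  list(z = z, doc = doc, word = word, n_dk = n_dk, n_kw = n_kw,
       n_k = rowSums(n_kw), N_d = rowSums(n_dk))
}

# Random strictly-positive probability vector.
rprob <- function(k) {
  x <- stats::runif(k, 0.05, 1)
  x / sum(x)
}

# Minimal label tibble from parallel lists.
make_labels <- function(drug_id, indications, bw = FALSE, atc = NA_character_,
                        ar_text = "") {
  n <- length(drug_id)
  tibble::tibble(
    drug_id = drug_id,
    effective_date = as.Date("2020-01-01"),
    bw_text = "",
    wp_text = "",
    ar_text = rep_len(ar_text, n),
    has_boxed_warning = rep_len(bw, n),
    atc_level1 = rep_len(atc, n),
    indications = indications
  )
}

# Exact expected random-pair recall by full enumeration over ordered pairs.
enumeration_null <- function(labels, max_m) {
  D <- nrow(labels)
  ind <- labels$indications
  n_ind <- lengths(ind)
  p <- vapply(seq_len(D), function(i) {
    mean(vapply(setdiff(seq_len(D), i), function(j) {
      length(intersect(ind[[i]], ind[[j]])) > 0
    }, TRUE))
  }, 0)
  vapply(seq_len(max_m), function(m) {
    el <- which(n_ind >= m)
    if (length(el) == 0) NA_real_ else mean(p[el])
  }, 0)
}
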