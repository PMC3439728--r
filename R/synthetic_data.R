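#' Sample rows from a symmetric Dirichlet distribution
#'
#' @param n Number of rows.
#' @param dim Dimension of each sample.
#' @param conc Symmetric concentration parameter.
#' @return An `n` by `dim` matrix with rows summing to 1.
#' @keywords internal
rdirichlet_sym <- function(n, dim, conc) {
  g <- matrix(stats::rgamma(n * dim, shape = conc, rate = 1), nrow = n)
  # guard against all-zero rows at very small concentrations
  zero <- rowSums(g) == 0
  if (any(zero)) g[zero, ] <- 1 / dim
  g / rowSums(g)
}

#' Generate a synthetic label corpus with ground truth
#'
#' Emulates a corpus of drug labels produced by the LDA generative process:
#' each topic gets a word distribution `phi_k ~ Dirichlet(beta)` over a
#' synthetic side-effect vocabulary, each drug a topic mixture
#' `theta_d ~ Dirichlet(alpha)`, and each of `N_d ~ max(1, Poisson(L))` tokens
#' is drawn by first picking a topic from `theta_d` and then a term from the
#' topic's word distribution. The drawn tokens are written space-joined into
#' the Adverse Reactions section of each label so the corpus can be pushed
#' back through [build_matrix()].
#'
#' Ground truth links downstream evaluation to the topics: every topic owns a
#' disjoint set of `indications_per_topic` indications; a drug receives all
#' indications of its dominant topic (the argmax of `theta_d`) and, with
#' probability `indication_noise` independently per indication, indications of
#' other topics. Boxed-Warning flags are Bernoulli(`bw_prob`), and each drug's
#' ATC anatomical main group letter is a fixed surjective function of its
#' dominant topic, so category enrichment has a genuine signal.
#'
#' @param n_drugs Number of drugs D.
#' @param vocab_size Number of side-effect terms V.
#' @param n_topics Number of latent topics K.
#' @param alpha Symmetric Dirichlet concentration over topics.
#' @param beta Symmetric Dirichlet concentration over terms.
#' @param mean_doc_length Poisson mean document length L (floored at 1 token).
#' @param indications_per_topic Indications owned by each topic.
#' @param indication_noise Probability of acquiring each off-topic indication.
#' @param bw_prob Probability that a drug carries a Boxed Warning.
#' @param n_atc Number of distinct ATC letters (<= `n_topics`).
#' @param disjoint_topics If `TRUE`, each topic's word distribution is
#'   supported on its own block of roughly `vocab_size / n_topics` terms
#'   (well-separated topics); if `FALSE` (default) topics share the full
#'   vocabulary as in the plain generative model.
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `se_corpus` with elements `labels` (a label
#'   tibble), `matrix` (the generated `drug_term_matrix`), `lexicon` (the
#'   [se_lexicon] of synthetic terms) and `truth` (list: `theta_true` D x K,
#'   `phi_true` K x V, `topic_indications`, `dominant_topic`).
#' @export
#' @examples
#' corp <- generate_corpus(n_drugs = 20, vocab_size = 30, n_topics = 3, seed = 1)
#' dim(corp$matrix)
generate_corpus <- function(n_drugs = 200, vocab_size = 100, n_topics = 5,
                            alpha = 0.1, beta = 0.1, mean_doc_length = 60,
                            indications_per_topic = 1, indication_noise = 0.1,
                            bw_prob = 0.4, n_atc = min(5, n_topics),
                            disjoint_topics = FALSE,
                            seed = 1) {
  stopifnot(n_drugs >= 1, vocab_size >= 1, n_topics >= 1,
            alpha > 0, beta > 0, mean_doc_length > 0,
            indications_per_topic >= 1,
            indication_noise >= 0, indication_noise <= 1,
            bw_prob >= 0, bw_prob <= 1,
            n_atc >= 1, n_atc <= n_topics)
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)

  D <- n_drugs; V <- vocab_size; K <- n_topics
  term_text <- sprintf("se%04d", seq_len(V))
  term_id <- sprintf("t%04d", seq_len(V))
  lexicon <- se_lexicon(term_id, term_text)
  drug_ids <- sprintf("drug%04d", seq_len(D))

  if (disjoint_topics) {
    block <- split(seq_len(V), cut(seq_len(V), K, labels = FALSE))
    phi <- matrix(0, nrow = K, ncol = V)
    for (k in seq_len(K)) {
      g <- stats::rgamma(length(block[[k]]), shape = beta, rate = 1)
      if (sum(g) == 0) g <- rep(1, length(g))
      phi[k, block[[k]]] <- g / sum(g)
    }
  } else {
    phi <- rdirichlet_sym(K, V, beta)
  }
  theta <- rdirichlet_sym(D, K, alpha)
  dominant <- max.col(theta, ties.method = "first")

  doc_len <- pmax(1L, stats::rpois(D, mean_doc_length))
  counts <- matrix(0L, nrow = D, ncol = V, dimnames = list(drug_ids, term_id))
  ar_text <- character(D)
  for (d in seq_len(D)) {
    z <- sample.int(K, doc_len[d], replace = TRUE, prob = theta[d, ])
    w <- integer(doc_len[d])
    for (k in unique(z)) {
      idx <- which(z == k)
      w[idx] <- sample.int(V, length(idx), replace = TRUE, prob = phi[k, ])
    }
    counts[d, ] <- tabulate(w, nbins = V)
    ar_text[d] <- paste(term_text[w], collapse = " ")
  }

  topic_ind <- lapply(seq_len(K), function(k) {
    sprintf("ind%02d_%02d", k, seq_len(indications_per_topic))
  })
  indications <- lapply(seq_len(D), function(d) {
    own <- topic_ind[[dominant[d]]]
    others <- unlist(topic_ind[-dominant[d]])
    noise <- others[stats::runif(length(others)) < indication_noise]
    sort(c(own, noise))
  })
  bw <- stats::runif(D) < bw_prob
  atc_map <- LETTERS[((seq_len(K) - 1L) %% n_atc) + 1L]
  atc <- atc_map[dominant]

  labels <- tibble::tibble(
    drug_id = drug_ids,
    effective_date = as.Date("2012-01-01"),
    bw_text = "",
    wp_text = "",
    ar_text = ar_text,
    has_boxed_warning = bw,
    atc_level1 = atc,
    indications = indications
  )
  # terms that never occur in any drug would be dropped by build_matrix();
  # drop them here too so the corpus round-trips exactly
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  truth <- list(
    theta_true = theta,
    phi_true = phi,
    topic_indications = topic_ind,
    dominant_topic = dominant,
    atc_map = atc_map
  )
  out <- list(labels = labels, matrix = as_drug_term_matrix(counts),
              lexicon = lexicon, truth = truth)
  class(out) <- "se_corpus"
  out
}

#' Extract the lexicon of a synthetic corpus
#'
#' Feeding the corpus labels and this lexicon through [build_matrix()]
#' reproduces the generated count matrix exactly.
#'
#' @param corpus An `se_corpus` from [generate_corpus()].
#' @return The corpus [se_lexicon].
#' @export
corpus_lexicon <- function(corpus) {
  stopifnot(inherits(corpus, "se_corpus"))
  corpus$lexicon
}

#' Write a synthetic corpus to disk
#'
#' Writes `labels.jsonl`, `lexicon.tsv`, `matrix.tsv` and `truth.json` into a
#' directory, using the package's plain-text interchange formats.
#'
#' @param corpus An `se_corpus`.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "se_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_labels(corpus$labels, file.path(dir, "labels.jsonl"))
  write_lexicon(corpus$lexicon, file.path(dir, "lexicon.tsv"))
  write_matrix(corpus$matrix, file.path(dir, "matrix.tsv"))
  truth <- corpus$truth
  jsonlite::write_json(
    list(theta_true = truth$theta_true, phi_true = truth$phi_true,
         topic_indications = truth$topic_indications,
         dominant_topic = truth$dominant_topic, atc_map = truth$atc_map),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = FALSE
  )
  invisible(dir)
}

#' @export
print.se_corpus <- function(x, ...) {
  cat(sprintf("<se_corpus: %d drugs, %d terms, %d true topics>\n",
              nrow(x$labels), nrow(x$lexicon), ncol(x$truth$theta_true)))
  invisible(x)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
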