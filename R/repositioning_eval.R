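indication_lookup <- function(labels) {
  stats::setNames(labels$indications, labels$drug_id)
}

# D x D logical matrix: does drug i share >= 1 indication with drug j?
share_matrix <- function(labels) {
  ind <- labels$indications
  D <- length(ind)
  all_ind <- sort(unique(unlist(ind)))
  if (length(all_ind) == 0) {
    s <- matrix(FALSE, D, D)
  } else {
    member <- vapply(ind, function(x) all_ind %in% x,
                     logical(length(all_ind)))
    member <- matrix(member, nrow = length(all_ind))
    s <- crossprod(member) > 0
  }
  diag(s) <- FALSE
  dimnames(s) <- list(labels$drug_id, labels$drug_id)
  s
}

#' Assess nearest-neighbor drug pairs for shared indications
#'
#' Intersects each query drug's indication set with its nearest neighbor's;
#' a pair is a success when the intersection is non-empty (the repositioning
#' signal: the neighbor is already used for one of the query's diseases).
#'
#' @param nn A nearest-neighbor tibble from [nearest_neighbors()].
#' @param labels A label tibble covering every drug id appearing in `nn`.
#' @return A tibble with columns `drug_id`, `neighbor_id`, `distance`,
#'   `shared_indications` (list), `success`, `n_indications` (the query
#'   drug's indication count).
#' @export
evaluate_pairs <- function(nn, labels) {
  lut <- indication_lookup(labels)
  missing <- setdiff(unique(c(nn$drug_id, nn$neighbor_id)), names(lut))
  if (length(missing) > 0) {
    stop(sprintf("no label record for drug(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  shared <- purrr::map2(nn$drug_id, nn$neighbor_id,
                        function(a, b) intersect(lut[[a]], lut[[b]]))
  dplyr::mutate(
    nn,
    shared_indications = shared,
    success = lengths(shared) > 0,
    n_indications = unname(lengths(lut[nn$drug_id]))
  )
}

#' Recall stratified by minimum indication count
#'
#' For each threshold `m = 1..max_m`, restricts to query drugs with at least
#' `m` indications and reports the fraction whose nearest neighbor shares an
#' indication. Thresholds with no eligible drug get `NA` recall (undefined,
#' not zero).
#'
#' @param assessments Output of [evaluate_pairs()].
#' @param max_m Largest threshold evaluated.
#' @return A tibble with columns `m`, `n_eligible`, `n_success`, `recall`.
#' @export
recall_curve <- function(assessments, max_m = 15) {
  stopifnot(max_m >= 1)
  purrr::map_dfr(seq_len(max_m), function(m) {
    el <- assessments[assessments$n_indications >= m, ]
    tibble::tibble(
      m = m,
      n_eligible = nrow(el),
      n_success = sum(el$success),
      recall = if (nrow(el) > 0) sum(el$success) / nrow(el) else NA_real_
    )
  })
}

#' Monte-Carlo null recall under random partner selection
#'
#' The chance-level counterpart of the nearest-neighbor recall: in each trial
#' every drug is paired with a partner drawn uniformly from the other drugs,
#' and the trial's stratified recall is computed as in [recall_curve()]. The
#' reported null is the mean over `n_trials` trials (default 10,000),
#' reproducible from `seed`.
#'
#' @param labels A label tibble with at least 2 drugs.
#' @param max_m Largest threshold evaluated.
#' @param n_trials Number of Monte-Carlo trials.
#' @param seed Integer seed.
#' @return A tibble with columns `m`, `n_eligible`, `null_recall`, and
#'   `mc_se` (the Monte-Carlo standard error of the mean recall).
#' @export
random_null <- function(labels, max_m = 15, n_trials = 10000, seed = 1) {
  D <- nrow(labels)
  stopifnot(D >= 2, n_trials >= 1, max_m >= 1)
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)

  s <- share_matrix(labels)
  n_ind <- lengths(labels$indications)
  # partner[d, t]: uniform over the other D - 1 drugs
  r <- matrix(sample.int(D - 1L, D * n_trials, replace = TRUE), nrow = D)
  partner <- r + (r >= seq_len(D))
  succ <- matrix(FALSE, nrow = D, ncol = n_trials)
  for (d in seq_len(D)) succ[d, ] <- s[d, partner[d, ]]

  purrr::map_dfr(seq_len(max_m), function(m) {
    el <- which(n_ind >= m)
    if (length(el) == 0) {
      return(tibble::tibble(m = m, n_eligible = 0L,
                            null_recall = NA_real_, mc_se = NA_real_))
    }
    trial_recall <- colMeans(succ[el, , drop = FALSE])
    tibble::tibble(
      m = m, n_eligible = length(el),
      null_recall = mean(trial_recall),
      mc_se = stats::sd(trial_recall) / sqrt(n_trials)
    )
  })
}

#' Exact expectation of the random-pairing null
#'
#' For each eligible drug the probability that a uniformly drawn partner
#' shares an indication is (number of sharing partners) / (D - 1); the
#' expected null recall at threshold `m` is the mean of these probabilities
#' over eligible drugs. This is the exact expectation of [random_null()].
#'
#' @inheritParams random_null
#' @return A tibble with columns `m`, `n_eligible`, `expected_recall`.
#' @export
analytic_null <- function(labels, max_m = 15) {
  D <- nrow(labels)
  stopifnot(D >= 2, max_m >= 1)
  s <- share_matrix(labels)
  p <- rowSums(s) / (D - 1)
  n_ind <- lengths(labels$indications)
  purrr::map_dfr(seq_len(max_m), function(m) {
    el <- which(n_ind >= m)
    tibble::tibble(
      m = m, n_eligible = length(el),
      expected_recall = if (length(el) > 0) mean(p[el]) else NA_real_
    )
  })
}

#' Boxed-Warning replacement candidates
#'
#' Filters the pair assessments to query drugs carrying a Boxed Warning whose
#' nearest neighbor both lacks a Boxed Warning and shares at least one
#' indication — i.e. candidate safer alternatives for the same disease. With
#' `nearest_non_bw = TRUE` the search instead takes each BW drug's nearest
#' neighbor among non-BW drugs (requires the distance matrix).
#'
#' @param assessments Output of [evaluate_pairs()].
#' @param labels A label tibble with `has_boxed_warning` flags.
#' @param dist Optional `kl_dist` matrix, required when `nearest_non_bw`.
#' @param nearest_non_bw Search the nearest non-BW neighbor instead of the
#'   unconditional nearest neighbor (off by default).
#' @return A list of class `bw_report`: `candidates` (tibble of
#'   `bw_drug_id`, `neighbor_id`, `shared_indications`), `n_bw_drugs`,
#'   `n_replaceable`.
#' @export
bw_replacements <- function(assessments, labels, dist = NULL,
                            nearest_non_bw = FALSE) {
  bw <- stats::setNames(labels$has_boxed_warning, labels$drug_id)
  lut <- indication_lookup(labels)
  n_bw <- sum(bw[assessments$drug_id])
  if (nearest_non_bw) {
    if (is.null(dist)) stop("nearest_non_bw = TRUE requires `dist`", call. = FALSE)
    ids <- rownames(dist)
    non_bw_ids <- ids[!bw[ids]]
    if (length(non_bw_ids) == 0) {
      cand <- tibble::tibble(bw_drug_id = character(0),
                             neighbor_id = character(0),
                             shared_indications = list())
    } else {
      bw_ids <- assessments$drug_id[bw[assessments$drug_id]]
      rows <- purrr::map(bw_ids, function(a) {
        cand <- setdiff(non_bw_ids, a)
        v <- dist[a, cand]
        nb <- sort(cand[v == min(v)])[1]
        shared <- intersect(lut[[a]], lut[[nb]])
        if (length(shared) == 0) return(NULL)
        tibble::tibble(bw_drug_id = a, neighbor_id = nb,
                       shared_indications = list(shared))
      })
      cand <- dplyr::bind_rows(rows)
      if (nrow(cand) == 0) {
        cand <- tibble::tibble(bw_drug_id = character(0),
                               neighbor_id = character(0),
                               shared_indications = list())
      }
    }
  } else {
    keep <- bw[assessments$drug_id] & !bw[assessments$neighbor_id] &
      assessments$success
    cand <- tibble::tibble(
      bw_drug_id = assessments$drug_id[keep],
      neighbor_id = assessments$neighbor_id[keep],
      shared_indications = assessments$shared_indications[keep]
    )
  }
  structure(list(candidates = cand, n_bw_drugs = as.integer(n_bw),
                 n_replaceable = nrow(cand)),
            class = "bw_report")
}

#' @export
print.bw_report <- function(x, ...) {
  cat(sprintf("<bw_report: %d BW drugs, %d with a safer-alternative candidate>\n",
              x$n_bw_drugs, x$n_replaceable))
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test by the point-probability method: the two-sided
#' p-value is the sum of probabilities, over all tables with the observed
#' margins, that do not exceed the observed table's probability. Computed from
#' hypergeometric point masses in log space; no continuity correction. Any
#' zero margin gives p = 1.
#'
#' @param tab A 2x2 matrix of non-negative integers with a positive total.
#' @return A p-value in (0, 1].
#' @export
#' @examples
#' fisher_exact_two_sided(matrix(c(8, 1, 2, 9), 2))
fisher_exact_two_sided <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab))) {
    stop("tab must be a 2x2 matrix of non-negative integers", call. = FALSE)
  }
  if (sum(tab) == 0) stop("table total must be positive", call. = FALSE)
  m <- sum(tab[1, ])          # first row total
  n <- sum(tab[2, ])          # second row total
  k <- sum(tab[, 1])          # first column total
  if (m == 0 || n == 0 || k == 0 || sum(tab[, 2]) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  logp <- stats::dhyper(support, m, n, k, log = TRUE)
  obs <- stats::dhyper(tab[1, 1], m, n, k, log = TRUE)
  # relative tolerance guards against ties missed by float rounding
  sum(exp(logp[logp <= obs + log(1 + 1e-7)]))
}

#' ATC first-level category enrichment of repositioning success
#'
#' For each ATC anatomical main group, builds the 2x2 table of
#' (in-category vs. out-of-category) x (nearest neighbor shares an indication
#' vs. not) over assessed drugs carrying an ATC code, and tests deviation from
#' the overall success rate with [fisher_exact_two_sided()]. Drugs without an
#' ATC code are excluded with a message.
#'
#' @param assessments Output of [evaluate_pairs()].
#' @param labels A label tibble with `atc_level1` codes.
#' @return A tibble sorted by success proportion descending, with columns
#'   `atc_level1`, `n_in`, `n_success_in`, `n_out`, `n_success_out`,
#'   `proportion`, `p_value`.
#' @export
atc_enrichment <- function(assessments, labels) {
  atc <- stats::setNames(labels$atc_level1, labels$drug_id)
  a <- dplyr::mutate(assessments, atc_level1 = unname(atc[.data$drug_id]))
  n_missing <- sum(is.na(a$atc_level1))
  if (n_missing > 0) {
    message(sprintf("excluding %d drug(s) without an ATC code", n_missing))
    a <- a[!is.na(a$atc_level1), ]
  }
  if (nrow(a) == 0) stop("no assessed drug carries an ATC code", call. = FALSE)
  cats <- sort(unique(a$atc_level1))
  out <- purrr::map_dfr(cats, function(cc) {
    inn <- a$atc_level1 == cc
    tab <- matrix(c(sum(a$success[inn]), sum(!a$success[inn]),
                    sum(a$success[!inn]), sum(!a$success[!inn])),
                  nrow = 2, byrow = TRUE)
    tibble::tibble(
      atc_level1 = cc,
      n_in = sum(inn), n_success_in = sum(a$success[inn]),
      n_out = sum(!inn), n_success_out = sum(a$success[!inn]),
      proportion = sum(a$success[inn]) / sum(inn),
      p_value = fisher_exact_two_sided(tab)
    )
  })
  dplyr::arrange(out, dplyr::desc(.data$proportion), .data$atc_level1)
}

#' Plot model vs. null recall against the indication-count threshold
#'
#' @param recall Output of [recall_curve()].
#' @param null Output of [random_null()] or [analytic_null()] (optional).
#' @return A ggplot object.
#' @export
plot_recall_curve <- function(recall, null = NULL) {
  df <- dplyr::mutate(recall, which = "nearest neighbor")
  if (!is.null(null)) {
    ncol_name <- if ("null_recall" %in% names(null)) "null_recall" else "expected_recall"
    df <- dplyr::bind_rows(
      df,
      tibble::tibble(m = null$m, recall = null[[ncol_name]], which = "random null")
    )
  }
  ggplot2::ggplot(df[!is.na(df$recall), ],
                  ggplot2::aes(x = .data$m, y = .data$recall,
                               color = .data$which)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "minimum number of indications m", y = "recall",
                  color = NULL) +
    ggplot2::theme_minimal()
}
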