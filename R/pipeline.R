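#' Derive a stage seed from the global seed
#'
#' Fixed labeled-hash scheme: the stage label is folded into a 31-bit integer
#' together with the global seed, so adding a stage never perturbs the
#' randomness of earlier stages.
#'
#' @param seed Global integer seed.
#' @param label Stage name.
#' @return An integer in `[1, 2^31 - 2]`.
#' @keywords internal
stage_seed <- function(seed, label) {
  mod <- 2147483647
  h <- as.numeric(seed) %% mod
  for (code in utf8ToInt(label)) h <- (h * 131 + code) %% mod
  as.integer(max(1, h))
}

#' Run the full repositioning pipeline
#'
#' Orchestrates the stages simulate (optional) -> build-matrix -> choose-k ->
#' fit-lda -> distances -> evaluate, writing every intermediate artifact as
#' plain TSV/JSON into `out_dir` together with a manifest (configuration echo,
#' stage seeds, wall times). Re-running with identical inputs and seed
#' reproduces identical outputs; each stage's seed is derived from the global
#' seed by a fixed labeled hash.
#'
#' Inputs are either a label tibble plus lexicon (or paths to their files) or
#' a `generator` list of [generate_corpus()] arguments for a synthetic run.
#'
#' @param out_dir Output directory (created if needed).
#' @param labels Label tibble, or `NULL`.
#' @param lexicon An [se_lexicon], or `NULL`.
#' @param labels_path,lexicon_path File paths read with [read_labels()] /
#'   [read_lexicon()] when the in-memory objects are not given.
#' @param generator Named list of [generate_corpus()] arguments (without
#'   `seed`) for a synthetic run; ignored when labels are supplied.
#' @param k Fixed number of topics; `NULL` (default) selects it with
#'   [choose_k()]. A fixed `k` is recorded as an override in the manifest.
#' @param lambda Penalty for [choose_k()].
#' @param lda Named list of [fit_lda()] arguments (e.g. `n_iter`, `burn_in`,
#'   `sample_lag`, `alpha`, `beta`).
#' @param n_trials Monte-Carlo trials for [random_null()].
#' @param max_m Largest indication-count threshold evaluated.
#' @param seed Global seed; all stage seeds derive from it.
#' @param binary Passed to [build_matrix()].
#' @return Invisibly, a list with every stage result (`corpus`, `matrix`,
#'   `selection`, `fit`, `dist`, `neighbors`, `assessments`, `recall`,
#'   `null`, `bw`, `atc`, `manifest`).
#' @export
run_pipeline <- function(out_dir, labels = NULL, lexicon = NULL,
                         labels_path = NULL, lexicon_path = NULL,
                         generator = list(), k = NULL, lambda = 2,
                         lda = list(), n_trials = 10000, max_m = 15,
                         seed = 1, binary = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stage_times <- list()
  timed <- function(name, expr) {
    s <- Sys.time()
    on.exit(stage_times[[name]] <<- as.numeric(difftime(Sys.time(), s, units = "secs")))
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  corpus <- NULL
  if (is.null(labels) && !is.null(labels_path)) labels <- read_labels(labels_path)
  if (is.null(lexicon) && !is.null(lexicon_path)) lexicon <- read_lexicon(lexicon_path)
  if (is.null(labels)) {
    corpus <- timed("simulate", {
      args <- generator
      args$seed <- stage_seed(seed, "simulate")
      do.call(generate_corpus, args)
    })
    labels <- corpus$labels
    lexicon <- corpus$lexicon
    write_corpus(corpus, out_dir)
  }
  if (is.null(lexicon)) stop("a lexicon is required with user-supplied labels",
                             call. = FALSE)

  m <- timed("build-matrix", {
    build_matrix(dedupe_labels(labels), lexicon, binary = binary)
  })
  write_matrix(m, file.path(out_dir, "matrix.tsv"))

  k_fixed <- !is.null(k)
  selection <- NULL
  if (!k_fixed) {
    selection <- timed("choose-k", choose_k(compute_spectrum(m), lambda = lambda))
    k <- selection$k_star
    readr::write_tsv(selection$loss_curve, file.path(out_dir, "loss_curve.tsv"))
    jsonlite::write_json(list(k_star = selection$k_star, lambda = lambda),
                         file.path(out_dir, "k_selection.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  fit <- timed("fit-lda", {
    args <- lda
    args$m <- m
    args$k <- k
    args$seed <- stage_seed(seed, "fit-lda")
    do.call(fit_lda, args)
  })
  write_named_tsv(fit$theta, "drug_id", file.path(out_dir, "theta.tsv"))
  write_named_tsv(fit$phi, "topic", file.path(out_dir, "phi.tsv"))
  readr::write_tsv(tibble::tibble(sweep = seq_along(fit$log_likelihood),
                                  log_likelihood = fit$log_likelihood),
                   file.path(out_dir, "trace.tsv"))

  dist <- timed("distances", pairwise_distances(fit))
  write_named_tsv(unclass(dist), "drug_id", file.path(out_dir, "dist.tsv"))
  nn <- nearest_neighbors(dist)
  readr::write_tsv(nn, file.path(out_dir, "neighbors.tsv"))

  eval_res <- timed("evaluate", {
    labs <- dedupe_labels(labels)
    labs <- labs[labs$drug_id %in% rownames(m), ]
    assessments <- evaluate_pairs(nn, labs)
    list(
      labels = labs,
      assessments = assessments,
      recall = recall_curve(assessments, max_m = max_m),
      null = random_null(labs, max_m = max_m, n_trials = n_trials,
                         seed = stage_seed(seed, "random-null")),
      analytic = analytic_null(labs, max_m = max_m),
      bw = bw_replacements(assessments, labs),
      atc = atc_enrichment(assessments, labs)
    )
  })
  readr::write_tsv(
    dplyr::mutate(eval_res$assessments,
                  shared_indications = purrr::map_chr(
                    .data$shared_indications, paste, collapse = ";")),
    file.path(out_dir, "pairs.tsv"))
  readr::write_tsv(eval_res$recall, file.path(out_dir, "recall_curve.tsv"))
  readr::write_tsv(eval_res$null, file.path(out_dir, "null_curve.tsv"))
  readr::write_tsv(
    dplyr::mutate(eval_res$bw$candidates,
                  shared_indications = purrr::map_chr(
                    .data$shared_indications, paste, collapse = ";")),
    file.path(out_dir, "bw_report.tsv"))
  readr::write_tsv(eval_res$atc, file.path(out_dir, "atc_enrichment.tsv"))

  overall <- eval_res$recall$recall[1]
  manifest <- list(
    stages = c(if (!is.null(corpus)) "simulate",
               "build-matrix", if (!k_fixed) "choose-k",
               "fit-lda", "distances", "evaluate"),
    seed = seed,
    stage_seeds = list(simulate = stage_seed(seed, "simulate"),
                       `fit-lda` = stage_seed(seed, "fit-lda"),
                       `random-null` = stage_seed(seed, "random-null")),
    k = k, k_override = k_fixed, lambda = lambda,
    lda = fit$config, n_trials = n_trials, max_m = max_m, binary = binary,
    n_drugs = nrow(m), n_terms = ncol(m),
    overall_recall = overall,
    n_bw_drugs = eval_res$bw$n_bw_drugs,
    n_replaceable = eval_res$bw$n_replaceable,
    wall_times_sec = stage_times,
    total_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(n_drugs = nrow(m), k = k, overall_recall = overall,
         null_recall_m1 = eval_res$null$null_recall[1],
         n_bw_drugs = eval_res$bw$n_bw_drugs,
         n_replaceable = eval_res$bw$n_replaceable),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(corpus = corpus, matrix = m, selection = selection, k = k,
                 fit = fit, dist = dist, neighbors = nn,
                 assessments = eval_res$assessments, recall = eval_res$recall,
                 null = eval_res$null, analytic = eval_res$analytic,
                 bw = eval_res$bw, atc = eval_res$atc, manifest = manifest))
}

write_named_tsv <- function(m, id_col, path) {
  df <- tibble::as_tibble(m, rownames = id_col)
  readr::write_tsv(df, path)
}
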