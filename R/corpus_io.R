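#' Normalize free text for term matching
#'
#' Lowercases, treats punctuation as token separators, and collapses runs of
#' whitespace to single spaces. Applied to both label text and lexicon terms so
#' that matching is purely token-based.
#'
#' @param x Character vector.
#' @return Character vector of the same length.
#' @keywords internal
normalize_text <- function(x) {
  x <- tolower(x)
  x <- gsub("[^[:alnum:]]+", " ", x)
  trimws(x)
}

normalize_indications <- function(x) {
  x <- trimws(tolower(x))
  unique(x[nzchar(x)])
}

#' Create a side-effect term lexicon
#'
#' A lexicon maps term ids to canonical side-effect term strings (the role the
#' MedDRA lowest-level terms play for real labels). Term ids must be unique and
#' non-empty, and term texts must be unique after normalization.
#'
#' @param term_id Character vector of unique, non-empty term ids.
#' @param term Character vector of canonical term strings.
#' @return A tibble with columns `term_id` and `term`, class `se_lexicon`.
#' @export
#' @examples
#' se_lexicon(c("t1", "t2"), c("nausea", "abdominal pain"))
se_lexicon <- function(term_id, term) {
  term_id <- as.character(term_id)
  term <- as.character(term)
  if (length(term_id) != length(term)) {
    stop("term_id and term must have the same length", call. = FALSE)
  }
  if (length(term_id) == 0) stop("lexicon must be non-empty", call. = FALSE)
  if (anyNA(term_id) || any(!nzchar(term_id))) {
    stop("term ids must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(term_id)) stop("term ids must be unique", call. = FALSE)
  norm <- normalize_text(term)
  if (any(!nzchar(norm))) stop("terms must be non-empty after normalization", call. = FALSE)
  if (anyDuplicated(norm)) {
    stop("terms must be unique after normalization", call. = FALSE)
  }
  out <- tibble::tibble(term_id = term_id, term = term)
  class(out) <- c("se_lexicon", class(out))
  out
}

#' Read a side-effect lexicon from a two-column TSV
#'
#' Expects `term_id<TAB>term_text` with no header.
#'
#' @param path Path to the TSV file.
#' @return An [se_lexicon] tibble.
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0) {
    stop(sprintf("lexicon line %d does not have exactly 2 tab-separated fields", bad[1]),
         call. = FALSE)
  }
  se_lexicon(vapply(parts, `[[`, "", 1L), vapply(parts, `[[`, "", 2L))
}

#' @rdname read_lexicon
#' @param lexicon An [se_lexicon].
#' @export
write_lexicon <- function(lexicon, path) {
  writeLines(paste(lexicon$term_id, lexicon$term, sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}

parse_label_line <- function(rec, lineno) {
  if (is.null(rec$drug_id) || !nzchar(rec$drug_id)) {
    stop(sprintf("line %d: missing or empty drug_id", lineno), call. = FALSE)
  }
  secs <- rec$sections
  if (!is.null(secs)) {
    extra <- setdiff(names(secs), c("BW", "WP", "AR"))
    if (length(extra) > 0) {
      stop(sprintf("line %d: unknown section key '%s'", lineno, extra[1]), call. = FALSE)
    }
  }
  get_sec <- function(key) {
    v <- secs[[key]]
    if (is.null(v) || is.na(v)) "" else as.character(v)
  }
  bw_text <- get_sec("BW")
  eff <- rec$effective_date
  eff <- if (is.null(eff) || is.na(eff) || !nzchar(eff)) as.Date(NA) else as.Date(eff)
  bw_flag <- rec$has_boxed_warning
  bw_flag <- if (is.null(bw_flag) || is.na(bw_flag)) nzchar(bw_text) else isTRUE(bw_flag)
  atc <- rec$atc_level1
  atc <- if (is.null(atc) || is.na(atc) || !nzchar(atc)) NA_character_ else as.character(atc)
  ind <- rec$indications
  ind <- if (is.null(ind)) character(0) else normalize_indications(unlist(ind))
  tibble::tibble(
    drug_id = as.character(rec$drug_id),
    effective_date = eff,
    bw_text = bw_text,
    wp_text = get_sec("WP"),
    ar_text = get_sec("AR"),
    has_boxed_warning = bw_flag,
    atc_level1 = atc,
    indications = list(ind)
  )
}

#' Read drug label records from a JSON-lines file
#'
#' Each line is one JSON object describing a label: `drug_id` (required),
#' `effective_date` (ISO date, optional), `sections` (object keyed `"BW"`,
#' `"WP"`, `"AR"`; missing sections become empty text), `has_boxed_warning`
#' (defaults to non-emptiness of the BW section), `atc_level1` (single-letter
#' ATC anatomical main group, optional) and `indications` (array of strings,
#' lowercased, trimmed and deduplicated on read).
#'
#' @param path Path to a UTF-8 JSON-lines file.
#' @return A tibble of labels with one row per record, columns `drug_id`,
#'   `effective_date`, `bw_text`, `wp_text`, `ar_text`, `has_boxed_warning`,
#'   `atc_level1`, and list-column `indications`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_labels())
  rows <- purrr::imap(lines, function(line, i) {
    rec <- tryCatch(
      jsonlite::fromJSON(line, simplifyVector = TRUE),
      error = function(e) stop(sprintf("line %d: malformed JSON (%s)",
                                       i, conditionMessage(e)), call. = FALSE)
    )
    parse_label_line(rec, i)
  })
  labels <- dplyr::bind_rows(rows)
  key <- paste(labels$drug_id, format(labels$effective_date), sep = "@")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop(sprintf("duplicate (drug_id, effective_date): %s", dup), call. = FALSE)
  }
  labels
}

empty_labels <- function() {
  tibble::tibble(
    drug_id = character(0),
    effective_date = as.Date(character(0)),
    bw_text = character(0),
    wp_text = character(0),
    ar_text = character(0),
    has_boxed_warning = logical(0),
    atc_level1 = character(0),
    indications = list()
  )
}

#' Write labels to a JSON-lines file
#'
#' Inverse of [read_labels()]; one JSON object per row.
#'
#' @param labels A label tibble as returned by [read_labels()].
#' @param path Output file path.
#' @export
write_labels <- function(labels, path) {
  lines <- purrr::map_chr(seq_len(nrow(labels)), function(i) {
    rec <- list(drug_id = labels$drug_id[i])
    if (!is.na(labels$effective_date[i])) {
      rec$effective_date <- format(labels$effective_date[i])
    }
    rec$sections <- list(BW = labels$bw_text[i], WP = labels$wp_text[i],
                         AR = labels$ar_text[i])
    rec$has_boxed_warning <- labels$has_boxed_warning[i]
    if (!is.na(labels$atc_level1[i])) rec$atc_level1 <- labels$atc_level1[i]
    rec$indications <- labels$indications[[i]]
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Keep the most recent label per drug
#'
#' Drugs are often marketed under multiple labels; only the one with the
#' latest effective date is retained. A record lacking a date loses to any
#' dated record; if the dates tie (or all candidates are undated) the record
#' with the lexicographically larger serialized form is kept, so the result is
#' deterministic.
#'
#' @param labels A label tibble possibly containing repeated `drug_id`s.
#' @return A label tibble with exactly one row per `drug_id`, in first-seen
#'   drug order.
#' @export
dedupe_labels <- function(labels) {
  if (nrow(labels) == 0) return(labels)
  serial <- purrr::map_chr(seq_len(nrow(labels)), function(i) {
    paste(labels$drug_id[i], format(labels$effective_date[i]),
          labels$bw_text[i], labels$wp_text[i], labels$ar_text[i],
          labels$has_boxed_warning[i], labels$atc_level1[i],
          paste(sort(labels$indications[[i]]), collapse = ";"),
          sep = "\x1f")
  })
  labels$.serial <- serial
  keep <- labels |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$drug_id) |>
    dplyr::arrange(dplyr::desc(!is.na(.data$effective_date)),
                   dplyr::desc(.data$effective_date),
                   dplyr::desc(.data$.serial), .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  keep <- keep[order(match(keep$drug_id, unique(labels$drug_id))), ]
  keep$.serial <- NULL
  keep$.row <- NULL
  keep
}

# Tokenized longest-match-first phrase matcher. Returns a named integer vector
# of per-term match counts (term_id -> count), zero-count terms omitted.
match_tokens <- function(tokens, lex_index) {
  counts <- integer(0)
  n <- length(tokens)
  i <- 1L
  while (i <= n) {
    cands <- lex_index[[tokens[i]]]
    matched <- FALSE
    if (!is.null(cands)) {
      for (j in seq_along(cands$len)) {
        len <- cands$len[j]
        if (i + len - 1L <= n &&
            identical(tokens[i:(i + len - 1L)], cands$tokens[[j]])) {
          id <- cands$term_id[j]
          counts[id] <- (if (is.na(counts[id])) 0L else counts[id]) + 1L
          i <- i + len
          matched <- TRUE
          break
        }
      }
    }
    if (!matched) i <- i + 1L
  }
  counts
}

# Index lexicon phrases by first token; candidates at each anchor token are
# ordered longest first (ties by lexicon order) so matching is deterministic.
build_lex_index <- function(lexicon) {
  toks <- strsplit(normalize_text(lexicon$term), " ", fixed = TRUE)
  first <- vapply(toks, `[[`, "", 1L)
  lens <- lengths(toks)
  idx <- split(seq_along(toks), first)
  lapply(idx, function(rows) {
    rows <- rows[order(-lens[rows], rows)]
    list(term_id = lexicon$term_id[rows], tokens = toks[rows], len = lens[rows])
  })
}

#' Extract side-effect term occurrences from label text
#'
#' Text and lexicon terms are normalized (lowercase, punctuation as token
#' separators) and matched as whole-token phrases. Overlapping candidates are
#' resolved longest-match-first and matched tokens are consumed, so
#' `"acute abdominal pain"` matches `abdominal pain` but not `pain`.
#'
#' @param text A single character string (may be empty).
#' @param lexicon An [se_lexicon].
#' @return A tibble with columns `term_id`, `term`, `count`, one row per term
#'   matched at least once, in lexicon order.
#' @export
#' @examples
#' lex <- se_lexicon(c("t1", "t2"), c("pain", "abdominal pain"))
#' extract_terms("acute abdominal pain", lex)
extract_terms <- function(text, lexicon) {
  stopifnot(length(text) == 1)
  if (!inherits(lexicon, "se_lexicon")) lexicon <- se_lexicon(lexicon$term_id, lexicon$term)
  tokens <- strsplit(normalize_text(text), " ", fixed = TRUE)[[1]]
  counts <- match_tokens(tokens, build_lex_index(lexicon))
  hit <- lexicon$term_id %in% names(counts)
  tibble::tibble(
    term_id = lexicon$term_id[hit],
    term = lexicon$term[hit],
    count = as.integer(counts[lexicon$term_id[hit]])
  )
}

#' Assemble the drug by side-effect-term count matrix
#'
#' Concatenates each drug's Boxed Warning, Warnings and Precautions, and
#' Adverse Reactions texts, extracts lexicon terms from the combined text, and
#' stacks the per-drug counts into the side-effect profile matrix used as
#' topic-model input. Columns are restricted to terms matched in at least one
#' drug (in lexicon order); drugs matching no term are dropped with a warning.
#'
#' @param labels A deduplicated label tibble.
#' @param lexicon An [se_lexicon].
#' @param binary If `TRUE`, reduce counts to presence/absence (0/1).
#' @return An integer matrix with `drug_id` rownames and `term_id` colnames,
#'   class `drug_term_matrix`.
#' @export
build_matrix <- function(labels, lexicon, binary = FALSE) {
  if (anyDuplicated(labels$drug_id)) {
    stop("labels must be deduplicated (one row per drug_id)", call. = FALSE)
  }
  lex_index <- build_lex_index(lexicon)
  per_drug <- purrr::map(seq_len(nrow(labels)), function(i) {
    text <- paste(labels$bw_text[i], labels$wp_text[i], labels$ar_text[i],
                  sep = " \n ")
    tokens <- strsplit(normalize_text(text), " ", fixed = TRUE)[[1]]
    match_tokens(tokens, lex_index)
  })
  n_hits <- vapply(per_drug, function(x) sum(x), 0L)
  dropped <- labels$drug_id[n_hits == 0L]
  if (length(dropped) == nrow(labels)) stop("empty corpus", call. = FALSE)
  if (length(dropped) > 0) {
    warning(sprintf("dropping %d drug(s) with no matched terms: %s",
                    length(dropped), paste(dropped, collapse = ", ")),
            call. = FALSE)
  }
  keep_rows <- which(n_hits > 0L)
  matched_ids <- unique(unlist(lapply(per_drug[keep_rows], names)))
  term_ids <- lexicon$term_id[lexicon$term_id %in% matched_ids]
  m <- matrix(0L, nrow = length(keep_rows), ncol = length(term_ids),
              dimnames = list(labels$drug_id[keep_rows], term_ids))
  for (r in seq_along(keep_rows)) {
    cnt <- per_drug[[keep_rows[r]]]
    m[r, names(cnt)] <- as.integer(cnt)
  }
  if (binary) m[] <- as.integer(m > 0L)
  as_drug_term_matrix(m)
}

#' Coerce a matrix to a drug-term matrix
#'
#' Validates non-negative integer counts, unique row (drug) and column (term)
#' names, and the absence of all-zero rows.
#'
#' @param m An integer matrix with dimnames.
#' @return The matrix with class `drug_term_matrix`.
#' @export
as_drug_term_matrix <- function(m) {
  stopifnot(is.matrix(m))
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("drug-term matrix requires drug_id rownames and term_id colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop("drug and term ids must be unique", call. = FALSE)
  }
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(m) == 0)) stop("drug-term matrix must have no all-zero rows",
                                 call. = FALSE)
  storage.mode(m) <- "integer"
  class(m) <- c("drug_term_matrix", class(m))
  m
}

#' Read or write a drug-term matrix as TSV
#'
#' The TSV has a header row of term ids, a first column `drug_id`, and integer
#' counts; `write_matrix()` followed by [read_matrix()] is the identity on ids
#' and counts.
#'
#' @param path Path to the TSV file.
#' @return `read_matrix()` returns a `drug_term_matrix`.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("matrix file must have a header and >= 1 row", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1]]
  if (header[1] != "drug_id") stop("first header field must be 'drug_id'", call. = FALSE)
  width <- length(header)
  ragged <- which(lengths(parts[-1]) != width)
  if (length(ragged) > 0) {
    stop(sprintf("ragged row at line %d", ragged[1] + 1L), call. = FALSE)
  }
  body <- parts[-1]
  ids <- vapply(body, `[[`, "", 1L)
  vals <- suppressWarnings(
    vapply(body, function(p) as.numeric(p[-1]), numeric(width - 1L))
  )
  vals <- if (width == 2L) matrix(vals, ncol = 1L) else t(vals)
  if (anyNA(vals)) stop("non-numeric count in matrix file", call. = FALSE)
  if (any(vals < 0) || any(vals != round(vals))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  dimnames(vals) <- list(ids, header[-1])
  as_drug_term_matrix(vals)
}

#' @rdname read_matrix
#' @param m A `drug_term_matrix`.
#' @export
write_matrix <- function(m, path) {
  header <- paste(c("drug_id", colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], m[i, ]), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.drug_term_matrix <- function(x, ...) {
  cat(sprintf("<drug_term_matrix: %d drugs x %d terms, %d tokens>\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}
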