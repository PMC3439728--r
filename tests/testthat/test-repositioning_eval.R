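nn_table <- function(drug_id, neighbor_id, distance = 0.1) {
  tibble::tibble(drug_id = drug_id, neighbor_id = neighbor_id,
                 distance = rep_len(distance, length(drug_id)))
}

test_that("pair assessment intersects indication sets", {
  labs <- make_labels(c("a", "b", "c", "d"),
                      list(c("pain", "fever"), c("pain"), c("cough"),
                           c("fever", "cough", "rash")))
  nn <- nn_table(c("a", "b", "c", "d"), c("b", "a", "d", "a"))
  a <- evaluate_pairs(nn, labs)
  expect_equal(a$shared_indications,
               list("pain", "pain", "cough", "fever"))
  expect_equal(a$success, rep(TRUE, 4))
  expect_equal(a$n_indications, c(2L, 1L, 1L, 3L))

  # universal shared indication: recall 1; disjoint sets: recall 0
  uni <- make_labels(c("x", "y"), list("pain", c("pain", "rash")))
  expect_true(all(evaluate_pairs(nn_table(c("x", "y"), c("y", "x")), uni)$success))
  dis <- make_labels(c("x", "y"), list("pain", "rash"))
  expect_false(any(evaluate_pairs(nn_table(c("x", "y"), c("y", "x")), dis)$success))

  expect_error(evaluate_pairs(nn_table("a", "zz"), labs), "zz")
})

test_that("the recall curve stratifies by minimum indication count", {
  labs <- make_labels(c("a", "b", "c", "d"),
                      list("i1", c("i2", "i3"), c("i2", "i3", "i4"),
                           c("i2", "i3", "i4", "i5")))
  # only the multi-indication drugs succeed
  nn <- nn_table(c("a", "b", "c", "d"), c("b", "c", "d", "c"))
  a <- evaluate_pairs(nn, labs)
  rc <- recall_curve(a, max_m = 6)
  expect_equal(rc$n_eligible, c(4L, 3L, 2L, 1L, 0L, 0L))
  # direct subset recomputation
  for (m in 1:4) {
    el <- a[a$n_indications >= m, ]
    expect_equal(rc$recall[m], mean(el$success))
  }
  expect_true(all(diff(rc$recall[1:4]) >= 0))
  expect_true(is.na(rc$recall[5]) && is.na(rc$recall[6]))

  # all drugs above every threshold: constant curve at the overall recall
  labs2 <- make_labels(c("a", "b"), list(c("i1", "i2", "i3"), c("i1", "i9", "i8")))
  rc2 <- recall_curve(evaluate_pairs(nn_table(c("a", "b"), c("b", "a")), labs2), 3)
  expect_equal(rc2$recall, rep(1, 3))
})

test_that("the analytic null equals full enumeration on small fixtures", {
  # one sharing pair among three drugs
  labs <- make_labels(c("a", "b", "c"), list("pain", "pain", "rash"))
  an <- analytic_null(labs, 1)
  expect_equal(an$expected_recall, mean(c(1 / 2, 1 / 2, 0)))

  # universal shared indication
  uni <- make_labels(c("a", "b", "c"), list("p", c("p", "q"), "p"))
  expect_equal(analytic_null(uni, 1)$expected_recall, 1)

  # random fixtures up to 20 drugs against ordered-pair enumeration
  set.seed(41)
  for (rep in 1:10) {
    D <- sample(3:20, 1)
    pool <- sprintf("i%d", 1:8)
    ind <- lapply(seq_len(D), function(i) sample(pool, sample(1:4, 1)))
    labs <- make_labels(sprintf("d%02d", seq_len(D)), ind)
    an <- analytic_null(labs, 4)
    expect_equal(an$expected_recall, enumeration_null(labs, 4), tolerance = 1e-12)
  }
})

test_that("the Monte-Carlo null converges to the analytic expectation", {
  set.seed(77)
  D <- 50
  pool <- sprintf("i%d", 1:12)
  ind <- lapply(seq_len(D), function(i) sample(pool, sample(1:5, 1)))
  labs <- make_labels(sprintf("d%02d", seq_len(D)), ind)
  an <- analytic_null(labs, 5)
  mc <- random_null(labs, 5, n_trials = 2000, seed = 123)
  for (m in 1:5) {
    if (is.na(an$expected_recall[m])) next
    expect_lt(abs(mc$null_recall[m] - an$expected_recall[m]), 3 * mc$mc_se[m])
  }
  # reproducible from the seed
  mc2 <- random_null(labs, 5, n_trials = 2000, seed = 123)
  expect_identical(mc, mc2)
})

test_that("Boxed-Warning replacement candidates follow the filter definition", {
  labs <- make_labels(
    sprintf("d%02d", 1:10),
    list(c("uti"), c("uti"), c("uti", "otitis"), c("flu"), c("flu"),
         c("rash"), c("rash"), c("pain"), c("pain"), c("pain")),
    bw = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  )
  nn <- nn_table(labs$drug_id,
                 c("d02", "d01", "d02", "d05", "d04",
                   "d07", "d06", "d09", "d08", "d08"))
  a <- evaluate_pairs(nn, labs)
  rep_ <- bw_replacements(a, labs)
  # independent filter recomputation
  bw <- stats::setNames(labs$has_boxed_warning, labs$drug_id)
  keep <- a$success & bw[a$drug_id] & !bw[a$neighbor_id]
  expect_equal(rep_$candidates$bw_drug_id, a$drug_id[keep])
  expect_equal(rep_$n_bw_drugs, sum(bw))
  expect_equal(rep_$n_replaceable, sum(keep))
  # cefazolin/cefuroxime pattern: BW query, non-BW neighbor sharing "uti"
  expect_true("d01" %in% rep_$candidates$bw_drug_id)
  # d04's neighbor has a BW itself: excluded
  expect_false("d04" %in% rep_$candidates$bw_drug_id)

  # no BW drugs: empty report
  none <- labs; none$has_boxed_warning <- FALSE
  r0 <- bw_replacements(evaluate_pairs(nn, none), none)
  expect_equal(r0$n_replaceable, 0)
  expect_equal(r0$n_bw_drugs, 0L)
})

test_that("the nearest-non-BW search finds safer alternatives further away", {
  labs <- make_labels(c("a", "b", "c"), list("uti", "uti", "uti"),
                      bw = c(TRUE, TRUE, FALSE))
  d <- matrix(c(0, 1, 2, 1, 0, 5, 2, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  a <- evaluate_pairs(nearest_neighbors(d), labs)
  strict <- bw_replacements(a, labs)
  expect_equal(strict$n_replaceable, 0)  # a and b are each other's neighbor
  relaxed <- bw_replacements(a, labs, dist = d, nearest_non_bw = TRUE)
  expect_equal(sort(relaxed$candidates$bw_drug_id), c("a", "b"))
  expect_equal(unique(relaxed$candidates$neighbor_id), "c")
})

test_that("Fisher's exact test matches enumeration and the stats oracle", {
  expect_equal(fisher_exact_two_sided(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact_two_sided(matrix(c(8, 1, 2, 9), 2)),
               920 / 167960, tolerance = 1e-12)
  # zero margin
  expect_equal(fisher_exact_two_sided(matrix(c(0, 0, 3, 4), 2)), 1)
  expect_error(fisher_exact_two_sided(matrix(c(1, -1, 2, 3), 2)))

  set.seed(53)
  for (rep in 1:40) {
    tab <- matrix(rpois(4, 4), 2)
    if (sum(tab) == 0) next
    p <- fisher_exact_two_sided(tab)
    expect_equal(p, fisher_enum_oracle(tab), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    # symmetry under transposition and joint row/column swaps
    expect_equal(fisher_exact_two_sided(t(tab)), p, tolerance = 1e-12)
    expect_equal(fisher_exact_two_sided(tab[2:1, 2:1]), p, tolerance = 1e-12)
  }
})

test_that("ATC enrichment assembles the 2x2 tables it tests", {
  set.seed(61)
  D <- 20
  labs <- make_labels(sprintf("d%02d", 1:D),
                      lapply(1:D, function(i) sprintf("i%d", i)),
                      atc = rep(c("M", "J", "N", "A"), 5))
  a <- tibble::tibble(
    drug_id = labs$drug_id,
    neighbor_id = rev(labs$drug_id),
    distance = 0.1,
    shared_indications = as.list(rep(list(character(0)), D)),
    success = rep(c(TRUE, FALSE), 10),
    n_indications = 1L
  )
  # make category M all-successes while global rate is 50%
  a$success[labs$atc_level1 == "M"] <- TRUE
  a$success[labs$atc_level1 == "A"] <- FALSE
  enr <- atc_enrichment(a, labs)
  expect_equal(enr$atc_level1[1], "M")
  m_row <- enr[enr$atc_level1 == "M", ]
  expect_equal(m_row$proportion, 1)
  tab <- matrix(c(m_row$n_success_in, m_row$n_in - m_row$n_success_in,
                  m_row$n_success_out, m_row$n_out - m_row$n_success_out),
                2, byrow = TRUE)
  expect_equal(m_row$p_value, fisher_exact_two_sided(tab))
  # per-category proportions equal direct recomputation
  for (cc in enr$atc_level1) {
    expect_equal(enr$proportion[enr$atc_level1 == cc],
                 mean(a$success[labs$atc_level1 == cc]))
  }
  # margins account for every assessed drug with a code
  expect_equal(unique(enr$n_in + enr$n_out), D)

  # single category: complement margin empty, p = 1
  one <- labs; one$atc_level1 <- "M"
  enr1 <- atc_enrichment(a, one)
  expect_equal(enr1$p_value, 1)

  # drugs without a code are excluded with a message
  some <- labs; some$atc_level1[1:3] <- NA
  expect_message(enr2 <- atc_enrichment(a, some), "without an ATC")
  expect_equal(unique(enr2$n_in + enr2$n_out), D - 3L)
})

test_that("recall plotting accepts model and null curves", {
  labs <- make_labels(c("a", "b"), list(c("i1", "i2"), c("i1")))
  a <- evaluate_pairs(nn_table(c("a", "b"), c("b", "a")), labs)
  rc <- recall_curve(a, 3)
  nl <- analytic_null(labs, 3)
  expect_s3_class(plot_recall_curve(rc, nl), "ggplot")
})
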