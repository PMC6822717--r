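test_that("data-type assignment follows the rule tree deterministically", {
  meta_cs <- tibble::tibble(field_id = "1",
                            field_type = "categorical-single",
                            ordering = "unspecified",
                            reference = NA_character_,
                            category_order = NA_character_)
  # two distinct values -> binary
  expect_identical(assign_data_type(meta_cs, c(0, 1, 0, 1, NA))$data_type,
                   "binary")
  # multi-level with declared ordering
  meta_ord <- meta_cs; meta_ord$ordering <- "ordered"
  expect_identical(assign_data_type(meta_ord, c(1, 2, 3))$data_type,
                   "ordered")
  meta_un <- meta_cs; meta_un$ordering <- "unordered"
  expect_identical(assign_data_type(meta_un, c(1, 2, 3))$data_type,
                   "unordered")
  # undeclared ordering for a multi-level field is a configuration error
  expect_error(assign_data_type(meta_cs, c(1, 2, 3)), "declare")
  # < 2 observed values: dropped with a logged reason
  dropped <- assign_data_type(meta_cs, c(1, 1, 1))
  expect_true(is.na(dropped$data_type))
  expect_match(dropped$provenance[2], "dropped")

  meta_int <- tibble::tibble(field_id = "2", field_type = "integer",
                             ordering = "unspecified",
                             reference = NA_character_,
                             category_order = NA_character_)
  expect_identical(assign_data_type(meta_int, seq_len(500))$data_type,
                   "continuous")
  expect_identical(assign_data_type(meta_int, rep(1:3, 10))$data_type,
                   "ordered")
  # cutoff is configurable
  expect_identical(assign_data_type(meta_int, rep(1:3, 10),
                                    max_ordered_levels = 2)$data_type,
                   "continuous")
  # pure function: rerunning yields identical assignments
  expect_identical(assign_data_type(meta_int, rep(1:3, 10)),
                   assign_data_type(meta_int, rep(1:3, 10)))
})

test_that("categorical-multiple fields expand to complete binary outcomes", {
  meta <- tibble::tibble(field_id = "50", field_type = "categorical-multiple",
                         ordering = "unspecified",
                         reference = NA_character_,
                         category_order = NA_character_)
  slots <- list(c("A", "B", NA, "A", NA, NA, "B", NA, NA, NA),
                c("B", NA, NA, NA, NA, NA, NA, NA, NA, NA))
  out <- expand_categorical_multiple(meta, slots)
  expect_identical(nrow(out), 2L)
  expect_setequal(out$value_code, c("A", "B"))
  # every participant assigned with no missing entries
  expect_true(all(vapply(out$values, function(v) !anyNA(v) &&
                           length(v) == 10, logical(1))))
  # participant 1 holds both codes -> TRUE in both derived outcomes
  expect_identical(vapply(out$values, function(v) v[1], integer(1)),
                   c(1L, 1L))
  # rare codes are kept here; the per-category filter excludes them later
  expect_true("B" %in% out$value_code)
  expect_warning(
    empty <- expand_categorical_multiple(meta, list(rep(NA_character_, 5))),
    "no recorded values")
  expect_identical(nrow(empty), 0L)
})

test_that("inverse normal transform matches closed-form quantiles", {
  got <- inverse_normal_transform(c(10, 20, 30))
  expect_equal(got, qnorm(c(1 / 6, 3 / 6, 5 / 6)), tolerance = 1e-12)
  expect_equal(got[2], 0)
  expect_equal(round(got[3], 4), 0.9674)

  # missing entries stay missing; order is preserved on untied entries
  x <- c(5, NA, 1, 7, 3)
  tx <- inverse_normal_transform(x)
  expect_true(is.na(tx[2]))
  expect_identical(order(tx[-2]), order(x[-2]))

  # symmetry of the quantile grid at large m
  big <- inverse_normal_transform(sample(seq_len(10001)))
  expect_lt(abs(mean(big)), 1e-6)
  expect_equal(stats::median(big), 0)

  # Blom offset option
  blom <- inverse_normal_transform(c(10, 20, 30), offset = "blom")
  expect_equal(blom, qnorm((1:3 - 3 / 8) / (3 + 1 / 4)), tolerance = 1e-12)

  expect_error(inverse_normal_transform(c(2, 2, 2)), "identical")
  expect_error(inverse_normal_transform(c(1, NA, NA)), "non-missing")

  # random tie-break is reproducible under a seed and yields no point mass
  ties <- c(rep(1, 50), rep(2, 50))
  t1 <- inverse_normal_transform(ties, seed = 9)
  expect_identical(t1, inverse_normal_transform(ties, seed = 9))
  expect_identical(anyDuplicated(t1), 0L)
})

test_that("transformed outcomes are close to standard normal in moments", {
  x <- withr::with_seed(2, rexp(10000))  # heavily skewed input
  tx <- inverse_normal_transform(x)
  m <- mean(tx); s <- sd(tx)
  expect_lt(abs(m), 1e-6)
  expect_lt(abs(s - 1), 0.01)
  expect_lt(abs(mean((tx - m)^3) / s^3), 0.05)
  expect_lt(abs(mean((tx - m)^4) / s^4 - 3), 0.1)
})

test_that("derive_outcomes types whole fields once and logs provenance", {
  data <- tiny_phenotypes()
  meta <- tiny_metadata()
  derived <- derive_outcomes(data, meta, seed = 1)
  types <- setNames(derived$data_type, derived$outcome_id)
  expect_identical(unname(types["10"]), "continuous")
  expect_identical(unname(types["20"]), "continuous")  # 31 distinct > 20
  expect_identical(unname(types["30"]), "ordered")
  expect_identical(unname(types["40"]), "unordered")
  expect_true(all(c("50#A", "50#B", "50#C") %in% derived$outcome_id))
  expect_true(all(lengths(derived$provenance) > 0))
  # continuous outcomes leave the transform with mean ~0, sd ~1
  f10 <- derived$values[[which(derived$outcome_id == "10")]]
  expect_lt(abs(mean(f10)), 1e-8)
  # unordered reference honoured from metadata
  expect_identical(derived$reference[derived$outcome_id == "40"], "1")
  # identical rerun (pure function of metadata + values + seed)
  expect_identical(derived$data_type,
                   derive_outcomes(data, meta, seed = 1)$data_type)
})

test_that("stratum filters apply the 500 and 10-per-category rules inclusively", {
  mk <- function(v, dt) {
    tibble::tibble(outcome_id = "x", field_id = "x",
                   value_code = NA_character_, data_type = dt,
                   values = list(v), categories = list(NULL),
                   reference = NA_character_, provenance = list("test"))
  }
  mask <- rep(TRUE, 600)

  # continuous with 499 non-missing -> excluded; 500 -> included
  v499 <- c(rnorm(499), rep(NA, 101))
  v500 <- c(rnorm(500), rep(NA, 100))
  expect_false(apply_stratum_filters(mk(v499, "continuous"), mask)$include)
  expect_true(apply_stratum_filters(mk(v500, "continuous"), mask)$include)

  # binary category counts (491, 9) -> excluded; (490, 10) -> included
  b_bad <- c(rep(0L, 491), rep(1L, 9), rep(NA, 100))
  b_ok <- c(rep(0L, 490), rep(1L, 10), rep(NA, 100))
  expect_false(apply_stratum_filters(mk(b_bad, "binary"), mask)$include)
  expect_true(apply_stratum_filters(mk(b_ok, "binary"), mask)$include)

  # ordered outcomes face only the total-count rule
  o <- factor(c(rep(1, 495), rep(2, 3), rep(3, 2), rep(NA, 100)),
              ordered = TRUE)
  expect_true(apply_stratum_filters(mk(o, "ordered"), mask)$include)

  # reasons are recorded
  res <- apply_stratum_filters(mk(v499, "continuous"), mask)
  expect_match(res$reason, "499")
})
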