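# shared small fixtures, built in code at test time

tiny_metadata <- function() {
  tibble::tibble(
    field_id = c("10", "20", "30", "40", "50"),
    field_type = c("continuous", "integer", "categorical-single",
                   "categorical-single", "categorical-multiple"),
    ordering = c("unspecified", "unspecified", "ordered", "unordered",
                 "unspecified"),
    reference = c(NA, NA, NA, "1", NA),
    category_order = c(NA, NA, "1,2,3", NA, NA))
}

tiny_phenotypes <- function(n = 60, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    snp = rbinom(n, 2, 0.3),
    age = runif(n, 40, 69),
    sex = rbinom(n, 1, 0.5),
    smoking_status = factor(sample(c("never", "ever"), n, replace = TRUE),
                            levels = c("never", "ever")),
    f10 = rnorm(n),
    f20 = sample(0:30, n, replace = TRUE),
    f30 = sample(1:3, n, replace = TRUE),
    f40 = sample(1:3, n, replace = TRUE),
    f50_0 = sample(c("A", "B", NA), n, replace = TRUE),
    f50_1 = sample(c("B", "C", NA), n, replace = TRUE)))
}
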