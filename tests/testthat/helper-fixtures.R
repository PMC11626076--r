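# shared fixture builders; everything is generated in code, no stored data

# logistic line profile sampled at `spacing` over [0, span] mm
make_profile <- function(theta0, theta1, theta_begin = -800, theta_end = 40,
                         span = 14, spacing = 0.35, noise_sd = 0) {
  l <- seq(0, span, by = spacing)
  h <- logistic_model(l, theta0, theta1, theta_begin, theta_end)
  if (noise_sd > 0) h <- h + rnorm(length(l), 0, noise_sd)
  list(distance_mm = l, hu = h)
}

# long-format rating table: one scan, `readers` readers, constant scores
make_ratings <- function(scan_ids = "s1", readers = c("A", "B", "C"),
                         item_score = 3L, overall_score = 3L) {
  long <- expand.grid(scan_id = scan_ids, reader_id = readers,
                      item = c("overall", rating_items()),
                      stringsAsFactors = FALSE)
  long$score <- ifelse(long$item == "overall", overall_score, item_score)
  rating_table(long)
}

# small phantom spec for plumbing tests (too small for 5000-px ROIs)
small_spec <- function(...) {
  args <- utils::modifyList(list(size = 128L, seed = 42L), list(...))
  do.call(phantom_spec, args)
}

# independent two-way ANOVA oracle for ICC(3,k), via lm/aov machinery
icc_oracle <- function(m) {
  d <- data.frame(score = as.vector(m),
                  scan = factor(rep(seq_len(nrow(m)), ncol(m))),
                  reader = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  ms <- summary(stats::aov(score ~ scan + reader, data = d))[[1]][, "Mean Sq"]
  (ms[1] - ms[3]) / ms[1]
}
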