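# small hand-built panels used across tests
toy_panel_df <- function() {
  data.frame(
    region = rep(c("A", "B"), each = 3),
    country = rep(c("X", "Y"), each = 3),
    week = rep(0:2, 2),
    total_count = c(10L, 12L, 9L, 20L, 18L, 25L),
    negative_count = c(2L, 3L, 1L, 4L, 5L, 6L),
    max_temperature = c(5, 10, 28, -1, 15, 20),
    stringsAsFactors = FALSE)
}

random_panel <- function(n_regions = 4, n_weeks = 10, n_countries = 2,
                         seed = 1) {
  set.seed(seed)
  regions <- sprintf("R%02d", seq_len(n_regions))
  countries <- sprintf("C%d", ((seq_len(n_regions) - 1) %% n_countries) + 1)
  df <- expand.grid(i = seq_len(n_regions), week = seq_len(n_weeks) - 1L)
  ct <- rpois(nrow(df), 50)
  data.frame(region = regions[df$i], country = countries[df$i],
             week = df$week, total_count = ct,
             negative_count = rbinom(nrow(df), ct, 0.2),
             x = rnorm(nrow(df)), stringsAsFactors = FALSE)
}

zero_effects <- function() lapply(default_true_effects(), function(v) v * 0)
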