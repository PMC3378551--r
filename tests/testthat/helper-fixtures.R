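# shared fixture builders; everything is generated in code

# small two-group expression matrix with optional shifted features
toy_matrix <- function(p = 30, n1 = 4, n2 = 4, shift_rows = integer(0),
                       shift = 0, seed = 42, prefix = "g") {
  set.seed(seed)
  x <- matrix(rnorm(p * (n1 + n2)), p, n1 + n2)
  if (length(shift_rows) > 0)
    x[shift_rows, (n1 + 1):(n1 + n2)] <- x[shift_rows, (n1 + 1):(n1 + n2)] + shift
  expression_matrix(x, sprintf("%s%03d", prefix, seq_len(p)),
                    sprintf("s%02d", seq_len(n1 + n2)))
}

toy_design <- function(n1 = 4, n2 = 4) {
  group_design(setNames(rep(c("A", "B"), c(n1, n2)),
                        sprintf("s%02d", seq_len(n1 + n2))))
}

# small, fast simulation configuration for unit tests
tiny_config <- function(...) {
  defaults <- list(n_per_group = 5, p_mir = 20, p_mrna = 200,
                   set_size_range = c(3, 6), n_runs = 2,
                   n_rot = 99, n_perm = 99)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# rank data with prescribed one-sided p-values
ranks_from_p <- function(p_up, ids = sprintf("g%03d", seq_along(p_up))) {
  fs <- data.frame(feature = ids, p_up = p_up, p_down = 1 - p_up,
                   stringsAsFactors = FALSE)
  rank_by_direction(fs)
}

expect_p <- function(p) {
  expect_true(all(p >= 0 & p <= 1))
}
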