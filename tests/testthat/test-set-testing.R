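test_that("direction-wise ranks order by one-sided p with id tie-break", {
  rk <- ranks_from_p(c(0.01, 0.5, 0.9))
  expect_equal(unname(rk$up), c(1L, 2L, 3L))
  expect_equal(unname(rk$down), c(3L, 2L, 1L))
  # up-rank + down-rank = p + 1 when p_up + p_down = 1 and no ties
  expect_equal(unname(rk$up + rk$down), rep(4L, 3))
  tied <- ranks_from_p(c(0.5, 0.5), ids = c("b", "a"))
  expect_equal(tied$up[["a"]], 1L)  # id order breaks the tie
  expect_equal(tied$up[["b"]], 2L)
})

test_that("KS set test matches the hand-computed one-sided statistic", {
  rk <- ranks_from_p(seq(0.05, 0.95, length.out = 10))
  # members occupy up-ranks 1 and 3: u = (0.1, 0.3),
  # D+ = max(1/2 - 0.1, 1 - 0.3) = 0.7
  res <- ks_set_test(rk, c("g001", "g003"), "m")
  expect_equal(res$p_set_up, exp(-2 * 2 * 0.7^2))
  # the same members sit at the bottom of the down ranking (ranks 8, 10):
  # u = (0.8, 1.0), D+ = max(0.5 - 0.8, 1 - 1) = 0
  expect_equal(res$p_set_down, 1)
  expect_false(res$complementary)

  # whole-universe set: u_(i) = i/m exactly, D+ = 0, p = 1
  all_res <- ks_set_test(rk, sprintf("g%03d", 1:10))
  expect_equal(all_res$p_set_up, 1)
  expect_equal(all_res$p_set_down, 1)

  # a set filling the top m ranks, m << p: p near exp(-2m(1-m/p)^2)
  rk2 <- ranks_from_p((1:100) / 101)
  top <- ks_set_test(rk2, sprintf("g%03d", 1:5))
  expect_lt(abs(top$p_set_up - exp(-2 * 5 * (1 - 5 / 100)^2)), 0.02)
  expect_lt(top$p_set_up, 0.001)
})

test_that("Wilcoxon set test matches the formula and enumeration oracle", {
  rk <- ranks_from_p((1:10) / 11)
  res <- wilcoxon_set_test(rk, c("g001", "g002", "g003"), "m")
  w <- 6; m <- 3; p <- 10
  z <- (w - m * (p + 1) / 2) / sqrt(m * (p - m) * (p + 1) / 12)
  expect_equal(res$p_set_up, pnorm(z))
  expect_equal(res$p_set_up + res$p_set_down, 1)

  # enumeration oracle: the normal approximation must sit close to the
  # exact rank-sum null P(W <= 6) over all C(10,3) member-rank subsets
  combos <- combn(10, 3)
  exact <- mean(colSums(combos) <= w)
  expect_lt(abs(res$p_set_up - exact), 0.03)

  # member ranks exactly average -> z = 0, both directions 0.5
  mid <- wilcoxon_set_test(ranks_from_p((1:11) / 12), c("g006"))
  expect_equal(mid$p_set_up, 0.5)
  expect_equal(mid$p_set_down, 0.5)

  expect_error(wilcoxon_set_test(rk, sprintf("g%03d", 1:10)),
               "whole universe")
})

test_that("directional Wilcoxon p-values sum to one for arbitrary sets", {
  set.seed(21)
  for (i in 1:20) {
    pv <- runif(50)
    rk <- ranks_from_p(pv)
    set <- sample(names(rk$up), sample(2:20, 1))
    res <- wilcoxon_set_test(rk, set)
    expect_equal(res$p_set_up + res$p_set_down, 1)
  }
})

test_that("Fisher-exact set test reproduces hypergeometric tails", {
  # table: in-set 3 DE / 7 not, out-set 2 DE / 88 not
  pv_up <- c(rep(0.01, 3), rep(0.5, 7), rep(0.01, 2), rep(0.5, 88))
  ids <- sprintf("g%03d", 1:100)
  fs <- data.frame(feature = ids, p_up = pv_up, p_down = 1 - pv_up,
                   stringsAsFactors = FALSE)
  res <- fisher_exact_set_test(fs, ids[1:10], tau = 0.05)
  expect_equal(res$p_set_up, phyper(2, 5, 95, 10, lower.tail = FALSE))
  # enumeration oracle over the hypergeometric support
  support <- 0:5
  pmf <- dhyper(support, 5, 95, 10)
  expect_equal(res$p_set_up, sum(pmf[support >= 3]))
  # agreement with fisher.test's one-sided p on the same 2x2 table
  ft <- fisher.test(matrix(c(3, 7, 2, 88), 2, byrow = TRUE),
                    alternative = "greater")
  expect_equal(res$p_set_up, ft$p.value, tolerance = 1e-12)

  # no DE calls anywhere -> degenerate table, p = 1
  fs0 <- data.frame(feature = ids, p_up = rep(0.5, 100),
                    p_down = rep(0.5, 100), stringsAsFactors = FALSE)
  res0 <- fisher_exact_set_test(fs0, ids[1:10], tau = 0.05)
  expect_equal(res0$p_set_up, 1)

  # all in-set DE, nothing outside: point mass 1/C(p, m) at the tail
  pv <- c(rep(0.01, 4), rep(0.9, 16))
  fs1 <- data.frame(feature = sprintf("g%03d", 1:20), p_up = pv,
                    p_down = 1 - pv, stringsAsFactors = FALSE)
  res1 <- fisher_exact_set_test(fs1, sprintf("g%03d", 1:4), tau = 0.05)
  expect_equal(res1$p_set_up, 1 / choose(20, 4))
})

test_that("direction splitting follows the group-mean comparison", {
  x <- expression_matrix(rbind(c(0, 0, 1, 1), c(2, 2, 0, 0), c(3, 3, 3, 3)),
                         c("up1", "dn1", "tie1"), sprintf("s%02d", 1:4))
  halves <- suppressMessages(
    split_set_by_direction(x, toy_design(2, 2), c("up1", "dn1", "tie1")))
  expect_equal(halves$up, "up1")
  expect_equal(halves$down, "dn1")
  # all genes higher in group 2 -> empty down subset
  x2 <- expression_matrix(rbind(c(0, 0, 1, 1), c(0, 0, 2, 2)),
                          c("a", "b"), sprintf("s%02d", 1:4))
  h2 <- split_set_by_direction(x2, toy_design(2, 2), c("a", "b"))
  expect_equal(length(h2$down), 0L)
})

test_that("global Q statistic matches the direct quadratic form", {
  x <- toy_matrix(p = 4, n1 = 3, n2 = 3, seed = 12)
  design <- toy_design(3, 3)
  subset <- c("g001", "g002")
  xs <- scale(t(unclass(x)[subset, ]), center = TRUE, scale = FALSE)
  y <- c(0, 0, 0, 1, 1, 1); yc <- y - mean(y)
  q_direct <- drop(t(yc) %*% xs %*% t(xs) %*% yc)
  # expose the observed Q through a degenerate permutation comparison:
  # with all-zero expression Q = 0 and p = 1
  zero <- expression_matrix(matrix(0, 2, 6), c("a", "b"),
                            sprintf("s%02d", 1:6))
  expect_equal(global_q_test(zero, design, c("a", "b"), n_perm = 99), 1)
  # permutation p floor
  set.seed(1)
  strong <- expression_matrix(
    rbind(rep(c(0, 5), each = 3) + rnorm(6, 0, .01),
          rep(c(0, 5), each = 3) + rnorm(6, 0, .01)),
    c("a", "b"), sprintf("s%02d", 1:6))
  p_strong <- global_q_test(strong, design, c("a", "b"), n_perm = 99)
  # only permutations preserving the grouping reach the observed Q;
  # 6 choose 3 = 20 distinct label splits, so small but not at the floor
  expect_lt(p_strong, 0.2)
  expect_gte(p_strong, 1 / 100)
  # empty subset warns and returns 1
  expect_warning(p_empty <- global_q_test(x, design, character(0)), "empty")
  expect_equal(p_empty, 1)
  # internal Q agrees with the hand computation (same centering path)
  q_internal <- sum(crossprod(xs, yc)^2)
  expect_equal(q_internal, q_direct)
})

test_that("rotation tests hit the add-one floor under a strong shift", {
  set.seed(14)
  x <- toy_matrix(p = 60, n1 = 5, n2 = 5, seed = 14,
                  shift_rows = 1:10, shift = 4)
  ctx <- rotation_context(x, toy_design(5, 5))
  up_set <- sprintf("g%03d", 1:10)
  set.seed(2)
  ro <- roast_set_test(ctx, up_set, n_rot = 199)
  # continuous mean-z statistic: the add-one floor is attained
  expect_equal(ro$p_set_up, 1 / 200)
  expect_equal(ro$p_set_up + ro$p_set_down, 1 + 1 / 200)
  set.seed(2)
  rm <- romer_set_test(ctx, list(m1 = up_set), n_rot = 199)
  # the mean-rank statistic is discrete; rotations that tie the observed
  # extreme count toward both tails, so p can sit above the floor
  expect_gte(rm$p_set_up, 1 / 200)
  expect_lte(rm$p_set_up, 0.05)
  expect_gte(rm$p_set_up + rm$p_set_down, 1)
  expect_lt(rm$p_set_up + rm$p_set_down, 1.1)
})

test_that("rotation p-values are null-uniform over replicates", {
  set.seed(15)
  p_roast <- replicate(400, {
    x <- expression_matrix(matrix(rnorm(40 * 8), 40, 8),
                           sprintf("g%03d", 1:40), sprintf("s%02d", 1:8))
    ctx <- rotation_context(x, toy_design(4, 4))
    roast_set_test(ctx, sprintf("g%03d", 1:8), n_rot = 99)$p_set_up
  })
  ks <- suppressWarnings(ks.test(p_roast, "punif"))
  expect_lt(unname(ks$statistic), 0.08)
})

test_that("competitive romer ignores a shift common to all genes", {
  set.seed(16)
  base <- matrix(rnorm(80 * 10), 80, 10)
  ids <- sprintf("g%03d", 1:80)
  samp <- sprintf("s%02d", 1:10)
  design <- toy_design(5, 5)
  shifted <- base
  shifted[, 6:10] <- shifted[, 6:10] + 3  # every gene up in group 2
  set.seed(99)
  p_base <- romer_set_test(rotation_context(expression_matrix(base, ids, samp),
                                            design),
                           list(s = ids[1:10]), n_rot = 199)$p_set_up
  set.seed(99)
  p_shift <- romer_set_test(
    rotation_context(expression_matrix(shifted, ids, samp), design),
    list(s = ids[1:10]), n_rot = 199)$p_set_up
  # relative ranks are what matters; a global shift leaves the competitive
  # p in the bulk of its null range
  expect_gt(p_shift, 0.05)
  expect_lt(p_shift, 0.95)
  expect_gt(p_base, 0.05)
})

test_that("rank-based tests depend on the data only through ranks", {
  pv <- c(0.01, 0.2, 0.35, 0.6, 0.8, 0.9, 0.95, 0.99)
  squashed <- pv^2 / 2  # strictly monotone, same ordering
  set <- c("g001", "g003")
  for (builder in list(ks_set_test, wilcoxon_set_test)) {
    a <- builder(ranks_from_p(pv), set)
    b <- builder(ranks_from_p(squashed), set)
    expect_equal(a$p_set_up, b$p_set_up)
  }
})

test_that("set tests are invariant to gene relabeling", {
  set.seed(17)
  pv <- runif(30)
  ids1 <- sprintf("a%03d", 1:30)
  ids2 <- sprintf("zz%03d", 1:30)
  r1 <- ks_set_test(ranks_from_p(pv, ids1), ids1[5:10])
  r2 <- ks_set_test(ranks_from_p(pv, ids2), ids2[5:10])
  expect_equal(r1$p_set_up, r2$p_set_up)
  expect_equal(r1$p_set_down, r2$p_set_down)
})

test_that("rotation tests are reproducible under a fixed seed", {
  x <- toy_matrix(p = 50, n1 = 4, n2 = 4, seed = 18)
  ctx <- rotation_context(x, toy_design(4, 4))
  set.seed(7); a <- roast_set_test(ctx, sprintf("g%03d", 1:6), n_rot = 99)
  set.seed(7); b <- roast_set_test(ctx, sprintf("g%03d", 1:6), n_rot = 99)
  expect_identical(a, b)
})

test_that("custom set tests can be registered and dispatched", {
  register_set_test("always-half", function(env, set, mirna_id)
    data.frame(mirna = mirna_id, test = "always-half",
               set_size = length(set), p_set_up = 0.5, p_set_down = 0.5,
               complementary = FALSE), complementary = FALSE)
  expect_true("always-half" %in% list_set_tests())
  expect_equal(choose_combiner("always-half"), "fisher")
  expect_error(choose_combiner("no-such-test"), "unknown set test")
})

test_that("rotation context reproduces the moderated statistics", {
  x <- toy_matrix(p = 80, n1 = 5, n2 = 5, seed = 19,
                  shift_rows = 1:5, shift = 2)
  fs <- feature_test(x, toy_design(5, 5))
  ctx <- rotation_context(x, toy_design(5, 5), attr(fs, "hyper"))
  expect_equal(unname(ctx$t_obs), fs$t_mod, tolerance = 1e-10)
})
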