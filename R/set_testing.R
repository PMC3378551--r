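#' Direction-wise ranks of all measured mRNAs
#'
#' Competitive enrichment tests operate on the positions of the gene-wise
#' one-sided p-values. Rank 1 is the most significant gene in the given
#' direction; ties are broken deterministically by feature id.
#'
#' @param mrna_stats a `"feature_stats"` data.frame for the mRNA matrix.
#' @return list of class `"rank_data"`: `up` and `down` (named integer rank
#'   vectors over all measured mRNAs), `p` (number of mRNAs).
#' @export
rank_by_direction <- function(mrna_stats) {
  ids <- mrna_stats$feature
  rank_of <- function(pv) {
    r <- integer(length(pv))
    r[order(pv, ids)] <- seq_along(pv)
    names(r) <- ids
    r
  }
  structure(list(up = rank_of(mrna_stats$p_up),
                 down = rank_of(mrna_stats$p_down),
                 p = length(ids)),
            class = "rank_data")
}

set_result <- function(mirna_id, test_name, m, p_up, p_down, complementary) {
  data.frame(mirna = mirna_id, test = test_name, set_size = m,
             p_set_up = min(max(p_up, 0), 1),
             p_set_down = min(max(p_down, 0), 1),
             complementary = complementary,
             stringsAsFactors = FALSE, row.names = NULL)
}

member_ranks <- function(ranks, set, direction) {
  r <- ranks[[direction]]
  mem <- intersect(set, names(r))
  if (length(mem) == 0) stop("empty set after matching to the measured genes")
  r[mem]
}

#' One-sided Kolmogorov-Smirnov enrichment test on ranks
#'
#' Tests, per direction, whether the set's normalized ranks pile up near the
#' top of the ranking (skew toward low ranks) against uniformity, using the
#' one-sided statistic D+ = max_i (i/m - u_(i)) and the asymptotic bound
#' p = exp(-2 m D+^2).
#'
#' @param ranks a [rank_by_direction()] result.
#' @param set character vector of member mRNA ids.
#' @param mirna_id id to report the result under.
#' @return one-row set-test data.frame (`complementary = FALSE`).
#' @export
ks_set_test <- function(ranks, set, mirna_id = NA_character_) {
  one_dir <- function(direction) {
    r <- member_ranks(ranks, set, direction)
    m <- length(r)
    u <- sort(r) / ranks$p
    d_plus <- max(seq_len(m) / m - u)
    min(1, exp(-2 * m * max(d_plus, 0)^2))
  }
  m <- length(intersect(set, names(ranks$up)))
  set_result(mirna_id, "ks", m, one_dir("up"), one_dir("down"), FALSE)
}

#' Wilcoxon rank-sum enrichment test on ranks
#'
#' Compares the ranks of set members against the rest of the genes with the
#' normal approximation of the rank-sum statistic, no continuity correction.
#' Low member ranks (enrichment toward the significant end) give a small
#' p-value for that direction. Because the up and down rankings are exact
#' reverses of each other (p_up + p_down = 1 gene-wise), the two directional
#' p-values sum to one.
#'
#' @inheritParams ks_set_test
#' @return one-row set-test data.frame (`complementary = TRUE`).
#' @export
wilcoxon_set_test <- function(ranks, set, mirna_id = NA_character_) {
  p <- ranks$p
  one_dir <- function(direction) {
    r <- member_ranks(ranks, set, direction)
    m <- length(r)
    if (m >= p) stop("set covers the whole universe; no outside genes")
    w <- sum(r)
    z <- (w - m * (p + 1) / 2) / sqrt(m * (p - m) * (p + 1) / 12)
    stats::pnorm(z)
  }
  m <- length(intersect(set, names(ranks$up)))
  set_result(mirna_id, "wilcoxon", m, one_dir("up"), one_dir("down"), TRUE)
}

#' Fisher-exact (hypergeometric) enrichment test on DE calls
#'
#' Dichotomizes the gene-wise one-sided p-values at `tau` and tests
#' over-representation of DE calls inside the set with the one-sided
#' hypergeometric tail of the 2x2 table (in/out of set) x (DE/not DE).
#'
#' @param mrna_stats a `"feature_stats"` data.frame for all measured mRNAs.
#' @param set character vector of member mRNA ids.
#' @param tau one-sided unadjusted p-value threshold for calling a gene DE
#'   (default 0.05).
#' @param mirna_id id to report the result under.
#' @return one-row set-test data.frame (`complementary = FALSE`).
#' @export
fisher_exact_set_test <- function(mrna_stats, set, tau = 0.05,
                                  mirna_id = NA_character_) {
  if (tau <= 0 || tau >= 1) stop("tau must be in (0,1)")
  in_set <- mrna_stats$feature %in% set
  m <- sum(in_set)
  if (m == 0) stop("empty set after matching to the measured genes")
  n_gene <- nrow(mrna_stats)
  if (m >= n_gene) stop("set covers the whole universe; no outside genes")
  one_dir <- function(pv) {
    de <- pv <= tau
    k <- sum(de & in_set)
    bigk <- sum(de)
    # P(X >= k), X ~ Hypergeom(total DE, total non-DE, draws = set size)
    stats::phyper(k - 1, bigk, n_gene - bigk, m, lower.tail = FALSE)
  }
  set_result(mirna_id, "fisher-exact", m,
             one_dir(mrna_stats$p_up), one_dir(mrna_stats$p_down), FALSE)
}

#' Split a target set by observed direction of regulation
#'
#' Global (self-contained) tests have no one-sided version; the set is split
#' into the genes observed higher in group 2 (`up`) and those lower (`down`),
#' each subset tested separately. Genes with exactly equal group means belong
#' to neither subset.
#'
#' @param mrna log-expression matrix of all measured mRNAs.
#' @param design a [group_design()].
#' @param set character vector of member mRNA ids.
#' @return list with character vectors `up` and `down`.
#' @export
split_set_by_direction <- function(mrna, design, set) {
  mem <- intersect(set, rownames(mrna))
  grp <- match_design(mrna, design)
  xs <- mrna[mem, , drop = FALSE]
  m1 <- rowMeans(xs[, grp == 1L, drop = FALSE])
  m2 <- rowMeans(xs[, grp == 2L, drop = FALSE])
  if (any(m1 == m2))
    message(sum(m1 == m2), " gene(s) with exactly equal group means ",
            "excluded from both direction subsets")
  list(up = mem[m2 > m1], down = mem[m2 < m1])
}

#' Quadratic-form global association test with a permutation null
#'
#' Self-contained score-type test of association between the group indicator
#' and the expression of a gene subset: Q = (y - ybar)' X X' (y - ybar) with
#' X the column-centered subset expression (samples x genes), referred to its
#' permutation distribution under random relabeling of the samples.
#'
#' @param mrna log-expression matrix.
#' @param design a [group_design()].
#' @param subset character vector of gene ids (a direction-split half of a
#'   target set).
#' @param n_perm number of label permutations (>= 99).
#' @return permutation p-value, floor 1/(n_perm+1); an empty subset returns
#'   p = 1 with a warning.
#' @export
global_q_test <- function(mrna, design, subset, n_perm = 1000) {
  if (length(subset) == 0) {
    warning("empty direction subset; p set to 1")
    return(1)
  }
  if (n_perm < 99) stop("n_perm must be at least 99")
  grp <- match_design(mrna, design)
  xs <- t(mrna[subset, , drop = FALSE])      # samples x genes
  xs <- scale(xs, center = TRUE, scale = FALSE)
  y <- as.numeric(grp == 2L)
  yc <- y - mean(y)
  q_obs <- sum(crossprod(xs, yc)^2)
  yperm <- replicate(n_perm, sample(yc))
  q_perm <- colSums(crossprod(xs, yperm)^2)
  (1 + sum(q_perm >= q_obs)) / (n_perm + 1)
}

#' Directional global-Q set test via direction splitting
#'
#' @inheritParams global_q_test
#' @param set full target set (split internally with
#'   [split_set_by_direction()]).
#' @param mirna_id id to report the result under.
#' @return one-row set-test data.frame (`complementary = FALSE`): `p_set_up`
#'   from the up-split subset, `p_set_down` from the down-split subset.
#' @export
globalq_set_test <- function(mrna, design, set, n_perm = 1000,
                             mirna_id = NA_character_) {
  halves <- split_set_by_direction(mrna, design, set)
  m <- length(intersect(set, rownames(mrna)))
  if (m == 0) stop("empty set after matching to the measured genes")
  set_result(mirna_id, "globalq", m,
             global_q_test(mrna, design, halves$up, n_perm),
             global_q_test(mrna, design, halves$down, n_perm), FALSE)
}

#' Reduced effect-plus-residual representation for rotation tests
#'
#' Projects every gene's sample vector onto an orthonormal basis in which the
#' first coordinate carries the two-group contrast and the remaining d
#' coordinates span the residual space (orthogonal to intercept and
#' contrast). Rotation tests resample by applying one random unit
#' (d+1)-vector to all genes jointly, which preserves inter-gene correlation.
#'
#' @param x log-expression matrix (the mRNA matrix for target-set testing).
#' @param design a [group_design()].
#' @param hyper optional `"eb_hyper"` prior; estimated from `x` if missing.
#' @return list of class `"rotation_context"`: `Y` (genes x (d+1) reduced
#'   data), `d`, `d0`, `s0_sq`, `df_total`, `t_obs` (named moderated t),
#'   `stats` (the `"feature_stats"` frame).
#' @export
rotation_context <- function(x, design, hyper = NULL) {
  grp <- match_design(x, design)
  n <- ncol(x)
  n1 <- sum(grp == 1L); n2 <- sum(grp == 2L)
  d <- n - 2L
  # orthonormal basis: intercept, normalized contrast, residual completion
  v1 <- rep(1 / sqrt(n), n)
  cvec <- ifelse(grp == 2L, 1 / n2, -1 / n1)
  v2 <- cvec / sqrt(sum(cvec^2))
  qrd <- qr(cbind(v1, v2))
  basis <- qr.Q(qrd, complete = TRUE)        # n x n orthonormal
  vres <- basis[, 3:n, drop = FALSE]
  u1 <- as.numeric(unclass(x) %*% v2)        # effect coordinate per gene
  ures <- unclass(x) %*% vres                # residual coordinates
  s_sq <- rowSums(ures^2) / d
  if (is.null(hyper)) hyper <- estimate_prior(s_sq, d)
  fit <- structure(list(diff = stats::setNames(u1 * sqrt(1/n1 + 1/n2),
                                               rownames(x)) ,
                        s_sq = stats::setNames(s_sq, rownames(x)),
                        d = d, n1 = n1, n2 = n2), class = "two_group_fit")
  fs <- moderated_stats(fit, hyper)
  structure(list(Y = cbind(u1, ures), d = d, d0 = hyper$d0,
                 s0_sq = hyper$s0_sq,
                 df_total = if (is.infinite(hyper$d0)) Inf else hyper$d0 + d,
                 t_obs = stats::setNames(fs$t_mod, fs$feature),
                 stats = fs),
            class = "rotation_context")
}

# moderated t of every gene under n_rot random rotations: genes x n_rot
rotated_t <- function(ctx, n_rot) {
  k <- ncol(ctx$Y)                            # d + 1
  r <- matrix(stats::rnorm(n_rot * k), n_rot, k)
  r <- r / sqrt(rowSums(r^2))                 # unit vectors on the sphere
  eff <- ctx$Y %*% t(r)                       # rotated effect coordinates
  tot <- rowSums(ctx$Y^2)
  s_sq <- (tot - eff^2) / ctx$d
  s_sq[s_sq < 0] <- 0                         # guard rounding
  if (is.infinite(ctx$d0)) {
    s_tilde <- matrix(ctx$s0_sq, nrow(eff), ncol(eff))
  } else {
    s_tilde <- (ctx$d0 * ctx$s0_sq + ctx$d * s_sq) / (ctx$d0 + ctx$d)
  }
  eff / sqrt(s_tilde)
}

# normal scores from moderated t via Student CDF then normal quantile
t_to_z <- function(t, df) {
  z <- stats::qnorm(stats::pt(t, df = df, log.p = TRUE), log.p = TRUE)
  # saturate the (vanishingly rare) infinities from CDF underflow
  z[!is.finite(z)] <- sign(t[!is.finite(z)]) * 40
  z
}

# column-wise ranks of a matrix in one radix sort (no ties expected in
# rotated statistics; ties get arbitrary but deterministic order)
col_ranks <- function(m) {
  p <- nrow(m); b <- ncol(m)
  o <- order(rep(seq_len(b), each = p), as.vector(m))
  rk <- integer(p * b)
  rk[o] <- rep(seq_len(p), times = b)
  matrix(rk, p, b)
}

# shared driver: roast (mean normal score) and romer (mean rank) for many
# sets against one rotation sample
rotation_tests_all <- function(ctx, sets, n_rot = 1000,
                               which = c("roast", "romer")) {
  which <- match.arg(which, several.ok = TRUE)
  genes <- names(ctx$t_obs)
  memb <- lapply(sets, function(s) match(intersect(s, genes), genes))
  sizes <- lengths(memb)
  idx_all <- unlist(memb)
  grp <- rep(seq_along(memb), sizes)
  tt <- rotated_t(ctx, n_rot)
  mean_by_set <- function(v) as.vector(rowsum(v[idx_all], grp)) / sizes
  means_matrix <- function(m)
    rowsum(m[idx_all, , drop = FALSE], grp) / sizes
  result_frame <- function(test_name, obs, rot) {
    up <- (1 + rowSums(rot >= obs)) / (n_rot + 1)
    down <- (1 + rowSums(rot <= obs)) / (n_rot + 1)
    data.frame(mirna = names(sets), test = test_name, set_size = sizes,
               p_set_up = unname(up), p_set_down = unname(down),
               complementary = TRUE, stringsAsFactors = FALSE,
               row.names = NULL)
  }
  out <- list()
  if ("roast" %in% which) {
    if (any(sizes < 2)) stop("roast needs sets of at least 2 measured genes")
    z_obs <- t_to_z(ctx$t_obs, ctx$df_total)
    z_rot <- t_to_z(tt, ctx$df_total)
    out$roast <- result_frame("roast", mean_by_set(z_obs),
                              means_matrix(z_rot))
  }
  if ("romer" %in% which) {
    if (any(length(genes) - sizes < 2))
      stop("romer needs at least 2 genes outside each set")
    rk_obs <- rank(ctx$t_obs)                 # high rank = up-regulated
    rk_rot <- col_ranks(tt)
    out$romer <- result_frame("romer", mean_by_set(rk_obs),
                              means_matrix(rk_rot))
  }
  out
}

#' Self-contained rotation set test (roast-style, unweighted mean statistic)
#'
#' Gene-wise moderated t statistics are mapped to normal scores through the
#' Student-t CDF; the set statistic is their unweighted mean over the set.
#' The null is sampled by random rotations: one unit vector per iteration,
#' uniform on the (d+1)-sphere, applied to every gene's reduced vector, which
#' preserves the inter-gene correlation within the set. p-values use the
#' add-one convention, so the smallest attainable value is 1/(n_rot+1).
#'
#' @param ctx a [rotation_context()].
#' @param set character vector of member mRNA ids (>= 2 measured members).
#' @param n_rot number of rotations (default 1000, >= 99).
#' @param mirna_id id to report the result under.
#' @return one-row set-test data.frame (`complementary = TRUE` up to
#'   rotation resolution).
#' @export
roast_set_test <- function(ctx, set, n_rot = 1000, mirna_id = NA_character_) {
  if (n_rot < 99) stop("n_rot must be at least 99")
  sets <- stats::setNames(list(set), mirna_id)
  rotation_tests_all(ctx, sets, n_rot, which = "roast")$roast
}

#' Competitive rotation set test (romer-style, mean-rank statistic)
#'
#' Moderated t statistics of all measured genes are ranked; the set statistic
#' is the mean rank of the member genes, compared against rotations of the
#' whole gene universe (one shared unit vector per iteration). Because mean
#' ranks are symmetric around their null center, the two directional
#' p-values sum to one up to the rotation resolution.
#'
#' @param ctx a [rotation_context()].
#' @param sets named list of target sets (or a single character vector).
#' @param n_rot number of rotations (default 1000, >= 99).
#' @return set-test data.frame, one row per set.
#' @export
romer_set_test <- function(ctx, sets, n_rot = 1000) {
  if (n_rot < 99) stop("n_rot must be at least 99")
  if (!is.list(sets)) sets <- list(set = sets)
  rotation_tests_all(ctx, sets, n_rot, which = "romer")$romer
}

# all-sets vectorized versions of the rank-based tests, used by the
# simulation driver; results agree with the per-set public functions
rank_tests_all <- function(env, sets, which) {
  ranks <- env$ranks
  genes <- names(ranks$up)
  memb <- lapply(sets, function(s) match(intersect(s, genes), genes))
  sizes <- lengths(memb)
  idx_all <- unlist(memb)
  grp <- rep(seq_along(memb), sizes)
  p <- ranks$p
  frame <- function(test_name, up, down, complementary) {
    data.frame(mirna = names(sets), test = test_name, set_size = sizes,
               p_set_up = pmin(pmax(unname(up), 0), 1),
               p_set_down = pmin(pmax(unname(down), 0), 1),
               complementary = complementary, stringsAsFactors = FALSE,
               row.names = NULL)
  }
  out <- list()
  if ("wilcoxon" %in% which) {
    pdir <- function(r) {
      w <- as.vector(rowsum(r[idx_all], grp))
      stats::pnorm((w - sizes * (p + 1) / 2) /
                     sqrt(sizes * (p - sizes) * (p + 1) / 12))
    }
    out$wilcoxon <- frame("wilcoxon", pdir(ranks$up), pdir(ranks$down), TRUE)
  }
  if ("ks" %in% which) {
    pdir <- function(r) vapply(memb, function(i) {
      m <- length(i)
      d_plus <- max(seq_len(m) / m - sort(r[i]) / p)
      min(1, exp(-2 * m * max(d_plus, 0)^2))
    }, numeric(1))
    out$ks <- frame("ks", pdir(ranks$up), pdir(ranks$down), FALSE)
  }
  if ("fisher-exact" %in% which) {
    pdir <- function(pv) {
      de <- pv <= env$tau
      k <- as.vector(rowsum(as.numeric(de)[idx_all], grp))
      stats::phyper(k - 1, sum(de), p - sum(de), sizes, lower.tail = FALSE)
    }
    out[["fisher-exact"]] <- frame("fisher-exact",
                                   pdir(env$mrna_stats$p_up),
                                   pdir(env$mrna_stats$p_down), FALSE)
  }
  out
}

# ---- pluggable set-test registry ------------------------------------------

set_test_registry <- new.env(parent = emptyenv())

#' Register a custom gene-set test
#'
#' Plug-in point for external set tests (e.g. published comparator methods).
#' The callable receives `(env, set, mirna_id)` where `env` is a list with
#' elements `mrna` (expression matrix), `design`, `mrna_stats`, `ranks`
#' (direction-wise), `rotation_ctx`, and the run parameters, and must return
#' a one-row data.frame with columns `mirna`, `test`, `set_size`,
#' `p_set_up`, `p_set_down`, `complementary`.
#'
#' @param name test name used on the command line and in `run_pipeline()`.
#' @param fun the callable.
#' @param complementary do the directional p-values of this test sum to one?
#'   Determines the p-value combiner (Stouffer if `TRUE`, Fisher otherwise).
#' @export
register_set_test <- function(name, fun, complementary = FALSE) {
  stopifnot(is.character(name), length(name) == 1, is.function(fun))
  assign(name, list(fun = fun, complementary = complementary),
         envir = set_test_registry)
  invisible(name)
}

#' Names of all available set tests
#' @return character vector of registered test names.
#' @export
list_set_tests <- function() sort(ls(set_test_registry))

get_set_test <- function(name) {
  if (!exists(name, envir = set_test_registry, inherits = FALSE))
    stop("unknown set test '", name, "'; available: ",
         paste(list_set_tests(), collapse = ", "))
  get(name, envir = set_test_registry, inherits = FALSE)
}

# built-in tests share the precomputed environment `env`
register_builtin_tests <- function() {
  register_set_test("ks", function(env, set, mirna_id)
    ks_set_test(env$ranks, set, mirna_id), complementary = FALSE)
  register_set_test("wilcoxon", function(env, set, mirna_id)
    wilcoxon_set_test(env$ranks, set, mirna_id), complementary = TRUE)
  register_set_test("fisher-exact", function(env, set, mirna_id)
    fisher_exact_set_test(env$mrna_stats, set, env$tau, mirna_id),
    complementary = FALSE)
  register_set_test("globalq", function(env, set, mirna_id)
    globalq_set_test(env$mrna, env$design, set, env$n_perm, mirna_id),
    complementary = FALSE)
  register_set_test("roast", function(env, set, mirna_id)
    roast_set_test(env$rotation_ctx, set, env$n_rot, mirna_id),
    complementary = TRUE)
  register_set_test("romer", function(env, set, mirna_id) {
    res <- romer_set_test(env$rotation_ctx,
                          stats::setNames(list(set), mirna_id), env$n_rot)
    res$mirna <- mirna_id
    res
  }, complementary = TRUE)
}
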