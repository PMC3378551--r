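#' Configuration of the synthetic miRNA/mRNA co-expression study
#'
#' Defaults define the study conditions used throughout: 10 samples per
#' group, 200 miRNAs, 2000 mRNAs, 10% DE miRNAs and 5% DE mRNAs (half up,
#' half down at log fold change delta), lognormal baseline means, unit-scale
#' covariance of block / AR(1) / unstructured type, a linear miRNA-on-target
#' degradation effect of strength beta with per-miRNA modification factors
#' c_i ~ N(1, 0.1), and target sets of 5-15 genes that either partition the
#' mRNAs (disjoint) or form a circular chain sharing half their members
#' (overlapping).
#'
#' @param n_per_group samples per group.
#' @param p_mir,p_mrna numbers of miRNA and mRNA features.
#' @param cov_type covariance structure: `"block"`, `"ar1"` or
#'   `"unstructured"`.
#' @param rho within-block / AR(1) correlation.
#' @param block_size features per block (block covariance).
#' @param wishart_df_offset Wishart df = dim + offset (unstructured).
#' @param sigma_sq marginal feature variance.
#' @param meanlog,sdlog lognormal parameters of the baseline mean vectors.
#' @param de_prop_mir,de_prop_mrna proportions of DE features.
#' @param delta_grid log fold changes to scan.
#' @param beta strength of the miRNA-on-target mean modification.
#' @param factor_mean,factor_sd distribution of the per-miRNA modification
#'   factors c_i.
#' @param overlap `"disjoint"` or `"overlapping"` target sets.
#' @param overlap_fraction fraction of each set shared with the next set in
#'   overlapping mode.
#' @param set_size_range integer range of target-set sizes.
#' @param n_runs simulation runs per delta.
#' @param alpha BH selection level.
#' @param n_rot,n_perm resampling sizes for rotation / permutation tests.
#' @param tau DE-call threshold of the Fisher-exact set test.
#' @param seed optional integer seed.
#' @return classed list `"sim_config"`.
#' @export
simulation_config <- function(n_per_group = 10, p_mir = 200, p_mrna = 2000,
                              cov_type = c("block", "ar1", "unstructured"),
                              rho = 0.5, block_size = 10,
                              wishart_df_offset = 10, sigma_sq = 1,
                              meanlog = 2, sdlog = 0.5,
                              de_prop_mir = 0.10, de_prop_mrna = 0.05,
                              delta_grid = 0:6, beta = 0.5,
                              factor_mean = 1, factor_sd = 0.1,
                              overlap = c("disjoint", "overlapping"),
                              overlap_fraction = 0.5,
                              set_size_range = c(5, 15),
                              n_runs = 100, alpha = 0.05,
                              n_rot = 1000, n_perm = 1000, tau = 0.05,
                              seed = NULL) {
  cov_type <- match.arg(cov_type)
  overlap <- match.arg(overlap)
  stopifnot(n_per_group >= 2, p_mir >= 1, p_mrna >= 2,
            de_prop_mir >= 0, de_prop_mir <= 1,
            de_prop_mrna >= 0, de_prop_mrna <= 1,
            all(delta_grid >= 0), beta >= 0, rho >= 0, rho < 1,
            overlap_fraction >= 0, overlap_fraction <= 1,
            length(set_size_range) == 2,
            set_size_range[1] >= 2, diff(set_size_range) >= 0,
            alpha > 0, alpha < 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Build a covariance matrix of the configured structure
#'
#' @param cov_type `"ar1"` (entry sigma_sq * rho^|i-j|), `"block"`
#'   (block-diagonal equicorrelation) or `"unstructured"` (Wishart-based
#'   random correlation scaled to unit diagonal).
#' @param dim matrix dimension.
#' @param rho correlation parameter (ar1/block), in [0, 1).
#' @param block_size block size (block type).
#' @param sigma_sq marginal variance.
#' @param wishart_df Wishart degrees of freedom (unstructured; must be
#'   >= dim for positive definiteness). Default dim + 10.
#' @return symmetric positive-definite dim x dim matrix.
#' @export
make_covariance <- function(cov_type = c("block", "ar1", "unstructured"),
                            dim, rho = 0.5, block_size = 10, sigma_sq = 1,
                            wishart_df = dim + 10) {
  cov_type <- match.arg(cov_type)
  if (cov_type != "unstructured" && (rho < 0 || rho >= 1))
    stop("rho must be in [0, 1) for a positive-definite matrix")
  corr <- switch(cov_type,
    ar1 = rho^abs(outer(seq_len(dim), seq_len(dim), "-")),
    block = {
      blk <- rep(seq_len(ceiling(dim / block_size)),
                 each = block_size)[seq_len(dim)]
      same <- outer(blk, blk, "==")
      ifelse(same, rho, 0) + diag(1 - rho, dim)
    },
    unstructured = {
      if (wishart_df < dim) stop("wishart_df must be at least dim")
      g <- matrix(stats::rnorm(wishart_df * dim), wishart_df, dim)
      w <- crossprod(g)
      d <- 1 / sqrt(diag(w))
      w * tcrossprod(d)
    })
  sigma_sq * corr
}

# sampler closure drawing p x n matrices ~ MVN(mu, Sigma) without forming
# Sigma when the structure allows it
make_sampler <- function(config, dim) {
  rho <- config$rho
  switch(config$cov_type,
    ar1 = function(mu, n) {
      e <- matrix(stats::rnorm(dim * n), dim, n)
      x <- e
      if (dim > 1) {
        a <- sqrt(1 - rho^2)
        for (t in 2:dim) x[t, ] <- rho * x[t - 1, ] + a * e[t, ]
      }
      sqrt(config$sigma_sq) * x + mu
    },
    block = function(mu, n) {
      blk <- rep(seq_len(ceiling(dim / config$block_size)),
                 each = config$block_size)[seq_len(dim)]
      z0 <- matrix(stats::rnorm(max(blk) * n), max(blk), n)
      e <- matrix(stats::rnorm(dim * n), dim, n)
      x <- sqrt(rho) * z0[blk, , drop = FALSE] + sqrt(1 - rho) * e
      sqrt(config$sigma_sq) * x + mu
    },
    unstructured = {
      sig <- make_covariance("unstructured", dim,
                             sigma_sq = config$sigma_sq,
                             wishart_df = dim + config$wishart_df_offset)
      cl <- chol(sig)
      function(mu, n) {
        crossprod(cl, matrix(stats::rnorm(dim * n), dim, n)) + mu
      }
    })
}

#' Draw a random allocation of target sets
#'
#' Disjoint mode partitions a random subset of the mRNAs (every mRNA in at
#' most one set); overlapping mode lays the sets along a circular chain in
#' which each set shares `round(overlap_fraction * size)` members with the
#' next, so sets of DE and non-DE miRNAs necessarily share genes.
#'
#' @param p_mir number of miRNAs (sets).
#' @param p_mrna size of the mRNA universe.
#' @param mode `"disjoint"` or `"overlapping"`.
#' @param set_size_range integer range to draw set sizes from (uniform).
#' @param overlap_fraction shared fraction in overlapping mode.
#' @param mir_ids,mrna_ids identifiers (defaults `mir...`/`gene...`).
#' @return a [target_sets()] object with one set per miRNA.
#' @export
make_allocation <- function(p_mir, p_mrna,
                            mode = c("disjoint", "overlapping"),
                            set_size_range = c(5, 15),
                            overlap_fraction = 0.5,
                            mir_ids = sprintf("mir%04d", seq_len(p_mir)),
                            mrna_ids = sprintf("gene%05d", seq_len(p_mrna))) {
  mode <- match.arg(mode)
  lo <- set_size_range[1]; hi <- set_size_range[2]
  if (lo < 2) stop("set sizes below 2 are not testable")
  if (mode == "disjoint" && p_mir * lo > p_mrna)
    stop("infeasible: ", p_mir, " disjoint sets of >= ", lo,
         " genes exceed the mRNA universe")
  draw_sizes <- function()
    lo + sample.int(hi - lo + 1, p_mir, replace = TRUE) - 1
  if (mode == "disjoint") {
    sizes <- draw_sizes()
    tries <- 0
    while (sum(sizes) > p_mrna) {
      tries <- tries + 1
      if (tries > 200) stop("infeasible: disjoint set sizes keep exceeding ",
                            "the mRNA universe")
      sizes <- draw_sizes()
    }
    pool <- sample.int(p_mrna, sum(sizes))
    ends <- cumsum(sizes)
    starts <- ends - sizes + 1
    sets <- lapply(seq_len(p_mir), function(k)
      mrna_ids[pool[starts[k]:ends[k]]])
  } else {
    sizes <- draw_sizes()
    shared <- pmin(round(overlap_fraction * sizes), sizes - 1)
    total <- sum(sizes - shared)
    if (total > p_mrna)
      stop("infeasible: overlapping chain needs ", total,
           " distinct genes but universe has ", p_mrna)
    pool <- sample.int(p_mrna, total)
    starts <- cumsum(c(0, (sizes - shared)[-p_mir]))
    sets <- lapply(seq_len(p_mir), function(k) {
      idx <- (starts[k] + seq_len(sizes[k]) - 1) %% total + 1
      mrna_ids[pool[idx]]
    })
  }
  target_sets(stats::setNames(sets, mir_ids))
}

#' Inject differential expression into a mean vector
#'
#' Randomly selects `round(prop * length(mu))` features; half of them (up to
#' rounding) get `+delta` added to the group-2 mean, the other half
#' `-delta`. Group-1 means are untouched.
#'
#' @param mu baseline mean vector (shared by both groups before injection).
#' @param prop proportion of DE features.
#' @param delta log fold change (>= 0).
#' @return list: `mu1` (group-1 means), `mu2` (group-2 means), `sign`
#'   (integer vector: +1 up, -1 down, 0 not selected).
#' @export
inject_de <- function(mu, prop, delta) {
  stopifnot(delta >= 0, prop >= 0, prop <= 1)
  p <- length(mu)
  n_de <- round(prop * p)
  sgn <- integer(p)
  if (n_de > 0) {
    sel <- sample.int(p, n_de)
    n_up <- ceiling(n_de / 2)
    sgn[sel[seq_len(n_up)]] <- 1L
    if (n_de > n_up) sgn[sel[(n_up + 1):n_de]] <- -1L
  }
  list(mu1 = mu, mu2 = mu + sgn * delta, sign = sgn)
}

#' Apply the linear miRNA-on-target mean modification
#'
#' Models target degradation: the mean of mRNA j in group g becomes
#' mu_jg - beta * sum_i a_ij c_i mu_ig^mir, with one modification factor c_i
#' per miRNA shared across groups. Only differentially expressed miRNAs
#' (whose group means differ) therefore induce a group effect in their
#' targets. Modified means are floored at a small positive constant.
#'
#' @param mrna_means list with group mean vectors `mu1`, `mu2` (named by
#'   mRNA id or aligned with `mrna_ids`).
#' @param mir_means list with miRNA group mean vectors `mu1`, `mu2`.
#' @param sets a [target_sets()] allocation (miRNA -> target mRNA ids).
#' @param beta modification strength (>= 0).
#' @param factors per-miRNA modification factors c_i (named by miRNA id);
#'   drawn N(factor_mean, factor_sd) by the caller.
#' @param mrna_ids identifiers aligning the mean vectors.
#' @param floor lower bound for modified means (default 0.1).
#' @return list with modified `mu1`, `mu2`.
#' @export
apply_mirna_effect <- function(mrna_means, mir_means, sets, beta, factors,
                               mrna_ids, floor = 0.1) {
  stopifnot(beta >= 0)
  adjust <- function(mu_mrna, mu_mir) {
    delta <- numeric(length(mu_mrna))
    for (i in seq_along(sets)) {
      j <- match(sets[[i]], mrna_ids)
      delta[j] <- delta[j] + factors[[names(sets)[i]]] * mu_mir[i]
    }
    pmax(mu_mrna - beta * delta, floor)
  }
  list(mu1 = adjust(mrna_means$mu1, mir_means$mu1),
       mu2 = adjust(mrna_means$mu2, mir_means$mu2))
}

#' Draw one synthetic miRNA/mRNA dataset
#'
#' Baseline means are lognormal; DE injection shifts the group-2 means of
#' the selected features by +/- delta; the miRNA effect modifies the mRNA
#' means in both groups; expression is then drawn per group from a
#' multivariate normal with the configured covariance structure.
#'
#' @param config a [simulation_config()].
#' @param delta log fold change for this draw (defaults to the first entry
#'   of the config grid).
#' @param samplers optional precomputed list with elements `mir`, `mrna`
#'   (from repeated calls this avoids re-deriving the unstructured
#'   covariance factor).
#' @param allocation optional fixed [target_sets()] allocation.
#' @return list: `mirna`, `mrna` (expression matrices), `design`
#'   ([group_design()]), `sets`, `truth` (list `de_mir`, `de_mrna` signed
#'   indicator vectors, `alloc`).
#' @export
draw_dataset <- function(config, delta = config$delta_grid[1],
                         samplers = NULL, allocation = NULL) {
  if (is.null(samplers))
    samplers <- list(mir = make_sampler(config, config$p_mir),
                     mrna = make_sampler(config, config$p_mrna))
  mir_ids <- sprintf("mir%04d", seq_len(config$p_mir))
  mrna_ids <- sprintf("gene%05d", seq_len(config$p_mrna))
  sets <- if (is.null(allocation)) {
    make_allocation(config$p_mir, config$p_mrna, config$overlap,
                    config$set_size_range, config$overlap_fraction,
                    mir_ids, mrna_ids)
  } else allocation

  mir_base <- stats::rlnorm(config$p_mir, config$meanlog, config$sdlog)
  mrna_base <- stats::rlnorm(config$p_mrna, config$meanlog, config$sdlog)
  mir_de <- inject_de(mir_base, config$de_prop_mir, delta)
  mrna_de <- inject_de(mrna_base, config$de_prop_mrna, delta)
  factors <- stats::setNames(
    stats::rnorm(config$p_mir, config$factor_mean, config$factor_sd),
    mir_ids)
  mrna_means <- apply_mirna_effect(mrna_de, mir_de, sets, config$beta,
                                   factors, mrna_ids)

  n <- config$n_per_group
  mirna <- cbind(samplers$mir(mir_de$mu1, n), samplers$mir(mir_de$mu2, n))
  mrna <- cbind(samplers$mrna(mrna_means$mu1, n),
                samplers$mrna(mrna_means$mu2, n))
  sample_ids <- sprintf("s%02d", seq_len(2 * n))
  design <- group_design(stats::setNames(rep(c("1", "2"), each = n),
                                         sample_ids))
  list(mirna = expression_matrix(mirna, mir_ids, sample_ids),
       mrna = expression_matrix(mrna, mrna_ids, sample_ids),
       design = design, sets = sets,
       truth = list(de_mir = stats::setNames(mir_de$sign, mir_ids),
                    de_mrna = stats::setNames(mrna_de$sign, mrna_ids),
                    alloc = sets))
}

#' Realized false-discovery proportion and power of one selection
#'
#' @param selection character vector of selected miRNA ids.
#' @param truth truth component of [draw_dataset()] (uses `de_mir`).
#' @return list `fdp` (FP / max(1, detections), so 0/0 := 0) and `apr`
#'   (TP / number of truly DE miRNAs).
#' @export
evaluate_run <- function(selection, truth) {
  de <- names(truth$de_mir)[truth$de_mir != 0]
  tp <- sum(selection %in% de)
  fp <- length(selection) - tp
  list(fdp = fp / max(1, length(selection)),
       apr = if (length(de) > 0) tp / length(de) else 0)
}

# selection for one method given the per-run shared computations
select_method <- function(method, shared, config) {
  alpha <- config$alpha
  if (method == "mirna_only") {
    sel <- shared$mir_stats$feature[bh_adjust(shared$mir_stats$p_two) <= alpha]
    return(sel)
  }
  parts <- strsplit(method, ":", fixed = TRUE)[[1]]
  flavor <- parts[1]; test_name <- parts[2]
  res <- shared$set_results[[test_name]]
  if (flavor == "set_only") {
    q <- pmin(1, 2 * pmin(res$p_set_up, res$p_set_down))
    return(res$mirna[bh_adjust(q) <= alpha])
  }
  if (flavor == "combined") {
    idx <- match(res$mirna, shared$mir_stats$feature)
    cmb <- combine_directions(shared$mir_stats$p_up[idx],
                              shared$mir_stats$p_down[idx],
                              res$p_set_up, res$p_set_down,
                              choose_combiner(test_name))
    return(res$mirna[bh_adjust(cmb$score) <= alpha])
  }
  stop("unknown method '", method, "'; use mirna_only, set_only:<test> or ",
       "combined:<test>")
}

run_one <- function(config, delta, samplers, test_names) {
  ds <- draw_dataset(config, delta, samplers)
  mir_stats <- feature_test(ds$mirna, ds$design)
  mrna_stats <- feature_test(ds$mrna, ds$design)
  env <- list(mrna = ds$mrna, design = ds$design, mrna_stats = mrna_stats,
              ranks = rank_by_direction(mrna_stats),
              tau = config$tau, n_rot = config$n_rot, n_perm = config$n_perm)
  need_rot <- any(test_names %in% c("roast", "romer"))
  ctx <- if (need_rot)
    rotation_context(ds$mrna, ds$design, attr(mrna_stats, "hyper")) else NULL
  env$rotation_ctx <- ctx
  set_results <- list()
  rot_tests <- intersect(test_names, c("roast", "romer"))
  if (length(rot_tests) > 0) {
    rr <- rotation_tests_all(ctx, ds$sets, config$n_rot, which = rot_tests)
    set_results[rot_tests] <- rr[rot_tests]
  }
  rank_tests <- intersect(test_names, c("ks", "wilcoxon", "fisher-exact"))
  if (length(rank_tests) > 0) {
    rr <- rank_tests_all(env, ds$sets, which = rank_tests)
    set_results[rank_tests] <- rr[rank_tests]
  }
  for (tn in setdiff(test_names, c(rot_tests, rank_tests))) {
    test <- get_set_test(tn)
    set_results[[tn]] <- do.call(rbind, lapply(names(ds$sets), function(id)
      test$fun(env, ds$sets[[id]], id)))
  }
  list(mir_stats = mir_stats, set_results = set_results, truth = ds$truth)
}

#' Run the simulation study
#'
#' Loops `n_runs` datasets per delta; in each run, every requested method is
#' evaluated on the same dataset (paired comparison), selections are made by
#' BH at the configured level, and realized FDP/APR recorded.
#'
#' @param config a [simulation_config()].
#' @param methods character vector drawn from `"mirna_only"`,
#'   `"set_only:<test>"`, `"combined:<test>"` with `<test>` a registered set
#'   test.
#' @param progress optional function(delta, run) called after each run (used
#'   by the CLI for progress logging and partial flushing).
#' @return list of class `"sim_metrics"`: `long` (data.frame method, delta,
#'   fdr, apr, se_fdr, n_runs), `per_run` (data.frame with per-run fdp/apr),
#'   `config`, `methods`.
#' @export
run_study <- function(config, methods = c("mirna_only", "combined:wilcoxon"),
                      progress = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  test_names <- unique(stats::na.omit(vapply(strsplit(methods, ":"),
                                             function(p) p[2], character(1))))
  for (tn in test_names) get_set_test(tn)  # fail fast on unknown tests
  samplers <- list(mir = make_sampler(config, config$p_mir),
                   mrna = make_sampler(config, config$p_mrna))
  rows <- vector("list", length(config$delta_grid) * config$n_runs *
                   length(methods))
  k <- 0
  for (delta in config$delta_grid) {
    for (run in seq_len(config$n_runs)) {
      shared <- run_one(config, delta, samplers, test_names)
      for (m in methods) {
        sel <- select_method(m, shared, config)
        ev <- evaluate_run(sel, shared$truth)
        k <- k + 1
        rows[[k]] <- data.frame(method = m, delta = delta, run = run,
                                fdp = ev$fdp, apr = ev$apr,
                                n_selected = length(sel),
                                stringsAsFactors = FALSE)
      }
      if (!is.null(progress)) progress(delta, run)
    }
  }
  per_run <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_run,
                                     per_run[c("method", "delta")],
                                     drop = TRUE), function(d) {
    data.frame(method = d$method[1], delta = d$delta[1],
               fdr = mean(d$fdp), apr = mean(d$apr),
               se_fdr = stats::sd(d$fdp) / sqrt(nrow(d)),
               n_runs = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg <- agg[order(agg$method, agg$delta), ]
  structure(list(long = agg, per_run = per_run, config = config,
                 methods = methods), class = "sim_metrics")
}

#' Min-median-max FDR summary across the delta grid
#'
#' The format used by the study's headline tables: for every method the
#' minimum, median and maximum of the per-delta mean FDR.
#'
#' @param metrics a [run_study()] result.
#' @return data.frame with method, fdr_min, fdr_median, fdr_max, apr_max.
#' @export
summarize_study <- function(metrics) {
  out <- do.call(rbind, lapply(split(metrics$long, metrics$long$method),
                               function(d) {
    data.frame(method = d$method[1],
               fdr_min = min(d$fdr), fdr_median = stats::median(d$fdr),
               fdr_max = max(d$fdr), apr_max = max(d$apr),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.sim_metrics <- function(x, ...) {
  cat("Simulation study:", length(unique(x$long$method)), "methods x",
      length(unique(x$long$delta)), "deltas,",
      x$config$n_runs, "runs each\n")
  print(summarize_study(x), ...)
  invisible(x)
}
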