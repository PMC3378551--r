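P_EPS <- 1e-300

clip_p <- function(p, lo = P_EPS, hi = 1) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-value outside [0,1]")
  pmin(pmax(p, lo), hi)
}

#' Which p-value combiner goes with which set test
#'
#' Stouffer's inverse-normal method requires the two directional set
#' p-values to sum to one (exactly for the Wilcoxon test, approximately for
#' the rotation tests); all other tests use Fisher's combination method.
#'
#' @param test_name a registered set-test name.
#' @return `"stouffer"` or `"fisher"`.
#' @export
choose_combiner <- function(test_name) {
  if (get_set_test(test_name)$complementary) "stouffer" else "fisher"
}

#' Fisher's combination of two p-values
#'
#' C = -2 (ln p_a + ln p_b) referred to the upper tail of the chi-square
#' distribution with four degrees of freedom. Zeros are clipped to 1e-300
#' before taking logs.
#'
#' @param p_a,p_b p-values in [0,1] (vectorized).
#' @return combined p-value(s).
#' @export
fisher_combine <- function(p_a, p_b) {
  p_a <- clip_p(p_a); p_b <- clip_p(p_b)
  stats::pchisq(-2 * (log(p_a) + log(p_b)), df = 4, lower.tail = FALSE)
}

#' Stouffer's inverse-normal combination of two p-values
#'
#' z = (qnorm(1-p_a) + qnorm(1-p_b)) / sqrt(2); returns 1 - pnorm(z).
#' Boundary values are clipped away from 0 and 1.
#'
#' @param p_a,p_b p-values in [0,1] (vectorized).
#' @return combined p-value(s).
#' @export
stouffer_combine <- function(p_a, p_b) {
  p_a <- clip_p(p_a, P_EPS, 1 - 1e-16)
  p_b <- clip_p(p_b, P_EPS, 1 - 1e-16)
  z <- (stats::qnorm(p_a, lower.tail = FALSE) +
        stats::qnorm(p_b, lower.tail = FALSE)) / sqrt(2)
  stats::pnorm(z, lower.tail = FALSE)
}

#' Combine miRNA and target-set directional p-values into a score
#'
#' A miRNA and its target set are expected to move in opposite directions, so
#' the miRNA's up-p is combined with the set's down-p (and vice versa). The
#' final score is q = min(1, 2 min(p_comb_up, p_comb_down)), a two-sided
#' summary of the more extreme pairing. With the Stouffer branch and
#' complementary inputs it behaves like a genuine two-sided p-value; with
#' rotation-based set tests it is slightly conservative.
#'
#' @param p_mir_up,p_mir_down miRNA one-sided p-values.
#' @param p_set_up,p_set_down set-level directional p-values.
#' @param method `"fisher"` or `"stouffer"`.
#' @return data.frame with `p_comb_up`, `p_comb_down`, `score`, `method`
#'   (vectorized over the inputs).
#' @export
combine_directions <- function(p_mir_up, p_mir_down, p_set_up, p_set_down,
                               method = c("stouffer", "fisher")) {
  method <- match.arg(method)
  comb <- if (method == "fisher") fisher_combine else stouffer_combine
  p_comb_up <- comb(p_mir_up, p_set_down)
  p_comb_down <- comb(p_mir_down, p_set_up)
  data.frame(p_comb_up = p_comb_up, p_comb_down = p_comb_down,
             score = pmin(1, 2 * pmin(p_comb_up, p_comb_down)),
             method = method, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param scores vector of scores/p-values in [0,1].
#' @return adjusted values in the input order.
#' @export
bh_adjust <- function(scores) {
  if (any(scores < 0 | scores > 1, na.rm = TRUE))
    stop("scores outside [0,1]")
  stats::p.adjust(scores, method = "BH")
}

#' Run the full miRNA + target-set combined testing pipeline
#'
#' Feature-wise moderated testing of both matrices (variance priors
#' estimated separately per platform), one-sided set testing of every
#' miRNA's target set, opposite-direction p-value combination, and BH
#' adjustment of the scores. miRNAs without a testable target set (absent
#' from `sets` or too small after intersection with the measured mRNAs) are
#' kept with their miRNA-only two-sided p-value as score and flagged.
#'
#' @param mirna,mrna log-expression matrices.
#' @param design a [group_design()] covering the columns of both matrices.
#' @param sets a [target_sets()] object (miRNA id -> target mRNA ids).
#' @param set_test registered set-test name (default `"romer"`; `"wilcoxon"`
#'   is the fast recommended alternative).
#' @param n_rot rotations for the rotation tests (default 1000).
#' @param n_perm permutations for the global Q test (default 1000).
#' @param tau DE-call threshold for the Fisher-exact enrichment test.
#' @param min_set_size smallest usable target set (default 2).
#' @param seed integer seed controlling rotation/permutation draws.
#' @return data.frame, one row per miRNA measured in `mirna`: set_size,
#'   the four directional p-values, combined p-values, `score`, `score_adj`,
#'   `method`, and `flag` (`"ok"` or `"no_set"`).
#' @export
run_pipeline <- function(mirna, mrna, design, sets,
                         set_test = "romer", n_rot = 1000, n_perm = 1000,
                         tau = 0.05, min_set_size = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  test <- get_set_test(set_test)
  mir_stats <- feature_test(mirna, design)
  mrna_stats <- feature_test(mrna, design)
  sets <- tryCatch(intersect_universe(sets, mrna, min_set_size),
                   error = function(e) target_sets(list()))
  testable <- intersect(mir_stats$feature, names(sets))

  env <- list(mrna = mrna, design = design, mrna_stats = mrna_stats,
              ranks = rank_by_direction(mrna_stats),
              rotation_ctx = if (set_test %in% c("roast", "romer"))
                rotation_context(mrna, design,
                                 hyper = attr(mrna_stats, "hyper")) else NULL,
              tau = tau, n_rot = n_rot, n_perm = n_perm)

  set_res <- if (length(testable) > 0) {
    do.call(rbind, lapply(testable, function(id)
      test$fun(env, sets[[id]], id)))
  } else {
    data.frame(mirna = character(), test = character(), set_size = integer(),
               p_set_up = numeric(), p_set_down = numeric(),
               complementary = logical())
  }

  idx <- match(mir_stats$feature, set_res$mirna)
  has_set <- !is.na(idx)
  out <- data.frame(mirna = mir_stats$feature,
                    set_size = ifelse(has_set, set_res$set_size[idx], 0L),
                    p_mir_up = mir_stats$p_up, p_mir_down = mir_stats$p_down,
                    p_set_up = set_res$p_set_up[idx],
                    p_set_down = set_res$p_set_down[idx],
                    stringsAsFactors = FALSE)
  method <- choose_combiner(set_test)
  cmb <- combine_directions(out$p_mir_up[has_set], out$p_mir_down[has_set],
                            out$p_set_up[has_set], out$p_set_down[has_set],
                            method)
  out$p_comb_up <- NA_real_
  out$p_comb_down <- NA_real_
  out$score <- NA_real_
  out$p_comb_up[has_set] <- cmb$p_comb_up
  out$p_comb_down[has_set] <- cmb$p_comb_down
  out$score[has_set] <- cmb$score
  out$score[!has_set] <- mir_stats$p_two[!has_set]  # miRNA-only fallback
  out$score_adj <- bh_adjust(out$score)
  out$method <- ifelse(has_set, method, "mirna-only")
  out$flag <- ifelse(has_set, "ok", "no_set")
  attr(out, "set_test") <- set_test
  out
}

#' Write a combined-results table as TSV
#'
#' @param results a [run_pipeline()] result.
#' @param path output path.
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
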