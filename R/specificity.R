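#' Midrank transform of the two motif-frequency samples
#'
#' The positive- and negative-pool frequency vectors are pooled, sorted
#' ascending, and ranked with tied values receiving the average of their
#' positions; the ranks are then split back into the two samples. The rank
#' transform makes the downstream Welch t-test robust to the non-normality
#' of motif-frequency distributions while the Welch form handles unequal
#' variances.
#'
#' @param freq_pos,freq_neg Equal-length numeric vectors (length >= 2).
#' @return A `ranked_samples` object: ranks, means, standard deviations
#'   (n-1 denominator), and sizes of both samples.
#' @export
rank_transform <- function(freq_pos, freq_neg) {
  n_p <- length(freq_pos)
  n_n <- length(freq_neg)
  if (n_p != n_n) stop("the two samples must have equal length")
  if (n_p < 2) stop("need at least 2 motifs per sample")
  r <- rank(c(freq_pos, freq_neg), ties.method = "average")
  ranks_pos <- r[seq_len(n_p)]
  ranks_neg <- r[n_p + seq_len(n_n)]
  structure(
    list(
      ranks_pos = ranks_pos, ranks_neg = ranks_neg,
      mean_pos = mean(ranks_pos), mean_neg = mean(ranks_neg),
      sd_pos = stats::sd(ranks_pos), sd_neg = stats::sd(ranks_neg),
      n_pos = n_p, n_neg = n_n
    ),
    class = "ranked_samples"
  )
}

#' Welch t statistic on ranked samples
#'
#' \eqn{t = (\bar x_P - \bar x_N) / \sqrt{s_P^2/n_P + s_N^2/n_N}}.
#' Undefined (`NA`) when both sample variances are zero.
#'
#' @param samples A `ranked_samples`.
#' @return The t score.
#' @export
welch_t <- function(samples) {
  se2 <- samples$sd_pos^2 / samples$n_pos + samples$sd_neg^2 / samples$n_neg
  if (se2 <= 0) return(NA_real_)
  (samples$mean_pos - samples$mean_neg) / sqrt(se2)
}

#' Welch-Satterthwaite degrees of freedom
#'
#' \eqn{f = (s_P^2/n_P + s_N^2/n_N)^2 /
#'   [(s_P^2/n_P)^2/(n_P-1) + (s_N^2/n_N)^2/(n_N-1)]}.
#' With equal sizes and variances this reduces to `2 * (n - 1)`; with one
#' variance zero, to `n - 1` of the varying sample.
#'
#' @param samples A `ranked_samples`.
#' @return Degrees of freedom, or `NA` when both variances are zero.
#' @export
welch_df <- function(samples) {
  a <- samples$sd_pos^2 / samples$n_pos
  b <- samples$sd_neg^2 / samples$n_neg
  if (a + b <= 0) return(NA_real_)
  (a + b)^2 / (a^2 / (samples$n_pos - 1) + b^2 / (samples$n_neg - 1))
}

#' Upper-tail Student-t probability with a log-space companion
#'
#' Computes \eqn{p = P(T_f \ge t)}, the probability that a Student-t
#' variate with `f` degrees of freedom is at least the observed score: a
#' larger positive separation of the positive over the negative sample
#' yields a smaller p. Published scores reach p values near the smallest
#' representable double (order 1e-303), so the base-10 log of p is
#' computed in log space and stays finite and accurate even where `p`
#' itself underflows; `log10_p` is the authoritative quantity for
#' thresholding.
#'
#' @param t t score.
#' @param f Degrees of freedom (> 0).
#' @return List with `p` and `log10_p`.
#' @export
t_tail_p <- function(t, f) {
  if (!is.finite(t)) stop("non-finite t")
  stopifnot(f > 0)
  list(
    p = stats::pt(t, df = f, lower.tail = FALSE),
    log10_p = stats::pt(t, df = f, lower.tail = FALSE, log.p = TRUE) / log(10)
  )
}

#' Cohen's d effect size on ranked samples
#'
#' Standardized mean difference with the pooled standard deviation
#' \eqn{\sqrt{[(n_P-1)s_P^2 + (n_N-1)s_N^2] / (n_P+n_N-2)}}, computed on
#' the same rank-transformed samples as the t score. A "huge" effect
#' (d > 2) is required alongside the p-value cut-off for a specificity
#' call.
#'
#' @param samples A `ranked_samples`.
#' @return Cohen's d, or `NA` when the pooled variance is zero.
#' @export
cohens_d <- function(samples) {
  pooled_var <- ((samples$n_pos - 1) * samples$sd_pos^2 +
    (samples$n_neg - 1) * samples$sd_neg^2) /
    (samples$n_pos + samples$n_neg - 2)
  if (pooled_var <= 0) return(NA_real_)
  (samples$mean_pos - samples$mean_neg) / sqrt(pooled_var)
}

#' Score one candidate clone's specificity
#'
#' Composes the full motif route: enumerate the candidate's admissible
#' consensus motifs in the positive pool, compute each motif's unique-
#' sequence frequency in both pools, rank-transform the two frequency
#' samples, and derive the Welch t score, Welch-Satterthwaite degrees of
#' freedom, upper-tail p value (with log10 companion) and Cohen's d. The
#' clone is called `specific` when `log10_p < log10(p_cut)` and
#' `d > d_cut`. Candidates with no admissible motifs, or with zero rank
#' variance, are reported unscorable rather than given a p value.
#'
#' @param paratope Named list or one-row data frame with `l3`, `h1`, `h2`,
#'   `h3`.
#' @param pos_pool,neg_pool `selection_pool`s (ignored when both indices
#'   are supplied).
#' @param constraints A [motif_constraints()].
#' @param p_cut,d_cut Decision thresholds (defaults 1e-10 and 2).
#' @param index_pos,index_neg Optional pre-built [build_index()] results,
#'   to amortize indexing over many candidates.
#' @return A `specificity_score` object; see [tidy.specificity_score()]
#'   and [glance.specificity_score()].
#' @export
score_candidate <- function(paratope, pos_pool = NULL, neg_pool = NULL,
                            constraints = motif_constraints(),
                            p_cut = 1e-10, d_cut = 2,
                            index_pos = NULL, index_neg = NULL) {
  index_pos <- index_pos %||% build_index(pos_pool)
  index_neg <- index_neg %||% build_index(neg_pool)
  profile <- candidate_motif_profile(paratope, index_pos, index_neg, constraints)
  out <- list(
    paratope = tibble::as_tibble(paratope[c("l3", "h1", "h2", "h3")]),
    profile = profile,
    n_motifs = nrow(profile),
    t = NA_real_, f = NA_real_, p = NA_real_, log10_p = NA_real_,
    d = NA_real_, specific = FALSE, unscorable = TRUE,
    p_cut = p_cut, d_cut = d_cut
  )
  if (nrow(profile) >= 2) {
    samples <- rank_transform(profile$freq_pos, profile$freq_neg)
    t <- welch_t(samples)
    if (!is.na(t)) {
      f <- welch_df(samples)
      tail <- t_tail_p(t, f)
      out$t <- t
      out$f <- f
      out$p <- tail$p
      out$log10_p <- tail$log10_p
      out$d <- cohens_d(samples)
      out$unscorable <- FALSE
      out$specific <- is.finite(out$log10_p) && is.finite(out$d) &&
        out$log10_p < log10(p_cut) && out$d > d_cut
    }
  }
  structure(out, class = "specificity_score")
}

#' @export
print.specificity_score <- function(x, ...) {
  cat("<specificity_score>", paste0(
    x$paratope$l3, "/", x$paratope$h1, "/", x$paratope$h2, "/", x$paratope$h3
  ), "\n")
  if (x$unscorable) {
    cat("  unscorable (", x$n_motifs, "admissible motifs )\n")
  } else {
    cat(sprintf(
      "  motifs %d | t = %.3f, f = %.1f, log10 p = %.2f, d = %.2f | %s\n",
      x$n_motifs, x$t, x$f, x$log10_p, x$d,
      if (x$specific) "SPECIFIC" else "not specific"
    ))
  }
  invisible(x)
}

#' Tidiers for specificity scores
#'
#' `tidy()` returns the motif-level profile (one row per admissible motif
#' with frequencies in both pools); `glance()` returns a one-row summary
#' with the test statistics and decision.
#'
#' @param x A `specificity_score`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.specificity_score <- function(x, ...) x$profile

#' @rdname tidy.specificity_score
#' @exportS3Method generics::glance
glance.specificity_score <- function(x, ...) {
  tibble::tibble(
    n_motifs = x$n_motifs, t = x$t, f = x$f,
    p = x$p, log10_p = x$log10_p, d = x$d,
    specific = x$specific, unscorable = x$unscorable
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Score candidate clones of a positive pool against the negative pool
#'
#' Runs [score_candidate()] over a set of candidates (default: every clone
#' in the positive pool) and returns a clone-level report mirroring
#' published summary tables: counts and frequencies in both pools, the
#' log10 positive/negative fold change, the motif-test statistics, and the
#' specificity call. Clones absent from the negative pool have infinite
#' fold ratio; for the log10 column their negative frequency is floored at
#' one read over the negative pool total and flagged `fc_floored`.
#'
#' @inheritParams score_candidate
#' @param candidates Data frame of paratopes to score (columns `l3`, `h1`,
#'   `h2`, `h3`); default all clones in `pos_pool`.
#' @return A tibble, one row per candidate.
#' @export
score_pool <- function(pos_pool, neg_pool, candidates = NULL,
                       constraints = motif_constraints(),
                       p_cut = 1e-10, d_cut = 2) {
  candidates <- tibble::as_tibble(candidates %||% pos_pool)
  index_pos <- build_index(pos_pool)
  index_neg <- build_index(neg_pool)
  pos_tab <- tibble::as_tibble(pos_pool)
  neg_tab <- tibble::as_tibble(neg_pool)
  key <- c("l3", "h1", "h2", "h3")
  base <- candidates[key] |>
    dplyr::left_join(dplyr::rename(pos_tab, count_pos = "count"), by = key) |>
    dplyr::left_join(dplyr::rename(neg_tab, count_neg = "count"), by = key) |>
    dplyr::mutate(
      count_pos = dplyr::coalesce(.data$count_pos, 0),
      count_neg = dplyr::coalesce(.data$count_neg, 0),
      freq_pos = .data$count_pos / pool_total_reads(pos_pool),
      freq_neg = .data$count_neg / pool_total_reads(neg_pool),
      fold_ratio = dplyr::if_else(
        .data$count_neg == 0, Inf, .data$freq_pos / .data$freq_neg
      ),
      fc_floored = .data$count_neg == 0,
      log10_fc = log10(.data$freq_pos /
        pmax(.data$freq_neg, 1 / pool_total_reads(neg_pool)))
    )
  scores <- purrr::map(seq_len(nrow(base)), function(i) {
    glance(score_candidate(
      base[i, key],
      constraints = constraints, p_cut = p_cut, d_cut = d_cut,
      index_pos = index_pos, index_neg = index_neg
    ))
  })
  dplyr::bind_cols(base, dplyr::bind_rows(scores))
}

#' Enrichment-ranking baseline: the count/fold-change quadrant
#'
#' The conventional NGS ranking selects clones occurring more than
#' `min_count` times in the positive pool and more than `min_fold`-fold
#' enriched in positive over negative frequency (both strict). Clones
#' absent from the negative pool have infinite ratio and satisfy any fold
#' threshold. The full scatter table behind the enrichment plot is
#' returned, with `in_quadrant` marking the selected clones.
#'
#' @param pos_pool,neg_pool `selection_pool`s.
#' @param min_count,min_fold Quadrant thresholds (defaults 200 and 4).
#' @return An `enrichment_table` tibble: `l3`, `h1`, `h2`, `h3`,
#'   `count_pos`, `count_neg`, `fold_ratio`, `in_quadrant`.
#' @export
enrichment_quadrant <- function(pos_pool, neg_pool, min_count = 200, min_fold = 4) {
  key <- c("l3", "h1", "h2", "h3")
  tab <- tibble::as_tibble(pos_pool) |>
    dplyr::rename(count_pos = "count") |>
    dplyr::left_join(
      dplyr::rename(tibble::as_tibble(neg_pool), count_neg = "count"),
      by = key
    ) |>
    dplyr::mutate(
      count_neg = dplyr::coalesce(.data$count_neg, 0),
      fold_ratio = dplyr::if_else(
        .data$count_neg == 0, Inf,
        (.data$count_pos / pool_total_reads(pos_pool)) /
          (.data$count_neg / pool_total_reads(neg_pool))
      ),
      in_quadrant = .data$count_pos > min_count & .data$fold_ratio > min_fold
    ) |>
    dplyr::arrange(dplyr::desc(.data$count_pos))
  structure(tab, class = c("enrichment_table", class(tibble::tibble())),
    min_count = min_count, min_fold = min_fold
  )
}

#' Cluster clones into homolog families by L3+H3 identity
#'
#' Single-linkage clustering on pairwise sequence identity of the
#' concatenated L3 and H3 strings, with identity defined as
#' `1 - edit_distance / max(length)` (lengths may differ, so the
#' normalized edit distance stands in for an alignment rule). Clones join
#' a family when identity meets the threshold. Family ids are deterministic:
#' family 1 holds the clone with the largest positive count, and so on.
#'
#' @param clones Data frame with `l3`, `h3` (and optionally `count_pos` or
#'   `count`, used to order families).
#' @param identity_threshold In (0, 1]; default 0.80.
#' @return `clones` with an integer `family` column.
#' @export
cluster_families <- function(clones, identity_threshold = 0.80) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  clones <- tibble::as_tibble(clones)
  n <- nrow(clones)
  if (n == 0) return(dplyr::mutate(clones, family = integer(0)))
  s <- paste0(clones$l3, clones$h3)
  d <- utils::adist(s)
  maxlen <- outer(nchar(s), nchar(s), pmax)
  identity <- 1 - d / maxlen
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (identity[i, j] >= identity_threshold) {
        parent[find(i)] <- find(j)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  wt <- clones[["count_pos"]] %||% clones[["count"]] %||% rep(0, n)
  top <- tapply(wt, comp, max)
  ord <- order(-top, as.integer(names(top)))
  fam_id <- stats::setNames(seq_along(ord), names(top)[ord])
  dplyr::mutate(clones, family = as.integer(fam_id[as.character(comp)]))
}
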