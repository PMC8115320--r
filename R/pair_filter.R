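#' Maximum between-class inertia cutoff on a 1-D sample
#'
#' Splits the sorted values into a contiguous low class and high class at
#' the boundary maximizing the between-class inertia
#' \eqn{n_1 n_2 / (n_1+n_2) \cdot (\mu_1-\mu_2)^2}. By the Koenig-Huygens
#' decomposition total inertia = within + between, so this equivalently
#' minimizes within-class inertia (the two-class criterion familiar from
#' Otsu thresholding). The returned threshold is the arithmetic midpoint of
#' the adjacent values across the best split. Degenerate inputs (< 2 values,
#' or all values equal) admit no informative split and return `NA`.
#'
#' @param values Positive numbers (e.g. per-partner read counts).
#' @return The threshold, or `NA_real_` when no split exists. Ties in the
#'   criterion resolve to the lowest split point, keeping the result
#'   deterministic.
#' @export
kh_cutoff <- function(values) {
  if (length(values) == 0) stop("values must be non-empty")
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("values must be positive and finite")
  }
  n <- length(values)
  v <- sort(values)
  if (n < 2 || v[1] == v[n]) return(NA_real_)
  # Between-class inertia for every split after position k, via prefix sums.
  k <- seq_len(n - 1L)
  cs <- cumsum(v)
  tot <- cs[n]
  mu1 <- cs[k] / k
  mu2 <- (tot - cs[k]) / (n - k)
  between <- k * (n - k) / n * (mu1 - mu2)^2
  best <- which.max(between)
  (v[best] + v[best + 1L]) / 2
}

#' Filter PCR hybridization artifacts from a selection pool
#'
#' PCR template switching at the fixed antibody framework creates chimeric
#' reads pairing the L3 of one clone with the H3 (and H1/H2) of another;
#' such amalgams surface as spurious novel clones. Because valid L3/H3
#' pairs are overrepresented relative to artifacts, the filter conditions
#' on each distinct H3, collects the observation counts of all its L3
#' partners, computes a per-H3 count cutoff by maximum between-class
#' inertia ([kh_cutoff()]), and removes every paratope whose L3 partner
#' count falls strictly below the cutoff. H3s with a single partner, or
#' with all partner counts equal, are kept whole (no evidence of
#' chimerism). The filter treats each pool independently.
#'
#' @param pool A `selection_pool`.
#' @param weight `"reads"` (default): an L3 partner's observation count is
#'   the summed read count of paratopes carrying that L3/H3 pair, since
#'   artifacts are read-level events. `"unique"`: count unique paratopes
#'   instead.
#' @param symmetric Also run the mirrored pass conditioning on L3 and
#'   scanning H3 partners (off by default).
#' @return The filtered `selection_pool`, with attribute `removed` holding
#'   the removed rows (also available via `pair_filter_report()`).
#' @export
filter_pairs <- function(pool, weight = c("reads", "unique"), symmetric = FALSE) {
  weight <- match.arg(weight)
  removed_all <- tibble::as_tibble(pool)[0, ]
  out <- pool
  passes <- if (symmetric) list(c("h3", "l3"), c("l3", "h3")) else list(c("h3", "l3"))
  for (p in passes) {
    res <- filter_pairs_once(out, cond = p[1], part = p[2], weight = weight)
    removed_all <- dplyr::bind_rows(removed_all, res$removed)
    out <- res$pool
  }
  attr(out, "removed") <- removed_all
  out
}

filter_pairs_once <- function(pool, cond, part, weight) {
  tab <- tibble::as_tibble(pool)
  if (nrow(tab) == 0) return(list(pool = pool, removed = tab))
  pairs <- tab |>
    dplyr::summarise(
      obs = if (weight == "reads") sum(.data$count) else dplyr::n(),
      .by = dplyr::all_of(c(cond, part))
    )
  split_obs <- split(pairs$obs, pairs[[cond]])
  cut <- vapply(split_obs, kh_cutoff_safe, numeric(1))
  pairs$cutoff <- cut[match(pairs[[cond]], names(cut))]
  pairs$drop <- !is.na(pairs$cutoff) & pairs$obs < pairs$cutoff
  tab <- dplyr::left_join(tab, pairs[c(cond, part, "drop")], by = c(cond, part))
  removed <- tab[tab$drop, setdiff(names(tab), "drop"), drop = FALSE]
  kept <- tab[!tab$drop, setdiff(names(tab), "drop"), drop = FALSE]
  list(pool = selection_pool(kept, pool_label(pool)), removed = removed)
}

kh_cutoff_safe <- function(v) if (length(v) < 2 || min(v) == max(v)) NA_real_ else kh_cutoff(v)

#' @rdname filter_pairs
#' @export
pair_filter_report <- function(pool) attr(pool, "removed")

#' Per-H3 partner distributions
#'
#' Diagnostic view of the pair filter: for each distinct H3 the observation
#' counts of its L3 partners and the computed inertia cutoff.
#'
#' @inheritParams filter_pairs
#' @return A tibble with columns `h3`, `l3`, `obs`, `cutoff`, `drop`.
#' @export
partner_distributions <- function(pool, weight = c("reads", "unique")) {
  weight <- match.arg(weight)
  pairs <- tibble::as_tibble(pool) |>
    dplyr::summarise(
      obs = if (weight == "reads") sum(.data$count) else dplyr::n(),
      .by = c("h3", "l3")
    )
  split_obs <- split(pairs$obs, pairs$h3)
  cut <- vapply(split_obs, kh_cutoff_safe, numeric(1))
  pairs$cutoff <- cut[match(pairs$h3, names(cut))]
  pairs$drop <- !is.na(pairs$cutoff) & pairs$obs < pairs$cutoff
  dplyr::arrange(pairs, .data$h3, dplyr::desc(.data$obs))
}
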