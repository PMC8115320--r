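#' Constraints on consensus-motif enumeration
#'
#' Consensus motifs are fixed-length patterns over amino-acid letters plus
#' the wildcard `X`. Three constraints keep the enumeration from exploding
#' while retaining informative patterns: a cap on the wildcard fraction
#' (default 55% of the motif length, floored, so a length-1 CDR admits no
#' wildcards); a floor on the number of unique positive-pool sequences
#' matching each motif (default 100); and the polymorphism rule that every
#' wildcard must match more than one distinct residue among the motif's
#' positive-pool matches (a wildcard that only ever matches one residue
#' carries no information beyond the fixed letter).
#'
#' @param max_wildcard_fraction In `[0, 1)`; default 0.55.
#' @param min_positive_support Minimum unique positive-pool sequences
#'   matching a motif; default 100.
#' @param require_polymorphic_wildcards Default `TRUE`.
#' @param cdrs_used CDRs whose motifs enter a candidate's profile. The
#'   default restricts profiles to L3 and H3, the loops that carry the
#'   library's sequence diversity (order 1e9 and 1e16 variants) and drive
#'   most antigen contacts: their motif frequencies directly reflect
#'   selection. The binary-degenerate H1/H2 loops (64 and 256 variants)
#'   are so common in any pool that their motifs track overall pool
#'   composition rather than clone-specific enrichment; including them
#'   (`cdrs_used = c("L3","H1","H2","H3")`) dilutes the separation signal
#'   of true binders and couples scores of unrelated clones to pool-level
#'   composition shifts.
#' @return A `motif_constraints` list.
#' @export
motif_constraints <- function(max_wildcard_fraction = 0.55,
                              min_positive_support = 100,
                              require_polymorphic_wildcards = TRUE,
                              cdrs_used = c("L3", "H3")) {
  stopifnot(
    max_wildcard_fraction >= 0, max_wildcard_fraction < 1,
    min_positive_support >= 1,
    all(cdrs_used %in% c("L3", "H1", "H2", "H3"))
  )
  structure(
    list(
      max_wildcard_fraction = max_wildcard_fraction,
      min_positive_support = min_positive_support,
      require_polymorphic_wildcards = require_polymorphic_wildcards,
      cdrs_used = cdrs_used
    ),
    class = "motif_constraints"
  )
}

#' Positional index over a pool's unique CDR sequences
#'
#' Pre-computes, per CDR and per observed loop length, the distinct CDR
#' strings, their multiplicity (how many unique paratopes carry each
#' string), and a position-by-position character matrix, so that a motif's
#' match set is the intersection of per-position residue lookups. Motif
#' frequencies are unique-sequence based: the index also records the total
#' number of unique paratopes in the pool, the denominator of every motif
#' frequency.
#'
#' @param pool A `selection_pool`.
#' @param cdrs CDRs to index (default all four).
#' @return A `pool_index`.
#' @export
build_index <- function(pool, cdrs = c("L3", "H1", "H2", "H3")) {
  tab <- tibble::as_tibble(pool)
  idx <- list()
  for (cdr in cdrs) {
    col <- tab[[tolower(cdr)]]
    agg <- tibble::tibble(seq = col) |>
      dplyr::count(.data$seq, name = "mult")
    lens <- nchar(agg$seq)
    idx[[cdr]] <- lapply(split(agg, lens), function(sub) {
      L <- nchar(sub$seq[1])
      list(
        strings = sub$seq,
        mult = sub$mult,
        mat = matrix(
          unlist(strsplit(sub$seq, "", fixed = TRUE), use.names = FALSE),
          nrow = nrow(sub), ncol = L, byrow = TRUE
        )
      )
    })
  }
  structure(
    list(cdrs = idx, total = nrow(tab), label = pool_label(pool)),
    class = "pool_index"
  )
}

# Match one pattern against an index; returns weighted unique-sequence
# count and the row selector (for polymorphism checks).
index_match <- function(index, cdr_id, pattern) {
  per_len <- index$cdrs[[cdr_id]]
  L <- nchar(pattern)
  entry <- per_len[[as.character(L)]]
  if (is.null(entry)) {
    return(list(n = 0L, rows = logical(0), entry = NULL))
  }
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  def <- which(chars != "X")
  rows <- rep(TRUE, nrow(entry$mat))
  for (p in def) rows <- rows & (entry$mat[, p] == chars[p])
  list(n = sum(entry$mult[rows]), rows = rows, entry = entry)
}

#' All wildcard patterns of a CDR sequence under the wildcard cap
#'
#' The raw pattern space of a length-L CDR: every way of replacing up to
#' `floor(max_wildcard_fraction * L)` positions by `X`, before any support
#' or polymorphism filtering. Patterns are ordered by ascending wildcard
#' count, then lexicographically by wildcard position set, so enumeration
#' is deterministic. The raw count is `sum(choose(L, 0:kmax))`.
#'
#' @param cdr_seq Amino-acid string.
#' @param max_wildcard_fraction Wildcard cap (default 0.55).
#' @return Character vector of patterns (the first is always `cdr_seq`).
#' @export
enumerate_raw_patterns <- function(cdr_seq, max_wildcard_fraction = 0.55) {
  L <- nchar(cdr_seq)
  kmax <- floor(max_wildcard_fraction * L)
  chars <- strsplit(cdr_seq, "", fixed = TRUE)[[1]]
  pats <- character(0)
  for (k in 0:kmax) {
    sets <- if (k == 0) list(integer(0)) else
      utils::combn(L, k, simplify = FALSE)
    pats <- c(pats, vapply(sets, function(w) {
      x <- chars
      x[w] <- "X"
      paste(x, collapse = "")
    }, character(1)))
  }
  pats
}

#' Enumerate a candidate's admissible consensus motifs in one CDR
#'
#' Exhaustively generates every wildcard pattern of the candidate's CDR
#' sequence under the wildcard cap and keeps a motif iff (i) at least
#' `min_positive_support` unique positive-pool sequences of the same length
#' match it, and (ii) when required, every wildcard position shows more
#' than one distinct residue among those matching sequences.
#'
#' @param candidate The candidate's CDR amino-acid string.
#' @param cdr_id `"L3"`, `"H1"`, `"H2"`, or `"H3"`.
#' @param pos_index `pool_index` built on the positive pool.
#' @param constraints A [motif_constraints()].
#' @return Tibble with columns `cdr`, `pattern`, `n_wildcards`, `n_pos`.
#' @export
enumerate_motifs <- function(candidate, cdr_id, pos_index,
                             constraints = motif_constraints()) {
  stopifnot(inherits(pos_index, "pool_index"), is.character(candidate))
  if (is.na(candidate) || nchar(candidate) == 0) {
    stop("candidate has no ", cdr_id, " sequence")
  }
  pats <- enumerate_raw_patterns(candidate, constraints$max_wildcard_fraction)
  keep <- logical(length(pats))
  n_pos <- integer(length(pats))
  for (i in seq_along(pats)) {
    m <- index_match(pos_index, cdr_id, pats[i])
    n_pos[i] <- m$n
    if (m$n < constraints$min_positive_support) next
    if (constraints$require_polymorphic_wildcards) {
      wpos <- which(strsplit(pats[i], "", fixed = TRUE)[[1]] == "X")
      if (length(wpos) > 0) {
        sub <- m$entry$mat[m$rows, wpos, drop = FALSE]
        poly <- vapply(
          seq_along(wpos),
          function(j) length(unique(sub[, j])) > 1L,
          logical(1)
        )
        if (!all(poly)) next
      }
    }
    keep[i] <- TRUE
  }
  tibble::tibble(
    cdr = cdr_id,
    pattern = pats[keep],
    n_wildcards = vapply(
      pats[keep],
      function(p) sum(strsplit(p, "", fixed = TRUE)[[1]] == "X"), integer(1),
      USE.NAMES = FALSE
    ),
    n_pos = n_pos[keep]
  )
}

#' Motif frequencies in the positive and negative pools
#'
#' For each motif, the frequency is the number of unique pool sequences
#' matching it divided by the total number of unique sequences in that
#' pool. Matching is same-length only; a motif whose length is absent from
#' a pool has frequency 0 there.
#'
#' @param motifs Tibble with columns `cdr`, `pattern` (from
#'   [enumerate_motifs()]).
#' @param index_pos,index_neg `pool_index`es of the two pools.
#' @return The motif tibble with added `n_pos`, `n_neg`, `freq_pos`,
#'   `freq_neg`.
#' @export
motif_frequencies <- function(motifs, index_pos, index_neg) {
  n_pos <- integer(nrow(motifs))
  n_neg <- integer(nrow(motifs))
  for (i in seq_len(nrow(motifs))) {
    n_pos[i] <- index_match(index_pos, motifs$cdr[i], motifs$pattern[i])$n
    n_neg[i] <- index_match(index_neg, motifs$cdr[i], motifs$pattern[i])$n
  }
  motifs$n_pos <- n_pos
  motifs$n_neg <- n_neg
  motifs$freq_pos <- n_pos / index_pos$total
  motifs$freq_neg <- n_neg / index_neg$total
  motifs
}

#' A candidate's full motif profile over both pools
#'
#' Pools the admissible motifs from the constraint's CDRs (default L3 and
#' H3, see [motif_constraints()]) into one profile and computes each
#' motif's frequency in the positive and negative pools.
#'
#' @param paratope One-row data frame or named list with `l3`, `h1`, `h2`,
#'   `h3`.
#' @inheritParams motif_frequencies
#' @inheritParams enumerate_motifs
#' @return A motif profile tibble (`cdr`, `pattern`, `n_wildcards`,
#'   `n_pos`, `n_neg`, `freq_pos`, `freq_neg`).
#' @export
candidate_motif_profile <- function(paratope, index_pos, index_neg,
                                    constraints = motif_constraints()) {
  motifs <- dplyr::bind_rows(lapply(constraints$cdrs_used, function(cdr) {
    enumerate_motifs(paratope[[tolower(cdr)]], cdr, index_pos, constraints)
  }))
  if (nrow(motifs) == 0) {
    return(tibble::tibble(
      cdr = character(0), pattern = character(0), n_wildcards = integer(0),
      n_pos = integer(0), n_neg = integer(0),
      freq_pos = numeric(0), freq_neg = numeric(0)
    ))
  }
  motif_frequencies(motifs, index_pos, index_neg)
}
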