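#' Selection pools of unique paratopes
#'
#' A selection pool is the unit of analysis: the multiset of unique paratopes
#' (clones identified by their four diversified CDR amino-acid sequences L3,
#' H1, H2, H3) observed in one selection arm, with per-clone read counts.
#' Pools are plain tibbles with columns `l3`, `h1`, `h2`, `h3`, `count` plus
#' a `label` attribute (`"positive"` or `"negative"`) and a `total_reads`
#' attribute equal to the sum of counts, so every dplyr verb applies; use
#' [selection_pool()] to re-assert the invariants after manual manipulation.
#'
#' @param entries A data frame with columns `l3`, `h1`, `h2`, `h3`, `count`.
#'   Duplicate paratopes are aggregated by summing counts.
#' @param label Pool label, `"positive"` or `"negative"`.
#' @return A `selection_pool` tibble.
#' @export
selection_pool <- function(entries, label = c("positive", "negative")) {
  label <- match.arg(label)
  entries <- tibble::as_tibble(entries)
  need <- c("l3", "h1", "h2", "h3", "count")
  if (!all(need %in% names(entries))) {
    stop("pool entries need columns: ", paste(need, collapse = ", "))
  }
  if (nrow(entries) > 0) {
    if (any(!is.finite(entries$count)) || any(entries$count < 1) ||
      any(entries$count != round(entries$count))) {
      stop("pool counts must be positive integers")
    }
  }
  entries <- entries |>
    dplyr::mutate(count = as.numeric(.data$count)) |>
    dplyr::summarise(
      count = sum(.data$count),
      .by = c("l3", "h1", "h2", "h3")
    )
  structure(
    entries,
    label = label,
    total_reads = sum(entries$count),
    class = c("selection_pool", class(tibble::tibble()))
  )
}

#' @rdname selection_pool
#' @param pool A `selection_pool`.
#' @export
pool_label <- function(pool) attr(pool, "label")

#' @rdname selection_pool
#' @export
pool_total_reads <- function(pool) attr(pool, "total_reads")

#' Build a pool from assembled, design-validated clone sequences
#'
#' Takes assembled clone nucleotide segments (one row per read, columns
#' `l3_nt`, `h1_nt`, `h2_nt`, `h3_nt`), validates each CDR codon-exactly
#' against the design, translates the survivors, and aggregates identical
#' paratopes. Reads carrying any codon outside the designed repertoire are
#' discarded and tallied in the discard report rather than entering the
#' pool, so clone frequencies are relative to design-valid reads only.
#'
#' @param assembled Data frame of assembled reads (`l3_nt`, `h1_nt`,
#'   `h2_nt`, `h3_nt`).
#' @param design A `library_design`.
#' @param label Pool label.
#' @return A `selection_pool`; the discard report (named integer vector,
#'   reason -> reads) is available via [discard_report()].
#' @export
build_pool <- function(assembled, design, label = c("positive", "negative")) {
  label <- match.arg(label)
  assembled <- tibble::as_tibble(assembled)
  need <- c("l3_nt", "h1_nt", "h2_nt", "h3_nt")
  if (!all(need %in% names(assembled))) {
    stop("assembled reads need columns: ", paste(need, collapse = ", "))
  }
  cdr_ids <- c(l3_nt = "L3", h1_nt = "H1", h2_nt = "H2", h3_nt = "H3")
  n <- nrow(assembled)
  reason <- rep(NA_character_, n)
  for (col in names(cdr_ids)) {
    verdicts <- validate_clone_nt_vec(design, cdr_ids[[col]], assembled[[col]])
    newly <- is.na(reason) & verdicts != "valid"
    reason[newly] <- paste0(tolower(cdr_ids[[col]]), "_", verdicts[newly])
  }
  keep <- is.na(reason)
  valid <- assembled[keep, , drop = FALSE]
  entries <- tibble::tibble(
    l3 = unname(translate_vec(valid$l3_nt)),
    h1 = unname(translate_vec(valid$h1_nt)),
    h2 = unname(translate_vec(valid$h2_nt)),
    h3 = unname(translate_vec(valid$h3_nt)),
    count = 1
  )
  pool <- selection_pool(entries, label)
  rep_tab <- table(reason[!keep])
  attr(pool, "discard_report") <- stats::setNames(as.integer(rep_tab), names(rep_tab))
  attr(pool, "raw_reads") <- n
  pool
}

# Vectorized codon-exact validation; returns verdict strings.
validate_clone_nt_vec <- function(design, cdr_id, nt) {
  vapply(nt, function(s) validate_clone_nt(design, cdr_id, s)$verdict, character(1),
    USE.NAMES = FALSE
  )
}

translate_vec <- function(nt) {
  if (length(nt) == 0) return(character(0))
  as.character(Biostrings::translate(
    Biostrings::DNAStringSet(toupper(nt)),
    no.init.codon = TRUE
  ))
}

#' @rdname build_pool
#' @param pool A `selection_pool`.
#' @export
discard_report <- function(pool) attr(pool, "discard_report") %||% integer(0)

#' Merge duplicate sequencing runs of one selection arm
#'
#' Deep-sequencing runs of the same pool are merged to maximize both clone
#' frequencies and the number of unique sequences: per-paratope counts and
#' total reads are summed. Pools must carry the same label.
#'
#' @param pool_a,pool_b `selection_pool`s with identical labels.
#' @return The merged `selection_pool`.
#' @export
merge_pools <- function(pool_a, pool_b) {
  if (!identical(pool_label(pool_a), pool_label(pool_b))) {
    stop("cannot merge pools with different labels")
  }
  selection_pool(
    dplyr::bind_rows(
      tibble::as_tibble(pool_a)[c("l3", "h1", "h2", "h3", "count")],
      tibble::as_tibble(pool_b)[c("l3", "h1", "h2", "h3", "count")]
    ),
    pool_label(pool_a)
  )
}

#' Read and write unique-paratope count tables
#'
#' Pool tables are TSV files with columns `L3`, `H1`, `H2`, `H3`, `count`
#' and, on write, a `frequency` column equal to `count / total_reads`
#' (written at full precision so the column sums to one). The format mirrors
#' published per-pool unique-sequence supplementary tables, so such tables
#' can be loaded directly as `selection_pool`s.
#'
#' @param path TSV path.
#' @param label Pool label to attach on read.
#' @return `read_pool_table()` returns a `selection_pool`;
#'   `write_pool_table()` returns `path` invisibly.
#' @export
read_pool_table <- function(path, label = c("positive", "negative")) {
  label <- match.arg(label)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tab) <- tolower(names(tab))
  need <- c("l3", "h1", "h2", "h3", "count")
  if (!all(need %in% names(tab))) {
    stop("pool table must have columns L3, H1, H2, H3, count")
  }
  if (nrow(tab) > 0 && (!is.numeric(tab$count) || any(tab$count != round(tab$count)))) {
    stop("pool table counts must be integers")
  }
  selection_pool(tab[need], label)
}

#' @rdname read_pool_table
#' @param pool A `selection_pool`.
#' @export
write_pool_table <- function(pool, path) {
  out <- tibble::as_tibble(pool) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$l3, .data$h1, .data$h2, .data$h3) |>
    dplyr::mutate(frequency = .data$count / pool_total_reads(pool)) |>
    dplyr::rename(L3 = "l3", H1 = "h1", H2 = "h2", H3 = "h3")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Clone frequency as printed in summary tables
#'
#' Formats `count / total_reads` to two significant digits, the "% total"
#' convention of published clone summary tables (a fraction, not a
#' percentage: a clone seen 137 times among 7,541,189 reads prints 1.8E-05).
#'
#' @param count Read count(s).
#' @param total_reads Pool total.
#' @return Numeric vector of two-significant-digit frequencies.
#' @export
pool_frequency <- function(count, total_reads) signif(count / total_reads, 2)
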