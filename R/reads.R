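#' Three-read amplicon trios
#'
#' Each sequenced amplicon yields three reads: PE2 covers the light-chain
#' loop L3 from one end, PE1 covers H3 from the other end (sequenced on the
#' opposite strand), and a custom-primer read covers H1 and H2 in the
#' middle. Trios are rows of a tibble with columns `id`, `pe1_seq`,
#' `pe1_qual`, `pe2_seq`, `pe2_qual`, `custom_seq`, `custom_qual`;
#' qualities are Phred+33 strings the same length as their bases.
#'
#' `read_fastq_trios()` loads three FASTQ files (plain or gzip) whose
#' records correspond positionally.
#'
#' @param pe1,pe2,custom FASTQ paths.
#' @return A trio tibble.
#' @export
read_fastq_trios <- function(pe1, pe2, custom) {
  rd <- function(path) {
    # Biostrings warns that FASTQ metadata columns are dropped; the ids
    # and qualities are all we carry forward.
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    tibble::tibble(
      id = names(x) %||% as.character(seq_along(x)),
      seq = as.character(x),
      qual = as.character(Biostrings::quality(x))
    )
  }
  a <- rd(pe1); b <- rd(pe2); c <- rd(custom)
  if (!(nrow(a) == nrow(b) && nrow(b) == nrow(c))) {
    stop("FASTQ files differ in record count")
  }
  tibble::tibble(
    id = a$id,
    pe1_seq = a$seq, pe1_qual = a$qual,
    pe2_seq = b$seq, pe2_qual = b$qual,
    custom_seq = c$seq, custom_qual = c$qual
  )
}

phred_values <- function(qual) utf8ToInt(qual) - 33L

#' Per-base quality filtering of read trios
#'
#' A trio passes when every base subject to filtering, in all three reads,
#' has Phred quality at or above `q_min`. The default cut-off Q = 30
#' corresponds to a 1:1000 base-call error probability. By default only
#' design-covered bases are filtered (everything beyond the barcode prefix
#' of the PE1/PE2 reads, i.e. the anchors and CDR segments that determine
#' the paratope); `scope = "whole_read"` filters every base including the
#' barcode.
#'
#' @param trios Trio tibble (see [read_fastq_trios()]).
#' @param q_min Minimum per-base Phred score (default 30).
#' @param barcode_length Integer: bases to exempt at the start of the PE1
#'   and PE2 reads when `scope = "design"`. Scalar or one per trio.
#' @param scope `"design"` or `"whole_read"`.
#' @return The trios that pass, same columns.
#' @export
quality_filter <- function(trios, q_min = 30, barcode_length = 0L,
                           scope = c("design", "whole_read")) {
  scope <- match.arg(scope)
  stopifnot(q_min >= 0)
  trios <- tibble::as_tibble(trios)
  if (nrow(trios) == 0) return(trios)
  bl <- rep_len(as.integer(barcode_length), nrow(trios))
  if (scope == "whole_read") bl <- rep_len(0L, nrow(trios))
  ok <- vapply(seq_len(nrow(trios)), function(i) {
    for (rd in c("pe1", "pe2", "custom")) {
      s <- trios[[paste0(rd, "_seq")]][i]
      q <- trios[[paste0(rd, "_qual")]][i]
      if (nchar(s) != nchar(q)) stop("base/quality length mismatch in trio ", i)
      v <- phred_values(q)
      if (rd != "custom" && bl[i] > 0) v <- v[-seq_len(min(bl[i], length(v)))]
      if (length(v) > 0 && min(v) < q_min) return(FALSE)
    }
    TRUE
  }, logical(1))
  trios[ok, , drop = FALSE]
}

#' Demultiplex read trios by exact barcode match
#'
#' Each trio is assigned to the pool whose 6-8 nt barcode exactly matches
#' the prefix of its PE2 read; anything else goes to the `"unassigned"`
#' bin. No barcode error correction is attempted. Barcodes must be distinct
#' and prefix-free.
#'
#' @param trios Trio tibble.
#' @param barcode_map Data frame with columns `barcode`, `pool_name`, and
#'   `label` (`"positive"`/`"negative"`).
#' @return `trios` with added columns `pool_name` (or `"unassigned"`),
#'   `label`, and `barcode_length`.
#' @export
demultiplex <- function(trios, barcode_map) {
  barcode_map <- tibble::as_tibble(barcode_map)
  stopifnot(all(c("barcode", "pool_name", "label") %in% names(barcode_map)))
  bc <- toupper(barcode_map$barcode)
  if (anyDuplicated(bc)) stop("duplicate barcode in map")
  for (i in seq_along(bc)) {
    for (j in seq_along(bc)) {
      if (i != j && startsWith(bc[j], bc[i])) {
        stop("barcodes are not prefix-free: ", bc[i], " prefixes ", bc[j])
      }
    }
  }
  trios <- tibble::as_tibble(trios)
  pool_name <- rep("unassigned", nrow(trios))
  label <- rep(NA_character_, nrow(trios))
  blen <- rep(0L, nrow(trios))
  for (i in seq_along(bc)) {
    hit <- startsWith(toupper(trios$pe2_seq), bc[i])
    pool_name[hit] <- barcode_map$pool_name[i]
    label[hit] <- barcode_map$label[i]
    blen[hit] <- nchar(bc[i])
  }
  dplyr::mutate(trios,
    pool_name = pool_name, label = label, barcode_length = blen
  )
}

#' Assemble a read trio into the clone's CDR nucleotide segments
#'
#' Locates the design's framework anchors in each read (the PE1 read is
#' reverse-complemented first, normalizing its orientation), extracts the
#' four CDR segments, and cross-checks framework bases sequenced by two
#' reads: the PE2 read may run past the L3 right anchor into H1, and the
#' PE1 read past the H3 left anchor into H2; where those overhangs overlap
#' the custom read they must agree base-for-base. Any missing anchor or
#' overlap disagreement rejects the trio with a reason rather than an
#' error.
#'
#' @param trios Trio tibble; columns `barcode_length` (from
#'   [demultiplex()]) or the `barcode_length` argument give the PE1/PE2
#'   barcode prefix to strip.
#' @param design A `library_design` with anchors for all four CDRs.
#' @param barcode_length Used when `trios` has no `barcode_length` column.
#' @return A tibble with one row per input trio: `id`, `status`
#'   (`"ok"`/`"reject"`), `reason` (`NA`, `"anchor_not_found"`, or
#'   `"inconsistent_overlap"`), and `l3_nt`, `h1_nt`, `h2_nt`, `h3_nt`.
#' @export
assemble_trios <- function(trios, design, barcode_length = 0L) {
  stopifnot(inherits(design, "library_design"))
  anc <- design$anchors
  if (!all(c("L3", "H1", "H2", "H3") %in% names(anc))) {
    stop("design must declare anchors for all four CDRs")
  }
  trios <- tibble::as_tibble(trios)
  bl <- trios[["barcode_length"]] %||% rep_len(as.integer(barcode_length), nrow(trios))
  res <- purrr::map(seq_len(nrow(trios)), function(i) {
    assemble_one(
      pe1 = trios$pe1_seq[i], pe2 = trios$pe2_seq[i], custom = trios$custom_seq[i],
      anc = anc, bl = bl[i]
    )
  })
  out <- dplyr::bind_rows(res)
  out$id <- trios[["id"]] %||% as.character(seq_len(nrow(trios)))
  dplyr::relocate(out, "id")
}

assemble_one <- function(pe1, pe2, custom, anc, bl) {
  reject <- function(reason) tibble::tibble(
    status = "reject", reason = reason,
    l3_nt = NA_character_, h1_nt = NA_character_,
    h2_nt = NA_character_, h3_nt = NA_character_
  )
  pe2 <- substring(toupper(pe2), bl + 1L)
  pe1 <- revcomp(substring(toupper(pe1), bl + 1L))
  custom <- toupper(custom)

  seg <- function(read, left, right) {
    i <- locate_anchor(read, left)
    if (is.na(i)) return(NULL)
    j <- locate_anchor(read, right, from = i + nchar(left))
    if (is.na(j)) return(NULL)
    list(
      cdr = substr(read, i + nchar(left), j - 1L),
      tail = substring(read, j + nchar(right))
    )
  }
  l3 <- seg(pe2, anc$L3$left, anc$L3$right)
  h1 <- seg(custom, anc$H1$left, anc$H1$right)
  h2 <- seg(custom, anc$H2$left, anc$H2$right)
  h3 <- seg(pe1, anc$H3$left, anc$H3$right)
  if (is.null(l3) || is.null(h1) || is.null(h2) || is.null(h3)) {
    return(reject("anchor_not_found"))
  }
  # PE2 overhang past the L3 right anchor re-sequences the start of H1;
  # the PE1 head before the H3 left anchor re-sequences the end of H2.
  over1 <- min(nchar(l3$tail), nchar(h1$cdr))
  if (over1 > 0 &&
    substr(l3$tail, 1L, over1) != substr(h1$cdr, 1L, over1)) {
    return(reject("inconsistent_overlap"))
  }
  k <- locate_anchor(pe1, anc$H3$left)
  head1 <- substr(pe1, 1L, k - 1L)
  over2 <- min(nchar(head1), nchar(h2$cdr))
  if (over2 > 0 &&
    substring(head1, nchar(head1) - over2 + 1L) !=
      substring(h2$cdr, nchar(h2$cdr) - over2 + 1L)) {
    return(reject("inconsistent_overlap"))
  }
  tibble::tibble(
    status = "ok", reason = NA_character_,
    l3_nt = l3$cdr, h1_nt = h1$cdr, h2_nt = h2$cdr, h3_nt = h3$cdr
  )
}

locate_anchor <- function(read, anchor, from = 1L) {
  if (nchar(anchor) == 0) return(NA_integer_)
  i <- regexpr(anchor, substring(read, from), fixed = TRUE)[1]
  if (i < 0) NA_integer_ else i + from - 1L
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Build per-pool paratope tables from raw FASTQ trios
#'
#' Runs the full read-level pipeline: demultiplex by barcode, per-base
#' quality filter at `q_min`, anchor-based trio assembly, codon-exact
#' design validation, translation, and aggregation into one
#' `selection_pool` per barcode. Read-level losses at every stage are
#' tallied so that discarded + pooled reads always equal the input reads.
#'
#' @inheritParams assemble_trios
#' @inheritParams demultiplex
#' @param q_min Per-base Phred cut-off (default 30).
#' @return A list with `pools` (named list of `selection_pool`s) and
#'   `report` (named list: reads in, per-stage losses per pool).
#' @export
build_pools_from_fastq <- function(trios, design, barcode_map, q_min = 30) {
  trios <- demultiplex(trios, barcode_map)
  pools <- list()
  report <- list(reads_in = nrow(trios),
                 unassigned = sum(trios$pool_name == "unassigned"))
  for (nm in unique(barcode_map$pool_name)) {
    sub <- trios[trios$pool_name == nm, , drop = FALSE]
    hi <- quality_filter(sub, q_min = q_min, barcode_length = sub$barcode_length)
    asm <- assemble_trios(hi, design)
    ok <- asm[asm$status == "ok", , drop = FALSE]
    label <- barcode_map$label[barcode_map$pool_name == nm][1]
    pool <- build_pool(ok[c("l3_nt", "h1_nt", "h2_nt", "h3_nt")], design, label)
    report[[nm]] <- list(
      reads = nrow(sub),
      low_quality = nrow(sub) - nrow(hi),
      assembly_rejects = as.list(table(asm$reason[asm$status == "reject"])),
      design_discards = as.list(discard_report(pool)),
      pooled = pool_total_reads(pool)
    )
    pools[[nm]] <- pool
  }
  list(pools = pools, report = report)
}
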