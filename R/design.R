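#' Synthetic antibody library designs
#'
#' A `library_design` is a declarative model of a restricted-diversity
#' synthetic Fab library: for each diversified CDR (L3, H1, H2, H3) it lists
#' the allowed loop lengths and, for every length, the set of nucleotide
#' codons allowed at each position. Framework anchor sequences flanking each
#' CDR are carried for read assembly and validation. Designs are the ground
#' truth against which observed NGS reads are validated: any codon outside a
#' position's allowed set marks the read as divergent from the synthetic
#' repertoire.
#'
#' @param cdrs Named list (names among `"L3"`, `"H1"`, `"H2"`, `"H3"`). Each
#'   element is a list with `lengths` (integer vector of allowed codon
#'   counts) and either `positions` (a list named by length, each entry a
#'   list of character vectors of allowed codons, one vector per position)
#'   or `codon_set` (a single codon vector applied at every position of
#'   every length).
#' @param anchors Named list mapping each CDR to `list(left = , right = )`
#'   nucleotide strings flanking the loop in the amplicon.
#' @return An object of class `library_design`.
#' @examples
#' d <- toy_design()
#' theoretical_diversity(d, "H1")
#' @export
library_design <- function(cdrs, anchors) {
  stopifnot(is.list(cdrs), length(cdrs) >= 1, !is.null(names(cdrs)))
  bad <- setdiff(names(cdrs), c("L3", "H1", "H2", "H3"))
  if (length(bad) > 0) {
    stop("unknown CDR identifier(s): ", paste(bad, collapse = ", "))
  }
  cdrs <- lapply(names(cdrs), function(nm) {
    spec <- normalize_cdr_spec(cdrs[[nm]], nm)
    for (len in names(spec$positions)) {
      pos <- spec$positions[[len]]
      if (length(pos) != as.integer(len)) {
        stop(sprintf("CDR %s: %s position specs for length %s", nm, length(pos), len))
      }
    }
    spec
  }) |> stats::setNames(names(cdrs))
  anchors <- anchors %||% list()
  for (nm in names(anchors)) {
    a <- anchors[[nm]]
    if (!all(c("left", "right") %in% names(a))) {
      stop("anchor for ", nm, " must have left and right strings")
    }
    if (!all(grepl("^[ACGT]*$", unlist(a)))) stop("anchor for ", nm, " has non-ACGT characters")
  }
  structure(list(cdrs = cdrs, anchors = anchors), class = "library_design")
}

# Accepts either the explicit per-length `positions` form or the compact
# `codon_set` form and returns the explicit form with derived residues.
# Codon strings are validated before translation.
normalize_cdr_spec <- function(spec, nm = "?") {
  lengths <- as.integer(spec$lengths)
  if (length(lengths) == 0 || any(lengths < 1)) stop("CDR lengths must be positive")
  if (is.null(spec$positions)) {
    if (is.null(spec$codon_set)) stop("CDR spec needs positions or codon_set")
    cs <- toupper(as.character(spec$codon_set))
    positions <- stats::setNames(
      lapply(lengths, function(L) rep(list(cs), L)),
      as.character(lengths)
    )
  } else {
    positions <- spec$positions
    if (!all(as.character(lengths) %in% names(positions))) {
      stop("positions must be given for every allowed length")
    }
    positions <- lapply(positions[as.character(lengths)], function(p) {
      lapply(p, function(cod) toupper(as.character(cod)))
    })
  }
  for (len in names(positions)) {
    for (i in seq_along(positions[[len]])) {
      cod <- positions[[len]][[i]]
      if (length(cod) == 0) {
        stop(sprintf("CDR %s length %s position %d: empty codon set", nm, len, i))
      }
      if (!all(grepl("^[ACGT]{3}$", cod))) {
        stop(sprintf("CDR %s length %s position %d: malformed codon", nm, len, i))
      }
    }
  }
  residues <- lapply(positions, function(p) lapply(p, codons_to_residues))
  list(lengths = lengths, positions = positions, residues = residues)
}

codons_to_residues <- function(codons) {
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(codons),
    no.init.codon = TRUE
  ))
  sort(unique(aa))
}

#' @export
print.library_design <- function(x, ...) {
  cat("<library_design>\n")
  for (nm in names(x$cdrs)) {
    spec <- x$cdrs[[nm]]
    cat(sprintf(
      "  %s: lengths %s, diversity %s\n", nm,
      paste(range(spec$lengths), collapse = "-"),
      format(theoretical_diversity(x, nm), big.mark = ",")
    ))
  }
  invisible(x)
}

#' Load a library design from a YAML or JSON document
#'
#' The document has top-level keys `cdrs` and `anchors` in the shapes
#' accepted by [library_design()]. Two designs ship with the package:
#' `design_file("toy")`, a minimal design used throughout the examples, and
#' `design_file("libf")`, a library with binary-degenerate H1/H2 positions
#' (6 and 8 positions) and a nine-residue alphabet at the variable-length
#' L3 (3-7 codons) and H3 (1-17 codons) loops.
#'
#' @param path Path to the design document (`.yaml`/`.yml` or `.json`).
#' @return A validated `library_design`.
#' @export
load_design <- function(path) {
  if (!file.exists(path)) stop("design document not found: ", path)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(doc$cdrs)) stop("malformed design document: missing 'cdrs'")
  library_design(doc$cdrs, doc$anchors)
}

#' @rdname load_design
#' @param which `"toy"` or `"libf"`.
#' @export
design_file <- function(which = c("toy", "libf")) {
  which <- match.arg(which)
  system.file("extdata", paste0("design_", which, ".yaml"),
    package = "phagemotifs", mustWork = TRUE
  )
}

#' @rdname load_design
#' @export
default_design <- function() load_design(design_file("libf"))

#' @rdname load_design
#' @export
toy_design <- function() load_design(design_file("toy"))

#' Theoretical amino-acid diversity of one CDR
#'
#' Counts the unique amino-acid sequences the design allows at a CDR: the
#' product over positions of the number of distinct encoded residues, summed
#' over the allowed loop lengths. For the bundled `libf` design this
#' reproduces the 64 (H1, six binary positions) and 256 (H2, eight binary
#' positions) sequence diversities, and order-1e9 / 1e16 diversities for the
#' nine-residue L3 and H3 loops.
#'
#' @param design A `library_design`.
#' @param cdr_id One of the design's CDR identifiers.
#' @return A number (exact for all designs whose diversity is below 2^53).
#' @export
theoretical_diversity <- function(design, cdr_id) {
  stopifnot(inherits(design, "library_design"))
  if (!cdr_id %in% names(design$cdrs)) stop("unknown cdr_id: ", cdr_id)
  spec <- design$cdrs[[cdr_id]]
  sum(vapply(
    spec$residues,
    function(res) prod(vapply(res, length, integer(1))),
    numeric(1)
  ))
}

#' Validate a clone's CDR nucleotide sequence against the design
#'
#' Checks an assembled CDR segment codon-by-codon against the design's
#' allowed codon sets. Validation is codon-exact (nucleotide level), not
#' residue-level: an unexpected synonymous codon at a diversified position
#' marks the read as divergent from the synthetic repertoire.
#'
#' @inheritParams theoretical_diversity
#' @param nt_sequence Nucleotide string covering exactly the CDR codons
#'   (anchors already trimmed).
#' @return A list with `verdict` (`"valid"`, `"bad_length"`, or
#'   `"bad_codon"`) and, for `bad_codon`, `position` (1-based codon index of
#'   the first offending codon).
#' @export
validate_clone_nt <- function(design, cdr_id, nt_sequence) {
  stopifnot(inherits(design, "library_design"))
  if (!cdr_id %in% names(design$cdrs)) stop("unknown cdr_id: ", cdr_id)
  spec <- design$cdrs[[cdr_id]]
  nt_sequence <- toupper(nt_sequence)
  n <- nchar(nt_sequence)
  if (n %% 3L != 0L) {
    return(list(verdict = "bad_length", position = NA_integer_))
  }
  len <- n %/% 3L
  if (!len %in% spec$lengths) {
    return(list(verdict = "bad_length", position = NA_integer_))
  }
  codons <- substring(nt_sequence, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  allowed <- spec$positions[[as.character(len)]]
  for (i in seq_len(len)) {
    if (!codons[i] %in% allowed[[i]]) {
      return(list(verdict = "bad_codon", position = i))
    }
  }
  list(verdict = "valid", position = NA_integer_)
}

#' Translate a design-valid CDR nucleotide segment to residues
#'
#' @inheritParams validate_clone_nt
#' @return Amino-acid string.
#' @export
translate_cdr <- function(nt_sequence) {
  as.character(Biostrings::translate(
    Biostrings::DNAString(toupper(nt_sequence)),
    no.init.codon = TRUE
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
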