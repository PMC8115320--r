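#' Configuration for the selection-pool simulator
#'
#' The generator emulates the structure of a cell-based phage selection
#' experiment sequenced at depth: a positive pool enriched for families of
#' homologous antigen-specific clones (sharing planted consensus motifs at
#' fixed L3/H3 positions and family-level H1/H2 sequences), a negative pool
#' of the same background, PCR hybridization chimeras, and base-call
#' errors at read emission.
#'
#' Defaults mirror the study conditions the package targets: read depth
#' 7e6 per pool, four specific families of 200 close homologs each (family
#' motifs must recruit more than the 100-sequence motif support floor,
#' with slack for members mutated at the defined positions), a log-uniform
#' background abundance law over 1e-7..0.3 with correlated read abundances
#' between pools, a 1e4-fold positive enrichment of specific clones (so
#' most family members have zero negative-pool observations), family head
#' frequencies of 0.3 (one immunodominant family) and 0.01, one designated
#' rare member per family pinned at positive frequency 1e-6, and a 10%
#' chimera rate.
#'
#' @param design A `library_design` (default the bundled `libf` design).
#' @param n_specific_families,clones_per_family Family structure.
#' @param family_motif_length Fixed (planted) H3 positions per family;
#'   families use H3 loops of twice this length, so members vary exactly
#'   the positions the wildcard cap can absorb. Members share the family
#'   H1/H2, differ from the family head at 1-2 free H3 positions (distinct
#'   per member), and mutate one family L3 position with probability
#'   `l3_mutation_rate` - keeping every member within 3 edits of the head,
#'   i.e. one single-linkage homolog family at 80% L3+H3 identity.
#' @param l3_mutation_rate Probability that a member carries one mutated
#'   L3 position (default 0.3).
#' @param n_background Background clones present in both pools.
#' @param abundance_range Log-uniform background abundance law.
#' @param background_log_sd Between-pool log-normal noise on background
#'   read abundance (natural log scale).
#' @param head_frequency,rare_frequency Positive-pool frequency of each
#'   family's most abundant member (the first family uses
#'   `immunodominant_frequency`) and of its pinned rare member.
#' @param immunodominant_frequency Positive-pool frequency of family 1's
#'   head clone.
#' @param member_freq_range Log-uniform law for the remaining members'
#'   positive frequencies.
#' @param enrichment_factor Positive/negative abundance ratio of specific
#'   clones.
#' @param chimera_rate Fraction of reads converted to L3/H3 amalgams.
#' @param error_rate,base_quality,low_q_rate,low_quality Read-emission
#'   model: per-base substitution probability and Phred labels.
#' @param reads_per_pool Sequencing depth per pool.
#' @param seed Mandatory integer seed; all stages draw from named
#'   substreams derived from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(design = default_design(),
                              n_specific_families = 4,
                              clones_per_family = 200,
                              family_motif_length = 7,
                              l3_mutation_rate = 0.3,
                              n_background = 5000,
                              abundance_range = c(1e-7, 0.3),
                              background_log_sd = 0.5,
                              head_frequency = 0.01,
                              immunodominant_frequency = 0.3,
                              rare_frequency = 1e-6,
                              member_freq_range = c(1e-6, 1e-3),
                              enrichment_factor = 1e4,
                              chimera_rate = 0.1,
                              error_rate = 1e-3,
                              base_quality = 40,
                              low_q_rate = 0,
                              low_quality = 20,
                              reads_per_pool = 7e6,
                              seed = NULL) {
  if (is.null(seed)) stop("seed is mandatory")
  stopifnot(
    chimera_rate >= 0, chimera_rate < 1,
    error_rate >= 0, error_rate <= 1,
    reads_per_pool >= 1
  )
  structure(as.list(environment()), class = "simulation_config")
}

# Substream seeds so individual stages are independently reproducible.
substream_seeds <- function(seed, n = 6) {
  old <- globalenv()$.Random.seed
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

sample_from <- function(x, n, replace = FALSE) {
  if (length(x) == 1) rep(x, n) else sample(x, n, replace = replace)
}

draw_logunif <- function(n, range) {
  exp(stats::runif(n, log(range[1]), log(range[2])))
}

# Random design-conformant CDR residue string of a given length.
random_cdr <- function(design, cdr_id, len, n = 1) {
  res <- design$cdrs[[cdr_id]]$residues[[as.character(len)]]
  vapply(seq_len(n), function(i) {
    paste(vapply(res, function(r) r[sample.int(length(r), 1)], character(1)),
      collapse = ""
    )
  }, character(1))
}

#' Simulate a positive/negative selection-pool pair with ground truth
#'
#' Draws the clone universe (specific families plus shared background),
#' assigns intended per-pool frequencies, samples read counts
#' multinomially at the configured depth, and injects hybridization
#' chimeras. Specific family members share fixed residues at
#' family-defined L3/H3 positions (and family-level H1/H2), vary at the
#' remaining positions, and are enriched only in the positive pool;
#' background clones appear in both pools at correlated abundances. Fully
#' reproducible from the config seed.
#'
#' @param config A [simulation_config()].
#' @return List with `pos` and `neg` (`selection_pool`s) and `truth`, a
#'   tibble with one row per parent clone (label `"specific"` or
#'   `"background"`, `family`, intended `freq_pos`/`freq_neg`) plus rows
#'   for injected chimera paratopes (label `"chimera"`, intended
#'   frequency 0).
#' @export
simulate_pools <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  seeds <- substream_seeds(config$seed, 6)
  design <- config$design

  set.seed(seeds[1])
  truth <- draw_clone_universe(config)

  set.seed(seeds[2])
  pos <- sample_pool(truth, "freq_pos", config$reads_per_pool, "positive")
  set.seed(seeds[3])
  neg <- sample_pool(truth, "freq_neg", config$reads_per_pool, "negative")

  chim <- tibble::tibble()
  if (config$chimera_rate > 0) {
    pos <- inject_chimeras(pos, config$chimera_rate, seed = seeds[4])
    neg <- inject_chimeras(neg, config$chimera_rate, seed = seeds[5])
    chim <- dplyr::bind_rows(
      attr(pos, "chimera_truth"), attr(neg, "chimera_truth")
    ) |>
      dplyr::distinct(.data$l3, .data$h1, .data$h2, .data$h3) |>
      dplyr::anti_join(truth, by = c("l3", "h1", "h2", "h3")) |>
      dplyr::mutate(
        clone_id = paste0("chimera_", dplyr::row_number()),
        label = "chimera", family = NA_integer_,
        freq_pos = 0, freq_neg = 0
      )
  }
  list(pos = pos, neg = neg, truth = dplyr::bind_rows(truth, chim))
}

# Clone universe with intended frequencies (sum to 1 per pool).
draw_clone_universe <- function(config) {
  design <- config$design
  fam_h3_len <- 2L * config$family_motif_length
  fam_l3_len <- 5L
  fams <- list()
  nf <- config$n_specific_families
  if (nf > 0) {
    stopifnot(
      fam_h3_len %in% design$cdrs$H3$lengths,
      fam_l3_len %in% design$cdrs$L3$lengths
    )
    for (f in seq_len(nf)) {
      # A family is a set of close homologs of a head clone: all members
      # share the family L3, H1 and H2 and the fixed half of the H3
      # positions (the planted consensus motif); each member carries a
      # distinct H3 differing from the head at 1-2 of the free positions.
      # Keeping every member within 2 edits of the head makes the family
      # one single-linkage cluster at 80% L3+H3 identity, and distinct
      # member H3s give every valid H3 a single dominant L3 partner (the
      # regime where the pair filter removes artifacts without touching
      # true clones).
      h3_fixed_pos <- sort(sample.int(fam_h3_len, config$family_motif_length))
      h3_free_pos <- setdiff(seq_len(fam_h3_len), h3_fixed_pos)
      head_h3 <- strsplit(random_cdr(design, "H3", fam_h3_len), "")[[1]]
      l3 <- random_cdr(design, "L3", fam_l3_len)
      h1 <- random_cdr(design, "H1", design$cdrs$H1$lengths[1])
      h2 <- random_cdr(design, "H2", design$cdrs$H2$lengths[1])
      h3_res <- design$cdrs$H3$residues[[as.character(fam_h3_len)]]
      l3_res <- design$cdrs$L3$residues[[as.character(fam_l3_len)]]
      n <- config$clones_per_family
      h3s <- paste(head_h3, collapse = "")
      while (length(h3s) < n) {
        k <- sample(1:2, 1, prob = c(0.5, 0.5))
        pos <- sample(h3_free_pos, k)
        var <- head_h3
        for (p in pos) var[p] <- sample(setdiff(h3_res[[p]], head_h3[p]), 1)
        h3s <- unique(c(h3s, paste(var, collapse = "")))
      }
      head_l3 <- strsplit(l3, "")[[1]]
      l3s <- vapply(seq_len(n), function(i) {
        if (i == 1 || stats::runif(1) >= config$l3_mutation_rate) return(l3)
        p <- sample.int(fam_l3_len, 1)
        var <- head_l3
        var[p] <- sample(setdiff(l3_res[[p]], head_l3[p]), 1)
        paste(var, collapse = "")
      }, character(1))
      head_f <- if (f == 1) config$immunodominant_frequency else config$head_frequency
      freq <- draw_logunif(n, config$member_freq_range)
      freq[1] <- head_f
      freq[n] <- config$rare_frequency
      fams[[f]] <- tibble::tibble(
        clone_id = sprintf("fam%d_%03d", f, seq_len(n)),
        l3 = l3s, h1 = h1, h2 = h2, h3 = h3s,
        label = "specific", family = f,
        raw_pos = freq, raw_neg = freq / config$enrichment_factor
      )
    }
  }
  fam_tab <- dplyr::bind_rows(fams)

  nb <- config$n_background
  bg_h3_lens <- sample_from(setdiff(design$cdrs$H3$lengths, 1L), nb, replace = TRUE)
  bg_l3_lens <- sample_from(design$cdrs$L3$lengths, nb, replace = TRUE)
  bg <- tibble::tibble(
    clone_id = sprintf("bg_%05d", seq_len(nb)),
    l3 = vapply(bg_l3_lens, function(L) random_cdr(config$design, "L3", L), character(1)),
    h1 = random_cdr(design, "H1", design$cdrs$H1$lengths[1], nb),
    h2 = random_cdr(design, "H2", design$cdrs$H2$lengths[1], nb),
    h3 = vapply(bg_h3_lens, function(L) random_cdr(config$design, "H3", L), character(1)),
    label = "background", family = NA_integer_
  )
  base <- draw_logunif(nb, config$abundance_range)
  bg$raw_pos <- base * exp(stats::rnorm(nb, 0, config$background_log_sd))
  bg$raw_neg <- base * exp(stats::rnorm(nb, 0, config$background_log_sd))
  bg <- bg[!duplicated(bg$h3), , drop = FALSE]
  if (nrow(fam_tab) > 0) bg <- bg[!bg$h3 %in% fam_tab$h3, , drop = FALSE]

  all <- dplyr::bind_rows(fam_tab, bg)
  # Specific clones keep their pinned frequencies; background scales to
  # fill the remaining probability mass of each pool.
  for (side in c("pos", "neg")) {
    raw <- all[[paste0("raw_", side)]]
    is_bg <- all$label == "background"
    spec_mass <- sum(raw[!is_bg])
    if (spec_mass >= 1) stop("specific clones exceed unit probability mass")
    raw[is_bg] <- raw[is_bg] / sum(raw[is_bg]) * (1 - spec_mass)
    all[[paste0("freq_", side)]] <- raw
  }
  all$raw_pos <- NULL
  all$raw_neg <- NULL
  all
}

sample_pool <- function(truth, freq_col, depth, label) {
  counts <- as.vector(stats::rmultinom(1, size = depth, prob = truth[[freq_col]]))
  keep <- counts > 0
  selection_pool(
    tibble::tibble(
      l3 = truth$l3[keep], h1 = truth$h1[keep],
      h2 = truth$h2[keep], h3 = truth$h3[keep],
      count = counts[keep]
    ),
    label
  )
}

#' Inject PCR hybridization chimeras into a pool
#'
#' Converts a binomial fraction of the pool's reads into recombinants:
#' each converted read keeps the L3 of its clone of origin and takes the
#' H1/H2/H3 cassettes of a second clone sampled abundance-proportionally
#' (whole-cassette recombination, as expected from template switching at
#' the fixed framework). Reads are conserved: converted reads are
#' subtracted from their L3 donor and reappear as chimeric paratopes. A
#' recombinant that reconstitutes an existing paratope simply adds to that
#' clone's count.
#'
#' @param pool A `selection_pool`.
#' @param rate Fraction of reads to convert, in `[0, 1)`.
#' @param seed Integer seed.
#' @return The pool with chimeras; attributes `n_chimeric_reads` and
#'   `chimera_truth` (tibble of injected paratopes) record the ground
#'   truth.
#' @export
inject_chimeras <- function(pool, rate, seed) {
  stopifnot(rate >= 0, rate < 1)
  set.seed(seed)
  tab <- tibble::as_tibble(pool)
  total <- sum(tab$count)
  n_chim <- stats::rbinom(1, total, rate)
  if (rate == 0 || n_chim == 0 || nrow(tab) < 2) {
    attr(pool, "n_chimeric_reads") <- 0L
    attr(pool, "chimera_truth") <- tab[0, c("l3", "h1", "h2", "h3")]
    return(pool)
  }
  a <- sample.int(nrow(tab), n_chim, replace = TRUE, prob = tab$count)
  b <- sample.int(nrow(tab), n_chim, replace = TRUE, prob = tab$count)
  same <- a == b
  for (i in 1:20) {
    if (!any(same)) break
    b[same] <- sample.int(nrow(tab), sum(same), replace = TRUE, prob = tab$count)
    same <- a == b
  }
  keep <- a != b
  # Cap conversions at each L3 donor's read count (cannot convert more
  # reads than the clone has).
  ord <- sample(which(keep))
  used <- integer(nrow(tab))
  for (i in ord) {
    if (used[a[i]] >= tab$count[a[i]]) keep[i] <- FALSE else used[a[i]] <- used[a[i]] + 1L
  }
  a <- a[keep]
  b <- b[keep]
  donor_loss <- tabulate(a, nbins = nrow(tab))
  chim <- tibble::tibble(
    l3 = tab$l3[a], h1 = tab$h1[b], h2 = tab$h2[b], h3 = tab$h3[b], count = 1
  ) |>
    dplyr::summarise(count = sum(.data$count), .by = c("l3", "h1", "h2", "h3"))
  out <- dplyr::bind_rows(
    dplyr::mutate(tab, count = .data$count - donor_loss) |>
      dplyr::filter(.data$count > 0),
    chim
  )
  res <- selection_pool(out, pool_label(pool))
  stopifnot(pool_total_reads(res) == total)
  attr(res, "n_chimeric_reads") <- length(a)
  # recombinants that reconstitute an existing paratope are not novel
  # clones; the truth table lists only genuinely chimeric paratopes
  attr(res, "chimera_truth") <- dplyr::anti_join(
    dplyr::distinct(chim[c("l3", "h1", "h2", "h3")]),
    tab[c("l3", "h1", "h2", "h3")],
    by = c("l3", "h1", "h2", "h3")
  )
  res
}

# residue -> codon lookup for back-translation under a design.
codon_lookup <- function(design, cdr_id, len) {
  pos <- design$cdrs[[cdr_id]]$positions[[as.character(len)]]
  lapply(pos, function(codons) {
    aa <- vapply(codons, function(cd) {
      as.character(Biostrings::translate(Biostrings::DNAString(cd), no.init.codon = TRUE))
    }, character(1))
    stats::setNames(codons[!duplicated(aa)], aa[!duplicated(aa)])
  })
}

back_translate <- function(design, cdr_id, seqs) {
  lens <- nchar(seqs)
  out <- character(length(seqs))
  for (L in unique(lens)) {
    lk <- codon_lookup(design, cdr_id, L)
    sel <- which(lens == L)
    m <- matrix(unlist(strsplit(seqs[sel], "")), ncol = L, byrow = TRUE)
    nt <- vapply(seq_len(L), function(p) {
      cd <- lk[[p]][m[, p]]
      if (anyNA(cd)) stop("residue not encodable at ", cdr_id, " position ", p)
      cd
    }, character(nrow(m)))
    if (length(sel) == 1) nt <- matrix(nt, nrow = 1)
    out[sel] <- apply(nt, 1, paste, collapse = "")
  }
  out
}

#' Emit three-read FASTQ trios for a pool
#'
#' Back-translates each clone to design-conformant nucleotides (first
#' allowed codon per residue), lays out the amplicon with the design's
#' framework anchors, and writes one PE1, one PE2 and one custom-read
#' FASTQ record per read. The PE2 read carries the barcode, the L3 region
#' and an `overhang` of bases into H1; the PE1 read is emitted
#' reverse-complemented and covers H3 plus an overhang into H2; the custom
#' read covers H1 and H2. Substitution errors are applied per base at
#' `error_rate`; qualities are `base_quality` except a `low_q_rate`
#' fraction of bases labelled `low_quality`. With a zero error rate,
#' [build_pools_from_fastq()] round-trips to exactly the input pool.
#'
#' @param pool A `selection_pool`.
#' @param design The `library_design` (with anchors).
#' @param dir Output directory.
#' @param barcode Barcode prefixed to the PE1/PE2 reads.
#' @param prefix File name prefix.
#' @inheritParams simulation_config
#' @param overhang Bases of double coverage at the read junctions.
#' @param seed Integer seed.
#' @return Named list of the three FASTQ paths.
#' @export
emit_read_trios <- function(pool, design, dir, barcode = "ACGTAA",
                            prefix = pool_label(pool),
                            error_rate = 0, base_quality = 40,
                            low_q_rate = 0, low_quality = 20,
                            overhang = 4, seed = 1) {
  set.seed(seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- tibble::as_tibble(pool)
  idx <- rep(seq_len(nrow(tab)), tab$count)
  l3 <- back_translate(design, "L3", tab$l3)[idx]
  h1 <- back_translate(design, "H1", tab$h1)[idx]
  h2 <- back_translate(design, "H2", tab$h2)[idx]
  h3 <- back_translate(design, "H3", tab$h3)[idx]
  anc <- design$anchors
  pe2 <- paste0(barcode, anc$L3$left, l3, anc$L3$right, substr(h1, 1, overhang))
  mid <- if (identical(anc$H1$right, anc$H2$left)) anc$H1$right else
    paste0(anc$H1$right, anc$H2$left)
  custom <- paste0(anc$H1$left, h1, mid, h2, anc$H2$right)
  pe1_fwd <- paste0(
    substring(h2, pmax(nchar(h2) - overhang + 1, 1)),
    anc$H3$left, h3, anc$H3$right
  )
  pe1 <- paste0(barcode, vapply(pe1_fwd, revcomp, character(1), USE.NAMES = FALSE))
  ids <- sprintf("read_%06d", seq_along(idx))
  paths <- list(
    pe1 = file.path(dir, paste0(prefix, "_pe1.fastq")),
    pe2 = file.path(dir, paste0(prefix, "_pe2.fastq")),
    custom = file.path(dir, paste0(prefix, "_custom.fastq"))
  )
  write_one <- function(seqs, path) {
    seqs <- apply_errors(seqs, error_rate)
    quals <- vapply(nchar(seqs), function(n) {
      q <- rep(base_quality, n)
      if (low_q_rate > 0) {
        low <- stats::runif(n) < low_q_rate
        q[low] <- low_quality
      }
      intToUtf8(q + 33L)
    }, character(1))
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(stats::setNames(seqs, ids)),
      Biostrings::PhredQuality(quals)
    )
    Biostrings::writeQualityScaledXStringSet(x, path)
  }
  write_one(pe1, paths$pe1)
  write_one(pe2, paths$pe2)
  write_one(custom, paths$custom)
  paths
}

apply_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(stats::runif(n) < error_rate)
    if (length(hit) == 0) return(s)
    ch <- strsplit(s, "")[[1]]
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(bases, b), 1), character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
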