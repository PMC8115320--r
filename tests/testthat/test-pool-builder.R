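test_that("build_pool counts reads, collapses synonyms and reports discards", {
  d <- synonymous_design()
  clone_a <- list(l3 = "TCTTATTAT", h1 = "TATTCT", h2 = "TCTTCT", h3 = "TATTGG")
  clone_b <- list(l3 = "TCTTCTTCT", h1 = "TATTAT", h2 = "TCTTCT", h3 = "TGGTGG")
  asm <- tibble::tibble(
    l3_nt = c(rep(clone_a$l3, 5), rep(clone_b$l3, 2)),
    h1_nt = c(rep(clone_a$h1, 5), rep(clone_b$h1, 2)),
    h2_nt = c(rep(clone_a$h2, 5), rep(clone_b$h2, 2)),
    h3_nt = c(rep(clone_a$h3, 5), rep(clone_b$h3, 2))
  )
  pool <- build_pool(asm, d, "positive")
  expect_equal(nrow(pool), 2)
  expect_setequal(pool$count, c(5, 2))
  expect_equal(pool_total_reads(pool), 7)

  # a read with an unexpected codon is discarded, not pooled
  bad <- asm
  bad$h3_nt[1] <- "GGGTGG"
  pool2 <- build_pool(bad, d, "positive")
  expect_equal(pool_total_reads(pool2), 6)
  expect_equal(sum(discard_report(pool2)), 1)
  expect_match(names(discard_report(pool2)), "h3_bad_codon")

  # synonymous codons (TCT/TCC, both Ser) collapse to one paratope
  syn <- tibble::tibble(
    l3_nt = c("TCTTATTAT", "TCCTATTAT"),
    h1_nt = clone_a$h1, h2_nt = clone_a$h2, h3_nt = clone_a$h3
  )
  pool3 <- build_pool(syn, d, "positive")
  expect_equal(nrow(pool3), 1)
  expect_equal(pool3$count, 2)
  expect_equal(pool3$l3, "SYY")
})

test_that("merging pools is additive, identity on empty, and label-checked", {
  a <- make_pool(c("YY", "WW"), count = c(2, 1))
  b <- make_pool("YY", count = 3)
  m <- merge_pools(a, b)
  expect_equal(dplyr::arrange(tibble::as_tibble(m), h3)$count, c(1, 2 + 3))
  expect_equal(pool_total_reads(m), 6)
  empty <- selection_pool(tibble::as_tibble(a)[0, ], "positive")
  expect_equal(
    dplyr::arrange(tibble::as_tibble(merge_pools(a, empty)), h3),
    dplyr::arrange(tibble::as_tibble(a), h3),
    ignore_attr = TRUE
  )
  neg <- make_pool("YY", label = "negative")
  expect_error(merge_pools(a, neg), "label")
  # same generator seed twice, merged: exactly doubled counts
  sim1 <- simulate_pools(small_sim_config(seed = 5, chimera_rate = 0))
  sim2 <- simulate_pools(small_sim_config(seed = 5, chimera_rate = 0))
  doubled <- merge_pools(sim1$pos, sim2$pos)
  expect_equal(pool_total_reads(doubled), 2 * pool_total_reads(sim1$pos))
  expect_true(all(dplyr::arrange(tibble::as_tibble(doubled), l3, h3)$count %% 2 == 0))
})

test_that("pool tables round-trip losslessly and enforce count invariants", {
  pool <- make_pool(c("YYY", "WWS", "SSY"), count = c(137, 7, 10))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_pool_table(pool, tmp)
  back <- read_pool_table(tmp, "positive")
  expect_equal(
    dplyr::arrange(tibble::as_tibble(back), h3),
    dplyr::arrange(tibble::as_tibble(pool), h3)
  )
  tab <- readr::read_tsv(tmp, show_col_types = FALSE)
  expect_equal(sum(tab$frequency), 1, tolerance = 1e-9)
  # zero counts violate the pool invariant
  writeLines(c("L3\tH1\tH2\tH3\tcount", "SSS\tYY\tSS\tYYY\t0"), tmp)
  expect_error(read_pool_table(tmp), "positive integers")
  writeLines(c("L3\tH1\tH2\tcount", "SSS\tYY\tSS\t1"), tmp)
  expect_error(read_pool_table(tmp), "columns")
})

test_that("printed-frequency arithmetic matches two-significant-digit convention", {
  expect_equal(pool_frequency(137, 7541189), 1.8e-5)
  expect_equal(pool_frequency(7, 7541189), 9.3e-7)
})

test_that("quality filter applies the per-base floor over design-covered bases", {
  trio <- tibble::tibble(
    id = "r1",
    pe1_seq = "ACGT", pe1_qual = "IIII",     # Q40
    pe2_seq = "ACGT", pe2_qual = "IIII",
    custom_seq = "ACGT", custom_qual = "IIII"
  )
  expect_equal(nrow(quality_filter(trio, q_min = 30)), 1)
  low <- trio
  low$custom_qual <- "II>I"                   # one base at Q29
  expect_equal(nrow(quality_filter(low, q_min = 30)), 0)
  expect_equal(nrow(quality_filter(low, q_min = 29)), 1)
  # a low-quality barcode base is exempt in design scope, fatal whole-read
  bc <- trio
  bc$pe2_qual <- ">III"
  expect_equal(nrow(quality_filter(bc, q_min = 30, barcode_length = 1)), 1)
  expect_equal(nrow(quality_filter(bc, q_min = 30, barcode_length = 1,
                                   scope = "whole_read")), 0)
  expect_equal(nrow(quality_filter(trio[0, ], q_min = 30)), 0)
  mismatch <- trio
  mismatch$pe1_qual <- "III"
  expect_error(quality_filter(mismatch), "length mismatch")
})

test_that("demultiplexing is exact-match and prefix-safe", {
  map <- tibble::tibble(
    barcode = c("ACGTAA", "TTGCAC"),
    pool_name = c("pos", "neg"),
    label = c("positive", "negative")
  )
  trios <- tibble::tibble(
    id = c("a", "b", "c"),
    pe1_seq = "AAAA", pe1_qual = "IIII",
    pe2_seq = c("ACGTAAGGG", "ACGTATGGG", "TTGCACGGG"),
    pe2_qual = "IIIIIIIII",
    custom_seq = "AAAA", custom_qual = "IIII"
  )
  dm <- demultiplex(trios, map)
  expect_equal(dm$pool_name, c("pos", "unassigned", "neg"))
  expect_equal(dm$barcode_length, c(6L, 0L, 6L))
  expect_error(
    demultiplex(trios, dplyr::mutate(map, barcode = c("ACGTAA", "ACGTAA"))),
    "duplicate"
  )
  expect_error(
    demultiplex(trios, dplyr::mutate(map, barcode = c("ACGTAA", "ACGTAATT"))),
    "prefix"
  )
})

test_that("error-free emission round-trips through the full read pipeline", {
  d <- toy_design()
  set.seed(11)
  sim <- simulate_pools(simulation_config(
    design = d, n_specific_families = 0, n_background = 40,
    abundance_range = c(1e-3, 0.2), reads_per_pool = 400,
    chimera_rate = 0, seed = 3
  ))
  dir <- withr::local_tempdir()
  paths <- emit_read_trios(sim$pos, d, dir, barcode = "ACGTAA", seed = 9)
  trios <- read_fastq_trios(paths$pe1, paths$pe2, paths$custom)
  expect_equal(nrow(trios), pool_total_reads(sim$pos))
  map <- tibble::tibble(barcode = "ACGTAA", pool_name = "pos", label = "positive")
  built <- build_pools_from_fastq(trios, d, map, q_min = 30)
  got <- dplyr::arrange(tibble::as_tibble(built$pools$pos), l3, h1, h2, h3)
  want <- dplyr::arrange(tibble::as_tibble(sim$pos), l3, h1, h2, h3)
  expect_equal(got, want, ignore_attr = TRUE)
  expect_equal(built$report$pos$low_quality, 0)
  expect_equal(sum(discard_report(built$pools$pos)), 0)
})

test_that("assembly rejects missing anchors and inconsistent overlaps", {
  d <- toy_design()
  pool <- make_pool("YW", count = 1, l3 = "YSG", h1 = "YS", h2 = "SS")
  dir <- withr::local_tempdir()
  paths <- emit_read_trios(pool, d, dir, barcode = "ACGTAA", seed = 2)
  trios <- read_fastq_trios(paths$pe1, paths$pe2, paths$custom)
  ok <- assemble_trios(trios, d, barcode_length = 6)
  expect_equal(ok$status, "ok")
  expect_equal(translate_cdr(ok$l3_nt), "YSG")
  expect_equal(translate_cdr(ok$h3_nt), "YW")

  broken <- trios
  broken$pe2_seq <- sub("TTCGGCCA", "TTCGACCA", broken$pe2_seq) # L3 right anchor
  r1 <- assemble_trios(broken, d, barcode_length = 6)
  expect_equal(r1$reason, "anchor_not_found")

  # corrupt the PE2 overhang into H1 so the two reads disagree
  clash <- trios
  n <- nchar(clash$pe2_seq)
  ch <- substr(clash$pe2_seq, n, n)
  substr(clash$pe2_seq, n, n) <- setdiff(c("A", "C", "G", "T"), ch)[1]
  r2 <- assemble_trios(clash, d, barcode_length = 6)
  expect_equal(r2$reason, "inconsistent_overlap")
})

test_that("read counts are conserved through every pipeline stage", {
  d <- toy_design()
  sim <- simulate_pools(simulation_config(
    design = d, n_specific_families = 0, n_background = 30,
    abundance_range = c(1e-3, 0.2), reads_per_pool = 300,
    chimera_rate = 0, seed = 13
  ))
  dir <- withr::local_tempdir()
  paths <- emit_read_trios(sim$pos, d, dir,
    barcode = "ACGTAA", seed = 4,
    error_rate = 0.01, low_q_rate = 0.01
  )
  trios <- read_fastq_trios(paths$pe1, paths$pe2, paths$custom)
  map <- tibble::tibble(barcode = "ACGTAA", pool_name = "pos", label = "positive")
  built <- build_pools_from_fastq(trios, d, map, q_min = 30)
  rep <- built$report$pos
  accounted <- rep$low_quality +
    sum(unlist(rep$assembly_rejects)) +
    sum(unlist(rep$design_discards)) +
    rep$pooled
  expect_equal(accounted + built$report$unassigned, nrow(trios))
  # with base-call errors some reads must fail design validation
  expect_gt(sum(unlist(rep$assembly_rejects)) + sum(unlist(rep$design_discards)), 0)
})
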