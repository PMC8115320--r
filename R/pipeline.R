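#' Pipeline run configuration
#'
#' Bundles the inputs and every module threshold for an end-to-end run:
#' pool sources (pre-built tables or a simulation config), the library
#' design, the per-base quality floor (Q = 30), the motif constraints
#' (support 100, wildcard fraction 0.55), the decision thresholds
#' (p < 1e-10, d > 2), the enrichment quadrant (count > 200, fold > 4)
#' and the family identity threshold (0.80). Round-trips losslessly
#' through [write_run_config()] / [read_run_config()].
#'
#' @param pos_table,neg_table Paths to pool TSVs (ignored when
#'   `simulation` is given).
#' @param simulation Optional [simulation_config()]; the run then starts
#'   from simulated pools and keeps the truth table.
#' @param design A `library_design` (defaults to the bundled design).
#' @param q_min,min_support,max_wildcard_fraction,p_cut,d_cut,min_count,min_fold,identity_threshold
#'   Module thresholds, each at its documented default.
#' @param filter_chimeras Run the pair filter before scoring (default
#'   `TRUE`).
#' @param candidates `NULL` to score every positive-pool clone, or a data
#'   frame of paratopes to score.
#' @param seed Integer seed.
#' @param outdir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(pos_table = NULL, neg_table = NULL, simulation = NULL,
                       design = default_design(),
                       q_min = 30, min_support = 100,
                       max_wildcard_fraction = 0.55,
                       p_cut = 1e-10, d_cut = 2,
                       min_count = 200, min_fold = 4,
                       identity_threshold = 0.80,
                       filter_chimeras = TRUE,
                       candidates = NULL,
                       seed = 1, outdir = tempfile("phagemotifs_run_")) {
  stopifnot(
    q_min >= 0, min_support >= 1,
    max_wildcard_fraction >= 0, max_wildcard_fraction < 1,
    p_cut > 0, p_cut <= 1, identity_threshold > 0, identity_threshold <= 1
  )
  if (is.null(simulation) && (is.null(pos_table) || is.null(neg_table))) {
    stop("either pool tables or a simulation config is required")
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full discovery pipeline
#'
#' Executes pool loading (or simulation), pair filtering, motif-based
#' specificity scoring, enrichment-quadrant ranking and homolog-family
#' clustering, writing every stage product (pool tables, removal report,
#' clone report, scatter table) plus a provenance log with per-stage
#' record counts to the configured output directory. Reruns with the same
#' config are deterministic.
#'
#' @param config A [run_config()].
#' @return (Invisibly) a `pipeline_result` list: `pools` (raw),
#'   `filtered`, `report` (clone-level tibble with family assignments),
#'   `quadrant`, `truth` (simulations only), `provenance`, `outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$outdir)) dir.create(config$outdir, recursive = TRUE)
  prov <- list(
    seed = config$seed,
    thresholds = config[c(
      "q_min", "min_support", "max_wildcard_fraction", "p_cut", "d_cut",
      "min_count", "min_fold", "identity_threshold", "filter_chimeras"
    )],
    stages = list()
  )
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf(
        "pipeline stage '%s' failed after stages [%s]: %s",
        name, paste(names(prov$stages), collapse = ", "), conditionMessage(e)
      ), call. = FALSE)
    })
    res
  }

  truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- stage("simulate", simulate_pools(config$simulation))
    pos <- sim$pos
    neg <- sim$neg
    truth <- sim$truth
    readr::write_tsv(truth, file.path(config$outdir, "truth.tsv"), progress = FALSE)
  } else {
    pos <- stage("load_pools", read_pool_table(config$pos_table, "positive"))
    neg <- stage("load_pools", read_pool_table(config$neg_table, "negative"))
  }
  prov$stages$pools <- list(unique_pos = nrow(pos), unique_neg = nrow(neg),
                            reads_pos = pool_total_reads(pos),
                            reads_neg = pool_total_reads(neg))
  write_pool_table(pos, file.path(config$outdir, "pool_pos_raw.tsv"))
  write_pool_table(neg, file.path(config$outdir, "pool_neg_raw.tsv"))

  if (isTRUE(config$filter_chimeras)) {
    pos_f <- stage("filter_pairs", filter_pairs(pos))
    neg_f <- stage("filter_pairs", filter_pairs(neg))
    removed <- list(
      positive = nrow(pair_filter_report(pos_f)),
      negative = nrow(pair_filter_report(neg_f))
    )
    jsonlite::write_json(removed, file.path(config$outdir, "pair_filter_removed.json"),
      auto_unbox = TRUE
    )
    # Conservation check: filtering removes whole clones, never partial reads.
    stopifnot(
      pool_total_reads(pos_f) + sum(pair_filter_report(pos_f)$count) ==
        pool_total_reads(pos)
    )
  } else {
    pos_f <- pos
    neg_f <- neg
    removed <- list(positive = 0L, negative = 0L)
  }
  prov$stages$pair_filter <- c(removed,
    list(unique_pos = nrow(pos_f), unique_neg = nrow(neg_f))
  )
  write_pool_table(pos_f, file.path(config$outdir, "pool_pos_filtered.tsv"))
  write_pool_table(neg_f, file.path(config$outdir, "pool_neg_filtered.tsv"))

  constraints <- motif_constraints(
    max_wildcard_fraction = config$max_wildcard_fraction,
    min_positive_support = config$min_support
  )
  report <- stage("score", score_pool(
    pos_f, neg_f,
    candidates = config$candidates,
    constraints = constraints, p_cut = config$p_cut, d_cut = config$d_cut
  ))
  prov$stages$score <- list(
    candidates = nrow(report),
    specific = sum(report$specific),
    unscorable = sum(report$unscorable)
  )

  quadrant <- stage("rank", enrichment_quadrant(
    pos_f, neg_f,
    min_count = config$min_count, min_fold = config$min_fold
  ))
  readr::write_tsv(tibble::as_tibble(quadrant),
    file.path(config$outdir, "enrichment_scatter.tsv"),
    progress = FALSE
  )
  prov$stages$rank <- list(in_quadrant = sum(quadrant$in_quadrant))

  report$family <- NA_integer_
  if (any(report$specific)) {
    fams <- stage("cluster", cluster_families(
      report[report$specific, , drop = FALSE],
      identity_threshold = config$identity_threshold
    ))
    report$family[report$specific] <- fams$family
  }
  prov$stages$cluster <- list(
    families = length(unique(stats::na.omit(report$family)))
  )
  readr::write_tsv(report, file.path(config$outdir, "clone_report.tsv"),
    progress = FALSE
  )
  jsonlite::write_json(prov, file.path(config$outdir, "provenance.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(structure(
    list(
      pools = list(pos = pos, neg = neg),
      filtered = list(pos = pos_f, neg = neg_f),
      report = report, quadrant = quadrant, truth = truth,
      provenance = prov, outdir = config$outdir
    ),
    class = "pipeline_result"
  ))
}

#' Compare pipeline arms run with and without chimera filtering
#'
#' Summarizes the before/after-filter contrast: unique-sequence counts per
#' pool, number of predicted (specific) candidates, and number of homolog
#' families in each arm.
#'
#' @param filtered,unfiltered `pipeline_result`s from [run_pipeline()]
#'   with `filter_chimeras = TRUE` and `FALSE` respectively.
#' @return A tibble with one row per arm.
#' @export
compare_methods <- function(filtered, unfiltered) {
  if (missing(filtered) || missing(unfiltered)) stop("both arms are required")
  one <- function(res, arm) {
    tibble::tibble(
      arm = arm,
      unique_pos = nrow(res$filtered$pos),
      unique_neg = nrow(res$filtered$neg),
      n_predicted = sum(res$report$specific),
      n_families = length(unique(stats::na.omit(res$report$family)))
    )
  }
  dplyr::bind_rows(one(unfiltered, "before_filter"), one(filtered, "after_filter"))
}

#' @rdname run_config
#' @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  flat <- config[setdiff(names(config), c("design", "simulation", "candidates"))]
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path, design = default_design()) {
  flat <- yaml::read_yaml(path)
  do.call(run_config, c(flat, list(design = design)))
}
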