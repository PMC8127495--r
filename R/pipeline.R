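# End-to-end run: clump (or threshold) -> all pairs -> optional coloc,
# with a reproducible run report.

#' Run configuration
#'
#' Collects every threshold of an end-to-end run. All values are echoed into
#' the run report. Unknown keys are rejected.
#'
#' @param population ancestry tag (`EUR`, `AFR`, `ASN`, or custom).
#' @param constants N_e table (see [population_constants()]).
#' @param query_p1 index threshold for the query trait (default 1e-5).
#' @param catalog_p1 index threshold for catalog traits (default 5e-8).
#' @param clump_p2,clump_r2,clump_kb clumping parameters.
#' @param r2_cutoff r-squared cutoff for proxy sharing (default 0.4).
#' @param r2_comparison `">"` (default) or `">="`.
#' @param fdr BH significance level (default 0.1).
#' @param m_override optional number of comparisons for correction.
#' @param coloc_priors priors for the colocalization stage.
#' @param n_coloc colocalize the top `n_coloc` shared blocks of the best
#'   pair when effect data allow (default 0 = skip).
#' @param coloc_window_bp colocalization window half-width.
#' @param workers parallel workers.
#' @param seed integer seed recorded in the report.
#' @return an object of class `run_config`.
#' @export
run_config <- function(population = "EUR", constants = population_constants(),
                       query_p1 = 1e-5, catalog_p1 = 5e-8, clump_p2 = 1,
                       clump_r2 = 0.4, clump_kb = 1000, r2_cutoff = 0.4,
                       r2_comparison = c(">", ">="), fdr = 0.1,
                       m_override = NULL, coloc_priors = pleioscan::coloc_priors(),
                       n_coloc = 0L, coloc_window_bp = 200000, workers = 1L,
                       seed = 1L) {
  r2_comparison <- match.arg(r2_comparison)
  cfg <- list(population = population, constants = constants,
              query_p1 = query_p1, catalog_p1 = catalog_p1,
              clump_p2 = clump_p2, clump_r2 = clump_r2, clump_kb = clump_kb,
              r2_cutoff = r2_cutoff, r2_comparison = r2_comparison, fdr = fdr,
              m_override = m_override, coloc_priors = coloc_priors,
              n_coloc = n_coloc, coloc_window_bp = coloc_window_bp,
              workers = workers, seed = seed)
  structure(cfg, class = "run_config")
}

#' Read a key=value configuration file into a run_config
#'
#' Plain-text `key = value` lines (``#`` comments allowed). Keys must be
#' [run_config()] argument names; unknown keys are a configuration error.
#'
#' @param path file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("File not found: %s", path))
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) abort_config("Malformed configuration line(s); expect key = value.")
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- vapply(kv, `[[`, character(1), 2)
  allowed <- setdiff(names(formals(run_config)), c("constants", "coloc_priors"))
  unknown <- setdiff(keys, c(allowed, "coloc_p1", "coloc_p2", "coloc_p12"))
  if (length(unknown)) {
    abort_config(sprintf("Unknown configuration key(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  args <- list()
  pri <- list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5)
  for (i in seq_along(keys)) {
    key <- keys[i]; val <- vals[i]
    if (key %in% c("coloc_p1", "coloc_p2", "coloc_p12")) {
      pri[[sub("coloc_", "", key)]] <- as.numeric(val)
    } else if (key %in% c("population", "r2_comparison")) {
      args[[key]] <- val
    } else if (key %in% c("workers", "n_coloc", "seed")) {
      args[[key]] <- as.integer(val)
    } else {
      args[[key]] <- as.numeric(val)
    }
  }
  args$coloc_priors <- coloc_priors(pri$p1, pri$p2, pri$p12)
  do.call(run_config, args)
}

loci_from_stats <- function(stats, p1, ld, config) {
  if (isTRUE(attr(stats, "is_clumped"))) {
    apply_threshold(stats, p1)
  } else {
    ld_clump(stats, ld, clump_config(p1 = p1, p2 = config$clump_p2,
                                     r2 = config$clump_r2,
                                     kb = config$clump_kb))
  }
}

#' Run the full cross-phenotype pipeline
#'
#' Clumps the query (or thresholds it when pre-clumped), does the same for
#' every catalog trait, runs the all-pairs cross-phenotype analysis, and
#' optionally colocalizes the top shared blocks of the best pair. Writes
#' `pairs.tsv`, `blocks.tsv`, `coloc.tsv` and `report.json` into `out_dir`.
#'
#' @param query a `gwas_sumstats`, or path to one (read with `query_config`).
#' @param catalog named list of `gwas_sumstats`, or path to a long-format
#'   catalog file.
#' @param ld a `proxy_table`, or path to a stored one.
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing); `NULL` skips file
#'   output.
#' @param query_config,catalog_config [column_config()]s used when `query` /
#'   `catalog` are paths.
#' @return list with `pairs` (a `cpag_result`), `coloc` (list of
#'   `coloc_result`, possibly empty), and `report` (the run report, also
#'   serialized as JSON).
#' @export
run_pipeline <- function(query, catalog, ld, config = run_config(),
                         out_dir = NULL, query_config = column_config(),
                         catalog_config = column_config(trait = "trait")) {
  if (is.character(query)) {
    query <- read_summary_stats(query, query_config)
  }
  if (is.character(catalog)) {
    catalog <- read_catalog(catalog, catalog_config)
  }
  if (is.character(ld)) ld <- read_proxy_table(ld)
  stopifnot(inherits(ld, "proxy_table"))
  query_loci <- loci_from_stats(query, config$query_p1, ld, config)
  if (nrow(query_loci) == 0L) {
    abort_data("Query trait has no lead SNPs after clumping/thresholding.")
  }
  catalog_loci <- lapply(catalog, loci_from_stats, p1 = config$catalog_p1,
                         ld = ld, config = config)
  catalog_loci <- catalog_loci[vapply(catalog_loci, nrow, integer(1)) > 0]
  if (length(catalog_loci) == 0L) {
    abort_data("No catalog trait has lead SNPs at the catalog threshold.")
  }
  pairs <- cpag_all_pairs(catalog_loci, ld, population = config$population,
                          constants = config$constants, query = list(query_loci),
                          fdr = config$fdr, m = config$m_override,
                          workers = config$workers)
  coloc_out <- list()
  if (config$n_coloc > 0 && nrow(pairs) > 0 && pairs$k[1] > 0) {
    top <- pairs[1, ]
    partner <- catalog[[top$trait2]]
    block_leads <- strsplit(strsplit(top$shared_snps, ";")[[1]], "\\|")
    block_leads <- vapply(block_leads, `[[`, character(1), 1)
    block_leads <- utils::head(block_leads, config$n_coloc)
    for (lead in block_leads) {
      res <- tryCatch(
        coloc_abf(extract_region(query, partner, lead,
                                 window_bp = config$coloc_window_bp),
                  config$coloc_priors),
        error = function(e) NULL)
      if (!is.null(res)) coloc_out[[lead]] <- res
    }
  }
  report <- list(
    config = config[setdiff(names(config), c("constants", "coloc_priors"))],
    coloc_priors = unclass(config$coloc_priors),
    n_e = lookup_n_e(config$constants, config$population),
    query_trait = attr(query_loci, "trait_id"),
    query_pre_clumped = isTRUE(attr(query, "is_clumped")),
    query_leads = nrow(query_loci),
    query_report = attr(query, "report"),
    catalog_traits = length(catalog_loci),
    pairs_tested = nrow(pairs),
    m = attr(pairs, "m"),
    significant_pairs = sum(pairs$significant),
    coloc_regions = length(coloc_out),
    ld_population = attr(ld, "population"),
    ld_r2_min = attr(ld, "r2_min"),
    ld_comparison = attr(ld, "comparison"),
    package_version = as.character(utils::packageVersion("pleioscan"))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pair_results(pairs, file.path(out_dir, "pairs.tsv"))
    blocks_df <- tidyr::separate_rows(
      dplyr::select(tibble::as_tibble(pairs), "trait1", "trait2",
                    "shared_snps"),
      "shared_snps", sep = ";")
    readr::write_tsv(blocks_df[blocks_df$shared_snps != "", ],
                     file.path(out_dir, "blocks.tsv"), progress = FALSE)
    coloc_df <- if (length(coloc_out)) {
      dplyr::bind_rows(lapply(coloc_out, function(x) x$summary))
    } else {
      tibble::tibble(trait1 = character(), trait2 = character(),
                     lead = character(), nsnps = integer(), pp0 = numeric(),
                     pp1 = numeric(), pp2 = numeric(), pp3 = numeric(),
                     pp4 = numeric(), lead_causal_snp = character())
    }
    readr::write_tsv(coloc_df, file.path(out_dir, "coloc.tsv"),
                     progress = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  list(pairs = pairs, coloc = coloc_out, report = report)
}
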