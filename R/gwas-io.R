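# Reading and writing GWAS summary statistics and association catalogs.

#' Declare the column layout of a summary-statistics file
#'
#' Maps the columns of a delimited text file onto the fields the package
#' understands. `rsid` and `p` are mandatory; the rest are optional and may be
#' `NULL` when the file does not carry them.
#'
#' @param rsid,p names of the mandatory rsID and p-value columns.
#' @param chrom,pos,beta,se,effect_allele,maf optional column names.
#' @param trait optional trait column (used by [read_catalog()]).
#' @param delim field delimiter (default tab).
#' @param header does the file carry a header line?
#' @return an object of class `column_config`.
#' @examples
#' column_config(rsid = "SNP", p = "P", delim = ",")
#' @export
column_config <- function(rsid = "rsid", p = "p", chrom = NULL, pos = NULL,
                          beta = NULL, se = NULL, effect_allele = NULL,
                          maf = NULL, trait = NULL, delim = "\t",
                          header = TRUE) {
  cfg <- list(rsid = rsid, p = p, chrom = chrom, pos = pos, beta = beta,
              se = se, effect_allele = effect_allele, maf = maf,
              trait = trait, delim = delim, header = header)
  for (fld in c("rsid", "p")) {
    if (!is.character(cfg[[fld]]) || length(cfg[[fld]]) != 1L) {
      abort_config(sprintf("column_config: `%s` must be a single column name.", fld))
    }
  }
  structure(cfg, class = "column_config")
}

new_sumstats <- function(df, trait_id, source = "user", is_clumped = FALSE,
                         report = list()) {
  need <- c("rsid", "chrom", "pos", "log_p", "beta", "se", "effect_allele", "maf")
  for (col in setdiff(need, names(df))) {
    df[[col]] <- if (col %in% c("rsid", "chrom", "effect_allele")) {
      NA_character_
    } else {
      NA_real_
    }
  }
  df <- tibble::as_tibble(df)[, need]
  df$pos <- as.numeric(df$pos)
  structure(df, class = c("gwas_sumstats", class(tibble::tibble())),
            trait_id = trait_id, source = source, is_clumped = is_clumped,
            report = report)
}

#' Construct summary statistics from a data frame
#'
#' Programmatic counterpart of [read_summary_stats()] for data already in
#' memory. Accepts a `p` column (numeric or character) or a ready-made
#' `log_p` column; applies the same validation and duplicate-rsID policy
#' (keep the record with the smallest p).
#'
#' @param df data frame with at least `rsid` and `p` (or `log_p`).
#' @param trait_id trait identifier.
#' @param source free-text source tag.
#' @param is_clumped set `TRUE` when rows are already independent lead SNPs.
#' @return a `gwas_sumstats` tibble; parsing/dedup counts are in
#'   `attr(x, "report")`.
#' @examples
#' summary_stats(data.frame(rsid = c("rs1", "rs2"), p = c(1e-9, 0.2)), "trait A")
#' @export
summary_stats <- function(df, trait_id, source = "user", is_clumped = FALSE) {
  df <- tibble::as_tibble(df)
  if (!"rsid" %in% names(df)) abort_config("summary_stats: missing `rsid` column.")
  if (!"log_p" %in% names(df)) {
    if (!"p" %in% names(df)) {
      abort_config("summary_stats: need a `p` or `log_p` column.")
    }
    df$log_p <- parse_log_p(df$p)
  }
  n_in <- nrow(df)
  df <- dplyr::filter(df, !is.na(.data$log_p))
  n_bad <- n_in - nrow(df)
  if ("chrom" %in% names(df)) {
    df$chrom <- sub("^chr", "", as.character(df$chrom))
  }
  # duplicate rsIDs: keep the smallest p (lead-signal semantics)
  n_pre <- nrow(df)
  df <- df |>
    dplyr::arrange(.data$log_p) |>
    dplyr::distinct(.data$rsid, .keep_all = TRUE)
  n_dup <- n_pre - nrow(df)
  df <- dplyr::arrange(df, .data$log_p, .data$rsid)
  rep <- list(rows_read = n_in, rows_dropped = n_bad, rows_deduplicated = n_dup,
              dedup_rule = "min_p")
  new_sumstats(df, trait_id = trait_id, source = source,
               is_clumped = is_clumped, report = rep)
}

#' Read one trait's GWAS summary statistics
#'
#' Reads a delimited text file under a user-declared [column_config()]. Rows
#' whose p-value cannot be parsed (or is outside `(0, 1]`) are dropped and
#' counted; duplicate rsIDs keep the record with the smallest p. p-values are
#' stored as natural logs so magnitudes such as 1e-195 survive intact.
#'
#' @param path file path.
#' @param config a [column_config()].
#' @param trait_id trait identifier (defaults to the file name).
#' @param source free-text source tag.
#' @return a `gwas_sumstats` tibble with columns `rsid`, `chrom`, `pos`,
#'   `log_p`, `beta`, `se`, `effect_allele`, `maf` and a parsing report in
#'   `attr(x, "report")`.
#' @export
read_summary_stats <- function(path, config = column_config(),
                               trait_id = basename(path), source = "user") {
  if (!file.exists(path)) abort_data(sprintf("File not found: %s", path))
  raw <- readr::read_delim(path, delim = config$delim,
                           col_names = config$header,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0L) abort_data(sprintf("Empty input file: %s", path))
  mapped <- map_columns(raw, config)
  summary_stats(mapped, trait_id = trait_id, source = source)
}

map_columns <- function(raw, config) {
  for (fld in c("rsid", "p")) {
    if (!config[[fld]] %in% names(raw)) {
      abort_config(sprintf("Mandatory column `%s` (mapped to %s) not found in file header.",
                           config[[fld]], fld))
    }
  }
  opt <- c("chrom", "pos", "beta", "se", "effect_allele", "maf", "trait")
  for (fld in opt) {
    if (!is.null(config[[fld]]) && !config[[fld]] %in% names(raw)) {
      abort_config(sprintf("Declared column `%s` (mapped to %s) not found in file header.",
                           config[[fld]], fld))
    }
  }
  out <- tibble::tibble(rsid = raw[[config$rsid]], p = raw[[config$p]])
  grab <- function(fld) if (is.null(config[[fld]])) NULL else raw[[config[[fld]]]]
  if (!is.null(config$chrom)) out$chrom <- grab("chrom")
  if (!is.null(config$pos)) out$pos <- as.numeric(grab("pos"))
  if (!is.null(config$beta)) out$beta <- as.numeric(grab("beta"))
  if (!is.null(config$se)) out$se <- as.numeric(grab("se"))
  if (!is.null(config$effect_allele)) out$effect_allele <- grab("effect_allele")
  if (!is.null(config$maf)) out$maf <- as.numeric(grab("maf"))
  if (!is.null(config$trait)) out$trait <- grab("trait")
  out
}

#' Read an association catalog (long format)
#'
#' A catalog is a long table with one row per trait-SNP association
#' (`trait`, `rsid`, `p`, optional `chrom`/`pos`). One `gwas_sumstats` object
#' is returned per distinct trait, with the same per-trait duplicate policy
#' as [read_summary_stats()].
#'
#' @param path file path.
#' @param config a [column_config()] whose `trait` field must be set.
#' @param source source tag recorded on every trait.
#' @param is_clumped whether catalog entries are already lead SNPs.
#' @return named list of `gwas_sumstats`, keyed by trait.
#' @export
read_catalog <- function(path, config = column_config(trait = "trait"),
                         source = basename(path), is_clumped = TRUE) {
  if (is.null(config$trait)) {
    abort_config("read_catalog: `config$trait` must name the trait column.")
  }
  if (!file.exists(path)) abort_data(sprintf("File not found: %s", path))
  raw <- readr::read_delim(path, delim = config$delim,
                           col_names = config$header,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  mapped <- map_columns(raw, config)
  mapped <- dplyr::filter(mapped, !is.na(.data$trait), .data$trait != "")
  traits <- unique(mapped$trait)
  if (length(traits) == 0L) abort_data("Catalog contains zero traits.")
  out <- lapply(traits, function(tr) {
    summary_stats(dplyr::select(mapped[mapped$trait == tr, ], -"trait"),
                  trait_id = tr, source = source, is_clumped = is_clumped)
  })
  names(out) <- traits
  out
}

pair_result_columns <- c("trait1", "trait2", "n1", "n2", "k", "k_direct",
                         "k_indirect", "p_fisher", "p_bh", "p_bonferroni",
                         "jaccard", "sorensen", "chao_sorensen",
                         "fold_enrichment", "shared_snps")

#' Write trait-pair results to a delimited file
#'
#' One row per trait pair, sorted by ascending enrichment p. The p-value
#' columns are serialized from the log representation, so values below 1e-300
#' appear in scientific notation rather than as 0. The `shared_snps` column
#' packs the member SNPs of each shared block (`|` within a block, `;`
#' between blocks). Round-trips through [read_pair_results()].
#'
#' @param results a `cpag_result` (see [cpag_all_pairs()]).
#' @param path output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_pair_results <- function(results, path) {
  df <- tibble::as_tibble(results)
  if (nrow(df) == 0L) {
    out <- tibble::as_tibble(sapply(pair_result_columns, function(x) {
      if (x %in% c("trait1", "trait2", "shared_snps",
                   "p_fisher", "p_bh", "p_bonferroni")) character() else numeric()
    }, simplify = FALSE))
    readr::write_tsv(out, path, progress = FALSE)
    return(invisible(path))
  }
  df <- dplyr::arrange(df, .data$log_p_fisher)
  out <- tibble::tibble(
    trait1 = df$trait1 %||% character(),
    trait2 = df$trait2 %||% character(),
    n1 = df$n1 %||% integer(), n2 = df$n2 %||% integer(),
    k = df$k %||% integer(), k_direct = df$k_direct %||% integer(),
    k_indirect = df$k_indirect %||% integer(),
    p_fisher = format_log_p(df$log_p_fisher %||% numeric()),
    p_bh = format_log_p(df$log_p_bh %||% numeric()),
    p_bonferroni = format_log_p(df$log_p_bonferroni %||% numeric()),
    jaccard = df$jaccard %||% numeric(),
    sorensen = df$sorensen %||% numeric(),
    chao_sorensen = df$chao_sorensen %||% numeric(),
    fold_enrichment = df$fold_enrichment %||% numeric(),
    shared_snps = df$shared_snps %||% character()
  )
  ok <- tryCatch({
    readr::write_tsv(out, path, progress = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort_data(sprintf("Cannot write results to %s", path))
  invisible(path)
}

#' Read back a trait-pair results table
#'
#' Companion reader for [write_pair_results()]; reconstructs the log-scale
#' p-value columns via [parse_log_p()].
#'
#' @param path file written by [write_pair_results()].
#' @return tibble with the pair-result schema plus `log_p_*` columns.
#' @export
read_pair_results <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    trait1 = "c", trait2 = "c", n1 = "i", n2 = "i", k = "i",
    k_direct = "i", k_indirect = "i", p_fisher = "c", p_bh = "c",
    p_bonferroni = "c", jaccard = "d", sorensen = "d", chao_sorensen = "d",
    fold_enrichment = "d", shared_snps = "c"), progress = FALSE,
    show_col_types = FALSE)
  df$shared_snps[is.na(df$shared_snps)] <- ""
  df$log_p_fisher <- parse_log_p(df$p_fisher)
  df$log_p_bh <- parse_log_p(df$p_bh)
  df$log_p_bonferroni <- parse_log_p(df$p_bonferroni)
  df
}

#' @export
print.gwas_sumstats <- function(x, ...) {
  cat(sprintf("<gwas_sumstats> trait: %s | source: %s | %d records%s\n",
              attr(x, "trait_id"), attr(x, "source"), nrow(x),
              if (isTRUE(attr(x, "is_clumped"))) " (clumped)" else ""))
  NextMethod()
}
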