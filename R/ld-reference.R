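# Ancestry-specific LD reference: haplotype panels, r2, proxy tables.

#' 1000 Genomes-style population presets
#'
#' Sample counts and member populations for the three ancestry groups the
#' LD reference is usually built from. Metadata only; no genotypes ship with
#' the package.
#'
#' @return tibble with `population`, `n_samples`, `members`.
#' @export
population_presets <- function() {
  tibble::tibble(
    population = c("EUR", "AFR", "ASN"),
    n_samples = c(503L, 661L, 504L),
    members = c("CEU,TSI,FIN,GBR,IBS",
                "YRI,LWK,GWD,MSL,ESN,ASW,ACB",
                "CHB,JPT,CHS,CDX,KHV")
  )
}

new_haplotype_panel <- function(variants, haplotypes, phased, population) {
  stopifnot(nrow(variants) == ncol(haplotypes))
  structure(list(variants = tibble::as_tibble(variants),
                 haplotypes = haplotypes, phased = phased,
                 population = population),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %s | %d variants x %d haplotypes (%s)\n",
              x$population, nrow(x$variants), nrow(x$haplotypes),
              if (x$phased) "phased" else "unphased"))
  invisible(x)
}

panel_allele_stats <- function(haplotypes) {
  n <- nrow(haplotypes)
  miss <- colMeans(is.na(haplotypes))
  af <- colMeans(haplotypes, na.rm = TRUE)
  af[is.nan(af)] <- NA_real_
  tibble::tibble(maf = pmin(af, 1 - af), missing_rate = miss)
}

#' Read a phased haplotype panel from VCF
#'
#' Parses GT fields with VariantAnnotation. Phased genotypes (`a|b`) are split
#' into two haplotypes per sample; if any genotype is unphased the panel is
#' tagged unphased and r-squared computations fall back to genotype-dosage
#' correlation. Missing alleles (`.`) become `NA`. Multi-allelic records are
#' dropped.
#'
#' @param path VCF file (plain or gzip).
#' @param population population tag (e.g. `"EUR"`).
#' @return a `haplotype_panel`: variant tibble (`rsid`, `chrom`, `pos`, `ref`,
#'   `alt`, `maf`, `missing_rate`) plus a haplotype matrix (rows =
#'   2 x samples).
#' @export
read_haplotype_panel <- function(path, population = "custom") {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    abort_config("read_haplotype_panel requires the VariantAnnotation package.")
  }
  if (!file.exists(path)) abort_data(sprintf("File not found: %s", path))
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  alt_chr <- vapply(seq_along(alt), function(i) {
    a <- as.character(alt[[i]])
    if (length(a) == 1L) a else NA_character_
  }, character(1))
  keep <- !is.na(alt_chr)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) abort_data("VCF has no GT field.")
  gt <- gt[keep, , drop = FALSE]
  phased <- !any(grepl("/", gt, fixed = TRUE))
  # rows: variants, cols: samples -> haplotype matrix (2*samples x variants)
  a1 <- sub("^([^|/]*)[|/].*$", "\\1", gt)
  a2 <- sub("^[^|/]*[|/](.*)$", "\\1", gt)
  to_int <- function(m) {
    v <- suppressWarnings(as.integer(m))
    matrix(v, nrow = nrow(m), ncol = ncol(m))
  }
  h <- rbind(t(to_int(a1)), t(to_int(a2)))
  variants <- tibble::tibble(
    rsid = names(rr)[keep],
    chrom = sub("^chr", "", as.character(GenomeInfoDb::seqnames(rr)))[keep],
    pos = BiocGenerics::start(rr)[keep],
    ref = as.character(VariantAnnotation::ref(vcf))[keep],
    alt = alt_chr[keep]
  )
  variants <- dplyr::bind_cols(variants, panel_allele_stats(h))
  new_haplotype_panel(variants, h, phased, population)
}

#' Filter a haplotype panel
#'
#' Applies the reference-panel variant filters: keep biallelic variants with
#' minor allele frequency at least `maf_min` and missingness at most
#' `missing_max`; merge records sharing identical (chrom, pos) to the first
#' occurrence; among duplicated rsIDs keep only the first.
#'
#' @param panel a `haplotype_panel`.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param missing_max maximum missing-allele fraction (default 0.1).
#' @return filtered `haplotype_panel` (a warning, not an error, if everything
#'   is removed).
#' @export
filter_panel <- function(panel, maf_min = 0.01, missing_max = 0.1) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (nrow(panel$variants) == 0L) abort_data("filter_panel: empty panel.")
  v <- panel$variants
  stats <- panel_allele_stats(panel$haplotypes)
  v$maf <- stats$maf
  v$missing_rate <- stats$missing_rate
  keep <- !is.na(v$maf) & v$maf >= maf_min & v$missing_rate <= missing_max
  idx <- which(keep)
  v2 <- v[idx, ]
  # merge identical coordinates (keep first), then dedup rsIDs (keep first)
  first_pos <- !duplicated(paste(v2$chrom, v2$pos))
  idx <- idx[first_pos]; v2 <- v2[first_pos, ]
  first_id <- !duplicated(v2$rsid)
  idx <- idx[first_id]; v2 <- v2[first_id, ]
  if (length(idx) == 0L) {
    rlang::warn("filter_panel: all variants removed by filters.")
  }
  new_haplotype_panel(v2, panel$haplotypes[, idx, drop = FALSE],
                      panel$phased, panel$population)
}

#' Haplotype r-squared between two variants
#'
#' Squared LD correlation from phased haplotype frequencies:
#' `r2 = D^2 / (pa (1 - pa) pb (1 - pb))` with `D = p_ab - pa * pb`. Missing
#' entries are excluded pairwise. For unphased data pass `phased = FALSE` to
#' use squared genotype-dosage correlation instead.
#'
#' @param a,b binary allele vectors over the same haplotype set (or dosage
#'   vectors when `phased = FALSE`).
#' @param phased interpret inputs as phased haplotypes (default).
#' @return r-squared in `[0, 1]`, or `NA` when either variant is monomorphic
#'   among the jointly observed entries.
#' @examples
#' compute_r2(c(1, 1, 1, 1, 0, 0, 0, 0), c(1, 1, 1, 0, 0, 0, 0, 0))  # 0.6
#' @export
compute_r2 <- function(a, b, phased = TRUE) {
  if (length(a) != length(b)) {
    abort_contract("compute_r2: vectors must have equal length.")
  }
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) == 0L) return(NA_real_)
  if (phased) {
    pa <- mean(a); pb <- mean(b)
    if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
    pab <- mean(a * b)
    d <- pab - pa * pb
    r2 <- d^2 / (pa * (1 - pa) * pb * (1 - pb))
  } else {
    if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
    r2 <- stats::cor(a, b)^2
  }
  min(max(r2, 0), 1)
}

new_proxy_table <- function(pairs, population, r2_min, comparison, estimator) {
  structure(tibble::as_tibble(pairs),
            class = c("proxy_table", class(tibble::tibble())),
            population = population, r2_min = r2_min,
            comparison = comparison, estimator = estimator)
}

#' Build an LD proxy table from a haplotype panel
#'
#' Computes r-squared for every same-chromosome variant pair lying within both
#' the physical window (`window_kb`) and the SNP-count window (`window_snps`),
#' and retains pairs whose r-squared clears `r2_min`. The comparison operator
#' defaults to strict `>` and is recorded on the table. Output is
#' deterministic: variants are ordered by (chrom, pos, rsid) before pairing,
#' and each pair is stored once with `rsid_a < rsid_b` lexicographically.
#'
#' @param panel a (filtered) `haplotype_panel`.
#' @param window_kb physical half-window in kilobases (default 1000).
#' @param window_snps maximum number of intervening SNP positions; pairs more
#'   than `window_snps - 1` index positions apart are skipped (default 10000).
#' @param r2_min retention cutoff (default 0.4).
#' @param comparison `">"` (strict, default) or `">="`.
#' @return a `proxy_table` tibble (`rsid_a`, `rsid_b`, `r2`) with metadata in
#'   attributes.
#' @export
build_proxy_table <- function(panel, window_kb = 1000, window_snps = 10000,
                              r2_min = 0.4, comparison = c(">", ">=")) {
  stopifnot(inherits(panel, "haplotype_panel"))
  comparison <- match.arg(comparison)
  v <- panel$variants
  ord <- order(v$chrom, v$pos, v$rsid)
  v <- v[ord, ]
  h <- panel$haplotypes[, ord, drop = FALSE]
  if (!panel$phased) {
    ns <- nrow(h) / 2
    h <- h[seq_len(ns), , drop = FALSE] + h[ns + seq_len(ns), , drop = FALSE]
  }
  res <- list()
  for (chr in unique(v$chrom)) {
    ci <- which(v$chrom == chr)
    if (length(ci) < 2L) next
    pos <- v$pos[ci]
    hc <- h[, ci, drop = FALSE]
    r2m <- suppressWarnings(stats::cor(hc, use = "pairwise.complete.obs"))^2
    n <- length(ci)
    ij <- which(upper.tri(r2m), arr.ind = TRUE)
    keep <- (pos[ij[, 2]] - pos[ij[, 1]]) <= window_kb * 1000 &
      (ij[, 2] - ij[, 1]) <= (window_snps - 1L)
    ij <- ij[keep, , drop = FALSE]
    r2v <- r2m[ij]
    pass <- !is.na(r2v) &
      (if (comparison == ">") r2v > r2_min else r2v >= r2_min)
    if (!any(pass)) next
    ij <- ij[pass, , drop = FALSE]
    res[[chr]] <- tibble::tibble(
      rsid_a = pmin(v$rsid[ci][ij[, 1]], v$rsid[ci][ij[, 2]]),
      rsid_b = pmax(v$rsid[ci][ij[, 1]], v$rsid[ci][ij[, 2]]),
      r2 = r2v[pass]
    )
  }
  pairs <- if (length(res)) {
    dplyr::arrange(dplyr::bind_rows(res), .data$rsid_a, .data$rsid_b)
  } else {
    tibble::tibble(rsid_a = character(), rsid_b = character(), r2 = numeric())
  }
  new_proxy_table(pairs, panel$population, r2_min, comparison,
                  estimator = if (panel$phased) "haplotype" else "dosage")
}

#' Query the LD partners of one SNP
#'
#' Symmetric lookup: partners of `rsid` at r-squared at or above the
#' effective cutoff. Overriding below the cutoff the table was built with is
#' an error (those pairs were never stored).
#'
#' @param table a `proxy_table`.
#' @param rsid SNP identifier.
#' @param r2_min optional override cutoff (must not undercut the table's).
#' @return tibble (`rsid`, `r2`) of partners; empty for unknown SNPs.
#' @export
query_proxies <- function(table, rsid, r2_min = NULL) {
  stopifnot(inherits(table, "proxy_table"))
  cutoff <- r2_min %||% attr(table, "r2_min")
  if (cutoff < attr(table, "r2_min")) {
    abort_contract(sprintf(
      "query_proxies: override cutoff %.3g is below the table's retention cutoff %.3g.",
      cutoff, attr(table, "r2_min")))
  }
  hit_a <- table$rsid_a == rsid
  hit_b <- table$rsid_b == rsid
  out <- tibble::tibble(
    rsid = c(table$rsid_b[hit_a], table$rsid_a[hit_b]),
    r2 = c(table$r2[hit_a], table$r2[hit_b])
  )
  if (!is.null(r2_min)) out <- out[out$r2 >= r2_min, ]
  dplyr::arrange(out, .data$rsid)
}

#' Write / read a proxy table as a flat TSV store
#'
#' The store is a tab-delimited file with `#key=value` metadata lines
#' (population, cutoff, comparison operator, estimator) followed by the
#' `rsid_a`, `rsid_b`, `r2` table.
#'
#' @param table a `proxy_table`.
#' @param path file path.
#' @return `path` (writer) or a `proxy_table` (reader).
#' @export
write_proxy_table <- function(table, path) {
  stopifnot(inherits(table, "proxy_table"))
  meta <- sprintf("#%s=%s",
                  c("population", "r2_min", "comparison", "estimator"),
                  c(attr(table, "population"), attr(table, "r2_min"),
                    attr(table, "comparison"), attr(table, "estimator")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines("rsid_a\trsid_b\tr2", con)
  if (nrow(table) > 0) {
    writeLines(sprintf("%s\t%s\t%.17g", table$rsid_a, table$rsid_b, table$r2),
               con)
  }
  invisible(path)
}

#' @rdname write_proxy_table
#' @export
read_proxy_table <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("File not found: %s", path))
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- stats::setNames(
    sub("^#[^=]*=", "", meta_lines),
    sub("=.*$", "", sub("^#", "", meta_lines))
  )
  body <- lines[!grepl("^#", lines)]
  df <- if (length(body) > 1L) {
    readr::read_tsv(I(paste(body, collapse = "\n")),
                    col_types = "ccd", progress = FALSE, show_col_types = FALSE)
  } else {
    tibble::tibble(rsid_a = character(), rsid_b = character(), r2 = numeric())
  }
  new_proxy_table(df, meta[["population"]] %||% "custom",
                  as.numeric(meta[["r2_min"]] %||% 0.4),
                  meta[["comparison"]] %||% ">",
                  meta[["estimator"]] %||% "haplotype")
}

#' @export
print.proxy_table <- function(x, ...) {
  cat(sprintf("<proxy_table> %s | %d pairs | r2 %s %.3g (%s)\n",
              attr(x, "population"), nrow(x), attr(x, "comparison"),
              attr(x, "r2_min"), attr(x, "estimator")))
  NextMethod()
}
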