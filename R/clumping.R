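# Greedy LD clumping of summary statistics to independent lead SNPs.

#' Clumping configuration
#'
#' PLINK-style thresholds: `p1` (index SNP p cutoff), `p2` (member p cutoff),
#' `r2` (LD threshold for clump membership) and `kb` (physical window).
#'
#' @param p1 index-SNP p-value threshold, in `(0, 1]`.
#' @param p2 member p-value threshold, `p1 <= p2 <= 1`.
#' @param r2 LD r-squared for membership, in `[0, 1]`.
#' @param kb window half-width in kilobases.
#' @return an object of class `clump_config`.
#' @examples
#' clump_config(p1 = 5e-8)
#' @export
clump_config <- function(p1 = 1e-5, p2 = 1, r2 = 0.4, kb = 1000) {
  if (!(p1 > 0 && p1 <= p2 && p2 <= 1)) {
    abort_contract("clump_config: need 0 < p1 <= p2 <= 1.")
  }
  if (!(r2 >= 0 && r2 <= 1)) abort_contract("clump_config: r2 must be in [0, 1].")
  if (!(kb > 0)) abort_contract("clump_config: kb must be positive.")
  structure(list(p1 = p1, p2 = p2, r2 = r2, kb = kb), class = "clump_config")
}

new_trait_loci <- function(leads, trait_id, threshold_used, clumps = NULL,
                           report = list()) {
  structure(tibble::as_tibble(leads),
            class = c("trait_loci", class(tibble::tibble())),
            trait_id = trait_id, threshold_used = threshold_used,
            clumps = clumps, report = report)
}

#' @export
print.trait_loci <- function(x, ...) {
  cat(sprintf("<trait_loci> trait: %s | %d lead SNPs at p <= %g\n",
              attr(x, "trait_id"), nrow(x), attr(x, "threshold_used")))
  NextMethod()
}

# r2 lookup closure over either a proxy table or a haplotype panel.
# SNPs absent from the LD source are treated as unlinked (r2 = 0).
make_r2_fun <- function(ld, config) {
  if (inherits(ld, "proxy_table")) {
    if (config$r2 < attr(ld, "r2_min")) {
      abort_config(sprintf(
        paste("Clump r2 threshold %.3g is below the proxy table's retention",
              "cutoff %.3g: pairs needed for clumping were never stored."),
        config$r2, attr(ld, "r2_min")))
    }
    key <- paste(ld$rsid_a, ld$rsid_b, sep = "\r")
    r2map <- stats::setNames(ld$r2, key)
    function(a, b) {
      v <- unname(r2map[paste(min(a, b), max(a, b), sep = "\r")])
      if (is.na(v)) 0 else v
    }
  } else if (inherits(ld, "haplotype_panel")) {
    idx <- stats::setNames(seq_len(nrow(ld$variants)), ld$variants$rsid)
    h <- ld$haplotypes
    phased <- ld$phased
    if (!phased) {
      ns <- nrow(h) / 2
      h <- h[seq_len(ns), , drop = FALSE] + h[ns + seq_len(ns), , drop = FALSE]
    }
    function(a, b) {
      ia <- unname(idx[a]); ib <- unname(idx[b])
      if (is.na(ia) || is.na(ib)) return(0)
      r2 <- compute_r2(h[, ia], h[, ib], phased = phased)
      if (is.na(r2)) 0 else r2
    }
  } else {
    abort_config("LD source must be a proxy_table or a haplotype_panel.")
  }
}

#' Greedy LD clumping
#'
#' Reduces one trait's summary statistics to independent lead (index) SNPs
#' with PLINK clumping semantics: records are ranked by ascending p (ties
#' broken by chrom, pos, rsid); the best unassigned record with `p <= p1`
#' opens a new clump, and every unassigned record with `p <= p2`, within `kb`
#' of the index, and r-squared at least `config$r2` with the index joins it.
#' Each record belongs to at most one clump. SNPs not covered by the LD
#' source are treated as being in linkage equilibrium; records without
#' positions are clumped by LD only (both are flagged in the report).
#'
#' @param stats a `gwas_sumstats`.
#' @param ld a `proxy_table` or `haplotype_panel`. A proxy table whose
#'   retention cutoff exceeds `config$r2` is refused (the needed pairs were
#'   never stored).
#' @param config a [clump_config()].
#' @return a `trait_loci` tibble of index SNPs in genomic order; full clump
#'   membership is in `attr(x, "clumps")` (`index_rsid`, `member_rsid`, `r2`).
#' @export
ld_clump <- function(stats, ld, config = clump_config()) {
  stopifnot(inherits(stats, "gwas_sumstats"))
  r2_fun <- make_r2_fun(ld, config)
  df <- tibble::as_tibble(stats)
  df <- df[order(df$log_p, df$chrom, df$pos, df$rsid, method = "radix"), ]
  log_p1 <- log(config$p1)
  log_p2 <- log(config$p2)
  n <- nrow(df)
  assigned <- rep(FALSE, n)
  no_pos <- sum(is.na(df$pos))
  clump_rows <- list()
  idx_rows <- integer()
  for (i in seq_len(n)) {
    if (assigned[i] || df$log_p[i] > log_p1) next
    assigned[i] <- TRUE
    idx_rows <- c(idx_rows, i)
    cand <- which(!assigned & df$log_p <= log_p2)
    if (length(cand)) {
      same_chr <- !is.na(df$chrom[cand]) & !is.na(df$chrom[i]) &
        df$chrom[cand] == df$chrom[i]
      within <- ifelse(is.na(df$pos[cand]) | is.na(df$pos[i]), TRUE,
                       abs(df$pos[cand] - df$pos[i]) <= config$kb * 1000)
      # records with no chromosome can only pair through LD
      dist_ok <- (same_chr & within) |
        (is.na(df$chrom[cand]) | is.na(df$chrom[i]))
      for (j in cand[dist_ok]) {
        r2 <- r2_fun(df$rsid[i], df$rsid[j])
        if (r2 >= config$r2) {
          assigned[j] <- TRUE
          clump_rows[[length(clump_rows) + 1L]] <-
            tibble::tibble(index_rsid = df$rsid[i],
                           member_rsid = df$rsid[j], r2 = r2)
        }
      }
    }
  }
  if (length(idx_rows) == 0L) {
    rlang::warn(sprintf("ld_clump: no record passes p1 = %g for trait %s.",
                        config$p1, attr(stats, "trait_id")))
  }
  leads <- df[idx_rows, , drop = FALSE]
  leads <- leads[order(leads$chrom, leads$pos, leads$rsid, method = "radix"), ]
  clumps <- if (length(clump_rows)) {
    dplyr::bind_rows(clump_rows)
  } else {
    tibble::tibble(index_rsid = character(), member_rsid = character(),
                   r2 = numeric())
  }
  new_trait_loci(leads, attr(stats, "trait_id"), config$p1, clumps,
                 report = list(n_input = n, n_leads = length(idx_rows),
                               n_no_position = no_pos,
                               uncovered_policy = "linkage_equilibrium"))
}

#' Threshold already-clumped statistics
#'
#' For input that is already reduced to lead variants: keep leads with
#' `p <= p1` and skip all LD work.
#'
#' @param stats a `gwas_sumstats` with `is_clumped = TRUE`.
#' @param p1 p-value threshold, strictly positive.
#' @return a `trait_loci` tibble.
#' @export
apply_threshold <- function(stats, p1 = 1e-5) {
  stopifnot(inherits(stats, "gwas_sumstats"))
  if (!isTRUE(attr(stats, "is_clumped"))) {
    abort_contract("apply_threshold: input is not flagged as clumped; use ld_clump().")
  }
  if (!(is.numeric(p1) && p1 > 0 && p1 <= 1)) {
    abort_contract("apply_threshold: p1 must be in (0, 1].")
  }
  df <- tibble::as_tibble(stats)
  df <- df[!is.na(df$log_p) & df$log_p <= log(p1), , drop = FALSE]
  df <- df[order(df$chrom, df$pos, df$rsid, method = "radix"), ]
  new_trait_loci(df, attr(stats, "trait_id"), p1,
                 report = list(n_input = nrow(stats), n_leads = nrow(df),
                               pre_clumped = TRUE))
}
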