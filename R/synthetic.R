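# Seeded synthetic data: haplotype panels with controlled LD blocks, GWAS
# pairs with planted shared loci, and brute-force oracles.

#' Generate a haplotype panel with controlled LD-block structure
#'
#' Each block is seeded with a founder haplotype; member SNPs are noisy
#' copies of the founder with a per-SNP flip probability tuned so that the
#' expected pairwise r-squared matches `r2_target`
#' (`eps = (1 - r2_target^(1/4)) / 2`; two independently mutated copies have
#' `r^2 = (1 - 2 eps)^4` around the founder frequency). A target of 1 copies
#' the founder exactly. Blocks are mutually independent. Fully deterministic
#' for a fixed seed.
#'
#' @param n_samples number of diploid samples (haplotypes = 2x).
#' @param blocks data frame with one row per block: `n_snps`, `r2_target`,
#'   `start` (bp of the first SNP), `spacing` (bp between SNPs).
#' @param chrom chromosome label for all blocks (or one label per block).
#' @param population tag recorded on the panel.
#' @param seed integer seed.
#' @param noise optional explicit flip probability overriding the tuned one;
#'   combining `noise > 0` with `r2_target = 1` is a contract error.
#' @param include_rare also append one rare variant (MAF just below 0.01) to
#'   exercise the panel filters.
#' @return a `haplotype_panel`.
#' @export
gen_panel <- function(n_samples = 200,
                      blocks = tibble::tibble(n_snps = 4, r2_target = 0.9,
                                              start = 1e6, spacing = 5000),
                      chrom = "1", population = "SYN", seed = 1,
                      noise = NULL, include_rare = FALSE) {
  blocks <- tibble::as_tibble(blocks)
  if (!is.null(noise) && any(blocks$r2_target == 1) && noise > 0) {
    abort_contract("gen_panel: r2_target = 1 with nonzero noise is impossible.")
  }
  if (length(chrom) == 1L) chrom <- rep(chrom, nrow(blocks))
  n_hap <- 2L * n_samples
  withr_seed(seed, {
    cols <- list()
    meta <- list()
    snp_i <- 0L
    for (b in seq_len(nrow(blocks))) {
      m <- blocks$n_snps[b]
      target <- blocks$r2_target[b]
      eps <- noise %||% ((1 - target^(1 / 4)) / 2)
      # founder frequency away from the boundaries so realized MAF is common
      founder <- NULL
      repeat {
        f <- stats::runif(1, 0.25, 0.75)
        founder <- stats::rbinom(n_hap, 1, f)
        fr <- mean(founder)
        if (fr >= 0.1 && fr <= 0.9) break
      }
      for (s in seq_len(m)) {
        snp_i <- snp_i + 1L
        flip <- stats::rbinom(n_hap, 1, eps)
        cols[[snp_i]] <- as.integer(xor(founder, flip))
        meta[[snp_i]] <- tibble::tibble(
          rsid = sprintf("rs%d%04d", b, s),
          chrom = chrom[b],
          pos = blocks$start[b] + (s - 1) * blocks$spacing[b],
          ref = "A", alt = "G")
      }
    }
    if (include_rare) {
      snp_i <- snp_i + 1L
      rare <- integer(n_hap)
      # MAF just below 0.01 (needs > 100 haplotypes to be possible at all)
      n_alt <- max(1L, as.integer(ceiling(0.01 * n_hap)) - 1L)
      rare[sample.int(n_hap, n_alt)] <- 1L
      cols[[snp_i]] <- rare
      last <- meta[[snp_i - 1L]]
      meta[[snp_i]] <- tibble::tibble(rsid = "rs_rare1", chrom = last$chrom,
                                      pos = last$pos + 1000, ref = "A",
                                      alt = "G")
    }
    h <- do.call(cbind, cols)
    variants <- dplyr::bind_rows(meta)
    variants <- dplyr::bind_cols(variants, panel_allele_stats(h))
    new_haplotype_panel(variants, h, phased = TRUE, population = population)
  })
}

# run code under a temporary RNG state
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Serialize a haplotype panel to a minimal VCF
#'
#' Writes a conformant VCFv4.2 file with phased GT fields; the companion
#' route back is [read_haplotype_panel()], so synthetic panels round-trip
#' through the standard parser.
#'
#' @param panel a `haplotype_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "haplotype_panel"))
  n_hap <- nrow(panel$haplotypes)
  n_samp <- n_hap / 2
  samples <- sprintf("S%04d", seq_len(n_samp))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pleioscan-synthetic",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  gt_chr <- function(v) ifelse(is.na(v), ".", as.character(v))
  h1 <- panel$haplotypes[seq_len(n_samp), , drop = FALSE]
  h2 <- panel$haplotypes[n_samp + seq_len(n_samp), , drop = FALSE]
  rows <- vapply(seq_len(nrow(panel$variants)), function(i) {
    v <- panel$variants[i, ]
    gts <- paste0(gt_chr(h1[, i]), "|", gt_chr(h2[, i]))
    paste(c(v$chrom, format(v$pos, scientific = FALSE, trim = TRUE),
            v$rsid, v$ref, v$alt, ".", "PASS", ".", "GT", gts),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Generate a GWAS pair with planted shared loci
#'
#' Places trait leads on distinct LD blocks of the panel. Direct overlaps put
#' the same SNP in both traits; proxy overlaps put the trait-2 lead on a
#' different SNP of the same block as a trait-1 lead (so sharing is only
#' detectable through the LD proxy table). Background SNPs receive uniform p
#' in `(p_background_min, 1]`. The truth record carries the expected
#' `k`, `k_direct` and `k_indirect`.
#'
#' @param panel a `haplotype_panel` built by [gen_panel()] (blocks are
#'   recovered from the rsID scheme).
#' @param n_lead_1,n_lead_2 lead loci per trait.
#' @param n_shared_direct,n_shared_proxy planted overlaps
#'   (`<= min(n_lead_1, n_lead_2)` in total).
#' @param p_signal range of signal p-values (log-uniform).
#' @param n_background background SNPs per trait (p above `p_background_min`).
#' @param p_background_min lower bound for background p (default 1e-5, the
#'   usual index threshold, so background never clumps into leads).
#' @param seed integer seed.
#' @return list with `stats1`, `stats2` (`gwas_sumstats`) and `truth`
#'   (list: `k`, `k_direct`, `k_indirect`, lead assignments).
#' @export
gen_gwas_pair <- function(panel, n_lead_1 = 10, n_lead_2 = 10,
                          n_shared_direct = 2, n_shared_proxy = 1,
                          p_signal = c(1e-12, 1e-8), n_background = 50,
                          p_background_min = 1e-5, seed = 1) {
  n_shared <- n_shared_direct + n_shared_proxy
  if (n_shared > min(n_lead_1, n_lead_2)) {
    abort_contract("gen_gwas_pair: planted overlaps exceed min(n_lead_1, n_lead_2).")
  }
  v <- panel$variants[panel$variants$maf >= 0.05, ]
  block_of <- sub("^rs([0-9]+)[0-9]{4}$", "\\1", v$rsid)
  blocks <- split(seq_len(nrow(v)), block_of)
  blocks <- blocks[vapply(blocks, length, integer(1)) >= 2L]
  n_blocks_needed <- n_lead_1 + n_lead_2 - n_shared
  if (length(blocks) < n_blocks_needed) {
    abort_contract(sprintf(
      "gen_gwas_pair: need %d blocks with >= 2 common SNPs, panel has %d.",
      n_blocks_needed, length(blocks)))
  }
  withr_seed(seed, {
    picked <- sample(names(blocks), n_blocks_needed)
    b_direct <- picked[seq_len(n_shared_direct)]
    b_proxy <- picked[n_shared_direct + seq_len(n_shared_proxy)]
    b_only1 <- picked[n_shared + seq_len(n_lead_1 - n_shared)]
    b_only2 <- picked[(n_lead_1) + seq_len(n_lead_2 - n_shared)]
    rsignal <- function(n) {
      exp(stats::runif(n, log(p_signal[1]), log(p_signal[2])))
    }
    lead_row <- function(bl, which = 1L) {
      i <- blocks[[bl]][which]
      v[i, c("rsid", "chrom", "pos", "maf")]
    }
    t1_rows <- dplyr::bind_rows(
      purrr::map_dfr(b_direct, lead_row),
      purrr::map_dfr(b_proxy, lead_row, which = 1L),
      purrr::map_dfr(b_only1, lead_row))
    t2_rows <- dplyr::bind_rows(
      purrr::map_dfr(b_direct, lead_row),
      purrr::map_dfr(b_proxy, lead_row, which = 2L),
      purrr::map_dfr(b_only2, lead_row))
    t1_rows$p <- rsignal(nrow(t1_rows))
    t2_rows$p <- rsignal(nrow(t2_rows))
    bg <- function(tag) {
      tibble::tibble(
        rsid = sprintf("rsbg_%s_%04d", tag, seq_len(n_background)),
        chrom = "99",
        pos = 1e6 + 1e4 * seq_len(n_background),
        maf = stats::runif(n_background, 0.05, 0.5),
        p = exp(stats::runif(n_background, log(p_background_min * 1.01), 0)))
    }
    stats1 <- summary_stats(dplyr::bind_rows(t1_rows, bg("a")),
                            trait_id = "synthetic_trait_1",
                            source = "synthetic")
    stats2 <- summary_stats(dplyr::bind_rows(t2_rows, bg("b")),
                            trait_id = "synthetic_trait_2",
                            source = "synthetic")
    truth <- list(
      k = n_shared, k_direct = n_shared_direct, k_indirect = n_shared_proxy,
      leads1 = t1_rows$rsid, leads2 = t2_rows$rsid,
      shared_direct = t1_rows$rsid[seq_len(n_shared_direct)],
      shared_proxy_a = t1_rows$rsid[n_shared_direct + seq_len(n_shared_proxy)],
      shared_proxy_b = t2_rows$rsid[n_shared_direct + seq_len(n_shared_proxy)])
    list(stats1 = stats1, stats2 = stats2, truth = truth)
  })
}

#' Brute-force hypergeometric upper tail
#'
#' Independent oracle for [fisher_enrichment()]: sums the PMF
#' `C(K, j) C(N - K, n - j) / C(N, n)` for `j >= k` using a rational
#' recurrence evaluated in probability space (no log-gamma anywhere), which
#' is exact to double precision for `N <= 2000`.
#'
#' @param N universe size (`<= 2000`).
#' @param K success states (trait-2 loci).
#' @param n draws (trait-1 loci).
#' @param k lower bound of the tail.
#' @return `P(X >= k)`.
#' @examples
#' oracle_hypergeom_tail(100, 10, 5, 2)
#' @export
oracle_hypergeom_tail <- function(N, K, n, k) {
  if (N > 2000) abort_contract("oracle_hypergeom_tail: N must be <= 2000.")
  if (K > N || n > N || k < 0 || k > min(n, K) + 1) {
    abort_contract("oracle_hypergeom_tail: inconsistent parameters.")
  }
  if (k == 0) return(1)
  j_min <- max(0L, n - (N - K))
  j_top <- min(n, K)
  # P(j_min) as an interleaved ratio product of falling factorials
  # P(j) = ff(K, j) ff(N - K, n - j) n! / (j! (n - j)! ff(N, n))
  pmf_at <- function(j) {
    num <- c(seq_len(j) + (K - j), seq_len(n - j) + (N - K - (n - j)),
             seq_len(n))
    den <- c(seq_len(j), seq_len(n - j), seq_len(n) + (N - n))
    prod(num / den)
  }
  p <- pmf_at(j_min)
  total <- if (j_min >= k) p else 0
  j <- j_min
  while (j < j_top) {
    j <- j + 1L
    p <- p * ((K - j + 1) * (n - j + 1)) / (j * (N - K - n + j))
    if (j >= k) total <- total + p
  }
  min(total, 1)
}

#' Connected components by repeated transitive closure
#'
#' Brute-force oracle for [merge_blocks()]: grows each component by repeated
#' neighbor expansion until a fixed point. Intended for graphs of at most a
#' few hundred nodes.
#'
#' @param edges two-column data frame or matrix of node labels.
#' @param nodes character vector of all node labels (isolated nodes allowed).
#' @return list of character vectors, one sorted component each, ordered by
#'   their smallest member.
#' @export
oracle_components <- function(edges, nodes) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  adj <- lapply(stats::setNames(nm = nodes), function(x) character())
  for (r in seq_len(nrow(edges))) {
    a <- as.character(edges[r, 1]); b <- as.character(edges[r, 2])
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  seen <- character()
  comps <- list()
  for (s in nodes) {
    if (s %in% seen) next
    comp <- s
    repeat {
      grown <- union(comp, unlist(adj[comp], use.names = FALSE))
      if (length(grown) == length(comp)) break
      comp <- grown
    }
    comp <- sort(comp)
    seen <- c(seen, comp)
    comps[[length(comps) + 1L]] <- comp
  }
  comps[order(vapply(comps, min, character(1)))]
}
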