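# Core cross-phenotype computation: shared loci, SNP blocks, enrichment,
# similarity, multiple-testing correction, all-pairs driver.

#' Per-ancestry effective numbers of independent SNPs
#'
#' The universe size N_e of the hypergeometric enrichment test, per ancestry.
#' Shipped defaults are derived from published per-ancestry genome-wide
#' significance thresholds via `N_e = 0.05 / alpha` (EUR: alpha ~ 3.06e-8;
#' AFR: alpha ~ 1.49e-8; ASN: alpha = 5e-8); the provenance string records
#' this. Override by passing your own tibble of the same shape wherever a
#' `constants` argument is accepted.
#'
#' @return tibble with `population`, `n_e`, `provenance`.
#' @export
population_constants <- function() {
  tibble::tibble(
    population = c("EUR", "AFR", "ASN"),
    n_e = c(1634000, 3355705, 1000000),
    provenance = c(
      "0.05 / 3.06e-8 European genome-wide significance threshold",
      "0.05 / 1.49e-8 African genome-wide significance threshold",
      "0.05 / 5e-8 Asian genome-wide significance threshold")
  )
}

lookup_n_e <- function(constants, population) {
  row <- constants[constants$population == population, ]
  if (nrow(row) != 1L) {
    abort_config(sprintf("No N_e constant for population '%s'.", population))
  }
  if (!(row$n_e > 0)) abort_config("N_e must be positive.")
  row$n_e
}

#' Find loci shared between two traits
#'
#' Direct sharing: the identical lead rsID appears in both traits' loci sets.
#' Indirect sharing: a lead of one trait has a stored LD proxy (r-squared at
#' or above the effective cutoff) that is a lead of the other. The result is
#' symmetric in trait order up to swapping the `snp_a`/`snp_b` labels.
#'
#' @param loci1,loci2 `trait_loci` objects (see [ld_clump()]).
#' @param proxies a `proxy_table`.
#' @param r2_min optional override cutoff passed to [query_proxies()].
#' @return tibble (`snp_a`, `snp_b`, `mode`, `r2`): `mode` is `"direct"`
#'   (`snp_a == snp_b`, `r2 = 1`) or `"indirect"`.
#' @export
find_shared <- function(loci1, loci2, proxies, r2_min = NULL) {
  a <- unique(loci1$rsid)
  b <- unique(loci2$rsid)
  direct <- intersect(a, b)
  out <- tibble::tibble(snp_a = direct, snp_b = direct,
                        mode = rep("direct", length(direct)),
                        r2 = rep(1, length(direct)))
  ind <- purrr::map_dfr(a, function(s) {
    part <- query_proxies(proxies, s, r2_min = r2_min)
    part <- part[part$rsid %in% b & part$rsid != s, ]
    if (nrow(part) == 0L) return(NULL)
    tibble::tibble(snp_a = s, snp_b = part$rsid, mode = "indirect",
                   r2 = part$r2)
  })
  out <- dplyr::bind_rows(out, ind)
  dplyr::arrange(out, .data$snp_a, .data$snp_b)
}

# Minimal union-find (roots keep the smallest index).
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}

#' Merge shared SNPs into independent blocks
#'
#' Union-find over every SNP appearing in the shared pairs, joining on
#' identity, on each shared pair itself, and on every stored proxy edge at or
#' above the cutoff among those SNPs, iterated to a fixed point. Each
#' resulting connected component is one SNP block; `k` downstream is the
#' number of blocks.
#'
#' @param shared output of [find_shared()].
#' @param proxies a `proxy_table`.
#' @param positions optional tibble (`rsid`, `chrom`, `pos`) used to pick the
#'   smallest-coordinate representative; without it the lexicographically
#'   smallest rsID represents the block.
#' @param r2_min optional override cutoff.
#' @return tibble (`block_id`, `representative`, `members` list-column,
#'   `contains_direct`, `n_members`).
#' @export
merge_blocks <- function(shared, proxies, positions = NULL, r2_min = NULL) {
  nodes <- sort(unique(c(shared$snp_a, shared$snp_b)))
  if (length(nodes) == 0L) {
    return(tibble::tibble(block_id = integer(), representative = character(),
                          members = list(), contains_direct = logical(),
                          n_members = integer()))
  }
  idx <- stats::setNames(seq_along(nodes), nodes)
  parent <- uf_new(length(nodes))
  for (r in seq_len(nrow(shared))) {
    parent <- uf_union(parent, idx[[shared$snp_a[r]]], idx[[shared$snp_b[r]]])
  }
  # proxy edges among the node set close the blocks transitively
  for (s in nodes) {
    part <- query_proxies(proxies, s, r2_min = r2_min)
    for (t in intersect(part$rsid, nodes)) {
      parent <- uf_union(parent, idx[[s]], idx[[t]])
    }
  }
  roots <- vapply(seq_along(nodes), function(i) uf_find(parent, i), integer(1))
  comp <- split(nodes, roots)
  direct_snps <- shared$snp_a[shared$mode == "direct"]
  blocks <- purrr::map_dfr(comp, function(members) {
    rep_snp <- if (!is.null(positions)) {
      pp <- positions[match(members, positions$rsid), ]
      ok <- !is.na(pp$pos)
      if (any(ok)) {
        o <- order(pp$chrom[ok], pp$pos[ok], members[ok], method = "radix")
        members[ok][o[1]]
      } else {
        min(members)
      }
    } else {
      min(members)
    }
    tibble::tibble(representative = rep_snp, members = list(sort(members)),
                   contains_direct = any(members %in% direct_snps),
                   n_members = length(members))
  })
  blocks <- dplyr::arrange(blocks, .data$representative)
  blocks$block_id <- seq_len(nrow(blocks))
  dplyr::relocate(blocks, "block_id")
}

#' Hypergeometric enrichment of shared loci
#'
#' One-sided upper-tail probability that two traits with `n1` and `n2`
#' independent lead SNPs drawn from a universe of `n_e` independent SNPs
#' share at least `k` independent SNP blocks:
#' `P(X >= k)` for `X ~ Hypergeometric(N = n_e, K = n2, n = n1)`.
#' The tail is summed in log space via `lchoose()` (log-gamma), so p-values
#' of magnitude 1e-200 and below are returned exactly on the log scale.
#' Symmetric under swapping `n1` and `n2`.
#'
#' @param k number of shared independent SNP blocks.
#' @param n1,n2 independent lead-SNP counts of the two traits.
#' @param n_e effective number of independent SNPs in the population.
#' @param log return the natural-log p-value (default `FALSE`).
#' @param method `"tail"` (default; Fisher-style `P(X >= k)`) or `"pmf"`
#'   (the point probability at exactly `k`, for comparison).
#' @return p-value (or its natural log).
#' @examples
#' fisher_enrichment(k = 2, n1 = 5, n2 = 10, n_e = 100)  # ~0.0769
#' @export
fisher_enrichment <- function(k, n1, n2, n_e, log = FALSE,
                              method = c("tail", "pmf")) {
  method <- match.arg(method)
  if (any(c(k, n1, n2, n_e) < 0) || k != round(k) || n1 != round(n1) ||
      n2 != round(n2)) {
    abort_contract("fisher_enrichment: k, n1, n2, n_e must be nonnegative integers.")
  }
  if (k > min(n1, n2)) {
    abort_contract("fisher_enrichment: k cannot exceed min(n1, n2).")
  }
  if (n1 > n_e || n2 > n_e) {
    abort_contract("fisher_enrichment: n1 and n2 cannot exceed n_e.")
  }
  lterm <- function(j) {
    lchoose(n2, j) + lchoose(n_e - n2, n1 - j) - lchoose(n_e, n1)
  }
  lp <- if (method == "pmf") {
    lterm(k)
  } else if (k == 0) {
    0
  } else {
    logsumexp(vapply(seq.int(k, min(n1, n2)), lterm, numeric(1)))
  }
  lp <- min(lp, 0)
  if (log) lp else exp(lp)
}

#' Similarity indices for two loci sets
#'
#' Jaccard `k / (n1 + n2 - k)`, Sorensen `2k / (n1 + n2)`, and the
#' abundance-based Chao-Sorensen `2UV / (U + V)` where `U` and `V` are the
#' shared fractions of total abundance in each trait. With unit weights
#' (the default) `U = k/n1`, `V = k/n2` and the Chao-Sorensen value reduces
#' exactly to the Sorensen value.
#'
#' @param n1,n2 lead-SNP counts.
#' @param k shared block count, `k <= min(n1, n2)`.
#' @param weights1,weights2 optional per-block abundance weights: numeric
#'   vectors of length `k` (shared part) plus implicit unit weight for
#'   unshared loci, or full-length vectors whose first `k` entries are the
#'   shared blocks. Lengths `k` are interpreted as shared-block weights with
#'   unshared loci weighted 1.
#' @return tibble (`jaccard`, `sorensen`, `chao_sorensen`), all in `[0, 1]`.
#' @examples
#' trait_similarity(n1 = 5, n2 = 10, k = 2)
#' @export
trait_similarity <- function(n1, n2, k, weights1 = NULL, weights2 = NULL) {
  if (n1 + n2 == 0) abort_contract("trait_similarity: n1 + n2 must be positive.")
  if (k > min(n1, n2)) abort_contract("trait_similarity: k cannot exceed min(n1, n2).")
  jaccard <- if (k == 0) 0 else k / (n1 + n2 - k)
  sorensen <- if (k == 0) 0 else 2 * k / (n1 + n2)
  shared_total <- function(w, n) {
    if (is.null(w)) {
      c(shared = k, total = n)
    } else if (length(w) == k) {
      c(shared = sum(w), total = sum(w) + (n - k))
    } else if (length(w) == n) {
      c(shared = sum(w[seq_len(k)]), total = sum(w))
    } else {
      abort_contract("trait_similarity: weights must have length k or n.")
    }
  }
  s1 <- shared_total(weights1, n1)
  s2 <- shared_total(weights2, n2)
  u <- if (s1[["total"]] > 0) s1[["shared"]] / s1[["total"]] else 0
  v <- if (s2[["total"]] > 0) s2[["shared"]] / s2[["total"]] else 0
  chao <- if (u + v == 0) 0 else 2 * u * v / (u + v)
  tibble::tibble(jaccard = jaccard, sorensen = sorensen, chao_sorensen = chao)
}

#' Multiple-testing correction across trait pairs
#'
#' Benjamini-Hochberg step-up (with enforced monotonicity) and Bonferroni,
#' both computed in log space so adjusted values below double underflow
#' remain exact. `m` defaults to the number of pairs tested in the run.
#'
#' @param log_p natural-log p-values for all tested pairs.
#' @param m number of comparisons (default `length(log_p)`).
#' @param fdr significance level for the BH flag (default 0.1).
#' @return tibble (`log_p`, `log_p_bh`, `log_p_bonferroni`, `significant`).
#' @export
adjust_pvalues <- function(log_p, m = length(log_p), fdr = 0.1) {
  out <- adjust_log_p(log_p, m = m)
  out$significant <- out$log_p_bh <= log(fdr)
  out
}

pack_blocks <- function(blocks) {
  if (nrow(blocks) == 0L) return("")
  paste(vapply(blocks$members, paste, character(1), collapse = "|"),
        collapse = ";")
}

pair_stats <- function(loci1, loci2, proxies, n_e, r2_min = NULL) {
  shared <- find_shared(loci1, loci2, proxies, r2_min = r2_min)
  positions <- dplyr::bind_rows(
    tibble::tibble(rsid = loci1$rsid, chrom = loci1$chrom, pos = loci1$pos),
    tibble::tibble(rsid = loci2$rsid, chrom = loci2$chrom, pos = loci2$pos))
  positions <- positions[!duplicated(positions$rsid), ]
  blocks <- merge_blocks(shared, proxies, positions = positions,
                         r2_min = r2_min)
  n1 <- nrow(loci1); n2 <- nrow(loci2)
  k <- nrow(blocks)
  if (k > min(n1, n2)) {
    rlang::warn("pair_stats: block count exceeds min(n1, n2); capping k.")
    k <- min(n1, n2)
  }
  k_direct <- sum(blocks$contains_direct)
  sim <- trait_similarity(n1, n2, k)
  tibble::tibble(
    trait1 = attr(loci1, "trait_id"), trait2 = attr(loci2, "trait_id"),
    n1 = n1, n2 = n2, k = k, k_direct = k_direct, k_indirect = k - k_direct,
    log_p_fisher = fisher_enrichment(k, n1, n2, n_e, log = TRUE),
    jaccard = sim$jaccard, sorensen = sim$sorensen,
    chao_sorensen = sim$chao_sorensen,
    fold_enrichment = if (n1 * n2 > 0) k * n_e / (n1 * n2) else NA_real_,
    shared_snps = pack_blocks(blocks)
  )
}

#' Cross-phenotype analysis over all trait pairs
#'
#' Runs the shared-loci detection, block merging, hypergeometric enrichment
#' and similarity scoring for every unordered pair of traits (or, when
#' `query` is given, for each query-vs-catalog pair), then corrects across
#' all computed pairs. Results are independent of `workers`.
#'
#' @param loci list of `trait_loci` (the catalog).
#' @param proxies a `proxy_table` for the run population.
#' @param population population tag; must match the proxy table's.
#' @param constants N_e table (default [population_constants()]).
#' @param query optional list of `trait_loci` compared against `loci`
#'   instead of all-vs-all.
#' @param fdr BH significance level (default 0.1).
#' @param m override for the number of comparisons used in correction
#'   (default: pairs tested in this run).
#' @param drop_empty drop pairs with `k = 0` (default keeps them at p = 1).
#' @param workers parallel workers via `parallel::mclapply` (default 1).
#' @param r2_min optional r-squared override for proxy queries.
#' @return a `cpag_result`: tibble with one row per pair (`trait1`, `trait2`,
#'   `n1`, `n2`, `k`, `k_direct`, `k_indirect`, log-scale and linear p-value
#'   columns, similarity indices, `fold_enrichment`, `significant`,
#'   `shared_snps`), sorted by ascending enrichment p.
#' @export
cpag_all_pairs <- function(loci, proxies, population = "EUR",
                           constants = population_constants(), query = NULL,
                           fdr = 0.1, m = NULL, drop_empty = FALSE,
                           workers = 1L, r2_min = NULL) {
  stopifnot(inherits(proxies, "proxy_table"))
  if (!identical(attr(proxies, "population"), population)) {
    abort_config(sprintf(
      "Population mismatch: proxy table is '%s', run requested '%s'.",
      attr(proxies, "population"), population))
  }
  n_e <- lookup_n_e(constants, population)
  if (is.null(query)) {
    if (length(loci) < 2L) {
      abort_data("cpag_all_pairs: need at least 2 traits (or a query).")
    }
    pairs <- utils::combn(length(loci), 2)
    jobs <- lapply(seq_len(ncol(pairs)), function(i) {
      list(a = loci[[pairs[1, i]]], b = loci[[pairs[2, i]]])
    })
  } else {
    if (length(query) < 1L || length(loci) < 1L) {
      abort_data("cpag_all_pairs: empty query or catalog.")
    }
    jobs <- list()
    for (q in query) for (cc in loci) {
      jobs[[length(jobs) + 1L]] <- list(a = q, b = cc)
    }
  }
  run_one <- function(job) {
    pair_stats(job$a, job$b, proxies, n_e, r2_min = r2_min)
  }
  rows <- if (workers > 1L) {
    parallel::mclapply(jobs, run_one, mc.cores = workers)
  } else {
    lapply(jobs, run_one)
  }
  res <- dplyr::bind_rows(rows)
  if (drop_empty) res <- res[res$k > 0, , drop = FALSE]
  adj <- adjust_pvalues(res$log_p_fisher, m = m %||% nrow(res), fdr = fdr)
  res$log_p_bh <- adj$log_p_bh
  res$log_p_bonferroni <- adj$log_p_bonferroni
  res$p_fisher <- exp(res$log_p_fisher)
  res$p_bh <- exp(res$log_p_bh)
  res$p_bonferroni <- exp(res$log_p_bonferroni)
  res$significant <- adj$significant
  res <- dplyr::arrange(res, .data$log_p_fisher, .data$trait1, .data$trait2)
  structure(res, class = c("cpag_result", class(tibble::tibble())),
            population = population, n_e = n_e,
            m = m %||% nrow(res), fdr = fdr,
            r2_cutoff = r2_min %||% attr(proxies, "r2_min"),
            comparison = attr(proxies, "comparison"))
}

#' @export
print.cpag_result <- function(x, ...) {
  cat(sprintf(
    "<cpag_result> %d pairs | pop %s (N_e = %g) | m = %d | FDR %.2g | %d significant\n",
    nrow(x), attr(x, "population"), attr(x, "n_e"), attr(x, "m"),
    attr(x, "fdr"), sum(x$significant)))
  NextMethod()
}
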