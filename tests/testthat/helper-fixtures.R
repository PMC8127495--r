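# Shared fixtures: tiny panels, proxy tables and summary statistics built in
# code, plus independent oracles used across test files.

# A proxy table from inline text, via the public store format.
proxy_tab <- function(rsid_a, rsid_b, r2, population = "SYN", r2_min = 0.4,
                      comparison = ">") {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  lines <- c(sprintf("#population=%s", population),
             sprintf("#r2_min=%s", r2_min),
             sprintf("#comparison=%s", comparison),
             "#estimator=haplotype",
             "rsid_a\trsid_b\tr2")
  if (length(rsid_a)) {
    lines <- c(lines, sprintf("%s\t%s\t%s", pmin(rsid_a, rsid_b),
                              pmax(rsid_a, rsid_b), r2))
  }
  writeLines(lines, path)
  read_proxy_table(path)
}

mk_stats <- function(rsid, p, chrom = "1", pos = NULL, trait = "trait",
                     clumped = FALSE, ...) {
  df <- tibble::tibble(rsid = rsid, p = p, chrom = chrom,
                       pos = pos %||% seq(1e6, by = 1e4,
                                          length.out = length(rsid)), ...)
  summary_stats(df, trait_id = trait, is_clumped = clumped)
}

mk_loci <- function(rsid, trait = "trait", chrom = "1", pos = NULL,
                    p = 1e-9) {
  stats <- mk_stats(rsid, rep_len(p, length(rsid)), chrom = chrom, pos = pos,
                    trait = trait, clumped = TRUE)
  apply_threshold(stats, 1e-5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a reusable small LD world: 20 four-SNP blocks at r2 ~ 0.9
fixture_panel <- local({
  panel <- NULL
  function() {
    if (is.null(panel)) {
      blocks <- tibble::tibble(n_snps = rep(4, 20), r2_target = 0.9,
                               start = 1e6 + (0:19) * 3e6, spacing = 5000)
      panel <<- gen_panel(200, blocks, seed = 42)
    }
    panel
  }
})

fixture_proxies <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- build_proxy_table(fixture_panel())
    tab
  }
})

# --- independent oracles -------------------------------------------------

# all-pairs brute-force proxy construction (window rules, per-pair compute_r2)
oracle_proxy_pairs <- function(panel, window_kb = 1000, window_snps = 10000,
                               r2_min = 0.4, comparison = ">") {
  v <- panel$variants
  ord <- order(v$chrom, v$pos, v$rsid, method = "radix")
  v <- v[ord, ]
  h <- panel$haplotypes[, ord, drop = FALSE]
  out <- list()
  n <- nrow(v)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (v$chrom[i] != v$chrom[j]) next
      if (abs(v$pos[j] - v$pos[i]) > window_kb * 1000) next
      if ((j - i) > (window_snps - 1)) next
      r2 <- compute_r2(h[, i], h[, j], phased = panel$phased)
      if (is.na(r2)) next
      pass <- if (comparison == ">") r2 > r2_min else r2 >= r2_min
      if (pass) {
        out[[length(out) + 1L]] <- tibble::tibble(
          rsid_a = min(v$rsid[i], v$rsid[j]),
          rsid_b = max(v$rsid[i], v$rsid[j]), r2 = r2)
      }
    }
  }
  if (length(out)) {
    dplyr::arrange(dplyr::bind_rows(out), rsid_a, rsid_b)
  } else {
    tibble::tibble(rsid_a = character(), rsid_b = character(), r2 = numeric())
  }
}

# independent greedy clumping reference (plain loops over a p-sorted list)
oracle_clump <- function(stats, r2_fun, p1, p2, r2, kb) {
  df <- as.data.frame(tibble::as_tibble(stats))
  df <- df[order(df$log_p, df$chrom, df$pos, df$rsid), ]
  taken <- rep(FALSE, nrow(df))
  leads <- character()
  for (i in seq_len(nrow(df))) {
    if (taken[i] || df$log_p[i] > log(p1)) next
    taken[i] <- TRUE
    leads <- c(leads, df$rsid[i])
    for (j in seq_len(nrow(df))) {
      if (taken[j] || df$log_p[j] > log(p2)) next
      if (!is.na(df$chrom[i]) && !is.na(df$chrom[j])) {
        if (df$chrom[i] != df$chrom[j]) next
        if (!is.na(df$pos[i]) && !is.na(df$pos[j]) &&
            abs(df$pos[i] - df$pos[j]) > kb * 1000) next
      }
      if (r2_fun(df$rsid[i], df$rsid[j]) >= r2) taken[j] <- TRUE
    }
  }
  sort(leads)
}

# plain-probability-space enumeration of the five coloc hypotheses
oracle_coloc <- function(beta1, se1, beta2, se2, p1 = 1e-4, p2 = 1e-4,
                         p12 = 1e-5, sd1 = 0.15, sd2 = 0.15) {
  wake <- function(beta, se, sd_prior) {
    w <- sd_prior^2
    sqrt(se^2 / (se^2 + w)) * exp(w * (beta / se)^2 / (2 * (se^2 + w)))
  }
  bf1 <- wake(beta1, se1, sd1)
  bf2 <- wake(beta2, se2, sd2)
  n <- length(bf1)
  s0 <- 1
  s1 <- p1 * sum(bf1)
  s2 <- p2 * sum(bf2)
  s3 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) s3 <- s3 + p1 * p2 * bf1[i] * bf2[j]
  }
  s4 <- p12 * sum(bf1 * bf2)
  tot <- s0 + s1 + s2 + s3 + s4
  c(pp0 = s0, pp1 = s1, pp2 = s2, pp3 = s3, pp4 = s4) / tot
}
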