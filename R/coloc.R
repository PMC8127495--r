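# Approximate-Bayes-factor colocalization of a shared region (PP0-PP4).

#' Colocalization priors
#'
#' Per-SNP prior probabilities of association with trait 1 only (`p1`),
#' trait 2 only (`p2`), and both (`p12`). Defaults are the standard
#' 1e-4 / 1e-4 / 1e-5. A `p12` above `min(p1, p2)` is allowed but warned
#' about.
#'
#' @param p1,p2,p12 per-SNP priors.
#' @return an object of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  if (p1 <= 0 || p2 <= 0 || p12 < 0) {
    abort_contract("coloc_priors: p1, p2 must be > 0 and p12 >= 0.")
  }
  if (p12 > min(p1, p2)) {
    rlang::warn("coloc_priors: p12 > min(p1, p2) is an unusual configuration.")
  }
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

# Effect-prior standard deviations of the Wakefield ABF, by trait type.
prior_sd <- function(trait_type) {
  switch(trait_type, quant = 0.15, cc = 0.2,
         abort_config(sprintf("Unknown trait type '%s' (use 'quant' or 'cc').",
                              trait_type)))
}

#' Wakefield log approximate Bayes factor
#'
#' `log ABF = 0.5 * (log(1 - r) + r * z^2)` with `z = beta / se` and
#' `r = W / (W + se^2)`, where `W` is the prior variance of the effect size
#' (sd 0.15 for quantitative traits, 0.2 for case-control by default).
#' Vectorized over `beta`/`se`.
#'
#' @param beta,se effect estimates and standard errors (`se > 0`).
#' @param trait_type `"quant"` or `"cc"`.
#' @param sd_prior override the prior effect standard deviation.
#' @return numeric vector of natural-log Bayes factors (association vs null).
#' @examples
#' snp_log_abf(beta = 0.5, se = 0.1, trait_type = "quant")
#' @export
snp_log_abf <- function(beta, se, trait_type = "quant",
                        sd_prior = prior_sd(trait_type)) {
  if (any(!is.finite(se)) || any(se <= 0)) {
    abort_contract("snp_log_abf: standard errors must be positive and finite.")
  }
  z <- beta / se
  w <- sd_prior^2
  r <- w / (w + se^2)
  0.5 * (log1p(-r) + r * z^2)
}

# Reconstruct (beta, se) from (p, maf, n) when effects are unavailable.
# Quantitative: se ~ 1/sqrt(2 maf (1-maf) n) on a unit-variance phenotype;
# case-control: multiply the denominator by s(1-s) with s the case fraction.
reconstruct_effects <- function(log_p, maf, n, trait_type, case_fraction = 0.5) {
  z <- stats::qnorm(log_p - log(2), lower.tail = FALSE, log.p = TRUE)
  denom <- 2 * maf * (1 - maf) * n
  if (trait_type == "cc") denom <- denom * case_fraction * (1 - case_fraction)
  se <- 1 / sqrt(denom)
  tibble::tibble(beta = z * se, se = se)
}

new_region_pair <- function(data, lead, window_bp, trait_types,
                            case_fractions, dropped, trait_ids) {
  structure(list(data = tibble::as_tibble(data), lead = lead,
                 window_bp = window_bp, trait_types = trait_types,
                 case_fractions = case_fractions, dropped = dropped,
                 trait_ids = trait_ids),
            class = "region_pair")
}

#' @export
print.region_pair <- function(x, ...) {
  cat(sprintf("<region_pair> lead %s +/- %g kb | %d shared SNPs (%s vs %s)\n",
              x$lead, x$window_bp / 1000, nrow(x$data),
              x$trait_ids[1], x$trait_ids[2]))
  invisible(x)
}

#' Extract the shared region around a lead SNP
#'
#' Restricts both traits to SNPs within `window_bp` of the lead position and
#' intersects them on rsID. Records the number of SNPs dropped from each
#' side. Effect columns are carried when present; otherwise z-scores are
#' later reconstructed from (p, maf, n) — flagged in the result because that
#' route is lossier.
#'
#' @param stats1,stats2 `gwas_sumstats` with positions.
#' @param lead lead rsID; must be present, with a position, in at least one
#'   trait.
#' @param window_bp half-width of the window (default 200000).
#' @param trait_types character 2-vector, each `"quant"` or `"cc"`.
#' @param case_fractions case fractions for case-control traits (ignored for
#'   quantitative).
#' @param n sample sizes (2-vector) used when reconstructing effects from p.
#' @return a `region_pair`.
#' @export
extract_region <- function(stats1, stats2, lead, window_bp = 200000,
                           trait_types = c("quant", "quant"),
                           case_fractions = c(0.5, 0.5), n = c(10000, 10000)) {
  pos_of <- function(s) {
    i <- match(lead, s$rsid)
    if (is.na(i)) NA_real_ else s$pos[i]
  }
  lead_pos <- pos_of(stats1)
  if (is.na(lead_pos)) lead_pos <- pos_of(stats2)
  if (is.na(lead_pos)) {
    abort_data(sprintf("Lead SNP %s has no position in either trait.", lead))
  }
  win <- function(s) {
    d <- tibble::as_tibble(s)
    d[!is.na(d$pos) & abs(d$pos - lead_pos) <= window_bp, ]
  }
  d1 <- win(stats1); d2 <- win(stats2)
  common <- intersect(d1$rsid, d2$rsid)
  dropped <- c(trait1 = nrow(d1) - length(common),
               trait2 = nrow(d2) - length(common))
  if (length(common) == 0L) {
    abort_data("extract_region: no shared SNPs in the window; colocalization impossible.")
  }
  d1 <- d1[match(common, d1$rsid), ]
  d2 <- d2[match(common, d2$rsid), ]
  data <- tibble::tibble(
    rsid = common, pos = d1$pos,
    beta1 = d1$beta, se1 = d1$se, log_p1 = d1$log_p,
    beta2 = d2$beta, se2 = d2$se, log_p2 = d2$log_p,
    maf = dplyr::coalesce(d1$maf, d2$maf),
    n1 = n[1], n2 = n[2]
  )
  new_region_pair(data, lead, window_bp, trait_types, case_fractions, dropped,
                  trait_ids = c(attr(stats1, "trait_id"),
                                attr(stats2, "trait_id")))
}

#' Backfill missing minor allele frequencies from a reference panel
#'
#' Fills `maf` from panel allele frequencies for SNPs lacking one; SNPs that
#' remain without a MAF (absent from the panel) are dropped and counted.
#' Existing values are never overwritten.
#'
#' @param region a `region_pair`.
#' @param panel a `haplotype_panel`.
#' @return the updated `region_pair` (dropped count in `region$dropped`).
#' @export
maf_backfill <- function(region, panel) {
  stopifnot(inherits(region, "region_pair"), inherits(panel, "haplotype_panel"))
  d <- region$data
  need <- is.na(d$maf)
  if (any(need)) {
    pm <- panel$variants$maf[match(d$rsid[need], panel$variants$rsid)]
    d$maf[need] <- pm
  }
  still <- is.na(d$maf)
  region$dropped <- c(region$dropped, maf_backfill = sum(still))
  region$data <- d[!still, ]
  region
}

region_abfs <- function(region) {
  d <- region$data
  get_side <- function(which) {
    beta <- d[[paste0("beta", which)]]
    se <- d[[paste0("se", which)]]
    tt <- region$trait_types[which]
    miss <- is.na(beta) | is.na(se) | se <= 0
    if (any(miss)) {
      rec <- reconstruct_effects(d[[paste0("log_p", which)]][miss],
                                 d$maf[miss], d[[paste0("n", which)]][miss],
                                 tt, region$case_fractions[which])
      beta[miss] <- rec$beta
      se[miss] <- rec$se
    }
    list(labf = snp_log_abf(beta, se, tt), reconstructed = sum(miss))
  }
  s1 <- get_side(1)
  s2 <- get_side(2)
  list(labf1 = s1$labf, labf2 = s2$labf,
       n_reconstructed = c(s1$reconstructed, s2$reconstructed))
}

coloc_posteriors <- function(labf1, labf2, priors) {
  l_h1 <- logsumexp(labf1)
  l_h2 <- logsumexp(labf2)
  l_h4 <- logsumexp(labf1 + labf2)
  # H3: sum over i != j of BF1_i * BF2_j = S1 * S2 - S4
  diff <- l_h4 - (l_h1 + l_h2)
  l_h3 <- if (length(labf1) < 2L || diff >= 0) -Inf else {
    l_h1 + l_h2 + log1p(-exp(diff))
  }
  lp <- c(0,
          log(priors$p1) + l_h1,
          log(priors$p2) + l_h2,
          log(priors$p1) + log(priors$p2) + l_h3,
          if (priors$p12 > 0) log(priors$p12) + l_h4 else -Inf)
  norm <- logsumexp(lp)
  stats::setNames(exp(lp - norm), paste0("pp", 0:4))
}

#' Colocalization by approximate Bayes factors
#'
#' Assembles the five-hypothesis posterior (PP0: no association; PP1/PP2:
#' one trait only; PP3: two distinct causal variants; PP4: one shared causal
#' variant) from per-SNP Wakefield ABFs, entirely in log space. Per-SNP H4
#' contributions are normalized to sum to 1; the SNP with the largest
#' contribution is reported as the candidate causal variant.
#'
#' @param region a `region_pair`.
#' @param priors a [coloc_priors()].
#' @return a `coloc_result`: list with `summary` (one row: `pp0`..`pp4`,
#'   `nsnps`, `lead_causal_snp`), `snps` (per-SNP log ABFs and normalized H4
#'   contribution), `priors`, and reconstruction counts.
#' @export
coloc_abf <- function(region, priors = coloc_priors()) {
  stopifnot(inherits(region, "region_pair"), inherits(priors, "coloc_priors"))
  if (nrow(region$data) == 0L) {
    abort_data("coloc_abf: region has no SNPs.")
  }
  ab <- region_abfs(region)
  pp <- coloc_posteriors(ab$labf1, ab$labf2, priors)
  joint <- ab$labf1 + ab$labf2
  h4_contrib <- exp(joint - logsumexp(joint))
  snps <- tibble::tibble(rsid = region$data$rsid, pos = region$data$pos,
                         labf1 = ab$labf1, labf2 = ab$labf2,
                         h4_contribution = h4_contrib)
  summary <- tibble::tibble(
    trait1 = region$trait_ids[1], trait2 = region$trait_ids[2],
    lead = region$lead, nsnps = nrow(snps),
    pp0 = pp[["pp0"]], pp1 = pp[["pp1"]], pp2 = pp[["pp2"]],
    pp3 = pp[["pp3"]], pp4 = pp[["pp4"]],
    lead_causal_snp = snps$rsid[which.max(snps$h4_contribution)]
  )
  structure(list(summary = summary, snps = snps, priors = priors,
                 n_reconstructed = ab$n_reconstructed),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<coloc_result> %s vs %s @ %s | %d SNPs\n",
              s$trait1, s$trait2, s$lead, s$nsnps))
  cat(sprintf("  PP0 %.3g  PP1 %.3g  PP2 %.3g  PP3 %.3g  PP4 %.3g\n",
              s$pp0, s$pp1, s$pp2, s$pp3, s$pp4))
  cat(sprintf("  candidate causal SNP: %s (%.1f%% of H4)\n",
              s$lead_causal_snp,
              100 * max(x$snps$h4_contribution)))
  invisible(x)
}

#' Sensitivity of the colocalization posterior to the p12 prior
#'
#' Re-evaluates the posterior over a grid of `p12` values, reusing the
#' per-SNP ABFs (computed once). PP4 is monotone nondecreasing in `p12`.
#'
#' @param region a `region_pair`.
#' @param p12_grid vector of `p12` values in `(0, min(p1, p2)]`.
#' @param priors base priors supplying `p1` and `p2`.
#' @return tibble with one row per grid point (`p12`, `pp0`..`pp4`).
#' @export
prior_sensitivity <- function(region, p12_grid = 10^seq(-8, -5, by = 0.5),
                              priors = coloc_priors()) {
  if (length(p12_grid) == 0L) {
    abort_contract("prior_sensitivity: empty p12 grid.")
  }
  ab <- region_abfs(region)
  purrr::map_dfr(p12_grid, function(p12) {
    pr <- coloc_priors(priors$p1, priors$p2, p12)
    pp <- coloc_posteriors(ab$labf1, ab$labf2, pr)
    tibble::tibble(p12 = p12, pp0 = pp[["pp0"]], pp1 = pp[["pp1"]],
                   pp2 = pp[["pp2"]], pp3 = pp[["pp3"]], pp4 = pp[["pp4"]])
  })
}
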