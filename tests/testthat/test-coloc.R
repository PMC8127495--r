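region_stats <- function(beta, se = 0.05, trait = "t", maf = 0.3,
                         nsnp = length(beta)) {
  mk_stats(sprintf("rs%03d", seq_len(nsnp)), rep(0.5, nsnp),
           pos = 1e6 + (seq_len(nsnp) - 1) * 2000, trait = trait,
           beta = beta, se = rep_len(se, nsnp), maf = rep_len(maf, nsnp))
}

test_that("region extraction windows and intersects on rsID", {
  s1 <- mk_stats(c("lead", "in1", "out1", "only1"),
                 rep(0.1, 4), pos = c(1e6, 1.15e6, 1.25e6, 1.1e6),
                 beta = 0.1, se = 0.05, maf = 0.2)
  s2 <- mk_stats(c("lead", "in1", "out1"),
                 rep(0.1, 3), pos = c(1e6, 1.15e6, 1.25e6),
                 beta = 0.1, se = 0.05, maf = 0.2)
  reg <- extract_region(s1, s2, "lead", window_bp = 200000)
  expect_setequal(reg$data$rsid, c("lead", "in1"))   # 1.25 Mb is outside
  # only1 is in trait 1's window but absent from trait 2: dropped (1, 0)
  expect_equal(unname(reg$dropped), c(1, 0))
  # no shared SNPs in the window is a data error
  s3 <- mk_stats("elsewhere", 0.1, pos = 9e6)
  expect_error(extract_region(s1, s3, "lead"), class = "pleioscan_data_error")
  # a 56-SNP overlap reports nsnps = 56
  b <- rnorm(56, 0, 0.01)
  reg56 <- extract_region(region_stats(b, trait = "a"),
                          region_stats(rnorm(56, 0, 0.01), trait = "b"),
                          "rs001")
  expect_equal(coloc_abf(reg56)$summary$nsnps, 56)
})

test_that("the Wakefield log ABF follows its closed form", {
  # beta = 0.5, se = 0.1, W = 0.15^2: r = 0.0225/0.0325
  r <- 0.0225 / 0.0325
  expect_equal(snp_log_abf(0.5, 0.1, "quant"),
               0.5 * (log(1 - r) + r * 25), tolerance = 1e-14)
  # null effect: evidence against association
  expect_lt(snp_log_abf(0, 0.1, "quant"), 0)
  expect_equal(snp_log_abf(0, 0.1, "quant"), 0.5 * log(1 - r),
               tolerance = 1e-14)
  # monotone in |z|
  expect_gt(snp_log_abf(1, 0.1, "quant"), snp_log_abf(0.5, 0.1, "quant"))
  # case-control uses the wider default prior
  expect_equal(snp_log_abf(0.5, 0.1, "cc"),
               snp_log_abf(0.5, 0.1, "quant", sd_prior = 0.2))
  expect_error(snp_log_abf(0.5, 0, "quant"),
               class = "pleioscan_contract_error")
})

test_that("posteriors match brute-force configuration enumeration on tiny regions", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(2:4, 1)
    beta1 <- rnorm(n, 0, 0.3)
    beta2 <- rnorm(n, 0, 0.3)
    se1 <- runif(n, 0.04, 0.1)
    se2 <- runif(n, 0.04, 0.1)
    s1 <- region_stats(beta1, se1, trait = "a")
    s2 <- region_stats(beta2, se2, trait = "b")
    reg <- extract_region(s1, s2, "rs001", window_bp = 1e6)
    got <- coloc_abf(reg)
    want <- oracle_coloc(beta1, se1, beta2, se2)
    pp <- unlist(got$summary[, paste0("pp", 0:4)])
    expect_equal(unname(pp), unname(want), tolerance = 1e-10)
    expect_equal(sum(pp), 1, tolerance = 1e-9)
  }
})

test_that("single-SNP and zero-prior corner cases behave exactly", {
  s1 <- region_stats(2, 0.05, trait = "a", nsnp = 1)
  s2 <- region_stats(1.5, 0.05, trait = "b", nsnp = 1)
  reg <- extract_region(s1, s2, "rs001")
  res <- coloc_abf(reg)
  expect_equal(res$summary$pp3, 0)          # H3 needs two SNPs
  expect_gt(res$summary$pp4, 0.99)
  expect_equal(res$summary$lead_causal_snp, "rs001")
  # p12 = 0 kills H4 exactly
  res0 <- coloc_abf(reg, coloc_priors(p12 = 0))
  expect_equal(res0$summary$pp4, 0)
})

test_that("posterior invariances: normalization, units, label symmetry", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(3:20, 1)
    beta1 <- rnorm(n, 0, 0.2); se1 <- runif(n, 0.02, 0.1)
    beta2 <- rnorm(n, 0, 0.2); se2 <- runif(n, 0.02, 0.1)
    reg <- extract_region(region_stats(beta1, se1, "a"),
                          region_stats(beta2, se2, "b"), "rs001",
                          window_bp = 1e6)
    pp <- unlist(coloc_abf(reg)$summary[, paste0("pp", 0:4)])
    expect_equal(sum(pp), 1, tolerance = 1e-9)
    # changing the units of one trait together with its prior sd is a no-op
    c_scale <- runif(1, 0.2, 5)
    reg_scaled <- reg
    reg_scaled$data$beta1 <- reg$data$beta1 * c_scale
    reg_scaled$data$se1 <- reg$data$se1 * c_scale
    ab <- pleioscan:::region_abfs(reg)
    ab_s <- list(
      labf1 = snp_log_abf(reg_scaled$data$beta1, reg_scaled$data$se1,
                          "quant", sd_prior = 0.15 * c_scale),
      labf2 = ab$labf2)
    pp_s <- pleioscan:::coloc_posteriors(ab_s$labf1, ab_s$labf2,
                                         coloc_priors())
    expect_equal(unname(pp_s), unname(pp), tolerance = 1e-9)
    # swapping traits swaps PP1 and PP2, fixes PP0, PP3, PP4
    reg_swap <- extract_region(region_stats(beta2, se2, "b"),
                               region_stats(beta1, se1, "a"), "rs001",
                               window_bp = 1e6)
    pp_swap <- unlist(coloc_abf(reg_swap)$summary[, paste0("pp", 0:4)])
    expect_equal(pp_swap[["pp1"]], pp[["pp2"]], tolerance = 1e-12)
    expect_equal(pp_swap[["pp2"]], pp[["pp1"]], tolerance = 1e-12)
    expect_equal(pp_swap[[c("pp0")]], pp[["pp0"]], tolerance = 1e-12)
    expect_equal(pp_swap[["pp3"]], pp[["pp3"]], tolerance = 1e-12)
    expect_equal(pp_swap[["pp4"]], pp[["pp4"]], tolerance = 1e-12)
  }
})

test_that("per-SNP H4 contributions localize the causal variant", {
  set.seed(23)
  n <- 25
  beta1 <- rnorm(n, 0, 0.01); beta2 <- rnorm(n, 0, 0.01)
  beta1[10] <- 0.5; beta2[10] <- 0.4
  reg <- extract_region(region_stats(beta1, trait = "a"),
                        region_stats(beta2, trait = "b"), "rs001",
                        window_bp = 1e6)
  res <- coloc_abf(reg)
  expect_equal(res$summary$lead_causal_snp, "rs010")
  expect_equal(sum(res$snps$h4_contribution), 1, tolerance = 1e-9)
  expect_gt(res$summary$pp4, 0.9)
})

test_that("MAF backfill fills gaps from the panel and drops uncovered SNPs", {
  panel <- fixture_panel()
  ids <- panel$variants$rsid[1:3]
  s1 <- mk_stats(c(ids, "rs_nowhere"), rep(0.1, 4),
                 pos = c(panel$variants$pos[1:3], panel$variants$pos[3] + 10),
                 beta = 0.2, se = 0.05,
                 maf = c(0.11, NA, NA, NA))
  s2 <- s1
  attr(s2, "trait_id") <- "t2"
  reg <- extract_region(s1, s2, ids[1], window_bp = 1e6)
  reg <- maf_backfill(reg, panel)
  expect_false("rs_nowhere" %in% reg$data$rsid)
  expect_equal(reg$dropped[["maf_backfill"]], 1)
  d <- reg$data
  expect_equal(d$maf[d$rsid == ids[1]], 0.11)  # existing value untouched
  expect_equal(d$maf[d$rsid == ids[2]],
               panel$variants$maf[2])
})

test_that("effects reconstructed from (p, maf, n) recover the z-score route", {
  # build a region with no beta/se at all
  n <- 10
  z <- c(8, rnorm(n - 1, 0, 0.5))
  p <- 2 * pnorm(abs(z), lower.tail = FALSE)
  s1 <- mk_stats(sprintf("rs%03d", 1:n), p, pos = 1e6 + (0:(n - 1)) * 1000,
                 maf = 0.25, trait = "a")
  s2 <- mk_stats(sprintf("rs%03d", 1:n), p, pos = 1e6 + (0:(n - 1)) * 1000,
                 maf = 0.25, trait = "b")
  reg <- extract_region(s1, s2, "rs001", n = c(5000, 5000))
  res <- coloc_abf(reg)
  expect_equal(unname(res$n_reconstructed), c(10, 10))
  expect_gt(res$summary$pp4, 0.5)
  expect_equal(res$summary$lead_causal_snp, "rs001")
})

test_that("prior sensitivity reuses ABFs and is monotone in p12", {
  set.seed(41)
  n <- 12
  beta1 <- rnorm(n, 0, 0.1); beta2 <- rnorm(n, 0, 0.1)
  beta1[4] <- 0.4; beta2[4] <- 0.35
  reg <- extract_region(region_stats(beta1, trait = "a"),
                        region_stats(beta2, trait = "b"), "rs001",
                        window_bp = 1e6)
  grid <- 10^seq(-8, -5, length.out = 5)
  sens <- prior_sensitivity(reg, grid)
  expect_equal(nrow(sens), 5)
  expect_true(all(diff(sens$pp4) >= -1e-12))
  # a one-point grid at the default prior reproduces coloc_abf
  one <- prior_sensitivity(reg, 1e-5)
  expect_equal(one$pp4, coloc_abf(reg)$summary$pp4, tolerance = 1e-12)
  expect_error(prior_sensitivity(reg, numeric()),
               class = "pleioscan_contract_error")
})
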