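syn_constants <- function(n_e = 1000) {
  tibble::tibble(population = "SYN", n_e = n_e, provenance = "test")
}

test_that("shared loci are found directly and through proxies", {
  tab <- proxy_tab("rs1", "rs2", 0.7)
  both <- find_shared(mk_loci("rs1", "A"), mk_loci("rs1", "B"), tab)
  expect_equal(both$mode, "direct")
  expect_equal(both$r2, 1)
  ind <- find_shared(mk_loci("rs1", "A"), mk_loci("rs2", "B"), tab)
  expect_equal(ind$mode, "indirect")
  expect_equal(ind$r2, 0.7)
  none <- find_shared(mk_loci("rs1", "A"), mk_loci("rs3", "B"), tab)
  expect_equal(nrow(none), 0)
  # symmetric in trait order up to label swap
  swapped <- find_shared(mk_loci("rs2", "B"), mk_loci("rs1", "A"), tab)
  expect_equal(swapped$snp_a, ind$snp_b)
  expect_equal(swapped$snp_b, ind$snp_a)
  expect_equal(swapped$r2, ind$r2)
})

test_that("shared SNPs merge into blocks by transitive LD closure", {
  tab <- proxy_tab(c("a", "b"), c("b", "c"), c(0.5, 0.45))
  shared <- tibble::tibble(snp_a = c("a", "b", "c", "d"),
                           snp_b = c("a", "b", "c", "d"),
                           mode = "direct", r2 = 1)
  blocks <- merge_blocks(shared, tab)
  expect_equal(nrow(blocks), 2)
  expect_equal(blocks$members[[1]], c("a", "b", "c"))
  expect_equal(blocks$members[[2]], "d")
  # no edges: three direct matches stay three blocks
  no_edges <- proxy_tab(character(), character(), numeric())
  shared3 <- shared[1:3, ]
  expect_equal(nrow(merge_blocks(shared3, no_edges)), 3)
  # a chain of five SNPs linked pairwise at 0.41 collapses to one block
  chain <- proxy_tab(paste0("x", 1:4), paste0("x", 2:5), rep(0.41, 4))
  shared5 <- tibble::tibble(snp_a = paste0("x", 1:5),
                            snp_b = paste0("x", 1:5), mode = "direct", r2 = 1)
  expect_equal(nrow(merge_blocks(shared5, chain)), 1)
})

test_that("merge_blocks agrees with the transitive-closure oracle on random graphs", {
  set.seed(101)
  has_igraph <- requireNamespace("igraph", quietly = TRUE)
  for (i in 1:50) {
    n_nodes <- sample(3:40, 1)
    nodes <- sprintf("n%03d", seq_len(n_nodes))
    n_edges <- sample(0:(2 * n_nodes), 1)
    e_a <- sample(nodes, n_edges, replace = TRUE)
    e_b <- sample(nodes, n_edges, replace = TRUE)
    ok <- e_a != e_b
    e_a <- e_a[ok]; e_b <- e_b[ok]
    tab <- proxy_tab(e_a, e_b, runif(length(e_a), 0.41, 1))
    shared <- tibble::tibble(snp_a = nodes, snp_b = nodes, mode = "direct",
                             r2 = 1)
    blocks <- merge_blocks(shared, tab)
    oracle <- oracle_components(cbind(e_a, e_b), nodes)
    expect_equal(length(blocks$block_id), length(oracle))
    expect_equal(blocks$members, oracle, ignore_attr = TRUE)
    if (has_igraph) {
      g <- igraph::graph_from_data_frame(
        data.frame(a = e_a, b = e_b), directed = FALSE,
        vertices = data.frame(name = nodes))
      expect_equal(nrow(blocks), igraph::components(g)$no)
    }
  }
})

test_that("enrichment matches exact rational tail values frozen from an oracle", {
  # exact rationals: 3653/47530, 1/252, 467658/1626905, and a larger case
  expect_equal(fisher_enrichment(2, 5, 10, 100), 3653 / 47530,
               tolerance = 1e-14)
  expect_equal(fisher_enrichment(5, 5, 5, 10), 1 / 252, tolerance = 1e-14)
  expect_equal(fisher_enrichment(3, 8, 12, 50), 467658 / 1626905,
               tolerance = 1e-13)
  expect_equal(fisher_enrichment(10, 30, 40, 200), 0.046325187919265865,
               tolerance = 1e-13)
  expect_equal(fisher_enrichment(0, 5, 10, 100), 1)
  # the package oracle reproduces the same values by rational recurrence
  expect_equal(oracle_hypergeom_tail(100, 10, 5, 2), 3653 / 47530,
               tolerance = 1e-14)
  expect_equal(oracle_hypergeom_tail(10, 5, 5, 5), 1 / 252, tolerance = 1e-14)
  expect_equal(oracle_hypergeom_tail(100, 10, 5, 0), 1)
})

test_that("enrichment is monotone in k, symmetric in traits, and contract-checked", {
  p_prev <- 1
  for (k in 1:10) {
    p_k <- fisher_enrichment(k, 10, 20, 500)
    expect_lt(p_k, p_prev)
    p_prev <- p_k
  }
  expect_equal(fisher_enrichment(3, 7, 19, 300),
               fisher_enrichment(3, 19, 7, 300), tolerance = 1e-12)
  expect_error(fisher_enrichment(6, 5, 10, 100),
               class = "pleioscan_contract_error")
  expect_error(fisher_enrichment(1, 5, 200, 100),
               class = "pleioscan_contract_error")
  # log representation supports astronomically small tails
  lp <- fisher_enrichment(120, 150, 160, 2e6, log = TRUE)
  expect_true(is.finite(lp))
  expect_lt(lp / log(10), -400)
  # pmf variant is the single displayed term
  expect_equal(fisher_enrichment(2, 5, 10, 100, method = "pmf"),
               choose(10, 2) * choose(90, 3) / choose(100, 5),
               tolerance = 1e-13)
})

test_that("enrichment agrees with stats::phyper across a parameter sweep", {
  set.seed(3)
  for (i in 1:200) {
    n_e <- sample(20:500, 1)
    n1 <- sample(1:min(50, n_e), 1)
    n2 <- sample(1:min(50, n_e), 1)
    k <- sample(0:min(n1, n2), 1)
    mine <- fisher_enrichment(k, n1, n2, n_e, log = TRUE)
    ref <- stats::phyper(k - 1, n2, n_e - n2, n1, lower.tail = FALSE,
                         log.p = TRUE)
    # relative on the log magnitude, absolute near log p = 0
    expect_lt(abs(mine - ref) / max(abs(ref), 1), 1e-12)
  }
})

test_that("similarity indices follow their formulas and reduce correctly", {
  same <- trait_similarity(4, 4, 4)
  expect_equal(unlist(same), c(jaccard = 1, sorensen = 1, chao_sorensen = 1))
  disj <- trait_similarity(5, 8, 0)
  expect_equal(unlist(disj), c(jaccard = 0, sorensen = 0, chao_sorensen = 0))
  mid <- trait_similarity(5, 10, 2)
  expect_equal(mid$jaccard, 2 / 13)
  expect_equal(mid$sorensen, 4 / 15)
  expect_equal(mid$chao_sorensen, mid$sorensen)  # unit weights reduce exactly
  # weighted Chao-Sorensen stays in [0, 1] and responds to abundance
  w <- trait_similarity(5, 10, 2, weights1 = c(5, 5), weights2 = c(4, 6))
  expect_gt(w$chao_sorensen, 0)
  expect_lte(w$chao_sorensen, 1)
  expect_gt(w$chao_sorensen, mid$chao_sorensen)  # heavier shared blocks
  expect_error(trait_similarity(0, 0, 0), class = "pleioscan_contract_error")
  expect_error(trait_similarity(2, 3, 3), class = "pleioscan_contract_error")
})

test_that("BH and Bonferroni corrections match the classic step-up", {
  adj <- adjust_pvalues(log(c(0.01, 0.02, 0.03, 0.04)))
  expect_equal(exp(adj$log_p_bh), rep(0.04, 4))
  expect_equal(exp(adj$log_p_bonferroni), c(0.04, 0.08, 0.12, 0.16))
  one <- adjust_pvalues(log(0.05))
  expect_equal(exp(one$log_p_bh), 0.05)
  expect_equal(exp(one$log_p_bonferroni), 0.05)
  # elementwise ordering and agreement with stats::p.adjust as oracle
  set.seed(9)
  p <- runif(50)
  adj2 <- adjust_pvalues(log(p))
  expect_true(all(adj2$log_p_bonferroni >= adj2$log_p_bh - 1e-12))
  expect_true(all(adj2$log_p_bh >= adj2$log_p - 1e-12))
  expect_equal(exp(adj2$log_p_bh), stats::p.adjust(p, "BH"), tolerance = 1e-12)
  expect_equal(exp(adj2$log_p_bonferroni), stats::p.adjust(p, "bonferroni"),
               tolerance = 1e-12)
  # survives magnitudes that underflow doubles
  tiny <- adjust_pvalues(c(-800 * log(10), log(0.5)))
  expect_true(is.finite(tiny$log_p_bh[1]))
  expect_lt(tiny$log_p_bh[1] / log(10), -790)
  expect_equal(nrow(adjust_pvalues(numeric())), 0)
})

test_that("the all-pairs driver enumerates pairs and is worker-invariant", {
  tab <- fixture_proxies()
  panel <- fixture_panel()
  set.seed(21)
  loci <- lapply(1:4, function(i) {
    ids <- sample(panel$variants$rsid, 6)
    mk_loci(ids, trait = paste0("T", i),
            chrom = panel$variants$chrom[match(ids, panel$variants$rsid)],
            pos = panel$variants$pos[match(ids, panel$variants$rsid)])
  })
  res <- cpag_all_pairs(loci, tab, population = "SYN",
                        constants = syn_constants())
  expect_equal(nrow(res), choose(4, 2))
  expect_true(all(res$k_direct + res$k_indirect == res$k))
  expect_true(all(res$log_p_bh >= res$log_p_fisher - 1e-12))
  expect_true(all(res$log_p_bonferroni >= res$log_p_bh - 1e-12))
  # query-vs-catalog mode gives exactly one pair per catalog trait
  res_q <- cpag_all_pairs(loci[2], tab, population = "SYN",
                          constants = syn_constants(), query = loci[1])
  expect_equal(nrow(res_q), 1)
  # worker count never changes the result
  res2 <- cpag_all_pairs(loci, tab, population = "SYN",
                         constants = syn_constants(), workers = 2L)
  expect_equal(tibble::as_tibble(res2), tibble::as_tibble(res))
  # trait order does not change k or p
  res_rev <- cpag_all_pairs(rev(loci), tab, population = "SYN",
                            constants = syn_constants())
  key <- function(x) paste(pmin(x$trait1, x$trait2), pmax(x$trait1, x$trait2))
  m <- match(key(res), key(res_rev))
  expect_equal(res$k, res_rev$k[m])
  expect_equal(res$log_p_fisher, res_rev$log_p_fisher[m])
  # population mismatch is a configuration error
  expect_error(cpag_all_pairs(loci, tab, population = "EUR"),
               class = "pleioscan_config_error")
})

test_that("fold enrichment exceeds 1 whenever the tail p is small", {
  set.seed(5)
  for (i in 1:100) {
    n_e <- sample(100:2000, 1)
    n1 <- sample(2:30, 1)
    n2 <- sample(2:30, 1)
    k <- sample(0:min(n1, n2), 1)
    p <- fisher_enrichment(k, n1, n2, n_e)
    if (p < 0.5 && k > 0) {
      expect_gte(k * n_e / (n1 * n2), 1)
    }
  }
})
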