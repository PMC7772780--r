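small_cfg <- function(...) {
  sim_config(n_genes = 6L, lib_total = 5e4, seed = 99, ...)
}

test_that("identical configurations produce identical experiments", {
  a <- simulate_ctss_experiment(small_cfg())
  b <- simulate_ctss_experiment(small_cfg())
  expect_equal(a$ctss, b$ctss)
  expect_equal(a$truth, b$truth)
  expect_equal(as.character(a$genome), as.character(b$genome))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_ctss_experiment(small_cfg(), out_dir = d1)
  simulate_ctss_experiment(small_cfg(), out_dir = d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("degenerate spread stacks all tags on the planted center", {
  cfg <- sim_config(n_genes = 1L, promoters_per_gene = 1L,
                    promoter_mix = 1, pos_spread = 0, noise = FALSE,
                    bg_positions = 0L, lib_total = 1e5,
                    category_mix = c(0, 1, 0), seed = 5)
  sim <- simulate_ctss_experiment(cfg)
  planted <- sim$ctss[[1]]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$pos, sim$truth$center)
})

test_that("truth categories are consistent with the breadth rule", {
  cfg <- small_cfg()
  sim <- simulate_ctss_experiment(cfg)
  profs <- as.matrix(sim$truth[, paste0("tpm.", cfg$tissues), with = FALSE])
  expect_equal(unname(classify_breadth(profs)), sim$truth$category)

  pure <- sim_config(n_genes = 10L, category_mix = c(1, 0, 0),
                     bg_positions = 0L, seed = 12)
  sim_pure <- simulate_ctss_experiment(pure)
  expect_true(all(sim_pure$truth$category == "non_ubiquitous"))
  profs_pure <- as.matrix(
    sim_pure$truth[, paste0("tpm.", pure$tissues), with = FALSE])
  expect_true(all(apply(profs_pure, 1, median) < 0.2))
})

test_that("Poisson-noised profiles keep >= 90% category recovery", {
  # ~500 planted promoters at base_tpm 5, classifier applied to noisy tag
  # masses at the library scale (1 tag per tpm at lib_total 1e6)
  cfg <- sim_config(n_genes = 250L, promoters_per_gene = 2L,
                    promoter_mix = 1, base_tpm = 5, bg_positions = 0L,
                    seed = 314)
  sim <- simulate_ctss_experiment(cfg)
  profs <- as.matrix(sim$truth[, paste0("tpm.", cfg$tissues), with = FALSE])
  expect_gte(nrow(profs), 500L)
  tags_per_tpm <- cfg$lib_total / 1e6
  set.seed(314)
  noisy <- matrix(rpois(length(profs), profs * tags_per_tpm) / tags_per_tpm,
                  nrow = nrow(profs))
  recovered <- classify_breadth(noisy)
  expect_gte(mean(recovered == sim$truth$category), 0.90)
})

test_that("pooled per-position counts refit the configured power law", {
  cfg <- sim_config(n_genes = 5L, lib_total = 1.5e5, count_alpha = 1.14,
                    seed = 777)
  sim <- simulate_ctss_experiment(cfg)
  pooled <- unlist(lapply(sim$ctss, `[[`, "count"))
  expect_gte(length(pooled), 1e5)
  fit <- fit_power_law_values(pooled, min_value = 2)
  expect_lt(abs(fit$alpha_s - cfg$count_alpha), 0.1)
})

test_that("planted promoters too close for the clustering framework error", {
  expect_error(sim_config(promoter_spacing = 30L, seed = 1),
               "identifiable")
})

test_that("UTR loci contain exactly the planted uORFs", {
  loc <- simulate_utr_locus(c(31L), seed = 8)
  rep <- utr_report(loc$transcript, loc$genome)
  expect_equal(rep$n_uorfs, 1L)
  expect_equal(rep$uorfs$aa_length[rep$uorfs$has_stop], 31L)

  none <- simulate_utr_locus(integer(), seed = 8)
  expect_equal(utr_report(none$transcript, none$genome)$n_uorfs, 0L)

  multi <- simulate_utr_locus(c(10L, 20L, 20L), leader_length = 400L,
                              seed = 9)
  rep_m <- utr_report(multi$transcript, multi$genome)
  expect_equal(sort(rep_m$uorfs$aa_length[rep_m$uorfs$has_stop]),
               c(10L, 20L, 20L))
  expect_error(simulate_utr_locus(c(100L, 100L), leader_length = 300L),
               "infeasible")
})

test_that("junction canonicity follows canonical_fraction", {
  all_can <- simulate_utr_locus(c(5L), canonical_fraction = 1, seed = 2)
  expect_true(all(check_canonical_junction(all_can$junctions$donor_seq,
                                           all_can$junctions$acceptor_seq)))
  expect_true(all(all_can$junctions$canonical))
  none_can <- simulate_utr_locus(c(5L), canonical_fraction = 0, seed = 2)
  expect_false(any(check_canonical_junction(none_can$junctions$donor_seq,
                                            none_can$junctions$acceptor_seq)))
})

test_that("junction truth matches the GT/AG check output", {
  loc <- simulate_utr_locus(c(8L), canonical_fraction = 0.5, seed = 64,
                            n_exons = 6L)
  expect_equal(check_canonical_junction(loc$junctions$donor_seq,
                                        loc$junctions$acceptor_seq),
               loc$junctions$canonical)
})
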