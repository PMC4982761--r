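test_that("tier assignment reproduces the documented boundary convention", {
  fpkms <- c(0, 9.999, 10, 100, 100.001, 500, 500.001, 1e4, 600)
  expect_equal(assign_tier(fpkms),
               c("No", "No", "Low", "Low", "Middle", "Middle", "High",
                 "High", "High"))
})

test_that("the ln fold-change filter uses the stabilized ratio", {
  expect_equal(diff_expression_filter(100, 100), "stable")
  # ln(130.1/100.1) ~= 0.262 > 0.2
  expect_equal(diff_expression_filter(100, 130), "up")
  expect_equal(diff_expression_filter(130, 100), "down")
  expect_equal(diff_expression_filter(0, 0), "stable")
  expect_equal(diff_expression_filter(c(1, 2), c(2, 1), ln_fc = 0.2),
               c("up", "down"))
})

test_that("read-through calls follow the fold and expression thresholds", {
  cfg <- classifier_config()
  up <- call_readthrough(c(1.0, 1.0), c(1.6, 1.6), cfg)
  expect_equal(up$call, "up")
  expect_equal(up$fold_change, 1.7 / 1.1)   # ~1.545 > 1.4

  low <- call_readthrough(c(0.3, 0.3), c(0.4, 0.4), cfg)
  expect_equal(low$call, "excluded_low")
  expect_true(is.na(low$fold_change))

  dn <- call_readthrough(c(2.0, 2.0), c(0.8, 0.8), cfg)
  expect_equal(dn$call, "down")
  expect_equal(dn$fold_change, 0.9 / 2.1)   # ~0.429 < 0.5

  # silent in control, expressed after perturbation: still callable
  gain <- call_readthrough(c(0, 0), c(1.2, 1.2), cfg)
  expect_equal(gain$call, "up")

  expect_error(call_readthrough(numeric(0), c(1, 1), cfg), "empty")
})

test_that("neighbour exclusion is strand-aware and expression-gated", {
  g <- tiny_gene("g1", start = 1000, end = 3000, strand = "+")
  nb_same <- tiny_gene("g2", start = 4000, end = 6000, strand = "+")
  nb_anti <- tiny_gene("g3", start = 4000, end = 6000, strand = "-")
  cm <- data.frame(gene_id = rep(c("g1", "g2", "g3"), each = 2),
                   condition = rep(c("a", "b"), 3),
                   mean_body_fpkm = c(20, 20, 50, 50, 50, 50),
                   mean_rt_fpkm = 0, n_replicates = 2)
  expect_true(has_expressed_downstream_neighbor(
    g, list(g, nb_same), cm, 5000))
  expect_false(has_expressed_downstream_neighbor(
    g, list(g, nb_anti), cm, 5000))
  expect_true(has_expressed_downstream_neighbor(
    g, list(g, nb_anti), cm, 5000, both_strands = TRUE))
  # below the expression floor the neighbour does not trigger exclusion
  cm2 <- cm; cm2$mean_body_fpkm[cm2$gene_id == "g2"] <- 0.5
  expect_false(has_expressed_downstream_neighbor(
    g, list(g, nb_same), cm2, 5000))
})

test_that("flagged neighbours on simulated annotation match recorded truth", {
  cfg <- sim_config(n_genes = 80L, fraction_closely_spaced = 0.3,
                    seed = 19L)
  ann <- simulate_annotation(cfg)
  cm <- data.frame(gene_id = ann$truth$gene_id, condition = "control",
                   mean_body_fpkm = 10, mean_rt_fpkm = 0,
                   n_replicates = 1)
  flags <- vapply(ann$models, has_expressed_downstream_neighbor,
                  logical(1), models = ann$models, cond_means = cm,
                  window_bp = cfg$d_max, min_neighbor_fpkm = 0)
  expect_equal(flags, ann$truth$close_packed)
})

test_that("classification recovers affected genes on a small simulation", {
  cfg <- small_sim_config(depth = 4e6)
  sim <- simulate_experiment(cfg)
  q <- quantify_all(sim$models, sim$libraries, 5000, cfg$chrom_length)
  calls <- classify_all(sim$models, q, "control", "treated",
                        classifier_config(), cfg$chrom_length)
  tr <- sim$truth
  eligible <- tr$affected & tr$fpkm >= 10 &
    calls$call != "excluded_overlap"
  expect_gte(mean(calls$call[eligible] == "up"), 0.9)
  ups <- calls$call == "up"
  expect_true(all(tr$affected[ups]))
})

test_that("zero-tag libraries exclude every gene as unexpressed", {
  cfg <- sim_config(n_genes = 5L, seed = 3L)
  ann <- simulate_annotation(cfg)
  empty <- function(cond, rep_i) {
    stranded_coverage(cond, rep_i, list(), library_size = 1e6)
  }
  libs <- list(empty("control", 1L), empty("control", 2L),
               empty("treated", 1L), empty("treated", 2L))
  q <- suppressWarnings(quantify_all(ann$models, libs, 5000,
                                     cfg$chrom_length))
  calls <- classify_all(ann$models, q, "control", "treated",
                        classifier_config(), cfg$chrom_length)
  expect_true(all(calls$call %in% c("excluded_low", "excluded_overlap")))
})

test_that("exchanging condition labels maps up calls to down calls", {
  cfg <- sim_config(n_genes = 40L, depth = 2e6, n_replicates = 1L,
                    seed = 29L, fraction_closely_spaced = 0)
  sim <- simulate_experiment(cfg)
  q <- quantify_all(sim$models, sim$libraries, 5000, cfg$chrom_length)
  # reciprocal thresholds so the inversion is exact with one replicate
  cc <- classifier_config(fc_up = 2, fc_down = 0.5)
  fwd <- classify_all(sim$models, q, "control", "treated", cc,
                      cfg$chrom_length)
  rev <- classify_all(sim$models, q, "treated", "control", cc,
                      cfg$chrom_length)
  swap <- c(up = "down", down = "up", unchanged = "unchanged",
            excluded_low = "excluded_low",
            excluded_overlap = "excluded_overlap")
  expect_equal(unname(swap[fwd$call]), rev$call)
  keep <- !is.na(fwd$fold_change)
  expect_equal(fwd$fold_change[keep], 1 / rev$fold_change[keep])
})

test_that("calls are invariant under joint rescaling of all libraries", {
  cfg <- sim_config(n_genes = 30L, depth = 1e6, seed = 37L)
  sim <- simulate_experiment(cfg)
  q1 <- quantify_all(sim$models, sim$libraries, 5000, cfg$chrom_length)
  doubled <- lapply(sim$libraries, function(l) {
    stranded_coverage(l$condition, l$replicate,
                      lapply(l$tags, function(p) rep(p, 2L)),
                      library_size = 2 * l$library_size)
  })
  q2 <- quantify_all(sim$models, doubled, 5000, cfg$chrom_length)
  c1 <- classify_all(sim$models, q1, "control", "treated",
                     classifier_config(), cfg$chrom_length)
  c2 <- classify_all(sim$models, q2, "control", "treated",
                     classifier_config(), cfg$chrom_length)
  expect_equal(c1, c2)
})

test_that("classifier configuration rejects out-of-range thresholds", {
  expect_error(classifier_config(fc_up = 0.9))
  expect_error(classifier_config(fc_down = 1.2))
  expect_error(classifier_config(epsilon = 0))
})
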