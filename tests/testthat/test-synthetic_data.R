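test_that("annotation generation is deterministic and honours n_genes", {
  expect_length(simulate_annotation(sim_config(n_genes = 0L))$models, 0L)

  cfg <- sim_config(n_genes = 25L, seed = 7L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  a1 <- simulate_annotation(cfg); a2 <- simulate_annotation(cfg)
  write_bed12(a1$models, file.path(d1, "g.bed12"))
  write_bed12(a2$models, file.path(d2, "g.bed12"))
  expect_identical(readLines(file.path(d1, "g.bed12")),
                   readLines(file.path(d2, "g.bed12")))
  expect_identical(a1$truth, a2$truth)
})

test_that("fraction_closely_spaced = 1 packs neighbours into every window", {
  cfg <- sim_config(n_genes = 30L, fraction_closely_spaced = 1,
                    seed = 2L)
  ann <- simulate_annotation(cfg)
  # chain construction: every junction is close and strand-matched, so
  # all genes except (possibly) the transcription-terminal one carry a
  # same-strand neighbour inside the 5-kb window
  expect_gte(sum(ann$truth$close_packed), cfg$n_genes - 1L)
  # and the recorded flag matches explicit geometry
  flags <- vapply(ann$models, function(g) {
    w <- downstream_window(g, cfg$d_max)
    any(vapply(ann$models, function(h) {
      h$gene_id != g$gene_id && h$strand == g$strand &&
        h$start < w$end && h$end > w$start
    }, logical(1)))
  }, logical(1))
  expect_equal(ann$truth$close_packed, flags)
})

test_that("infeasible packing errors point at chrom_length", {
  cfg <- sim_config(n_genes = 50L, chrom_length = 20000)
  expect_error(simulate_annotation(cfg), "chrom_length")
})

test_that("rho = 0 yields no tag strictly past any TTS", {
  # no close packing, so downstream windows contain no other gene's body
  cfg <- small_sim_config(rho0 = 0, rho_fold = 1,
                          fraction_closely_spaced = 0)
  sim <- simulate_experiment(cfg)
  for (lib in sim$libraries) {
    for (g in sim$models) {
      w <- downstream_window(g, cfg$d_max, cfg$chrom_length)
      expect_equal(count_tags(lib, w), 0L)
    }
  }
})

test_that("fragment counts are Poisson with the FPKM-implied mean", {
  cfg <- sim_config(n_genes = 1L, gene_length_range = c(1000, 1000),
                    tier_mix = c(High = 0, Middle = 0, Low = 1, No = 0),
                    base_fpkm = c(High = 1, Middle = 1, Low = 10, No = 1),
                    fpkm_jitter_sdlog = 0, rho0 = 0, rho_fold = 1,
                    affected_fraction = 0, depth = 1e6, seed = 9L,
                    fraction_closely_spaced = 0)
  ann <- simulate_annotation(cfg)
  expect_equal(ann$truth$fpkm, 10)
  counts <- vapply(1:200, function(r) {
    lib <- simulate_library(ann$models, ann$truth, "control", r, cfg)
    n_stored_tags(lib)
  }, integer(1))
  se <- sqrt(10 / 200)
  expect_lt(abs(mean(counts) - 10), 3 * se)
  # and variance consistent with Poisson (loose 4-sigma band)
  expect_lt(abs(var(counts) - 10), 4 * 10 * sqrt(2 / 199))
})

test_that("fraction of tags past the TTS matches the placement geometry", {
  L <- 2000; D <- 5000; rho <- 0.5
  cfg <- sim_config(n_genes = 1L, gene_length_range = c(L, L),
                    tier_mix = c(High = 0, Middle = 0, Low = 1, No = 0),
                    base_fpkm = c(High = 1, Middle = 1, Low = 80, No = 1),
                    fpkm_jitter_sdlog = 0, rho0 = rho, rho_fold = 1,
                    affected_fraction = 0, d_max = D, depth = 1e6,
                    seed = 13L, fraction_closely_spaced = 0)
  ann <- simulate_annotation(cfg)
  g <- ann$models[[1L]]
  w <- downstream_window(g, D, cfg$chrom_length)
  past <- tot <- 0
  for (r in 1:200) {
    lib <- simulate_library(ann$models, ann$truth, "control", r, cfg)
    past <- past + count_tags(lib, w)
    tot <- tot + n_stored_tags(lib)
  }
  p_expected <- rho * expected_past_tts_fraction(L, D)
  se <- sqrt(p_expected * (1 - p_expected) / tot)
  expect_lt(abs(past / tot - p_expected), 3 * se)
})

test_that("libraries are deterministic and conserve fragments", {
  cfg <- small_sim_config(library_size_mode = "stored")
  ann <- simulate_annotation(cfg)
  l1 <- simulate_library(ann$models, ann$truth, "control", 1L, cfg)
  l2 <- simulate_library(ann$models, ann$truth, "control", 1L, cfg)
  expect_identical(l1$tags, l2$tags)
  l3 <- simulate_library(ann$models, ann$truth, "control", 2L, cfg)
  expect_false(identical(l1$tags, l3$tags))
  expect_equal(l1$library_size, n_stored_tags(l1))
})

test_that("raising rho_fold increases affected read-through, not unaffected", {
  base <- list(n_genes = 40L, depth = 4e6, seed = 21L,
               fraction_closely_spaced = 0, rho0 = 0.15,
               affected_fraction = 0.5)
  cfg_lo <- do.call(sim_config, c(base, rho_fold = 1.5))
  cfg_hi <- do.call(sim_config, c(base, rho_fold = 4))
  rt_mean <- function(cfg) {
    sim <- simulate_experiment(cfg)
    q <- quantify_all(sim$models, sim$libraries, cfg$d_max,
                      cfg$chrom_length)
    cm <- condition_means(q)
    trt <- cm[cm$condition == "treated", ]
    trt <- trt[order(trt$gene_id), ]
    tr <- as.data.frame(sim$truth)
    list(rt = trt$mean_rt_fpkm, truth = tr[order(tr$gene_id), ])
  }
  lo <- rt_mean(cfg_lo); hi <- rt_mean(cfg_hi)
  aff <- lo$truth$affected & lo$truth$fpkm > 20
  expect_true(all(hi$rt[aff] > lo$rt[aff]))
  una <- !lo$truth$affected & lo$truth$fpkm > 20
  expect_lt(abs(mean(hi$rt[una] / lo$rt[una]) - 1), 0.15)
})

test_that("ChIP track sampling localizes kernels at the anchors", {
  g <- tiny_gene(start = 50000, end = 55000)
  spec <- list(background = 0, kernels = list())
  expect_equal(n_stored_tags(
    simulate_chip_track(list(g), spec, seed = 1L, chrom_length = 1e5)), 0L)
  expect_error(simulate_chip_track(
    list(g), list(background = 0,
                  kernels = list(list(anchor = "TSS", height = -1,
                                      width = 100))),
    seed = 1L, chrom_length = 1e5), "negative kernel height")

  spec2 <- list(background = 1e-4,
                kernels = list(list(anchor = "TSS", height = 2,
                                    width = 100)))
  pos <- unlist(lapply(1:100, function(s) {
    simulate_chip_track(list(g), spec2, seed = s,
                        chrom_length = 1e5)$tags[["chr1:+"]]
  }))
  edges <- seq(0, 1e5, by = 50)
  counts <- brute_bin_counts(pos, edges[-length(edges)], edges[-1])
  peak_bin <- which.max(counts)
  tss_bin <- findInterval(g$tss, edges)
  expect_lte(abs(peak_bin - tss_bin), 2)

  t1 <- simulate_chip_track(list(g), spec2, seed = 5L, chrom_length = 1e5)
  t2 <- simulate_chip_track(list(g), spec2, seed = 5L, chrom_length = 1e5)
  expect_identical(t1$tags, t2$tags)
})

test_that("written simulations round-trip through the standard formats", {
  cfg <- sim_config(n_genes = 12L, depth = 2e5, seed = 31L)
  sim <- simulate_experiment(cfg)
  d <- withr::local_tempdir()
  write_simulation(sim, d)
  models <- read_gene_models(file.path(d, "genes.bed12"), "BED12")
  expect_equal(vapply(models, `[[`, character(1), "gene_id"),
               vapply(sim$models, `[[`, character(1), "gene_id"))
  lib <- load_stranded_tags(file.path(d, "control_1.bed6"), "control", 1L,
                            library_size = sim$libraries[["control_1"]]$library_size)
  expect_equal(lib$tags, sim$libraries[["control_1"]]$tags)
  truth <- data.table::fread(file.path(d, "truth.tsv"))
  expect_equal(truth$gene_id, sim$truth$gene_id)
})
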