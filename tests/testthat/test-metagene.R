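make_uniform_cov <- function(lo, hi, per_base = 2L, strand = "+",
                             library_size = 1e6) {
  tiny_cov(rep(seq(lo, hi - 1L), each = per_base), strand = strand,
           library_size = library_size)
}

test_that("uniform coverage gives constant bins of 50 * c * 1e6 / L", {
  g <- tiny_gene(start = 10000, end = 14000)
  cov <- make_uniform_cov(5000, 20000, per_base = 2L)
  spec <- profile_spec("TTS", upstream_bp = 1000, downstream_bp = 5000)
  v <- per_gene_bins(g, cov, spec)
  expect_equal(v, rep(50 * 2 * 1e6 / 1e6, length(v)))
})

test_that("minus-strand bins mirror the plus-strand layout exactly", {
  spec <- profile_spec("TTS", upstream_bp = 1000, downstream_bp = 5000)
  gp <- tiny_gene(start = 10000, end = 14000, strand = "+")   # tts 14000
  cp <- tiny_cov(14120, library_size = 1e6)                   # 120 bp past
  gm <- tiny_gene(start = 36000, end = 40000, strand = "-")   # tts 36000
  cm <- tiny_cov(36000 - 1 - 120, strand = "-", library_size = 1e6)
  vp <- per_gene_bins(gp, cp, spec)
  vm <- per_gene_bins(gm, cm, spec)
  expect_equal(vp, vm)
  hit <- which(vp > 0)
  expect_equal(hit, 1000 / 50 + 3)   # third bin past the anchor (120 bp)
})

test_that("random fixtures bin identically to a brute-force per-tag loop", {
  set.seed(55)
  spec <- profile_spec("TSS", upstream_bp = 500, downstream_bp = 1500,
                       bin_bp = 50)
  for (strand in c("+", "-")) {
    g <- tiny_gene(start = 20000, end = 23000, strand = strand)
    pos <- sample(18000:26000, 800, replace = TRUE)
    cov <- tiny_cov(pos, strand = strand, library_size = 2e6)
    v <- per_gene_bins(g, cov, spec)
    offs <- seq(-500, 1450, by = 50)
    lo <- if (strand == "+") g$tss + offs else g$tss - offs - 50
    hi <- lo + 50
    expect_equal(v, brute_bin_counts(pos, lo, hi) * 1e6 / 2e6)
  }
})

test_that("bins beyond the chromosome are missing, not zero", {
  g <- tiny_gene(start = 100, end = 1100, strand = "-")   # tts 100
  cov <- tiny_cov(50, strand = "-", library_size = 1e6)
  spec <- profile_spec("TTS", upstream_bp = 0, downstream_bp = 500)
  v <- per_gene_bins(g, cov, spec)
  expect_true(all(is.na(v[3:10])))    # windows reaching below position 0
  expect_false(anyNA(v[1:2]))
  prof <- average_profile(list(g), cov, spec)
  expect_equal(prof$n_contributing, c(1, 1, rep(0, 8)))
})

test_that("average profiles are per-bin means and conserve tag mass", {
  spec <- profile_spec("TTS", upstream_bp = 500, downstream_bp = 1000)
  g1 <- tiny_gene("a", start = 10000, end = 12000)
  g2 <- tiny_gene("b", start = 50000, end = 52500)
  cov <- make_uniform_cov(9000, 13500, per_base = 1L)
  # identical per-gene vectors -> mean equals either one
  p1 <- average_profile(list(g1, g1), cov, spec)
  expect_equal(p1$values, per_gene_bins(g1, cov, spec))
  expect_equal(p1$n_genes, 2L)
  expect_error(average_profile(list(), cov, spec), "empty")

  # conservation: sum(bin means) * n_genes = total normalized tags in the
  # profiled regions (regions disjoint, fully on-chromosome)
  set.seed(66)
  pos <- sample(8000:56000, 5000, replace = TRUE)
  cov2 <- tiny_cov(pos, library_size = 1e6)
  p2 <- average_profile(list(g1, g2), cov2, spec)
  regions <- rbind(c(g1$tts - 500, g1$tts + 1000),
                   c(g2$tts - 500, g2$tts + 1000))
  total <- sum(vapply(1:2, function(i) {
    brute_count(pos, regions[i, 1], regions[i, 2])
  }, numeric(1))) * 1e6 / 1e6
  expect_equal(sum(p2$values) * p2$n_genes, total, tolerance = 1e-9)
})

test_that("perturbation raises downstream-of-TTS profile bins", {
  cfg <- small_sim_config(depth = 4e6)
  sim <- simulate_experiment(cfg)
  spec <- profile_spec("TTS", upstream_bp = 1000, downstream_bp = 5000)
  keep <- sim$models[sim$truth$fpkm >= 10]
  pc <- average_profile(keep, sim$libraries[["control_1"]], spec,
                        cfg$chrom_length)
  pt <- average_profile(keep, sim$libraries[["treated_1"]], spec,
                        cfg$chrom_length)
  dn <- pc$offsets >= 0
  expect_gt(mean(pt$values[dn]), mean(pc$values[dn]))
})

test_that("scaled metagene equalizes body and flank bins under uniform coverage", {
  spec <- profile_spec("scaled-body", upstream_bp = 3000,
                       downstream_bp = 3000, body_bins = 60)
  # gene of exactly 3 kb: no rescaling needed
  g3 <- tiny_gene(start = 20000, end = 23000)
  cov <- make_uniform_cov(15000, 30000, per_base = 1L)
  v3 <- scaled_metagene(list(g3), cov, spec)$values
  expect_equal(v3, rep(50 * 1e6 / 1e6, length(v3)))
  # gene of 6 kb: density invariance after width rescaling
  g6 <- tiny_gene(start = 20000, end = 26000)
  cov6 <- make_uniform_cov(15000, 30000, per_base = 1L)
  v6 <- scaled_metagene(list(g6), cov6, spec)$values
  expect_equal(v6, rep(50 * 1e6 / 1e6, length(v6)))
  expect_length(v6, 60 + 60 + 60)
})

test_that("scaled metagene matches a fractional-overlap oracle on mixed lengths", {
  spec <- profile_spec("scaled-body", upstream_bp = 0, downstream_bp = 0,
                       body_bins = 10)
  set.seed(77)
  genes <- list(tiny_gene("a", start = 1000, end = 1123, strand = "+"),
                tiny_gene("b", start = 5000, end = 5777, strand = "-"))
  pos <- sort(c(sample(1000:1122, 200, replace = TRUE),
                sample(5000:5776, 300, replace = TRUE)))
  results <- lapply(genes, function(g) {
    cov <- tiny_cov(pos[pos >= g$start & pos < g$end], strand = g$strand,
                    library_size = 1e6)
    got <- scaled_metagene(list(g), cov, spec)$values
    # oracle: assign each unit tag interval fractionally to slices
    L <- g$body_length; B <- 10; wd <- L / B
    p <- cov$tags[[paste0("chr1:", g$strand)]]
    t <- if (g$strand == "+") p - g$start else g$end - 1 - p
    mass <- numeric(B)
    for (ti in t) {
      for (j in 0:(B - 1)) {
        ov <- max(0, min((j + 1) * wd, ti + 1) - max(j * wd, ti))
        mass[j + 1] <- mass[j + 1] + ov
      }
    }
    expected <- mass * 1e6 / 1e6 / wd * 50
    expect_equal(got, expected, tolerance = 1e-9)
  })
})

test_that("too-short genes are skipped with a warning", {
  spec <- profile_spec("scaled-body", upstream_bp = 0, downstream_bp = 0,
                       body_bins = 60)
  short <- tiny_gene("s", start = 100, end = 130)
  long <- tiny_gene("l", start = 10000, end = 13000)
  cov <- make_uniform_cov(9000, 14000)
  expect_warning(res <- scaled_metagene(list(short, long), cov, spec),
                 "skipped")
  expect_equal(res$n_genes, 1L)
})

test_that("heatmap rows order by FPKM and column means equal the profile", {
  set.seed(88)
  g1 <- tiny_gene("a", start = 20000, end = 24000)
  g2 <- tiny_gene("b", start = 60000, end = 63000)
  pos <- sample(15000:70000, 4000, replace = TRUE)
  cov <- tiny_cov(pos, library_size = 1e6)
  hm <- heatmap_matrix(list(g1, g2), cov, anchor = "TSS",
                       order_fpkm = c(5, 50), halfspan = 4000)
  expect_equal(hm$gene_ids, c("b", "a"))
  expect_equal(ncol(hm$matrix), 160L)
  spec <- profile_spec("TSS", upstream_bp = 4000, downstream_bp = 4000)
  prof <- average_profile(list(g1, g2), cov, spec)
  expect_equal(unname(colMeans(hm$matrix, na.rm = TRUE)), prof$values)
})

test_that("TSS-anchored ChIP heatmap peaks at the centre columns", {
  genes <- lapply(1:8, function(i) {
    tiny_gene(paste0("g", i), start = i * 30000, end = i * 30000 + 3000)
  })
  spec <- list(background = 2e-5,
               kernels = list(list(anchor = "TSS", height = 1.5,
                                   width = 120)))
  pos <- unlist(lapply(1:40, function(s) {
    simulate_chip_track(genes, spec, seed = s,
                        chrom_length = 3e5)$tags[["chr1:+"]]
  }))
  cov <- tiny_cov(pos, library_size = length(pos))
  # anchored signal is unstranded: genes here are all '+'
  hm <- heatmap_matrix(genes, cov, anchor = "TSS",
                       order_fpkm = rep(1, 8), halfspan = 4000)
  cm <- colMeans(hm$matrix, na.rm = TRUE)
  centre <- which(hm$offsets == 0)
  expect_lte(abs(which.max(cm) - centre), 2)
})

test_that("mirroring the genome leaves profiles unchanged", {
  cfg <- sim_config(n_genes = 20L, depth = 5e5, seed = 41L)
  sim <- simulate_experiment(cfg)
  L <- cfg$chrom_length
  spec <- profile_spec("TTS", upstream_bp = 1000, downstream_bp = 5000)
  lib <- sim$libraries[["treated_1"]]
  p1 <- average_profile(sim$models, lib, spec, L)
  p2 <- average_profile(lapply(sim$models, mirror_gene_model, genome_length = L),
                        mirror_coverage(lib, L), spec, L)
  expect_equal(p1$values, p2$values)
})
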