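test_that("raw enrichment matches hand-computed values", {
  # equal pre/post ratios cancel exactly
  ct <- as_count_table("b1", 100, 100, pre_tot = 1e6, post_tot = 1e6)
  lk <- simple_lookup("b1", "A2C")
  e <- compute_enrichment(ct, lk, enrichment_config(c_min = 0, alpha_p = 3.65e-7))
  expect_equal(e$e_raw, 0)

  # dropout barcode: pseudo-counts carry the ratio
  ct2 <- as_count_table("b1", 0, 10, pre_tot = 1e6, post_tot = 1e6)
  e2 <- compute_enrichment(ct2, lk, enrichment_config(0, 3.65e-7))
  expect_equal(e2$e_raw, log10(10.365 / 0.365), tolerance = 1e-12)

  # barcodes below c_min are excluded; a variant with none is missing
  ct3 <- as_count_table(c("b1", "b2"), c(2, 50), c(3, 60),
                        pre_tot = 1e6, post_tot = 1e6)
  lk3 <- simple_lookup(c("b1", "b2"), c("A2C", "A2D"))
  e3 <- compute_enrichment(ct3, lk3, enrichment_config(c_min = 5, alpha_p = 1e-7))
  expect_true(is.na(e3$e_raw[e3$variant_id == "A2C"]))
  expect_equal(e3$n_barcodes[e3$variant_id == "A2C"], 0L)
  expect_false(is.na(e3$e_raw[e3$variant_id == "A2D"]))

  expect_error(compute_enrichment(as_count_table("b1", 1, 1, pre_tot = 0,
                                                 post_tot = 10), lk),
               "empty condition")
})

test_that("enrichment equals the brute-force per-barcode oracle", {
  set.seed(404)
  for (rep in 1:100) {
    n <- sample(3:20, 1)
    barcodes <- sprintf("bc%02d", seq_len(n))
    variant_of <- sample(c("WT", "A2C", "A2D", "A2E"), n, replace = TRUE)
    n_pre <- rpois(n, 40)
    n_post <- rpois(n, 40)
    pre_tot <- sum(n_pre) + sample(1e3:1e5, 1)
    post_tot <- sum(n_post) + sample(1e3:1e5, 1)
    c_min <- sample(0:6, 1)
    alpha_p <- 10^runif(1, -9, -5)
    ct <- as_count_table(barcodes, n_pre, n_post,
                         pre_tot = pre_tot, post_tot = post_tot)
    got <- compute_enrichment(ct, simple_lookup(barcodes, variant_of),
                              enrichment_config(c_min, alpha_p))
    want <- brute_enrichment(n_pre, n_post, pre_tot, post_tot, variant_of,
                             c_min, alpha_p)
    expect_equal(got$e_raw, unname(want[got$variant_id]), tolerance = 1e-12)
  }
})

test_that("scaling every post count by a common factor leaves enrichment fixed", {
  set.seed(7)
  n <- 12
  barcodes <- sprintf("b%02d", 1:n)
  lk <- simple_lookup(barcodes, rep(c("WT", "A2C", "A2D"), each = 4))
  n_pre <- rpois(n, 100); n_post <- rpois(n, 100)
  ct1 <- as_count_table(barcodes, n_pre, n_post)
  ct2 <- as_count_table(barcodes, n_pre, n_post * 7)
  cfg <- enrichment_config(c_min = 0, alpha_p = 1e-6)
  expect_equal(compute_enrichment(ct1, lk, cfg)$e_raw,
               compute_enrichment(ct2, lk, cfg)$e_raw, tolerance = 1e-12)
})

test_that("normalization maps wild type to 1 and the dead median to 0", {
  # toy raw table: 1 condition/replicate, explicit dead panel at position 3
  raw <- structure(data.frame(
    variant_id = c("WT", "A3C", "A3D", "A3E", "K5R"),
    position = c(NA, 3L, 3L, 3L, 5L),
    condition = "c1", co2_um = 1000, replicate = 1L,
    e_raw = c(2.0, 0.1, 0.2, 0.3, 1.1), n_barcodes = 5L,
    stringsAsFactors = FALSE), class = c("enrichment_table", "data.frame"))
  norm <- normalize_enrichment(raw, dead_positions = 3L)
  e_dead <- 0.2
  expect_equal(norm$e_norm[norm$variant_id == "WT"], 1)
  expect_equal(median(norm$e_norm[which(norm$position == 3)]), 0)
  expect_equal(norm$e_norm[norm$variant_id == "K5R"], (1.1 - 0.2) / (2 - 0.2))
  # midpoint maps to one half
  raw$e_raw[raw$variant_id == "K5R"] <- (2 + e_dead) / 2
  norm2 <- normalize_enrichment(raw, dead_positions = 3L)
  expect_equal(norm2$e_norm[norm2$variant_id == "K5R"], 0.5)

  # idempotence: renormalizing an already-normalized table is the identity
  raw2 <- raw
  raw2$e_raw <- norm$e_norm
  expect_equal(normalize_enrichment(raw2, dead_positions = 3L)$e_norm,
               norm$e_norm)

  # degenerate: wild type indistinguishable from dead panel
  raw3 <- raw
  raw3$e_raw <- rep(1, 5)
  expect_error(normalize_enrichment(raw3, dead_positions = 3L),
               "no selection signal")
})

test_that("replicate correlation averages all unordered pairs", {
  mk <- function(e, rep) data.frame(
    variant_id = c("A2C", "A2D", "A2E"), position = 2L, condition = "c1",
    co2_um = 1000, replicate = rep, e_raw = e, n_barcodes = 3L, e_norm = e,
    stringsAsFactors = FALSE)
  ident <- rbind(mk(c(1, 2, 3), 1L), mk(c(1, 2, 3), 2L))
  expect_equal(pairwise_replicate_correlation(ident), 1.0)
  anti <- rbind(mk(c(1, 2, 3), 1L), mk(c(3, 2, 1), 2L))
  expect_equal(pairwise_replicate_correlation(anti), -1.0)

  three <- rbind(mk(c(1, 2, 3), 1L), mk(c(1.1, 2.3, 2.9), 2L),
                 mk(c(0.6, 2.4, 3.2), 3L))
  direct <- mean(c(cor(c(1, 2, 3), c(1.1, 2.3, 2.9)),
                   cor(c(1, 2, 3), c(0.6, 2.4, 3.2)),
                   cor(c(1.1, 2.3, 2.9), c(0.6, 2.4, 3.2))))
  expect_equal(pairwise_replicate_correlation(three), direct)

  # a variant missing in one replicate drops out of that pair only
  miss <- three
  miss$e_norm[miss$replicate == 2 & miss$variant_id == "A2E"] <- NA
  d12 <- cor(c(1, 2), c(1.1, 2.3))
  d13 <- cor(c(1, 2, 3), c(0.6, 2.4, 3.2))
  d23 <- cor(c(1.1, 2.3), c(0.6, 2.4))
  expect_equal(pairwise_replicate_correlation(miss), mean(c(d12, d13, d23)))

  expect_error(pairwise_replicate_correlation(mk(c(1, 2, 3), 1L)),
               "replicates")
})

test_that("the processing-parameter sweep scores every grid cell", {
  w <- toy_world(n_positions = 4, barcodes_per_variant = 4, depth = 2e4,
                 replicates = 2, co2_percent = c(1.5, 5),
                 dead_positions = 3L, seed = 31)
  res <- sweep_processing_params(w$counts, w$lookup,
                                 c_min_grid = c(0, 5, 10),
                                 alpha_p_grid = c(1e-8, 1e-7),
                                 dead_positions = 3L)
  expect_equal(nrow(res$surface), 6)
  expect_true(all(is.finite(res$surface$correlation)))
  expect_equal(res$correlation, max(res$surface$correlation))
  # the full grids of the optimized analysis evaluate 110 combinations
  full <- expand.grid(c_min = seq(0, 50, length.out = 11),
                      alpha_p = 10^seq(-9, -6, length.out = 10))
  expect_equal(nrow(full), 110)
})

test_that("sweep ties break toward the smallest thresholds", {
  # identical replicates: every cell ties at correlation 1
  n <- 9
  barcodes <- sprintf("b%d", 1:n)
  assign <- rep(c("WT", "A3C", "K5R"), each = 3)
  n_pre <- rep(c(100L, 120L, 90L), each = 3)
  n_post <- c(400L, 410L, 390L, 10L, 12L, 9L, 200L, 210L, 190L)
  one <- function(r) as_count_table(barcodes, n_pre, n_post, replicate = r)
  ct <- rbind(one(1L), one(2L))
  attr(ct, "totals") <- rbind(attr(one(1L), "totals"), attr(one(2L), "totals"))
  class(ct) <- c("count_table", "data.frame")
  lk <- simple_lookup(barcodes, assign)
  res <- sweep_processing_params(ct, lk, c_min_grid = c(0, 5, 20),
                                 alpha_p_grid = c(1e-8, 1e-6),
                                 dead_positions = 3L)
  expect_equal(res$correlation, 1.0)
  expect_equal(res$c_min, 0)
  expect_equal(res$alpha_p, 1e-8)
})

test_that("spiked low-count noise drives the selected c_min above zero", {
  # two replicates agree on well-covered barcodes; each variant also carries
  # a low-count noise barcode whose counts are independent between replicates
  set.seed(99)
  n_var <- 30
  ids <- c("WT", sprintf("A%d%s", rep(3:17, each = 2),
                         rep(c("C", "D"), 15)))[1:n_var]
  good_bc <- sprintf("good%02d", 1:n_var)
  noise_bc <- sprintf("noise%02d", 1:n_var)
  ratio <- exp(seq(-2, 1, length.out = n_var))
  mk_rep <- function(r) {
    pre_good <- rep(1000L, n_var)
    post_good <- as.integer(round(1000 * ratio))
    pre_noise <- rep(2L, n_var)
    post_noise <- sample(0:3, n_var, replace = TRUE)  # replicate-specific noise
    as_count_table(c(good_bc, noise_bc), c(pre_good, pre_noise),
                   c(post_good, post_noise), replicate = r)
  }
  a <- mk_rep(1L); b <- mk_rep(2L)
  ct <- rbind(a, b)
  attr(ct, "totals") <- rbind(attr(a, "totals"), attr(b, "totals"))
  class(ct) <- c("count_table", "data.frame")
  lk <- simple_lookup(c(good_bc, noise_bc), c(ids, ids))
  res <- sweep_processing_params(ct, lk, c_min_grid = c(0, 5, 10),
                                 alpha_p_grid = c(1e-7, 1e-6),
                                 dead_positions = 3L)
  expect_gt(res$c_min, 0)
})
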