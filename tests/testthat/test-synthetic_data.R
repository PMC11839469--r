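test_that("library enumeration covers every designed substitution", {
  ref <- random_reference(466, seed = 3)
  design <- reference_design(ref$protein, ref$cds)
  expect_equal(nrow(design$variants), 8835)  # 465 positions x 19
  expect_true(all(design$variants$mut_aa != design$variants$wt_aa))
  expect_false(any(duplicated(design$variants$variant_id)))

  two <- reference_design(ref$protein, mutable_positions = c(10, 20))
  expect_equal(nrow(two$variants), 38)

  expect_error(reference_design("MA", mutable_positions = integer(0)),
               "empty design")
})

test_that("generated libraries carry barcodes, kinetics and a dead panel", {
  w <- toy_world(n_positions = 4, dead_positions = 3L)
  gt <- w$lib$ground_truth
  expect_equal(nrow(gt), 4 * 19 + 1)
  expect_true("WT" %in% gt$variant_id)
  expect_true(all(gt$true_KC > 0))
  expect_true(all(gt$true_kcat >= 0))
  expect_true(all(gt$true_kcat[gt$is_dead] == 0))
  expect_setequal(unique(gt$position[gt$is_dead]), 3L)
  # every entry holds its configured number of unique 30-nt barcodes
  bm <- w$lib$barcode_map
  expect_false(any(duplicated(bm$barcode)))
  expect_true(all(nchar(bm$barcode) == 30))
  expect_true(all(table(bm$variant_id) == w$lib$config$barcodes_per_variant))
})

test_that("the master seed fully determines library and counts", {
  w1 <- toy_world(seed = 77, depth = 2e4)
  w2 <- toy_world(seed = 77, depth = 2e4)
  w3 <- toy_world(seed = 78, depth = 2e4)
  expect_identical(w1$lib$ground_truth, w2$lib$ground_truth)
  expect_identical(w1$lib$barcode_map, w2$lib$barcode_map)
  expect_identical(as.data.frame(w1$counts), as.data.frame(w2$counts))
  expect_false(identical(w1$lib$ground_truth$true_KC,
                         w3$lib$ground_truth$true_KC))
})

test_that("dissolved CO2 follows Henry's law with temperature correction", {
  c5 <- dissolved_co2(5, 37)
  expect_gt(c5, 1200 * 0.9)
  expect_lt(c5, 1200 * 1.1)
  expect_identical(dissolved_co2(0, 25), 0)
  # linear in the gas fraction
  expect_equal(dissolved_co2(10, 37), 2 * dissolved_co2(5, 37))
  # colder water dissolves more CO2
  expect_gt(dissolved_co2(5, 25), dissolved_co2(5, 37))
  expect_error(dissolved_co2(-1, 37))
  expect_error(dissolved_co2(5, -4))
})

test_that("expected counts match the exponential-growth closed form", {
  w <- toy_world(n_positions = 4, replicates = 1, co2_percent = 5,
                 sampling = FALSE, dead_positions = 3L)
  growth <- growth_model()
  cond <- w$conditions[1, ]
  t_sel <- cond$wt_doublings * log(2) / growth$mu_wt
  gt <- w$lib$ground_truth
  kc_wt <- gt$true_KC[gt$variant_id == "WT"]
  counts <- w$counts
  v_id <- w$lib$barcode_map$variant_id[match(counts$barcode,
                                             w$lib$barcode_map$barcode)]
  i <- match(v_id, gt$variant_id)
  vmr <- gt$true_kcat[i] * gt$expression_factor[i] /
    (gt$true_kcat[gt$variant_id == "WT"])
  v_rel <- ifelse(gt$is_dead[i], 0,
                  vmr * (kc_wt + cond$co2_um) / (gt$true_KC[i] + cond$co2_um))
  mu <- growth$mu_dead + (growth$mu_wt - growth$mu_dead) * v_rel
  ratio <- counts$n_post / counts$n_pre
  # per barcode, post/pre equals 2^(mu t / ln 2) up to the common depth factor
  scaled <- ratio / 2^(mu * t_sel / log(2))
  expect_equal(max(scaled) / min(scaled), 1, tolerance = 1e-12)
  # a wild-type barcode expands by exactly the configured doublings
  wt_bc <- counts$barcode[v_id == "WT"][1]
  k <- which(counts$barcode == wt_bc)
  expect_equal(ratio[k] / scaled[k], 100, tolerance = 1e-9)
})

test_that("sampled barcode counts sum exactly to the configured depth", {
  w <- toy_world(n_positions = 3, depth = 12345, replicates = 2,
                 co2_percent = c(1, 5))
  sums <- aggregate(cbind(n_pre, n_post) ~ condition + replicate,
                    as.data.frame(w$counts), sum)
  expect_true(all(sums$n_pre == 12345))
  expect_true(all(sums$n_post == 12345))
  expect_error(toy_world(depth = 0), "depth")
})

test_that("simulated FASTQ output is seed-deterministic and error-rate aware", {
  w <- toy_world(n_positions = 2, barcodes_per_variant = 2, seed = 5,
                 long_read_error = 0, reads_per_barcode = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- simulate_reads(w$lib, dir = d1)
  p2 <- simulate_reads(w$lib, dir = d2)
  expect_identical(readLines(p1$long), readLines(p2$long))
  expect_identical(readLines(p1$short), readLines(p2$short))
  # error rate 0: every read bundle is the exact variant sequence
  lookup <- build_lookup(p1$long, w$design, min_support = 1)
  truth <- w$lib$barcode_map
  m <- merge(lookup, truth, by = "barcode")
  expect_equal(nrow(m), nrow(truth))
  expect_true(all(m$assignment == m$variant_id))
})
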