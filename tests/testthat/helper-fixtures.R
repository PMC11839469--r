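# Shared fixtures: small synthetic worlds built in code.

# A compact selection world: short protein, a designated dead position, and
# simulated counts across a CO2 titration. Everything derives from `seed`.
toy_world <- function(n_positions = 6, seed = 101, barcodes_per_variant = 8,
                      depth = 1e5, replicates = 3,
                      co2_percent = c(0.3, 0.7, 1.5, 3, 5, 10),
                      dead_positions = c(3L, 5L), sampling = TRUE, ...) {
  ref <- random_reference(n_res = n_positions + 4, seed = seed)
  design <- reference_design(ref$protein, ref$cds,
                             mutable_positions = seq(2, n_positions + 1))
  config <- sim_config(seed = seed, barcodes_per_variant = barcodes_per_variant,
                       depth = depth, dead_positions = dead_positions, ...)
  lib <- generate_library(design, config)
  conditions <- selection_conditions(co2_percent = co2_percent,
                                     replicates = replicates)
  counts <- simulate_selection(lib, conditions, sampling = sampling)
  list(lib = lib, design = design, counts = counts,
       lookup = lookup_from_library(lib), conditions = conditions,
       dead_positions = dead_positions)
}

# Independent brute-force implementation of the enrichment equation, written
# directly from the definition: per-barcode total-normalized log10 ratio with
# total-weighted pseudo-counts, median over barcodes passing the threshold.
brute_enrichment <- function(n_pre, n_post, pre_tot, post_tot, variant_of,
                             c_min, alpha_p) {
  variants <- sort(unique(variant_of))
  out <- stats::setNames(rep(NA_real_, length(variants)), variants)
  for (v in variants) {
    vals <- c()
    for (i in which(variant_of == v)) {
      if (max(n_pre[i], n_post[i]) >= c_min) {
        li <- log10((n_post[i] + post_tot * alpha_p) /
                      (n_pre[i] + pre_tot * alpha_p)) -
          log10(post_tot / pre_tot)
        vals <- c(vals, li)
      }
    }
    if (length(vals) > 0) out[v] <- stats::median(vals)
  }
  out
}

# Wrap a plain one-condition table in the count_table layout.
as_count_table <- function(barcode, n_pre, n_post, condition = "c1",
                           co2_um = 1000, replicate = 1L,
                           pre_tot = sum(n_pre), post_tot = sum(n_post)) {
  structure(data.frame(barcode = barcode, condition = condition,
                       co2_um = co2_um, replicate = replicate,
                       n_pre = n_pre, n_post = n_post,
                       stringsAsFactors = FALSE),
            totals = data.frame(condition = condition, co2_um = co2_um,
                                replicate = replicate, pre_tot = pre_tot,
                                post_tot = post_tot, stringsAsFactors = FALSE),
            class = c("count_table", "data.frame"))
}

simple_lookup <- function(barcodes, assignments) {
  structure(data.frame(barcode = barcodes, assignment = assignments,
                       support = NA_integer_, stringsAsFactors = FALSE),
            class = c("barcode_lookup", "data.frame"))
}
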