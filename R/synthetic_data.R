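# Synthetic ground-truth libraries and simulation of the growth-coupled
# selection experiment (growth -> barcode counts -> reads), so that every
# downstream stage of the pipeline can be validated against known kinetics.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# one representative codon per amino acid (used when building mutant CDS)
.codon_of <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
  H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT",
  P = "CCG", Q = "CAA", R = "CGT", S = "TCT", T = "ACT", V = "GTT",
  W = "TGG", Y = "TAT")

#' Deterministic child seed
#'
#' Derives a per-operation seed from a master seed and a text tag so that a
#' single master seed fully determines every stochastic step while keeping the
#' draws of different steps independent. Result is kept below 2^31.
#'
#' @param seed master seed (integer).
#' @param tag character tag naming the operation.
#' @return an integer seed.
#' @keywords internal
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_len(nchar(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483629L)
}

.translate <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     no.init.codon = TRUE))
}

#' Generate a random reference protein and coding sequence
#'
#' Produces a synthetic reference of `n_res` residues (position 1 is the
#' initiator methionine) together with an in-frame coding sequence assembled
#' from standard codons. The default length matches a Form II rubisco large
#' subunit (466 residues).
#'
#' @param n_res protein length in residues.
#' @param seed integer seed; the same seed yields the same reference.
#' @return list with elements `protein` (character scalar) and `cds`
#'   (character scalar, `3 * n_res` nucleotides, no stop codon).
#' @export
random_reference <- function(n_res = 466, seed = 42) {
  stopifnot(n_res >= 2)
  set.seed(child_seed(seed, "reference"))
  aa <- c("M", sample(AA20, n_res - 1, replace = TRUE))
  cds <- paste(.codon_of[aa], collapse = "")
  list(protein = paste(aa, collapse = ""), cds = cds)
}

#' Describe a designed single-substitution library
#'
#' Enumerates the designed variants of a reference protein: every mutable
#' position crossed with the 19 non-wild-type amino acids (all point mutants
#' were designed). Variant identifiers follow the `<wt><position><mut>`
#' convention (e.g. `"K191E"`), positions 1-based with position 1 the
#' initiator methionine (not mutable by default).
#'
#' @param protein reference amino-acid sequence (character scalar).
#' @param cds optional in-frame coding sequence (needed for read simulation
#'   and consensus classification); must translate to `protein`.
#' @param mutable_positions integer vector of 1-based mutable positions;
#'   default all positions except 1.
#' @return an object of class `reference_design`: list with `protein`, `cds`,
#'   `mutable_positions` and `variants` (data.frame: `variant_id`, `position`,
#'   `wt_aa`, `mut_aa`).
#' @examples
#' d <- reference_design(random_reference(10)$protein)
#' nrow(d$variants)  # 9 positions x 19 = 171
#' @export
reference_design <- function(protein, cds = NULL, mutable_positions = NULL) {
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  if (is.null(mutable_positions)) mutable_positions <- setdiff(seq_len(n), 1L)
  mutable_positions <- sort(unique(as.integer(mutable_positions)))
  if (length(mutable_positions) == 0) stop("empty design")
  if (any(mutable_positions < 1 | mutable_positions > n))
    stop("mutable positions outside the reference")
  if (!is.null(cds)) {
    if (nchar(cds) != 3 * n) stop("cds length must be 3 x protein length")
    if (.translate(cds) != protein) stop("cds does not translate to protein")
  }
  pos <- rep(mutable_positions, each = 19L)
  wt <- aa[pos]
  mut <- unlist(lapply(aa[mutable_positions],
                       function(w) setdiff(AA20, w)), use.names = FALSE)
  variants <- data.frame(
    variant_id = paste0(wt, pos, mut),
    position = pos, wt_aa = wt, mut_aa = mut,
    stringsAsFactors = FALSE)
  structure(list(protein = protein, cds = cds,
                 mutable_positions = mutable_positions, variants = variants),
            class = "reference_design")
}

#' Catalytic dead-panel positions
#'
#' The active-site positions whose mutants define zero carboxylation activity
#' and hence the fitness baseline: K166, K191, D193, E194, H287 and K329.
#'
#' @return integer vector of 1-based protein positions.
#' @export
dead_panel_positions <- function() c(166L, 191L, 193L, 194L, 287L, 329L)

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults state the
#' emulated experiment: ~20 barcodes per variant, deep short-read counting,
#' long-read bundles of 20 reads per barcode with a 10% per-base substitution
#' error (PacBio-like raw accuracy), and kinetic priors anchored on the
#' wild-type enzyme (KC 149 uM, kcat 8 1/s): mutant KC log-normal (two-sided
#' — rare affinity improvements exist), mutant kcat a half-normal decrement
#' on the log scale (no mutant exceeds wild-type turnover; apparent fitness
#' gains arise through the two-sided expression factor), pre-selection
#' barcode abundances log-normal (sdlog 0.5) to mimic library bottlenecking.
#'
#' @param seed master seed; fully determines all output.
#' @param barcodes_per_variant unique 30-nt barcodes per variant (and for the
#'   wild type).
#' @param depth short-read depth per condition per timepoint.
#' @param reads_per_barcode long reads per barcode.
#' @param long_read_error per-base substitution error rate in `[0, 0.5)`.
#' @param kc_wt,kcat_wt wild-type CO2 Michaelis constant (uM) and turnover
#'   (1/s); prior medians.
#' @param sdlog_kc,sdlog_kcat,sdlog_expression log-normal scale of the
#'   mutant KC, kcat and expression-factor priors.
#' @param sdlog_abundance log-normal scale of pre-selection barcode abundance.
#' @param dead_positions positions assigned to the catalytic dead panel
#'   (their mutants get `true_kcat = 0`).
#' @param short_depth reads for the simulated barcode amplicon run.
#' @return an object of class `sim_config` (a list).
#' @export
sim_config <- function(seed = 1L,
                       barcodes_per_variant = 20L,
                       depth = 1e6,
                       reads_per_barcode = 20L,
                       long_read_error = 0.1,
                       kc_wt = 149,
                       kcat_wt = 8,
                       sdlog_kc = 0.5,
                       sdlog_kcat = 0.7,
                       sdlog_expression = 0.25,
                       sdlog_abundance = 0.5,
                       dead_positions = dead_panel_positions(),
                       short_depth = NULL) {
  stopifnot(barcodes_per_variant >= 1, depth >= 1, reads_per_barcode >= 1,
            long_read_error >= 0, long_read_error < 0.5,
            kc_wt > 0, kcat_wt > 0)
  structure(list(seed = as.integer(seed),
                 barcodes_per_variant = as.integer(barcodes_per_variant),
                 depth = depth,
                 reads_per_barcode = as.integer(reads_per_barcode),
                 long_read_error = long_read_error,
                 kc_wt = kc_wt, kcat_wt = kcat_wt,
                 sdlog_kc = sdlog_kc, sdlog_kcat = sdlog_kcat,
                 sdlog_expression = sdlog_expression,
                 sdlog_abundance = sdlog_abundance,
                 dead_positions = as.integer(dead_positions),
                 short_depth = short_depth),
            class = "sim_config")
}

.random_barcodes <- function(n, width = 30L) {
  # collisions among random 30-mers are negligible but we guard anyway
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    m <- matrix(sample(c("A", "C", "G", "T"), (need + 8) * width,
                       replace = TRUE), ncol = width)
    out <- unique(c(out, apply(m, 1, paste, collapse = "")))
  }
  out[seq_len(n)]
}

#' Generate a ground-truth variant library
#'
#' Assigns each designed variant true kinetics drawn from the configured
#' log-normal priors, marks dead-panel mutants as catalytically dead
#' (`true_kcat = 0`, zero velocity at every CO2 level), adds a wild-type
#' entry, and attaches `barcodes_per_variant` unique 30-nt barcodes to every
#' entry. The same seed reproduces the table byte for byte.
#'
#' @param design a [reference_design()].
#' @param config a [sim_config()].
#' @return object of class `dms_library`: list with `ground_truth`
#'   (data.frame: `variant_id`, `position`, `wt_aa`, `mut_aa`, `true_kcat`,
#'   `true_KC`, `expression_factor`, `is_dead`), `barcode_map` (data.frame:
#'   `barcode`, `variant_id`), and the `design` and `config` used.
#' @export
generate_library <- function(design, config = sim_config()) {
  if (!inherits(design, "reference_design")) stop("design must be a reference_design")
  if (nrow(design$variants) == 0) stop("empty design")
  set.seed(child_seed(config$seed, "library"))
  v <- design$variants
  n <- nrow(v)
  gt <- data.frame(
    variant_id = c("WT", v$variant_id),
    position = c(NA_integer_, v$position),
    wt_aa = c(NA_character_, v$wt_aa),
    mut_aa = c(NA_character_, v$mut_aa),
    true_kcat = c(config$kcat_wt,
                  config$kcat_wt * exp(-abs(stats::rnorm(n, 0, config$sdlog_kcat)))),
    true_KC = c(config$kc_wt,
                config$kc_wt * exp(stats::rnorm(n, 0, config$sdlog_kc))),
    expression_factor = c(1, exp(stats::rnorm(n, 0, config$sdlog_expression))),
    stringsAsFactors = FALSE)
  gt$is_dead <- !is.na(gt$position) & gt$position %in% config$dead_positions
  gt$true_kcat[gt$is_dead] <- 0
  bc <- .random_barcodes(nrow(gt) * config$barcodes_per_variant)
  barcode_map <- data.frame(
    barcode = bc,
    variant_id = rep(gt$variant_id, each = config$barcodes_per_variant),
    stringsAsFactors = FALSE)
  structure(list(ground_truth = gt, barcode_map = barcode_map,
                 design = design, config = config),
            class = "dms_library")
}

#' Equilibrium dissolved CO2 from a gas-phase percentage
#'
#' Henry's-law conversion of a CO2 gas fraction at 1 atm total pressure to the
#' equilibrium dissolved concentration, with a van 't Hoff temperature
#' correction of the Henry constant: `KH(T) = KH25 * exp(C * (1/T - 1/298.15))`
#' with `KH25 = 0.0334 mol/(L atm)` and `C = 2400 K`. At 5% CO2 and 37 C this
#' gives about 1,220 uM, the concentration the selection at 5% CO2 sees.
#' Linear in the gas percentage.
#'
#' @param co2_percent CO2 percentage of the gas phase, in `[0, 100]`.
#' @param temperature_c temperature in degrees Celsius, in `(0, 100)`.
#' @param kh_25 Henry solubility at 25 C in mol/(L atm).
#' @param vant_hoff_k van 't Hoff temperature-dependence constant in K.
#' @param pressure_atm total pressure in atm.
#' @return dissolved CO2 concentration in uM (vectorized over
#'   `co2_percent`).
#' @examples
#' dissolved_co2(5, 37)  # ~1220 uM
#' @export
dissolved_co2 <- function(co2_percent, temperature_c = 37,
                          kh_25 = 0.0334, vant_hoff_k = 2400,
                          pressure_atm = 1) {
  if (any(co2_percent < 0) || any(co2_percent > 100))
    stop("co2_percent must be within [0, 100]")
  if (any(temperature_c <= 0) || any(temperature_c >= 100))
    stop("temperature_c must be within (0, 100)")
  t_k <- temperature_c + 273.15
  kh <- kh_25 * exp(vant_hoff_k * (1 / t_k - 1 / 298.15))
  co2_percent / 100 * pressure_atm * kh * 1e6
}

#' Selection conditions for a CO2 titration
#'
#' One row per CO2 level per replicate. The wild type completes
#' `wt_doublings` doublings during selection (default `log2(100)`, the
#' 100-fold expansion of the cultures).
#'
#' @param co2_percent CO2 gas percentages of the titration.
#' @param replicates number of replicate selections per level.
#' @param temperature_c growth temperature (C), used for the dissolved-CO2
#'   conversion.
#' @param wt_doublings wild-type doublings during selection.
#' @return data.frame with columns `condition` (label), `co2_percent`,
#'   `co2_um`, `replicate`, `wt_doublings`.
#' @export
selection_conditions <- function(co2_percent = c(0.3, 0.7, 1.5, 3, 5, 10),
                                 replicates = 3, temperature_c = 37,
                                 wt_doublings = log2(100)) {
  stopifnot(replicates >= 1, wt_doublings > 0, all(co2_percent > 0))
  grid <- expand.grid(replicate = seq_len(replicates),
                      co2_percent = co2_percent)
  data.frame(condition = sprintf("co2_%g", grid$co2_percent),
             co2_percent = grid$co2_percent,
             co2_um = dissolved_co2(grid$co2_percent, temperature_c),
             replicate = grid$replicate,
             wt_doublings = wt_doublings,
             stringsAsFactors = FALSE)
}

#' Growth model linking enzyme velocity to growth rate
#'
#' Growth-rate differences are proportional to velocity differences, so the
#' mutant growth rate interpolates linearly between the dead-variant rate and
#' the wild-type rate: `mu(v) = mu_dead + (mu_wt - mu_dead) * v / v_WT`.
#' The proportionality constant cancels in the normalized enrichment, so the
#' absolute rates only set the dynamic range of the simulated counts.
#'
#' @param mu_wt wild-type growth rate (1/h).
#' @param mu_dead growth rate with catalytically dead rubisco (1/h),
#'   `0 <= mu_dead < mu_wt`.
#' @return object of class `growth_model`.
#' @export
growth_model <- function(mu_wt = 0.6, mu_dead = 0.06) {
  stopifnot(mu_wt > mu_dead, mu_dead >= 0)
  structure(list(mu_wt = mu_wt, mu_dead = mu_dead), class = "growth_model")
}

# relative velocity v_mut/v_WT at dissolved CO2 c (uM):
# vmax_ratio * (KC_wt + c) / (KC_mut + c), zero for dead variants
.relative_velocity <- function(gt, co2_um, kc_wt) {
  vr <- gt$true_kcat * gt$expression_factor /
    (gt$true_kcat[gt$variant_id == "WT"] *
       gt$expression_factor[gt$variant_id == "WT"])
  ifelse(gt$is_dead | gt$true_kcat == 0, 0,
         vr * (kc_wt + co2_um) / (gt$true_KC + co2_um))
}

#' Simulate the selection experiment into a count table
#'
#' For every condition and replicate, barcodes start at log-normal
#' pre-selection abundances; each grows exponentially at
#' `mu = mu_dead + (mu_wt - mu_dead) * v/v_WT` evaluated at that condition's
#' dissolved CO2, for the time in which the wild type completes its configured
#' doublings. Pre- and post-selection reads are then drawn multinomially at
#' the configured depth (so barcode counts sum to the depth exactly). With
#' `sampling = FALSE` the expected (unsampled) counts are returned, scaled to
#' the depth, for closed-form checks.
#'
#' @param lib a [generate_library()] result.
#' @param conditions a [selection_conditions()] data.frame.
#' @param growth a [growth_model()].
#' @param sampling draw multinomial reads (default) or return expected counts.
#' @return object of class `count_table`: data.frame with columns `barcode`,
#'   `condition`, `co2_um`, `replicate`, `n_pre`, `n_post`; attribute
#'   `totals` is a data.frame of per condition/replicate totals.
#' @export
simulate_selection <- function(lib, conditions = selection_conditions(),
                               growth = growth_model(), sampling = TRUE) {
  if (!inherits(lib, "dms_library")) stop("lib must be a dms_library")
  if (nrow(conditions) == 0) stop("conditions non-empty")
  config <- lib$config
  if (config$depth <= 0) stop("zero read depth")
  gt <- lib$ground_truth
  bm <- lib$barcode_map
  kc_wt <- gt$true_KC[gt$variant_id == "WT"]
  idx <- match(bm$variant_id, gt$variant_id)
  n_bc <- nrow(bm)
  out <- vector("list", nrow(conditions))
  for (k in seq_len(nrow(conditions))) {
    cond <- conditions[k, ]
    # selection time: WT completes wt_doublings
    t_sel <- cond$wt_doublings * log(2) / growth$mu_wt
    v_rel <- .relative_velocity(gt, cond$co2_um, kc_wt)[idx]
    mu <- growth$mu_dead + (growth$mu_wt - growth$mu_dead) * v_rel
    set.seed(child_seed(config$seed,
                        paste0("selection/", cond$condition, "/r", cond$replicate)))
    pre_ab <- exp(stats::rnorm(n_bc, 0, config$sdlog_abundance))
    post_ab <- pre_ab * exp(mu * t_sel)
    if (sampling) {
      n_pre <- as.vector(stats::rmultinom(1, config$depth, pre_ab))
      n_post <- as.vector(stats::rmultinom(1, config$depth, post_ab))
    } else {
      n_pre <- pre_ab / sum(pre_ab) * config$depth
      n_post <- post_ab / sum(post_ab) * config$depth
    }
    out[[k]] <- data.frame(barcode = bm$barcode,
                           condition = cond$condition,
                           co2_um = cond$co2_um,
                           replicate = cond$replicate,
                           n_pre = n_pre, n_post = n_post,
                           stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, out)
  totals <- do.call(rbind, lapply(out, function(d) data.frame(
    condition = d$condition[1], co2_um = d$co2_um[1],
    replicate = d$replicate[1],
    pre_tot = sum(d$n_pre), post_tot = sum(d$n_post),
    stringsAsFactors = FALSE)))
  structure(counts, totals = totals, class = c("count_table", "data.frame"))
}

#' Default read anchors
#'
#' Fixed flanking sequences delimiting the 30-nt barcode in simulated reads;
#' the coding sequence follows the 3' anchor in long reads.
#'
#' @param five,three anchor sequences 5' and 3' of the barcode.
#' @return list with `five` and `three`.
#' @export
read_anchors <- function(five = "ACGTGCTAGCTAGGTACCTA",
                         three = "TGCATGCGATATCGGATCCA") {
  list(five = five, three = three)
}

# i.i.d. substitution errors on a bundle of identical sequences;
# returns character vector of n mutated copies of seq
.mutate_copies <- function(seq, n, error_rate) {
  base <- strsplit(seq, "")[[1]]
  L <- length(base)
  m <- matrix(rep(base, n), nrow = L)
  if (error_rate > 0) {
    hit <- which(stats::runif(L * n) < error_rate)
    if (length(hit)) {
      # substitute with one of the three other bases
      alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
      k <- sample.int(3, length(hit), replace = TRUE)
      m[hit] <- substring(alt[m[hit]], k, k)
    }
  }
  apply(m, 2, paste, collapse = "")
}

.write_fastq <- function(ids, seqs, path) {
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), con)
  invisible(path)
}

#' Simulate long-read and short-read FASTQ files
#'
#' Long reads emulate the per-barcode bundles of a PacBio run on the plasmid
#' library: each read is `anchor5 + barcode + anchor3 + coding sequence`, with
#' i.i.d. substitution errors on the coding-sequence payload at the configured
#' rate (barcode read-out is taken as exact; 30-nt random barcodes make
#' collisions and mis-grouping negligible). Short reads are barcode amplicons
#' (`anchor5 + barcode + anchor3`) drawn multinomially from log-normal
#' abundances. Output is reproducible byte for byte from the master seed.
#'
#' @param lib a [generate_library()] result (its design must carry a `cds`).
#' @param dir output directory.
#' @param anchors a [read_anchors()] list.
#' @return list with paths `long` and `short`.
#' @export
simulate_reads <- function(lib, dir = tempdir(), anchors = read_anchors()) {
  config <- lib$config
  design <- lib$design
  if (is.null(design$cds)) stop("design must carry a coding sequence")
  gt <- lib$ground_truth
  bm <- lib$barcode_map
  # per-variant coding sequence: replace the codon at the mutated position
  cds_of <- function(variant_id) {
    i <- match(variant_id, gt$variant_id)
    if (gt$variant_id[i] == "WT") return(design$cds)
    p <- gt$position[i]
    paste0(substr(design$cds, 1, 3 * (p - 1)),
           .codon_of[[gt$mut_aa[i]]],
           substr(design$cds, 3 * p + 1, nchar(design$cds)))
  }
  variant_cds <- vapply(gt$variant_id, cds_of, "")
  names(variant_cds) <- gt$variant_id

  set.seed(child_seed(config$seed, "long-reads"))
  long_ids <- character(0); long_seqs <- character(0)
  prefix <- paste0(anchors$five, bm$barcode, anchors$three)
  chunks <- vector("list", nrow(bm))
  for (i in seq_len(nrow(bm))) {
    payload <- .mutate_copies(variant_cds[[bm$variant_id[i]]],
                              config$reads_per_barcode, config$long_read_error)
    chunks[[i]] <- paste0(prefix[i], payload)
  }
  long_seqs <- unlist(chunks, use.names = FALSE)
  long_ids <- sprintf("long_%06d", seq_along(long_seqs))
  long_path <- file.path(dir, "long_reads.fastq")
  .write_fastq(long_ids, long_seqs, long_path)

  set.seed(child_seed(config$seed, "short-reads"))
  depth <- if (is.null(config$short_depth)) 10L * nrow(bm) else config$short_depth
  ab <- exp(stats::rnorm(nrow(bm), 0, config$sdlog_abundance))
  n <- as.vector(stats::rmultinom(1, depth, ab))
  short_seqs <- rep(paste0(anchors$five, bm$barcode, anchors$three), n)
  short_ids <- sprintf("short_%06d", seq_along(short_seqs))
  short_path <- file.path(dir, "short_reads.fastq")
  .write_fastq(short_ids, short_seqs, short_path)
  list(long = long_path, short = short_path)
}
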