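#' Simulation configuration
#'
#' A single configuration object drives every generator. Defaults state
#' the simulated world: library depth around 1e6 gene-mapped reads per
#' species (deep bulk RNA-seq), negative-binomial counts with moderate
#' dispersion, a small baseline cross-mapping fraction (~0.5% of a
#' gene's reads) with planted contaminated genes around 50%, a
#' 50-gene signature with a 1 log2-unit shift, a hazard ratio of 4 for
#' signature-high samples, and piecewise-exponential burden trajectories
#' (growth 0.2/day, regression -0.15/day, half of animals resistant)
#' observed weekly.
#'
#' @param seed integer RNG seed; identical config + seed gives
#'   byte-identical outputs
#' @param n_human_genes,n_mouse_genes gene counts per species
#' @param n_xeno,n_human_ctrl,n_mouse_ctrl sample counts per class
#' @param lib_size target gene-mapped reads per species library
#' @param dispersion NB dispersion (variance mu + mu^2 * dispersion);
#'   0 degenerates to Poisson
#' @param crossmap_rates optional explicit per-gene cross-mapping rates
#'   (length `n_human_genes + n_mouse_genes`, or a scalar); overrides the
#'   fraction-based defaults below
#' @param n_contaminated number of human genes planted as contaminated
#' @param contam_fraction target cross-mapped read fraction for
#'   contaminated genes
#' @param clean_fraction target cross-mapped read fraction for all other
#'   genes
#' @param stroma_fraction mouse (stromal) share of a xenograft library
#' @param n_sig_genes signature size; `sig_effect` log2 shift planted in
#'   affected samples/cells
#' @param hazard_ratio relative event hazard of planted signature-high
#'   samples
#' @param base_hazard events per day for signature-low samples
#' @param censor_horizon administrative censoring day
#' @param dropout_rate independent exponential dropout rate (per day)
#' @param n_animals,n_timepoints,obs_interval burden-trajectory sampling
#' @param treatment_start day treatment begins (must lie on the grid)
#' @param growth_rate,regression_rate exponential rates per day
#'   (growth > 0, regression < 0)
#' @param resistant_fraction fraction of animals that regrow; planted as
#'   an exact count `round(n_animals * resistant_fraction)`
#' @param regrowth_latency days after `treatment_start` at which a
#'   resistant animal's regrowth begins
#' @param burden_noise_sd lognormal measurement noise sigma
#' @param n_variants,n_true_persistent variant-table sizes
#' @return a validated `SimConfig` list.
#' @export
sim_config <- function(seed = 1L,
                       n_human_genes = 500L, n_mouse_genes = 500L,
                       n_xeno = 6L, n_human_ctrl = 2L, n_mouse_ctrl = 2L,
                       lib_size = 1e6, dispersion = 0.05,
                       crossmap_rates = NULL,
                       n_contaminated = 25L,
                       contam_fraction = 0.5, clean_fraction = 0.005,
                       stroma_fraction = 0.5,
                       n_sig_genes = 50L, sig_effect = 1,
                       hazard_ratio = 4, base_hazard = 0.01,
                       censor_horizon = 365, dropout_rate = 0.001,
                       n_animals = 20L, n_timepoints = 16L,
                       obs_interval = 7, treatment_start = 21,
                       growth_rate = 0.2, regression_rate = -0.15,
                       resistant_fraction = 0.5, regrowth_latency = 21,
                       burden_noise_sd = 0.1,
                       n_variants = 40L, n_true_persistent = 5L) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_human_genes >= 1, cfg$n_mouse_genes >= 1,
    cfg$dispersion >= 0, cfg$lib_size > 0,
    cfg$contam_fraction >= 0, cfg$contam_fraction < 1,
    cfg$clean_fraction >= 0, cfg$clean_fraction < 1,
    cfg$stroma_fraction > 0, cfg$stroma_fraction < 1,
    cfg$n_contaminated <= cfg$n_human_genes,
    cfg$sig_effect >= 0, cfg$hazard_ratio > 0, cfg$base_hazard > 0,
    cfg$resistant_fraction >= 0, cfg$resistant_fraction <= 1,
    cfg$burden_noise_sd >= 0,
    cfg$n_true_persistent <= cfg$n_variants
  )
  if (!is.null(crossmap_rates)) {
    n_genes <- cfg$n_human_genes + cfg$n_mouse_genes
    if (!length(crossmap_rates) %in% c(1L, n_genes))
      stop("crossmap_rates must be scalar or one per gene")
    if (any(crossmap_rates < 0 | crossmap_rates >= 1))
      stop("crossmap_rates must lie in [0, 1)")
  }
  structure(cfg, class = "SimConfig")
}

# NB draw with variance mu + mu^2 * dispersion; dispersion 0 -> Poisson
rnbinom_disp <- function(n, mu, dispersion) {
  if (dispersion == 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

# lognormal gene base means scaled to sum to `total`
gene_means <- function(n, total) {
  m <- stats::rlnorm(n, meanlog = 0, sdlog = 1)
  m / sum(m) * total
}

#' Generate a dual-species count matrix with planted contamination
#'
#' Builds gene base means per species (lognormal, scaled to the library
#' size), draws negative-binomial "true" counts, then plants
#' cross-mapped reads: in any library containing mouse material, human
#' gene g additionally receives `Poisson(rate_g * mouse_gene_total)`
#' reads, and symmetrically. Rates default to values that put
#' contaminated human genes near `contam_fraction` of their observed
#' xenograft reads and every other gene near `clean_fraction`.
#' Human-only controls carry no mouse material and vice versa, so
#' opposite-species counts in controls are pure cross-mapping.
#'
#' @param cfg a [sim_config()]
#' @return list with `data` (a [DualSpeciesCounts()]), `truth`
#'   (data.frame `gene_id, sample_id, true_count, crossmap_count,
#'   crossmap_fraction` over xenograft samples), `contaminated_genes`
#'   (planted ids), `rates` (the planted per-gene rates) and
#'   `gene_means` (the planted per-gene expression means).
#' @export
gen_dual_species_counts <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (cfg$n_human_ctrl < 1L || cfg$n_mouse_ctrl < 1L)
    stop("need at least one human_only and one mouse_only control")
  set.seed(cfg$seed)
  nh <- cfg$n_human_genes; nm <- cfg$n_mouse_genes
  hg <- sprintf("HG%05d", seq_len(nh))
  mg <- sprintf("MG%05d", seq_len(nm))
  mu_h <- stats::setNames(gene_means(nh, cfg$lib_size), hg)
  mu_m <- stats::setNames(gene_means(nm, cfg$lib_size), mg)

  contaminated <- sample(hg, cfg$n_contaminated)
  if (is.null(cfg$crossmap_rates)) {
    # rate_g chosen so expected crossmap / (crossmap + true) hits the
    # target fraction given the expected opposite-species library size
    frac <- stats::setNames(rep(cfg$clean_fraction, nh + nm), c(hg, mg))
    frac[contaminated] <- cfg$contam_fraction
    mu_all <- c(mu_h, mu_m)
    # in a xenograft, human true means are scaled by (1 - stroma_fraction)
    scale_true <- ifelse(names(mu_all) %in% hg,
                         1 - cfg$stroma_fraction, cfg$stroma_fraction)
    opp_total <- ifelse(names(mu_all) %in% hg,
                        cfg$lib_size * cfg$stroma_fraction,
                        cfg$lib_size * (1 - cfg$stroma_fraction))
    rates <- frac / (1 - frac) * mu_all * scale_true / opp_total
  } else {
    rates <- rep(cfg$crossmap_rates, length.out = nh + nm)
    names(rates) <- c(hg, mg)
  }

  sample_ids <- c(sprintf("xeno%02d", seq_len(cfg$n_xeno)),
                  sprintf("hctrl%02d", seq_len(cfg$n_human_ctrl)),
                  sprintf("mctrl%02d", seq_len(cfg$n_mouse_ctrl)))
  classes <- rep(c("xenograft", "human_only", "mouse_only"),
                 c(cfg$n_xeno, cfg$n_human_ctrl, cfg$n_mouse_ctrl))

  counts <- matrix(0L, nrow = nh + nm, ncol = length(sample_ids),
                   dimnames = list(c(hg, mg), sample_ids))
  truth <- vector("list", cfg$n_xeno)

  for (j in seq_along(sample_ids)) {
    cls <- classes[j]
    h_scale <- switch(cls, xenograft = 1 - cfg$stroma_fraction,
                      human_only = 1, mouse_only = 0)
    m_scale <- switch(cls, xenograft = cfg$stroma_fraction,
                      human_only = 0, mouse_only = 1)
    true_h <- if (h_scale > 0)
      rnbinom_disp(nh, mu_h * h_scale, cfg$dispersion) else integer(nh)
    true_m <- if (m_scale > 0)
      rnbinom_disp(nm, mu_m * m_scale, cfg$dispersion) else integer(nm)
    # cross-mapping driven by the realized opposite-species totals
    cm_h <- if (sum(true_m) > 0)
      stats::rpois(nh, rates[hg] * sum(true_m)) else integer(nh)
    cm_m <- if (sum(true_h) > 0)
      stats::rpois(nm, rates[mg] * sum(true_h)) else integer(nm)
    obs <- c(true_h + cm_h, true_m + cm_m)
    counts[, j] <- obs
    if (cls == "xenograft") {
      truth[[j]] <- data.frame(
        gene_id = c(hg, mg),
        sample_id = sample_ids[j],
        true_count = c(true_h, true_m),
        crossmap_count = c(cm_h, cm_m),
        crossmap_fraction = ifelse(obs > 0, c(cm_h, cm_m) / obs, 0),
        stringsAsFactors = FALSE
      )
    }
  }

  gene_info <- data.frame(
    gene_id = c(hg, mg),
    species = rep(c("human", "mouse"), c(nh, nm)),
    length_bp = stats::setNames(
      sample(500:5000, nh + nm, replace = TRUE), NULL),
    stringsAsFactors = FALSE
  )
  sample_info <- data.frame(sample_id = sample_ids, class = classes,
                            stringsAsFactors = FALSE)
  list(
    data = DualSpeciesCounts(counts, gene_info, sample_info),
    truth = do.call(rbind, truth),
    contaminated_genes = sort(contaminated),
    rates = rates,
    gene_means = c(mu_h, mu_m)
  )
}

#' Generate a single-cell expression matrix with a planted group shift
#'
#' Cells carry Gaussian log-scale expression; cells in the
#' `"progressive"` group have each signature gene shifted up by
#' `sig_effect`. Groups are `"TN"` (treatment-naive) and
#' `"progressive"`.
#'
#' @param cfg a [sim_config()]
#' @param n_cells_per_group cells per group (>= 2)
#' @param n_genes total genes in the matrix
#' @return list with `expr` (cell x gene matrix), `groups`, `signature`
#'   (the planted gene ids).
#' @export
gen_single_cell_matrix <- function(cfg = sim_config(),
                                   n_cells_per_group = 100L,
                                   n_genes = 200L) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (n_cells_per_group < 2L) stop("need at least 2 cells per group")
  if (cfg$n_sig_genes < 1L) stop("empty signature")
  if (cfg$n_sig_genes > n_genes) stop("signature larger than gene panel")
  set.seed(cfg$seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  signature <- sample(genes, cfg$n_sig_genes)
  groups <- rep(c("TN", "progressive"), each = n_cells_per_group)
  n_cells <- length(groups)
  expr <- matrix(stats::rnorm(n_cells * n_genes, mean = 2, sd = 1),
                 nrow = n_cells, ncol = n_genes,
                 dimnames = list(sprintf("cell%04d", seq_len(n_cells)),
                                 genes))
  expr[groups == "progressive", signature] <-
    expr[groups == "progressive", signature] + cfg$sig_effect
  list(expr = expr, groups = groups, signature = sort(signature))
}

#' Generate an expression cohort with survival tied to a planted score
#'
#' Half the cohort (above the median of a latent per-sample score) is
#' planted signature-high: its signature genes are shifted up by
#' `sig_effect` on the log scale. Event times are exponential with
#' hazard `base_hazard`, multiplied by `hazard_ratio` for planted-high
#' samples; censoring is administrative at `censor_horizon` plus
#' independent exponential dropout at `dropout_rate`.
#'
#' @param cfg a [sim_config()]
#' @param n_samples cohort size
#' @param n_genes total genes in the matrix
#' @return list with `expr` (gene x sample log-scale matrix),
#'   `survival` (data.frame `unit_id, time, event`), `signature`
#'   (planted gene ids) and `truth` (data.frame with `planted_high`).
#' @export
gen_survival_cohort <- function(cfg = sim_config(), n_samples = 100L,
                                n_genes = 200L) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (cfg$n_sig_genes > n_genes) stop("signature larger than gene panel")
  set.seed(cfg$seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  signature <- sample(genes, cfg$n_sig_genes)
  ids <- sprintf("S%03d", seq_len(n_samples))
  latent <- stats::rnorm(n_samples)
  planted_high <- latent > stats::median(latent)
  expr <- matrix(stats::rnorm(n_genes * n_samples, mean = 5, sd = 1),
                 nrow = n_genes, ncol = n_samples,
                 dimnames = list(genes, ids))
  expr[signature, planted_high] <-
    expr[signature, planted_high] + cfg$sig_effect

  hazard <- cfg$base_hazard * ifelse(planted_high, cfg$hazard_ratio, 1)
  t_event <- stats::rexp(n_samples, hazard)
  t_drop <- if (cfg$dropout_rate > 0)
    stats::rexp(n_samples, cfg$dropout_rate) else rep(Inf, n_samples)
  t_cens <- pmin(t_drop, cfg$censor_horizon)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  list(
    expr = expr,
    survival = data.frame(unit_id = ids, time = time, event = event,
                          stringsAsFactors = FALSE),
    signature = sort(signature),
    truth = data.frame(unit_id = ids, planted_high = planted_high,
                       latent = latent, stringsAsFactors = FALSE)
  )
}

# noise-free piecewise-exponential burden at day t
burden_model <- function(t, cfg, resistant) {
  ts <- cfg$treatment_start
  tr <- ts + cfg$regrowth_latency
  b0 <- 100  # arbitrary burden unit at injection
  pre <- b0 * exp(cfg$growth_rate * pmin(t, ts))
  phase2 <- exp(cfg$regression_rate * pmax(pmin(t, if (resistant) tr else Inf) - ts, 0))
  phase3 <- if (resistant) exp(cfg$growth_rate * pmax(t - tr, 0)) else 1
  pre * phase2 * phase3
}

# planted call days for one noise-free trajectory on the observation grid
planted_crossings <- function(cfg, resistant, grid) {
  ts <- cfg$treatment_start
  clean <- burden_model(grid, cfg, resistant)
  pre_idx <- grid <= ts
  baseline <- clean[max(which(pre_idx))]
  post <- grid[grid > ts]
  # PFS: continuous crossing of 2x baseline happens only during regrowth
  pfs_day <- NA_real_
  if (resistant) {
    hit <- post[burden_model(post, cfg, resistant) >= 2 * baseline - 1e-9]
    if (length(hit)) pfs_day <- hit[1]
  }
  # resistance: nadir on the grid is the minimum observed clean burden
  res_day <- NA_real_
  if (resistant) {
    post_all <- grid[grid >= ts]
    vals <- burden_model(post_all, cfg, resistant)
    nadir <- cummin(vals)
    cross <- which(vals >= 10 * nadir - 1e-9)
    if (length(cross)) res_day <- post_all[cross[1]]
  }
  c(pfs = pfs_day, resistance = res_day)
}

#' Generate tumor-burden trajectories with planted resistance
#'
#' Noise-free dynamics are piecewise exponential: growth at
#' `growth_rate` until `treatment_start`, regression at
#' `regression_rate` afterwards; a planted subset of exactly
#' `round(n_animals * resistant_fraction)` animals resumes growth
#' `regrowth_latency` days after treatment start. Multiplicative
#' lognormal measurement noise (`burden_noise_sd`) is applied to every
#' observation. Truth labels carry each animal's resistant flag and the
#' planted grid days at which the PFS (2x last pre-treatment burden) and
#' resistance (10x running nadir) rules fire on the noise-free series.
#'
#' @param cfg a [sim_config()] with `n_timepoints >= 3`
#' @return list with `series` (list of [BurdenSeries()]) and `truth`
#'   (data.frame `animal_id, resistant, pfs_day, resistance_day`).
#' @export
gen_burden_trajectories <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (cfg$n_timepoints < 3L) stop("need at least 3 timepoints")
  if (cfg$growth_rate <= 0) stop("growth_rate must be > 0")
  if (cfg$regression_rate >= 0) stop("regression_rate must be < 0")
  set.seed(cfg$seed)
  grid <- seq(0, by = cfg$obs_interval, length.out = cfg$n_timepoints)
  if (!cfg$treatment_start %in% grid)
    stop("treatment_start must lie on the observation grid")
  n_res <- round(cfg$n_animals * cfg$resistant_fraction)
  resistant <- rep(FALSE, cfg$n_animals)
  resistant[sample(cfg$n_animals, n_res)] <- TRUE

  series <- vector("list", cfg$n_animals)
  truth <- data.frame(
    animal_id = sprintf("A%03d", seq_len(cfg$n_animals)),
    resistant = resistant,
    pfs_day = NA_real_, resistance_day = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(cfg$n_animals)) {
    clean <- burden_model(grid, cfg, resistant[i])
    noise <- if (cfg$burden_noise_sd > 0)
      exp(stats::rnorm(length(grid), 0, cfg$burden_noise_sd)) else 1
    series[[i]] <- BurdenSeries(
      animal_id = truth$animal_id[i],
      time = grid, burden = clean * noise,
      treatment_start = cfg$treatment_start,
      compartment = "cranial"
    )
    cross <- planted_crossings(cfg, resistant[i], grid)
    truth$pfs_day[i] <- cross[["pfs"]]
    truth$resistance_day[i] <- cross[["resistance"]]
  }
  list(series = series, truth = truth)
}

#' Generate a variant table with planted persistent variants and decoys
#'
#' Planted persistent variants pass every quality, persistence and
#' expression criterion with wide margin. Decoys are each assigned one
#' criterion from the independently violable pool (quality: damaging,
#' vqsr, maf, dp, gq, mq, pldiff, lcr; persistence: dp_c, dp_r, ref_c,
#' delta_nraf, rol; expression: rpkm) and constructed to fail exactly
#' that criterion while passing all others. Three criteria are implied
#' by the rest and cannot be violated in isolation: quality depth
#' (DP >= 8 follows from persistence DP > 11), resistant alt reads and
#' resistant NRAF (any variant with DP > 11 and delta-NRAF > 0.25
#' necessarily has > 2 alt reads and NRAF > 0.15). Those are exercised
#' by boundary unit tests instead of decoys.
#'
#' @param cfg a [sim_config()]
#' @return list with `records` (variant table data.frame), `rpkm_table`
#'   (`gene_id, mean_rpkm`) and `truth` (`variant_id, persistent,
#'   decoy_criterion`).
#' @export
gen_variant_table <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  n <- cfg$n_variants
  n_pos <- cfg$n_true_persistent
  pool <- c("damaging", "vqsr", "maf", "gq", "mq", "pldiff", "lcr",
            "dp_c", "dp_r", "ref_c", "delta_nraf", "rol", "rpkm")
  decoy_crit <- if (n > n_pos)
    rep(pool, length.out = n - n_pos) else character(0)

  base_record <- function(i) {
    ref <- sample(c("A", "C", "G", "T"), 1)
    data.frame(
    variant_id = sprintf("V%03d", i),
    chrom = sample(paste0("chr", 1:22), 1),
    pos = sample.int(1e8, 1),
    ref = ref,
    alt = sample(setdiff(c("A", "C", "G", "T"), ref), 1),
    gene_id = sprintf("VG%03d", i),
    consequence = sample(c("LoF", "missense"), 1),
    metasvm_deleterious = TRUE,
    vqsr_pass = TRUE,
    gnomad_maf = stats::runif(1, 0, 2e-5),
    dp_C2D = 40L, alt_C2D = 0L, ref_C2D = 40L,
    dp_R2D = 40L, alt_R2D = 20L, ref_R2D = 20L,
    gq = 60, mq = 60, pldiff = 400, lcr = FALSE,
    present_RoL1 = TRUE, present_RoL2 = TRUE,
    present_RoL3 = TRUE, present_RoL4 = TRUE,
    stringsAsFactors = FALSE
  )}
  records <- do.call(rbind, lapply(seq_len(n), base_record))
  rpkm_vals <- stats::runif(n, 20, 80)

  for (k in seq_along(decoy_crit)) {
    i <- n_pos + k
    switch(decoy_crit[k],
      damaging = {
        records$consequence[i] <- "missense"
        records$metasvm_deleterious[i] <- FALSE
      },
      vqsr = records$vqsr_pass[i] <- FALSE,
      maf = records$gnomad_maf[i] <- 1e-4,
      gq = records$gq[i] <- 10,
      mq = records$mq[i] <- 30,
      pldiff = records$pldiff[i] <- 40,  # 40/40 = 1 < 8
      lcr = records$lcr[i] <- TRUE,
      dp_c = {
        records$dp_C2D[i] <- 11L
        records$ref_C2D[i] <- 11L
      },
      dp_r = {
        records$dp_R2D[i] <- 11L
        records$alt_R2D[i] <- 6L
        records$ref_R2D[i] <- 5L
      },
      ref_c = {
        # depth slack: alt + ref < DP keeps NRAF_C low while ref_C <= 2
        records$ref_C2D[i] <- 2L
        records$alt_C2D[i] <- 2L
      },
      delta_nraf = {
        records$alt_C2D[i] <- 12L
        records$ref_C2D[i] <- 28L  # NRAF_C = 0.3, delta = 0.2
      },
      rol = records$present_RoL4[i] <- FALSE,
      rpkm = rpkm_vals[i] <- 10  # boundary: mean RPKM exactly 10 fails
    )
  }
  truth <- data.frame(
    variant_id = records$variant_id,
    persistent = c(rep(TRUE, n_pos), rep(FALSE, n - n_pos)),
    decoy_criterion = c(rep(NA_character_, n_pos), decoy_crit),
    stringsAsFactors = FALSE
  )
  list(
    records = records,
    rpkm_table = data.frame(gene_id = records$gene_id,
                            mean_rpkm = rpkm_vals,
                            stringsAsFactors = FALSE),
    truth = truth
  )
}
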