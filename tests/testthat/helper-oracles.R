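# Independent oracles and tiny fixture builders shared across tests.
# Oracles are deliberately naive (loops, complete enumeration) and never
# call the implementation paths they check.

# brute-force classic enrichment score: explicit running-sum loop kept
# exact by working on the common denominator nh*nm (integers)
oracle_es <- function(ranked_ids, set) {
  hit <- ranked_ids %in% set
  nh <- sum(hit)
  nm <- length(ranked_ids) - nh
  run <- 0
  best <- 0
  for (i in seq_along(ranked_ids)) {
    run <- run + if (hit[i]) nm else -nh
    if (abs(run) > abs(best)) best <- run
  }
  best / (nh * nm)
}

# exhaustive two-sided Mann-Whitney p: enumerate every split of the
# pooled values into groups of the observed sizes
oracle_mw_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(x, y) sum(outer(x, y, function(p, q) (p > q) + 0.5 * (p == q)))
  dev_obs <- abs(u_of(a, b) - na * length(b) / 2)
  combos <- utils::combn(length(pooled), na)
  devs <- apply(combos, 2, function(ia) {
    abs(u_of(pooled[ia], pooled[-ia]) - na * length(b) / 2)
  })
  mean(devs >= dev_obs - 1e-9)
}

# minimal dual-species fixture: counts chosen by the caller
make_dual <- function(counts, species, classes) {
  gi <- data.frame(gene_id = rownames(counts), species = species,
                   length_bp = 1000L, stringsAsFactors = FALSE)
  si <- data.frame(sample_id = colnames(counts), class = classes,
                   stringsAsFactors = FALSE)
  DualSpeciesCounts(counts, gi, si)
}

# one fully passing variant record (wide margins on every criterion)
make_variant <- function(id = "V1", ...) {
  rec <- data.frame(
    variant_id = id, chrom = "chr1", pos = 1000L, ref = "A", alt = "T",
    gene_id = paste0("G_", id),
    consequence = "LoF", metasvm_deleterious = TRUE, vqsr_pass = TRUE,
    gnomad_maf = 1e-6,
    dp_C2D = 40L, alt_C2D = 0L, ref_C2D = 40L,
    dp_R2D = 40L, alt_R2D = 20L, ref_R2D = 20L,
    gq = 60, mq = 60, pldiff = 400, lcr = FALSE,
    present_RoL1 = TRUE, present_RoL2 = TRUE,
    present_RoL3 = TRUE, present_RoL4 = TRUE,
    stringsAsFactors = FALSE
  )
  over <- list(...)
  rec[names(over)] <- over
  rec
}

make_rpkm <- function(records, value = 50) {
  data.frame(gene_id = records$gene_id, mean_rpkm = value,
             stringsAsFactors = FALSE)
}

make_series <- function(time, burden, treatment_start = 0,
                        threshold = NA_real_) {
  BurdenSeries("A001", time, burden, treatment_start,
               compartment = "cranial", detection_threshold = threshold)
}
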