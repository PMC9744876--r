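#' Variant-filter threshold configuration
#'
#' Thresholds for the two-stage damaging-variant filter. Stage one is the
#' generic quality filter (inclusive thresholds); stage two is the paired
#' control-vs-resistant persistence filter (strict inequalities). The
#' `dominant` preset is the default rare-variant mode; `recessive`
#' relaxes the population-frequency cap to 1e-3 and requires a
#' non-reference genotype in the control sample (homozygous /
#' compound-heterozygous screening mode).
#'
#' @param preset `"dominant"` (default) or `"recessive"`
#' @param ... named overrides of individual thresholds
#' @return a `FilterConfig` list.
#' @export
filter_config <- function(preset = c("dominant", "recessive"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    # stage one: quality (inclusive unless noted)
    maf_max = 2e-5,        # gnomAD MAF cap
    dp_min = 8,            # per-record min depth, DP >= 8
    gq_min = 20,
    mq_min = 40,
    pldiff_dp_min = 8,     # PLdiff / DP >= 8
    # stage two: persistence (all strict)
    dp_paired_min = 11,    # DP > 11 in both control and resistant
    alt_r_min = 2,         # alt reads > 2 in resistant
    ref_c_min = 2,         # ref reads > 2 in control
    nraf_r_min = 0.15,     # NRAF > 0.15 in resistant
    delta_nraf_min = 0.25, # NRAF_R - NRAF_C > 0.25
    rol_required = 4L,     # variant present in all 4 late in vivo samples
    rpkm_min = 10,         # mean RPKM > 10 (expression gate)
    require_control_genotype = FALSE,
    preset = preset
  )
  if (preset == "recessive") {
    cfg$maf_max <- 1e-3
    cfg$require_control_genotype <- TRUE
  }
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown threshold(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "FilterConfig")
}

#' Non-reference allele frequency
#'
#' `NRAF = alt_reads / DP` at one site in one sample. DP (total depth) is
#' the denominator rather than `alt + ref`; uncalled bases count against
#' the frequency, matching the conventional VCF reading.
#'
#' @param alt_reads non-reference read count
#' @param dp total depth (> 0)
#' @return numeric frequency in \[0, 1\] (vectorized).
#' @export
nraf <- function(alt_reads, dp) {
  if (any(dp <= 0)) stop("NRAF undefined at DP = 0")
  if (any(alt_reads > dp)) stop("alt reads exceed depth")
  alt_reads / dp
}

.quality_criteria <- c("damaging", "vqsr", "maf", "dp", "gq", "mq",
                       "pldiff", "lcr")
.persistence_criteria <- c("dp_c", "dp_r", "alt_r", "ref_c",
                           "nraf_r", "delta_nraf", "rol")

# required variant-table columns (per-sample fields suffixed _C2D / _R2D;
# RoL presence flags present_RoL1..4)
.variant_columns <- c(
  "variant_id", "chrom", "pos", "ref", "alt", "gene_id",
  "consequence", "metasvm_deleterious", "vqsr_pass", "gnomad_maf",
  "dp_C2D", "alt_C2D", "ref_C2D", "dp_R2D", "alt_R2D", "ref_R2D",
  "gq", "mq", "pldiff", "lcr",
  "present_RoL1", "present_RoL2", "present_RoL3", "present_RoL4"
)

check_variant_table <- function(records) {
  miss <- setdiff(.variant_columns, names(records))
  if (length(miss))
    stop("variant table missing column(s): ", paste(miss, collapse = ", "))
  if (any(records$pos < 1)) stop("positions must be 1-based (>= 1)")
  if (any(records$gnomad_maf < 0 | records$gnomad_maf > 1))
    stop("gnomad_maf outside [0, 1]")
  for (s in c("C2D", "R2D")) {
    a <- records[[paste0("alt_", s)]]; r <- records[[paste0("ref_", s)]]
    d <- records[[paste0("dp_", s)]]
    if (any(a + r > d)) stop("alt + ref exceeds DP in sample ", s)
  }
  invisible(records)
}

#' Generic damaging-variant quality filter
#'
#' Stage one of the two-stage filter. A record survives iff it is
#' potentially damaging (loss-of-function, or missense predicted
#' deleterious) AND passes VQSR AND has population MAF <= `maf_max` AND
#' min-sample DP >= `dp_min` AND GQ >= `gq_min` AND MQ >= `mq_min` AND
#' PLdiff/DP >= `pldiff_dp_min` AND does not fall in a low-complexity
#' region. The rejection tally reports, per rejected record, the first
#' failing criterion in the order listed.
#'
#' @param records variant table data.frame (see [gen_variant_table()] for
#'   the column contract)
#' @param cfg a [filter_config()]
#' @return list with `records` (survivors), `tally` (named counts of first
#'   failing criterion) and `first_fail` (per-record criterion or NA).
#' @export
quality_filter <- function(records, cfg = filter_config()) {
  check_variant_table(records)
  dp_min_sample <- pmin(records$dp_C2D, records$dp_R2D)
  damaging <- records$consequence == "LoF" |
    (records$consequence == "missense" & records$metasvm_deleterious)
  checks <- list(
    damaging = damaging,
    vqsr = records$vqsr_pass,
    maf = records$gnomad_maf <= cfg$maf_max,
    dp = dp_min_sample >= cfg$dp_min,
    gq = records$gq >= cfg$gq_min,
    mq = records$mq >= cfg$mq_min,
    pldiff = records$pldiff / dp_min_sample >= cfg$pldiff_dp_min,
    lcr = !records$lcr
  )
  first_fail <- first_failing(checks, .quality_criteria)
  keep <- is.na(first_fail)
  list(
    records = records[keep, , drop = FALSE],
    tally = fail_tally(first_fail, .quality_criteria),
    first_fail = first_fail
  )
}

#' Paired control-vs-resistant persistence filter
#'
#' Stage two. A variant persists iff, with strict inequalities
#' throughout: depth exceeds `dp_paired_min` in both the control (C2D)
#' and resistant (R2D) in vitro samples; the resistant sample has more
#' than `alt_r_min` non-reference reads and the control more than
#' `ref_c_min` reference reads; resistant NRAF exceeds `nraf_r_min`; the
#' resistant-minus-control NRAF difference exceeds `delta_nraf_min`; and
#' the variant was called in all `rol_required` resistant-on-drug late
#' in vivo samples. Under the recessive preset the control sample must
#' additionally carry a non-reference genotype (alt reads > 0).
#'
#' @inheritParams quality_filter
#' @return list with `records`, `tally`, `first_fail` as in
#'   [quality_filter()].
#' @export
persistence_filter <- function(records, cfg = filter_config()) {
  check_variant_table(records)
  rol_cols <- paste0("present_RoL", seq_len(4))
  rol <- as.matrix(records[, rol_cols, drop = FALSE])
  if (anyNA(rol)) stop("missing RoL presence flags")
  nraf_c <- ifelse(records$dp_C2D > 0, records$alt_C2D / records$dp_C2D, NA_real_)
  nraf_r <- ifelse(records$dp_R2D > 0, records$alt_R2D / records$dp_R2D, NA_real_)
  checks <- list(
    dp_c = records$dp_C2D > cfg$dp_paired_min,
    dp_r = records$dp_R2D > cfg$dp_paired_min,
    alt_r = records$alt_R2D > cfg$alt_r_min,
    ref_c = records$ref_C2D > cfg$ref_c_min,
    nraf_r = !is.na(nraf_r) & nraf_r > cfg$nraf_r_min,
    delta_nraf = !is.na(nraf_r) & !is.na(nraf_c) &
      (nraf_r - nraf_c) > cfg$delta_nraf_min,
    rol = rowSums(rol) >= cfg$rol_required
  )
  if (cfg$require_control_genotype)
    checks$control_genotype <- records$alt_C2D > 0
  first_fail <- first_failing(checks, names(checks))
  keep <- is.na(first_fail)
  list(
    records = records[keep, , drop = FALSE],
    tally = fail_tally(first_fail, names(checks)),
    first_fail = first_fail
  )
}

#' Expression gate on variant-bearing genes
#'
#' Retains variants whose gene has mean RPKM strictly greater than
#' `rpkm_min` across all samples.
#'
#' @inheritParams quality_filter
#' @param rpkm_table data.frame with columns `gene_id`, `mean_rpkm`
#' @return list with `records` and `first_fail` (`"rpkm"` or NA).
#' @export
expression_filter <- function(records, rpkm_table, cfg = filter_config()) {
  if (nrow(records) == 0L)
    return(list(records = records,
                first_fail = character(0)))
  idx <- match(records$gene_id, rpkm_table$gene_id)
  if (anyNA(idx))
    stop("gene(s) absent from RPKM table: ",
         paste(unique(records$gene_id[is.na(idx)]), collapse = ", "))
  keep <- rpkm_table$mean_rpkm[idx] > cfg$rpkm_min
  list(
    records = records[keep, , drop = FALSE],
    first_fail = ifelse(keep, NA_character_, "rpkm")
  )
}

#' Run the full two-stage variant filter
#'
#' [quality_filter()], then [persistence_filter()], then
#' [expression_filter()]; returns survivors plus a per-record account of
#' the first criterion each rejected variant failed.
#'
#' @inheritParams expression_filter
#' @return list with `records` (survivors), `first_fail` (named by
#'   `variant_id`, NA for survivors) and `tally`.
#' @export
variant_filter <- function(records, rpkm_table, cfg = filter_config()) {
  q <- quality_filter(records, cfg)
  p <- persistence_filter(q$records, cfg)
  e <- expression_filter(p$records, rpkm_table, cfg)
  first_fail <- stats::setNames(q$first_fail, records$variant_id)
  first_fail[p$records$variant_id[!is.na(e$first_fail)]] <- "rpkm"
  pf <- stats::setNames(p$first_fail, q$records$variant_id)
  first_fail[names(pf)[!is.na(pf)]] <- pf[!is.na(pf)]
  all_crit <- c(.quality_criteria, .persistence_criteria,
                "control_genotype", "rpkm")
  list(
    records = e$records,
    first_fail = first_fail,
    tally = fail_tally(first_fail, all_crit)
  )
}

# first criterion (by the given order) failing per record; NA if none
first_failing <- function(checks, order) {
  n <- length(checks[[1]])
  out <- rep(NA_character_, n)
  for (crit in rev(order)) if (!is.null(checks[[crit]]))
    out[!checks[[crit]]] <- crit
  out
}

fail_tally <- function(first_fail, criteria) {
  table(factor(first_fail, levels = criteria))
}
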