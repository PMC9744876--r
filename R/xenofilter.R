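#' Estimate per-gene cross-species mapping rates from control libraries
#'
#' In a xenograft library sequenced against a combined human+mouse
#' annotation, a fraction of reads originating from one species aligns to
#' genes of the other. Species-pure control libraries expose this
#' directly: any read assigned to a human gene in a mouse-only library is
#' a cross-mapping artifact. The rate for human gene g is the pooled ratio
#'
#'   c_g = sum over mouse-only controls of counts(g) /
#'         sum over those controls of reads mapped to mouse genes
#'
#' and symmetrically for mouse genes over human-only controls. The rate is
#' read as "expected cross-mapped reads per read of the opposite-species
#' library".
#'
#' @param data a [DualSpeciesCounts()] object containing at least one
#'   `human_only` and one `mouse_only` sample.
#' @param pooling `"pooled"` (default; ratio of pooled sums across
#'   controls) or `"mean_of_ratios"` (per-control ratio, averaged).
#' @return A `CrossMapModel`: list with `rate` (named per-gene vector),
#'   `control_totals` (per-control opposite-species library totals),
#'   `n_controls_used` (per species) and `species` (per-gene labels).
#' @export
estimate_crossmap_rates <- function(data, pooling = c("pooled", "mean_of_ratios")) {
  stopifnot(inherits(data, "DualSpeciesCounts"))
  pooling <- match.arg(pooling)
  mouse_ctrl <- samples_of_class(data, "mouse_only")
  human_ctrl <- samples_of_class(data, "human_only")
  if (length(mouse_ctrl) == 0L)
    stop("no mouse_only control samples: cross-mapping to human genes unestimable")
  if (length(human_ctrl) == 0L)
    stop("no human_only control samples: cross-mapping to mouse genes unestimable")

  # totals of the *native* species in each control library
  mtot <- species_totals(data, "mouse", mouse_ctrl)
  htot <- species_totals(data, "human", human_ctrl)
  if (any(mtot <= 0)) stop("mouse_only control with zero mouse-gene library total")
  if (any(htot <= 0)) stop("human_only control with zero human-gene library total")

  is_h <- data$gene_info$species == "human"
  rate <- numeric(nrow(data$counts))
  names(rate) <- rownames(data$counts)

  rate_for <- function(gene_idx, ctrl_samples, ctrl_totals) {
    sub <- data$counts[gene_idx, ctrl_samples, drop = FALSE]
    if (pooling == "pooled") {
      rowSums(sub) / sum(ctrl_totals)
    } else {
      rowMeans(sweep(sub, 2, ctrl_totals, "/"))
    }
  }
  rate[is_h]  <- rate_for(which(is_h),  mouse_ctrl, mtot)
  rate[!is_h] <- rate_for(which(!is_h), human_ctrl, htot)

  structure(
    list(
      rate = rate,
      species = stats::setNames(data$gene_info$species, rownames(data$counts)),
      control_totals = list(mouse_only = mtot, human_only = htot),
      n_controls_used = c(human = length(human_ctrl), mouse = length(mouse_ctrl)),
      pooling = pooling
    ),
    class = "CrossMapModel"
  )
}

#' @export
print.CrossMapModel <- function(x, ...) {
  cat(sprintf(
    "CrossMapModel: %d genes; controls used: %d human_only, %d mouse_only (%s)\n",
    length(x$rate), x$n_controls_used[["human"]],
    x$n_controls_used[["mouse"]], x$pooling))
  cat(sprintf("  nonzero rates: %d; max rate: %.3g\n",
              sum(x$rate > 0), max(x$rate)))
  invisible(x)
}

#' Predict cross-mapped reads for one xenograft sample
#'
#' For human gene g in xenograft sample x the predicted contamination is
#' `rate_g * (reads of sample x mapped to mouse genes)`, and symmetrically
#' for mouse genes against the human-gene total.
#'
#' @param model a `CrossMapModel` from [estimate_crossmap_rates()]
#' @param data the [DualSpeciesCounts()] the model was fitted on
#' @param sample a single xenograft sample id
#' @return named numeric vector of predicted cross-mapped read counts,
#'   one entry per gene.
#' @export
predict_crossmapped_reads <- function(model, data, sample) {
  stopifnot(inherits(model, "CrossMapModel"),
            inherits(data, "DualSpeciesCounts"))
  if (length(sample) != 1L || !sample %in% colnames(data$counts))
    stop("unknown sample id: ", paste(sample, collapse = ", "))
  cls <- data$sample_info$class[data$sample_info$sample_id == sample]
  if (cls != "xenograft")
    stop("sample '", sample, "' has class '", cls, "', expected xenograft")
  if (!identical(names(model$rate), rownames(data$counts)))
    stop("model gene index does not match the count matrix")
  mouse_total <- species_totals(data, "mouse", sample)
  human_total <- species_totals(data, "human", sample)
  opp <- ifelse(model$species == "human", mouse_total, human_total)
  model$rate * opp
}

#' Exclude genes whose predicted cross-mapped reads exceed a threshold
#'
#' A gene is excluded when the mean (over xenograft samples) of
#' predicted cross-mapped reads / observed reads strictly exceeds
#' `threshold` (default 0.10, i.e. contamination "exceeding 10% of the
#' total reads mapped to that gene"). A fraction of exactly the threshold
#' is retained. Per-sample guards: observed 0 with a positive prediction
#' contributes fraction 1; observed 0 with prediction 0 contributes 0.
#' Genes with zero observed reads in every xenograft sample are excluded
#' with reason `"no_signal"`.
#'
#' @param model a `CrossMapModel`
#' @param data the matching [DualSpeciesCounts()]
#' @param threshold exclusion threshold in (0, 1); default 0.10
#' @param aggregate `"mean"` (default) averages the per-sample predicted
#'   fraction over xenograft samples; `"max"` excludes when any single
#'   sample exceeds the threshold.
#' @return list with `retained` / `excluded` gene-id vectors and `report`,
#'   a data.frame `gene_id, species, rate, mean_pred_fraction, decision,
#'   reason`.
#' @export
filter_genes <- function(model, data, threshold = 0.10,
                         aggregate = c("mean", "max")) {
  stopifnot(inherits(model, "CrossMapModel"),
            inherits(data, "DualSpeciesCounts"))
  aggregate <- match.arg(aggregate)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("`threshold` must be a single number in (0, 1)")
  xeno <- samples_of_class(data, "xenograft")
  if (length(xeno) == 0L) stop("no xenograft samples to filter on")
  if (!identical(names(model$rate), rownames(data$counts)))
    stop("model gene index does not match the count matrix")

  obs <- data$counts[, xeno, drop = FALSE]
  pred <- vapply(xeno, function(s) predict_crossmapped_reads(model, data, s),
                 numeric(nrow(obs)))
  frac <- pred / obs
  frac[obs == 0 & pred > 0] <- 1
  frac[obs == 0 & pred == 0] <- 0
  agg <- if (aggregate == "mean") rowMeans(frac) else apply(frac, 1, max)

  no_signal <- rowSums(obs) == 0
  excluded <- agg > threshold | no_signal
  reason <- ifelse(no_signal, "no_signal",
                   ifelse(excluded, "crossmap_fraction", "ok"))
  report <- data.frame(
    gene_id = rownames(obs),
    species = model$species,
    rate = model$rate,
    mean_pred_fraction = agg,
    decision = ifelse(excluded, "excluded", "retained"),
    reason = reason,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  list(
    retained = report$gene_id[!excluded],
    excluded = report$gene_id[excluded],
    report = report
  )
}
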