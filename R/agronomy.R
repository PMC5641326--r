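# Nitrogen-use-efficiency metrics and yield-component bookkeeping.
#
# Units are normalized internally to kg/ha for grain yield and kg/ha for N
# supply, so aNUE and NPFP come out in g grain per g N (kg/ha divided by
# kg/ha is unitless mass per mass).

#' Reference N fertilization schedules
#'
#' The ten treatment regimens of the trial: total N supply (kg/ha) split over
#' pre-sowing, emergence (January), tillering (February) and booting (April)
#' applications. Used as the default design of the synthetic trial.
#'
#' @return data.frame with columns `treatment`, `total_n` and the four split
#'   doses.
#' @export
n_treatment_schedules <- function() {
  read.csv(system.file("extdata", "table1_n_treatments.csv", package = "canopyx"),
           stringsAsFactors = FALSE)
}

#' Reference aNUE/NPFP grid
#'
#' Published per-genotype treatment means of agronomic N use efficiency and
#' N partial factor productivity (g grain per g N) for the nine non-zero
#' N regimens; the consistency-check fixture.
#'
#' @return data.frame with columns `treatment`, `genotype`, `anue`, `npfp`.
#' @export
nue_reference_table <- function() {
  read.csv(system.file("extdata", "table2_nue.csv", package = "canopyx"),
           stringsAsFactors = FALSE)
}

#' Agronomic nitrogen use efficiency
#'
#' aNUE = (GY - GY at zero N) / Nsupply, the yield gain over the unfertilized
#' control per unit of applied N. The zero-N reference is the mean yield of
#' the same genotype's N0 plots.
#'
#' @param gy grain yield (kg/ha).
#' @param gy_zero_n zero-N reference yield of the same genotype (kg/ha).
#' @param n_supply total applied N (kg/ha).
#' @return aNUE in g grain per g N; `NA` (flagged undefined) where
#'   `n_supply` is 0.
#' @export
compute_anue <- function(gy, gy_zero_n, n_supply) {
  ifelse(n_supply > 0, (gy - gy_zero_n) / n_supply, NA_real_)
}

#' Nitrogen partial factor productivity
#'
#' NPFP = GY / Nsupply, yield per unit applied N without control subtraction.
#'
#' @inheritParams compute_anue
#' @return NPFP in g grain per g N; `NA` where `n_supply` is 0.
#' @export
compute_npfp <- function(gy, n_supply) {
  ifelse(n_supply > 0, gy / n_supply, NA_real_)
}

#' Zero-N baseline yield implied by aNUE and NPFP
#'
#' Inverts the two definitions: GY_zeroN = (NPFP - aNUE) x Nsupply. Used to
#' check the internal consistency of a published aNUE/NPFP grid.
#'
#' @param anue,npfp metrics in g grain per g N.
#' @param n_supply total applied N (kg/ha), > 0.
#' @return implied baseline yield (kg/ha); warns when negative.
#' @export
implied_baseline_yield <- function(anue, npfp, n_supply) {
  stopifnot(all(n_supply > 0))
  if (any(npfp < anue))
    warning("NPFP < aNUE implies a negative zero-N baseline yield", call. = FALSE)
  (npfp - anue) * n_supply
}

#' Internal-consistency report for an aNUE/NPFP grid
#'
#' For each genotype, every non-zero-N row implies a zero-N baseline yield via
#' [implied_baseline_yield()]; if the grid is internally consistent all rows
#' imply (nearly) the same baseline. The report gives per-genotype baseline
#' statistics and the worst error of cross-row NPFP prediction: predicting
#' each row's NPFP as `anue + baseline/ n_supply` with the baseline taken from
#' every other row.
#'
#' @param table data.frame with columns `treatment`, `genotype`, `anue`,
#'   `npfp` (as [nue_reference_table()]); treatments must resolve to the
#'   reference schedules for their N supply.
#' @return data.frame, one row per genotype: `genotype`, `n_rows`,
#'   `baseline_mean` (kg/ha), `baseline_cv` (proportion), `max_npfp_error`
#'   (g/g, worst cross-row prediction error).
#' @export
table2_consistency <- function(table = nue_reference_table()) {
  sched <- n_treatment_schedules()
  table$n_supply <- sched$total_n[match(table$treatment, sched$treatment)]
  if (anyNA(table$n_supply))
    stop("unknown treatment labels: ",
         paste(unique(table$treatment[is.na(table$n_supply)]), collapse = ", "),
         call. = FALSE)
  table <- table[table$n_supply > 0, ]
  out <- lapply(split(table, table$genotype), function(g) {
    base <- implied_baseline_yield(g$anue, g$npfp, g$n_supply)
    # predict row i's NPFP from row j's baseline, all i != j
    err <- 0
    if (nrow(g) > 1) {
      pred <- outer(seq_len(nrow(g)), seq_len(nrow(g)), function(i, j)
        g$anue[i] + base[j] / g$n_supply[i])
      err <- max(abs(pred - g$npfp)[row(pred) != col(pred)])
    }
    data.frame(genotype = g$genotype[1], n_rows = nrow(g),
               baseline_mean = mean(base),
               baseline_cv = sd(base) / mean(base),
               max_npfp_error = err, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Yield-component consistency check
#'
#' Grain yield, grain number per area and thousand grain weight are linked by
#' GY = NG x TGW (per unit area): NG [grains/m2] x TGW [g] / 1000 gives
#' g/m2, i.e. 0.01 x NG x TGW in kg/ha.
#'
#' @param gy grain yield (kg/ha).
#' @param ng grains per m2.
#' @param tgw thousand grain weight (g).
#' @return relative discrepancy `|GY - 0.01 NG TGW| / GY`; `NA` (flagged)
#'   where GY = 0.
#' @export
yield_component_check <- function(gy, ng, tgw) {
  ifelse(gy > 0, abs(gy - 0.01 * ng * tgw) / gy, NA_real_)
}

#' Per-plot NUE metrics for a trial table
#'
#' Computes aNUE and NPFP for every plot, taking each genotype's zero-N
#' reference as the mean yield of its N0 plots, plus genotype x treatment
#' means.
#'
#' @param design data.frame with columns `genotype`, `treatment`, `gy` and
#'   `n_supply` (kg/ha). `gy_units` declares the yield unit.
#' @param gy_units "kg_ha" (default) or "t_ha".
#' @return list with `plots` (per-plot table with `anue`, `npfp` columns
#'   added) and `means` (genotype x treatment means of both metrics).
#' @export
nue_metrics <- function(design, gy_units = c("kg_ha", "t_ha")) {
  gy_units <- match.arg(gy_units)
  gy <- if (gy_units == "t_ha") design$gy * 1000 else design$gy
  zero <- tapply(gy[design$n_supply == 0], design$genotype[design$n_supply == 0], mean)
  if (length(zero) == 0) stop("no zero-N plots to define the aNUE baseline", call. = FALSE)
  gy0 <- zero[design$genotype]
  design$anue <- compute_anue(gy, gy0, design$n_supply)
  design$npfp <- compute_npfp(gy, design$n_supply)
  means <- aggregate(cbind(anue, npfp) ~ genotype + treatment,
                     data = design[design$n_supply > 0, ], FUN = mean)
  list(plots = design, means = means)
}
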