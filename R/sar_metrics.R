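# Ligand-efficiency metrics used to prioritise a congeneric inhibitor
# series: lipophilic ligand efficiency (LLE), ligand efficiency (LE) and
# size-normalised fit quality (FQ).

#' Lipophilic ligand efficiency
#'
#' LLE = pIC50 - logP. High lipophilicity inflates apparent potency against
#' membrane transporters such as P-glycoprotein simply through membrane
#' partitioning; LLE normalises for that and highlights ligands whose
#' activity reflects direct protein interaction.
#'
#' @param pIC50 negative log10 molar potency.
#' @param logP octanol/water partition coefficient (measured or calculated).
#' @return LLE at full precision (round for display with
#'   [round_half_up()]).
#' @examples
#' round_half_up(lipophilic_efficiency(7.24, 4.15)) # 3.09
#' @export
lipophilic_efficiency <- function(pIC50, logP) {
  if (!all(is.finite(pIC50)) || !all(is.finite(logP))) {
    stop("pIC50 and logP must be finite")
  }
  pIC50 - logP
}

#' Ligand efficiency
#'
#' LE = pIC50 / HAC: potency per heavy atom. Note this is the plain
#' per-atom potency, without the 1.37 kcal/mol conversion — the convention
#' matching the published table for this series; [fit_quality()] uses the
#' kcal-scaled form internally because the reference scales were fit on it.
#'
#' @param pIC50 negative log10 molar potency.
#' @param HAC heavy-atom count (>= 1).
#' @return LE at full precision.
#' @examples
#' round_half_up(ligand_efficiency(6.22, 27)) # 0.23
#' @export
ligand_efficiency <- function(pIC50, HAC) {
  if (!all(is.finite(pIC50))) stop("pIC50 must be finite")
  if (any(HAC < 1) || any(HAC != as.integer(HAC))) {
    stop("HAC must be a positive integer")
  }
  pIC50 / HAC
}

#' Size-normalised fit quality
#'
#' FQ = LE_kcal / LE_scale(HAC), where LE_kcal = 1.37 * pIC50 / HAC and
#' LE_scale is a size-dependent reference ligand efficiency. Two published
#' reference scales are supported plus an identity scale:
#' \describe{
#'   \item{reynolds_polynomial}{LE_scale = 0.0715 + 7.5328/HAC +
#'     25.7079/HAC^2 - 361.4722/HAC^3}
#'   \item{reynolds_exponential}{LE_scale = 0.873 * exp(-0.026 * HAC)}
#'   \item{identity}{LE_scale = 1 (returns the kcal-scaled LE itself)}
#' }
#' FQ magnitudes depend on the chosen scale and LE convention; within one
#' variant the ranking of a series is what matters.
#'
#' @param pIC50 negative log10 molar potency.
#' @param HAC heavy-atom count (>= 1).
#' @param variant reference scale (see Details).
#' @return FQ at full precision.
#' @export
fit_quality <- function(pIC50, HAC,
                        variant = c("reynolds_polynomial",
                                    "reynolds_exponential", "identity")) {
  variant <- match.arg(variant)
  le_kcal <- 1.37 * ligand_efficiency(pIC50, HAC)
  scale <- switch(variant,
    reynolds_polynomial = 0.0715 + 7.5328 / HAC + 25.7079 / HAC^2 -
      361.4722 / HAC^3,
    reynolds_exponential = 0.873 * exp(-0.026 * HAC),
    identity = rep(1, length(HAC))
  )
  le_kcal / scale
}

#' Efficiency metrics for an activity table
#'
#' @param activity data.frame with columns `ligand_id`, `pIC50`, `HAC`,
#'   `logP` (see [read_activity_table()]).
#' @param fq_variant reference scale passed to [fit_quality()].
#' @param digits display rounding (half-up); `NULL` for full precision.
#' @return the input with columns `LLE`, `LE`, `FQ` and `fq_variant`
#'   appended.
#' @export
efficiency_table <- function(activity, fq_variant = "reynolds_polynomial",
                             digits = 2) {
  req <- c("ligand_id", "pIC50", "HAC", "logP")
  if (!all(req %in% names(activity))) {
    stop("activity table needs columns: ", paste(req, collapse = ", "))
  }
  out <- activity
  out$LLE <- lipophilic_efficiency(activity$pIC50, activity$logP)
  out$LE <- ligand_efficiency(activity$pIC50, activity$HAC)
  out$FQ <- fit_quality(activity$pIC50, activity$HAC, fq_variant)
  if (!is.null(digits)) {
    out$LLE <- round_half_up(out$LLE, digits)
    out$LE <- round_half_up(out$LE, digits)
    out$FQ <- round_half_up(out$FQ, digits)
  }
  out$fq_variant <- fq_variant
  out
}

#' Read a ligand activity table
#'
#' CSV with columns `ligand_id`, `pIC50`, `HAC`, `logP`. The packaged
#' default (`system.file("extdata", "propafenone_activities.csv",
#' package = "sarpose")`) holds the published activities of the five
#' propafenone-type P-gp inhibitors GPV005/019/062/186/366.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_activity_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  act <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("ligand_id", "pIC50", "HAC", "logP")
  if (!all(req %in% names(act))) {
    stop("activity table needs columns: ", paste(req, collapse = ", "))
  }
  if (any(!is.finite(act$pIC50))) stop("non-finite pIC50")
  if (any(act$HAC < 1)) stop("HAC must be >= 1")
  act
}
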