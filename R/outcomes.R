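# Economic endpoints: per-arm totals, incremental cost-effectiveness
# (cost per life-year) and cost-utility (cost per QALY) ratios.

#' Aggregate two cohort traces into incremental economic endpoints
#'
#' Totals are summed over the trial and extrapolation phases;
#' incrementals are intervention minus comparator. The ICER is
#' \code{delta_cost / delta_lys} and the ICUR
#' \code{delta_cost / delta_qalys}. When an increment is zero, or when one
#' strategy dominates (is no more costly and no less effective, or the
#' reverse), the affected ratios are reported as \code{NA} and the
#' dominance flag is set instead of returning a signed, uninterpretable
#' ratio.
#'
#' @param trace_int cohort trace for the intervention arm (e.g. TAC).
#' @param trace_ref cohort trace for the comparator arm (e.g. FAC).
#' @return An object of class \code{cea_result}: per-arm totals,
#'   incremental \code{delta_cost}, \code{delta_lys}, \code{delta_qalys},
#'   \code{icer}, \code{icur} and \code{dominance_flag} in
#'   \code{c("none", "dominant", "dominated")} (relative to the
#'   intervention).
#' @export
compute_ce_result <- function(trace_int, trace_ref) {
  arms <- list(trace_int, trace_ref)
  labels <- vapply(seq_along(arms), function(i) {
    if (!is.null(arms[[i]]$arm)) arms[[i]]$arm else c("int", "ref")[i]
  }, character(1))
  totals <- data.frame(
    arm = labels,
    total_cost = vapply(arms, `[[`, numeric(1), "total_cost"),
    total_lys = vapply(arms, `[[`, numeric(1), "total_lys"),
    total_qalys = vapply(arms, `[[`, numeric(1), "total_qalys")
  )
  dc <- totals$total_cost[1] - totals$total_cost[2]
  dl <- totals$total_lys[1] - totals$total_lys[2]
  dq <- totals$total_qalys[1] - totals$total_qalys[2]

  flag <- "none"
  if (dc <= 0 && dl >= 0 && dq >= 0) {
    flag <- "dominant"
  } else if (dc >= 0 && dl <= 0 && dq <= 0) {
    flag <- "dominated"
  }
  icer <- if (flag == "none" && dl != 0) dc / dl else NA_real_
  icur <- if (flag == "none" && dq != 0) dc / dq else NA_real_

  res <- list(
    totals = totals,
    delta_cost = dc, delta_lys = dl, delta_qalys = dq,
    icer = icer, icur = icur,
    dominance_flag = flag
  )
  class(res) <- "cea_result"
  res
}

fmt_cad <- function(x) {
  ifelse(is.na(x), "NA",
         formatC(round(x, 2), format = "f", digits = 2, big.mark = ","))
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Cost-effectiveness result\n")
  for (i in seq_len(nrow(x$totals))) {
    cat(sprintf("  %-4s cost %14s  LYs %8.4f  QALYs %8.4f\n",
                x$totals$arm[i], fmt_cad(x$totals$total_cost[i]),
                x$totals$total_lys[i], x$totals$total_qalys[i]))
  }
  cat(sprintf("  incremental cost %s, LYs %.4f, QALYs %.4f\n",
              fmt_cad(x$delta_cost), x$delta_lys, x$delta_qalys))
  cat(sprintf("  ICER %s /LY gained; ICUR %s /QALY gained%s\n",
              fmt_cad(x$icer), fmt_cad(x$icur),
              if (x$dominance_flag != "none")
                paste0(" [", x$dominance_flag, "]") else ""))
  invisible(x)
}

#' Tabulate a cost-effectiveness result
#'
#' @param result a \code{cea_result}.
#' @return A \code{data.frame} with per-arm totals followed by an
#'   incremental row carrying the ratios (rounded to 2 decimals).
#' @export
ce_summary_table <- function(result) {
  inc <- data.frame(
    arm = "incremental",
    total_cost = result$delta_cost,
    total_lys = result$delta_lys,
    total_qalys = result$delta_qalys
  )
  out <- rbind(result$totals, inc)
  out$icer <- c(rep(NA_real_, nrow(result$totals)), round(result$icer, 2))
  out$icur <- c(rep(NA_real_, nrow(result$totals)), round(result$icur, 2))
  out$dominance <- c(rep("", nrow(result$totals)), result$dominance_flag)
  out
}
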