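#' Health states of the cohort model
#'
#' The model distributes a cohort of women treated with adjuvant
#' chemotherapy across four mutually exclusive health states:
#' \describe{
#'   \item{no_recurrence}{No disease progression since adjuvant treatment.}
#'   \item{locoregional}{Locoregional recurrence without metastases.}
#'   \item{distant}{Distant (metastatic) recurrence.}
#'   \item{dead}{Absorbing state; death from any cause.}
#' }
#'
#' @return Character vector of the four state keys, in transition-matrix
#'   order (the absorbing state last).
#' @export
#' @examples
#' health_states()
health_states <- function() {
  c("no_recurrence", "locoregional", "distant", "dead")
}

#' Human-readable state labels
#'
#' @param states character vector of state keys (default: all four).
#' @return Named character vector mapping keys to display labels.
#' @export
state_labels <- function(states = health_states()) {
  lab <- c(
    no_recurrence = "No Recurrence",
    locoregional  = "Locoregional Recurrence",
    distant       = "Distant (Metastatic) Recurrence",
    dead          = "Dead"
  )
  unknown <- setdiff(states, names(lab))
  if (length(unknown)) {
    stop("unknown health state(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  lab[states]
}

# non-absorbing states, i.e. those that carry costs and utilities
alive_states <- function() setdiff(health_states(), "dead")
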