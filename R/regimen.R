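#' Dosing events and regimens
#'
#' A regimen is an ordered table of oral dose events (time in hours from
#' simulation start, amount in mg). Repeating patterns expand
#' deterministically; same-time events are summed by the solver, so the input
#' order of simultaneous events never affects a trajectory.
#'
#' @param time Dose times (h from simulation start), >= 0.
#' @param amount Dose amounts (mg), >= 0. Recycled to the length of `time`.
#' @return An object of class `regimen`: a data.frame with columns `time`
#'   and `amount`, sorted by time.
#' @examples
#' regimen_qd(600, days = 7)            # 600 mg once daily for a week
#' regimen_bid(15, days = 3, start = 24) # 15 mg twice daily, days 2-4
#' @export
regimen <- function(time = numeric(0), amount = numeric(0)) {
  if (length(time) == 0L)
    return(structure(data.frame(time = numeric(0), amount = numeric(0)),
                     class = c("regimen", "data.frame")))
  amount <- rep_len(amount, length(time))
  if (any(!is.finite(time)) || any(time < 0))
    stop("regimen: dose times must be finite and >= 0")
  if (any(!is.finite(amount)) || any(amount < 0))
    stop("regimen: dose amounts must be finite and >= 0")
  o <- order(time)
  structure(data.frame(time = time[o], amount = amount[o]),
            class = c("regimen", "data.frame"))
}

#' @rdname regimen
#' @param dose Dose per administration (mg).
#' @param days Number of dosing days.
#' @param start Clock time of the first dose (h).
#' @export
regimen_qd <- function(dose, days, start = 0) {
  stopifnot(days >= 1)
  regimen(start + 24 * (seq_len(days) - 1), dose)
}

#' @rdname regimen
#' @export
regimen_bid <- function(dose, days, start = 0) {
  stopifnot(days >= 1)
  t0 <- start + 24 * (seq_len(days) - 1)
  regimen(c(t0, t0 + 12), dose)
}

#' @rdname regimen
#' @param ... Regimens to concatenate into one event table.
#' @export
regimen_join <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, logical(1), "regimen")))
  regimen(unlist(lapply(parts, `[[`, "time")),
          unlist(lapply(parts, `[[`, "amount")))
}

#' @rdname regimen
#' @param freq `"qd"` or `"bid"`.
#' @export
regimen_pattern <- function(dose, freq = c("qd", "bid"), days, start = 0) {
  freq <- match.arg(freq)
  if (freq == "qd") regimen_qd(dose, days, start)
  else regimen_bid(dose, days, start)
}

#' @export
print.regimen <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("<regimen> no doses\n")
  } else {
    cat(sprintf("<regimen> %d doses, %g-%g mg, t = %g..%g h\n", nrow(x),
                min(x$amount), max(x$amount), min(x$time), max(x$time)))
  }
  invisible(x)
}
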