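#' Simulate a branch-event table
#'
#' Branch initiations per neuron and type (GCB = growth cone bifurcation,
#' IB = interstitial back-branching) are Poisson with the spec rates over
#' the observation window; initiation times are uniform over the window.
#' Each event retracts with the type-specific loss probability; retracted
#' events get a retraction time uniform between initiation and the end of
#' the window and a direction label (anterior with probability
#' `anteriorFractionOfLost`, else posterior).
#'
#' @param spec an [EventTableSpec-class].
#' @return data.frame with columns `neuron_id`, `embryo_id`, `type`
#'   (GCB/IB), `t_init_min`, `retracted` (logical), `t_retract_min`
#'   (NA when not retracted), `direction` (anterior/posterior, NA when not
#'   retracted).
#' @examples
#' ev <- simulateEventTable(eventTableSpec(nNeurons = 5, seed = 4))
#' initiationRate(ev, nNeurons = 5, durationH = 2)
#' @export
simulateEventTable <- function(spec) {
  stopifnot(is(spec, "EventTableSpec"))
  validObject(spec)
  set.seed(spec@seed)
  dur_min <- spec@durationH * 60
  rows <- list()
  for (nid in seq_len(spec@nNeurons)) {
    for (ty in c("GCB", "IB")) {
      rate <- if (ty == "GCB") spec@gcbRatePerH else spec@ibRatePerH
      lossP <- if (ty == "GCB") spec@gcbLossProb else spec@ibLossProb
      k <- stats::rpois(1, rate * spec@durationH)
      if (k == 0) next
      t0 <- sort(stats::runif(k, 0, dur_min))
      retr <- stats::runif(k) < lossP
      tr <- rep(NA_real_, k)
      tr[retr] <- t0[retr] + stats::runif(sum(retr), 0, dur_min - t0[retr])
      dirn <- rep(NA_character_, k)
      dirn[retr] <- ifelse(stats::runif(sum(retr)) <
                             spec@anteriorFractionOfLost,
                           "anterior", "posterior")
      rows[[length(rows) + 1L]] <- data.frame(
        neuron_id = nid, embryo_id = (nid - 1L) %/% 4L + 1L, type = ty,
        t_init_min = t0, retracted = retr, t_retract_min = tr,
        direction = dirn)
    }
  }
  if (!length(rows))
    return(data.frame(neuron_id = integer(), embryo_id = integer(),
                      type = character(), t_init_min = numeric(),
                      retracted = logical(), t_retract_min = numeric(),
                      direction = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
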