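# Transition state theory rate constants assembled from log-scale
# partition functions: log k = ln(kB T/h) + log Q_TS - log Q_R - Ea/(kB T).
# The transmission coefficient is fixed at 1.

.ea_to_joule <- function(ea, unit = c("J", "hartree", "kJ_per_mol")) {
  unit <- match.arg(unit)
  switch(unit,
         J = ea,
         hartree = ea * .pc$hartree,
         kJ_per_mol = ea * 1000 / .pc$NA_avog)
}

#' TST rate constant (log scale)
#'
#' Assembles the unimolecular transition-state-theory rate constant from
#' the transition-state and reactant log partition functions and the
#' activation energy (the TS - reactant ground-state energy difference).
#' Any common additive shift of the two log Q inputs cancels exactly, so
#' the translational volume convention does not affect the rate.
#'
#' @param log_q_ts,log_q_r natural-log partition functions of transition
#'   state and reactant (ZPE included in Q_vib).
#' @param ea activation energy in the declared unit; no silent unit
#'   guessing.
#' @param state a `qest_thermo`.
#' @param ea_unit `"J"` (per molecule), `"hartree"` or `"kJ_per_mol"`.
#' @return an object of class `qest_rate` with `log_k` (k in 1/s),
#'   `temperature`, `log_prefactor` = ln[(kB T/h) Q_TS/Q_R] and
#'   `arrhenius_term` = -beta*Ea; `log_k == log_prefactor + arrhenius_term`
#'   exactly.
#' @export
tst_log_rate <- function(log_q_ts, log_q_r, ea, state,
                         ea_unit = c("J", "hartree", "kJ_per_mol")) {
  stopifnot(inherits(state, "qest_thermo"))
  if (!all(is.finite(c(log_q_ts, log_q_r, ea)))) {
    stop("log partition functions and activation energy must be finite")
  }
  ea_j <- .ea_to_joule(ea, match.arg(ea_unit))
  log_prefactor <- log(.pc$kB * state$temperature / .pc$h) + log_q_ts - log_q_r
  arrhenius_term <- -state$beta * ea_j
  res <- list(log_k = log_prefactor + arrhenius_term,
              temperature = state$temperature,
              log_prefactor = log_prefactor,
              arrhenius_term = arrhenius_term)
  class(res) <- "qest_rate"
  res
}

#' @export
print.qest_rate <- function(x, ...) {
  cat(sprintf("<qest_rate @ %.1f K> log k = %.4f (k = %.4e 1/s)\n",
              x$temperature, x$log_k, exp(x$log_k)))
  invisible(x)
}

#' Log prefactor ratio log(Q_TS/Q_R)
#'
#' The partition-function part of the TST prefactor; with a null model
#' applied to both species the ratio is 1 (log ratio 0), the classical
#' "ratio of partition functions equals one" assumption.
#'
#' @param log_q_ts,log_q_r log partition functions.
#' @return `log_q_ts - log_q_r`.
#' @export
log_prefactor_ratio <- function(log_q_ts, log_q_r) {
  log_q_ts - log_q_r
}

#' TST rate table over a temperature grid
#'
#' @param reaction a `qest_reaction`.
#' @param temperatures numeric vector of temperatures, K.
#' @param log_q_source function(structure, T_K) returning log Q; defaults
#'   to the computed RRHO value.  Supplying a trained estimator's predictor
#'   swaps in machine-learned partition functions.
#' @param standard_pressure Pa.
#' @return data.frame with columns `T_K`, `log_k`, `log_prefactor`.
#' @export
tst_rate_table <- function(reaction, temperatures,
                           log_q_source = NULL, standard_pressure = 1e5) {
  stopifnot(inherits(reaction, "qest_reaction"))
  if (is.null(log_q_source)) {
    terms_r <- .pf_terms(reaction$reactant)
    terms_ts <- .pf_terms(reaction$ts)
    log_q_source <- function(s, T_K) {
      terms <- if (identical(s$id, reaction$ts$id)) terms_ts else terms_r
      .pf_eval(terms, thermo_state(T_K, standard_pressure))$log_q_total
    }
  }
  rows <- lapply(temperatures, function(T_K) {
    st <- thermo_state(T_K, standard_pressure)
    r <- tst_log_rate(log_q_source(reaction$ts, T_K),
                      log_q_source(reaction$reactant, T_K),
                      reaction$ea, st, ea_unit = "hartree")
    data.frame(T_K = T_K, log_k = r$log_k, log_prefactor = r$log_prefactor)
  })
  do.call(rbind, rows)
}
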