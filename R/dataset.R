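# Dataset construction: per-reaction temperature sampling uniform in 1/T,
# partition-function table assembly, and outlier filtering.

#' Sample temperatures uniformly in inverse temperature
#'
#' Draws u ~ Uniform(1/t_max, 1/t_min) and returns T = 1/u, so the sample
#' is uniform in 1/T over the configured range -- the convention used to
#' cover low temperatures densely when building the training dataset.
#'
#' @param n number of draws.
#' @param t_min,t_max temperature range bounds, K (default 50 and 2000).
#' @param seed optional integer; when given, draws are taken under this
#'   seed without disturbing the caller's RNG stream, so each reaction can
#'   receive its own reproducible set.
#' @return numeric vector of temperatures in (t_min, t_max).
#' @export
sample_temperatures <- function(n, t_min = 50, t_max = 2000, seed = NULL) {
  if (!(t_min > 0 && t_min < t_max)) stop("need 0 < t_min < t_max")
  if (n < 1) stop("n must be >= 1")
  .with_seed(seed, 1 / stats::runif(n, 1 / t_max, 1 / t_min))
}

#' Count distinct structures across reactions
#'
#' @param reactions list of `qest_reaction`.
#' @return number of distinct structure ids over all reactant/TS/product
#'   entries.
#' @export
count_structures <- function(reactions) {
  ids <- unlist(lapply(reactions, function(r) {
    c(r$reactant$id, r$ts$id, r$product$id)
  }))
  length(unique(ids))
}

#' Build the partition-function dataset
#'
#' For every reaction: sample (or reuse) the per-reaction temperature set,
#' then evaluate log Q for the reactant, transition state and product at
#' each temperature.  One row per (structure, temperature) pair.  A
#' reaction whose structures fail validation is skipped with a message;
#' skipped ids are attached as the `"skipped"` attribute.
#'
#' @param reactions list of `qest_reaction`.
#' @param n_temps temperatures per reaction (default 50) when the record
#'   carries none.
#' @param seed master seed; per-reaction seeds are fanned out by stable
#'   hashing of the reaction id, giving each reaction a unique set.
#' @param t_min,t_max temperature range, K.
#' @param standard_pressure Pa, translational volume convention.
#' @param ... tolerances forwarded to [total_log_q()].
#' @return data.frame with columns `structure_id`, `reaction_id`, `role`,
#'   `inv_T_K`, `log_q`.
#' @export
build_q_dataset <- function(reactions, n_temps = 50, seed = 1,
                            t_min = 50, t_max = 2000,
                            standard_pressure = 1e5, ...) {
  out <- vector("list", length(reactions))
  skipped <- character(0)
  for (i in seq_along(reactions)) {
    r <- reactions[[i]]
    temps <- if (length(r$temperatures) > 0) r$temperatures else {
      sample_temperatures(n_temps, t_min, t_max,
                          seed = .fanout_seed(seed, r$reaction_id))
    }
    rows <- tryCatch({
      recs <- list(r$reactant, r$ts, r$product)
      terms <- lapply(recs, .pf_terms, ...)
      do.call(rbind, lapply(seq_along(recs), function(k) {
        lq <- vapply(temps, function(T_K) {
          .pf_eval(terms[[k]], thermo_state(T_K, standard_pressure))$log_q_total
        }, numeric(1))
        data.frame(structure_id = recs[[k]]$id,
                   reaction_id = r$reaction_id,
                   role = recs[[k]]$role,
                   inv_T_K = 1 / temps, log_q = lq)
      }))
    }, error = function(e) {
      skipped <<- c(skipped, r$reaction_id)
      message("skipping reaction ", r$reaction_id, ": ", conditionMessage(e))
      NULL
    })
    out[[i]] <- rows
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(structure_id = character(0), reaction_id = character(0),
                      role = character(0), inv_T_K = numeric(0),
                      log_q = numeric(0))
  }
  rownames(res) <- NULL
  if (length(skipped) > 0) {
    message(length(skipped), " reaction(s) skipped")
  }
  attr(res, "skipped") <- skipped
  res
}

#' Drop log Q outliers by quantile envelope
#'
#' Removes rows whose log Q falls outside the [lower_q, upper_q] quantile
#' envelope of the reference set (the development rows, to avoid peeking
#' at the hold-out; defaults to the rows themselves).  The removal report
#' per role is attached as the `"outlier_report"` attribute.
#'
#' @param rows dataset rows from [build_q_dataset()].
#' @param lower_q,upper_q quantiles in `[0, 1]`, `lower_q < upper_q`
#'   (defaults 0.0005 and 0.9995).
#' @param reference rows on which the envelope is computed.
#' @return the filtered rows.
#' @export
drop_outliers <- function(rows, lower_q = 0.0005, upper_q = 0.9995,
                          reference = rows) {
  if (!(lower_q >= 0 && upper_q <= 1 && lower_q < upper_q)) {
    stop("need 0 <= lower_q < upper_q <= 1")
  }
  env <- stats::quantile(reference$log_q, c(lower_q, upper_q), names = FALSE)
  keep <- rows$log_q >= env[1] & rows$log_q <= env[2]
  removed <- rows[!keep, , drop = FALSE]
  roles <- sort(unique(rows$role))
  report <- data.frame(role = roles,
                       removed = vapply(roles, function(rr) {
                         sum(removed$role == rr)
                       }, numeric(1)), row.names = NULL)
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "outlier_report") <- report
  attr(out, "envelope") <- env
  out
}
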