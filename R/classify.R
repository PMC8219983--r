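#' Classify a stem-loop from its poly(U) features
#'
#' Rule set distinguishing stabilizer (SSL), stabilizer-and-terminator
#' (STSL) and terminator (TSL) stem-loops from the downstream-window U
#' features:
#' * TSL: poly(U) tail >= 4 and U content >= 7 and a downstream tail
#'   (all three);
#' * SSL: U content <= 5 and poly(U) tail <= 3 (both);
#' * STSL: a discontinuous tail, an upstream tail, or U content > 5 (any).
#'
#' Rules are evaluated in the order TSL, SSL, STSL; anything matching none
#' is `unclassified`. With `stsl_priority = TRUE` (the default) an upstream
#' or discontinuous tail forces STSL even when the SSL numeric bounds hold,
#' since such tails mark partial terminator character.
#'
#' @param polyU_len longest U run in the 10-nt downstream window.
#' @param U_content total U count in the window.
#' @param tail_position `"downstream"`, `"upstream"`, `"discontinuous"` or
#'   `"none"` (see [u_features()]).
#' @param stsl_priority let an upstream/discontinuous tail override the SSL
#'   numeric rules.
#' @return list with `label` and `rule_trace` (ordered record of the rules
#'   evaluated and their outcomes).
#' @export
classify_sl <- function(polyU_len, U_content, tail_position,
                        stsl_priority = TRUE) {
  trace <- character(0)
  note <- function(rule, hit) {
    trace <<- c(trace, paste0(rule, ": ", if (hit) "yes" else "no"))
    hit
  }
  tsl <- note("TSL polyU>=4", polyU_len >= 4) &
    note("TSL U_content>=7", U_content >= 7) &
    note("TSL downstream tail", tail_position == "downstream")
  if (tsl) return(list(label = "TSL", rule_trace = trace))
  if (stsl_priority &&
      note("STSL-priority upstream/discontinuous tail",
           tail_position %in% c("upstream", "discontinuous")))
    return(list(label = "STSL", rule_trace = trace))
  ssl <- note("SSL U_content<=5", U_content <= 5) &
    note("SSL polyU<=3", polyU_len <= 3)
  if (ssl) return(list(label = "SSL", rule_trace = trace))
  stsl <- note("STSL discontinuous tail", tail_position == "discontinuous") |
    note("STSL upstream tail", tail_position == "upstream") |
    note("STSL U_content>5", U_content > 5)
  if (stsl) return(list(label = "STSL", rule_trace = trace))
  list(label = "unclassified", rule_trace = trace)
}

#' Classify every stem-loop in a table
#'
#' @param sls stem-loop data.frame with `polyU_len`, `U_content`,
#'   `tail_position` columns (see [u_features()]).
#' @inheritParams classify_sl
#' @return `sls` with a `class` column appended.
#' @export
classify_sls <- function(sls, stsl_priority = TRUE) {
  sls$class <- vapply(seq_len(nrow(sls)), function(i) {
    classify_sl(sls$polyU_len[i], sls$U_content[i], sls$tail_position[i],
                stsl_priority = stsl_priority)$label
  }, "")
  sls
}
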