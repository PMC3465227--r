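#' Health states of the renal replacement therapy model
#'
#' The model follows a closed cohort across six states: maintenance
#' hemodialysis (HD), peritoneal dialysis (PD), functioning kidney transplant
#' (Tx), late-referral hemodialysis (LRHD), late-referral peritoneal dialysis
#' (LRPD) and death (D). D is absorbing.
#'
#' @return Character vector of the six state labels, in canonical order.
#' @export
#' @examples
#' rrt_states()
rrt_states <- function() c("HD", "PD", "Tx", "LRHD", "LRPD", "D")

#' @rdname rrt_states
#' @export
rrt_alive_states <- function() c("HD", "PD", "Tx", "LRHD", "LRPD")

# per-cycle discount factors (1 + r)^-t for t = 0..horizon
discount_factors <- function(rate, horizon) {
  stopifnot(rate >= 0, horizon >= 1)
  (1 + rate)^-(0:horizon)
}

# rolling polynomial hash over the serialized object; short stable
# provenance fingerprint (not cryptographic)
object_fingerprint <- function(x) {
  bytes <- as.integer(serialize(x, connection = NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b + 1) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# derive a per-stage RNG seed from the master seed; fixed offsets per stage so
# adding a stage never perturbs another stage's draws
stage_seed <- function(seed, stage) {
  offsets <- c(psa = 101L, base_transitions = 211L, components = 307L,
               acceptance = 401L)
  if (!stage %in% names(offsets)) stop("unknown RNG stage: ", stage)
  as.integer((as.numeric(seed) * 7919 + offsets[[stage]]) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
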