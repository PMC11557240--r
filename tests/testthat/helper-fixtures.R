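# shared fixtures: all built in code, nothing read from disk

# the package's reference co-ageing condition (C_A = 0.015 vs 0)
ref_params <- function(C_A = 0.015) default_coageing_params(C_A)

# a fresh node-state tibble with an explicit dysfunctional set
make_state <- function(n, dead = integer(0), cause = "intrinsic") {
  st <- tibble::tibble(
    node = seq_len(n) - 1L,
    status = "functional",
    cause = "none"
  )
  if (length(dead)) {
    idx <- dead + 1L
    st$status[idx] <- "dysfunctional"
    st$cause[idx] <- rep_len(cause, length(dead))
  }
  st
}

state_of <- function(state, nodes) {
  state$status[match(nodes, state$node)]
}

cause_of <- function(state, nodes) {
  state$cause[match(nodes, state$node)]
}
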