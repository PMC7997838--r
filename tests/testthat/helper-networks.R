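# Small hand-built networks used across the tests.

# Linear chain A -> B (-> sink if sink_on_b), both first-order.
chain_network <- function(kA = 1e-3, kB = 1e-3, sink_on_b = FALSE) {
  cp <- tibble::tibble(
    compound = c("A", "B"), class = "other",
    measurable = TRUE, initial = c(100, 0)
  )
  rx <- tibble::tibble(
    substrate = if (sink_on_b) c("A", "B") else "A",
    product = if (sink_on_b) c("B", NA) else "B",
    law = "first_order",
    k = if (sink_on_b) c(kA, kB) else kA
  )
  aromatic_network(cp, rx)
}

# Single-compound first-order decay, for closed-form comparisons.
decay_network <- function(k, s0 = 100) {
  aromatic_network(
    tibble::tibble(compound = "A", class = "other", measurable = TRUE,
                   initial = s0),
    tibble::tibble(substrate = "A", product = NA_character_,
                   law = "first_order", k = k)
  )
}

# Sink-free variant of a shipped case network: terminal consumption
# reactions removed so total molar concentration is conserved.
sink_free_case <- function(case_id) {
  net <- case_network(case_id)
  net$reactions <- net$reactions[!is.na(net$reactions$product), ]
  net$free_parameters <-
    net$free_parameters[net$free_parameters$substrate %in% net$reactions$substrate, ]
  net
}
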