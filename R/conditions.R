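# Classed error conditions so callers can distinguish failure modes
# programmatically (tests match on the class, not the message).

stop_diffnetx <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "diffnetx_error"), call = call))
}

# Field separator for canonical edge keys; never appears in trimmed identifiers.
.KEYSEP <- "\x1f"

#' Canonical undirected edge key
#'
#' Builds an order-independent key for an endpoint pair, used to deduplicate
#' and intersect edge sets.
#'
#' @param a,b Character vectors of endpoint identifiers (recycled).
#' @return Character vector of keys.
#' @keywords internal
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = .KEYSEP)
}

key_to_pair <- function(key) {
  do.call(rbind, strsplit(key, .KEYSEP, fixed = TRUE))
}
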