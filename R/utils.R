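# internal error helpers and small utilities

abort_indeterminate <- function(where) {
  abort(
    paste0("indeterminate level: not-testable (NT) score at or rostral to ",
           "the candidate level (", where, ")"),
    class = "vmscore_error_indeterminate"
  )
}

abort_config <- function(msg) {
  abort(msg, class = "vmscore_error_config")
}

abort_validation <- function(msg) {
  abort(msg, class = "vmscore_error_validation")
}

# cheap deterministic string hash used to stamp output files with the
# configuration they came from (provenance only, not cryptographic)
string_hash <- function(s) {
  b <- utf8ToInt(paste(s, collapse = "\x1f"))
  h <- 7
  m <- 2147483647
  for (x in b) h <- (h * 31 + x) %% m
  sprintf("%08x", h)
}

# draw one value from 0..(k-1) with probabilities p (stats::sample wrapper
# kept separate so every random draw in the generator is easy to audit)
draw_int <- function(values, prob, n = 1L) {
  if (length(values) == 1L) return(rep(values, n))
  sample(values, size = n, replace = TRUE, prob = prob)
}

check_prob_vector <- function(p, what, tol = 1e-9) {
  if (any(p < 0)) abort_config(paste0(what, " contains negative probabilities"))
  if (abs(sum(p) - 1) > tol) {
    abort_config(paste0(what, " must sum to 1 (got ", format(sum(p)), ")"))
  }
  invisible(p)
}
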