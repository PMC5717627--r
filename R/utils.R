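# Internal helpers shared across modules.

# Classed conditions so callers can distinguish user errors (bad input,
# bad geometry) from numerical failures without parsing messages.
dl_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "dl_error")))
}

is_uniform_grid <- function(times, rel_tol = 1e-6) {
  if (length(times) < 2) return(FALSE)
  dt <- diff(times)
  m <- mean(dt)
  m > 0 && all(abs(dt - m) <= rel_tol * m)
}

# Recursive list merge: values in `user` override `defaults`.
merge_config <- function(defaults, user) {
  if (is.null(user)) return(defaults)
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(defaults[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}
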