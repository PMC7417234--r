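#' Inverse logit (expit)
#'
#' Maps a value on the log-odds scale to a probability. Stable for large
#' negative and positive inputs.
#'
#' @param x numeric vector on the logit scale.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
inv_logit <- function(x) {
  p <- ifelse(x >= 0, 1 / (1 + exp(-x)), exp(x) / (1 + exp(x)))
  p
}

#' Logit
#'
#' @param p probabilities in (0, 1).
#' @return log-odds.
#' @export
logit <- function(p) log(p / (1 - p))

# log(sum(exp(x))) without overflow; returns -Inf for empty/all -Inf input
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Structured log line to stderr: "[LEVEL] timestamp module: msg"
ua_log <- function(level, module, ...) {
  message(sprintf("[%s] %s %s: %s", level,
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), module,
                  paste0(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
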