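# internal helpers shared across the package

# classed errors so callers/tests can distinguish contract violations
stop_emg <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "emgnarx_error", "error"),
                      call = call))
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    abs(x - round(x)) < .Machine$double.eps^0.5
}

as_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1)
  storage.mode(x) <- "double"
  x
}

# population (biased) variance, the convention used throughout
pop_var <- function(x) mean((x - mean(x))^2)
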