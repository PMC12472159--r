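# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fundus <- function(msg, class) {
  stop(structure(
    class = c(class, "fundusXAI_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Run `expr` with a deterministic RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

assert_binary_matrix <- function(m, what = "mask") {
  if (!is.matrix(m) || !all(m %in% c(0, 1))) {
    stop_fundus(sprintf("%s must be a 0/1 matrix", what), "fundusXAI_input_error")
  }
  invisible(TRUE)
}

# Simple leveled logger; level controlled by option fundusXAI.log_level
# (one of "debug", "info", "warn", "quiet").
fx_log <- function(level = c("info", "debug", "warn"), fmt, ...) {
  level <- match.arg(level)
  threshold <- getOption("fundusXAI.log_level", "warn")
  ranks <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  if (ranks[[level]] >= ranks[[threshold]]) {
    message(sprintf("[fundusXAI %s] %s", level, sprintf(fmt, ...)))
  }
  invisible(NULL)
}
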