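# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Classed conditions so the command-line wrapper can map errors to exit codes.
usage_error <- function(msg) {
  stop(structure(
    class = c("ligmodes_usage_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

parse_error <- function(msg) {
  stop(structure(
    class = c("ligmodes_parse_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

numeric_error <- function(msg) {
  stop(structure(
    class = c("ligmodes_numeric_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Fixed-precision JSON writer so reruns with identical inputs are
# byte-identical.
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(path)
}

# Squared euclidean distances between one point and the rows of a matrix.
dist2_point <- function(points, p) {
  (points[, 1] - p[1])^2 + (points[, 2] - p[2])^2 + (points[, 3] - p[3])^2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
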