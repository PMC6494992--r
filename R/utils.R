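#' @importFrom rlang abort warn .data
#' @importFrom stats rnorm runif
NULL

# Classed conditions so callers (and the CLI) can map failures to exit codes.
stop_validation <- function(msg, ...) abort(sprintf(msg, ...), class = "ecggan_error_validation")
stop_io         <- function(msg, ...) abort(sprintf(msg, ...), class = "ecggan_error_io")
stop_format     <- function(msg, ...) abort(sprintf(msg, ...), class = "ecggan_error_format")
stop_shape      <- function(msg, ...) abort(sprintf(msg, ...), class = "ecggan_error_shape")
stop_domain     <- function(msg, ...) abort(sprintf(msg, ...), class = "ecggan_error_domain")
stop_index      <- function(msg, ...) abort(sprintf(msg, ...), class = "ecggan_error_index")

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x) && x >= min
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_count <- function(x, name, min = 1L) {
  if (!is_count(x, min)) {
    stop_validation("`%s` must be a single integer >= %d (got %s)", name, min,
                    paste(format(x), collapse = ","))
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is_number(x) || x < min || x > max || (strict_min && x <= min)) {
    stop_validation("`%s` must be a finite number in [%s, %s]%s (got %s)",
                    name, format(min), format(max),
                    if (strict_min) " (exclusive lower bound)" else "",
                    paste(format(x), collapse = ","))
  }
  as.numeric(x)
}

# Evaluate `code` with a temporary RNG state; the caller's stream is untouched.
# `seed = NULL` runs in the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Coerce the accepted window representations (sequence_windows tibble with a
# `values` list-column, plain matrix, or list of equal-length numeric vectors)
# to an n_windows x length numeric matrix.
as_window_matrix <- function(data) {
  if (is.matrix(data)) {
    storage.mode(data) <- "double"
    return(data)
  }
  if (is.data.frame(data)) {
    if (!"values" %in% names(data)) {
      stop_validation("window data frame must have a `values` list-column")
    }
    data <- data$values
  }
  if (is.numeric(data)) data <- list(data)
  if (!is.list(data) || length(data) == 0L) {
    stop_validation("windows must be a matrix, a sequence_windows tibble, or a list of numeric vectors")
  }
  lens <- lengths(data)
  if (length(unique(lens)) != 1L) {
    stop_validation("all windows must have equal length (got lengths %s)",
                    paste(unique(lens), collapse = ", "))
  }
  do.call(rbind, lapply(data, as.numeric))
}

matrix_to_windows <- function(mat, record_ids = NULL, start_index = NULL) {
  n <- nrow(mat)
  tibble::tibble(
    source_record = record_ids %||% rep("", n),
    start_index = start_index %||% rep(0L, n),
    length = rep(ncol(mat), n),
    values = lapply(seq_len(n), function(i) mat[i, ])
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
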